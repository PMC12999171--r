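# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators are deterministic
# without clobbering the session RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  force(code)
}

# Derive `n` well-level seeds from one plate-level seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A window of `w` seconds at `rate` Hz spans floor(w * rate) frames.
window_frames <- function(w, rate) {
  as.integer(floor(w * rate))
}

stop_ss <- function(...) stop(..., call. = FALSE)

#' Pulse rate implied by an inter-pulse interval
#'
#' Converts the interval between successive field-stimulation pulses into the
#' pulse delivery rate. An interval of 12 ms between pulses corresponds to a
#' train rate of about 83 Hz.
#'
#' @param interval_s Inter-pulse interval in seconds (> 0).
#' @return Pulse rate in Hz.
#' @examples
#' pulse_rate(0.012)
#' @export
pulse_rate <- function(interval_s) {
  if (!is.numeric(interval_s) || any(interval_s <= 0)) {
    stop_ss("`interval_s` must be a positive inter-pulse interval in seconds")
  }
  1 / interval_s
}
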