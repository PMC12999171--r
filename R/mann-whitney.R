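#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Rank-sum test used throughout the screen to compare pre- and
#' post-stimulation intensity samples. For small samples (both sizes at most
#' `exact_max`) the null distribution of U is obtained by complete
#' enumeration of all assignments of the pooled (mid)ranks, which is exact
#' even in the presence of ties. Larger samples use the normal approximation
#' with midranks, tie-corrected variance and a continuity correction.
#'
#' The degenerate case in which every pooled observation is identical carries
#' no evidence either way and returns p = 1 with `degenerate = TRUE`.
#'
#' @param sample_a,sample_b Numeric vectors, both non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` (a tends larger)
#'   or `"less"`.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the enumeration path;
#'   `NULL` (default) selects it when both samples have at most `exact_max`
#'   observations.
#' @param exact_max Sample-size limit for the automatic exact path.
#' @return A list of class `mw_test` with elements `statistic` (U for
#'   `sample_a`), `p.value`, `method`, `alternative` and `degenerate`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.1 by enumeration
#' @export
mann_whitney_u <- function(sample_a, sample_b,
                           alternative = c("two.sided", "greater", "less"),
                           exact = NULL, exact_max = 10L) {
  alternative <- match.arg(alternative)
  a <- as.numeric(sample_a)
  b <- as.numeric(sample_b)
  if (length(a) == 0L || length(b) == 0L) {
    stop_ss("both samples must be non-empty")
  }
  if (anyNA(a) || anyNA(b)) stop_ss("samples must not contain NA")
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (diff(range(pooled)) == 0) {
    return(structure(
      list(statistic = u, p.value = 1, method = "degenerate (all ties)",
           alternative = alternative, degenerate = TRUE),
      class = "mw_test"))
  }

  use_exact <- exact %||% (n1 <= exact_max && n2 <= exact_max)
  if (use_exact) {
    p <- mw_exact_p(r, n1, u, alternative)
    method <- "exact enumeration"
  } else {
    p <- mw_approx_p(u, r, n1, n2, alternative)
    method <- "normal approximation (tie-corrected, continuity-corrected)"
  }
  structure(
    list(statistic = u, p.value = p, method = method,
         alternative = alternative, degenerate = FALSE),
    class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, ")\n", sep = "")
  cat("U =", format(x$statistic), "  p =", format(x$p.value),
      " (", x$alternative, ")\n")
  if (x$degenerate) cat("note: degenerate pooled sample (all tied)\n")
  invisible(x)
}

# Exact permutation null of U over all choose(n1+n2, n1) assignments of the
# pooled midranks. Handles ties because midranks are permuted as observed.
mw_exact_p <- function(r, n1, u, alternative) {
  n <- length(r)
  idx <- utils::combn(n, n1)
  us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  p_le <- mean(us <= u + eps)
  p_ge <- mean(us >= u - eps)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater   = p_ge,
         less      = p_le)
}

# Normal approximation with midranks, tie-corrected variance and a 0.5
# continuity correction toward the mean.
mw_approx_p <- function(u, r, n1, n2, alternative) {
  n <- n1 + n2
  ties <- rle(sort(r))$lengths
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  sigma <- sqrt(sigma2)
  z2 <- (u - mu - sign(u - mu) * 0.5) / sigma
  switch(alternative,
         two.sided = min(1, 2 * stats::pnorm(-abs(z2))),
         greater   = stats::pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE),
         less      = stats::pnorm((u - mu + 0.5) / sigma))
}

# Vectorized two-sided Mann-Whitney p-values across the rows of a matrix:
# the first n1 columns of X are the pre-stimulus sample, the rest the
# post-stimulus sample. Used per pixel; normal approximation with midranks,
# tie correction and continuity correction. Degenerate rows return p = 1.
mw_p_rows <- function(X, n1) {
  n <- ncol(X)
  n2 <- n - n1
  stopifnot(n2 >= 1L, n1 >= 1L)
  stats_uv <- apply(X, 1L, function(x) {
    r <- rank(x)
    c(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2,
      sum(rle(sort(r))$lengths^3) - n)
  })
  u <- stats_uv[1L, ]
  tie_term <- stats_uv[2L, ]
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  p <- rep(1, length(u))
  ok <- sigma2 > 0
  z <- (u[ok] - mu - sign(u[ok] - mu) * 0.5) / sqrt(sigma2[ok])
  p[ok] <- pmin(1, 2 * stats::pnorm(-abs(z)))
  p
}
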