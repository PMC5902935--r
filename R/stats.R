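#' @title Exact and multiplicity statistics
#' @name stats-core
#' @description Self-contained implementations of the exact and
#'   multiple-testing statistics used throughout the workflow: a two-sided
#'   Fisher exact test for 2x2 tables (minimum-likelihood convention),
#'   Benjamini-Hochberg and Bonferroni adjustment, and the Pearson
#'   product-moment correlation.
NULL

#' Two-sided Fisher exact test for a 2x2 contingency table
#'
#' Computes the two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric point probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table (within
#' a small relative tolerance, the convention of mainstream
#' implementations). Factorials are evaluated in log space so totals up to
#' at least 1e5 are handled without overflow.
#'
#' The cells follow the DEG/Alu crosstab layout: `a` = DEGs with Alu
#' insertion, `b` = DEGs without, `c` = non-DEGs with, `d` = non-DEGs
#' without -- but any 2x2 count table is accepted.
#'
#' @param a,b,c,d Non-negative integer cell counts. Alternatively `a` may be
#'   a length-4 vector `c(a, b, c, d)` or a 2x2 matrix (filled row-wise as
#'   `a`, `b` / `c`, `d`).
#' @param rel_tol Relative tolerance used when comparing point
#'   probabilities to the observed table's probability. Default `1e-7`.
#' @return The two-sided p-value in `[0, 1]`. Any zero margin yields `p = 1`
#'   (no association is testable).
#' @examples
#' fisher_exact_two_sided(1, 1, 1, 1) # 1
#' fisher_exact_two_sided(3, 1, 1, 3) # 0.4857143
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL,
                                   rel_tol = 1e-7) {
  if (is.null(b)) {
    x <- as.vector(t(a))
    if (length(x) != 4L) stop("expected 4 cell counts")
    a <- x[1L]; b <- x[2L]; c <- x[3L]; d <- x[4L]
  }
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("cell counts must be finite and non-negative")
  }
  if (any(abs(cells - round(cells)) > 1e-8)) {
    stop("cell counts must be integers")
  }
  cells <- round(cells)
  a <- cells[1L]; b <- cells[2L]; c <- cells[3L]; d <- cells[4L]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  n <- r1 + r2
  if (n == 0L) stop("table is empty (N = 0)")
  if (min(r1, r2, c1, c2) == 0L) return(1)

  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  aa <- lo:hi
  logp <- lchoose(r1, aa) + lchoose(r2, c1 - aa) - lchoose(n, c1)
  log_obs <- logp[aa == a]
  p <- sum(exp(logp[logp <= log_obs + log1p(rel_tol)]))
  p <- min(1, p)
  if (1 - p < 1e-12) p <- 1 # absorb summation round-off at the boundary
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR-adjusted p-values: with `p` sorted ascending and `m`
#' hypotheses, `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, returned in the
#' input order. Ties are broken by stable input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order; `numeric(0)` for empty
#'   input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  check_pvalues(p)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` with `m = length(p)`.
#'
#' @inheritParams bh_adjust
#' @return Adjusted p-values in the input order.
#' @export
bonferroni_adjust <- function(p) {
  check_pvalues(p)
  pmin(1, p * length(p))
}

check_pvalues <- function(p) {
  if (length(p) && (any(!is.finite(p)) || any(p < 0) || any(p > 1))) {
    stop("p-values must be finite and in [0, 1]")
  }
  invisible(p)
}

#' Pearson product-moment correlation
#'
#' @param x,y Finite numeric vectors of equal length >= 3.
#' @return The correlation coefficient in `[-1, 1]`; if either vector has
#'   zero variance the result is undefined and `NA_real_` is returned with a
#'   warning.
#' @examples
#' pearson_r(1:5, 2 * (1:5) + 1) # 1
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  dx <- x - mean(x)
  dy <- y - mean(y)
  ssx <- sum(dx^2)
  ssy <- sum(dy^2)
  if (ssx == 0 || ssy == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  r <- sum(dx * dy) / sqrt(ssx * ssy)
  max(-1, min(1, r))
}
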