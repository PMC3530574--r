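#' Bonferroni correction of a p-value
#'
#' `p_corr = min(1, p * m)` for `m` tests.
#'
#' @param p p-value(s) in \[0, 1\].
#' @param m number of tests (>= 1).
#' @return adjusted p-value(s), capped at 1.
#' @examples
#' bonferroni_adjust(7.8e-8, 638845)
#' @export
bonferroni_adjust <- function(p, m) {
  stop_if_not_prob(p[!is.na(p)], "p")
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  pmin(1, p * m)
}

#' Per-test Bonferroni significance threshold
#'
#' The observed p-value required for family-wise significance at level
#' `alpha` over `m` tests: `alpha / m`.
#'
#' @param alpha family-wise error level.
#' @param m number of tests (>= 1).
#' @return per-test threshold.
#' @examples
#' bonferroni_threshold(0.05, 638845)
#' @export
bonferroni_threshold <- function(alpha, m) {
  stop_if_not_prob(alpha, "alpha")
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Linear step-up: with p-values sorted ascending, the raw adjusted value at
#' rank `i` is `(m / i) * p_(i)`; values that do not monotonically increase
#' are replaced with the smallest adjusted value at any higher rank, capped
#' at 1, and mapped back to the input order. `NA` entries stay `NA` and do
#' not count toward `m`.
#'
#' @param p vector of p-values.
#' @return adjusted p-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03))
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  stop_if_not_prob(pv, "p")
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv)
  raw <- (m / seq_len(m)) * pv[o]
  adj <- rev(cummin(rev(raw)))
  adj <- pmin(1, adj)
  res <- numeric(m)
  res[o] <- adj
  out[ok] <- res
  out
}

#' Add multiple-testing columns to an association scan
#'
#' Appends `p_bonf` (Bonferroni) and `p_fdr` (Benjamini-Hochberg) columns.
#' The test count `m` is the number of retained (post-filter, non-missing)
#' tests in the scan and is recorded as an attribute and column so every
#' output states which denominator was used.
#'
#' @param records a [run_scan()] data.frame.
#' @param m optional explicit test count overriding the default.
#' @return `records` with `p_bonf`, `p_fdr` and `m` columns;
#'   `attr(, "m")` set.
#' @export
adjust_scan <- function(records, m = NULL) {
  m <- m %||% sum(!is.na(records$p))
  records$p_bonf <- bonferroni_adjust(records$p, max(1, m))
  records$p_fdr <- bh_adjust(records$p)
  records$m <- m
  attr(records, "m") <- m
  records
}
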