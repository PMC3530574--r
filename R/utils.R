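# Internal helpers shared across modules.

clip01 <- function(x) {
  # keeps dims/dimnames and NAs (pmin/pmax with a scalar first arg drops dims)
  x[which(x < 0)] <- 0
  x[which(x > 1)] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) ||
      any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a finite probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Fast ordinary least squares with a t-test on one coefficient
#'
#' QR-based fit used by both association scans. Returns coefficients,
#' standard errors and two-sided t-test p-values. Rank-deficient designs
#' leave the aliased coefficients as `NA`.
#'
#' @param y numeric response.
#' @param X numeric design matrix (no missing values).
#' @return list with `coef`, `se`, `t`, `p`, `df`, `rss`.
#' @keywords internal
#' @noRd
ols_fit <- function(y, X) {
  n <- length(y)
  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  df <- n - r
  pn <- ncol(X)
  se <- rep(NA_real_, pn)
  if (df > 0 && r > 0) {
    rss <- sum(fit$residuals^2)
    s2 <- rss / df
    R <- fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]
    R[lower.tri(R)] <- 0
    V <- chol2inv(R)
    se[fit$qr$pivot[seq_len(r)]] <- sqrt(pmax(diag(V), 0) * s2)
  } else {
    rss <- NA_real_
  }
  b <- fit$coefficients
  tv <- b / se
  p <- 2 * stats::pt(-abs(tv), df)
  names(se) <- names(tv) <- names(p) <- colnames(X)
  list(coef = b, se = se, t = tv, p = p, df = df, rss = rss)
}
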