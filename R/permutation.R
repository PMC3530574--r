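#' Draw one permutation of sample identifiers
#'
#' The permutation is applied to the genotype/phase side of a scan only
#' (see `genotype_perm` in [run_scan()]): the genotype-phenotype linkage is
#' broken while the ASE and expression matrices — and hence phasing and the
#' transcript-level aggregation — are untouched.
#'
#' @param n_samples number of samples.
#' @param seed optional integer seed.
#' @return an integer permutation of `1:n_samples`.
#' @export
permute_labels <- function(n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(n_samples)
}

#' Permutation-based null calibration of a scan
#'
#' Re-runs the chosen scan `n_permutations` times, each with one fresh
#' shuffle of the sample identifiers on the genotype side, pools the
#' post-filter p-values and summarizes their uniformity: the
#' Kolmogorov-Smirnov distance to Uniform(0, 1) and the fraction of null
#' p-values below 0.05. With the group-size filters active the pooled null
#' p-values are uniform; with `filtered = FALSE` (no group-size filter)
#' low-MAF SNPs with tiny genotype groups inflate the small-p tail.
#'
#' @param cohort an `ase_cohort`.
#' @param method `"ase"` or `"gte"`.
#' @param ase `transcript_ase` object (required for ASE), computed once on
#'   the unshuffled data.
#' @param n_permutations number of shuffles (the full design uses 500; a
#'   smaller number is adequate at desk scale).
#' @param seed integer seed for the shuffle stream.
#' @param filtered apply the group-size filters (min 4 ASE / 3 GTE); if
#'   `FALSE`, `min_group = 1`.
#' @param flank cis flank in bases.
#' @return object of class `perm_null`: list with pooled `p`, per-record
#'   `maf` and smallest non-empty group size `min_group_size`, `frac_below_05`,
#'   `ks_stat`, `ks_p`, `n_tests`, `n_permutations` and settings.
#' @export
null_calibration <- function(cohort, method = c("ase", "gte"), ase = NULL,
                             n_permutations = 500L, seed = 1L,
                             filtered = TRUE, flank = 100000L) {
  method <- match.arg(method)
  min_group <- if (filtered) NULL else 1L
  set.seed(seed)
  n <- length(cohort$samples)
  ## phenotypes must never be recomputed or modified by permutation
  pheno_before <- if (method == "ase") ase$ase else cohort$expression
  ps <- vector("list", n_permutations)
  mafs <- vector("list", n_permutations)
  gmins <- vector("list", n_permutations)
  for (i in seq_len(n_permutations)) {
    perm <- sample.int(n)
    rec <- run_scan(cohort, method = method, ase = ase, flank = flank,
                    min_group = min_group, genotype_perm = perm)
    ok <- !is.na(rec$p)
    ps[[i]] <- rec$p[ok]
    mafs[[i]] <- rec$maf[ok]
    g <- cbind(rec$n_lo, rec$n_mid, rec$n_hi)[ok, , drop = FALSE]
    g[g == 0] <- NA
    gmins[[i]] <- apply(g, 1L, min, na.rm = TRUE)
  }
  pheno_after <- if (method == "ase") ase$ase else cohort$expression
  stopifnot(identical(pheno_before, pheno_after))
  p <- unlist(ps)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  structure(list(
    p = p, maf = unlist(mafs), min_group_size = unlist(gmins),
    frac_below_05 = mean(p < 0.05),
    ks_stat = unname(ks$statistic), ks_p = ks$p.value,
    n_tests = length(p), n_permutations = n_permutations,
    method = method, filtered = filtered, seed = seed
  ), class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf(
    "perm_null (%s, %s): %d pooled p-values from %d permutations\n  frac(p < 0.05) = %.4f, KS distance = %.4f (KS p = %.3g)\n",
    x$method, if (x$filtered) "filtered" else "unfiltered",
    x$n_tests, x$n_permutations, x$frac_below_05, x$ks_stat, x$ks_p
  ))
  invisible(x)
}

#' QQ points of pooled null p-values against the uniform distribution
#'
#' @param x a `perm_null` object.
#' @param n_points number of quantile points.
#' @return data.frame with `expected` and `observed` quantiles (both on the
#'   -log10 scale columns included for plotting convenience).
#' @export
qq_points <- function(x, n_points = 200L) {
  probs <- (seq_len(n_points) - 0.5) / n_points
  data.frame(
    expected = probs,
    observed = unname(stats::quantile(x$p, probs, type = 1L)),
    neglog10_expected = -log10(probs),
    neglog10_observed = -log10(unname(stats::quantile(x$p, probs, type = 1L)))
  )
}
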