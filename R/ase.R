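#' Allele fraction from a two-channel signal
#'
#' `allele1 / (allele1 + allele2)`. Observations with zero (or negative)
#' total signal are missing data, never 0 or 0.5.
#'
#' @param allele1,allele2 non-negative intensities (vectorized).
#' @return numeric fraction in \[0, 1\], `NA` where the total is not positive.
#' @examples
#' allele_fraction(60, 40)
#' @export
allele_fraction <- function(allele1, allele2) {
  total <- allele1 + allele2
  f <- allele1 / total
  f[!is.finite(total) | total <= 0] <- NA_real_
  f
}

#' Quadratic intensity-dependent normalization of allele fractions
#'
#' Fits, per sample array, a least-squares quadratic of the heterozygous gDNA
#' allele-fraction deviation from 0.5 against `log10(total signal)`, and
#' subtracts the fitted curve from every fraction (gDNA and cDNA) on that
#' array. Heterozygous gDNA observations are the only internal standard with
#' a known truth (0.5), so the fit uses them alone.
#'
#' @param gdna,cdna lists with matrices `a1`, `a2` (SNPs x samples).
#' @param het logical matrix, `TRUE` where the sample is heterozygous.
#' @param min_het minimum heterozygous gDNA observations required to fit one
#'   array; below this the array is passed through with a warning.
#' @return list with `gdna_frac`, `cdna_frac` (corrected, clipped to
#'   \[0, 1\]) and `coefficients` (3 x samples matrix of fitted quadratic
#'   coefficients; `NA` where the fit was skipped).
#' @export
normalize_fractions <- function(gdna, cdna, het, min_het = 30L) {
  gfrac <- allele_fraction(gdna$a1, gdna$a2)
  cfrac <- allele_fraction(cdna$a1, cdna$a2)
  g_t <- log10(gdna$a1 + gdna$a2)
  c_t <- log10(cdna$a1 + cdna$a2)
  ns <- ncol(gfrac)
  coefs <- matrix(NA_real_, 3L, ns, dimnames = list(
    c("c0", "c1", "c2"), colnames(gfrac)
  ))
  skipped <- character(0)
  for (j in seq_len(ns)) {
    use <- het[, j] & !is.na(gfrac[, j]) & is.finite(g_t[, j])
    if (sum(use) < min_het) {
      skipped <- c(skipped, colnames(gfrac)[j] %||% as.character(j))
      next
    }
    tt <- g_t[use, j]
    X <- cbind(1, tt, tt^2)
    b <- stats::lm.fit(X, gfrac[use, j] - 0.5)$coefficients
    coefs[, j] <- b
    gfrac[, j] <- gfrac[, j] - (b[1] + b[2] * g_t[, j] + b[3] * g_t[, j]^2)
    cfrac[, j] <- cfrac[, j] - (b[1] + b[2] * c_t[, j] + b[3] * c_t[, j]^2)
  }
  if (length(skipped)) {
    warning(sprintf(
      "normalization skipped for %d array(s) with < %d heterozygous gDNA observations: %s",
      length(skipped), min_het, paste(utils::head(skipped, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  list(gdna_frac = clip01(gfrac), cdna_frac = clip01(cfrac),
       coefficients = coefs)
}

#' Per-SNP ASE level: cDNA allele fraction minus gDNA allele fraction
#'
#' Defined only for heterozygous calls; the result lies in \[-1, 1\].
#'
#' @param cdna_a1,cdna_a2,gdna_a1,gdna_a2 two-channel intensities
#'   (vectorized).
#' @return numeric ASE level, `NA` where either total signal is not positive.
#' @examples
#' snp_ase_level(60, 40, 55, 45)
#' @export
snp_ase_level <- function(cdna_a1, cdna_a2, gdna_a1, gdna_a2) {
  allele_fraction(cdna_a1, cdna_a2) - allele_fraction(gdna_a1, gdna_a2)
}

#' Orient a per-SNP ASE level to the sample's haplotype 1
#'
#' Flips the sign iff allele 1 lies on haplotype 2, so that a positive level
#' always means "haplotype 1 over-expressed" within the sample.
#'
#' @param level per-SNP ASE level(s), signed toward allele 1.
#' @param allele1_on_hap1 logical (vectorized): does allele 1 sit on
#'   haplotype 1 for this heterozygous call?
#' @return oriented level(s).
#' @export
orient_by_phase <- function(level, allele1_on_hap1) {
  ifelse(allele1_on_hap1, level, -level)
}

#' Quantify transcript-level ASE from two-channel allele signals
#'
#' Full quantification path: allele fractions, optional quadratic
#' normalization, per-SNP ASE levels at phased heterozygous body SNPs,
#' orientation to each sample's haplotype 1, and aggregation over the
#' transcript body. A SNP is informative if at least one sample in the
#' cohort is heterozygous for it; transcripts with fewer than
#' `min_informative` informative body SNPs are dropped.
#'
#' @param cohort an `ase_cohort`.
#' @param min_informative minimum cohort-level informative body SNPs for a
#'   transcript to be retained (default 5; the relaxed alternative is 3).
#' @param aggregate `"mean"` (default) or `"median"` across a sample's
#'   heterozygous body SNPs.
#' @param normalize apply [normalize_fractions()] before computing levels.
#' @return object of class `transcript_ase`: list with `ase` (kept
#'   transcripts x samples matrix of signed ASE levels, `NA` where a sample
#'   has no usable heterozygous body SNP), `informative` (named counts for
#'   all transcripts), `kept`, `levels` (oriented per-SNP matrix),
#'   `norm_coefficients` and the settings used.
#' @export
quantify_ase <- function(cohort, min_informative = 5L,
                         aggregate = c("mean", "median"),
                         normalize = TRUE) {
  aggregate <- match.arg(aggregate)
  gt <- cohort$gt
  het <- !is.na(gt) & gt == 1L
  if (normalize) {
    nf <- normalize_fractions(cohort$gdna, cohort$cdna, het)
    gfrac <- nf$gdna_frac
    cfrac <- nf$cdna_frac
    coefs <- nf$coefficients
  } else {
    gfrac <- allele_fraction(cohort$gdna$a1, cohort$gdna$a2)
    cfrac <- allele_fraction(cohort$cdna$a1, cohort$cdna$a2)
    coefs <- NULL
  }
  levels <- cfrac - gfrac
  usable <- het & cohort$phased & !is.na(levels)
  levels[!usable] <- NA_real_
  ## orient: allele 1 is the reference allele; it sits on haplotype 1 where
  ## the hap1 allele code is 0
  flip <- !is.na(cohort$hap1) & cohort$hap1 == 1L
  levels[flip] <- -levels[flip]

  tx <- cohort$transcripts
  n <- length(cohort$samples)
  agg_fun <- if (aggregate == "mean") mean else stats::median
  informative <- integer(nrow(tx))
  names(informative) <- tx$transcript
  ase <- matrix(NA_real_, nrow(tx), n,
                dimnames = list(tx$transcript, cohort$samples))
  for (t in seq_len(nrow(tx))) {
    body <- which(cohort$sites$chrom == tx$chrom[t] &
                    cohort$sites$pos >= tx$start[t] &
                    cohort$sites$pos < tx$end[t])
    if (!length(body)) next
    informative[t] <- sum(rowSums(het[body, , drop = FALSE]) > 0L)
    lv <- levels[body, , drop = FALSE]
    ase[t, ] <- apply(lv, 2L, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else agg_fun(v)
    })
  }
  kept <- names(informative)[informative >= min_informative]
  structure(list(
    ase = ase[kept, , drop = FALSE],
    informative = informative,
    kept = kept,
    levels = levels,
    norm_coefficients = coefs,
    min_informative = as.integer(min_informative),
    aggregate = aggregate
  ), class = "transcript_ase")
}

#' @export
print.transcript_ase <- function(x, ...) {
  cat(sprintf(
    "transcript_ase: %d/%d transcripts kept (>= %d informative SNPs), %d samples, %s aggregation\n",
    length(x$kept), length(x$informative), x$min_informative,
    ncol(x$ase), x$aggregate
  ))
  invisible(x)
}

#' Region-level standard-deviation QC of ASE measurements
#'
#' For every (sample, transcript) cell, the SD of the oriented per-SNP ASE
#' levels across the transcript body is compared with the absolute cell mean.
#' Transcripts where more than half of the evaluable samples have
#' SD > |mean| are flagged: such regions are candidates for alternative
#' splicing, phasing errors or noisy fluorescence signals.
#'
#' @param ase_obj a `transcript_ase` object (from [quantify_ase()]).
#' @param cohort the `ase_cohort` it was computed from.
#' @return data.frame with one row per kept transcript: number of evaluable
#'   samples (`n_eval`, cells with >= 2 heterozygous body SNPs), fraction of
#'   cells whose SD exceeds the absolute mean (`frac_exceed`) and `flagged`.
#' @export
region_sd_qc <- function(ase_obj, cohort) {
  tx <- cohort$transcripts
  tx <- tx[tx$transcript %in% ase_obj$kept, , drop = FALSE]
  out <- data.frame(transcript = tx$transcript, n_eval = 0L,
                    frac_exceed = NA_real_, flagged = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tx))) {
    body <- which(cohort$sites$chrom == tx$chrom[i] &
                    cohort$sites$pos >= tx$start[i] &
                    cohort$sites$pos < tx$end[i])
    lv <- ase_obj$levels[body, , drop = FALSE]
    cell_n <- colSums(!is.na(lv))
    eval_cells <- cell_n >= 2L
    if (!any(eval_cells)) next
    sds <- apply(lv[, eval_cells, drop = FALSE], 2L, stats::sd, na.rm = TRUE)
    mns <- colMeans(lv[, eval_cells, drop = FALSE], na.rm = TRUE)
    out$n_eval[i] <- sum(eval_cells)
    out$frac_exceed[i] <- mean(sds > abs(mns))
    out$flagged[i] <- out$frac_exceed[i] > 0.5
  }
  out
}
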