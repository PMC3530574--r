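#' Cis windows around transcripts
#'
#' The tested region for a transcript is the transcript body plus `flank`
#' bases up- and downstream (default 100 kb; the wide alternative is 500 kb),
#' clipped at the chromosome start.
#'
#' @param transcripts data.frame with `transcript`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param flank flank size in bases.
#' @return data.frame with `transcript`, `chrom`, `window_start`,
#'   `window_end` (closed interval on SNP positions).
#' @export
cis_window <- function(transcripts, flank = 100000L) {
  if (flank < 0) stop("flank must be >= 0", call. = FALSE)
  data.frame(
    transcript = transcripts$transcript,
    chrom = transcripts$chrom,
    window_start = pmax(0L, transcripts$start - as.integer(flank)),
    window_end = transcripts$end - 1L + as.integer(flank),
    stringsAsFactors = FALSE
  )
}

#' Select test SNPs inside one cis window
#'
#' @param window one row of [cis_window()] output (or a list with `chrom`,
#'   `window_start`, `window_end`).
#' @param sites SNP table with `snp`, `chrom`, `pos`.
#' @return the subset of `sites` inside the closed window interval.
#' @export
select_test_snps <- function(window, sites) {
  sites[sites$chrom == window$chrom &
          sites$pos >= window$window_start &
          sites$pos <= window$window_end, , drop = FALSE]
}

#' Phase-aware group coding for the ASE regression
#'
#' Heterozygotes form two groups by phase: minor allele on haplotype 1 is
#' coded +1, on haplotype 2 is coded -1. Homozygotes (either kind) form the
#' baseline group, coded 0. Missing genotypes and unphased heterozygotes are
#' `NA` (excluded from the test).
#'
#' @param gt genotype vector (0/1/2 minor-allele counts, `NA` missing).
#' @param hap1 haplotype-1 allele vector (0 = reference, 1 = alternate).
#' @param phased logical vector: is the call phased?
#' @param minor_is_alt is the cohort minor allele the alternate allele?
#'   (If not, the haplotype carrying the reference allele gets the +1 code.)
#' @return numeric vector in \{+1, 0, -1, NA\}.
#' @export
ase_groups <- function(gt, hap1, phased = TRUE, minor_is_alt = TRUE) {
  x <- rep(NA_real_, length(gt))
  hom <- !is.na(gt) & gt != 1L
  x[hom] <- 0
  het <- !is.na(gt) & gt == 1L & phased & !is.na(hap1)
  minor_on_hap1 <- if (minor_is_alt) hap1 == 1L else hap1 == 0L
  x[het] <- ifelse(minor_on_hap1[het], 1, -1)
  x
}

#' @keywords internal
#' @noRd
group_filter_ok <- function(counts, min_group, require_all_groups) {
  nonempty <- counts > 0L
  if (require_all_groups) {
    all(counts >= min_group)
  } else {
    sum(nonempty) >= 2L && all(counts[nonempty] >= min_group)
  }
}

#' Phase-aware ASE association test at one SNP
#'
#' Regression of transcript ASE levels on the phase-coded covariate
#' (+1 / 0 / -1, see [ase_groups()]) through the origin: the homozygote
#' group is the zero baseline, and the test is exactly invariant under
#' relabelling any sample's haplotypes (which flips that sample's covariate
#' and its oriented ASE level jointly). Two-sided t-test on the slope.
#'
#' The test is skipped (returns `NULL`) unless every non-empty group among
#' \{+1, 0, -1\} has at least `min_group` values and at least two groups are
#' present.
#'
#' @param ase transcript ASE values per sample.
#' @param x phase-coded covariate per sample.
#' @param min_group minimum values per non-empty genotype group (default 4).
#' @param require_all_groups require all three groups to be populated.
#' @return list with `slope`, `se`, `p`, `df`, group counts `n_neg`,
#'   `n_zero`, `n_pos` and `degenerate` (zero response variance, `p` is
#'   `NA`), or `NULL` if the group filter rejects the test.
#' @export
ase_association <- function(ase, x, min_group = 4L,
                            require_all_groups = FALSE) {
  keep <- !is.na(ase) & !is.na(x)
  y <- ase[keep]
  xv <- x[keep]
  counts <- c(n_neg = sum(xv == -1), n_zero = sum(xv == 0),
              n_pos = sum(xv == 1))
  if (!group_filter_ok(counts, min_group, require_all_groups)) return(NULL)
  n <- length(y)
  sxx <- sum(xv^2)
  degenerate <- stats::var(y) == 0
  slope <- sum(xv * y) / sxx
  rss <- sum((y - slope * xv)^2)
  df <- n - 1L
  se <- sqrt(rss / df / sxx)
  p <- if (degenerate) NA_real_ else 2 * stats::pt(-abs(slope / se), df)
  list(slope = slope, se = se, p = p, df = df,
       n_neg = counts[["n_neg"]], n_zero = counts[["n_zero"]],
       n_pos = counts[["n_pos"]], degenerate = degenerate)
}

#' Covariate-adjusted GTE (cis-eQTL) association test at one SNP
#'
#' Ordinary least squares of total expression on minor-allele dosage with
#' age and sex as confounders; two-sided t-test on the dosage slope. The
#' test is skipped (returns `NULL`) unless every non-empty dosage class
#' \{0, 1, 2\} has at least `min_group` values and at least two classes are
#' present. A covariate with no variance in the analyzed subset (e.g. a
#' single-sex subset) is dropped with a warning.
#'
#' @param expression expression values per sample.
#' @param dosage minor-allele dosage (0/1/2, `NA` missing).
#' @param age,sex optional confounders.
#' @param min_group minimum values per non-empty genotype group (default 3).
#' @return list with `slope`, `se`, `p`, `df`, class counts `n_0`, `n_1`,
#'   `n_2` and `degenerate`, or `NULL` if the group filter rejects the test.
#' @export
gte_association <- function(expression, dosage, age = NULL, sex = NULL,
                            min_group = 3L) {
  keep <- !is.na(expression) & !is.na(dosage)
  if (!is.null(age)) keep <- keep & !is.na(age)
  if (!is.null(sex)) keep <- keep & !is.na(sex)
  y <- expression[keep]
  d <- dosage[keep]
  counts <- c(n_0 = sum(d == 0), n_1 = sum(d == 1), n_2 = sum(d == 2))
  if (!group_filter_ok(counts, min_group, FALSE)) return(NULL)
  X <- cbind(intercept = 1, dosage = d)
  for (nm in c("age", "sex")) {
    v <- switch(nm, age = age, sex = sex)
    if (is.null(v)) next
    v <- v[keep]
    if (stats::var(v) == 0) {
      warning(sprintf("covariate `%s` is constant in this subset; dropped", nm),
              call. = FALSE)
    } else {
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- nm
    }
  }
  degenerate <- stats::var(y) == 0
  fit <- ols_fit(y, X)
  p <- if (degenerate) NA_real_ else fit$p[["dosage"]]
  list(slope = fit$coef[["dosage"]], se = fit$se[["dosage"]], p = p,
       df = fit$df, n_0 = counts[["n_0"]], n_1 = counts[["n_1"]],
       n_2 = counts[["n_2"]], degenerate = degenerate)
}

#' Run a full cis association scan
#'
#' One test per (SNP, transcript) pair where the SNP lies in the
#' transcript's cis window and the group-size filter passes. For the ASE
#' method the phenotype is the transcript ASE matrix; for GTE it is total
#' expression with age/sex adjustment. The minor allele and MAF are the
#' empirical ones of the analyzed sample set. Records carry strand-oriented
#' signed distances to the TSS and TTS (upstream negative).
#'
#' @param cohort an `ase_cohort`.
#' @param method `"ase"` or `"gte"`.
#' @param ase a `transcript_ase` object (required for `method = "ase"`).
#' @param flank cis flank in bases (default 100000; 500000 is the wide
#'   variant).
#' @param sample_subset optional integer indices (or sample names) selecting
#'   the analyzed samples.
#' @param min_group group-size filter threshold; defaults to 4 for ASE and
#'   3 for GTE. Set to 1 to disable filtering (used to demonstrate null
#'   inflation at low-MAF SNPs).
#' @param require_all_groups ASE only: require all three phase groups.
#' @param genotype_perm optional permutation of sample indices applied to the
#'   genotype/phase side only, breaking the genotype-phenotype linkage while
#'   leaving phenotypes untouched (see [null_calibration()]).
#' @return data.frame of association records ordered by transcript then
#'   position: `transcript`, `snp`, `chrom`, `pos`, `method`, `maf`,
#'   `n_lo`, `n_mid`, `n_hi` (group sizes: -1/0/+1 for ASE, dosage 0/1/2 for
#'   GTE), `slope`, `se`, `p`, `dist_tss`, `dist_tts`, `degenerate`.
#' @export
run_scan <- function(cohort, method = c("ase", "gte"), ase = NULL,
                     flank = 100000L, sample_subset = NULL,
                     min_group = NULL, require_all_groups = FALSE,
                     genotype_perm = NULL) {
  method <- match.arg(method)
  if (method == "ase" && is.null(ase)) {
    stop("method = \"ase\" requires a `transcript_ase` object", call. = FALSE)
  }
  min_group <- min_group %||% if (method == "ase") 4L else 3L

  n_all <- length(cohort$samples)
  gt <- cohort$gt
  hap1 <- cohort$hap1
  phased <- cohort$phased
  if (!is.null(genotype_perm)) {
    if (length(genotype_perm) != n_all ||
        !setequal(genotype_perm, seq_len(n_all))) {
      stop("genotype_perm must be a permutation of the sample indices",
           call. = FALSE)
    }
    gt <- gt[, genotype_perm, drop = FALSE]
    hap1 <- hap1[, genotype_perm, drop = FALSE]
    phased <- phased[, genotype_perm, drop = FALSE]
  }
  idx <- seq_len(n_all)
  if (!is.null(sample_subset)) {
    idx <- if (is.character(sample_subset)) {
      match(sample_subset, cohort$samples)
    } else as.integer(sample_subset)
    if (anyNA(idx) || any(idx < 1L) || any(idx > n_all)) {
      stop("sample_subset indices out of range", call. = FALSE)
    }
  }
  gt <- gt[, idx, drop = FALSE]
  hap1 <- hap1[, idx, drop = FALSE]
  phased <- phased[, idx, drop = FALSE]

  if (method == "ase") {
    Y <- ase$ase[, idx, drop = FALSE]
    tx <- cohort$transcripts[match(rownames(Y), cohort$transcripts$transcript),
                             , drop = FALSE]
  } else {
    Y <- cohort$expression[, idx, drop = FALSE]
    tx <- cohort$transcripts
    age <- cohort$covariates$age[idx]
    sex <- cohort$covariates$sex[idx]
  }
  windows <- cis_window(tx, flank)
  sites <- cohort$sites

  ord <- order(tx$transcript)
  acc <- vector("list", nrow(tx))
  for (k in seq_along(ord)) {
    t <- ord[k]
    snp_rows <- which(sites$chrom == windows$chrom[t] &
                        sites$pos >= windows$window_start[t] &
                        sites$pos <= windows$window_end[t])
    if (!length(snp_rows)) next
    snp_rows <- snp_rows[order(sites$pos[snp_rows])]
    y <- Y[t, ]
    plus <- tx$strand[t] == "+"
    tss <- if (plus) tx$start[t] else tx$end[t] - 1L
    tts <- if (plus) tx$end[t] - 1L else tx$start[t]
    recs <- vector("list", length(snp_rows))
    for (i in seq_along(snp_rows)) {
      s <- snp_rows[i]
      g <- gt[s, ]
      nn <- sum(!is.na(g))
      if (nn == 0L) next
      alt_freq <- sum(g, na.rm = TRUE) / (2 * nn)
      maf <- min(alt_freq, 1 - alt_freq)
      if (method == "ase") {
        x <- ase_groups(g, hap1[s, ], phased[s, ],
                        minor_is_alt = alt_freq <= 0.5)
        r <- ase_association(y, x, min_group, require_all_groups)
        if (is.null(r)) next
        grp <- c(r$n_neg, r$n_zero, r$n_pos)
      } else {
        d <- if (alt_freq <= 0.5) g else 2L - g
        r <- gte_association(y, d, age, sex, min_group)
        if (is.null(r)) next
        grp <- c(r$n_0, r$n_1, r$n_2)
      }
      recs[[i]] <- list(
        transcript = tx$transcript[t], snp = sites$snp[s],
        chrom = sites$chrom[s], pos = sites$pos[s], maf = maf,
        n_lo = grp[1], n_mid = grp[2], n_hi = grp[3],
        slope = r$slope, se = r$se, p = r$p,
        dist_tss = if (plus) sites$pos[s] - tss else tss - sites$pos[s],
        dist_tts = if (plus) sites$pos[s] - tts else tts - sites$pos[s],
        degenerate = r$degenerate
      )
    }
    acc[[k]] <- recs[!vapply(recs, is.null, logical(1))]
  }
  recs <- unlist(acc, recursive = FALSE)
  if (!length(recs)) {
    return(data.frame(
      transcript = character(0), snp = character(0), chrom = character(0),
      pos = integer(0), method = character(0), maf = numeric(0),
      n_lo = integer(0), n_mid = integer(0), n_hi = integer(0),
      slope = numeric(0), se = numeric(0), p = numeric(0),
      dist_tss = integer(0), dist_tts = integer(0), degenerate = logical(0),
      stringsAsFactors = FALSE
    ))
  }
  out <- data.frame(
    transcript = vapply(recs, `[[`, character(1), "transcript"),
    snp = vapply(recs, `[[`, character(1), "snp"),
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    pos = vapply(recs, `[[`, numeric(1), "pos"),
    method = method,
    maf = vapply(recs, `[[`, numeric(1), "maf"),
    n_lo = vapply(recs, `[[`, numeric(1), "n_lo"),
    n_mid = vapply(recs, `[[`, numeric(1), "n_mid"),
    n_hi = vapply(recs, `[[`, numeric(1), "n_hi"),
    slope = vapply(recs, `[[`, numeric(1), "slope"),
    se = vapply(recs, `[[`, numeric(1), "se"),
    p = vapply(recs, `[[`, numeric(1), "p"),
    dist_tss = vapply(recs, `[[`, numeric(1), "dist_tss"),
    dist_tts = vapply(recs, `[[`, numeric(1), "dist_tts"),
    degenerate = vapply(recs, `[[`, logical(1), "degenerate"),
    stringsAsFactors = FALSE
  )
  attr(out, "n_samples") <- length(idx)
  out
}
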