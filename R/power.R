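#' Ratio of ASE to GTE detection counts
#'
#' `Inf` when the GTE count is zero but the ASE count is not; `NA` when both
#' are zero.
#'
#' @param ase_count,gte_count non-negative counts.
#' @return numeric ratio(s).
#' @export
ase_gte_ratio <- function(ase_count, gte_count) {
  r <- ase_count / gte_count
  r[gte_count == 0 & ase_count == 0] <- NA_real_
  r
}

#' Best (minimum-p) association record per SNP
#'
#' Ties in p are broken by the smallest transcript id for determinism.
#'
#' @param records adjusted scan records.
#' @return one row per SNP.
#' @export
best_per_snp <- function(records) {
  ok <- !is.na(records$p)
  r <- records[ok, , drop = FALSE]
  r <- r[order(r$snp, r$p, r$transcript), , drop = FALSE]
  r[!duplicated(r$snp), , drop = FALSE]
}

#' Count significant associations at a threshold
#'
#' Three counts as in the standard power-comparison layout: significant
#' SNP-transcript associations, unique significant SNPs (a SNP counts once,
#' via its best association), and transcripts with at least one significant
#' SNP.
#'
#' @param records adjusted scan records (see [adjust_scan()]).
#' @param threshold `"bonferroni"` or `"fdr"`.
#' @param alpha significance level.
#' @return list with `associations`, `snps`, `transcripts`.
#' @export
count_significant <- function(records, threshold = c("bonferroni", "fdr"),
                              alpha = 0.05) {
  threshold <- match.arg(threshold)
  col <- if (threshold == "bonferroni") "p_bonf" else "p_fdr"
  if (is.null(records[[col]])) {
    stop("records lack adjusted p-values; run adjust_scan() first",
         call. = FALSE)
  }
  sig <- !is.na(records[[col]]) & records[[col]] <= alpha
  list(
    associations = sum(sig),
    snps = length(unique(records$snp[sig])),
    transcripts = length(unique(records$transcript[sig]))
  )
}

#' Significance counts under down-sampling
#'
#' Draws `n_runs` random sample subsets of size `n` without replacement,
#' re-runs the full scan plus multiple-testing adjustment on each, and
#' reports the median of each count across runs. With `n` equal to the full
#' cohort a single run is performed.
#'
#' @param cohort an `ase_cohort`.
#' @param method `"ase"` or `"gte"`.
#' @param n subset size (<= cohort size).
#' @param ase `transcript_ase` object for the ASE method.
#' @param n_runs number of random subsets (default 10).
#' @param seed integer seed for subset draws.
#' @param thresholds data.frame with columns `threshold`
#'   (`"bonferroni"`/`"fdr"`) and `alpha`; defaults to the four standard
#'   threshold types.
#' @param flank cis flank in bases.
#' @return data.frame with one row per threshold type: median
#'   `associations`, `snps`, `transcripts`, plus `method`, `n`, `n_runs`.
#' @export
downsample_counts <- function(cohort, method = c("ase", "gte"), n,
                              ase = NULL, n_runs = 10L, seed = 1L,
                              thresholds = standard_thresholds(),
                              flank = 100000L) {
  method <- match.arg(method)
  n_total <- length(cohort$samples)
  if (n > n_total) stop("n exceeds the cohort size", call. = FALSE)
  if (n == n_total) n_runs <- 1L
  set.seed(seed)
  counts <- array(NA_real_, dim = c(n_runs, nrow(thresholds), 3L))
  for (r in seq_len(n_runs)) {
    subset <- if (n == n_total) seq_len(n_total) else sample.int(n_total, n)
    rec <- adjust_scan(run_scan(cohort, method = method, ase = ase,
                                flank = flank, sample_subset = subset))
    for (j in seq_len(nrow(thresholds))) {
      cs <- count_significant(rec, thresholds$threshold[j],
                              thresholds$alpha[j])
      counts[r, j, ] <- c(cs$associations, cs$snps, cs$transcripts)
    }
  }
  med <- apply(counts, c(2L, 3L), stats::median)
  data.frame(
    method = method, n = n, n_runs = n_runs,
    threshold = thresholds$threshold, alpha = thresholds$alpha,
    associations = med[, 1L], snps = med[, 2L], transcripts = med[, 3L],
    stringsAsFactors = FALSE
  )
}

#' The four standard threshold types
#'
#' FDR 5%, FDR 1%, Bonferroni 0.05 and Bonferroni 0.01.
#'
#' @return data.frame with `threshold` and `alpha`.
#' @export
standard_thresholds <- function() {
  data.frame(
    threshold = c("fdr", "fdr", "bonferroni", "bonferroni"),
    alpha = c(0.05, 0.01, 0.05, 0.01),
    stringsAsFactors = FALSE
  )
}

#' Power-comparison table across methods and sample sizes
#'
#' Builds the power summary: for each method and sample size, the median
#' (over down-sampling runs) counts of significant associations, unique
#' SNPs and transcripts at each threshold type, plus ASE/GTE ratio columns.
#'
#' @param cohort an `ase_cohort`.
#' @param ase `transcript_ase` object.
#' @param sizes sample sizes to evaluate.
#' @param n_runs down-sampling runs per size (full-cohort sizes use 1).
#' @param seed integer seed.
#' @param flank cis flank in bases.
#' @return data.frame in long layout with an `ase_gte_ratio` column joined
#'   per (threshold, n).
#' @export
power_table <- function(cohort, ase, sizes = c(188L, 95L, 50L),
                        n_runs = 10L, seed = 1L, flank = 100000L) {
  rows <- list()
  for (n in sizes) {
    rows[[length(rows) + 1L]] <-
      downsample_counts(cohort, "ase", n, ase = ase, n_runs = n_runs,
                        seed = seed, flank = flank)
    rows[[length(rows) + 1L]] <-
      downsample_counts(cohort, "gte", n, n_runs = n_runs, seed = seed + 1L,
                        flank = flank)
  }
  tab <- do.call(rbind, rows)
  key <- paste(tab$threshold, tab$alpha, tab$n)
  ratio <- rep(NA_real_, nrow(tab))
  for (k in unique(key)) {
    i_ase <- which(key == k & tab$method == "ase")
    i_gte <- which(key == k & tab$method == "gte")
    if (length(i_ase) == 1L && length(i_gte) == 1L) {
      ratio[c(i_ase, i_gte)] <- ase_gte_ratio(tab$snps[i_ase],
                                              tab$snps[i_gte])
    }
  }
  tab$ase_gte_snp_ratio <- ratio
  tab
}

#' Top-list overlap between the two methods
#'
#' Eligible SNPs are those tested by both methods. Within the eligible set,
#' each method contributes its top-k SNPs by best (minimum) p-value; the
#' overlap percentage is the intersection size divided by the GTE top-list
#' size.
#'
#' @param ase_records,gte_records adjusted scan records.
#' @param k_ase,k_gte top-list sizes (capped at the eligible set size with a
#'   warning).
#' @return list with `eligible`, `k_ase`, `k_gte`, `intersection`,
#'   `overlap_pct`.
#' @export
toplist_overlap <- function(ase_records, gte_records, k_ase, k_gte) {
  eligible <- intersect(unique(ase_records$snp), unique(gte_records$snp))
  n_el <- length(eligible)
  if (n_el == 0L) stop("no SNPs tested by both methods", call. = FALSE)
  if (k_ase > n_el || k_gte > n_el) {
    warning("top-list size exceeds the eligible SNP set; capped",
            call. = FALSE)
    k_ase <- min(k_ase, n_el)
    k_gte <- min(k_gte, n_el)
  }
  top_of <- function(records, k) {
    b <- best_per_snp(records[records$snp %in% eligible, , drop = FALSE])
    b <- b[order(b$p, b$snp), , drop = FALSE]
    utils::head(b$snp, k)
  }
  top_ase <- top_of(ase_records, k_ase)
  top_gte <- top_of(gte_records, k_gte)
  inter <- length(intersect(top_ase, top_gte))
  list(eligible = n_el, k_ase = k_ase, k_gte = k_gte,
       intersection = inter, overlap_pct = 100 * inter / k_gte)
}

#' MAF-binned detection-power curve
#'
#' Bins SNPs by their empirical cohort MAF into 1% bins over (0, 50%]
#' (MAF = 0.5 falls in the last bin) and reports, per bin, the number of
#' tested SNPs, the number significantly associated (via each SNP's best
#' association) and their fraction, plus a centred 5-bin sliding-window
#' average of the fraction (truncated at the edges; empty bins are excluded
#' from smoothing).
#'
#' @param records adjusted scan records.
#' @param threshold,alpha significance rule (default Bonferroni 0.05).
#' @return data.frame with `bin` (0-based index), `maf_lo`, `maf_hi`,
#'   `tested`, `significant`, `fraction`, `fraction_smooth`.
#' @export
maf_power_curve <- function(records, threshold = "bonferroni", alpha = 0.05) {
  col <- if (threshold == "bonferroni") "p_bonf" else "p_fdr"
  b <- best_per_snp(records)
  sig <- !is.na(b[[col]]) & b[[col]] <= alpha
  bin <- pmin(floor(b$maf * 100), 49L)
  tested <- tabulate(bin + 1L, nbins = 50L)
  signif_n <- tabulate(bin[sig] + 1L, nbins = 50L)
  fraction <- ifelse(tested > 0L, signif_n / tested, NA_real_)
  smooth <- rep(NA_real_, 50L)
  for (i in seq_len(50L)) {
    w <- max(1L, i - 2L):min(50L, i + 2L)
    v <- fraction[w]
    if (any(!is.na(v))) smooth[i] <- mean(v, na.rm = TRUE)
  }
  data.frame(
    bin = 0:49, maf_lo = (0:49) / 100, maf_hi = (1:50) / 100,
    tested = tested, significant = signif_n,
    fraction = fraction, fraction_smooth = smooth
  )
}

#' Positional enrichment of significant SNPs around TSS and TTS
#'
#' Bins the strand-oriented signed distances (upstream negative) carried in
#' the scan records into fixed-width bins and reports tested and significant
#' association counts plus their fraction per bin, separately for the
#' distance to the transcription start and termination sites.
#'
#' @param records adjusted scan records.
#' @param threshold,alpha significance rule.
#' @param bin_size bin width in bases (default 1000).
#' @return list with data.frames `tss` and `tts`, each with `bin` (index,
#'   `floor(distance / bin_size)`), `tested`, `significant`, `fraction`.
#' @export
positional_enrichment <- function(records, threshold = "bonferroni",
                                  alpha = 0.05, bin_size = 1000L) {
  col <- if (threshold == "bonferroni") "p_bonf" else "p_fdr"
  sig <- !is.na(records[[col]]) & records[[col]] <= alpha
  profile <- function(dist) {
    bin <- floor(dist / bin_size)
    tested <- table(bin)
    signif_n <- table(factor(bin[sig], levels = names(tested)))
    data.frame(
      bin = as.integer(names(tested)),
      tested = as.integer(tested),
      significant = as.integer(signif_n),
      fraction = as.integer(signif_n) / as.integer(tested)
    )
  }
  list(tss = profile(records$dist_tss), tts = profile(records$dist_tts))
}

#' Reference significance counts from a large monocyte cohort comparison
#'
#' Published power-comparison counts (significant associations, unique SNPs
#' and transcripts for ASE and GTE at four threshold types and several
#' sample sizes, medians of 10 down-sampling runs) from a genome-wide
#' monocyte study, shipped as a plain-text table. Used to exercise the
#' reporting arithmetic (ASE/GTE ratios); the package never presents these
#' counts as its own computed results.
#'
#' @return data.frame with `panel`, `threshold`, `alpha`, `n`, `ase`,
#'   `gte`, `ratio_printed`.
#' @export
monocyte_reference_counts <- function() {
  path <- system.file("extdata", "monocyte_cohort_counts.tsv",
                      package = "asepower")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
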