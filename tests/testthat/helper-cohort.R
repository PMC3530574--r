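# Shared fixtures, built in code at test time.

small_cohort <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_samples = 60L, n_transcripts = 20L, seed = seed),
    list(...)
  )
  simulate_cohort(do.call(sim_config, args))
}

null_cohort <- function(seed = 1, ...) {
  small_cohort(seed, causal_fraction = 0, ase_effect = 0, gte_effect = 0, ...)
}

# swap one sample's haplotype labels everywhere (genotypes unchanged)
flip_sample_haps <- function(cohort, s) {
  tmp <- cohort$hap1[, s]
  cohort$hap1[, s] <- cohort$hap2[, s]
  cohort$hap2[, s] <- tmp
  cohort
}

# hand-built adjusted record table for the counting/overlap operations
fake_records <- function(snp, transcript, p, m = length(p), maf = NULL,
                         dist_tss = 0L, dist_tts = 0L) {
  df <- data.frame(
    transcript = transcript, snp = snp, chrom = "chr1",
    pos = seq_along(p), method = "ase",
    maf = maf %||% rep(0.25, length(p)),
    n_lo = 5L, n_mid = 5L, n_hi = 5L,
    slope = 0.1, se = 0.01, p = p,
    dist_tss = dist_tss, dist_tts = dist_tts,
    degenerate = FALSE, stringsAsFactors = FALSE
  )
  adjust_scan(df, m = m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
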