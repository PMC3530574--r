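#' Simulation configuration for a synthetic ASE/GTE cohort
#'
#' Builds and validates the parameter set controlling [simulate_cohort()].
#' The cohort emulates a monocyte-style design: HWE genotypes across a MAF
#' spectrum, per-sample haplotype phase, cis-regulatory SNP effects expressed
#' both as allelic imbalance in heterozygotes and as additive total-expression
#' shifts, two-channel allele-intensity signals with gDNA allele-ratio noise
#' and per-region RNA allele-ratio noise, a quadratic intensity-dependent dye
#' bias, age/sex confounders, and missing genotype calls.
#'
#' @param n_samples number of samples (>= 2).
#' @param n_transcripts number of transcript models.
#' @param snps_per_transcript SNPs placed inside each transcript body.
#' @param flank_snp_density SNPs per kb placed in each cis flank.
#' @param maf_range minor-allele-frequency interval within (0, 0.5].
#' @param causal_fraction fraction of transcripts given a cis-rSNP.
#' @param ase_effect mean allelic-fraction shift in heterozygotes, in
#'   \[0, 0.5\]: the cDNA allele fraction of the over-expressed haplotype is
#'   `0.5 + ase_effect`.
#' @param gte_effect additive expression shift per minor allele, on the
#'   normalized (unit-noise) expression scale.
#' @param gdna_ratio_sd SD of the gDNA allele-ratio noise (default 0.014,
#'   the observed cohort-average region SD in genomic DNA).
#' @param rna_region_sd per-SNP SD of the RNA allele ratio within a
#'   transcript region (default 0.10, the observed per-sample region average).
#' @param dye_bias_coeffs quadratic dye-bias coefficients `c(c0, c1, c2)`;
#'   the observed allele fraction is shifted by `c0 + c1*t + c2*t^2` with
#'   `t = log10(total signal)`.
#' @param switch_error_rate per-heterozygote probability of a phase switch
#'   applied at generation time (usually 0; see
#'   [introduce_phasing_errors()]).
#' @param missing_rate per-call probability of a missing genotype (MCAR).
#' @param age_effect expression shift per year of (centred) age.
#' @param sex_effect expression shift for sex = 1.
#' @param body_length transcript body length in bases.
#' @param flank cis flank size in bases used for SNP placement.
#' @param seed integer seed making the cohort reproducible.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_samples = 20, n_transcripts = 5, seed = 1)
#' @export
sim_config <- function(n_samples = 188L,
                       n_transcripts = 200L,
                       snps_per_transcript = 8L,
                       flank_snp_density = 0.05,
                       maf_range = c(0.01, 0.5),
                       causal_fraction = 0.5,
                       ase_effect = 0.2,
                       gte_effect = 0.6,
                       gdna_ratio_sd = 0.014,
                       rna_region_sd = 0.10,
                       dye_bias_coeffs = c(0.03, -0.01, 0.002),
                       switch_error_rate = 0,
                       missing_rate = 0.02,
                       age_effect = 0.005,
                       sex_effect = 0.1,
                       body_length = 20000L,
                       flank = 100000L,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_transcripts = as.integer(n_transcripts),
    snps_per_transcript = as.integer(snps_per_transcript),
    flank_snp_density = flank_snp_density,
    maf_range = as.numeric(maf_range),
    causal_fraction = causal_fraction,
    ase_effect = ase_effect,
    gte_effect = gte_effect,
    gdna_ratio_sd = gdna_ratio_sd,
    rna_region_sd = rna_region_sd,
    dye_bias_coeffs = as.numeric(dye_bias_coeffs),
    switch_error_rate = switch_error_rate,
    missing_rate = missing_rate,
    age_effect = age_effect,
    sex_effect = sex_effect,
    body_length = as.integer(body_length),
    flank = as.integer(flank),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @keywords internal
#' @noRd
validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 2L) stop("n_samples must be >= 2", call. = FALSE)
  if (cfg$n_transcripts < 1L) stop("n_transcripts must be >= 1", call. = FALSE)
  if (cfg$snps_per_transcript < 1L) {
    stop("snps_per_transcript must be >= 1", call. = FALSE)
  }
  mr <- cfg$maf_range
  if (length(mr) != 2L || anyNA(mr) || mr[1] <= 0 || mr[2] > 0.5 ||
      mr[1] > mr[2]) {
    stop("maf_range must lie within (0, 0.5] with maf_range[1] <= maf_range[2]",
         call. = FALSE)
  }
  if (cfg$ase_effect < 0 || cfg$ase_effect + 0.5 > 1) {
    stop("ase_effect must lie in [0, 0.5]", call. = FALSE)
  }
  stop_if_not_prob(cfg$causal_fraction, "causal_fraction")
  stop_if_not_prob(cfg$switch_error_rate, "switch_error_rate")
  stop_if_not_prob(cfg$missing_rate, "missing_rate")
  if (cfg$gdna_ratio_sd < 0 || cfg$rna_region_sd < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  if (length(cfg$dye_bias_coeffs) != 3L || anyNA(cfg$dye_bias_coeffs)) {
    stop("dye_bias_coeffs must be three finite numbers (c0, c1, c2)",
         call. = FALSE)
  }
  if (cfg$body_length < cfg$snps_per_transcript) {
    stop("body_length must allow distinct SNP positions", call. = FALSE)
  }
  if (cfg$flank < 0L) stop("flank must be >= 0", call. = FALSE)
  cfg
}

#' Simulate phased genotypes for one SNP under Hardy-Weinberg equilibrium
#'
#' Each sample's two haplotype alleles are drawn independently with
#' minor-allele probability `maf`; the genotype is the haplotype sum.
#'
#' @param n_samples number of samples.
#' @param maf minor-allele frequency, in (0, 0.5].
#' @param seed optional integer seed.
#' @return list with integer vectors `hap1`, `hap2` (0 = reference allele,
#'   1 = minor allele) and `gt = hap1 + hap2`.
#' @examples
#' g <- simulate_genotypes(100, maf = 0.3, seed = 1)
#' table(g$gt)
#' @export
simulate_genotypes <- function(n_samples, maf, seed = NULL) {
  if (!is.numeric(maf) || length(maf) != 1L || !is.finite(maf) ||
      maf <= 0 || maf > 0.5) {
    stop("`maf` must be a finite frequency in (0, 0.5]", call. = FALSE)
  }
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  hap1 <- stats::rbinom(n_samples, 1L, maf)
  hap2 <- stats::rbinom(n_samples, 1L, maf)
  list(hap1 = hap1, hap2 = hap2, gt = hap1 + hap2)
}

#' Simulate a complete synthetic cohort with known ground truth
#'
#' Generates transcript models on spaced genomic positions, phased HWE
#' genotypes for body and flank SNPs, two-channel gDNA and cDNA allele
#' signals (cDNA only for transcribed body SNPs), a normalized total
#' expression matrix, age/sex covariates and a truth table naming each
#' transcript's causal cis-rSNP (if any).
#'
#' For a causal transcript, heterozygotes at the causal SNP over-express the
#' haplotype carrying the minor allele: at every heterozygous body SNP of such
#' a sample the cDNA fraction of the allele on the over-expressed haplotype is
#' shifted to `0.5 + ase_effect`. Total expression gains
#' `gte_effect * dosage` at the causal SNP. Both signal channels are
#' distorted by the configured quadratic dye bias before emission.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `ase_cohort`: a list with phased genotype
#'   matrices (`gt`, `hap1`, `hap2`, `phased`; SNPs x samples), `sites`
#'   and `transcripts` tables, `gdna`/`cdna` two-channel signal matrices,
#'   `expression` (transcripts x samples), `covariates`, `samples`, `truth`
#'   (causal table plus unmasked truth haplotypes) and the `config`.
#' @examples
#' co <- simulate_cohort(sim_config(n_samples = 20, n_transcripts = 4, seed = 1))
#' dim(co$gt)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)

  n <- config$n_samples
  nt <- config$n_transcripts
  samples <- sprintf("S%04d", seq_len(n))

  ## transcript models: 20 per chromosome, spaced 400 kb so that 100 kb cis
  ## windows are disjoint while 500 kb windows reach the neighbours
  per_chrom <- 20L
  slot <- (seq_len(nt) - 1L) %% per_chrom
  tx_chrom <- paste0("chr", (seq_len(nt) - 1L) %/% per_chrom + 1L)
  tx_start <- 150000L + slot * 400000L
  tx_end <- tx_start + config$body_length
  tx_strand <- sample(c("+", "-"), nt, replace = TRUE)
  tx_id <- sprintf("tx%04d", seq_len(nt))
  transcripts <- data.frame(
    transcript = tx_id, chrom = tx_chrom, start = tx_start, end = tx_end,
    strand = tx_strand, stringsAsFactors = FALSE
  )

  ## SNP placement: body SNPs plus flank SNPs at the configured density
  nf <- as.integer(round(config$flank_snp_density * config$flank / 1000))
  site_list <- vector("list", nt)
  for (t in seq_len(nt)) {
    body_pos <- sort(sample.int(config$body_length, config$snps_per_transcript)) +
      tx_start[t] - 1L
    left_pos <- if (nf > 0L) {
      sort(tx_start[t] - sample.int(config$flank, nf))
    } else integer(0)
    right_pos <- if (nf > 0L) {
      sort(tx_end[t] + sample.int(config$flank, nf) - 1L)
    } else integer(0)
    pos <- c(left_pos, body_pos, right_pos)
    site_list[[t]] <- data.frame(
      chrom = tx_chrom[t], pos = pos,
      transcript = tx_id[t],
      role = rep(c("flank", "body", "flank"),
                 c(length(left_pos), length(body_pos), length(right_pos))),
      stringsAsFactors = FALSE
    )
  }
  sites <- do.call(rbind, site_list)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  n_snp <- nrow(sites)
  sites$snp <- sprintf("snp%05d", seq_len(n_snp))
  sites$ref <- "A"
  sites$alt <- "G"
  sites$maf <- stats::runif(n_snp, config$maf_range[1], config$maf_range[2])
  rownames(sites) <- sites$snp
  sites <- sites[, c("snp", "chrom", "pos", "ref", "alt", "maf",
                     "transcript", "role")]

  ## phased HWE genotypes; the alt allele is the (truth) minor allele
  hap1 <- matrix(stats::rbinom(n_snp * n, 1L, sites$maf), n_snp, n)
  hap2 <- matrix(stats::rbinom(n_snp * n, 1L, sites$maf), n_snp, n)
  gt <- hap1 + hap2
  dimnames(hap1) <- dimnames(hap2) <- dimnames(gt) <- list(sites$snp, samples)

  ## causal assignment: one SNP per causal transcript, uniform over its window
  is_causal <- stats::runif(nt) < config$causal_fraction
  causal_snp <- rep(NA_character_, nt)
  for (t in which(is_causal)) {
    cand <- which(sites$transcript == tx_id[t])
    causal_snp[t] <- sites$snp[cand[sample.int(length(cand), 1L)]]
  }
  truth_tab <- data.frame(
    transcript = tx_id, causal_snp = causal_snp,
    ase_effect = ifelse(is_causal, config$ase_effect, 0),
    gte_effect = ifelse(is_causal, config$gte_effect, 0),
    stringsAsFactors = FALSE
  )

  ## covariates and expression on the normalized (unit-noise) scale
  age <- as.integer(round(stats::runif(n, 18, 65)))
  sex <- stats::rbinom(n, 1L, 0.5)
  covariates <- data.frame(sample = samples, age = age, sex = sex,
                           stringsAsFactors = FALSE)
  expr <- matrix(stats::rnorm(nt * n), nt, n,
                 dimnames = list(tx_id, samples))
  expr <- expr + rep(config$age_effect * (age - 41.5), each = nt) +
    rep(config$sex_effect * sex, each = nt)
  for (t in which(is_causal)) {
    expr[t, ] <- expr[t, ] + config$gte_effect * gt[causal_snp[t], ]
  }

  ## per-(transcript, sample) over-expressed haplotype: +1 = hap1, -1 = hap2,
  ## 0 = balanced (non-causal transcript or sample homozygous at causal SNP)
  over_hap <- matrix(0, nt, n)
  for (t in which(is_causal)) {
    cs <- causal_snp[t]
    het <- gt[cs, ] == 1L
    over_hap[t, het] <- ifelse(hap1[cs, het] == 1L, 1, -1)
  }

  ## gDNA allele-1 (reference) fractions: genotype-implied value plus noise
  g_frac <- (2L - gt) / 2 + stats::rnorm(n_snp * n, sd = config$gdna_ratio_sd)

  ## cDNA fractions: only transcript-body SNPs are transcribed
  c_frac <- matrix(NA_real_, n_snp, n)
  c_sd <- sqrt(config$gdna_ratio_sd^2 + config$rna_region_sd^2)
  for (t in seq_len(nt)) {
    rows <- which(sites$transcript == tx_id[t] & sites$role == "body")
    G <- gt[rows, , drop = FALSE]
    base <- (2L - G) / 2
    het <- G == 1L
    ref_on_hap1 <- hap1[rows, , drop = FALSE] == 0L
    O <- matrix(over_hap[t, ], nrow = length(rows), ncol = n, byrow = TRUE)
    shift <- config$ase_effect * O * ifelse(ref_on_hap1, 1, -1)
    f <- base
    f[het] <- 0.5 + shift[het]
    c_frac[rows, ] <- f + stats::rnorm(length(rows) * n, sd = c_sd)
  }

  ## two-channel intensities with the quadratic dye bias
  cb <- config$dye_bias_coeffs
  emit <- function(frac, log_total) {
    total <- 10^log_total
    fobs <- clip01(frac + cb[1] + cb[2] * log_total + cb[3] * log_total^2)
    a1 <- fobs * total
    list(a1 = a1, a2 = total - a1)
  }
  g_log_total <- matrix(stats::runif(n_snp * n, 2, 4), n_snp, n)
  gdna <- emit(clip01(g_frac), g_log_total)
  c_log_total <- matrix(stats::runif(n_snp * n, 2, 4), n_snp, n)
  cdna <- emit(clip01(c_frac), c_log_total)
  cdna$a1[is.na(c_frac)] <- 0
  cdna$a2[is.na(c_frac)] <- 0
  dimnames(gdna$a1) <- dimnames(gdna$a2) <- list(sites$snp, samples)
  dimnames(cdna$a1) <- dimnames(cdna$a2) <- list(sites$snp, samples)

  ## truth haplotypes kept before masking/switching
  truth <- list(table = truth_tab, hap1 = hap1, hap2 = hap2)

  cohort <- structure(list(
    gt = gt, hap1 = hap1, hap2 = hap2,
    phased = matrix(TRUE, n_snp, n, dimnames = list(sites$snp, samples)),
    sites = sites, transcripts = transcripts,
    gdna = gdna, cdna = cdna,
    expression = expr, covariates = covariates,
    samples = samples, truth = truth, config = config
  ), class = "ase_cohort")

  ## optional switch errors at generation time
  if (config$switch_error_rate > 0) {
    cohort <- introduce_phasing_errors(cohort, config$switch_error_rate)
  }

  ## missing genotype calls (MCAR), masking genotype and phase but not signals
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n_snp * n) < config$missing_rate, n_snp, n)
    cohort$gt[miss] <- NA_integer_
    cohort$hap1[miss] <- NA_integer_
    cohort$hap2[miss] <- NA_integer_
    cohort$phased[miss] <- FALSE
  }
  cohort
}

#' @export
print.ase_cohort <- function(x, ...) {
  cat(sprintf(
    "ase_cohort: %d samples, %d SNPs, %d transcripts (%d causal)\n",
    length(x$samples), nrow(x$sites), nrow(x$transcripts),
    sum(!is.na(x$truth$table$causal_snp))
  ))
  invisible(x)
}

#' Introduce switch errors into the haplotype phase
#'
#' Each heterozygous, phased call's haplotype assignment is flipped
#' independently with probability `switch_error_rate`. Genotypes are
#' unchanged; only the phase is perturbed.
#'
#' @param cohort an `ase_cohort` (or any list with `gt`, `hap1`, `hap2`
#'   matrices).
#' @param switch_error_rate per-heterozygote flip probability in \[0, 1\].
#' @param seed optional integer seed.
#' @return the cohort with perturbed `hap1`/`hap2`.
#' @export
introduce_phasing_errors <- function(cohort, switch_error_rate, seed = NULL) {
  stop_if_not_prob(switch_error_rate, "switch_error_rate")
  if (!is.null(seed)) set.seed(seed)
  het <- which(cohort$gt == 1L & !is.na(cohort$gt))
  flip <- het[stats::runif(length(het)) < switch_error_rate]
  if (length(flip)) {
    tmp <- cohort$hap1[flip]
    cohort$hap1[flip] <- cohort$hap2[flip]
    cohort$hap2[flip] <- tmp
  }
  cohort
}
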