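test_that("allele fractions follow the two-channel definition", {
  expect_equal(allele_fraction(50, 50), 0.5)
  expect_equal(allele_fraction(100, 0), 1.0)
  expect_equal(allele_fraction(60, 40), 0.6)
  expect_true(is.na(allele_fraction(0, 0)))   # missing, never 0 or 0.5
})

test_that("per-SNP ASE level is the cDNA minus gDNA fraction difference", {
  expect_equal(snp_ase_level(50, 50, 50, 50), 0)
  expect_equal(snp_ase_level(100, 0, 50, 50), 0.5)
  expect_equal(snp_ase_level(60, 40, 55, 45), 0.05)
  expect_true(all(abs(snp_ase_level(runif(50, 1, 100), runif(50, 1, 100),
                                    runif(50, 1, 100), runif(50, 1, 100))) <= 1))
})

test_that("phase orientation flips signs consistently and is an involution", {
  expect_equal(orient_by_phase(0.2, TRUE), 0.2)
  expect_equal(orient_by_phase(0.2, FALSE), -0.2)
  v <- c(-0.3, 0.1, 0.25)
  on1 <- c(TRUE, FALSE, FALSE)
  expect_equal(orient_by_phase(orient_by_phase(v, on1), on1), v)
})

make_array <- function(n_het, coefs, noise_sd = 0.01, seed = 1) {
  # one-sample arrays with known dye bias on the fractions
  set.seed(seed)
  tt <- runif(n_het, 2, 4)
  f_true <- 0.5
  f_obs <- f_true + coefs[1] + coefs[2] * tt + coefs[3] * tt^2 +
    rnorm(n_het, sd = noise_sd)
  total <- 10^tt
  gdna <- list(a1 = cbind(f_obs * total), a2 = cbind((1 - f_obs) * total))
  ct <- runif(n_het, 2, 4)
  fc <- f_true + coefs[1] + coefs[2] * ct + coefs[3] * ct^2 +
    rnorm(n_het, sd = noise_sd)
  cdna <- list(a1 = cbind(fc * 10^ct), a2 = cbind((1 - fc) * 10^ct))
  list(gdna = gdna, cdna = cdna, het = matrix(TRUE, n_het, 1))
}

test_that("quadratic normalization recovers injected dye bias", {
  # no injected bias: fitted coefficients ~ 0 and corrected ~ raw
  a0 <- make_array(2000, c(0, 0, 0), noise_sd = 0.01, seed = 2)
  n0 <- normalize_fractions(a0$gdna, a0$cdna, a0$het)
  expect_lt(max(abs(n0$coefficients)), 0.05)
  raw <- allele_fraction(a0$gdna$a1, a0$gdna$a2)
  expect_lt(max(abs(n0$gdna_frac - raw)), 0.01)

  # constant bias only: fitted curve is ~ 0.05 across the intensity range
  ac <- make_array(2000, c(0.05, 0, 0), noise_sd = 0.005, seed = 3)
  nc <- normalize_fractions(ac$gdna, ac$cdna, ac$het)
  b <- nc$coefficients[, 1]
  tt <- seq(2, 4, length.out = 9)
  expect_equal(unname(b[1] + b[2] * tt + b[3] * tt^2), rep(0.05, 9),
               tolerance = 0.01)

  # generator-style quadratic bias: post-correction het mean back at 0.5
  ag <- make_array(2000, c(0.03, -0.01, 0.002), noise_sd = 0.014, seed = 4)
  ng <- normalize_fractions(ag$gdna, ag$cdna, ag$het)
  expect_lt(abs(mean(ng$gdna_frac) - 0.5), 0.005)
})

test_that("normalization is skipped with a warning on thin het support", {
  a <- make_array(10, c(0.05, 0, 0), seed = 5)
  expect_warning(n <- normalize_fractions(a$gdna, a$cdna, a$het),
                 "skipped")
  expect_equal(n$gdna_frac, allele_fraction(a$gdna$a1, a$gdna$a2))
  expect_true(all(is.na(n$coefficients)))
})

test_that("informative-SNP filter excludes thin transcripts at 5 but keeps them at 3", {
  co <- small_cohort(seed = 12, snps_per_transcript = 4L,
                     maf_range = c(0.2, 0.5), missing_rate = 0)
  a5 <- quantify_ase(co, min_informative = 5L)
  a3 <- quantify_ase(co, min_informative = 3L)
  expect_length(a5$kept, 0)
  expect_true(all(a3$informative <= 4))
  expect_gt(length(a3$kept), 0)
  expect_true(all(a5$kept %in% a3$kept))
})

test_that("noise-free causal heterozygotes recover the exact effect size", {
  e <- 0.25
  co <- small_cohort(seed = 13, causal_fraction = 1, ase_effect = e,
                     gdna_ratio_sd = 0, rna_region_sd = 0,
                     dye_bias_coeffs = c(0, 0, 0), missing_rate = 0)
  ase <- quantify_ase(co)
  tt <- co$truth$table
  for (t in seq_len(nrow(tt))) {
    if (!(tt$transcript[t] %in% ase$kept)) next
    cs <- tt$causal_snp[t]
    for (s in seq_along(co$samples)) {
      v <- ase$ase[tt$transcript[t], s]
      if (is.na(v)) next
      if (co$gt[cs, s] == 1L) {
        expect_equal(abs(v), e, tolerance = 1e-10)
      } else {
        expect_equal(v, 0, tolerance = 1e-10)
      }
    }
  }
})

test_that("transcript aggregation averages oriented levels and stays in range", {
  co <- small_cohort(seed = 14)
  am <- quantify_ase(co, aggregate = "mean")
  amed <- quantify_ase(co, aggregate = "median")
  expect_true(all(abs(am$ase) <= 1, na.rm = TRUE))
  # aggregation never exceeds the range of its per-SNP inputs
  tx <- co$transcripts
  for (t in sample(which(tx$transcript %in% am$kept), 5)) {
    body <- which(co$sites$chrom == tx$chrom[t] &
                    co$sites$pos >= tx$start[t] & co$sites$pos < tx$end[t])
    for (s in sample(seq_along(co$samples), 5)) {
      lv <- am$levels[body, s]
      lv <- lv[!is.na(lv)]
      v <- am$ase[tx$transcript[t], s]
      if (!length(lv)) {
        expect_true(is.na(v))
      } else {
        expect_gte(v, min(lv) - 1e-12)
        expect_lte(v, max(lv) + 1e-12)
        expect_equal(v, mean(lv), tolerance = 1e-12)
        expect_equal(amed$ase[tx$transcript[t], s], median(lv),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("region SD QC applies the two-point SD rule and stays quiet on clean data", {
  # hand case: levels (0.0, 0.4) in one sample: SD 0.283 > |mean| 0.2
  expect_equal(sd(c(0, 0.4)), 0.2828427, tolerance = 1e-6)
  lev <- matrix(c(0, 0.4), 2, 1, dimnames = list(c("s1", "s2"), "S1"))
  fake_ase <- structure(list(levels = lev, kept = "t1"),
                        class = "transcript_ase")
  fake_co <- list(
    transcripts = data.frame(transcript = "t1", chrom = "chr1",
                             start = 0L, end = 100L, strand = "+"),
    sites = data.frame(snp = c("s1", "s2"), chrom = "chr1", pos = c(10L, 20L))
  )
  qc <- region_sd_qc(fake_ase, fake_co)
  expect_equal(qc$frac_exceed, 1)
  expect_true(qc$flagged)

  # constant levels within a region: SD 0, never flagged
  fake_ase$levels[] <- 0.3
  qc0 <- region_sd_qc(fake_ase, fake_co)
  expect_false(qc0$flagged)

  # with a real effect well above the region noise, few transcripts flagged
  co <- small_cohort(seed = 15, causal_fraction = 1, ase_effect = 0.3)
  a <- quantify_ase(co)
  qc_sim <- region_sd_qc(a, co)
  expect_lt(mean(qc_sim$flagged), 0.5)
})
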