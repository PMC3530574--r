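test_that("cis windows select SNPs by position with chromosome-start clipping", {
  sites <- data.frame(
    snp = sprintf("s%d", 1:6), chrom = "chr1",
    pos = c(50000L, 99999L, 100000L, 250000L, 310000L, 310001L)
  )
  tx <- data.frame(transcript = "t1", chrom = "chr1",
                   start = 200000L, end = 210001L, strand = "+")
  w <- cis_window(tx, 100000L)
  expect_equal(w$window_start, 100000L)
  expect_equal(w$window_end, 310000L)
  got <- select_test_snps(w[1, ], sites)
  expect_setequal(got$snp, c("s3", "s4", "s5"))

  # window clipped at the chromosome start
  tx0 <- data.frame(transcript = "t0", chrom = "chr1",
                    start = 30000L, end = 40000L, strand = "+")
  w0 <- cis_window(tx0, 100000L)
  expect_equal(w0$window_start, 0L)

  # 500 kb windows select a superset of the 100 kb windows
  wide <- select_test_snps(cis_window(tx, 500000L)[1, ], sites)
  expect_true(all(got$snp %in% wide$snp))
  expect_gt(nrow(wide), nrow(got))
})

test_that("phase groups code heterozygotes by the minor-allele haplotype", {
  #          0|1  1|0  1|1  0|0  ./.  0/1(unphased)
  gt <-    c(1L,  1L,  2L,  0L,  NA,  1L)
  hap1 <-  c(0L,  1L,  1L,  0L,  NA,  0L)
  phased <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  x <- ase_groups(gt, hap1, phased, minor_is_alt = TRUE)
  expect_equal(x, c(-1, 1, 0, 0, NA, NA))
  # when the reference allele is the cohort minor allele, codes flip
  x2 <- ase_groups(gt, hap1, phased, minor_is_alt = FALSE)
  expect_equal(x2, c(1, -1, 0, 0, NA, NA))
})

test_that("ASE group-size filter skips under-populated tests", {
  set.seed(1)
  x <- c(rep(-1, 3), rep(1, 10), rep(0, 20))
  y <- rnorm(33)
  expect_null(ase_association(y, x, min_group = 4))          # hetA = 3 < 4
  expect_false(is.null(ase_association(y, x, min_group = 3)))
  # one populated group only: never testable
  expect_null(ase_association(rnorm(30), rep(0, 30), min_group = 4))
  # require_all_groups demands all three populated
  x2 <- c(rep(1, 10), rep(0, 20))
  expect_false(is.null(ase_association(rnorm(30), x2, min_group = 4)))
  expect_null(ase_association(rnorm(30), x2, min_group = 4,
                              require_all_groups = TRUE))
})

test_that("perfect allelic signal yields slope 1 with vanishing p", {
  x <- c(rep(-1, 6), rep(0, 8), rep(1, 6))
  r <- ase_association(x, x, min_group = 4)
  expect_equal(r$slope, 1)
  expect_equal(r$p, 0)
})

test_that("zero response variance is flagged with missing p", {
  x <- c(rep(-1, 5), rep(0, 5), rep(1, 5))
  r <- ase_association(rep(0.2, 15), x)
  expect_true(r$degenerate)
  expect_true(is.na(r$p))
})

test_that("ASE regression matches the independent linear-model route", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    x <- sample(c(-1, 0, 1), n, replace = TRUE,
                prob = c(0.3, 0.4, 0.3))
    y <- 0.1 * x + rnorm(n, sd = 0.2)
    r <- ase_association(y, x, min_group = 1)
    if (is.null(r)) next
    ref <- summary(lm(y ~ x + 0))$coefficients
    expect_equal(r$slope, ref[1, 1], tolerance = 1e-10)
    expect_equal(r$se, ref[1, 2], tolerance = 1e-10)
    expect_equal(r$p, ref[1, 4], tolerance = 1e-10)
  }
})

test_that("GTE regression matches lm with covariates and applies its filter", {
  set.seed(43)
  n <- 80
  d <- sample(0:2, n, replace = TRUE, prob = c(0.45, 0.4, 0.15))
  age <- runif(n, 18, 65)
  sex <- rbinom(n, 1, 0.5)
  y <- 0.4 * d + 0.01 * age + 0.2 * sex + rnorm(n)
  r <- gte_association(y, d, age, sex)
  ref <- summary(lm(y ~ d + age + sex))$coefficients
  expect_equal(r$slope, ref["d", 1], tolerance = 1e-10)
  expect_equal(r$se, ref["d", 2], tolerance = 1e-10)
  expect_equal(r$p, ref["d", 4], tolerance = 1e-10)

  # group filter: dosage classes (2, 30, 30) rejected at min 3
  d2 <- c(rep(0, 2), rep(1, 30), rep(2, 30))
  expect_null(gte_association(rnorm(62), d2, min_group = 3))
  expect_false(is.null(gte_association(rnorm(62), d2, min_group = 2)))

  # constant covariate (single-sex subset) dropped with a warning
  expect_warning(
    r1 <- gte_association(y, d, age, rep(1, n)),
    "constant"
  )
  ref1 <- summary(lm(y ~ d + age))$coefficients
  expect_equal(r1$slope, ref1["d", 1], tolerance = 1e-10)
})

test_that("scan emits ordered records with correct strand-aware distances", {
  co <- small_cohort(seed = 16)
  ase <- quantify_ase(co)
  rec <- adjust_scan(run_scan(co, "ase", ase = ase))
  expect_gt(nrow(rec), 0)
  # deterministic order: transcript, then position
  expect_false(is.unsorted(order(rec$transcript, rec$pos)))
  expect_identical(rec, adjust_scan(run_scan(co, "ase", ase = ase)))

  tx <- co$transcripts
  i <- match(rec$transcript, tx$transcript)
  plus <- tx$strand[i] == "+"
  tss <- ifelse(plus, tx$start[i], tx$end[i] - 1L)
  tts <- ifelse(plus, tx$end[i] - 1L, tx$start[i])
  expect_equal(rec$dist_tss, ifelse(plus, rec$pos - tss, tss - rec$pos))
  expect_equal(rec$dist_tts, ifelse(plus, rec$pos - tts, tts - rec$pos))
  # flank SNPs upstream of the TSS have negative distance
  expect_true(any(rec$dist_tss < 0) && any(rec$dist_tss > 0))
})

test_that("raising the group threshold never increases the number of tests", {
  co <- small_cohort(seed = 17)
  ase <- quantify_ase(co)
  n_prev <- Inf
  for (mg in c(1L, 2L, 4L, 8L, 16L)) {
    n_now <- nrow(run_scan(co, "ase", ase = ase, min_group = mg))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("relabelling a sample's haplotypes leaves every ASE p-value unchanged", {
  # run without the group-size filter: the regression itself is exactly
  # label-invariant, while the filter's per-group counts (which samples sit
  # in the +1 vs -1 het group) legitimately depend on the labels
  co <- small_cohort(seed = 18, missing_rate = 0)
  rec <- run_scan(co, "ase", ase = quantify_ase(co), min_group = 1L)
  co_f <- flip_sample_haps(co, 7L)
  rec_f <- run_scan(co_f, "ase", ase = quantify_ase(co_f), min_group = 1L)
  expect_identical(paste(rec$transcript, rec$snp),
                   paste(rec_f$transcript, rec_f$snp))
  expect_equal(rec$p, rec_f$p, tolerance = 1e-12)
  expect_equal(abs(rec$slope), abs(rec_f$slope), tolerance = 1e-12)
})

test_that("the 500 kb flank variant multiplies the number of tests", {
  co <- small_cohort(seed = 19)
  ase <- quantify_ase(co)
  n_narrow <- nrow(run_scan(co, "ase", ase = ase, flank = 100000L))
  n_wide <- nrow(run_scan(co, "ase", ase = ase, flank = 500000L))
  expect_gt(n_wide, n_narrow)
})

test_that("the causal SNP attains the window minimum p in most transcripts", {
  co <- simulate_cohort(sim_config(
    n_samples = 188L, n_transcripts = 40L, causal_fraction = 1,
    ase_effect = 0.3, maf_range = c(0.1, 0.5), seed = 23
  ))
  ase <- quantify_ase(co)
  rec <- run_scan(co, "ase", ase = ase)
  tt <- co$truth$table
  hits <- 0L
  total <- 0L
  for (t in seq_len(nrow(tt))) {
    sub <- rec[rec$transcript == tt$transcript[t] & !is.na(rec$p), ]
    if (!nrow(sub) || !(tt$causal_snp[t] %in% sub$snp)) next
    total <- total + 1L
    if (sub$snp[which.min(sub$p)] == tt$causal_snp[t]) hits <- hits + 1L
  }
  expect_gt(total, 20)
  expect_gte(hits / total, 0.9)
})
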