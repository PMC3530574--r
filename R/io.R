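# Readers/writers for the package's on-disk artifacts. Internal coordinates
# are 0-based (BED-style half-open transcript intervals); VCF positions are
# 1-based and converted on the way in/out. Floats are written with 12
# significant digits so write-then-read round-trips to full working
# precision.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.12g", x))
}

#' Write phased genotypes as VCF 4.2
#'
#' Emits biallelic SNP records with phased GT (`h1|h2`), missing calls as
#' `./.`, and the (truth) minor-allele frequency in the INFO field.
#'
#' @param cohort an `ase_cohort` (or a list with `gt`, `hap1`, `hap2`,
#'   `phased`, `sites`, `samples`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(cohort, path) {
  s <- cohort$sites
  n_snp <- nrow(s)
  gt_str <- matrix("./.", n_snp, length(cohort$samples))
  known <- !is.na(cohort$gt)
  sep <- ifelse(cohort$phased, "|", "/")
  gt_str[known] <- paste0(cohort$hap1[known], sep[known], cohort$hap2[known])
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=asepower",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  )
  body <- paste(
    s$chrom, s$pos + 1L, s$snp, s$ref, s$alt, ".", "PASS",
    sprintf("MAF=%.6g", s$maf), "GT",
    apply(gt_str, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into genotype/haplotype matrices
#'
#' Biallelic SNPs only (multi-allelic sites are skipped with a warning).
#' `|` marks phased calls, `/` unphased; `./.` is missing. VCF 1-based
#' positions become internal 0-based positions.
#'
#' @param path VCF file path.
#' @return list with `gt`, `hap1`, `hap2`, `phased` matrices
#'   (SNPs x samples), `sites` table (with `maf` from INFO when present)
#'   and `samples`.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipped %d multi-allelic site(s)", sum(multi)),
            call. = FALSE)
  }
  keep <- !multi
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt_raw <- gt_raw[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  samples <- colnames(gt_raw)
  phased <- matrix(grepl("|", gt_raw, fixed = TRUE), nrow(gt_raw))
  alleles <- gsub("[|/]", " ", gt_raw)
  a1 <- suppressWarnings(as.integer(vapply(
    strsplit(alleles, " "), `[`, character(1), 1L)))
  a2 <- suppressWarnings(as.integer(vapply(
    strsplit(alleles, " "), `[`, character(1), 2L)))
  hap1 <- matrix(a1, nrow(gt_raw))
  hap2 <- matrix(a2, nrow(gt_raw))
  gt <- hap1 + hap2
  miss <- is.na(gt)
  phased[miss] <- FALSE
  info <- fix[, "INFO"]
  maf <- suppressWarnings(as.numeric(sub(".*MAF=([0-9eE.+-]+).*", "\\1", info)))
  sites <- data.frame(
    snp = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L,
    ref = fix[, "REF"], alt = fix[, "ALT"], maf = maf,
    stringsAsFactors = FALSE
  )
  rownames(sites) <- sites$snp
  dimnames(gt) <- dimnames(hap1) <- dimnames(hap2) <- dimnames(phased) <-
    list(sites$snp, samples)
  list(gt = gt, hap1 = hap1, hap2 = hap2, phased = phased,
       sites = sites, samples = samples)
}

write_signal_tsv <- function(signal, samples, path) {
  df <- data.frame(snp = rownames(signal$a1), stringsAsFactors = FALSE)
  for (j in seq_along(samples)) {
    df[[paste0(samples[j], ".A1")]] <- fmt_num(signal$a1[, j])
    df[[paste0(samples[j], ".A2")]] <- fmt_num(signal$a2[, j])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_signal_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- names(df)[-1L]
  samples <- unique(sub("\\.A[12]$", "", cols))
  a1 <- as.matrix(df[, paste0(samples, ".A1"), drop = FALSE])
  a2 <- as.matrix(df[, paste0(samples, ".A2"), drop = FALSE])
  dimnames(a1) <- dimnames(a2) <- list(df$snp, samples)
  list(a1 = a1, a2 = a2)
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), stringsAsFactors = FALSE)
  names(df) <- id_col
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmt_num(m[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  m
}

#' Write a synthetic cohort to a directory of standard-format files
#'
#' Phased genotypes as VCF 4.2, transcript models as BED6 (0-based
#' half-open, strand in column 6), gDNA/cDNA two-channel signal matrices and
#' the expression matrix as TSV (two columns per sample for the signals),
#' covariates and the ground-truth table as TSV.
#'
#' @param cohort an `ase_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_phased_vcf(cohort, file.path(dir, "genotypes.vcf"))
  tx <- cohort$transcripts
  utils::write.table(
    data.frame(tx$chrom, tx$start, tx$end, tx$transcript, 0L, tx$strand),
    file.path(dir, "transcripts.bed"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  write_signal_tsv(cohort$gdna, cohort$samples, file.path(dir, "gdna_signals.tsv"))
  write_signal_tsv(cohort$cdna, cohort$samples, file.path(dir, "cdna_signals.tsv"))
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"),
                   "transcript")
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$table, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return an `ase_cohort` (without the generator's truth haplotype
#'   matrices; the truth table is retained).
#' @export
read_cohort <- function(dir) {
  geno <- read_phased_vcf(file.path(dir, "genotypes.vcf"))
  bed <- utils::read.delim(file.path(dir, "transcripts.bed"), header = FALSE,
                           stringsAsFactors = FALSE)
  transcripts <- data.frame(
    transcript = bed$V4, chrom = bed$V1, start = bed$V2, end = bed$V3,
    strand = bed$V6, stringsAsFactors = FALSE
  )
  covariates <- utils::read.delim(file.path(dir, "covariates.tsv"),
                                  stringsAsFactors = FALSE)
  truth_tab <- utils::read.delim(file.path(dir, "truth.tsv"),
                                 stringsAsFactors = FALSE)
  structure(list(
    gt = geno$gt, hap1 = geno$hap1, hap2 = geno$hap2, phased = geno$phased,
    sites = geno$sites, transcripts = transcripts,
    gdna = read_signal_tsv(file.path(dir, "gdna_signals.tsv")),
    cdna = read_signal_tsv(file.path(dir, "cdna_signals.tsv")),
    expression = read_matrix_tsv(file.path(dir, "expression.tsv")),
    covariates = covariates, samples = geno$samples,
    truth = list(table = truth_tab), config = NULL
  ), class = "ase_cohort")
}

#' Cross-platform genotype concordance
#'
#' Compares two genotype matrices (SNPs x samples, 0/1/2/NA) over their
#' shared SNPs and samples, excluding missing calls from the denominator.
#'
#' @param a,b genotype matrices with SNP rownames and sample colnames.
#' @return list with `call_discordance` (fraction of discordant non-missing
#'   overlapping calls), `snp_discordance` (fraction of shared SNPs with at
#'   least one discordant call), `n_calls`, `n_snps`.
#' @export
genotype_concordance <- function(a, b) {
  snps <- intersect(rownames(a), rownames(b))
  samples <- intersect(colnames(a), colnames(b))
  if (!length(snps) || !length(samples)) {
    stop("no shared SNPs/samples between the two genotype sets",
         call. = FALSE)
  }
  aa <- a[snps, samples, drop = FALSE]
  bb <- b[snps, samples, drop = FALSE]
  ok <- !is.na(aa) & !is.na(bb)
  disc <- ok & (aa != bb)
  snp_hit <- rowSums(disc) > 0L
  list(
    call_discordance = sum(disc) / sum(ok),
    snp_discordance = mean(snp_hit),
    n_calls = sum(ok),
    n_snps = length(snps)
  )
}

#' Load and validate a pipeline configuration
#'
#' YAML file with optional blocks `simulation` (fields of [sim_config()]),
#' `analysis` (`flank`, `min_informative`, `min_group_ase`, `min_group_gte`,
#' `aggregate`), `permutation` (`n_permutations`) and `power`
#' (`sample_sizes`, `n_runs`). Unknown fields are rejected with a
#' field-level message.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return validated configuration list with defaults filled in.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    yaml::read_yaml(path)
  } else path
  defaults <- list(
    simulation = list(),
    analysis = list(flank = 100000L, min_informative = 5L,
                    min_group_ase = 4L, min_group_gte = 3L,
                    aggregate = "mean"),
    permutation = list(n_permutations = 100L),
    power = list(sample_sizes = NULL, n_runs = 10L)
  )
  bad_blocks <- setdiff(names(cfg), names(defaults))
  if (length(bad_blocks)) {
    stop(sprintf("unknown config block(s): %s",
                 paste(bad_blocks, collapse = ", ")), call. = FALSE)
  }
  sim_fields <- names(formals(sim_config))
  bad_sim <- setdiff(names(cfg$simulation), sim_fields)
  if (length(bad_sim)) {
    stop(sprintf("unknown simulation field(s): %s",
                 paste(bad_sim, collapse = ", ")), call. = FALSE)
  }
  for (blk in c("analysis", "permutation", "power")) {
    bad <- setdiff(names(cfg[[blk]]), names(defaults[[blk]]))
    if (length(bad)) {
      stop(sprintf("unknown %s field(s): %s", blk,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    cfg[[blk]] <- utils::modifyList(defaults[[blk]], cfg[[blk]] %||% list())
  }
  cfg
}

#' Run the full pipeline end to end
#'
#' simulate -> quantify -> scan (ASE and GTE) -> multiple-testing
#' correction -> permutation null -> power summary, writing every artifact
#' under `out_dir`. Association TSVs carry `#`-prefixed provenance header
#' lines recording the seed and the test count `m`. Re-running with the
#' same configuration and seed reproduces the outputs.
#'
#' @param config a [load_config()] result, a path to a YAML config, or a
#'   plain list in the same structure.
#' @param out_dir output directory.
#' @param seed integer seed (overrides the simulation block's seed).
#' @return list with the in-memory objects (`cohort`, `ase`, `scan_ase`,
#'   `scan_gte`, `null_ase`, `power`), invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$simulation$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  message("simulating cohort (seed ", cfg$simulation$seed %||% 1L, ")")
  cohort <- simulate_cohort(do.call(sim_config, cfg$simulation))
  write_cohort(cohort, file.path(out_dir, "cohort"))

  message("quantifying transcript ASE")
  ase <- quantify_ase(cohort, min_informative = cfg$analysis$min_informative,
                      aggregate = cfg$analysis$aggregate)
  write_matrix_tsv(ase$ase, file.path(out_dir, "transcript_ase.tsv"),
                   "transcript")
  utils::write.table(region_sd_qc(ase, cohort),
                     file.path(out_dir, "region_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  write_scan <- function(rec, path) {
    hdr <- c(
      sprintf("# asepower association scan (%s)", rec$method[1] %||% "empty"),
      sprintf("# n_samples=%d", attr(rec, "n_samples") %||% NA_integer_),
      sprintf("# m=%d retained tests", attr(rec, "m"))
    )
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(
      rec, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE
    ))
  }
  message("running ASE scan")
  scan_ase <- adjust_scan(run_scan(cohort, "ase", ase = ase,
                                   flank = cfg$analysis$flank,
                                   min_group = cfg$analysis$min_group_ase))
  message("  m = ", attr(scan_ase, "m"), " retained ASE tests")
  write_scan(scan_ase, file.path(out_dir, "scan_ase.tsv"))
  message("running GTE scan")
  scan_gte <- adjust_scan(run_scan(cohort, "gte",
                                   flank = cfg$analysis$flank,
                                   min_group = cfg$analysis$min_group_gte))
  message("  m = ", attr(scan_gte, "m"), " retained GTE tests")
  write_scan(scan_gte, file.path(out_dir, "scan_gte.tsv"))

  message("permutation null calibration (",
          cfg$permutation$n_permutations, " permutations)")
  null_ase <- null_calibration(cohort, "ase", ase = ase,
                               n_permutations = cfg$permutation$n_permutations,
                               seed = (cfg$simulation$seed %||% 1L) + 1L,
                               flank = cfg$analysis$flank)
  jsonlite::write_json(
    list(method = "ase", n_tests = null_ase$n_tests,
         frac_below_05 = null_ase$frac_below_05,
         ks_stat = null_ase$ks_stat, ks_p = null_ase$ks_p,
         qq = qq_points(null_ase, 100L)),
    file.path(out_dir, "null_calibration.json"),
    auto_unbox = TRUE, digits = NA
  )

  message("power summary")
  sizes <- cfg$power$sample_sizes %||% length(cohort$samples)
  pw <- power_table(cohort, ase, sizes = sizes, n_runs = cfg$power$n_runs,
                    seed = (cfg$simulation$seed %||% 1L) + 2L,
                    flank = cfg$analysis$flank)
  utils::write.table(pw, file.path(out_dir, "power_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(maf_power_curve(scan_ase),
                     file.path(out_dir, "maf_curve_ase.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(maf_power_curve(scan_gte),
                     file.path(out_dir, "maf_curve_gte.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(cohort = cohort, ase = ase, scan_ase = scan_ase,
                 scan_gte = scan_gte, null_ase = null_ase, power = pw))
}
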