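#' Write / read an additive genotype table (TSV)
#'
#' Rows are samples, columns rsIDs, cells are minor-allele dosages 0/1/2 or
#' `NA`; the first column is `sample_id`.
#'
#' @param genotypes Samples-by-SNPs numeric matrix with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- tibble::as_tibble(genotypes, rownames = "sample_id")
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @return For the reader: a numeric matrix with sample IDs as rownames.
#' @export
read_genotypes_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- df[[1]]
  g
}

#' Write / read the phenotype table (CSV)
#'
#' Columns: `sample_id`, `sex` (0/1), `age` (years), `bmi` (kg/m^2), `fpg`
#' (mg/dL), `hba1c` (%), `pg2h` (mg/dL), `dm_history` (0/1), `onset_age`
#' (years or NA), `status` (case/control/NA). Excluded subjects are written
#' with `status = NA` and read back as `"excluded"`.
#'
#' @param cohort Tibble with the columns above (`status` may use "excluded").
#' @param path Output file path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_phenotypes_csv <- function(cohort, path) {
  out <- cohort
  if ("status" %in% names(out)) {
    out$status[out$status == "excluded"] <- NA_character_
  }
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = "NA")
  if ("status" %in% names(df)) {
    df$status[is.na(df$status)] <- "excluded"
  }
  df
}

#' Export genotypes as a minimal VCF
#'
#' One biallelic record per SNP (GT field only); dosages 0/1/2 map to
#' `0/0`, `0/1`, `1/1` and missing calls to `./.`.
#'
#' @param genotypes Samples-by-SNPs numeric matrix with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=psmsnp",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes))) {
    d <- genotypes[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1])
    writeLines(paste(c("1", j, colnames(genotypes)[j], "A", "G", ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into an additive dosage matrix
#'
#' Counts ALT alleles in the GT field (0/1/2; missing `./.` becomes `NA`).
#' Requires the vcfR package.
#'
#' @param path Path to a VCF file.
#' @return A samples-by-SNPs numeric matrix.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_dosage() requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]))
  })
  t(dos)
}

#' Write a synthetic cohort to disk
#'
#' Writes `genotypes.tsv`, `phenotypes.csv`, `truth.json` and `config.json`
#' (plus `genotypes.vcf` if requested) into a directory. Files round-trip
#' losslessly through [read_cohort()].
#'
#' @param cohort A `psm_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @param vcf Also write a VCF export of the genotypes.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, vcf = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genotypes_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_phenotypes_csv(cohort$cohort, file.path(dir, "phenotypes.csv"))
  readr::write_tsv(cohort$annotation, file.path(dir, "annotation.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"))
  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (vcf) write_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory containing `genotypes.tsv` and `phenotypes.csv`.
#' @return A `psm_cohort` (config restored when `config.json` is present).
#' @export
read_cohort <- function(dir) {
  genotypes <- read_genotypes_tsv(file.path(dir, "genotypes.tsv"))
  cohort <- read_phenotypes_csv(file.path(dir, "phenotypes.csv"))
  ann_path <- file.path(dir, "annotation.tsv")
  annotation <- if (file.exists(ann_path)) {
    readr::read_tsv(ann_path, show_col_types = FALSE)
  } else NULL
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    lapply(jsonlite::read_json(truth_path), unlist)
  } else NULL
  cfg_path <- file.path(dir, "config.json")
  config <- NULL
  seed_used <- NA_integer_
  if (file.exists(cfg_path)) {
    raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    config <- structure(raw, class = "sim_config")
    config$gamma_demo <- stats::setNames(as.numeric(raw$gamma_demo),
                                         c("sex", "age", "bmi"))
    seed_used <- config$seed
  }
  structure(list(genotypes = genotypes, cohort = cohort, truth = truth,
                 annotation = annotation, config = config,
                 seed_used = seed_used),
            class = "psm_cohort")
}
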