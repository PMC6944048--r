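#' Candidate SNP set
#'
#' Constructor used by the three set recipes; users normally call
#' [build_kare_set()], [build_gwas_kare_set()] or [build_catagene_set()].
#'
#' @param name Set label, e.g. `"KARE-500"`.
#' @param rsids Ordered rsID vector (no duplicates).
#' @param recipe One of `"kare"`, `"gwas_kare"`, `"catagene"`.
#' @param k Target size (length of `rsids` is at most `k`).
#' @return An object of class `snp_set`.
#' @export
snp_set <- function(name, rsids, recipe, k) {
  assert_that(!anyDuplicated(rsids), "rsids must be unique")
  assert_that(length(rsids) <= k, "set larger than its target size")
  structure(list(name = name, rsids = rsids, recipe = recipe, k = k),
            class = "snp_set")
}

#' @export
print.snp_set <- function(x, ...) {
  cat(sprintf("<snp_set> %s: %d/%d SNPs (%s recipe)\n",
              x$name, length(x$rsids), x$k, x$recipe))
  invisible(x)
}

# Top-k rows of scan results by (p-value, rsid); rsid order is the stated
# data-independent tie rule.
top_by_p <- function(results, k) {
  results |>
    dplyr::arrange(.data$p_value, .data$rsid) |>
    utils::head(k)
}

#' Data-driven SNP set: top-k by association p-value
#'
#' @param results Scan results from [single_snp_scan()].
#' @param k Target set size.
#' @param name Optional label; default `"KARE-<k>"`.
#' @return A [snp_set()].
#' @export
build_kare_set <- function(results, k, name = NULL) {
  if (nrow(results) < k) {
    warning(sprintf("only %d SNPs available for a top-%d set",
                    nrow(results), k), call. = FALSE)
  }
  snp_set(name %||% sprintf("KARE-%d", k),
          top_by_p(results, k)$rsid, "kare", k)
}

#' Catalog-plus-scan SNP set
#'
#' Catalog rsIDs present among the genotyped (scanned) SNPs are included
#' first; remaining slots are filled with the top scan SNPs not already
#' included, to a total of `k`. Catalog variants absent from the data are
#' dropped (genotyped-only rule).
#'
#' @param catalog_rsids Character vector of catalog rsIDs.
#' @param results Scan results from [single_snp_scan()].
#' @param k Target set size.
#' @param name Optional label; default `"GWAS+KARE-<k>"`.
#' @return A [snp_set()].
#' @export
build_gwas_kare_set <- function(catalog_rsids, results, k, name = NULL) {
  in_data <- intersect(unique(catalog_rsids), results$rsid)
  if (length(in_data) > k) {
    warning("catalog overlap exceeds k; keeping the top-p catalog SNPs",
            call. = FALSE)
    in_data <- top_by_p(dplyr::filter(results, .data$rsid %in% in_data),
                        k)$rsid
  }
  fill <- top_by_p(dplyr::filter(results, !(.data$rsid %in% in_data)),
                   k - length(in_data))$rsid
  snp_set(name %||% sprintf("GWAS+KARE-%d", k), c(in_data, fill),
          "gwas_kare", k)
}

#' Gene-restricted SNP set
#'
#' Candidate pool: SNPs annotated to a catalog gene; the set is the top-k of
#' the pool by scan p-value.
#'
#' @param annotation Tibble with columns `rsid`, `gene` (unannotated SNPs are
#'   treated as intergenic).
#' @param catalog_genes Character vector of catalog gene symbols.
#' @param results Scan results from [single_snp_scan()].
#' @param k Target set size.
#' @param name Optional label; default `"CATAGENE-<k>"`.
#' @return A [snp_set()].
#' @export
build_catagene_set <- function(annotation, catalog_genes, results, k,
                               name = NULL) {
  pool <- annotation$rsid[!is.na(annotation$gene) &
                            annotation$gene %in% catalog_genes]
  pool_results <- dplyr::filter(results, .data$rsid %in% pool)
  if (nrow(pool_results) == 0) {
    warning("no genotyped SNPs fall in catalog genes; returning an empty set",
            call. = FALSE)
  }
  snp_set(name %||% sprintf("CATAGENE-%d", k),
          top_by_p(pool_results, k)$rsid, "catagene", k)
}

#' Read catalog and annotation input files
#'
#' `read_snp_catalog()` and `read_gene_list()` read one identifier per line
#' (blank lines and `#` comments skipped). `read_snp_annotation()` reads a
#' 2- or 3-column TSV whose first column is the rsID and last column the gene
#' symbol.
#'
#' @param path Input file path.
#' @return A character vector (catalog/gene list) or a tibble with `rsid`,
#'   `gene` (annotation).
#' @export
read_snp_catalog <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname read_snp_catalog
#' @export
read_gene_list <- read_snp_catalog

#' @rdname read_snp_catalog
#' @export
read_snp_annotation <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(rsid = as.character(df[[1]]),
                 gene = as.character(df[[ncol(df)]]))
}
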