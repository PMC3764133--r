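#' GWAS-reported SNPs near LRRK2
#'
#' The eight SNPs in or near the LRRK2 gene on chromosome 12 (NCBI build 36
#' coordinates) reported at or near genome-wide significance for Parkinson's
#' disease in Japanese and Caucasian genome-wide association studies. These
#' anchor the focal-SNP LD profiles and the region of interest
#' (38.705-39.049 Mb after 10 kb padding).
#'
#' @return A tibble with columns `id`, `chrom`, `pos`,
#'   `association_population`.
#' @export
lrrk2_gwas_snps <- function() {
  path <- system.file("extdata", "lrrk2_gwas_snps.tsv", package = "ldcontrast")
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE,
                               colClasses = c("character", "character",
                                              "integer", "character")))
}

#' Pairwise distance between two SNPs in kb
#'
#' Absolute base-pair distance converted to kb and rounded to 0.1 kb, the
#' convention used when quoting inter-SNP distances in the region.
#'
#' @param snps Data frame with columns `id` and `pos` (e.g.
#'   [lrrk2_gwas_snps()] or a panel's `variants` table).
#' @param id1,id2 SNP identifiers.
#' @return Distance in kb, rounded to one decimal.
#' @export
snp_distance_kb <- function(snps, id1, id2) {
  idx <- match(c(id1, id2), snps$id)
  if (anyNA(idx)) {
    abort(paste0("unknown SNP id(s): ",
                 paste(c(id1, id2)[is.na(idx)], collapse = ", ")))
  }
  round(abs(snps$pos[idx[1]] - snps$pos[idx[2]]) / 1000, 1)
}
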