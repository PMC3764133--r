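# Small hand-built panels used across the suite.

# Unphased panel from a dosage matrix (rows = samples).
make_panel <- function(dosages, pos = NULL, chrom = "12", population = "TEST",
                       allele_a = NULL, allele_b = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = m)
  if (is.null(allele_a)) allele_a <- rep_len(c("A", "C"), m)
  if (is.null(allele_b)) allele_b <- rep_len(c("G", "T"), m)
  variants <- tibble::tibble(
    id = sprintf("rs%03d", seq_len(m)), chrom = chrom, pos = as.integer(pos),
    allele_a = allele_a, allele_b = allele_b
  )
  genotype_panel(variants, dosages, population)
}

# Phased panel from a haplotype matrix (2 rows per individual).
make_phased_panel <- function(haplotypes, pos = NULL, chrom = "12",
                              population = "TEST") {
  haplotypes <- as.matrix(haplotypes)
  stopifnot(nrow(haplotypes) %% 2 == 0)
  i1 <- seq(1L, nrow(haplotypes), by = 2L)
  dosages <- haplotypes[i1, , drop = FALSE] + haplotypes[i1 + 1L, , drop = FALSE]
  m <- ncol(haplotypes)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = m)
  variants <- tibble::tibble(
    id = sprintf("rs%03d", seq_len(m)), chrom = chrom, pos = as.integer(pos),
    allele_a = rep_len(c("A", "C"), m), allele_b = rep_len(c("G", "T"), m)
  )
  genotype_panel(variants, dosages, population, haplotypes = haplotypes,
                 phased = TRUE)
}

# Draw n diploid individuals' haplotypes from an explicit haplotype
# frequency distribution over k SNPs (binary-string names).
draw_from_hap_freqs <- function(hap_freqs, n, seed) {
  haps <- names(hap_freqs)
  k <- nchar(haps[1])
  withr::with_seed(seed, {
    idx <- sample(length(haps), 2 * n, replace = TRUE, prob = hap_freqs)
  })
  mat <- do.call(rbind, lapply(strsplit(haps[idx], ""), as.numeric))
  mat
}

subset_variants_public <- function(panel, idx) {
  ldcontrast:::subset_variants(panel, idx)
}

null_pvalue_run <- function(i, m = 20, n = 50, b = 199, base_seed = 0) {
  cfg <- sim_config(m = m, n1 = n, n2 = n, seed = base_seed + i)
  pair <- simulate_pair(cfg)
  h <- suppressMessages(harmonize_panels(pair[[1]], pair[[2]]))
  varld_test(h[[1]], h[[2]], b = b, mode = "genotype_corr",
             seed = base_seed + 100000 + i)$p_value
}
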