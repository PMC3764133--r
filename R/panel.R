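#' Construct a genotype panel
#'
#' A genotype panel bundles one population's samples over an ordered set of
#' biallelic SNPs: a variant table, a sample-by-variant dosage matrix counting
#' copies of `allele_b`, and (for phased data) the underlying haplotype matrix
#' with two rows per individual.
#'
#' @param variants Data frame with columns `id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`: one row per SNP, sorted by (`chrom`, `pos`), 1-based
#'   positions, single-nucleotide alleles in A/C/G/T.
#' @param dosages Numeric matrix, samples x variants, values in `{0, 1, 2, NA}`;
#'   `NA` is a missing genotype. Column order must match `variants`.
#' @param population Population label, e.g. `"CEU"`.
#' @param haplotypes Optional binary matrix with `2 * nrow(dosages)` rows
#'   (haplotypes of individual i in rows `2i - 1`, `2i`); required when
#'   `phased = TRUE`.
#' @param phased Logical; whether `haplotypes` carries phase information.
#'
#' @return An object of class `genotype_panel`.
#' @seealso [read_vcf()], [read_hapmap_table()], [simulate_haplotypes()]
#' @export
genotype_panel <- function(variants, dosages, population,
                           haplotypes = NULL, phased = !is.null(haplotypes)) {
  variants <- tibble::as_tibble(variants)
  required <- c("id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(required %in% names(variants))) {
    abort(paste0("`variants` must have columns: ", paste(required, collapse = ", ")))
  }
  variants$pos <- as.integer(variants$pos)
  variants$chrom <- as.character(variants$chrom)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (ncol(dosages) != nrow(variants)) {
    abort("`dosages` must have one column per variant.")
  }
  colnames(dosages) <- variants$id
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("%s_S%03d", population, seq_len(nrow(dosages)))
  }
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    storage.mode(haplotypes) <- "double"
    if (nrow(haplotypes) != 2L * nrow(dosages) || ncol(haplotypes) != ncol(dosages)) {
      abort("`haplotypes` must be 2 * n_samples rows by n_variants columns.")
    }
    colnames(haplotypes) <- variants$id
  }
  if (isTRUE(phased) && is.null(haplotypes)) {
    abort("`phased = TRUE` requires a haplotype matrix.")
  }
  panel <- structure(
    list(
      population = as.character(population),
      variants = variants,
      dosages = dosages,
      haplotypes = haplotypes,
      phased = isTRUE(phased)
    ),
    class = "genotype_panel"
  )
  validate_panel(panel)
}

validate_panel <- function(panel) {
  v <- panel$variants
  if (nrow(v) == 0L) abort("panel has no variants (empty-panel error)")
  if (any(v$pos < 1L)) abort("variant positions must be >= 1")
  if (any(v$id == "" | is.na(v$id))) abort("variant ids must be non-empty")
  if (anyDuplicated(v$id)) abort("variant ids must be unique within a panel")
  ok_alleles <- v$allele_a %in% c("A", "C", "G", "T") &
    v$allele_b %in% c("A", "C", "G", "T")
  if (!all(ok_alleles)) abort("alleles must be single nucleotides in {A,C,G,T}")
  if (any(v$allele_a == v$allele_b)) abort("allele_a and allele_b must differ")
  ord <- order(v$chrom, v$pos)
  if (!identical(ord, seq_len(nrow(v)))) {
    abort("variants must be sorted by (chrom, pos)")
  }
  key <- paste(v$chrom, v$pos, pmin(v$allele_a, v$allele_b),
               pmax(v$allele_a, v$allele_b))
  if (anyDuplicated(key)) abort("duplicate (chrom, pos, alleles) variant")
  d <- panel$dosages
  if (any(!is.na(d) & !(d %in% c(0, 1, 2)))) {
    abort("dosages must be 0, 1, 2 or NA")
  }
  if (any(colSums(!is.na(d)) == 0L)) {
    abort("every variant needs at least one non-missing observation")
  }
  if (panel$phased) {
    h <- panel$haplotypes
    if (any(!is.na(h) & !(h %in% c(0, 1)))) abort("haplotypes must be 0, 1 or NA")
    i1 <- seq(1L, nrow(h), by = 2L)
    hs <- h[i1, , drop = FALSE] + h[i1 + 1L, , drop = FALSE]
    both <- !is.na(hs) & !is.na(d)
    if (any(hs[both] != d[both])) {
      abort("phased haplotype pair sums disagree with dosages")
    }
  }
  panel
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %s: %d samples x %d SNPs (%s:%s-%s), %s\n",
    x$population, nrow(x$dosages), nrow(x$variants),
    x$variants$chrom[1], format(min(x$variants$pos), big.mark = ","),
    format(max(x$variants$pos), big.mark = ","),
    if (x$phased) "phased" else "unphased"
  ))
  invisible(x)
}

#' @describeIn genotype_panel Long genotype tibble: one row per (sample, SNP)
#'   with the dosage of `allele_b`.
#' @param x A `genotype_panel`.
#' @param ... Unused.
#' @method tidy genotype_panel
#' @export
tidy.genotype_panel <- function(x, ...) {
  tibble::tibble(
    sample = rep(rownames(x$dosages), times = ncol(x$dosages)),
    id = rep(x$variants$id, each = nrow(x$dosages)),
    chrom = rep(x$variants$chrom, each = nrow(x$dosages)),
    pos = rep(x$variants$pos, each = nrow(x$dosages)),
    dosage = as.vector(x$dosages)
  )
}

#' @describeIn genotype_panel One-row summary of a panel.
#' @method glance genotype_panel
#' @export
glance.genotype_panel <- function(x, ...) {
  tibble::tibble(
    population = x$population,
    n_samples = nrow(x$dosages),
    n_snps = nrow(x$variants),
    chrom = x$variants$chrom[1],
    start_bp = min(x$variants$pos),
    end_bp = max(x$variants$pos),
    phased = x$phased,
    missing_rate = mean(is.na(x$dosages))
  )
}

n_samples <- function(panel) nrow(panel$dosages)
n_snps <- function(panel) nrow(panel$variants)

#' Specify a genomic region
#'
#' Regions are 1-based and inclusive at both ends; `pad_bp` extends the
#' interval symmetrically (the regional analysis this package targets padded
#' its gene interval by 10 kb on each side).
#'
#' @param chrom Chromosome label.
#' @param start_bp,end_bp 1-based inclusive bounds.
#' @param pad_bp Symmetric extension in bp (default 0).
#' @return A `region_spec` object.
#' @export
region_spec <- function(chrom, start_bp, end_bp, pad_bp = 0) {
  check_scalar_number(start_bp, "start_bp", lower = 1)
  check_scalar_number(end_bp, "end_bp", lower = 1)
  check_scalar_number(pad_bp, "pad_bp", lower = 0)
  if (start_bp > end_bp) abort("`start_bp` must be <= `end_bp`.")
  structure(
    list(chrom = as.character(chrom), start_bp = as.integer(start_bp),
         end_bp = as.integer(end_bp), pad_bp = as.integer(pad_bp)),
    class = "region_spec"
  )
}

#' Parse a "chr:start-end" region string
#'
#' Accepts plain base-pair bounds ("12:38705000-39049000") and Mb suffixes
#' ("12:38.705Mb-39.049Mb").
#'
#' @param x Region string.
#' @param pad_bp Symmetric padding in bp.
#' @return A `region_spec`.
#' @export
parse_region <- function(x, pad_bp = 0) {
  m <- regmatches(x, regexec("^([^:]+):([0-9.]+)(Mb)?-([0-9.]+)(Mb)?$", x))[[1]]
  if (length(m) == 0L) abort(sprintf("cannot parse region string '%s'", x))
  to_bp <- function(num, suffix) {
    val <- as.numeric(num)
    if (nzchar(suffix)) val <- val * 1e6
    round(val)
  }
  region_spec(m[2], to_bp(m[3], m[4]), to_bp(m[5], m[6]), pad_bp = pad_bp)
}

#' Subset a panel to a genomic region
#'
#' Keeps variants with `start_bp - pad_bp <= pos <= end_bp + pad_bp` on the
#' region's chromosome, preserving order. An empty result is allowed (logged),
#' but the returned object is then `NULL` because a panel cannot be empty.
#'
#' @param panel A [genotype_panel()].
#' @param region A [region_spec()].
#' @return A `genotype_panel` restricted to the region, or `NULL` if no
#'   variant falls inside it.
#' @export
extract_region <- function(panel, region) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(region, "region_spec"))
  lo <- region$start_bp - region$pad_bp
  hi <- region$end_bp + region$pad_bp
  keep <- panel$variants$chrom == region$chrom &
    panel$variants$pos >= lo & panel$variants$pos <= hi
  if (!any(keep)) {
    log_note("extract_region: no variants of %s fall in %s:%d-%d",
             panel$population, region$chrom, lo, hi)
    return(NULL)
  }
  subset_variants(panel, which(keep))
}

# Index-based column subset preserving panel structure.
subset_variants <- function(panel, idx) {
  hap <- if (!is.null(panel$haplotypes)) panel$haplotypes[, idx, drop = FALSE]
  genotype_panel(
    variants = panel$variants[idx, , drop = FALSE],
    dosages = panel$dosages[, idx, drop = FALSE],
    population = panel$population,
    haplotypes = hap,
    phased = panel$phased
  )
}

# Row (sample) subset.
subset_samples <- function(panel, idx) {
  hap <- NULL
  if (!is.null(panel$haplotypes)) {
    hrows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    hap <- panel$haplotypes[hrows, , drop = FALSE]
  }
  genotype_panel(
    variants = panel$variants,
    dosages = panel$dosages[idx, , drop = FALSE],
    population = panel$population,
    haplotypes = hap,
    phased = panel$phased
  )
}

#' Keep only the listed samples
#'
#' Used e.g. to restrict a trio panel to unrelated founders before any LD
#' computation.
#'
#' @param panel A [genotype_panel()].
#' @param sample_ids Character vector of sample ids to retain (or the path of
#'   a text file with one id per line).
#' @return The restricted panel.
#' @export
keep_samples <- function(panel, sample_ids) {
  if (length(sample_ids) == 1L && file.exists(sample_ids)) {
    sample_ids <- readLines(sample_ids)
    sample_ids <- sample_ids[nzchar(trimws(sample_ids))]
  }
  idx <- match(sample_ids, rownames(panel$dosages))
  if (anyNA(idx)) {
    abort(paste0("unknown sample id(s): ",
                 paste(sample_ids[is.na(idx)], collapse = ", ")))
  }
  subset_samples(panel, idx)
}

#' Allele-B frequency of one SNP
#'
#' Frequency of `allele_b` among non-missing alleles in the panel.
#'
#' @param panel A [genotype_panel()].
#' @param variant_id SNP identifier.
#' @return A fraction in `[0, 1]`.
#' @export
allele_frequency <- function(panel, variant_id) {
  j <- match(variant_id, panel$variants$id)
  if (is.na(j)) abort(sprintf("unknown variant id '%s'", variant_id))
  d <- panel$dosages[, j]
  mean(d, na.rm = TRUE) / 2
}

allele_frequencies <- function(panel) {
  colMeans(panel$dosages, na.rm = TRUE) / 2
}

#' Harmonize two panels onto a shared variant set
#'
#' Intersects the panels by (chrom, pos), aligns allele labels so that
#' `allele_b` denotes the same nucleotide in both (complementing dosages
#' `d -> 2 - d` where the sources are flipped, and trying a strand
#' complement where the allele sets disagree), drops strand-ambiguous A/T and
#' C/G SNPs whose allele sets cannot be reconciled, and removes SNPs that are
#' monomorphic or below `maf_min` in either panel. Cross-population LD
#' comparisons require this step first.
#'
#' @param p1,p2 [genotype_panel()] objects on the same chromosome.
#' @param maf_min Minor-allele-frequency threshold applied to each panel
#'   (default 0.01); monomorphic SNPs are always dropped since r is undefined.
#' @return A list of the two harmonized panels (same order as the input),
#'   sharing an identical ordered variant table.
#' @export
harmonize_panels <- function(p1, p2, maf_min = 0.01) {
  stopifnot(inherits(p1, "genotype_panel"), inherits(p2, "genotype_panel"))
  if (!identical(unique(p1$variants$chrom), unique(p2$variants$chrom))) {
    abort("panels must be on the same chromosome")
  }
  v1 <- p1$variants
  v2 <- p2$variants
  key1 <- paste(v1$chrom, v1$pos)
  key2 <- paste(v2$chrom, v2$pos)
  common <- intersect(key1, key2)
  if (length(common) == 0L) abort("harmonization error: no shared (chrom, pos)")
  i1 <- match(common, key1)
  i2 <- match(common, key2)

  a1 <- v1$allele_a[i1]; b1 <- v1$allele_b[i1]
  a2 <- v2$allele_a[i2]; b2 <- v2$allele_b[i2]

  same <- a1 == a2 & b1 == b2
  flipped <- a1 == b2 & b1 == a2
  # Strand complement rescue for non-ambiguous discordant sets.
  ca2 <- dna_complement(a2); cb2 <- dna_complement(b2)
  ambiguous <- is_strand_ambiguous(a1, b1) | is_strand_ambiguous(a2, b2)
  comp_same <- !same & !flipped & !ambiguous & a1 == ca2 & b1 == cb2
  comp_flip <- !same & !flipped & !ambiguous & a1 == cb2 & b1 == ca2
  usable <- same | flipped | comp_same | comp_flip
  n_drop <- sum(!usable)
  if (n_drop > 0L) {
    log_note("harmonize_panels: dropped %d SNP(s) with irreconcilable or strand-ambiguous alleles",
             n_drop)
  }
  keep <- which(usable)
  if (length(keep) == 0L) abort("harmonization error: no reconcilable shared SNPs")

  i1 <- i1[keep]; i2 <- i2[keep]
  flip2 <- (flipped | comp_flip)[keep]

  q1 <- subset_variants(p1, i1)
  q2 <- subset_variants(p2, i2)
  if (any(flip2)) q2 <- flip_alleles(q2, which(flip2))
  # Adopt p1's allele labels throughout (covers strand-complement cases).
  q2$variants$allele_a <- q1$variants$allele_a
  q2$variants$allele_b <- q1$variants$allele_b
  q2$variants$id <- q1$variants$id
  colnames(q2$dosages) <- q1$variants$id
  if (!is.null(q2$haplotypes)) colnames(q2$haplotypes) <- q1$variants$id

  f1 <- allele_frequencies(q1)
  f2 <- allele_frequencies(q2)
  maf <- function(f) pmin(f, 1 - f)
  poly <- maf(f1) >= maf_min & maf(f2) >= maf_min & maf(f1) > 0 & maf(f2) > 0
  if (!any(poly)) abort("harmonization error: no SNP passes the MAF filter in both panels")
  if (any(!poly)) {
    log_note("harmonize_panels: dropped %d SNP(s) monomorphic or below MAF %.3g in either panel",
             sum(!poly), maf_min)
  }
  list(subset_variants(q1, which(poly)), subset_variants(q2, which(poly)))
}

#' Flip the allele coding of selected SNPs
#'
#' Swaps `allele_a`/`allele_b` and recodes dosages `d -> 2 - d` (haplotypes
#' `h -> 1 - h`) at the given variant indices. LD r changes sign at flipped
#' SNPs; r squared and all eigenvalue-based summaries are invariant.
#'
#' @param panel A [genotype_panel()].
#' @param idx Integer indices of variants to flip.
#' @return The recoded panel.
#' @export
flip_alleles <- function(panel, idx) {
  v <- panel$variants
  tmp <- v$allele_a[idx]
  v$allele_a[idx] <- v$allele_b[idx]
  v$allele_b[idx] <- tmp
  d <- panel$dosages
  d[, idx] <- 2 - d[, idx]
  h <- panel$haplotypes
  if (!is.null(h)) h[, idx] <- 1 - h[, idx]
  genotype_panel(v, d, panel$population, haplotypes = h, phased = panel$phased)
}

#' Row-concatenate two harmonized panels
#'
#' Builds the merged pool from which the Monte Carlo permutation test
#' resamples: `n1 + n2` individuals over the shared variant list.
#'
#' @param p1,p2 Harmonized [genotype_panel()] objects (identical variant
#'   tables).
#' @param population Label for the merged panel.
#' @return A `genotype_panel` with the samples of both inputs.
#' @export
merge_panels <- function(p1, p2, population = paste0(p1$population, "+", p2$population)) {
  if (!identical(p1$variants$id, p2$variants$id) ||
      !identical(p1$variants$pos, p2$variants$pos)) {
    abort("variant mismatch: run harmonize_panels() before merge_panels()")
  }
  d <- rbind(p1$dosages, p2$dosages)
  rownames(d) <- make.unique(c(rownames(p1$dosages), rownames(p2$dosages)))
  hap <- NULL
  phased <- p1$phased && p2$phased
  if (phased) hap <- rbind(p1$haplotypes, p2$haplotypes)
  genotype_panel(p1$variants, d, population, haplotypes = hap, phased = phased)
}
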