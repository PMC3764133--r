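#' Read a VCF file into a genotype panel
#'
#' Reads diploid genotypes from a VCF 4.x file, retaining only biallelic SNP
#' records (single-nucleotide REF and ALT). Multi-allelic and non-SNP records
#' are skipped with a logged count. `allele_b` is the ALT allele, so dosages
#' count ALT copies. The panel is flagged phased only when every retained
#' non-missing genotype uses the `|` separator.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param population Population label for the panel.
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path, population) {
  if (!file.exists(path)) abort(sprintf("cannot read VCF '%s'", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) abort(sprintf("empty-panel error: no records in '%s'", path))
  is_snp <- fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snp)
  if (n_skip > 0L) {
    log_note("read_vcf: skipped %d multi-allelic or non-SNP record(s)", n_skip)
  }
  if (!any(is_snp)) abort(sprintf("empty-panel error: no biallelic SNPs in '%s'", path))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]

  alleles <- t(apply(gt, 1, parse_gt_row))
  n_var <- nrow(fix)
  n_smp <- ncol(gt)
  a1 <- matrix(alleles[, seq_len(n_smp)], nrow = n_var)
  a2 <- matrix(alleles[, n_smp + seq_len(n_smp)], nrow = n_var)
  phased_flag <- !grepl("/", gt[!is.na(gt)], fixed = TRUE)
  phased <- length(phased_flag) > 0L && all(phased_flag)

  dos <- t(a1 + a2)  # samples x variants
  rownames(dos) <- colnames(gt)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- tibble::tibble(
    id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    allele_a = fix$REF, allele_b = fix$ALT
  )
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dos <- dos[, ord, drop = FALSE]
  hap <- NULL
  if (phased) {
    hap <- matrix(NA_real_, nrow = 2L * n_smp, ncol = n_var)
    hap[seq(1L, 2L * n_smp, by = 2L), ] <- t(a1)[, ord, drop = FALSE]
    hap[seq(2L, 2L * n_smp, by = 2L), ] <- t(a2)[, ord, drop = FALSE]
  }
  genotype_panel(variants, dos, population, haplotypes = hap, phased = phased)
}

# "0|1" / "0/1" / "./." -> c(allele1, allele2) as 0/1/NA per variant row.
parse_gt_row <- function(g) {
  out <- matrix(NA_real_, nrow = 2L, ncol = length(g))
  nonmiss <- !is.na(g)
  parts <- strsplit(g[nonmiss], "[/|]")
  vals <- vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (length(p) != 2L) p <- c(NA_real_, NA_real_)
    p
  }, numeric(2))
  if (any(nonmiss)) out[, nonmiss] <- vals
  c(out[1L, ], out[2L, ])
}

#' Write a panel as VCF
#'
#' Emits a minimal VCF 4.2 file with GT-only genotypes. Phased panels use the
#' `|` separator and preserve haplotype order; unphased panels use `/` with an
#' arbitrary but consistent heterozygote ordering. Round-trips through
#' [read_vcf()] at the dosage level.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(panel, path) {
  v <- panel$variants
  n <- n_samples(panel)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(panel$dosages)), collapse = "\t")
  )
  sep <- if (panel$phased) "|" else "/"
  gt_field <- function(j) {
    if (panel$phased) {
      h1 <- panel$haplotypes[seq(1L, 2L * n, by = 2L), j]
      h2 <- panel$haplotypes[seq(2L, 2L * n, by = 2L), j]
    } else {
      d <- panel$dosages[, j]
      h1 <- ifelse(d >= 1, 1, 0)
      h2 <- ifelse(d == 2, 1, 0)
    }
    g <- paste0(h1, sep, h2)
    g[is.na(h1) | is.na(h2)] <- paste0(".", sep, ".")
    g
  }
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$allele_a[j], v$allele_b[j],
            ".", "PASS", ".", "GT", gt_field(j)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a HapMap-style genotype table
#'
#' Parses the whitespace-delimited dialect: a header row, then one row per SNP
#' with columns `rsID`, `alleles` (e.g. `A/G`), `chrom`, `pos`, followed by
#' one two-letter genotype string per sample (`AG`, `GG`, ...; `NN` missing).
#' Dosages count copies of the second declared allele (`allele_b`).
#'
#' @param path Path to the table.
#' @param population Population label.
#' @return A [genotype_panel()] (unphased).
#' @export
read_hapmap_table <- function(path, population) {
  if (!file.exists(path)) abort(sprintf("cannot read table '%s'", path))
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 5L) abort("HapMap-style table needs 4 meta columns plus samples")
  sample_ids <- names(tab)[-(1:4)]
  al <- strsplit(tab[[2]], "/", fixed = TRUE)
  bad <- lengths(al) != 2L
  if (any(bad)) abort(sprintf("row %d: malformed allele column '%s'",
                              which(bad)[1], tab[[2]][which(bad)[1]]))
  allele_a <- vapply(al, `[`, character(1), 1L)
  allele_b <- vapply(al, `[`, character(1), 2L)
  chrom <- sub("^chr", "", tab[[3]])
  dos <- matrix(NA_real_, nrow = length(sample_ids), ncol = nrow(tab),
                dimnames = list(sample_ids, tab[[1]]))
  for (j in seq_len(nrow(tab))) {
    g <- toupper(as.character(tab[j, -(1:4)]))
    miss <- g == "NN" | g == "--" | is.na(g)
    letters2 <- strsplit(g[!miss], "")
    valid <- vapply(letters2, function(x) {
      length(x) == 2L && all(x %in% c(allele_a[j], allele_b[j]))
    }, logical(1))
    if (!all(valid)) {
      bad_s <- sample_ids[!miss][which(!valid)[1]]
      abort(sprintf("parse error at SNP '%s', sample '%s': genotype letter not in declared alleles %s/%s",
                    tab[[1]][j], bad_s, allele_a[j], allele_b[j]))
    }
    dos[!miss, j] <- vapply(letters2, function(x) sum(x == allele_b[j]), numeric(1))
  }
  variants <- tibble::tibble(
    id = tab[[1]], chrom = chrom, pos = as.integer(tab[[4]]),
    allele_a = allele_a, allele_b = allele_b
  )
  ord <- order(variants$chrom, variants$pos)
  genotype_panel(variants[ord, ], dos[, ord, drop = FALSE], population)
}

#' Write a panel as a HapMap-style genotype table
#'
#' Inverse of [read_hapmap_table()] at the dosage level (phase is not
#' representable in this dialect).
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hapmap_table <- function(panel, path) {
  v <- panel$variants
  lines <- paste(c("rsID", "alleles", "chrom", "pos", rownames(panel$dosages)),
                 collapse = " ")
  geno_col <- function(j) {
    d <- panel$dosages[, j]
    g <- c(strrep(v$allele_a[j], 2),
           paste0(v$allele_a[j], v$allele_b[j]),
           strrep(v$allele_b[j], 2))[d + 1]
    g[is.na(d)] <- "NN"
    g
  }
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$id[j], paste0(v$allele_a[j], "/", v$allele_b[j]),
            v$chrom[j], v$pos[j], geno_col(j)), collapse = " ")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a panel fixture in a chosen format
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @param format `"vcf"` or `"hapmap_table"`.
#' @return The path, invisibly.
#' @export
write_fixture <- function(panel, path, format = c("vcf", "hapmap_table")) {
  format <- match.arg(format)
  switch(format,
    vcf = write_vcf(panel, path),
    hapmap_table = write_hapmap_table(panel, path)
  )
}
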