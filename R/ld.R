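#' Pairwise LD from phased haplotypes
#'
#' Classic two-locus LD from binary haplotype vectors (1 = `allele_b`). With
#' haplotype frequency \eqn{p_{AB}} and allele frequencies \eqn{p_A, p_B}:
#' \eqn{D = p_{AB} - p_A p_B},
#' \eqn{r = D / \sqrt{p_A(1-p_A)p_B(1-p_B)}}, and
#' \eqn{D' = |D| / D_{max}} with
#' \eqn{D_{max} = \min(p_A p_B, (1-p_A)(1-p_B))} for negative D, else
#' \eqn{\min(p_A(1-p_B), (1-p_A)p_B)}.
#'
#' @param hap_a,hap_b Binary vectors of equal length (0/1/NA), one entry per
#'   haplotype. Entries missing in either vector are dropped pairwise.
#' @return A one-row tibble of class `pair_ld` with columns `d`, `d_prime`,
#'   `r`, `r2`, `n` (haplotypes used).
#' @export
pair_ld_haplotypes <- function(hap_a, hap_b) {
  if (length(hap_a) != length(hap_b)) abort("haplotype vectors must have equal length")
  keep <- !is.na(hap_a) & !is.na(hap_b)
  a <- hap_a[keep]; b <- hap_b[keep]
  n <- length(a)
  if (n < 4L) abort("undefined LD: fewer than 4 pairwise-complete haplotypes")
  p_a <- mean(a); p_b <- mean(b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    abort("undefined LD: monomorphic locus among retained haplotypes")
  }
  p_ab <- mean(a == 1 & b == 1)
  d <- p_ab - p_a * p_b
  r <- d / sqrt(p_a * (1 - p_a) * p_b * (1 - p_b))
  d_max <- if (d < 0) min(p_a * p_b, (1 - p_a) * (1 - p_b)) else
    min(p_a * (1 - p_b), (1 - p_a) * p_b)
  d_prime <- if (d_max == 0) 0 else abs(d) / d_max
  new_pair_ld(d = d, d_prime = min(d_prime, 1), r = r, n = n)
}

new_pair_ld <- function(d, d_prime, r, n) {
  out <- tibble::tibble(d = d, d_prime = d_prime, r = r, r2 = r^2, n = n)
  class(out) <- c("pair_ld", class(out))
  out
}

#' Pairwise LD from unphased genotype dosages
#'
#' Two routes for unphased data: `genotype_corr` is the composite Pearson
#' correlation of the dosage vectors (returns `r`/`r2` only, `d` and
#' `d_prime` are `NA`); `haplotype_em` estimates the four two-locus haplotype
#' frequencies by EM under Hardy-Weinberg and applies the haplotype formulas
#' of [pair_ld_haplotypes()].
#'
#' @param g1,g2 Dosage vectors in `{0,1,2,NA}`; pairwise-complete entries used.
#' @param mode `"genotype_corr"` or `"haplotype_em"`.
#' @return A one-row `pair_ld` tibble.
#' @export
pair_ld_genotypes <- function(g1, g2, mode = c("genotype_corr", "haplotype_em")) {
  mode <- match.arg(mode)
  if (length(g1) != length(g2)) abort("dosage vectors must have equal length")
  keep <- !is.na(g1) & !is.na(g2)
  x <- g1[keep]; y <- g2[keep]
  n <- length(x)
  if (n < 4L) abort("undefined LD: fewer than 4 pairwise-complete genotypes")
  if (sd(x) == 0 || sd(y) == 0) abort("undefined LD: zero dosage variance (monomorphic locus)")
  if (mode == "genotype_corr") {
    r <- cor(x, y)
    return(new_pair_ld(d = NA_real_, d_prime = NA_real_, r = r, n = n))
  }
  f <- em_freqs_matrix(cbind(x, y))$frequencies  # order 00,01,10,11 over bits
  p_a <- f[3] + f[4]  # locus 1 allele 1
  p_b <- f[2] + f[4]  # locus 2 allele 1
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) abort("undefined LD: EM frequencies monomorphic")
  d <- f[4] - p_a * p_b
  r <- d / sqrt(p_a * (1 - p_a) * p_b * (1 - p_b))
  d_max <- if (d < 0) min(p_a * p_b, (1 - p_a) * (1 - p_b)) else
    min(p_a * (1 - p_b), (1 - p_a) * p_b)
  d_prime <- if (d_max == 0) 0 else abs(d) / d_max
  new_pair_ld(d = d, d_prime = min(d_prime, 1), r = r, n = n)
}

#' Regional LD matrix
#'
#' Signed-r LD matrix over all SNPs of a panel. Modes: `haplotype_counted`
#' (direct haplotype correlation; phased panels only), `genotype_corr`
#' (composite dosage correlation), `haplotype_em` (per-pair EM haplotype
#' frequencies), or `"auto"` which picks haplotype counting when the panel is
#' phased and genotype correlation otherwise. Pairs whose LD is undefined
#' after pairwise-complete deletion are set to 0 and counted in a log
#' message (`strict = TRUE` raises instead); the diagonal is forced to 1.
#'
#' @param panel A [genotype_panel()] with at least 2 polymorphic SNPs.
#' @param mode LD mode (see Details).
#' @param strict Raise an error on undefined pairs instead of zero-filling.
#' @return An object of class `ld_matrix`: list with `variant_ids`,
#'   `positions`, `r_signed` (symmetric, unit diagonal), `method`,
#'   `population`.
#' @export
ld_matrix <- function(panel,
                      mode = c("auto", "haplotype_counted", "genotype_corr", "haplotype_em"),
                      strict = FALSE) {
  mode <- match.arg(mode)
  mode <- resolve_mode(mode, panel)
  m <- n_snps(panel)
  if (m < 2L) abort("ld_matrix needs at least 2 variants")
  poly <- apply(panel$dosages, 2, function(d) sd(d, na.rm = TRUE) > 0)
  if (sum(poly) < 2L) abort("ld_matrix needs at least 2 polymorphic variants")

  if (mode == "haplotype_em") {
    r <- diag(1, m)
    n_undef <- 0L
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        val <- tryCatch(
          pair_ld_genotypes(panel$dosages[, i], panel$dosages[, j],
                            mode = "haplotype_em")$r,
          error = function(e) NA_real_)
        if (is.na(val)) {
          if (strict) abort(sprintf("undefined LD between '%s' and '%s'",
                                    panel$variants$id[i], panel$variants$id[j]))
          n_undef <- n_undef + 1L
          val <- 0
        }
        r[i, j] <- r[j, i] <- val
      }
    }
  } else {
    mat <- if (mode == "haplotype_counted") panel$haplotypes else panel$dosages
    r <- signed_r_matrix(mat)
    n_undef <- sum(!is.finite(r[upper.tri(r)]))
    if (n_undef > 0L && strict) abort(sprintf("%d undefined LD pair(s)", n_undef))
    r[!is.finite(r)] <- 0
    diag(r) <- 1
  }
  if (n_undef > 0L) log_note("ld_matrix: %d undefined pair(s) set to r = 0", n_undef)
  structure(
    list(variant_ids = panel$variants$id, positions = panel$variants$pos,
         r_signed = r, method = mode, population = panel$population),
    class = "ld_matrix"
  )
}

resolve_mode <- function(mode, panel) {
  if (mode == "auto") {
    mode <- if (panel$phased) "haplotype_counted" else "genotype_corr"
  }
  if (mode == "haplotype_counted" && !panel$phased) {
    abort("haplotype_counted mode requires a phased panel")
  }
  mode
}

# Column correlation with pairwise-complete observations; NaN where undefined.
signed_r_matrix <- function(mat) {
  if (anyNA(mat)) {
    suppressWarnings(cor(mat, use = "pairwise.complete.obs"))
  } else {
    suppressWarnings(cor(mat))
  }
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %s: %d SNPs, method = %s\n",
              x$population, length(x$variant_ids), x$method))
  invisible(x)
}

#' @describeIn ld_matrix Long-format LD table: one row per SNP pair with
#'   `snp1`, `snp2`, `r`, `r2`.
#' @param x An `ld_matrix`.
#' @param ... Unused.
#' @method tidy ld_matrix
#' @export
tidy.ld_matrix <- function(x, ...) {
  m <- length(x$variant_ids)
  idx <- which(upper.tri(x$r_signed), arr.ind = TRUE)
  tibble::tibble(
    snp1 = x$variant_ids[idx[, 1]],
    snp2 = x$variant_ids[idx[, 2]],
    pos1 = x$positions[idx[, 1]],
    pos2 = x$positions[idx[, 2]],
    r = x$r_signed[idx],
    r2 = x$r_signed[idx]^2
  )
}

#' Export an LD matrix as delimited text
#'
#' @param x An [ld_matrix()].
#' @param path Output path.
#' @param format `"square"` (tab-delimited matrix with id header row/column)
#'   or `"long"` (snp1, snp2, r, r2 table).
#' @return The path, invisibly.
#' @export
write_ld_matrix <- function(x, path, format = c("square", "long")) {
  format <- match.arg(format)
  if (format == "square") {
    mat <- x$r_signed
    dimnames(mat) <- list(x$variant_ids, x$variant_ids)
    utils::write.table(mat, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    utils::write.table(tidy(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' LD profile around a focal SNP
#'
#' r-squared of a focal SNP against every other SNP of the panel, ordered by
#' position — the per-population series behind focal-SNP LD decay figures.
#'
#' @param panel A [genotype_panel()].
#' @param focal_id Identifier of the focal SNP (must be present and
#'   polymorphic).
#' @param mode LD mode as in [ld_matrix()].
#' @return A tibble of class `ld_profile` with columns `population`,
#'   `focal_id`, `id`, `pos`, `r2`; the focal SNP's own entry is 1.
#' @export
ld_profile <- function(panel, focal_id,
                       mode = c("auto", "haplotype_counted", "genotype_corr", "haplotype_em")) {
  mode <- match.arg(mode)
  mode <- resolve_mode(mode, panel)
  j <- match(focal_id, panel$variants$id)
  if (is.na(j)) abort(sprintf("focal SNP '%s' not present in panel", focal_id))
  if (sd(panel$dosages[, j], na.rm = TRUE) == 0) {
    abort(sprintf("focal SNP '%s' is monomorphic", focal_id))
  }
  m <- n_snps(panel)
  r2 <- numeric(m)
  for (k in seq_len(m)) {
    if (k == j) { r2[k] <- 1; next }
    val <- tryCatch({
      if (mode == "haplotype_counted") {
        pair_ld_haplotypes(panel$haplotypes[, j], panel$haplotypes[, k])$r2
      } else if (mode == "haplotype_em") {
        pair_ld_genotypes(panel$dosages[, j], panel$dosages[, k],
                          mode = "haplotype_em")$r2
      } else {
        pair_ld_genotypes(panel$dosages[, j], panel$dosages[, k],
                          mode = "genotype_corr")$r2
      }
    }, error = function(e) NA_real_)
    r2[k] <- val
  }
  out <- tibble::tibble(
    population = panel$population,
    focal_id = focal_id,
    id = panel$variants$id,
    pos = panel$variants$pos,
    r2 = r2
  )
  class(out) <- c("ld_profile", class(out))
  out
}
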