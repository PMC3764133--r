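#' Descending eigenvalues of an LD matrix
#'
#' Eigendecomposition of the signed-correlation matrix via the symmetric
#' solver; eigenvalues are returned in decreasing order and their sum equals
#' the number of SNPs (the trace of a unit-diagonal matrix). Matrices with
#' zero-filled undefined entries are used as-is — eigenvalues may then be
#' slightly negative, which is harmless for the score below.
#'
#' @param ld An [ld_matrix()] or a symmetric numeric matrix with unit
#'   diagonal.
#' @return Numeric vector of eigenvalues, length m, descending.
#' @export
eigenvalues_sorted <- function(ld) {
  r <- if (inherits(ld, "ld_matrix")) ld$r_signed else as.matrix(ld)
  if (max(abs(r - t(r))) > 1e-8) abort("LD matrix is not symmetric")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  sort(ev, decreasing = TRUE)
}

#' varLD regional dissimilarity score
#'
#' The raw varLD score between two populations over a common ordered SNP set:
#' the sum of absolute differences of the rank-ordered eigenvalues of their
#' signed-correlation LD matrices,
#' \eqn{\mathrm{varLD} = \sum_i |\lambda_1^{(i)} - \lambda_2^{(i)}|}.
#' It is 0 iff the eigenvalue spectra coincide and is bounded above by 2m.
#' Allele recoding at any SNP conjugates its correlation matrix by a sign
#' matrix and leaves the score unchanged.
#'
#' @param ld1,ld2 [ld_matrix()] objects over identical `variant_ids` in
#'   identical order (harmonize the panels first).
#' @return An object of class `varld_score`: list with `score`,
#'   `eigenvalues_1`, `eigenvalues_2`, `m`.
#' @export
varld_score <- function(ld1, ld2) {
  if (!identical(ld1$variant_ids, ld2$variant_ids)) {
    abort("mismatched SNP lists: run harmonize_panels() before comparing LD matrices")
  }
  e1 <- eigenvalues_sorted(ld1)
  e2 <- eigenvalues_sorted(ld2)
  structure(
    list(score = sum(abs(e1 - e2)), eigenvalues_1 = e1, eigenvalues_2 = e2,
         m = length(e1)),
    class = "varld_score"
  )
}

#' @export
print.varld_score <- function(x, ...) {
  cat(sprintf("<varld_score> %.6g over %d SNPs\n", x$score, x$m))
  invisible(x)
}

#' @describeIn varld_score One-row summary tibble.
#' @param x A `varld_score`.
#' @param ... Unused.
#' @method glance varld_score
#' @export
glance.varld_score <- function(x, ...) {
  tibble::tibble(score = x$score, m = x$m,
                 max_eigenvalue_1 = x$eigenvalues_1[1],
                 max_eigenvalue_2 = x$eigenvalues_2[1])
}

# Fast internal path: descending eigenvalues from a raw data matrix
# (columns = SNPs), zero-filling undefined correlations.
eigenvalues_from_data <- function(mat) {
  r <- signed_r_matrix(mat)
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  eigen(r, symmetric = TRUE, only.values = TRUE)$values
}

#' Sliding-window varLD scores
#'
#' One score per window of `window_snps` consecutive shared SNPs, advanced by
#' `step_snps`; a final partial window is dropped. With `window_snps` equal
#' to the number of shared SNPs this reduces to the single region-wide score.
#'
#' @param p1,p2 Harmonized [genotype_panel()] objects.
#' @param window_snps Window size in SNPs (>= 2).
#' @param step_snps Step between window starts (default `window_snps`).
#' @param mode LD mode as in [ld_matrix()].
#' @return A tibble, one row per window: `window_id`, `start_bp`, `end_bp`,
#'   `m_snps`, `score`.
#' @export
varld_windows <- function(p1, p2, window_snps, step_snps = window_snps,
                          mode = "auto") {
  if (!identical(p1$variants$id, p2$variants$id)) {
    abort("panels must be harmonized before varld_windows()")
  }
  m <- n_snps(p1)
  if (window_snps < 2L) abort("window_snps must be >= 2")
  if (window_snps > m) abort("window_snps exceeds the number of shared SNPs")
  ld1 <- ld_matrix(p1, mode = mode)
  ld2 <- ld_matrix(p2, mode = mode)
  starts <- seq.int(1L, m - window_snps + 1L, by = step_snps)
  purrr::map_dfr(seq_along(starts), function(w) {
    idx <- starts[w]:(starts[w] + window_snps - 1L)
    e1 <- sort(eigen(ld1$r_signed[idx, idx], symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    e2 <- sort(eigen(ld2$r_signed[idx, idx], symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    tibble::tibble(
      window_id = w,
      start_bp = p1$variants$pos[idx[1]],
      end_bp = p1$variants$pos[idx[length(idx)]],
      m_snps = window_snps,
      score = sum(abs(e1 - e2))
    )
  })
}

#' Standardize a vector of scores
#'
#' Utility z-standardization (mean 0, unit SD) for use when ranking window
#' scores against a broader score distribution. The permutation test operates
#' on raw scores — standardization is monotone and leaves permutation
#' p-values unchanged.
#'
#' @param scores Numeric vector, length >= 2.
#' @return Standardized numeric vector.
#' @export
standardize_scores <- function(scores) {
  if (length(scores) < 2L) abort("need at least 2 scores to standardize")
  ctr <- scores - mean(scores)
  s <- sqrt(mean(ctr^2))  # population SD, so the output has unit scale exactly
  if (s == 0) abort("zero variance: scores cannot be standardized")
  ctr / s
}
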