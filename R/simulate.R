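# Gaussian-copula two-population haplotype simulator. A latent multivariate
# normal draw with the population's target correlation matrix is thresholded
# at each SNP's allele-frequency quantile to produce binary haplotypes;
# consecutive haplotypes are paired into diploid individuals. The binary-
# scale correlation is attenuated relative to the latent target, so tests
# assert on empirical matrices, never on latent targets.

#' Target correlation structures for the simulator
#'
#' @param rho AR(1) autocorrelation in (-1, 1): latent correlation
#'   `rho^|i-j|` between SNPs i and j.
#' @return A structure descriptor for [sim_config()].
#' @export
structure_ar1 <- function(rho) {
  check_scalar_number(rho, "rho", lower = -1, upper = 1)
  if (abs(rho) >= 1) abort("rho must be in (-1, 1)")
  list(type = "ar1", rho = rho)
}

#' @rdname structure_ar1
#' @param sizes Integer vector of block sizes (must sum to `m`).
#' @param within_r Latent correlation inside a block.
#' @param between_r Latent correlation between blocks (default 0).
#' @export
structure_block <- function(sizes, within_r, between_r = 0) {
  list(type = "block", sizes = as.integer(sizes),
       within_r = within_r, between_r = between_r)
}

#' @rdname structure_ar1
#' @param R An m x m correlation matrix supplied directly.
#' @export
structure_custom <- function(R) {
  list(type = "custom", R = as.matrix(R))
}

#' Divergence settings for a two-population pair
#'
#' `divergence_none()` gives both populations one shared correlation target
#' (the null used for type-I-error checks). `divergence_ar1_contrast()`
#' assigns AR(1) targets with different autocorrelations (population 1 gets
#' `rho1`). `divergence_block_permute()` permutes a fraction of SNP labels
#' within population 2's target, destroying positional LD while preserving
#' the spectrum's scale.
#'
#' @return A divergence descriptor for [sim_config()].
#' @export
divergence_none <- function() list(type = "none")

#' @rdname divergence_none
#' @param rho1,rho2 AR(1) autocorrelations for populations 1 and 2.
#' @export
divergence_ar1_contrast <- function(rho1, rho2) {
  list(type = "ar1_contrast", rho1 = rho1, rho2 = rho2)
}

#' @rdname divergence_none
#' @param fraction Fraction of SNP labels permuted in population 2's target.
#' @export
divergence_block_permute <- function(fraction) {
  check_scalar_number(fraction, "fraction", lower = 0, upper = 1)
  list(type = "block_permute", fraction = fraction)
}

#' Simulation configuration
#'
#' Defaults emulate the regional panels this package targets: ~200 SNPs
#' spanning ~345 kb on chromosome 12 starting at 38,705,000 (uniform 1.6 kb
#' spacing, cosmetic only) and diploid sample sizes of order 80-200.
#'
#' @param m Number of SNPs (default 200).
#' @param n1,n2 Diploid sample sizes (default 100 each).
#' @param freq_range MAF interval for the allele-frequency marginals, drawn
#'   uniformly (default `c(0.05, 0.5)`).
#' @param structure Correlation structure from [structure_ar1()],
#'   [structure_block()] or [structure_custom()] (default AR(1), rho 0.8).
#' @param divergence Divergence descriptor from [divergence_none()] and
#'   friends (default none).
#' @param chrom,start_bp,spacing_bp Variant coordinates.
#' @param missing_rate Fraction of genotypes masked at random (default 0).
#' @param seed Base RNG seed (default 1). Allele frequencies and any label
#'   permutation derive from it independently of the population index, so
#'   both populations share one marginal law.
#' @param shared_draw If `TRUE`, both populations reuse population 1's latent
#'   draw (byte-identical panels under `divergence_none()`).
#' @return A `sim_config` object.
#' @export
sim_config <- function(m = 200L, n1 = 100L, n2 = 100L,
                       freq_range = c(0.05, 0.5),
                       structure = structure_ar1(0.8),
                       divergence = divergence_none(),
                       chrom = "12", start_bp = 38705000L,
                       spacing_bp = 1600L, missing_rate = 0,
                       seed = 1L, shared_draw = FALSE) {
  check_scalar_number(m, "m", lower = 2)
  check_scalar_number(missing_rate, "missing_rate", lower = 0)
  if (missing_rate >= 0.5) abort("missing_rate must be < 0.5")
  stopifnot(length(freq_range) == 2L, freq_range[1] <= freq_range[2],
            freq_range[1] > 0, freq_range[2] <= 0.5)
  out <- list(m = as.integer(m), n1 = as.integer(n1), n2 = as.integer(n2),
              freq_range = freq_range, structure = structure,
              divergence = divergence, chrom = as.character(chrom),
              start_bp = as.integer(start_bp), spacing_bp = as.integer(spacing_bp),
              missing_rate = missing_rate, seed = as.integer(seed),
              shared_draw = isTRUE(shared_draw))
  class(out) <- "sim_config"
  out
}

# Target latent correlation matrix for one population, with positive-definite
# repair by eigenvalue clipping at 1e-6 and renormalization to unit diagonal.
target_correlation <- function(config, population_index) {
  m <- config$m
  build <- function(st) {
    switch(st$type,
      ar1 = st$rho^abs(outer(seq_len(m), seq_len(m), "-")),
      block = {
        if (sum(st$sizes) != m) abort("block sizes must sum to m")
        lab <- rep(seq_along(st$sizes), st$sizes)
        R <- matrix(st$between_r, m, m)
        same <- outer(lab, lab, "==")
        R[same] <- st$within_r
        diag(R) <- 1
        R
      },
      custom = {
        if (!all(dim(st$R) == m)) abort("custom correlation matrix must be m x m")
        st$R
      },
      abort("unknown structure type")
    )
  }
  div <- config$divergence
  R <- switch(div$type,
    none = build(config$structure),
    ar1_contrast = build(structure_ar1(if (population_index == 1L) div$rho1 else div$rho2)),
    block_permute = {
      R0 <- build(config$structure)
      if (population_index == 1L) R0 else {
        k <- round(div$fraction * m)
        perm <- seq_len(m)
        if (k >= 2L) {
          moved <- with_seed(derive_seed(config$seed, 777L),
                             sample(seq_len(m), k))
          perm[moved] <- with_seed(derive_seed(config$seed, 778L), sample(moved))
        }
        R0[perm, perm]
      }
    },
    abort("unknown divergence type")
  )
  repair_correlation(R)
}

repair_correlation <- function(R) {
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    log_note("simulate: correlation target repaired by clipping %d eigenvalue(s)",
             sum(ev$values < 1e-6))
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    R <- stats::cov2cor(R)
  }
  R
}

sim_freqs <- function(config) {
  with_seed(derive_seed(config$seed, 0L),
            runif(config$m, config$freq_range[1], config$freq_range[2]))
}

#' Simulate one population's haplotype panel
#'
#' Gaussian-copula draw: latent N(0, R) haplotype vectors are thresholded at
#' the normal quantile of each SNP's allele frequency (latent value below the
#' quantile codes a copy of `allele_b`); haplotypes are paired into diploid
#' individuals. Missing genotypes, when requested, mask both haplotypes of an
#' individual at a SNP. The panel is phased.
#'
#' @param config A [sim_config()].
#' @param population_index 1 or 2 — selects the population's correlation
#'   target under the configured divergence and its RNG sub-stream.
#' @return A [genotype_panel()].
#' @export
simulate_haplotypes <- function(config, population_index = 1L) {
  stopifnot(inherits(config, "sim_config"), population_index %in% 1:2)
  m <- config$m
  n <- if (population_index == 1L) config$n1 else config$n2
  R <- target_correlation(config, population_index)
  freqs <- sim_freqs(config)
  draw_index <- if (config$shared_draw) 1L else population_index
  hap <- with_seed(derive_seed(config$seed, draw_index), {
    z <- matrix(rnorm(2L * n * m), nrow = 2L * n) %*% chol(R)
    (z < matrix(qnorm(freqs), nrow = 2L * n, ncol = m, byrow = TRUE)) * 1
  })
  dos <- hap[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  if (config$missing_rate > 0) {
    mask <- with_seed(derive_seed(config$seed, 10L + draw_index),
                      matrix(runif(n * m) < config$missing_rate, nrow = n))
    dos[mask] <- NA
    hap[mask[rep(seq_len(n), each = 2L), , drop = FALSE]] <- NA
  }
  pop <- paste0("SIM", population_index)
  variants <- tibble::tibble(
    id = sprintf("snp%04d", seq_len(m)),
    chrom = config$chrom,
    pos = config$start_bp + (seq_len(m) - 1L) * config$spacing_bp,
    allele_a = rep_len(c("A", "C"), m),
    allele_b = rep_len(c("G", "T"), m)
  )
  rownames(dos) <- sprintf("%s_S%03d", pop, seq_len(n))
  genotype_panel(variants, dos, pop, haplotypes = hap, phased = TRUE)
}

#' Simulate a two-population pair
#'
#' Under `divergence_none()` both panels are independent draws from one
#' shared law (the permutation null); `divergence_ar1_contrast()` and
#' `divergence_block_permute()` give the populations different LD targets
#' while keeping identical allele-frequency marginals.
#'
#' @param config A [sim_config()].
#' @return List of two [genotype_panel()] objects.
#' @export
simulate_pair <- function(config) {
  list(simulate_haplotypes(config, 1L), simulate_haplotypes(config, 2L))
}
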