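# Monte Carlo permutation significance for the varLD score.

#' Randomly split a merged panel into two groups
#'
#' Draws a uniformly random partition (without replacement) of the merged
#' samples into groups of sizes `n1` and `n2`; whole individuals — both
#' haplotypes — move together. Uses the session RNG unless `seed` is given.
#'
#' @param merged A [genotype_panel()], e.g. from [merge_panels()].
#' @param n1,n2 Group sizes; must sum to the merged sample count.
#' @param seed Optional RNG seed.
#' @return List of two `genotype_panel` objects.
#' @export
resample_split <- function(merged, n1, n2, seed = NULL) {
  n <- n_samples(merged)
  if (n1 + n2 != n) abort("n1 + n2 must equal the merged sample count")
  perm <- with_seed(seed, sample.int(n))
  i1 <- sort(perm[seq_len(n1)])
  i2 <- sort(perm[n1 + seq_len(n2)])
  list(subset_samples(merged, i1), subset_samples(merged, i2))
}

# Scoring matrix for the permutation loop: one row per individual for
# dosages; for haplotype counting, rows are haplotypes and `rows_per_ind`
# maps individuals to row pairs.
mc_score_data <- function(p1, p2, mode) {
  mode <- resolve_mode(mode, p1)
  if (mode == "haplotype_counted") resolve_mode(mode, p2)
  if (mode == "haplotype_em") {
    # generic (slow) path: full panel machinery per replicate
    return(list(mode = mode, p1 = p1, p2 = p2))
  }
  m1 <- if (mode == "haplotype_counted") p1$haplotypes else p1$dosages
  m2 <- if (mode == "haplotype_counted") p2$haplotypes else p2$dosages
  list(mode = mode, merged = rbind(m1, m2),
       per_ind = if (mode == "haplotype_counted") 2L else 1L)
}

mc_score_split <- function(data, idx1, idx2) {
  if (data$mode == "haplotype_em") {
    merged <- merge_panels(data$p1, data$p2)
    q1 <- subset_samples(merged, idx1)
    q2 <- subset_samples(merged, idx2)
    ld1 <- suppressMessages(ld_matrix(q1, mode = "haplotype_em"))
    ld2 <- suppressMessages(ld_matrix(q2, mode = "haplotype_em"))
    return(varld_score(ld1, ld2)$score)
  }
  if (data$per_ind == 2L) {
    idx1 <- as.vector(rbind(2L * idx1 - 1L, 2L * idx1))
    idx2 <- as.vector(rbind(2L * idx2 - 1L, 2L * idx2))
  }
  e1 <- eigenvalues_from_data(data$merged[idx1, , drop = FALSE])
  e2 <- eigenvalues_from_data(data$merged[idx2, , drop = FALSE])
  sum(abs(e1 - e2))
}

#' Monte Carlo permutation test of the varLD score
#'
#' Computes the observed regional varLD score between two harmonized panels,
#' then compares it with `b` replicate scores obtained by merging both
#' populations and repeatedly resampling groups of the original sizes from
#' the pool (a permutation of population labels; individuals move with both
#' haplotypes). The empirical p-value uses +1 smoothing,
#' \eqn{p = (1 + \#\{\mathrm{replicate} \ge \mathrm{observed}\}) / (1 + B)},
#' so the smallest attainable p at B = 10000 is 1/10001, printed as 0.0001.
#'
#' @param p1,p2 Harmonized [genotype_panel()] objects (identical variant
#'   lists); run [harmonize_panels()] first.
#' @param b Number of Monte Carlo iterations (default 10000).
#' @param mode LD mode as in [ld_matrix()]; both populations use the same
#'   mode.
#' @param seed RNG seed for reproducibility.
#' @return An object of class `varld_test`: `observed`, `replicates`, `b`,
#'   `p_value`, `seed`, `n1`, `n2`, `m`, `mode`.
#' @export
varld_test <- function(p1, p2, b = 10000L, mode = "auto", seed = NULL) {
  if (b < 1L) abort("b must be >= 1")
  if (!identical(p1$variants$id, p2$variants$id)) {
    abort("mismatched SNP lists: run harmonize_panels() before varld_test()")
  }
  mode_res <- resolve_mode(mode, p1)
  ld1 <- suppressMessages(ld_matrix(p1, mode = mode_res))
  ld2 <- suppressMessages(ld_matrix(p2, mode = mode_res))
  observed <- varld_score(ld1, ld2)$score

  n1 <- n_samples(p1)
  n2 <- n_samples(p2)
  data <- mc_score_data(p1, p2, mode_res)
  replicates <- with_seed(seed, {
    vapply(seq_len(b), function(i) {
      perm <- sample.int(n1 + n2)
      mc_score_split(data, perm[seq_len(n1)], perm[n1 + seq_len(n2)])
    }, numeric(1))
  })
  p_value <- (1 + sum(replicates >= observed)) / (1 + b)
  structure(
    list(observed = observed, replicates = replicates, b = as.integer(b),
         p_value = p_value, seed = seed, n1 = n1, n2 = n2,
         m = n_snps(p1), mode = mode_res,
         populations = c(p1$population, p2$population)),
    class = "varld_test"
  )
}

#' @export
print.varld_test <- function(x, ...) {
  cat(sprintf(
    "<varld_test> %s vs %s: score %.6g over %d SNPs, p = %.4f (B = %d)\n",
    x$populations[1], x$populations[2], x$observed, x$m, x$p_value, x$b))
  invisible(x)
}

#' @describeIn varld_test Replicate scores as a tibble (one row per
#'   iteration).
#' @param x A `varld_test`.
#' @param ... Unused.
#' @method tidy varld_test
#' @export
tidy.varld_test <- function(x, ...) {
  tibble::tibble(iteration = seq_len(x$b), score = x$replicates)
}

#' @describeIn varld_test One-row test summary.
#' @method glance varld_test
#' @export
glance.varld_test <- function(x, ...) {
  tibble::tibble(
    pop1 = x$populations[1], pop2 = x$populations[2],
    m_snps = x$m, n1 = x$n1, n2 = x$n2, mode = x$mode,
    score = x$observed, b = x$b, p_value = x$p_value
  )
}

#' Bonferroni correction across comparisons
#'
#' Family-wise error control by dividing the family alpha by the number of
#' comparisons (e.g. 0.05 / 10 = 0.005 for ten population pairs); a p-value
#' is flagged significant only when strictly below the per-test threshold.
#'
#' @param p_values Numeric vector of p-values.
#' @param alpha_family Family-wise level in (0, 1) (default 0.05).
#' @return A tibble with columns `p_value`, `alpha_per_test`, `significant`;
#'   attributes `alpha_family`, `n_comparisons`.
#' @export
bonferroni_adjust <- function(p_values, alpha_family = 0.05) {
  if (length(p_values) == 0L) abort("no p-values supplied")
  check_scalar_number(alpha_family, "alpha_family")
  if (alpha_family <= 0 || alpha_family >= 1) abort("alpha_family must be in (0, 1)")
  n <- length(p_values)
  thr <- alpha_family / n
  structure(
    tibble::tibble(p_value = p_values, alpha_per_test = thr,
                   significant = p_values < thr),
    alpha_family = alpha_family,
    n_comparisons = n
  )
}

#' Multi-pair varLD comparison table
#'
#' Runs the full pipeline — region extraction, pairwise harmonization, varLD
#' score, Monte Carlo permutation test — for each requested population pair
#' and applies a Bonferroni correction across exactly those pairs. Pooled
#' panels (e.g. an "Asian" pool concatenating several panels) can be declared
#' via `pools`; a pool is built by multi-way harmonization of its member
#' panels to their common SNP set followed by row concatenation.
#'
#' @param panels Named list of [genotype_panel()] objects.
#' @param pairs List of 2-element character vectors (or a 2-column matrix /
#'   data frame) naming the comparisons.
#' @param region Optional [region_spec()] applied to every panel first.
#' @param b Monte Carlo iterations per pair (default 10000).
#' @param alpha_family Family-wise level (default 0.05).
#' @param mode LD mode as in [ld_matrix()].
#' @param seed Base RNG seed; each pair uses a deterministic sub-seed so rows
#'   are reproducible independently.
#' @param pools Named list of character vectors defining pooled panels.
#' @param maf_min MAF threshold for harmonization (default 0.01).
#' @return A tibble of class `varld_comparison_tbl`, one row per pair:
#'   `pop1`, `pop2`, `chrom`, `start_bp`, `end_bp`, `m_snps`, `score`,
#'   `p_value`, `alpha_per_test`, `significant`. Attributes: `alpha_family`,
#'   `n_comparisons`, `b`, `seed`.
#' @export
pairwise_comparison_table <- function(panels, pairs, region = NULL,
                                      b = 10000L, alpha_family = 0.05,
                                      mode = "auto", seed = NULL,
                                      pools = NULL, maf_min = 0.01) {
  stopifnot(is.list(panels), !is.null(names(panels)))
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(pairs[i, 1:2]))
  }
  if (length(pairs) == 0L) abort("no pairs requested")
  for (nm in names(pools)) {
    panels[[nm]] <- pool_panels(panels[pools[[nm]]], nm, maf_min = maf_min)
  }
  labels <- unique(unlist(pairs))
  unknown <- setdiff(labels, names(panels))
  if (length(unknown) > 0L) {
    abort(paste0("unknown population label(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(region)) {
    panels[labels] <- lapply(panels[labels], extract_region, region = region)
    if (any(vapply(panels[labels], is.null, logical(1)))) {
      abort("a panel has no SNPs in the requested region")
    }
  }
  rows <- purrr::map_dfr(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    h <- suppressMessages(harmonize_panels(panels[[pr[1]]], panels[[pr[2]]],
                                           maf_min = maf_min))
    fit <- varld_test(h[[1]], h[[2]], b = b, mode = mode,
                      seed = derive_seed(seed, i))
    tibble::tibble(
      pop1 = pr[1], pop2 = pr[2],
      chrom = h[[1]]$variants$chrom[1],
      start_bp = min(h[[1]]$variants$pos),
      end_bp = max(h[[1]]$variants$pos),
      m_snps = fit$m, score = fit$observed, p_value = fit$p_value
    )
  })
  adj <- bonferroni_adjust(rows$p_value, alpha_family = alpha_family)
  rows$alpha_per_test <- adj$alpha_per_test
  rows$significant <- adj$significant
  structure(rows,
            alpha_family = alpha_family,
            n_comparisons = length(pairs),
            b = as.integer(b),
            seed = seed,
            class = c("varld_comparison_tbl", class(rows)))
}

# Multi-way harmonization to the common SNP set, then row concatenation.
pool_panels <- function(members, label, maf_min = 0.01) {
  if (length(members) < 1L) abort("empty pool definition")
  if (length(members) == 1L) {
    out <- members[[1]]
    out$population <- label
    return(out)
  }
  # iterate pairwise harmonization until the id set is stable across all
  repeat {
    ids_before <- lapply(members, function(p) paste(p$variants$chrom, p$variants$pos))
    for (i in seq_along(members)[-1]) {
      h <- suppressMessages(harmonize_panels(members[[1]], members[[i]],
                                             maf_min = maf_min))
      members[[1]] <- h[[1]]
      members[[i]] <- h[[2]]
    }
    common <- Reduce(intersect, lapply(members, function(p)
      paste(p$variants$chrom, p$variants$pos)))
    members <- lapply(members, function(p) {
      subset_variants(p, which(paste(p$variants$chrom, p$variants$pos) %in% common))
    })
    ids_after <- lapply(members, function(p) paste(p$variants$chrom, p$variants$pos))
    if (identical(ids_before, ids_after)) break
  }
  merged <- Reduce(function(a, b) merge_panels(a, b, population = label), members)
  merged$population <- label
  merged
}

#' Write a comparison table as tab-delimited text
#'
#' Scores are printed to 6 significant figures and p-values to 4 decimal
#' places; the returned object retains full precision.
#'
#' @param x A `varld_comparison_tbl` from [pairwise_comparison_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_comparison_table <- function(x, path) {
  df <- data.frame(
    start_end = sprintf("%.3f-%.3f", x$start_bp / 1e6, x$end_bp / 1e6),
    pop1 = x$pop1, pop2 = x$pop2, m_snps = x$m_snps,
    score = signif(x$score, 6), p_value = sprintf("%.4f", x$p_value),
    significant = x$significant
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.varld_comparison_tbl <- function(x, ...) {
  cat(sprintf("varLD comparison table: %d pair(s), alpha %.3g / %d = %.4g per test, B = %d\n",
              nrow(x), attr(x, "alpha_family"), attr(x, "n_comparisons"),
              attr(x, "alpha_family") / attr(x, "n_comparisons"), attr(x, "b")))
  NextMethod()
}
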