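test_that("merging concatenates samples and pools allele counts", {
  p1 <- make_panel(rbind(c(0, 1), c(1, 2), c(2, 0)), population = "A")
  p2 <- make_panel(rbind(c(2, 2), c(1, 1), c(0, 1), c(1, 0)), population = "B")
  m <- merge_panels(p1, p2)
  expect_equal(nrow(m$dosages), 7L)
  f_merged <- allele_frequency(m, "rs001")
  n1 <- 3; n2 <- 4
  expect_equal(f_merged,
               (n1 * allele_frequency(p1, "rs001") +
                  n2 * allele_frequency(p2, "rs001")) / (n1 + n2))
  dup <- merge_panels(p1, p1)
  expect_equal(unname(dup$dosages), unname(rbind(p1$dosages, p1$dosages)))
  p3 <- make_panel(rbind(c(0, 1), c(1, 2), c(2, 0)), pos = c(100, 300))
  expect_error(merge_panels(p1, p3), "variant mismatch")
})

test_that("resample_split partitions whole individuals uniformly", {
  p <- make_phased_panel(matrix(rbinom(16, 1, 0.5), ncol = 2))
  sp <- resample_split(p, 2, 2, seed = 1)
  ids <- c(rownames(sp[[1]]$dosages), rownames(sp[[2]]$dosages))
  expect_setequal(ids, rownames(p$dosages))
  expect_equal(nrow(sp[[1]]$dosages), 2L)
  expect_equal(nrow(sp[[2]]$dosages), 2L)
  # individuals carry both haplotypes
  expect_equal(nrow(sp[[1]]$haplotypes), 4L)
  expect_error(resample_split(p, 3, 2), "n1 \\+ n2")

  # uniformity over the 6 labelled 2/2 partitions of 4 individuals
  counts <- withr::with_seed(10, {
    draws <- replicate(10000, {
      g1 <- sort(sample.int(4, 2))
      paste(g1, collapse = ",")
    })
    table(draws)
  })
  # direct check of the same scheme used by resample_split
  expect_equal(length(counts), 6L)
  sigma <- sqrt(10000 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - 10000 / 6) < 3 * sigma))
  # and the function itself visits all partitions
  parts <- vapply(1:300, function(i) {
    s <- resample_split(p, 2, 2, seed = i)
    paste(sort(rownames(s[[1]]$dosages)), collapse = ",")
  }, character(1))
  expect_equal(length(unique(parts)), 6L)
})

test_that("identical panels give observed score 0 and p = 1", {
  cfg <- sim_config(m = 8, n1 = 20, n2 = 20, seed = 2, shared_draw = TRUE)
  pair <- simulate_pair(cfg)
  fit <- varld_test(pair[[1]], pair[[2]], b = 49, seed = 5)
  expect_equal(fit$observed, 0)
  expect_equal(fit$p_value, 1)
})

test_that("the permutation p-value uses +1 smoothing with a 1/(B+1) floor", {
  cfg <- sim_config(m = 10, n1 = 40, n2 = 40,
                    divergence = divergence_ar1_contrast(0.95, 0.05), seed = 6)
  pair <- simulate_pair(cfg)
  h <- suppressMessages(harmonize_panels(pair[[1]], pair[[2]]))
  fit <- varld_test(h[[1]], h[[2]], b = 199, seed = 11)
  k <- sum(fit$replicates >= fit$observed)
  expect_equal(fit$p_value, (1 + k) / (1 + 199))
  expect_gte(fit$p_value, 1 / 200)
  expect_length(fit$replicates, 199)
  expect_error(varld_test(h[[1]], h[[2]], b = 0), ">= 1")
})

test_that("the test is deterministic given a seed", {
  cfg <- sim_config(m = 8, n1 = 30, n2 = 30, seed = 14)
  pair <- simulate_pair(cfg)
  h <- suppressMessages(harmonize_panels(pair[[1]], pair[[2]]))
  f1 <- varld_test(h[[1]], h[[2]], b = 99, seed = 33)
  f2 <- varld_test(h[[1]], h[[2]], b = 99, seed = 33)
  expect_identical(f1$replicates, f2$replicates)
  expect_identical(f1$p_value, f2$p_value)
  f3 <- varld_test(h[[1]], h[[2]], b = 99, seed = 34)
  expect_false(identical(f1$replicates, f3$replicates))
})

test_that("dosage and haplotype permutation routes agree on the observed score", {
  cfg <- sim_config(m = 10, n1 = 40, n2 = 40, seed = 26)
  pair <- simulate_pair(cfg)
  f_hap <- varld_test(pair[[1]], pair[[2]], b = 5, mode = "haplotype_counted",
                      seed = 1)
  s_direct <- varld_score(ld_matrix(pair[[1]], mode = "haplotype_counted"),
                          ld_matrix(pair[[2]], mode = "haplotype_counted"))$score
  expect_equal(f_hap$observed, s_direct)
  f_gen <- varld_test(pair[[1]], pair[[2]], b = 5, mode = "genotype_corr",
                      seed = 1)
  s_gen <- varld_score(ld_matrix(pair[[1]], mode = "genotype_corr"),
                       ld_matrix(pair[[2]], mode = "genotype_corr"))$score
  expect_equal(f_gen$observed, s_gen)
})

test_that("Bonferroni adjustment divides alpha and flags strictly", {
  adj <- bonferroni_adjust(rep(0.01, 10), alpha_family = 0.05)
  expect_equal(unique(adj$alpha_per_test), 0.005)
  single <- bonferroni_adjust(0.03, alpha_family = 0.05)
  expect_equal(single$alpha_per_test, 0.05)
  expect_true(single$significant)
  # boundary: p exactly at the threshold is NOT significant
  at <- bonferroni_adjust(c(0.005, 0.0049), alpha_family = 0.05)
  expect_equal(unique(at$alpha_per_test), 0.025)
  at10 <- bonferroni_adjust(c(0.005, rep(0.5, 9)), alpha_family = 0.05)
  expect_false(at10$significant[1])
  expect_error(bonferroni_adjust(numeric(0)), "no p-values")
  expect_error(bonferroni_adjust(0.1, alpha_family = 1.2), "\\(0, 1\\)")
})

test_that("the comparison table runs harmonize + test per pair with pooling", {
  cfg_a <- sim_config(m = 15, n1 = 30, n2 = 30, seed = 51)
  cfg_b <- sim_config(m = 15, n1 = 30, n2 = 30, seed = 52)
  cfg_c <- sim_config(m = 15, n1 = 30, n2 = 30,
                      structure = structure_ar1(0.1), seed = 53)
  panels <- list(
    A = simulate_haplotypes(cfg_a, 1),
    B = simulate_haplotypes(cfg_b, 1),
    C = simulate_haplotypes(cfg_c, 1)
  )
  tbl <- suppressMessages(pairwise_comparison_table(
    panels, pairs = list(c("A", "B"), c("A", "C"), c("B", "C")),
    b = 999, seed = 99, mode = "genotype_corr"
  ))
  expect_equal(nrow(tbl), 3L)
  expect_equal(unique(tbl$alpha_per_test), 0.05 / 3)
  # only the LD-divergent pairs are flagged
  expect_false(tbl$significant[tbl$pop1 == "A" & tbl$pop2 == "B"])
  expect_true(all(tbl$significant[tbl$pop2 == "C"]))

  # self-pair: p = 1, never significant
  self_tbl <- suppressMessages(pairwise_comparison_table(
    panels, pairs = list(c("A", "A")), b = 49, seed = 1))
  expect_equal(self_tbl$p_value, 1)
  expect_false(self_tbl$significant)

  # pooled panel = concatenation after multi-way harmonization
  tbl_pool <- suppressMessages(pairwise_comparison_table(
    panels, pairs = list(c("A", "BC")), b = 49, seed = 7,
    pools = list(BC = c("B", "C"))))
  expect_equal(nrow(tbl_pool), 1L)
  expect_error(suppressMessages(pairwise_comparison_table(
    panels, pairs = list(c("A", "Z")), b = 9)), "unknown population")
})

test_that("swapped arguments give an equivalent null distribution", {
  cfg <- sim_config(m = 8, n1 = 25, n2 = 35, seed = 61)
  pair <- simulate_pair(cfg)
  h <- suppressMessages(harmonize_panels(pair[[1]], pair[[2]]))
  p_fwd <- vapply(1:30, function(i)
    varld_test(h[[1]], h[[2]], b = 99, seed = i)$p_value, numeric(1))
  p_rev <- vapply(1:30, function(i)
    varld_test(h[[2]], h[[1]], b = 99, seed = i)$p_value, numeric(1))
  expect_equal(varld_test(h[[1]], h[[2]], b = 9, seed = 1)$observed,
               varld_test(h[[2]], h[[1]], b = 9, seed = 1)$observed)
  expect_gt(stats::ks.test(p_fwd, p_rev)$p.value, 0.01)
})
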