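test_that("haplotype pair LD reproduces hand-counted D, D', r", {
  # perfect LD: haplotypes AB x2, ab x2
  perfect <- pair_ld_haplotypes(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$d, 0.25)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$d_prime, 1)

  # counts AB=3, Ab=1, aB=1, ab=3 -> D = 1/8, r = 0.5
  a <- c(rep(1, 3), 1, 0, rep(0, 3))
  b <- c(rep(1, 3), 0, 1, rep(0, 3))
  x <- pair_ld_haplotypes(a, b)
  expect_equal(x$d, 1 / 8)
  expect_equal(x$r, 0.5)
  expect_equal(x$r2, 0.25)
  expect_equal(x$r2, x$r^2)
  expect_true(x$d_prime >= 0 && x$d_prime <= 1)
  expect_true(abs(x$d) <= 0.25)

  # symmetry
  y <- pair_ld_haplotypes(b, a)
  expect_equal(y$r, x$r)
  expect_equal(y$r2, x$r2)

  expect_error(pair_ld_haplotypes(c(1, 1, 1, 1), c(0, 1, 0, 1)), "monomorphic")
  expect_error(pair_ld_haplotypes(c(1, 0, NA), c(0, 1, 1)), "fewer than 4")
})

test_that("independent loci give mean r2 near the 1/(2n) sampling floor", {
  n <- 500
  r2s <- withr::with_seed(99, {
    replicate(200, {
      a <- rbinom(2 * n, 1, 0.4)
      b <- rbinom(2 * n, 1, 0.4)
      pair_ld_haplotypes(a, b)$r2
    })
  })
  expect_lt(abs(mean(r2s) - 1 / (2 * n)), 3e-4)
})

test_that("genotype-based pair LD handles identity, relabeling and EM mode", {
  g <- c(0, 1, 2, 1, 0, 2, 1, 1)
  expect_equal(pair_ld_genotypes(g, g)$r, 1)
  flipped <- pair_ld_genotypes(g, 2 - g)
  expect_equal(flipped$r, -1)
  expect_equal(flipped$r2, 1)
  expect_true(is.na(pair_ld_genotypes(g, rev(g), mode = "genotype_corr")$d))
  expect_error(pair_ld_genotypes(g, rep(2, 8)), "zero dosage variance")

  # EM on dosages equals haplotype counting on the phased source when the
  # fixture has no ambiguous double heterozygotes
  hap_a <- c(1, 1, 1, 0, 0, 0, 1, 0, 0, 1, 1, 0)
  hap_b <- c(1, 1, 1, 0, 0, 0, 1, 0, 0, 1, 1, 0)  # perfect LD, unambiguous
  h <- cbind(hap_a, hap_b)
  truth <- pair_ld_haplotypes(hap_a, hap_b)
  i1 <- seq(1, length(hap_a), by = 2)
  em <- pair_ld_genotypes(hap_a[i1] + hap_a[i1 + 1], hap_b[i1] + hap_b[i1 + 1],
                          mode = "haplotype_em")
  expect_equal(em$r2, truth$r2, tolerance = 1e-6)
  expect_equal(em$d, truth$d, tolerance = 1e-6)
})

test_that("EM-mode pair LD matches phased counting on a simulated panel", {
  cfg <- sim_config(m = 2, n1 = 80, n2 = 80, structure = structure_ar1(0.9),
                    freq_range = c(0.3, 0.5), seed = 17)
  p <- simulate_haplotypes(cfg, 1)
  truth <- pair_ld_haplotypes(p$haplotypes[, 1], p$haplotypes[, 2])
  em <- pair_ld_genotypes(p$dosages[, 1], p$dosages[, 2], mode = "haplotype_em")
  # EM converges to the MLE, which tracks the phased counts closely at this
  # LD level but is not identical in the presence of double heterozygotes
  expect_equal(em$r, truth$r, tolerance = 0.02)
})

test_that("ld_matrix agrees with a brute-force per-pair loop", {
  cfg <- sim_config(m = 5, n1 = 40, n2 = 40, seed = 7)
  p <- simulate_haplotypes(cfg, 1)
  ld <- ld_matrix(p, mode = "haplotype_counted")
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(ld$r_signed[i, j],
                   pair_ld_haplotypes(p$haplotypes[, i], p$haplotypes[, j])$r,
                   tolerance = 1e-12)
    }
  }
  expect_equal(unname(diag(ld$r_signed)), rep(1, 5))
  expect_equal(ld$r_signed, t(ld$r_signed))
  expect_true(all(abs(ld$r_signed) <= 1 + 1e-12))

  # duplicated SNP column -> off-diagonal 1
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1), ncol = 2)
  ld2 <- ld_matrix(make_panel(d), mode = "genotype_corr")
  expect_equal(ld2$r_signed[1, 2], 1)
})

test_that("AR(1) panels show |r| decaying with SNP lag", {
  cfg <- sim_config(m = 30, n1 = 150, n2 = 150, structure = structure_ar1(0.8),
                    freq_range = c(0.2, 0.5), seed = 31)
  p <- simulate_haplotypes(cfg, 1)
  ld <- ld_matrix(p, mode = "haplotype_counted")
  mean_abs_r_at_lag <- function(l) {
    idx <- cbind(seq_len(30 - l), seq_len(30 - l) + l)
    mean(abs(ld$r_signed[idx]))
  }
  lags <- c(1, 5, 10, 20)
  vals <- vapply(lags, mean_abs_r_at_lag, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("undefined LD pairs are zero-filled with a log, or raise in strict mode", {
  # SNP 2 and SNP 3 never observed together
  d <- rbind(c(0, 1, NA), c(1, 2, NA), c(2, 0, NA),
             c(1, NA, 0), c(0, NA, 1), c(2, NA, 2))
  p <- make_panel(d)
  expect_message(ld <- ld_matrix(p, mode = "genotype_corr"), "undefined")
  expect_equal(ld$r_signed[2, 3], 0)
  expect_error(suppressMessages(ld_matrix(p, mode = "genotype_corr", strict = TRUE)),
               "undefined")
})

test_that("allele recoding negates a SNP's r row but leaves r2 unchanged", {
  cfg <- sim_config(m = 6, n1 = 50, n2 = 50, seed = 13)
  p <- simulate_haplotypes(cfg, 1)
  ld <- ld_matrix(p)
  q <- flip_alleles(p, 3)
  ld2 <- ld_matrix(q)
  expect_equal(ld2$r_signed[3, -3], -ld$r_signed[3, -3])
  expect_equal(ld2$r_signed[-3, -3], ld$r_signed[-3, -3])
  expect_equal(ld2$r_signed^2, ld$r_signed^2)
})

test_that("ld_profile is the focal row of the LD matrix", {
  cfg <- sim_config(m = 8, n1 = 60, n2 = 60, seed = 19)
  p <- simulate_haplotypes(cfg, 1)
  focal <- p$variants$id[4]
  prof <- ld_profile(p, focal)
  ld <- ld_matrix(p)
  expect_equal(prof$r2, unname(ld$r_signed[4, ]^2), tolerance = 1e-12)
  expect_equal(prof$r2[4], 1)
  expect_equal(prof$pos, p$variants$pos)

  # focal vs an independent column at n = 200 stays below r2 = 0.1
  ind <- withr::with_seed(5, {
    h <- cbind(rbinom(400, 1, 0.4), rbinom(400, 1, 0.4))
    make_phased_panel(h)
  })
  prof2 <- ld_profile(ind, "rs001")
  expect_lt(prof2$r2[2], 0.1)

  expect_error(ld_profile(p, "absent"), "not present")
  mono <- make_panel(cbind(c(1, 1, 1, 1), c(0, 1, 2, 1)))
  expect_error(ld_profile(mono, "rs001"), "monomorphic")
})

test_that("LD statistics are invariant under sample permutation", {
  cfg <- sim_config(m = 5, n1 = 40, n2 = 40, seed = 43)
  p <- simulate_haplotypes(cfg, 1)
  perm <- withr::with_seed(2, sample(40))
  q <- ldcontrast:::subset_samples(p, perm)
  expect_equal(ld_matrix(q)$r_signed, ld_matrix(p)$r_signed, tolerance = 1e-12)
})

test_that("genotype correlation approaches haplotype r under HWE", {
  cfg <- sim_config(m = 2, n1 = 500, n2 = 500, structure = structure_ar1(0.7),
                    freq_range = c(0.2, 0.5), seed = 47)
  p <- simulate_haplotypes(cfg, 1)
  r_hap <- pair_ld_haplotypes(p$haplotypes[, 1], p$haplotypes[, 2])$r
  r_gen <- pair_ld_genotypes(p$dosages[, 1], p$dosages[, 2],
                             mode = "genotype_corr")$r
  expect_lt(abs(r_hap - r_gen), 0.05)
})

test_that("LD matrix export writes square and long formats", {
  cfg <- sim_config(m = 4, n1 = 20, n2 = 20, seed = 3)
  ld <- ld_matrix(simulate_haplotypes(cfg, 1))
  sq <- withr::local_tempfile(fileext = ".tsv")
  lg <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, sq, format = "square")
  write_ld_matrix(ld, lg, format = "long")
  m <- as.matrix(read.table(sq, header = TRUE, row.names = 1, sep = "\t"))
  expect_equal(unname(m), unname(ld$r_signed), tolerance = 1e-12)
  long <- read.table(lg, header = TRUE, sep = "\t")
  expect_equal(nrow(long), choose(4, 2))
  expect_named(long, c("snp1", "snp2", "pos1", "pos2", "r", "r2"))
})
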