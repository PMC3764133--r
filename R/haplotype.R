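# Multilocus haplotype-frequency EM and the block / tag-SNP analyses built
# on it. Haplotypes over k SNPs are coded as binary strings, first SNP most
# significant, so the frequency vector is indexed 1..2^k in lexicographic
# order ("00...0" first).

# Enumerate, for one multilocus genotype row, all ordered haplotype pairs
# (h1, h2) consistent with it. `g` has entries 0/1/2/NA. Returns a 2-column
# integer matrix of 1-based haplotype indices.
consistent_pairs <- function(g, k) {
  pow <- 2^((k - 1):0)
  # choices for h1 bit at each site; h2 bit is determined at observed sites
  h1_choices <- vector("list", k)
  free2 <- is.na(g)
  for (j in seq_len(k)) {
    h1_choices[[j]] <- if (is.na(g[j])) c(0, 1)
    else if (g[j] == 0) 0 else if (g[j] == 2) 1 else c(0, 1)
  }
  h1_grid <- as.matrix(expand.grid(h1_choices, KEEP.OUT.ATTRS = FALSE))
  res1 <- integer(0); res2 <- integer(0)
  miss_idx <- which(free2)
  h2_free_grid <- if (length(miss_idx)) {
    as.matrix(expand.grid(rep(list(c(0, 1)), length(miss_idx)),
                          KEEP.OUT.ATTRS = FALSE))
  } else matrix(0, nrow = 1, ncol = 0)
  for (row in seq_len(nrow(h1_grid))) {
    h1 <- h1_grid[row, ]
    h2_base <- ifelse(is.na(g), 0, g - h1)
    for (fr in seq_len(nrow(h2_free_grid))) {
      h2 <- h2_base
      if (length(miss_idx)) h2[miss_idx] <- h2_free_grid[fr, ]
      res1 <- c(res1, sum(h1 * pow) + 1L)
      res2 <- c(res2, sum(h2 * pow) + 1L)
    }
  }
  cbind(res1, res2)
}

# EM over a dosage matrix (n x k), k <= 12. Returns list(frequencies,
# log_likelihood, n_iter, converged, n_chromosomes). Rows that are entirely
# missing are dropped (logged by callers that care).
em_freqs_matrix <- function(geno, max_iter = 1000L, tol = 1e-7) {
  k <- ncol(geno)
  nh <- 2L^k
  all_miss <- rowSums(!is.na(geno)) == 0L
  geno <- geno[!all_miss, , drop = FALSE]
  n <- nrow(geno)
  if (n == 0L) abort("EM: no informative samples")

  # collapse identical genotype rows into weighted classes
  key <- apply(geno, 1, paste, collapse = ",")
  classes <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[classes])))
  geno_u <- geno[classes, , drop = FALSE]
  pairs <- lapply(seq_len(nrow(geno_u)), function(i) consistent_pairs(geno_u[i, ], k))

  # initialize at linkage equilibrium
  p <- colMeans(geno, na.rm = TRUE) / 2
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  bits <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
  f <- apply(bits, 1, function(b) prod(ifelse(b == 1, p, 1 - p)))
  f <- f / sum(f)

  ll_old <- -Inf
  n_iter <- 0L
  converged <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    counts <- numeric(nh)
    ll <- 0
    for (i in seq_along(pairs)) {
      pr <- pairs[[i]]
      wt <- f[pr[, 1]] * f[pr[, 2]]
      s <- sum(wt)
      if (s <= 0) { wt <- rep(1 / nrow(pr), nrow(pr)); s <- 1e-300 }
      ll <- ll + w[i] * log(s)
      q <- wt / sum(wt)
      inc1 <- tapply(q, pr[, 1], sum)
      inc2 <- tapply(q, pr[, 2], sum)
      counts[as.integer(names(inc1))] <- counts[as.integer(names(inc1))] + w[i] * inc1
      counts[as.integer(names(inc2))] <- counts[as.integer(names(inc2))] + w[i] * inc2
    }
    f <- counts / (2 * n)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; ll_old <- ll; break }
    ll_old <- ll
    if (n_iter >= max_iter) break
  }
  list(frequencies = f, log_likelihood = ll_old, n_iter = n_iter,
       converged = converged, n_chromosomes = 2L * n)
}

#' Haplotype frequencies by EM (or direct counting when phased)
#'
#' Estimates multilocus haplotype frequencies for up to 12 SNPs. For phased
#' panels, frequencies are counted directly from the haplotype matrix. For
#' unphased panels, an EM algorithm distributes each ambiguous multilocus
#' genotype over its consistent haplotype pairs in proportion to current
#' frequency products (E-step) and renormalizes expected counts (M-step); the
#' log-likelihood is non-decreasing across iterations.
#'
#' @param panel A [genotype_panel()].
#' @param snp_ids SNP identifiers to include, 2 to 12 of them, in panel order
#'   or any order (output follows the given order).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param tol Convergence tolerance on the log-likelihood change (default
#'   1e-7).
#' @return A tibble of class `haplotype_freqs` with columns `haplotype`
#'   (binary string, 1 = `allele_b`, first SNP leftmost) and `frequency`,
#'   sorted by decreasing frequency, zero-frequency haplotypes omitted.
#'   Attributes: `snp_ids`, `n_chromosomes`, `log_likelihood`, `n_iter`,
#'   `converged`.
#' @export
em_haplotype_freqs <- function(panel, snp_ids, max_iter = 1000L, tol = 1e-7) {
  k <- length(snp_ids)
  if (k < 2L || k > 12L) abort("em_haplotype_freqs supports 2 to 12 SNPs")
  idx <- match(snp_ids, panel$variants$id)
  if (anyNA(idx)) {
    abort(paste0("unknown SNP id(s): ", paste(snp_ids[is.na(idx)], collapse = ", ")))
  }
  if (panel$phased) {
    h <- panel$haplotypes[, idx, drop = FALSE]
    complete <- rowSums(is.na(h)) == 0L
    h <- h[complete, , drop = FALSE]
    if (nrow(h) == 0L) abort("no complete haplotypes at the requested SNPs")
    codes <- apply(h, 1, paste, collapse = "")
    tab <- table(codes)
    f <- as.numeric(tab) / sum(tab)
    haps <- names(tab)
    ll <- sum(as.numeric(tab) * log(f))
    res <- list(frequencies = f, haplotypes = haps, log_likelihood = ll,
                n_iter = 0L, converged = TRUE, n_chromosomes = nrow(h))
  } else {
    geno <- panel$dosages[, idx, drop = FALSE]
    n_drop <- sum(rowSums(!is.na(geno)) == 0L)
    if (n_drop > 0L) log_note("em_haplotype_freqs: dropped %d all-missing sample(s)", n_drop)
    em <- em_freqs_matrix(geno, max_iter = max_iter, tol = tol)
    bits <- expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE]
    haps <- apply(bits, 1, paste, collapse = "")
    res <- list(frequencies = em$frequencies, haplotypes = haps,
                log_likelihood = em$log_likelihood, n_iter = em$n_iter,
                converged = em$converged, n_chromosomes = em$n_chromosomes)
  }
  keep <- res$frequencies > 1e-12
  out <- tibble::tibble(haplotype = res$haplotypes[keep],
                        frequency = res$frequencies[keep])
  out <- out[order(-out$frequency, out$haplotype), ]
  structure(out,
            snp_ids = snp_ids,
            n_chromosomes = res$n_chromosomes,
            log_likelihood = res$log_likelihood,
            n_iter = res$n_iter,
            converged = res$converged,
            class = c("haplotype_freqs", class(out)))
}

#' Likelihood-based confidence interval for D'
#'
#' Profiles the two-locus multinomial genotype log-likelihood over a grid of
#' D' values in [0, 1] (step 0.001), holding allele frequencies at their
#' estimates and the sign of D at the EM estimate. The interval is the range
#' of grid values within the chi-squared(1)-based drop from the maximum.
#'
#' @param panel A [genotype_panel()].
#' @param snp_i,snp_j SNP identifiers.
#' @param confidence Confidence level (default 0.95).
#' @return Named numeric vector `c(d_prime_low, d_prime_high)`.
#' @export
dprime_ci <- function(panel, snp_i, snp_j, confidence = 0.95) {
  idx <- match(c(snp_i, snp_j), panel$variants$id)
  if (anyNA(idx)) abort("unknown SNP id in dprime_ci")
  g1 <- panel$dosages[, idx[1]]
  g2 <- panel$dosages[, idx[2]]
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  if (sd(g1) == 0 || sd(g2) == 0) abort("undefined LD: monomorphic SNP")

  em <- em_freqs_matrix(cbind(g1, g2))
  f <- em$frequencies  # order 00,01,10,11
  p_a <- f[3] + f[4]; p_b <- f[2] + f[4]
  d_hat <- f[4] - p_a * p_b
  s <- if (d_hat < 0) -1 else 1
  d_max <- if (s < 0) min(p_a * p_b, (1 - p_a) * (1 - p_b)) else
    min(p_a * (1 - p_b), (1 - p_a) * p_b)
  if (d_max <= 0) abort("undefined LD: degenerate allele frequencies")

  counts <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  grid <- seq(0, 1, by = 0.001)
  d_grid <- s * grid * d_max
  eps <- 1e-12
  p11 <- pmax(p_a * p_b + d_grid, eps)
  p10 <- pmax(p_a * (1 - p_b) - d_grid, eps)
  p01 <- pmax((1 - p_a) * p_b - d_grid, eps)
  p00 <- pmax((1 - p_a) * (1 - p_b) + d_grid, eps)
  # genotype-class probabilities under HWE: G[gi, gj]
  ll <- numeric(length(grid))
  cls <- list(
    c(0, 0), c(0, 1), c(0, 2),
    c(1, 0), c(1, 1), c(1, 2),
    c(2, 0), c(2, 1), c(2, 2)
  )
  hap_p <- function(x, y) {  # P(haplotype carrying allele x at locus1, y at locus2)
    if (x == 0 && y == 0) p00 else if (x == 0 && y == 1) p01
    else if (x == 1 && y == 0) p10 else p11
  }
  for (cl in cls) {
    n_cl <- counts[cl[1] + 1L, cl[2] + 1L]
    if (n_cl == 0) next
    # sum over ordered haplotype pairs consistent with (gi, gj)
    x1s <- if (cl[1] == 0) 0 else if (cl[1] == 2) 1 else c(0, 1)
    pr <- 0
    for (x1 in x1s) {
      x2 <- cl[1] - x1
      y1s <- if (cl[2] == 0) 0 else if (cl[2] == 2) 1 else c(0, 1)
      for (y1 in y1s) {
        y2 <- cl[2] - y1
        pr <- pr + hap_p(x1, y1) * hap_p(x2, y2)
      }
    }
    ll <- ll + n_cl * log(pr)
  }
  cut <- max(ll) - qchisq(confidence, df = 1) / 2
  inside <- grid[ll >= cut]
  c(d_prime_low = min(inside), d_prime_high = max(inside))
}

#' Haplotype block detection
#'
#' Two block definitions over the panel's positional SNP ordering:
#' \describe{
#'   \item{gabriel}{Confidence-interval blocks: a SNP pair is in "strong LD"
#'     when its D' interval ([dprime_ci()]) has lower bound >= `strong_low`
#'     and upper bound >= `strong_high`; it shows "strong recombination" when
#'     the upper bound is < `recomb_high`. A span is a candidate block when
#'     its end pair is in strong LD and at least `informative_frac` of its
#'     informative pairs (strong LD or strong recombination) are strong.
#'     Maximal non-overlapping blocks are chosen greedily by bp span, ties to
#'     the leftmost.}
#'   \item{four_gamete}{Maximal runs in which every internal pair shows at
#'     most 3 of the 4 possible gametes at frequency >= `gamete_min`.}
#' }
#'
#' @param panel A [genotype_panel()] with >= 2 polymorphic SNPs.
#' @param method `"gabriel"` or `"four_gamete"`.
#' @param strong_low,strong_high,recomb_high,informative_frac Gabriel
#'   thresholds (defaults 0.70, 0.98, 0.90, 0.95).
#' @param gamete_min Minimum gamete frequency for the four-gamete rule
#'   (default 0.01).
#' @param max_span_snps Largest span (in SNPs) examined for Gabriel blocks
#'   (default 50), bounding the quadratic pair scan.
#' @param confidence Confidence level for the D' intervals (default 0.95).
#' @return A tibble of class `ld_blocks`, one row per block: `block_id`,
#'   `chrom`, `start_bp`, `end_bp`, `n_snps`, `length_kb`, `snp_ids`
#'   (list-column). Blocks are disjoint and sorted by position.
#' @export
find_blocks <- function(panel, method = c("gabriel", "four_gamete"),
                        strong_low = 0.70, strong_high = 0.98,
                        recomb_high = 0.90, informative_frac = 0.95,
                        gamete_min = 0.01, max_span_snps = 50L,
                        confidence = 0.95) {
  method <- match.arg(method)
  m <- n_snps(panel)
  if (m < 2L) abort("find_blocks needs at least 2 SNPs")
  member <- switch(method,
    gabriel = gabriel_blocks(panel, strong_low, strong_high, recomb_high,
                             informative_frac, max_span_snps, confidence),
    four_gamete = four_gamete_blocks(panel, gamete_min)
  )
  if (length(member) == 0L) {
    out <- tibble::tibble(block_id = integer(), chrom = character(),
                          start_bp = integer(), end_bp = integer(),
                          n_snps = integer(), length_kb = numeric(),
                          snp_ids = list())
  } else {
    member <- member[order(vapply(member, min, integer(1)))]
    v <- panel$variants
    out <- tibble::tibble(
      block_id = seq_along(member),
      chrom = v$chrom[vapply(member, min, integer(1))],
      start_bp = v$pos[vapply(member, min, integer(1))],
      end_bp = v$pos[vapply(member, max, integer(1))],
      n_snps = lengths(member),
      snp_ids = lapply(member, function(i) v$id[i])
    )
    out$length_kb <- (out$end_bp - out$start_bp) / 1000
    out <- out[, c("block_id", "chrom", "start_bp", "end_bp", "n_snps",
                   "length_kb", "snp_ids")]
  }
  class(out) <- c("ld_blocks", class(out))
  out
}

gabriel_blocks <- function(panel, strong_low, strong_high, recomb_high,
                           informative_frac, max_span_snps, confidence) {
  m <- n_snps(panel)
  strong <- matrix(NA, m, m)
  informative <- matrix(NA, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, min(m, i + max_span_snps - 1L))) {
      ci <- tryCatch(
        dprime_ci(panel, panel$variants$id[i], panel$variants$id[j],
                  confidence = confidence),
        error = function(e) c(NA_real_, NA_real_))
      if (anyNA(ci)) { strong[i, j] <- FALSE; informative[i, j] <- FALSE; next }
      s <- ci[1] >= strong_low && ci[2] >= strong_high
      rec <- ci[2] < recomb_high
      strong[i, j] <- s
      informative[i, j] <- s || rec
    }
  }
  # candidate spans: end pair strong, >=informative_frac of informative pairs strong
  cand <- list()
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, min(m, i + max_span_snps - 1L))) {
      if (!isTRUE(strong[i, j])) next
      sub_s <- strong[i:j, i:j]
      sub_i <- informative[i:j, i:j]
      n_inf <- sum(sub_i, na.rm = TRUE)
      n_str <- sum(sub_s & sub_i, na.rm = TRUE)
      if (n_inf >= 1 && n_str / n_inf >= informative_frac) {
        cand[[length(cand) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(cand) == 0L) return(list())
  span_bp <- vapply(cand, function(x) {
    panel$variants$pos[x[2]] - panel$variants$pos[x[1]]
  }, numeric(1))
  starts <- vapply(cand, `[`, integer(1), 1L)
  ord <- order(-span_bp, starts)
  taken <- rep(FALSE, m)
  blocks <- list()
  for (k in ord) {
    rng <- cand[[k]][1]:cand[[k]][2]
    if (any(taken[rng])) next
    taken[rng] <- TRUE
    blocks[[length(blocks) + 1L]] <- rng
  }
  blocks
}

four_gamete_blocks <- function(panel, gamete_min) {
  m <- n_snps(panel)
  compatible <- function(i, j) {
    f <- if (panel$phased) {
      h <- panel$haplotypes[, c(i, j), drop = FALSE]
      h <- h[rowSums(is.na(h)) == 0L, , drop = FALSE]
      codes <- h[, 1] * 2 + h[, 2]
      as.numeric(table(factor(codes, levels = 0:3))) / nrow(h)
    } else {
      em_freqs_matrix(panel$dosages[, c(i, j), drop = FALSE])$frequencies
    }
    sum(f >= gamete_min) <= 3L
  }
  blocks <- list()
  i <- 1L
  while (i < m) {
    j <- i
    repeat {
      if (j + 1L > m) break
      ok <- all(vapply(i:j, function(a) compatible(a, j + 1L), logical(1)))
      if (!ok) break
      j <- j + 1L
    }
    if (j > i) blocks[[length(blocks) + 1L]] <- i:j
    i <- j + 1L
  }
  blocks
}

#' Write blocks as BED-like text
#'
#' BED uses 0-based half-open coordinates; this is the only output in the
#' package that does.
#'
#' @param blocks An `ld_blocks` tibble from [find_blocks()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_blocks_bed <- function(blocks, path) {
  df <- data.frame(
    chrom = blocks$chrom,
    start = blocks$start_bp - 1L,
    end = blocks$end_bp,
    name = paste0("block", blocks$block_id),
    n_snps = blocks$n_snps
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Greedy tag-SNP selection
#'
#' Repeatedly picks the SNP that covers the most still-uncovered SNPs at
#' r-squared >= `r2_threshold` (ties broken toward the lower position index)
#' until every SNP is covered by some tag.
#'
#' @param ld An [ld_matrix()].
#' @param r2_threshold Coverage threshold (default 0.8).
#' @return An object of class `tag_set`: list with `tags` (identifiers),
#'   `r2_threshold`, and `coverage` — a tibble mapping every SNP to its best
#'   covering tag and the corresponding r-squared.
#' @export
select_tags <- function(ld, r2_threshold = 0.8) {
  stopifnot(inherits(ld, "ld_matrix"))
  r2 <- ld$r_signed^2
  diag(r2) <- 1
  m <- nrow(r2)
  covered <- rep(FALSE, m)
  tags <- integer(0)
  while (!all(covered)) {
    gain <- colSums((r2 >= r2_threshold) & !covered)
    best <- which(gain == max(gain))[1]  # which() scans in position order: ties to lower index
    tags <- c(tags, best)
    covered <- covered | r2[, best] >= r2_threshold
  }
  tags <- sort(tags)
  cover_tag <- vapply(seq_len(m), function(i) tags[which.max(r2[i, tags])], integer(1))
  coverage <- tibble::tibble(
    id = ld$variant_ids,
    pos = ld$positions,
    tag = ld$variant_ids[cover_tag],
    r2 = r2[cbind(seq_len(m), cover_tag)],
    is_tag = seq_len(m) %in% tags
  )
  structure(
    list(tags = ld$variant_ids[tags], r2_threshold = r2_threshold,
         coverage = coverage),
    class = "tag_set"
  )
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("<tag_set> %d tag(s) at r2 >= %.2f: %s\n",
              length(x$tags), x$r2_threshold, paste(x$tags, collapse = ", ")))
  invisible(x)
}

#' @describeIn select_tags Coverage map as a tibble.
#' @param x A `tag_set`.
#' @param ... Unused.
#' @method tidy tag_set
#' @export
tidy.tag_set <- function(x, ...) x$coverage
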