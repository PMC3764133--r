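---
title: "Comparing regional LD structure between populations with ldcontrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing regional LD structure between populations with ldcontrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldcontrast)
```

## The problem

Genome-wide association findings often fail to replicate across ancestry
groups. One mechanism is purely statistical: an association signal is carried
by linkage disequilibrium (LD) between a genotyped SNP and an ungenotyped
causal variant, and the strength and extent of that LD differ between
populations. Around the Parkinson's disease gene *LRRK2* on chromosome 12,
for instance, Japanese and Caucasian GWAS implicated different SNPs in the
same ~345 kb interval (the package ships their positions via
`lrrk2_gwas_snps()`). `ldcontrast` asks the quantitative question behind such
discrepancies: *is the regional LD structure of two population panels more
different than sampling variation alone would produce?*

## Model and procedure

### Pairwise LD

For two biallelic loci with allele-B indicator frequencies $p_A$, $p_B$ and
haplotype frequency $p_{AB}$,

$$D = p_{AB} - p_A p_B, \qquad
  r = \frac{D}{\sqrt{p_A(1-p_A)\,p_B(1-p_B)}}, \qquad
  D' = \frac{|D|}{D_{\max}},$$

with $D_{\max} = \min\{p_A p_B, (1-p_A)(1-p_B)\}$ for $D<0$ and
$\min\{p_A(1-p_B), (1-p_A)p_B\}$ otherwise. Three estimation routes are
exposed and every comparison must use the same route for both populations:

* `haplotype_counted` — direct counting on phased haplotypes (the default
  when a panel is phased);
* `genotype_corr` — the composite Pearson correlation of dosage vectors,
  which converges to the haplotype $r$ under Hardy–Weinberg equilibrium (a
  property the test suite checks by simulation at $n = 500$);
* `haplotype_em` — two-locus haplotype frequencies by EM, then the haplotype
  formulas. Accurate for unphased data but quadratic-in-pairs slow, so it is
  not the default inside permutation loops.

Missing genotypes are handled by pairwise-complete deletion, the behaviour
of standard LD tools; nothing is imputed. A pair needs at least 4 complete
observations and two polymorphic loci, otherwise its LD is *undefined*.

### The regional varLD score

Each population's LD over $m$ shared SNPs is summarised by the signed
correlation matrix $R$ (unit diagonal, symmetric). With
$\lambda^{(1)} \ge \dots$ and $\lambda^{(2)} \ge \dots$ the rank-ordered
eigenvalues of the two populations' matrices, the score is

$$\mathrm{varLD} = \sum_{i=1}^{m} \left|\lambda^{(1)}_i - \lambda^{(2)}_i\right|.$$

Because each spectrum sums to $m$ (the trace), the score is 0 exactly when
the spectra coincide and can never exceed $2m$. Flipping the allele coding
of any SNP conjugates $R$ by a $\pm 1$ diagonal matrix and leaves the
spectrum — hence the score — unchanged, so the statistic is robust to
arbitrary reference-allele conventions *after* harmonization.

The package computes one region-wide score per population pair by default.
A sliding-window variant (`varld_windows()`) and a z-standardization utility
(`standardize_scores()`) exist for exploratory use; standardization is
monotone and therefore irrelevant to the permutation test below, which is
why raw scores feed the test.

### Monte Carlo permutation significance

Under the null hypothesis that both panels are samples from one population,
the group labels are exchangeable. `varld_test()` merges the two panels,
draws $B$ uniformly random re-partitions into groups of the original sizes
$n_1$ and $n_2$ — whole individuals move with both haplotypes — and recomputes
the score for each. The p-value uses add-one smoothing,

$$p = \frac{1 + \#\{\text{replicate} \ge \text{observed}\}}{1 + B},$$

which keeps $p > 0$, counts ties conservatively (with $\ge$), and gives a
floor of $1/(B{+}1)$ — at the conventional $B = 10000$, a printed `0.0001`.
Permutation (without replacement) was chosen over a bootstrap because label
exchange gives exact finite-sample validity. Across $k$ requested population
pairs, `pairwise_comparison_table()` applies a Bonferroni correction:
per-test threshold $\alpha/k$ (0.05/10 = 0.005 for a ten-pair family),
flagged on strict inequality, so $p = 0.005$ itself is *not* significant.

A pooled group (such as a combined "Asian" panel) is constructed by
multi-way harmonization of its member panels to their common SNP set
followed by row concatenation, and is labelled as such in output. Pooling
was chosen over averaging pairwise results because it matches the "merge
then resample" logic of the test itself; this is a package design choice, as
pooled-group construction has no single field convention.

### Harmonization

Cross-population comparison is only meaningful on a shared, consistently
oriented SNP set. `harmonize_panels()` intersects panels by (chromosome,
position), aligns allele labels (recoding dosages $d \to 2-d$ where the
sources flip reference and alternate), attempts a strand complement for
non-ambiguous discordant allele sets, drops strand-ambiguous A/T and C/G
SNPs that cannot be reconciled, and removes SNPs monomorphic or below
`maf_min` in either panel. The default `maf_min = 0.01` discards SNPs whose
$r$ is dominated by a handful of chromosomes; monomorphic SNPs are always
dropped because $r$ is undefined. Safety was preferred over coverage: an
ambiguous SNP silently flipped to the wrong strand corrupts the signed
matrix, whereas dropping it costs one of hundreds of SNPs.

## Haplotype analysis

`em_haplotype_freqs()` estimates multilocus haplotype frequencies for up to
12 SNPs (the $2^k$ enumeration limit). Phased panels are counted directly.
For unphased panels the EM algorithm distributes each multilocus genotype
over its consistent ordered haplotype pairs proportionally to current
frequency products and renormalizes expected counts; partially missing
genotypes are marginalized over the unobserved sites rather than dropped.
Initialization is at linkage equilibrium; the stopping rule is
$|\Delta \log L| < 10^{-7}$ or 1000 iterations. No random restarts are used:
at $k \le 12$ and these sample sizes the likelihood surface is
well-behaved, and the log-likelihood is verifiably non-decreasing per
iteration (a property test in the suite).

Blocks and tags follow the de facto standards:

* **Gabriel-style CI blocks** (`find_blocks(method = "gabriel")`): a pair is
  in *strong LD* when its profile-likelihood $D'$ interval (`dprime_ci()`,
  grid step 0.001, $\chi^2_1$ drop) has lower bound ≥ 0.70 and upper bound
  ≥ 0.98; *strong recombination* when the upper bound is < 0.90; pairs in
  neither category are uninformative. A span qualifies when its end pair is
  strong and ≥ 95% of informative pairs are strong; maximal non-overlapping
  spans are kept, longest (in bp) first, ties to the leftmost. The one
  convention left open by the CI-block idea — which pairs count as
  "informative" — follows Haploview: strong-LD or strong-recombination
  pairs, nothing else. A `max_span_snps` bound (default 50, ≈ 80 kb at the
  simulator's SNP spacing) caps the quadratic pair scan; regional blocks in
  data of this kind are an order of magnitude shorter.
* **Four-gamete blocks**: maximal runs where every internal pair shows at
  most 3 of the 4 gametes at frequency ≥ 0.01.
* **Greedy tagging** (`select_tags()`): repeatedly pick the SNP covering the
  most uncovered SNPs at $r^2 \ge$ threshold (default 0.8), ties to the
  lower position index, until all SNPs are covered. Tagging operates on the
  same LD mode as the rest of a run.

Common haplotypes are conventionally reported at ≥ 5% frequency.

## The synthetic-data generator

`simulate_haplotypes()` draws binary haplotypes through a Gaussian copula: a
latent multivariate normal vector with the population's target correlation
matrix is thresholded at each SNP's allele-frequency quantile, and
consecutive haplotypes are paired into diploid individuals. Defaults emulate
the regional panels the package targets: ~200 SNPs uniformly spaced over
~345 kb of chromosome 12 starting at 38,705,000, allele frequencies uniform
on [0.05, 0.5], and sample sizes of order 80–200 diploid individuals.
Divergence between the two populations of a pair is controlled explicitly:
`divergence_none()` (the permutation null), `divergence_ar1_contrast()`
(different AR(1) decay rates), or `divergence_block_permute()` (SNP-label
permutation in one target, destroying positional LD while preserving the
spectrum's scale). Allele frequencies and any label permutation derive from
the seed independently of the population index, so the two populations
always share one marginal law — divergence is purely an LD-structure
contrast.

The copula was chosen over coalescent simulation deliberately: the varLD
machinery consumes correlation matrices, and the copula gives direct,
seedable control over exactly that object. Two caveats follow. First, the
binary-scale correlation is *attenuated* relative to the latent target
(thresholding loses dependence), so all tests assert on empirical LD, never
on latent parameters. Second, the generator makes no attempt at demographic
realism — no mutation/recombination process, no allele-frequency divergence,
no trio structure, no genotyping error beyond a uniform missingness mask.
Passing validity and power checks on these panels therefore demonstrates the
statistical machinery is correct and well-calibrated for panels with
realistic marginals and LD scale; it does not certify behaviour under
population-specific allele-frequency differences or ascertainment quirks of
real genotyping platforms.

Non-positive-definite correlation targets (easy to write by hand for block
structures) are repaired by clipping eigenvalues at $10^{-6}$ and
renormalizing to unit diagonal, with a logged message.

## Numerical choices and degenerate inputs

* Eigenvalues come from the symmetric solver; ordering ties are broken by
  value then original index (no effect on the score).
* Matrix entries whose LD is undefined (monomorphic after missingness,
  < 4 complete observations) are set to 0 with a logged count so the
  eigendecomposition never sees `NaN`; `strict = TRUE` raises instead.
  Zero-filled matrices are *not* projected back to positive semidefinite —
  slightly negative eigenvalues are harmless because the score depends only
  on ordered eigenvalue differences.
* Coordinates are 1-based inclusive everywhere except the BED block export
  (0-based half-open, the BED convention).
* `p = threshold` is not significant (strict inequality), and replicates
  tied with the observed score count against the hypothesis (conservative).
* Score standardization uses the population SD so the output has unit scale
  exactly.
* Per-pair sub-seeds in `pairwise_comparison_table()` derive
  deterministically from the base seed and pair index, so any row can be
  reproduced independently.

## Validation problem sizes

The test suite and the acceptance script validate the pipeline at sizes
chosen to be informative yet desk-scale: type-I error from 400 null runs
($m = 20$, $n = 50$ per panel, $B = 199$), power from 200 runs of an AR(1)
0.9-vs-0.2 contrast ($m = 30$, $n = 100$, $B = 199$), the p-value floor on
one strongly divergent pair at $B = 10000$, and oracle equivalences (2-SNP
closed form $2|r_1 - r_2|$, characteristic-polynomial eigenvalues at
$m = 3$, EM versus direct counting) at machine tolerance.

## Known limitations

* Real HapMap and SGVP genotype panels are not bundled and are not fetched:
  published p-values for the *LRRK2* region depend on specific external data
  releases (and on unstated choices such as phased-versus-genotype input to
  the LD matrices), so they are not reproducible from this package alone.
  The pipeline accepts such panels via `read_vcf()`/`read_hapmap_table()`
  when the user supplies them.
* The EM enumeration limit ($k \le 12$) rules out chromosome-scale
  haplotype frequency tables; that is out of scope by design.
* No phasing, imputation, liftover, or pedigree inference; trio panels must
  be reduced to founders with `keep_samples()` before LD computation.
* `haplotype_em` mode inside the permutation loop is exact but slow; for
  unphased data at $B = 10000$, `genotype_corr` is the practical choice.
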