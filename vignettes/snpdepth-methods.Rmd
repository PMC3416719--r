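---
title: "Depth-aware SNP frequency estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-aware SNP frequency estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpdepth)
```

## Why depth belongs in the model

When a transcriptome is assembled from pooled reads and SNPs are scored by
comparing each contig's consensus to its constituent reads, the number of
variants found in a contig grows with both the contig's length (more sites
to be variable at) and its depth (more chances to sample the rarer
haplotype, and more sites clearing the minimum-read filters). Dividing SNP
counts by length alone — the ubiquitous "SNPs/kb" — therefore confounds
polymorphism with sequencing effort. `snpdepth` models per-contig SNP
counts explicitly as a function of length, depth, and transcript class,
and reports polymorphism as the *standardized* expected SNP count at a
reference length and depth.

## The SNP caller

The caller scores one consensus column at a time on contigs that pass an
eligibility gate, applying these rules (all thresholds live in
`filter_config()`):

* **Eligibility**: consensus length ≥ `min_contig_length` (default 100 bp;
  501 bp for a long-contig analysis) and ≥ `min_depth` (10) aligned reads.
* **Base quality**: a read base is counted only if its quality score is
  *strictly* greater than `min_base_quality` (20). Sub-threshold bases are
  ignored entirely — they neither support an allele nor disqualify the
  column. Read `N`s are likewise ignored.
* **Biallelism**: the quality-passing counts must contain exactly two
  distinct bases and *zero* gap observations. Gap characters are tallied
  unconditionally (they carry no quality), so any deletion evidence at a
  column vetoes it; columns with three alleles are likewise discarded.
* **Minor-allele support**: minor fraction ≥ `min_maf` (0.01) **or** minor
  count ≥ `min_minor_reads` (2). The OR is deliberate: below depth 200 the
  two-read arm binds, above it the frequency arm can rescue rare alleles.
  The MAF denominator is the quality-passing read count *at that column*,
  not the contig read count — the only denominator that stays meaningful
  when reads partially span a contig.
* **Flanks**: all `flank_len` (20) consensus positions on each side must
  exist, have consensus quality > 20, and not be `N`. Flank quality is
  judged on the *consensus* scores, since "high-quality sites" are defined
  by the assembler's per-base consensus quality.
* **Homopolymers**: a site inside, or immediately adjacent to, a maximal
  run of more than `max_homopolymer` (4) identical consensus bases is
  discarded. Adjacency is included because pyrosequencing homopolymer
  miscalls concentrate at run boundaries.
* **Ties**: if the two alleles have equal counts, the lexicographically
  later base is labelled minor — an arbitrary but deterministic
  convention; the call itself is retained (MAF = 0.5).

Accepted substitutions are classified as transitions (A↔G, C↔T) or
transversions. Coordinates are 1-based in every output (VCF convention).

## The count model and model selection

Per-contig SNP (or Ti, or Tv) counts are modelled as NB2:

$$\log \mu_i = \beta_0 + \beta_L\,\mathrm{LENGTH}_i +
  \beta_D\,\mathrm{DEPTH}_i + \beta_C\,\mathrm{C/NC}_i,
  \qquad \mathrm{Var}(y_i) = \mu_i + \alpha\,\mu_i^2 .$$

Covariates enter untransformed (bp and read counts), so $\beta_L$ is a
per-bp and $\beta_D$ a per-read log-rate increment. Four candidates are
fitted — global, depth+class, length+class, class-only; the class
indicator is kept everywhere so the coding/non-coding contrast is always
estimable. Fitting is maximum likelihood via `MASS::glm.nb`; the reported
AIC counts the dispersion as a parameter, $\mathrm{AIC} = -2\log L +
2(p+1)$. Because absolute AICs depend on the fitting software's
likelihood-constant and parameter-counting conventions, only ΔAIC-derived
quantities (weights, evidence ratios) should be compared across software.

Akaike weights are computed as $w_i = \exp(-\Delta_i/2)/\sum_j
\exp(-\Delta_j/2)$ with a log-sum-exp normalization, so a candidate
sitting 465 AIC units above the best model still gets its ~$10^{-101}$
weight rather than underflowing to zero. Evidence ratios are plain weight
quotients; a zero denominator (a weight that did underflow) yields a
flagged `Inf` rather than an error.

Confidence limits are Wald, $\hat\beta \pm 1.96\,\mathrm{se}$, with
two-sided normal p-values, and no multiple-testing correction is applied
anywhere — coefficients are reported raw. Prediction intervals on the
standardized count use the delta method on the link scale:
$\exp(\hat\beta x \pm 1.96\sqrt{x^\top \Sigma x})$.

### Numerical choices

* `glm.nb` is run with `epsilon = 1e-10`, `maxit = 200`.
* On equidispersed data the NB shape estimate diverges and `glm.nb` can
  fail outright. `fit_nb()` then falls back to the Poisson limit: the
  coefficients come from the Poisson GLM, the dispersion is floored at
  $\alpha = 10^{-8}$, the log-likelihood is evaluated as NB2 at the floor,
  and the fit is flagged `poisson_limit`.
* An all-zero response is refused with a pointer to the Poisson limit:
  no dispersion is identifiable.
* `run_full_selection()` captures per-model fit errors and ranks whatever
  candidates converged, so one degenerate response does not abort the
  other responses.

## What the simulator emulates — and what it does not

`simulate_alignments()` generates the caller's whole input universe:
contig lengths from a lognormal truncated to 100–5,400 bp (mean ≈ 800),
depths from a shifted lognormal truncated to 10–315 reads (mean ≈ 30) —
both bracketing the ranges typical of a 454 transcriptome assembly —
full-length reads over a random consensus, planted biallelic SNPs with
known minor counts, and six decoy classes, each violating exactly one
filter rule (homopolymer, indel, triallelic, single-minor-read at
MAF < 1%, contig-edge, low-quality flank). Events on a contig are spaced
≥ 45 bp so one event's side effects (an injected 6-base run, a degraded
flank score) cannot leak into another's acceptance region, and the
background consensus is kept free of runs longer than 4.

Two idealizations matter for interpreting test results:

* **Quality scores are informative.** Sequencing errors are injected with
  low quality scores (default uniform 5–15, below the filter) while true
  bases carry 30–40. Under this assumption the caller's recall and
  precision against the truth table are exactly 1, and the test suite
  asserts that. Real basecallers miscalibrate; on real data the same
  filters trade recall against precision rather than achieving both.
* **Reads span their whole contig** by default, so contig depth equals
  per-column depth (a `partial_span_reads` flag enables ragged reads for
  stress tests, at the cost of the planted-count guarantees). Real
  assemblies have ragged coverage, which is precisely why the per-column
  MAF denominator was chosen.

The simulator does not emulate flowgram chemistry, basecalling error
spectra, assembly errors, or a coding-potential classifier's score
distribution: coding labels are drawn as Bernoulli truth.

`simulate_count_table()` draws counts directly from the NB2 regression
above. The default coefficients $(-0.9828,\ 0.0002,\ 0.0146,\ -0.0999)$
put simulations in the regime of a real transcriptome-scale analysis
(about 0.8 SNPs per long contig). The NB dispersion of that regime is not
publicly reported, so the default $\alpha = 0.5$ — moderate
overdispersion for low-mean counts — is a package choice, stated here and
in the config rather than inferred from anywhere. The transition share
defaults to `ti_prop = 0.64`, reproducing the Ti/Tv ≈ 1.8 regime of
transcriptome SNP sets. Alignment simulation uses one root seed with
per-contig counter-derived substreams, so contig *i* is reproducible
regardless of `n_contigs`; the count table uses a single vectorized
stream.

## Test problem sizes

The property suites run at sizes chosen to make their statistical claims
meaningful while keeping a full test run in a few minutes: the
caller-truth battery uses 260 contigs (≈ 680 planted SNPs, ≥ 100 decoys
per class); oracle equivalence compares the caller to an independently
coded brute-force scorer on 1,000 random ≤ 50-column alignments
(partial-span reads, gaps, `N`s, mixed qualities); parameter recovery
fits 100 replicates at n = 3,181 and requires each true coefficient
inside its 95% CI in ≥ 90 of them; selection consistency simulates 200
replicates at n = 3,000 with $\beta_L = 0$ and requires the
depth-containing models to carry ≥ 0.99 combined weight in ≥ 95% of
replicates.

## Known limitations

* Pooled-read depth is not a haplotype count: with pooled individuals the
  standardized SNP count is a *relative* polymorphism measure, not an
  estimator of nucleotide diversity (θ-class estimators are out of scope).
* The caller has no genotype-likelihood model; it is a deterministic
  filter cascade, appropriate for conservative marker discovery rather
  than frequency estimation at low depth.
* MAF uses the per-column quality-passing denominator and flank checks use
  consensus quality; both are documented decisions where reasonable
  alternatives exist (contig-depth denominators, read-level flank
  quality), and both are trivially changeable via `filter_config()`
  plus a recall of `call_snps()`.
* Insertions relative to the consensus are not representable in the
  alignment container; SAM `I`/`S` bases are dropped on import. Indel
  *evidence* (deletions) is retained and vetoes columns as designed.
```{r}
sessionInfo()
```
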