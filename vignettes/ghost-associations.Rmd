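---
title: "Dissecting allelic heterogeneity, ghost associations and field selection at a dormancy locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting allelic heterogeneity, ghost associations and field selection at a dormancy locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghostmap)
```

## The problem

Genome-wide association studies fit a single-locus, two-allele model at
every marker.  When a locus carries *several* functionally distinct alleles
— allelic heterogeneity — no single biallelic marker tags the causal
variation, but a nearby marker whose minor allele happens to co-occur with
two or more of the causal alleles can proxy their *combined* effect.  Such
a marker produces a strong "synthetic" or *ghost* association: a genuine
statistical signal at a non-causal position, possibly tens of kilobases
from the causal gene.  Seed dormancy in Swedish *Arabidopsis thaliana* is
the canonical plant example: germination rate after 21 days of
after-ripening (GR21, in percent) is strongly bimodal across inbred lines,
several distinct dormant alleles segregate at one locus on chromosome 5,
and the most significant marginal GWAS hit sits ~21 kb away from the gene.

`ghostmap` re-implements, as a tested pipeline, the statistical machinery
needed to (i) detect this situation, (ii) resolve it into its component
alleles, and (iii) estimate the strength of natural selection on those
alleles from a staged field-sampling design.  Because the original
genotype and field data live in external repositories, the package ships a
synthetic-data generator that emulates the study system with known ground
truth; every statistical claim the test suite makes is checked against
that truth or against an independent oracle.

## The models

### Mixed-model association scan

The marginal scan fits, for each marker $g$,
$y = X\beta + g\beta_g + u + e$, with $u \sim N(0, \sigma_g^2 K)$ and
$e \sim N(0, \sigma_e^2 I)$, where $K$ is a centered-IBS kinship matrix
rescaled to mean diagonal 1.  The null variance components are estimated
by REML after a single spectral decomposition of $K$: writing
$\delta = \sigma_e^2/\sigma_g^2$, the restricted likelihood is maximized
over $\delta$ on a 121-point log grid refined by golden-section search
(tolerance $10^{-10}$ on $\log\delta$).  Markers are then tested by
generalized least squares in the eigenbasis, either re-using the null
$\delta$ for every marker (the fast, EMMAX-style default) or re-optimizing
$\delta$ per marker (exact mode).  P-values come from the F test with
$n - \mathrm{rank}(X) - 1$ residual degrees of freedom, which is correct at
the small sample sizes typical of inbred panels.  The two modes agree to
within 0.2 $-\log_{10}p$ units at $n = 200$ in the test suite.

### Pseudo-SNP pairwise scan

If two mutually exclusive dormant alleles are tagged by markers $g_i$ and
$g_j$, their combined carrier status is the elementwise logical OR
($0\,\mathrm{or}\,0=0$, otherwise 1).  `make_pseudo_snps()` forms all
$m(m-1)/2$ such pairs from the markers in a region that pass a 5% MAF
filter, and `scan_pseudo_snps()` tests each pair exactly as the marginal
model tests a marker.  The MAF filter belongs *only* to this pairwise
scan; the marginal scan is unfiltered, because rare variants (down to
MAF 0.018 in the motivating study) are legitimate single-marker signals.

### Multi-locus mixed model with a forced start

`mlmm()` adds markers as fixed cofactors stepwise: at each forward step
the remaining markers are tested with the shared-$\delta$ fast path,
the most significant one enters, and the variance components are
re-estimated by REML.  After `max_forward` forward steps (default 4,
mirroring the four forward and four backward steps of the motivating
analysis), the same number of backward steps removes the least significant
cofactor each time.  Each step records the partition of phenotypic
variance into explained (cofactors), genetic (kinship) and error shares,
which sum to one.  Model selection uses the extended BIC
$\mathrm{extBIC} = -2\ell_{ML} + k\log n + 2\log\binom{m}{k}$ for $k$
cofactors among $m$ candidates ($\gamma = 1$ in the Chen–Chen family —
the convention of the multi-locus method this follows; the criterion
equals the plain BIC at $k = 0$).  A `start_marker` can be forced in at
step 1, which is the key device for interrogating a suspected ghost: start
from the suspected *causal* marker and see whether the proxy ever enters.

### Local/global variance decomposition

`local_global_decomposition()` fits
$y = \mu + u_{local} + u_{global} + \psi$ with two random effects governed
by kinships built from the candidate-region markers and from the rest of
the genome, by direct REML over the two log variance ratios
(Nelder–Mead from 5 fixed starts, relative tolerance $10^{-8}$), returning
normalized variance fractions.  Both kinships use the same centered-IBS
estimator; the original analysis used IBD relatedness from an external
tool whose construction is unpublished, so IBS is a documented
substitution, not asserted equivalent.  Identical (off-diagonal
correlation > 0.99) local and global kinships raise a non-identifiability
error rather than returning an arbitrary split.

### Partial Mantel test

`partial_mantel()` residualizes the off-diagonal entries of the phenotype
and environment distance matrices on the covariate (kinship-derived)
distances on the rank scale and correlates the residuals — algebraically
the partial Spearman correlation (the test suite verifies exact agreement
with `vegan::mantel.partial`).  Significance permutes the row/column
labels of the dependent matrix only, with
$p = (\#\{|r^{perm}| \ge |r^{obs}|\} + 1)/(n_{perm} + 1)$.  Kinship is
converted to a distance by $\max(K) - K$, an order-preserving choice.

### Field-selection estimators

The field design disperses pooled F3 seeds in framed plots, samples all
visible seedlings destructively in September (point 1) and November
(point 2), and recovers the newly formed seed bank from a soil sample
(point 3) covering `soil_sampled_cm2 / frame_area_cm2` of each frame
(3% at the defaults: 18 of 600 cm²).  The estimators are:

* `starting_frequencies()` — each F3 family contributes
  `seeds × viability` weight, split by Mendelian selfing of its F2 parent
  (heterozygotes give 1/4, 1/2, 1/4).
* `estimate_moved()` — outside-frame seedlings over all seedlings at
  points 1–2.
* `ending_genotype_counts()` — the corrected ending genotype count
  $\mathrm{CEGC} = GC_1 + GC_2 + GC_3 \times \mathrm{area} \times
  (1 + \mathrm{moved})$, with area $= 100/3$ when 3% of the frame was
  sampled.  CEGC is kept real-valued; only frequencies flow downstream.
* `fitness_estimates()` — marginal fitness
  $w_g = (p'_g / p_g)\,\bar w$ per genotype and relative fitnesses
  normalized to the fittest genotype.  Heterozygote estimates with
  starting frequency below 0.05 are flagged low-confidence.

Counts are aggregated at the block level before frequency estimation.
`window_genotype_call()` bins read-backed SNP calls into 200 kb windows
(half-open, tiled from position 1) and calls `hom_A`/`het`/`hom_B` at
parent-A allele fractions ≥ 0.9 / 0.3–0.7 / ≤ 0.1 with a minimum of 10
informative calls; the window size is from the motivating study, the
thresholds are this package's choice since no calling rule was published.

## The synthetic generator and its defaults

The generator's defaults *are* the study conditions; they were chosen once
from the published description and are not tuned to test outcomes.

* **Panel**: 161 inbred lines, Balding–Nichols structure with 2
  subpopulations (a southern and a northern group, with matching latitude
  bands) at $F_{ST} = 0.1$ — the published design gives the panel size;
  the two-group split and $F_{ST}$ emulate the strong north–south
  structure of the source population without attempting to match its full
  demography.  2000 markers by default, 60 of them packed into the 50 kb
  candidate region (a scaled-down stand-in for the ~1800 regional SNPs of
  the real matrix; scaling keeps the test suite inside its time budget).
* **Locus**: haplogroup frequencies ND 0.50, D2 0.30, D3 0.18, D4 0.02 —
  ND near one half, D2 the common dormant class, D3 rarer, D4 rare, as in
  the published haplogroup barplot.  The dormant tags SNP2–SNP4 are
  mutually exclusive by construction.  The proxy SNP1 is the OR of SNP2
  and SNP3 with signed, calibrated noise (bisection, 50 calibration
  replicates) targeting $r^2(\mathrm{SNP1}, \mathrm{SNP2}) = 0.61$.  A
  subtlety: at these haplogroup frequencies a *pure* OR has
  $r^2 = 0.46 < 0.61$, and symmetric flips can only lower it; the
  calibration therefore removes the proxy allele from SNP3-only carriers
  to raise $r^2$ toward the target (and flips uniformly to lower it),
  which keeps SNP1 a proxy for both dormant alleles at the published LD.
* **Phenotype**: liability $L$ = baseline (+2.5 for ND) + allele effects
  (−6 per dormant tag) + polygenic background (share `h2_background`
  = 0.3 of the residual variance, covariance $\propto K$) + Gaussian
  noise (sd 1.5); $\mathrm{GR21} = 100 \cdot \mathrm{logistic}(L)$.
  Bimodality thus arises from one mechanism — large liability effects
  through a saturating link — not from an explicit mixture.  These
  defaults put ~44% of lines below GR21 = 20 and ~36% above 80, emulating
  the published 46% / 35%.
* **Crosses**: F2 gametes carry Poisson crossovers (1 Morgan per
  chromosome, no interference, genetic positions linear in physical
  ones); F3 pools take exactly `seeds_per_family` seeds per family
  (185 × 5 = 925 and 214 × 4 = 856 at the published family counts).
* **Field cohort**: per genotype, a viable seed germinates by point 1, by
  point 2, enters the seed bank, or dies ungerminated (multinomial —
  conservation is exact); germinants survive to their sampling point per
  genotype; sampled seedlings are outside the frame with probability
  `moved_prob` (default 0.04, inside the published 0.009–0.053 range);
  bank seeds still inside the frame are recovered with probability 3%.
  Each frame sows an identical copy of the pool with independent fates —
  a simplification of the real design, where each frame received its own
  pool of the same construction.  The default germination/survival tables
  make dormant homozygotes bank heavily and non-dormant ones germinate
  early and die more, giving a closed-form relative fitness of the
  non-dormant homozygote of 0.53, inside the published 50–60% band (used
  as simulated truth, never fitted to data).  The `TruthRecord` carries
  the exact expected ending frequencies
  $p'_g \propto p_g(\gamma_{1g} s_{1g} + \gamma_{2g} s_{2g} + b_g)$, so
  estimator bias is measurable without Monte-Carlo truth.

Every operation takes an explicit seed and is bit-reproducible; child
streams are derived from the root seed by fixed offsets, so
sub-experiments can be reproduced in isolation.

## What the synthetic data does not emulate

Real genotype matrices have LD decay within and between chromosomes,
mutation/recombination history, and missingness patterns that
Balding–Nichols sampling does not generate; background markers here are
exchangeable given their subpopulation frequencies.  Haplogroups are
assigned independently of subpopulation, so the locus is *not* confounded
with structure — the real locus is geographically stratified, which makes
the real problem harder, not easier.  The field model has a single-year
horizon, no density dependence, and no seed-bank mortality.  Passing
tests therefore demonstrate correctness of the estimators under the
generative model, and power/calibration at these effect sizes — not
performance guarantees on any particular real data set.

## Numerical choices and degenerate inputs

* REML: log-grid $\delta \in 10^{[-5,5]}$, golden-section refinement;
  identical optima to a 1000-point dense grid within $10^{-4}$
  log-likelihood units at $n \le 30$ (tested).
* An identity kinship leaves only $\sigma_g^2 + \sigma_e^2$ identifiable;
  the fit warns and flags `identifiable = FALSE`, and the marker test
  collapses to the ordinary regression F test.
* Monomorphic markers: MAF 0, p-value 1 in scans (not an error); LD with
  a monomorphic marker is an error for `ld_r2()` and a flagged `NA` row in
  `ld_profile()`; missing dosages are mean-imputed per marker in kinship
  and scans, pairwise-complete (minimum 10 pairs) in LD.
* Ties in scan ranking break by position then marker id; pseudo-SNP
  output ties break lexicographically by pair ids.  Perfectly correlated
  markers (the published case of a tag in complete LD with two others)
  are all reported; no winner is chosen.
* The variance partition at an MLMM step uses the GLS cofactor
  coefficients at that step's $\delta$; `explained + genetic + error = 1`
  to $10^{-9}$ by construction.
* `extBIC` penalizes with $2\log\binom{m}{k}$ where $m$ counts the
  *polymorphic candidate markers of that run* (a local scan penalizes
  against its region's marker count, matching how the criterion is used).

## Design choices where the design was open

* The published analyses name the mixed-model class but not the kinship
  estimator or LMM flavour; this package adopts centered-IBS kinship and
  EMMA-style exact REML with an EMMAX-style shared-$\delta$ fast path,
  which keeps the 654,940-pair pseudo-SNP scan tractable.
* The starting-frequency "adjustment for viability" is implemented as
  per-family `viability × seeds` weighting — the natural reading of the
  verbal description; soil-tray germination flushes are pooled into the
  single soil count, as no per-flush weighting was described.
* The null-simulation behaviour of the two-component variance
  decomposition reflects REML boundary theory (each component positive
  with probability ~1/2 under the null, magnitudes driven by the leading
  kinship axes), so single null fits occasionally place ~10–30% in one
  genetic component; the median fit is at zero.  Tests assert the median
  behaviour.
* Problem sizes in the test suite (e.g. 100 replicates of 200 × 2000 for
  the ghost property, 300 × 500 for MLMM recovery, 50,000-seed cohorts
  for the fitness estimators, a 20-cohort average for the GR21 class
  fractions) were chosen so the whole suite runs in a few minutes while
  leaving the checked rates far from their thresholds.

## Known limitations

The MLMM implementation handles the forward/backward schedule of the
motivating analysis, not arbitrary stepwise plans; there are no
genome-wide window partitions in the variance decomposition, no
haplotype-phased D′, no exhaustive marker triplets, and no multi-year
demography.  The pairwise scan's memory use is linear in the number of
pairs per block (`block_size`), not in the total pair count.
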