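---
title: "Methods: drift moments, f-statistics and split-time inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drift moments, f-statistics and split-time inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`fourstrand` analyses merged panels of modern and ancient genotypes with the
standard toolkit of allele-frequency population genetics: f-statistics with
block-jackknife errors, outgroup-f3 affinity and topology tests, admixture-f3
source scans, f4-ratio ancestry proportions, PCA with least-squares
projection of incomplete samples, and runs-of-homozygosity profiles.  Its
motivating application is the deep structure of West Eurasian ancestry: a
"fourth strand" of hunter-gatherer ancestry from the Caucasus (CHG) that
separated from western hunter-gatherers (WHG) around 45 thousand years ago,
from early farmers (EF) around the Last Glacial Maximum ~25 kya, and later
contributed about half of the ancestry of Bronze Age steppe herders
(Yamnaya), the other half being related to eastern hunter-gatherers (EHG).

Because real panels of this kind require large external downloads, the
package pairs every estimator with a generative counterpart: a drift
simulator over population graphs and an exact moment engine that yields the
expected value of any f-statistic under the same model.  All statistical
claims in the test suite are checked against this oracle rather than against
stored numbers.

# The demographic model

A `DemographyModel` is a rooted graph.  Tree edges carry either a
dimensionless drift amount $d \in [0,1)$ or a duration in years; admixture
events create a population as the exact linear mixture
$p_M = \alpha p_A + (1-\alpha) p_B$ of two existing ones.  Durations convert
to drift through the diffusion-time scaling for a diploid population of
constant effective size $N_e$ and generation time $g$:

$$d = 1 - \exp\!\big(-t \,/\, (2 N_e g)\big).$$

Successive edges compose as $1 - \prod_i (1 - d_i)$, so drift accumulates
like diffusion time.  The root allele frequency is drawn per SNP from a
Uniform(0.05, 0.95) by default (a flat ascertained spectrum typical of
SNP-array panels; a Beta alternative is available), and each edge applies the
Balding–Nichols transition
$p' \sim \mathrm{Beta}\big(p\tfrac{1-d}{d},\,(1-p)\tfrac{1-d}{d}\big)$,
which preserves the mean and has variance $d\,p(1-p)$; 0 and 1 are
absorbing.  SNPs are independent given the graph — there is no linkage in
the generator, a deliberate simplification discussed under Limitations.

The built-in preset (`buildPreset("jones2015")`) encodes the published
topology and the two reported split times (WHG at 45 kya, CHG–EF at 25 kya)
plus an even CHG/EHG mixture for Yamnaya.  Quantities the source model never
states — the outgroup divergence (100 ky), the EHG split (20 ky), the
within-WHG and within-CHG tip splits (17 ky), the admixture date (5 ky),
$N_e = 10{,}000$, $g = 29$ y — are package defaults exposed as arguments and
chosen once as round, field-typical values.  The default sampling spec
mirrors realistic study designs: a 10-sample diploid outgroup, 4 diploid
farmers, and 1–4 pseudo-haploid genomes per hunter-gatherer population (the
farmers are kept at the modern-panel minimum of four individuals so the
merge filter never removes them).

# Exact moments and the f-statistic oracle

For every node the engine propagates $E[p_X]$ and all cross-moments
$E[p_X p_Y]$: a drift edge leaves the mean and all cross-moments with other
populations unchanged and moves the own second moment toward fixation,
$E[p_C^2] = E[p_P^2] + d\,(E[p_P] - E[p_P^2])$; an admixture node is bilinear
in its sources.  Expected f-statistics are then linear combinations, e.g.
$f_2(A,B) = E[p_A^2] + E[p_B^2] - 2E[p_A p_B]$.  These identities are exact,
not approximations, which is what makes the oracle usable at tolerance
$4\,\mathrm{SE}$ on $10^5$-SNP Monte-Carlo runs.

# Estimators

Sample frequencies count chromosomes: a diploid contributes its dosage out
of 2, a pseudo-haploid sample its single sampled allele out of 1 (the
duplicated homozygote carries no second observation).  The estimators are
the standard unbiased moment forms: $f_2$ subtracts
$\hat p(1-\hat p)/(n-1)$ on both sides, $f_3(C;A,B)$ subtracts it for the
target only, $f_4$ needs no correction, and $D$ is the normalized ratio.
With `inbreed = TRUE` the $f_3$ correction divides by the number of
individuals rather than chromosomes, the appropriate choice when the target
consists of pseudo-haploid ancient genomes whose within-individual
heterozygosity is unobservable.  Standard errors come from the weighted
delete-one-block jackknife over 5 cM blocks, with the unequal-block-size
weighting of the classic implementations, and $|Z|>3$ is the conventional
significance line throughout.

# Split-time fitting

`fitSplitTimes()` minimizes
$\sum_i \big[(\mathrm{obs}_i - \mathrm{exp}_i(t))/\mathrm{se}_i\big]^2$ over
free split times, with expectations from the moment engine.  Two design
choices deserve note:

* **Observed statistics are outgroup-f3 values** over all pairs of ancient
  leaves.  With single pseudo-haploid genomes the $f_2$ correction
  $\hat a(1-\hat a)/(n-1)$ is undefined at $n = 1$ chromosome, while
  outgroup-f3 needs the correction only on the well-sampled outgroup, so the
  fit stays well-defined for exactly the samples this field works with.
* **The model enters through a builder function** `(times, Ne, genTime) ->
  DemographyModel` rather than a partially-free model object.  This keeps
  the optimizer generic (any nesting constraint lives in the builder, which
  simply errors on invalid candidates) and makes the fitted parameterization
  explicit at the call site.

$N_e$ and $g$ scale drift into years and are not identifiable from
f-statistics alone; they must be supplied explicitly and are reported with
the fit.  After convergence the objective is probed around the optimum; a
flat response flags the fit as non-identifiable instead of returning an
arbitrary time.  `fitPresetSplitTimes()` packages the full recovery
experiment (simulate the preset, estimate, fit) behind a single seed.

# Panel handling

EIGENSTRAT triplets are read and written directly (the format is three plain
text files; genetic positions are Morgans on disk, centimorgans in memory).
Merging an ancient panel into a modern one applies the conventional filter
cascade — intersect on SNP id, drop non-autosomal SNPs, drop modern
populations below four individuals, drop SNPs monomorphic across the
retained moderns, and drop SNPs whose allele pairs do not match (recoding
swapped pairs, never strand-flipping, since A/T and C/G pairs are
undecidable).  Pseudo-haploid calling draws one allele per covered SNP with
probability equal to its frequency among the reads and discards sites
showing any base outside the panel's two alleles.  LD pruning is
sliding-window pairwise (`200 25 0.5` for clustering analyses; the same
window at $r^2 > 0.2$ ahead of PCA — the PCA threshold is published without
a window, and a windowed scan is the field's standard implementation; a
global all-pairs pass would be quadratic in panel size).  PCA standardizes
by $\sqrt{p(1-p)}$, and incomplete samples are placed by least squares over
their observed SNPs, which reduces to the exact score when nothing is
missing.

# Problem sizes

The package's own working scales, used by its tests and replay pipeline, are
chosen so that every effect the model predicts is resolvable: 100k SNPs on
22 chromosomes of 100 cM (~440 jackknife blocks) for single-panel analyses,
200k SNPs and five replicate seeds for split-time recovery, 30k SNPs for the
shared unit-test simulation, and 10–20k frequency-level SNPs for calibration
sweeps.  At these sizes the admixture-scan and topology signals sit near
$|Z| \approx 5$–$30$, comfortably beyond the $|Z|>3$ line without being
trivially saturated.

# Limitations

* The generator draws SNPs independently: there is no linkage, so jackknife
  blocks are calibrated under the model's own independence assumption rather
  than under realistic LD decay.
* Constant $N_e$ per branch and a single global generation time; no
  bottlenecks or growth.  Fitted times inherit any misspecification of
  these, exactly as in the moment-based methods the package mirrors.
* The Balding–Nichols transition is an approximation to the Wright–Fisher
  diffusion; it matches the first two moments, which is all the
  f-statistic machinery consumes, but tail behaviour near fixation differs.
* Pseudo-haploid calling models sequencing error as uniform
  base-substitution; no post-mortem damage asymmetry (C>T/G>A) is simulated.
* ROH detection is a PLINK-style physical-distance scan; it does not model
  genotyping error rates per site or use genetic distance.
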