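---
title: "Methods: SLA dissimilarity between mating partners and reproductive traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SLA dissimilarity between mating partners and reproductive traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SLAdissim)
```

# The question and the data model

The swine leukocyte antigen (SLA) complex is the pig MHC: class I genes
*SLA-1*, *SLA-2*, *SLA-3* and class II genes *DRB1*, *DQB1*.  In a closed,
highly inbred herd, every breeding animal carries an unordered pair of SLA
haplotypes (a diplotype); each haplotype fixes one allele per locus —
except a duplicated-gene family (the Hp-35 haplotypes) that carries two
*SLA-1* alleles at once (`SLA-1*12:01` and `SLA-1*13:01`).  The package
asks whether matings between partners with more dissimilar SLA alleles
have better reproductive outcomes: larger litters, more live and weaned
piglets, fewer stillbirths and pre-weaning deaths, higher survival and
weaning rates.

The analysis chain is: protein-level allele distances → per-mating
dissimilarity scores → incremental range groups → group trait summaries →
rank correlation of group centers against summaries.

# Amino-acid distances under JTT(+gamma)

Allele dissimilarity is measured as the expected number of amino-acid
substitutions per site separating two aligned allele protein sequences
under the JTT empirical substitution model.  The model is specified by the
published symmetric exchangeabilities $S$ and equilibrium frequencies
$\pi$ (taken at run time from the phylogenetics package **phangorn**); the
rate matrix $Q_{ij} = S_{ij}\pi_j$ is normalised so one unit of distance
is one expected substitution per site.  Because $Q$ is reversible it is
symmetrised by $D_\pi^{1/2} Q D_\pi^{-1/2}$ and eigendecomposed once per
model object; the transition kernel is then

$$P(d) = D_\pi^{-1/2}\, U\, g(\Lambda d)\, U^\top D_\pi^{1/2},$$

with $g(\lambda d) = e^{\lambda d}$ for homogeneous rates and, under
continuous Gamma($\alpha,\alpha$) site-rate variation, the closed-form
rate expectation $g(\lambda d) = (1 - \lambda d/\alpha)^{-\alpha}$ applied
to the eigenvalues $\lambda \le 0$.  The test suite verifies this
transform against direct numerical integration of the homogeneous kernel
over the gamma density (composite Gauss–Legendre with a substitution
removing the $r^{\alpha-1}$ endpoint singularity), to better than $10^{-7}$
per entry.

The pairwise distance is the maximiser of the pair log-likelihood
$\ell(d) = \sum_s \log\!\big(\pi_{a_s} P_{a_s b_s}(d)\big)$ over
$d \in [0, d_{\max}]$.  Choices made here, all visible as arguments:

* **Gamma shape `gammaShape`** — typical study reports do not state the
  value used; the package default is 1 (moderate heterogeneity) and every
  distance-matrix object records the shape it was built with.  A shape of
  `NA` switches to rate homogeneity; the two agree to $10^{-4}$ as
  $\alpha \to \infty$.
* **Gap handling `gapMode`** — sites containing `-` or `X` are removed;
  `"complete"` (default) removes such alignment columns across the whole
  allele set before any pair is computed, `"pairwise"` removes them per
  pair.  For a single pair the two coincide.
* **Optimiser** — bracketed scalar maximisation (`stats::optimize`) on
  $[0, 10]$ with absolute tolerance $10^{-7}$; identical surviving sites
  short-circuit to exactly 0; flat likelihoods resolve to the smallest
  maximising $d$; a likelihood still rising at $d_{\max} = 10$ returns
  $d_{\max}$ flagged as saturated, with a warning.
* **Sequence region** — the engine is region-agnostic: it scores whatever
  aligned residues it is given (full mature protein or antigen-binding
  domains alike).  The synthetic generator uses 180 residues, a typical
  mature MHC domain-region length.

The estimator is validated by simulate-then-recover: pairs simulated at a
known distance (5\,000 sites) are recovered within $\pm 0.02$ with mean
bias below $0.005$ over 100 seeds, the error shrinks with sequence length
(500 → 5\,000 → 50\,000 sites), and the profiled log-likelihood is
unimodal on the search interval for non-saturated pairs.  An independent
ML implementation (`phangorn::dist.ml` under the same model) agrees to
$10^{-4}$ on simulated pairs.

# Haplotype registry and frequency accounting

The packaged registry holds the herd's eleven haplotypes (eight parental,
three recombinant — a recombinant pairs the class I component of one
family with the class II component of another) together with dam/sire
haplotype counts accumulated over the 650-mating series.  Counting is
**per mating event**: each mating contributes the dam's two and the sire's
two haplotypes, so the denominator is $4 \times$ the number of matings and
an animal used in $k$ matings contributes $k$ times.  A per-animal
weighting is available behind a flag for sensitivity checks.

Allele frequencies pool haplotype counts onto the alleles they carry;
alleles shared across haplotypes accumulate, and the two duplicated
*SLA-1* alleles are reported as one pooled row since every carrier
haplotype carries both.  Each locus therefore conserves the haplotype
denominator exactly.  Percentages are rounded half-up to two decimals
(one decimal for homozygosity rates), matching how such tables are
printed; the packaged counts reproduce the published frequency table
exactly at that rounding.  Two-digit (low-resolution) allele calls are
resolved to four digits through the class II haplotype context, erroring
with the candidate list when the context is ambiguous.

One source inconsistency is worth noting: the herd is described in
different places as having 104 or 106 sows; the packaged defaults use
106, consistent with the mating-series accounting.

# Per-mating scores, range groups and correlation

At one locus, with sire alleles $\{A, a\}$ and dam alleles $\{B, b\}$
(homozygotes repeat their allele), the mating's dissimilarity is

$$D = D_{AB} + D_{Ab} + D_{aB} + D_{ab},$$

which is 0 exactly when all four cross pairs are identical-allele pairs.
*SLA-1* is scored twice — once substituting each duplicated-family variant
for every carrier haplotype — giving six locus keys in total; matings with
no carrier haplotype get two equal values.

Scores are binned into a singleton zero group ($|D| \le 10^{-9}$) plus
half-open groups $[kw, (k+1)w)$ of width $w$ (0.1 by default, 0.05 for
*DQB1*, whose allele distances are several-fold smaller).  The zero group
is kept separate from $(0, w)$ because "identical alleles" is a
qualitatively distinct category.  A printed range like "0.1–0.199" is
interpreted as $[0.1, 0.2)$: the boundary value belongs to the upper
group.  Groups with fewer matings than `minGroupN` (default 2, i.e.
singleton groups) merge into their nearest non-empty neighbour — upward
on ties — and the merged group's center is the midpoint of the merged
span rounded to two decimals; empty groups are dropped.

Each group is summarised per trait: arithmetic means for count traits
over the members that carry them; rates as the pooled ratio (total live /
total born; total weaned / total live) by default, with mean-of-ratios
behind `rateMode = "per-mating"` — whether published group rates were
pooled or averaged is not stated, so both modes ship and the default is
the pooled ratio, which is the natural aggregate of a count process.
Birth-stage traits use all matings; weaning-stage traits use only
weaning-complete matings, re-binned on that subset (the two stages have
separate group layouts).  Missing weaning records are absent fields, not
zeros.

Correlation is computed **on group-level points** — center value against
group summary — matching the reported "n = number of groups" convention;
a per-mating correlation mode is deliberately not the default since the
method under study is the binned one.  Spearman's $r_s$ uses average
ranks.  Two p-value methods ship:

* `"t"` (default): $t = r_s\sqrt{(n-2)/(1-r_s^2)}$ on $n-2$ degrees of
  freedom; $|r_s| = 1$ reports the smallest positive double rather than
  dividing by zero.
* `"permutation"`: the exact two-sided p-value over all $n!$ orderings,
  enumerable for $n \le 9$ (layouts larger than 9 groups fall back to the
  t transform).

The t transform is the conventional choice at 9–12 groups but is
anticonservative at very small $n$ (at $n = 5$ its true level at nominal
0.05 is about 0.08), which is why the calibration property below is
stated for the exact method.  Cells whose correlation is undefined
(fewer than 3 groups, or zero variance, as in a degenerate herd where
every mating shares one diplotype pair) are reported as `NA` with a note;
the run always completes.  No multiple-testing correction is applied —
the method under study uses raw p-values — so users reading 42-cell grids
should keep that in mind.

# The synthetic-data generator

The generator exists so that every stage is exercisable against known
truth.  What it emulates:

* **Herd and matings** — 106 sows and 42 boars; diplotypes drawn from the
  registry's haplotype frequencies with optional excess homozygosity $F$
  (the second haplotype copies the first with probability $F$; expected
  homozygosity $\sum p_i^2 + F(1-\sum p_i^2)$); 650 matings pairing a
  uniform random sow with a uniform random boar, as in a herd mated at
  random.  $F$ defaults to 0 because the registry frequencies alone
  already give ~20% expected homozygosity, at or above the observed
  rates.
* **Alleles** — per locus, the registry's allele set (9, 8, 8, 8, 6
  alleles) evolved from a common ancestor on a star tree; branch lengths
  $\mathrm{scale}/2 \times U(0.85, 1.15)$, so true pairwise distances
  (sums of two branches) sit within 15% of the locus scale.  Scales
  default to the published per-locus overall mean distances (0.1972,
  0.1178, 0.2330, 0.1695, 0.0651 for *SLA-1*, *SLA-3*, *SLA-2*, *DRB1*,
  *DQB1*).  Site rates honour the model's gamma shape and are shared
  across branches, as in the standard rate-heterogeneity model.
* **Outcomes** — litter $= 1 + \mathrm{Poisson}(e^{\beta_0 + \beta_1
  z_{DQB1}})$ (the $1+$ excludes zero litters: a litter of zero is a
  non-farrowing, which this analysis excludes); stillborn
  $\sim \mathrm{Bin}(\mathrm{litter}, p_{\mathrm{still}})$; pre-weaning
  deaths $\sim \mathrm{Bin}(\mathrm{live}, \mathrm{logit}^{-1}(\gamma_0 +
  \gamma_1 z_{SLA2}))$; weaned $=$ live $-$ deaths.  The $z$ covariates
  are the **true** (generator-side) per-mating scores, standardised — so
  when the analysis re-estimates distances from the simulated sequences,
  estimator noise is part of what recovery tests exercise.  Baselines are
  anchored to the emulated cohort: $\beta_0 = \log 4.47$ (mean litter
  $1 + 4.47 = 5.47$), $p_{\mathrm{still}} = 0.17$ ($\approx 0.93/5.47$),
  $\gamma_0 = \mathrm{logit}(0.15)$ ($\approx 0.68/4.54$).  A fixed-size
  random subset of $33/650$ of the matings has its weaning fields
  blanked, reproducing the 650-at-birth / 617-at-weaning split exactly.
* **Effect sizes** — defaults $\beta_1 = 0.1$ and $\gamma_1 = -0.4$ were
  sized a priori: across the $\pm 2$ SD score range they move the litter
  mean by $\pm 20\%$ and the death probability between roughly 0.09 and
  0.25, several times the standard error of a group mean at typical group
  sizes ($\approx \sqrt{4.5/80}$), which puts the group-level rank
  correlation near 0.9.

All randomness flows from the single seed given to `simulateStudy()`;
identical seeds give byte-identical output.

What the generator does **not** emulate: mate choice (matings are
random), parity/season/sow-age structure, litter-size heritability,
linkage between loci beyond what the shared haplotype structure induces,
and real MHC sequence features (indel structure, domain-specific
conservation, alignment error).  Passing recovery tests therefore shows
the pipeline is correct and powered under its own assumptions — not that
real herds satisfy those assumptions.

# Problem sizes used by the checks

The packaged checks run at sizes chosen to make their tolerances
meaningful while staying quick: estimator recovery uses 100 seeds at
5\,000 sites; the kernel oracle uses 50 random (shape, distance) draws;
end-to-end sign recovery uses 100 seeded full datasets (650 matings each,
distances re-estimated from 180-site sequences); null calibration pools
200 datasets under $\beta_1 = \gamma_1 = 0$ with exact permutation
p-values, where the rejection rate at 0.05 sits within $\pm 0.02$ of
nominal.  The per-cell matrix-recovery check builds its low-divergence
fixture at 6\,000 sites so that the $\pm 0.01$ tolerance exceeds the
estimator's sampling noise at that length.

# Known limitations

* The real study's distance matrices are not reproducible on desk: they
  require the original allele sequences, an unstated gamma shape, gap
  treatment and sequence region.  The engine exposes all of these as
  parameters; reproduction of the published per-locus ranges and means is
  best-effort and non-gating.
* Group-level correlation discards within-group variation and its n is
  the number of groups, so p-values are driven by a handful of points;
  the t approximation is anticonservative below ~9 groups (use
  `pMethod = "permutation"` there).
* The merged-group center convention (midpoint of the merged span,
  half-up to 2 decimals) follows the published layout but is one of
  several defensible choices; it only matters for sparse layouts.
* `spearmanCorrelation(pMethod = "permutation")` enumerates $n!$
  orderings and is limited to $n \le 9$.
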