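---
title: "Selection scans and tiller-number association: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans and tiller-number association: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tillersweep)
```

This vignette documents the statistical models behind the package, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design choices made where the methodology was genuinely
open.

## The scientific setting

Upland japonica rice evolved from irrigated japonica under human selection
for dryland agronomy, which favours fewer tillers and larger panicles. A
locus carried to (near-)fixation by that selection shows elevated
differentiation against irrigated japonica, a deficit of polymorphism
relative to fixed differences, and a hitch-hiking footprint in the derived
allele-frequency spectrum (AFS) of linked SNPs. The package implements the
scan statistics that detect these signatures, plus the association layer
that connects a candidate gene's variants (here a coding 3-bp indel and a
3'UTR T/C SNP) to tiller number in natural panels and biparental crosses.

## Scan statistics

**Per-site FST** is Nei's GST computed from allele frequencies without
sample-size correction: with unweighted mean frequency
$\bar p = (p_1 + p_2)/2$,

$$F_{ST} = \frac{H_T - H_S}{H_T},\qquad H_T = 2\bar p(1-\bar p),\qquad
H_S = \tfrac12\sum_i 2p_i(1-p_i).$$

Omitting the sample-size correction keeps the statistic in $[0,1]$ and makes
it a pure function of frequencies, so all window and gene summaries are
exactly reproducible from a frequency table. A site monomorphic in both
populations has $H_T=0$; its FST is defined as 0 and flagged
non-segregating.

**Windowed scan.** Windows of 20 kb sliding by 2 kb, anchored at coordinate
0; the window value is the unweighted mean of per-site FST over the SNPs in
`[start, start + window)`. The genome-wide top 5 per-mille of window means
is flagged (empirical quantile, ties at the threshold included). The
unweighted mean makes a window's value independent of SNP density, at the
price of higher variance in sparse windows; `n_snps` is reported so users
can filter.

**PBS.** Pairwise FST among the three populations (target, sister,
outgroup), each transformed by Cavalli-Sforza's $T = -\ln(1-F_{ST})$, gives
the focal branch length

$$\mathrm{PBS}_1 = \frac{T_{12} + T_{13} - T_{23}}{2}.$$

The default is this standard form, which may legitimately be negative (the
focal population is *less* diverged than its partners). A `mode = "paper"`
option computes $(T_{12}+T_{13}+T_{23})/2$, the literal form printed in the
source methods; that form is almost certainly a typesetting slip (it is not
a branch length and is never negative), but the package does not silently
decide — the mode used is recorded in the output. The natural logarithm
follows the convention of the PBS literature.

**HKA-style test.** Per gene, over coding SNPs only: $A$ counts sites
segregating within the focal population; $B$ counts sites with pairwise
FST strictly above 0.9 against *both* other populations ("fixed"
differences). The gene's $A\!:\!B$ ratio is compared with the genome-wide
totals by Pearson's chi-square (2×2 table, df = 1, no continuity
correction). Two readings of $A$ are possible from the source description —
segregating in the focal population, or in any population — and both are
implemented (`a_definition`), with the focal reading as default since the
test targets a loss of polymorphism in the swept lineage. Counts $A$ and
$B$ are not mutually exclusive site classes (a site can be both segregating
and strongly differentiated); this mirrors the operational definition used
in the original analysis and is documented rather than "fixed". Genes with
$A+B=0$ have an undefined table and report missing results; expected cells
below 1 set a `low_count` flag.

**Candidate call.** PBS at or above the genome-wide 95th percentile *and*
HKA p below 0.05 (nominal; the original analysis applied no multiple-testing
correction, and the package reports raw p-values — Benjamini–Hochberg can be
added by the user from the returned table, never silently).

## Hitch-hiking diagnostics

Sites are polarized against an outgroup population: the ancestral allele is
the outgroup's major allele provided its frequency is at least 0.9; more
polymorphic or missing outgroup calls exclude the site. This misorients the
small fraction of sites whose true derived allele has drifted to high
frequency in the outgroup (a few percent under the neutral frequency law);
the test suite checks both the overall agreement with the simulator's truth
and that the residual disagreement is confined to that class.

Derived spectra are collected in distance bins $((k-1)b, kb]$ ($b$ = 10 kb
up to 80 kb, both sides of the focal position combined, fixed and absent
sites excluded). Each bin is compared with the genome background — derived
frequencies of segregating sites outside the focal ±80 kb, excluded so the
null set is not contaminated by the sweep itself — by a two-sample
Kolmogorov–Smirnov test with asymptotic p-values; bins with fewer than 5
sites are flagged rather than tested. The source analysis states no numeric
"U-shape" statistic, so the KS comparison against background is treated as
the operative definition of the decay diagnostic; `u_shape_index` (the
proportion of sites in the two frequency tails) is an explicitly labelled
convenience summary, not a test. The decay summary is the Spearman rank
correlation between bin distance and KS D — negative under hitch-hiking.
Frequencies on a sample of $2n$ chromosomes are discrete, so KS ties make
the asymptotic test conservative; the calibration experiment measures the
realized rejection rate under neutrality.

## Association layer

Accessions are split at each site into the two homozygote classes
(heterozygotes and missing excluded, counts logged). The test is Student's
pooled-variance two-sample t-test, two-sided, as in the original analysis;
Welch is available but never the default. Reported summaries follow the
published table layout, with definitions the source tables leave unstated
resolved as follows and documented:

* `effect_size` — absolute difference of group means, in tillers (matches
  the published 0.47–2.77 range read as tiller-scale differences);
* `mean_value_difference` — percent difference relative to the lower group
  mean ("X% more tillers");
* `pooled_variance` — the pooled within-group variance of the analysed
  values.

Sites whose minor homozygote class is under 5% of homozygotes are flagged
rare and excluded from testing (the source tables mark such a site "rare
SNPs" without stating a threshold). Conditional association subsets to the
accessions homozygous for a required class at the conditioning site before
testing — the device used to disentangle two variants ~700 bp apart.
Segregation distortion is a Pearson goodness-of-fit chi-square against the
Mendelian ratio (1:1 for RIL homozygotes, 1:2:1 in an F2).

## The synthetic-data generator

The original study simulates nothing; the generator exists so every stage
is testable at desk scale, and its defaults define the package's study
conditions.

* **Populations.** Ancestral derived frequencies follow the neutral
  $1/i$ law; each population drifts from the ancestor under the
  Balding–Nichols model (Beta with mean $p$ and shape $(1-F)/F$).
  Balding–Nichols was chosen over coalescent simulation because it is
  dependency-free and analytically checkable (expected FST is monotone in
  $F$, and the frequency oracle is exact). Defaults: three populations of
  40 diploids; drift $F = 0.2$ within japonica and $0.5$ to indica —
  reflecting the strong differentiation of selfing rice subpopulations — on
  a 5-Mb chromosome with 50,000 SNPs.
* **Sweep.** A phenomenological mixture: at distance $d$ from the focal
  site, with probability $w_0 e^{-d/\lambda}$ the target population's
  derived frequency is replaced by a uniform draw on `[high_freq_floor, 1]`.
  This is the minimal model producing a U-shaped AFS decaying with distance;
  it makes no demographic claims. "Strong sweep" in the experiments means
  $w_0 = 0.9$, $\lambda = 25$ kb, floor 0.95, fixed before the test
  expectations were frozen.
* **Crosses.** F2: one meiosis from a fully heterozygous F1; F8 RIL: seven
  successive selfings with recombination at each meiosis, so residual
  heterozygosity is $(1/2)^7$ per locus. Distortion is viability selection
  (rejection sampling on the product of per-locus genotype weights), which
  reproduces the reweighted-and-renormalized 1:2:1 in closed form for a
  single distorted locus; under tight linkage, weights at multiple loci
  compound multiplicatively — the analysis scripts therefore place
  distortion at one locus and let the linked locus mirror it.
* **Phenotypes.** Plant-level tiller count = timepoint baseline + additive
  locus effects + Gaussian noise; line value = mean of 8 plants (the field
  protocol's replication). Defaults: baselines 10 and 20 tillers at 40 and
  50 days after germination; plant-level residual SD 3.0 and 6.5 tillers.
  The squared values (9 and ~42) match the order of the published
  within-group variances at the two timepoints when those are read as
  plant-level variances; the published tables do not state variance
  components, so this reading was fixed once, a priori — under it the
  line-mean standard error at the published panel sizes (135 vs 60) makes
  the ±0.6-tiller recovery band for a 2.77-tiller contrast attainable at
  roughly the 90% rate the recovery experiment checks.

What the generator does **not** emulate: linkage disequilibrium between
neutral sites (sites are exchangeable given position), recombination-map
realism, demography beyond single-parameter drift, sequencing error and
genotype likelihoods, and polarization error (truth is emitted; an error
rate parameter, default 0, can corrupt it). Passing tests therefore
demonstrate correctness of the statistics and the qualitative behaviour of
the signatures, not calibration on real resequencing data.

## Numerical and experimental choices

* Empirical quantiles are type-7 with ties at the threshold included, so
  "all values equal" flags everything rather than nothing.
* $F_{ST}=1$ is clamped to $1-10^{-12}$ (with a warning) before the log
  transform.
* The windowed scan reports empty windows (`n_snps = 0`) instead of
  dropping them; `step > window` is rejected because it would silently drop
  SNPs.
* Monte-Carlo tolerances: calibration rates are compared with the nominal
  level within $3\sqrt{\alpha(1-\alpha)/R}$, $R$ the number of seeded
  replicates (one summary per replicate). Problem sizes — 200 replicates of
  1-Mb/5k-SNP genomes for the HKA and KS calibrations, 2000 t-test
  replicates, 50 replicates of the 5-Mb sweep-detection genome, 2000
  recovery replicates — were chosen as the smallest designs at which the
  binomial tolerance is meaningfully tight.
* The HKA calibration runs at drift $F=0.6$ for all populations: the
  fixation count $B$ must be non-degenerate genome-wide for the 2×2
  chi-square to be defined and approximately valid, and weak drift produces
  essentially no FST > 0.9 sites. This is a validity requirement of the
  chi-square, not a tuning decision.
* Every generator is a pure function of (parameters, seed); the pipelines
  stamp outputs with the package version, seed and a config hash, and
  identical configs re-run byte-identically.

## Known limitations

* The HKA-style 2×2 test inherits the chi-square approximation's weakness
  at small fixed-site counts; `low_count` flags mark affected genes, and
  under sparse counts the test is conservative rather than anti-conservative
  in the calibration experiment.
* Asymptotic KS p-values on discrete frequency supports are conservative;
  exact small-sample computation is deliberately out of scope.
* The scan assumes biallelic SNPs on a single chromosome per matrix;
  genome-wide analyses pool per-chromosome runs (quantiles are pooled by
  the caller).
* The published genome-scan headline numbers (the candidate count and the
  specific gene's HKA p-value) depend on the study's resequencing panel and
  are not reproducible from synthetic data; the package reproduces the
  published arithmetic that is self-contained (segregation chi-squares,
  test statistics) and the qualitative signatures otherwise.
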