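---
title: "Recombination maps and heterochiasmy from pedigree-phased genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination maps and heterochiasmy from pedigree-phased genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

caprimap estimates meiotic recombination rates along a genome from phased
parent–offspring SNP genotypes in a pedigreed population, the setting typical
of livestock breeding programs where selection candidates are routinely
genotyped on a medium-density chip. This vignette describes the statistical
model, the design decisions behind the implementation, and what the bundled
synthetic-data generator does and does not emulate.

```{r setup}
library(caprimap)
```

## Crossover detection and informativity

A crossover in a parental meiosis is visible as a switch of grandparental
origin along the haplotype the offspring inherited from that parent. Origin
can only be read at markers where the parent is heterozygous with resolved
phase and the offspring's inherited allele is resolved; these are the
*informative* markers of a meiosis. A crossover is therefore never observed at
a point but within a *detection interval* bounded by the two flanking
informative markers, and nothing can be detected before the first or after
the last informative marker of a chromosome. `crossover_scan()` records, per
meiosis, the events, the informativity mask (the span between the first and
last informative marker) and per-chromosome origin counts.

Two quality-control stages follow the field's standard practice:

* `meiosis_qc()` removes meioses whose parent or offspring has less than 90%
  of markers resolved, and meioses whose parent has no genotyped parents and
  a single genotyped offspring (its phase cannot be anchored, so no crossover
  is observable).
* `filter_double_crossovers()` removes both members of any adjacent event
  pair whose closest detection-interval boundaries are less than 5 Mb apart.
  Genuine close double crossovers are rare in most mammals because of
  crossover interference, so such pairs almost always betray a local phasing
  error. Marking is done in one pass, so chains of mutually close events are
  removed entirely and isolated events are never touched.

Note one deliberate asymmetry: the synthetic-data generator draws crossovers
*without* interference, because the estimation model assumes independent
counts. Under that generator, sub-5 Mb double crossovers are genuine and
relatively common (about one event in five at chip densities), so the
parameter-recovery analyses in the test suite run on unfiltered detections.
On real data the filter should stay on; its justification (interference) is
exactly the feature the generator deliberately omits.

## The Gamma-Poisson model

The genome is tiled into 1 Mb intervals (`genome_grid()`). For interval $i$
and meiosis $m$, the crossover count is modelled as

$$Y_{mi} \mid c_i \sim \mathrm{Poisson}(0.01\, c_i\, l_{mi}),$$

where $c_i$ is the interval's rate in cM/Mb, and $l_{mi}$ is the *informative
length* of the interval in that meiosis (the overlap of the interval with the
meiosis' informativity mask, in Mb) — meioses that cannot see an interval
contribute no exposure. A conjugate gamma prior $c_i \sim \Gamma(\alpha,
\beta)$ gives the closed-form posterior

$$c_i \mid Y \sim \Gamma\!\big(\alpha + \textstyle\sum_m Y_{mi},\;
\beta + 0.01 \sum_m l_{mi}\big).$$

The prior is set empirically (`fit_gamma_prior()`): a maximum-likelihood
gamma fit to the genome-wide distribution of per-interval MLE rates
$\hat c_i = \sum Y_{mi} / (0.01 \sum l_{mi})$, restricted to strictly
positive MLEs from intervals whose total informative length reaches at least
half the genome-wide maximum. The restriction keeps sparsely observed
intervals (whose MLEs are wildly dispersed) from inflating the prior
variance. Chromosome-wide rates use the same posterior with
chromosome-aggregated sufficient statistics; the $0.01$ factor is applied on
the informative length there too, keeping cM/Mb units consistent across
scales.

### Crossover placement uncertainty

Detection intervals at chip density average around a megabase, comparable to
the analysis intervals, so where a crossover count lands matters. Two
assignment schemes are provided by `assemble_observations()`:

* **fractional** (deterministic default): each event is split across grid
  intervals proportionally to the overlap of its detection interval — the
  expected assignment under a uniform position;
* **midpoint**: the whole event goes to the interval containing the
  detection-interval midpoint.

`mc_rate_estimate()` integrates over placement explicitly: in each of $K$
replicates (default 100) every event's position is drawn uniformly in its
detection interval, the posterior is recomputed, and the reported estimate is
the mean of the $K$ posterior means $b_{ik}$. The combined variance uses the
total-variance decomposition $\mathbb{E}_k[\mathrm{Var}_k] +
\mathrm{Var}_k[b_{ik}]$ — both components are reported — and credible bounds
come from the equal-weight mixture of the $K$ gamma posteriors, inverted
numerically. When every detection interval has zero width the replicates
coincide and the machinery reduces exactly to the single-pass posterior.

## Testing for heterochiasmy

Sex differences in local rates are measured by $d_i = \log_2 \hat c_{Mi} -
\log_2 \hat c_{Fi}$. Comparing the posterior means directly would confound
rate differences with informativity differences: in a male-oriented breeding
program the female estimates carry far less data and sit closer to the prior
mean. The null is therefore built by permutation (`permutation_null()`):
the sex labels are permuted across meioses — each meiosis keeps its
crossovers and its informativity mask — so every permutation has exactly the
observed number of male and female meioses and reproduces the observed
informativity imbalance. The observed $d_i$ is computed with the identical
deterministic fractional-assignment estimator as the permuted ones, making
the two exchangeable when the sexes share one map.

The permutation unit deserves a note. Permuting labels at the *parent* level
(all meioses of a parent moving together) respects within-parent correlation
of recombination, but in a design where a handful of sires carry two orders
of magnitude more meioses than the dams, the observed labelling is
structurally unlike almost every permutation, and the resulting null is
centred wrongly wherever the local rate differs from the prior mean; in our
simulations this produced realized false-discovery proportions near one.
Meiosis-level permutation preserves the group informativity profiles exactly
and behaved correctly under identical-map null simulations, so it is what the
package uses. Its cost is a slightly narrow null if strong inter-meiosis
correlation within parents exists (heritabilities of recombination phenotypes
are of the order of 0.1, so the effect is small).

Per interval, the permuted $d_i$ are summarised by a normal distribution
(sample mean and sd) and a two-sided tail probability is reported, alongside
the raw empirical permutation p-value as a diagnostic. With many parents the
permutation null is close to normal; with few heavy parents it can be
skewed, and the far normal tail should be read with care. Multiplicity is
handled by Storey q-values (`qvalues()`): $\pi_0$ estimated on the
$\lambda$ grid $0.05, 0.10, \ldots, 0.95$ with a cubic smoothing spline
evaluated at the largest $\lambda$, clipped to $(0, 1]$, falling back to
$\pi_0 = 1$ (Benjamini–Hochberg) below 100 p-values; intervals with
$q < 0.05$ are called significant.

## Recombination phenotypes

`meiosis_phenotypes()` computes, per meiosis:

* **GRR**, the genome-wide recombination rate: $100 \times$ autosomal
  crossover count / informative genome length in Mb — an
  informativity-corrected intensity in cM/Mb;
* **intra-chromosomal shuffling** $\bar r_{\mathrm{intra}} = \sum_k 2 p_k
  (1 - p_k) L_k^2$, the probability that two uniformly drawn loci on the
  same chromosome uncouple their alleles, where $p_k$ is the proportion of
  informative markers on chromosome $k$ inherited from one grandparent and
  $L_k$ the chromosome's share of the autosomal genome.

$p_k$ is computed over informative markers only (origin is unobservable
elsewhere), and chromosomes with no informative marker contribute $p_k = 0$.
$L_k$ uses physical bp proportions by default; a marker-count weighting is
available behind a flag. The statistic is invariant to grandparental
labelling polarity and bounded by $0.5 \sum_k L_k^2$.

## Marker-order and genotype quality control

Spurious crossovers concentrate at misordered markers, so marker order is
validated against an independent physical map (e.g. a radiation hybrid map):
external markers carry positions on both maps, each chip SNP gets an
interpolated external position from its two flanking external markers
(`project_onto_rh()`), and per chromosome only the longest increasing
subsequence of the external-map order is kept
(`longest_increasing_subsequence()`, `consistent_marker_set()`). Markers
outside the external span cannot be projected and are kept on the strength
of the assembly order. Among equal-length subsequences the lexicographically
smallest value sequence is returned, making the filter deterministic.

Genotype filters run in a fixed, documented order: marker call rate
(< 99% removed), then sample call rate, then monomorphic markers — no
minor-allele-frequency filter, since rare alleles are informative in the
families segregating for them. The Hardy–Weinberg filter (p < 1e-7,
1-df chi-square without continuity correction by default, exact test behind
a flag, computed within population labels when given) excludes offspring of
sires with more than 50 genotyped offspring from the counts, because one
sire carrying a rare allele distorts genotype proportions in a large
half-sib family. `mendel_check()` counts opposite-homozygote conflicts per
parent–offspring pair and flags pairs above a 1% rate for pedigree review;
no automatic re-assignment is attempted. `flag_excess_recombination()`
screens the interval MLE map for runs above 10x the genome-wide median — a
surrogate for the manual synteny inspection such regions normally get, with
removal left to the user.

## Association peaks and candidate genes

Significant SNPs (s-value < 0.01, consumed as input) are clustered per
chromosome into peaks: edges where dosage $r^2 \ge 0.2$, peaks = connected
components, lead = smallest s-value (ties: larger $|\beta|$, then smaller
position). The high-LD area runs from the furthest SNP with $r^2 > 0.6$ with
the lead on each side, over all panel SNPs (not only significant ones — a
documented choice), collapsing to the lead where no SNP qualifies. Every
gene on the chromosome is scored 0–5 by counting: within 2 Mb of the lead;
closest gene to the right of the lead; closest to the left (a gene
containing the lead is closest on both sides); closest gene to another
significant member SNP; overlapping the high-LD area. Distances are to the
gene body, containment counting as zero, and ties for "closest" award the
criterion to every tied gene. Between-group effect agreement is summarised
by a weighted Pearson correlation of effect estimates with weights
$1/(se_a^2 + se_b^2)$ — the exact weighting is a documented package choice.

## The synthetic-data generator

The generator provides ground truth for every downstream stage:

* `simulate_pedigree()` builds a male-biased breeding design: few heavily
  used sires, many dams, only a fraction of dams genotyped
  (`prop_dams_genotyped`). The male bias in observable meioses must come
  from ungenotyped dams rather than single-offspring dams, because the
  meiosis QC removes unanchored single-offspring parents.
* `simulate_true_maps()` makes the male map `end_fold` times higher in the
  first and last `end_fraction` of each chromosome (all chromosomes are
  treated as acrocentric, centromere at coordinate 0) and the female map
  flat — the qualitative sex pattern seen in ruminants.
* `simulate_meioses()` draws interval counts Poisson from the sex map, with
  positions uniform in the interval, no interference, no obligate
  crossover, and a fair-coin initial grandparental origin per chromosome.
* `simulate_genotypes()` places markers uniformly, draws founder haplotypes
  with allele frequencies uniform in the MAF range, copies parental
  haplotypes into gametes switching at the true crossover positions, and
  masks genotypes missing at a fixed rate. True phases are retained so
  detection can be validated exactly.

What it does **not** emulate: founder linkage disequilibrium (founder
markers are independent, so there is no background LD structure),
genotyping error, clustered marker placement, crossover interference, and
real allele-frequency spectra. Passing tests therefore demonstrate the
correctness of the machinery under the model's own assumptions, not
robustness to phasing error or array artefacts.

Default study conditions used across the test suite (the package's choice of
a realistic desk-scale design): 5 acrocentric chromosomes of 100 Mb, male
map 1.2 cM/Mb with 3-fold terminal-decile elevation, female flat at
1.15 cM/Mb, 10 sires with 30 offspring each (300 paternal meioses), 15
genotyped dams with 2 offspring each (30 maternal meioses), about 21
markers/Mb with 1% missingness, 100 Monte-Carlo placement replicates, and
200 permutations in replicated calibration runs.

## Numerical choices and degenerate inputs

* The informative-length factor 0.01 is applied in the chromosome-rate
  denominator as at interval scale, for dimensional consistency.
* The combined Monte-Carlo variance uses the total-variance law; a
  subtraction form requiring the unknown marginal variance of the rate is
  not evaluable and is not used.
* Intervals with no informative mass return the prior (interval posterior)
  or are reported as missing (MLE).
* A degenerate permutation null (every permutation identical, only possible
  when the observed statistic equals the same value) reports p = 1.
* Markers with fewer than two observed genotype classes skip the HWE test;
  monomorphic SNPs yield missing LD with a warning.
* LIS ties break towards the lexicographically smallest value sequence; tied
  "closest gene" criteria award all tied genes.
* Gamma prior fitting requires at least 30 positive finite MLEs and rejects
  zero-variance input.

## Known limitations

* **Empirical-Bayes shrinkage at low meiosis counts.** With ~30 meioses in a
  group, the per-interval informative mass ($0.01 \sum l \approx 0.3$) is
  small against the fitted prior rate ($\beta \approx 1.5$–2.3), so group
  estimates shrink most of the way to the pooled prior mean. Credible
  intervals remain honest (coverage holds), but totals such as the female
  map length are biased towards the pooled-data mean by tens of percent.
  Map-length point estimates should only be trusted with hundreds of
  meioses per group.
* **Per-interval power.** A two-fold sex difference in an interval where the
  scarcer sex expects well under one crossover is undetectable at
  genome-wide FDR control, whatever the estimator; significance scans need
  either many more meioses in the scarce sex or aggregation over regions.
* **Normal tail of the permutation null.** Far-tail p-values inherit any
  skewness of the permutation distribution; the empirical permutation
  p-value is reported alongside for diagnostics.
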