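---
title: "Measuring crossover interference from fluorescent pollen tetrads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring crossover interference from fluorescent pollen tetrads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

Meiotic crossovers (COs) in most eukaryotes come from two pathways: the
interference-sensitive Class I (ZMM) pathway, whose sites are marked by
MLH1/HEI10 foci, and the interference-insensitive Class II pathway resolved
mainly by MUS81. In Arabidopsis, fluorescent-tagged lines (FTLs) in a
*qrt1* background keep the four pollen grains of one meiosis together, so
three linked pollen-expressed fluorophores turn every pollen tetrad into a
readable two-interval recombination experiment.

Scoring the presence of each fluorophore in each spore classifies a tetrad,
per interval, as parental ditype (P), tetratype (T, one visible CO), or
non-parental ditype (N, a four-strand double CO). From class counts this
package computes:

* **Perkins map distance** per interval,
  \(X = 100\,(T/2 + 3\,\mathrm{NPD})/n\) cM;
* **coefficient of coincidence**
  \(\mathrm{CoC} = f_{12}/(f_1 f_2)\), where \(f_i\) is the fraction of
  tetrads recombinant (T or N) in interval \(i\) and \(f_{12}\) the
  fraction recombinant in both;
* **interference** \(= 1 - \mathrm{CoC}\): 0 means independent intervals,
  values near 1 mean strong suppression of nearby double COs.

A genotype that re-channels Class II precursors into the Class I pathway
shows a characteristic signature: unchanged map distances and total
chiasma count, more MLH1/HEI10 foci, fewer residual COs in *zmm*
backgrounds, and higher interference. The package's simulator, estimators
and tests exist to compute, calibrate and power that comparison.

## The two-pathway generative model

`simulate_tetrads()` places crossovers on a bivalent in genetic
coordinates (Morgans internally, cM at every interface):

* **Class I** events are a *stationary gamma-renewal process*: inter-event
  distances are Gamma(shape \(\nu\), mean \(1/\lambda_1\)). \(\nu = 1\)
  is a Poisson process; larger \(\nu\) spaces events more evenly, which is
  the operational meaning of interference. The first event is drawn from
  the equilibrium residual distribution (a uniform fraction of a
  length-biased Gamma(\(\nu + 1\)) interval), so expected counts are
  \(\lambda_1 S\) on any span \(S\) and interval position on the
  chromosome is irrelevant.
* **Class II** events are homogeneous Poisson with rate \(\lambda_2\),
  independent of Class I (superposition; no cross-pathway interference is
  modelled).
* Each event receives one chromatid from each homolog, uniformly and
  independently (no chromatid interference). Spore genotypes follow from
  path traversal over the exchanges: an exchange swaps which spore-path
  occupies which template chromatid from that point rightward. This
  bookkeeping guarantees 2:2 segregation at every marker and makes every
  crossover locally visible on exactly two chromatids; a naive
  "swap material between physical strands" bookkeeping fails both
  properties and was rejected during development.

Parameters (`pathway_params()`), with defaults chosen once as
wild-type-like Arabidopsis conditions:

| parameter     | meaning                                   | default | why |
|---------------|-------------------------------------------|---------|-----|
| `nu`          | gamma shape of Class I spacing (unitless) | 8       | strong interference, in the range reported for Arabidopsis chromosomes |
| `frac_class2` | share of COs from Class II                | 0.15    | the \(\sim\)15–20% MUS81-dependent share of wild-type COs |
| `total_rate`  | expected COs per bivalent per Morgan      | 2       | one CO recombines 2 of 4 chromatids, so a density of 2 makes recombinant-spore fraction equal map distance |

`simulate_metaphase_cells()` draws per-arm Poisson CO counts for 5
bivalents per cell and reports ring/rod/univalent shapes together with the
true chiasma count, so the bias of the shape-based estimator (ring = 2,
rod = 1) can be measured: the estimator is a per-cell lower bound and
undercounts when arms carry multiple COs. `simulate_foci()` draws
Poisson, negative-binomial or zero-inflated-Poisson focus counts.

## Classification

`enumerate_tetrad_classes()` brute-forces every spore-phenotype multiset
reachable with 0–2 COs per interval over all chromatid assignments and
orders. Exactly 12 distinct multisets exist, and they coincide with *all*
multisets of four 3-marker phenotypes obeying 2:2 segregation, so
classification is total on valid tetrads; anything else is aberrant
segregation and is flagged as an overflow class (`"X"`), never silently
dropped or guessed.

The canonical letters are assigned A = (P,P); B, C the single-CO classes;
D, E the within-interval four-strand doubles (N,P)/(P,N); F–I the four
across-interval (T,T) classes ordered by strand configuration (2-strand,
two 3-strand forms, 4-strand); J, K, L the (T,N), (N,T), (N,N) classes.
Letters are presentation only — every estimator works from the ditype
pair, so count tables keyed with a different letter convention can be
ingested via the remap facility of `read_tetrad_table()`. One subtlety:
relabelling fluorophore presence/absence (swapping parental phases) fixes
every class except the two 3-strand (T,T) classes, which exchange; all
ditype assignments, and hence all estimates, are invariant.

## Estimation and testing choices

* "CO frequency in an interval" is operationalised as the fraction of
  tetrads recombinant (T or N) there; an NPD tetrad is counted once, not
  double-weighted. A CO-number weighting is what Perkins distance provides
  alongside.
* The headline interference per genotype is computed from pooled counts,
  with the per-plant mean reported next to it (plots show per-plant dots
  with a mean bar; pooling weights plants by tetrad number). Plants with
  no recombinants in either interval have undefined CoC and are excluded
  from the per-plant mean, with an exclusion log.
* The SE of interference is a multinomial delta method on the 2×2
  recombinant/non-recombinant tetrad table; a seeded tetrad-resampling
  bootstrap is the reference implementation (the two agree to a few
  percent at realistic sizes). Zero observed doubles yields interference
  1 with a `no_doubles` flag rather than an error, because per-plant
  values of exactly 1 do occur in short intervals.
* Genotypes are compared with Z-tests: pooled-variance two-proportion Z
  for recombinant frequencies, and
  \(z = (I_1 - I_2)/\sqrt{se_1^2 + se_2^2}\) for interference. The exact
  variant used on the published data is not specified anywhere, so the
  delta-method form was chosen and validated by simulation: its type-I
  error at \(\alpha = 0.05\) over 1,000 replicate null experiments of
  2,000 tetrads per genotype lands inside [0.03, 0.07], and it separates
  \(\nu = 1\) from \(\nu = 8\) genotypes (5,000 tetrads each) at
  p < 0.01 in over 95% of replicates.
* Cytology comparisons use the field's standard tests via base R:
  `mann_whitney()` (exact null for small tie-free samples; otherwise a
  continuity-corrected normal approximation with tie-corrected variance
  and, for tie-free data, an Edgeworth kurtosis correction — worst-case
  disagreement with the exact two-sided p is about \(10^{-4}\) already at
  15 vs 15), `kruskal_dunn()` (tie-corrected H plus Dunn's pairwise z
  with a configurable adjustment, Bonferroni by default), and
  `ttest_unpaired()` (pooled variance, Welch optional). A
  D'Agostino–Pearson-style normality screen is advisory output only; the
  test applied is always an explicit choice.
* Foci histograms use the closed bins {0}, [1,2], [3,10], [11,20],
  [21,50], [51,∞) exactly as printed in the source figures. A ring
  bivalent scores 2 chiasmata unless the input table explicitly annotates
  it as 3 (`ring3`); no cytological rule for the 3-CO call is invented.

## Numerical behaviour worth knowing

* **Perkins truncation.** The formula is exact for up to two COs per
  interval. Under a pure Poisson process at 15 cM the ≥3-CO classes bias
  it low by about 0.3 cM; under the default interfering parameters
  multi-CO tetrads are rare and 50,000 tetrads recover 6–15 cM intervals
  within ±0.5 cM. Parameter-recovery checks therefore run at the default
  conditions.
* **Haldane correction.** The recombinant-spore fraction for a d-cM
  interval is \((1 - e^{-2d/100})/2\), not \(d/100\); at 6 cM the
  difference (0.0034) is already resolved by 20,000 tetrads, so tests
  compare against the exact expectation.
* **Window truncation.** Inter-event gaps collected from many short
  simulation windows are length-biased; distributional checks of the gap
  law use one long realisation.

## Problem sizes

Simulation-based checks use 50,000 tetrads for estimates and invariants
(Monte-Carlo SE of interference ≈ 0.02 at two 10 cM intervals), 1,000
replicate experiments of 2,000 tetrads per genotype for test calibration,
and 10,000 tetrads for classification cross-checks; these sizes hold all
Monte-Carlo margins at 2–3 SE while a full run of the suite stays in the
tens of seconds.

## What the synthetic data do and do not show

The simulator reproduces the statistical structure the estimators assume:
coupling-phase markers, 2:2 segregation, stationary interference,
independent Class II events, overdispersed or zero-inflated focus counts.
It does not model physical (bp) coordinates, recombination hot/cold spots,
the obligate crossover, chromosome pairing dynamics or synaptonemal-complex
biology. Passing tests therefore demonstrate that the *arithmetic and
inference* are right and well-calibrated under the stated model — not that
real chromosomes follow a gamma-renewal law (the gamma choice is a
standard modelling convention, not an empirical claim of the analysed
experiments).

The count tables shipped under `inst/extdata/` with a `synthetic_` prefix
are reconstructions, not the original raw data: the published raw counts
ship as spreadsheet supplements, so tables of the same layout, size and
composition were built whose summary statistics equal the published
values (interference 0.53/0.65/0.8/0.93/0.63; chiasma means 8.8/9.2;
bivalent means 1.34/1.05/1.04/0.84; focus means 8.4/9.2/11.4/12.2). Tests
against them verify the classification → estimation arithmetic end to
end; given the originals, `reproduce_interference()` consumes them via
the same readers after a CSV export and, if needed, a letter remap.

## Worked example

```{r, eval = FALSE}
library(tetraco)
map <- interval_pair_map(d1 = 10, d2 = 10)

wt  <- simulate_tetrads(50000, map, pathway_params(frac_class2 = 0.15), seed = 101)
mut <- simulate_tetrads(50000, map, pathway_params(frac_class2 = 0),    seed = 102)

counts <- list(tabulate_tetrads(wt,  genotype = "two_pathway"),
               tabulate_tetrads(mut, genotype = "class1_only"))
coc_interference(counts[[1]])
coc_interference(counts[[2]])
ztest_interference(counts[[1]], counts[[2]])

hs <- headline_simulation(map, pathway_params(frac_class2 = 0.15),
                          pathway_params(frac_class2 = 0), n = 50000, seed = 1)
hs
```

## Limitations

* Interference is summarised by a single CoC over one interval pair;
  genome-wide CoC curves over many interval pairs are out of scope.
* Only the Perkins tetrad distance is provided (no Haldane/Kosambi map
  functions).
* The simulator draws no obligate CO, so very low `total_rate` settings
  produce achiasmate bivalents at rates real wild-type meiosis would not.
* The letter→pattern key of any external count table must be confirmed
  against its source figure before ingestion; the remap facility plus the
  counts-sum-to-n validation is the contract for that step.
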