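---
title: "Methods: control-anchored hit calling and senescence-response classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: control-anchored hit calling and senescence-response classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senescreen)
```

## The decision model

High-content senescence screens measure, for every well, a panel of
image-derived phenotypes: mean nuclear area (µm²), object (nucleus)
count, SAβGal signal, p21 mean nuclear intensity, 53BP1 foci per
nucleus, and optionally secreted cytokines (pg/mL). `senescreen` does
not model these phenotypes mechanistically; it implements the
*decision layer* that converts them into hits and response classes.

Every threshold is anchored to the scrambled (non-targeting) controls
of the same plate: with control mean $\mu$ and sample SD $\sigma$
(denominator $n-1$; control well counts are small), a marker cut-off is
$\mu + k\sigma$ and the proliferation cut-off is $\mu - k\sigma$ on the
object count. Anchoring per plate means any additive plate-wide offset
— staining batch, imaging session — shifts controls and samples alike
and cancels exactly; this equivariance is asserted in the test suite.
Per-experiment pooling of controls is available via `scope =
"experiment"` for designs where plates within an experiment are
genuinely exchangeable.

Three rules sit on top of the anchor:

1. **Primary hits** (`call_primary_hits()`): a siRNA passes at level
   $k$ when its nuclear area exceeds $\mu + k\sigma$ *and* its object
   count falls below $\mu - \sigma$. The siRNA value is the mean of its
   replicate wells within an experiment before thresholding (one point
   per oligo; per-well scoring is available with `unit = "well"`). The
   largest $k \in \{1,2,3\}$ passed is the siRNA's `best_k`, and
   `rank_confidence()` counts siRNAs per gene at each best level,
   rendering labels such as `"2 siRNA at 3 x SD; 1 siRNA at 2 x SD"`
   and ordering genes lexicographically descending on the count triple.
2. **Validated hits** (`call_validated_hit()` / `validated_hits()`):
   a replicate-reproducibility m-of-n rule. A unit passes an experiment
   when its value beats $\mu + 3\sigma$; an experiment passes when at
   least $\lceil \tfrac{2}{3}\,\text{units} \rceil$ pass; the gene is a
   hit when at least $\lceil \tfrac{2}{3}\,\text{experiments} \rceil$
   pass. The reported `n_experiments_pass` is the per-box count of the
   screen's heat-maps.
3. **Phenotype classes**: endpoint cell number as a percentage of
   seeding density partitions into *toxic* (< 100%), *cytostasis*
   (100–150%, both ends inclusive) and *growth* (> 150%); the
   senescence response is *complete* when nuclear-area hit, SAβGal hit
   and cytostasis coincide, *none* when no marker hit coincides with
   growth, and *partial* otherwise — including marker induction on a
   toxic background, which is deliberately not special-cased (whether
   SAβGal failure in dying cells is an assay artefact is an open
   biological question, and the classifier should not pre-judge it).
   Sub-threshold growth reduction is visible in the reported
   `pct_of_seeding` but never changes the class.

## Conventions where the field's phrasing is ambiguous

Several conventions had to be fixed; they are exposed as parameters so
a user can flip them, and the defaults are:

- **Strict vs inclusive comparison.** Biomarker rules use strict `>`
  ("greater than mean + 3 SD"); cytokine induction uses inclusive `>=`
  ("by at least mean + 3 SD"). Both phrasings circulate; the package
  unifies them behind `comparison = c("gt", "ge")`, and a value landing
  exactly on the threshold is the only case where they differ.
- **Replicate unit.** Heat-map box definitions are variously quoted
  per-well and per-siRNA. A single m-of-n rule with a configurable
  `unit` covers both; the default is `unit = "sirna"` for multi-siRNA
  panels (3 library siRNAs per gene), `"well"` being the natural choice
  when a single siRNA is arrayed in replicate wells.
- **Rounding of m-of-n.** "At least 2/3" at a non-divisible count uses
  the ceiling, computed with an epsilon guard so `2/3 × 3` is exactly 2
  in floating point.
- **Count criterion in the primary screen.** The reduced-proliferation
  requirement (count below $\mu - \sigma$) is on by default and can be
  disabled (`count_k = NULL`) for designs that score morphology only.

## The synthetic screen generator

`simulate_screen()` exists so every downstream stage is testable and
calibratable without imaging data. Its defaults *are* the study
conditions the rules assume: 3000 cells seeded per well, 3 library
siRNAs per gene, 3 replicate wells, 3 independent experiments, each
cell line × experiment on its own plate with 6 scrambled wells plus
CDK1 positive-control and etoposide wells. Marker values are Normal
around `control_mean + shift × control_sd`, truncated at zero (markers
are non-negative); object counts are Poisson around the profile's
proliferation percentage of seeding. Plate effects are additive,
shared by every well of the plate including controls — precisely the
nuisance per-plate anchoring removes — with SD 0.25 control-SDs by
default. Per-gene `effect_profile()`s carry per-marker shifts in
control-SD units, a proliferation percentage, and the number of active
siRNAs (default 3), the latter modelling the off-target/efficacy
heterogeneity that mixed confidence rankings imply.

Control levels (nuclear area 200 ± 20 µm², SAβGal 10 ± 1.5, p21
500 ± 50, 53BP1 1.5 ± 0.3 foci, nine cytokines 20 ± 3 pg/mL, scrambled
endpoint 250% of seeding) are package conventions in plausible assay
units: published screens report thresholds relative to control mean and
SD, not control coefficients of variation, and only the relative scale
enters any decision. These defaults were chosen once and are not
fitted to anything.

What the generator *does not* emulate — and hence what passing tests do
not show about real data: heavy-tailed or skewed marker distributions,
spatial within-plate gradients (edge effects), correlated markers within
a well, transfection-efficiency drift between experiments, and
cell-death-induced assay dropout. The calibration results below are
exact for Gaussian noise with additive plate effects and should be read
as a correctness baseline, not as an error model for microscopes.

Under these conditions the null behaviour is analytically pinned: a
single well beats $\mu + 3\sigma$ with probability
$1-\Phi(3) \approx 1.35\times10^{-3}$; a per-siRNA mean of three wells
beats it with probability $1-\Phi(3\sqrt3) \approx 10^{-7}$; the
full 2-of-3-siRNAs-in-2-of-3-experiments rule drives the per-gene
false-call rate far below $10^{-3}$, which the test suite verifies on
1000 simulated null genes. Power at a +5 SD shift with 120% seeding is
essentially 1 for the complete-response call, verified over 200 seeds.
The monotonicity of sensitivity in the shift is checked with common
random numbers — the same simulated noise re-evaluated at every shift —
which makes the non-decreasing property hold replicate-by-replicate
instead of only in Monte-Carlo expectation.

## Expression and network stage

`normalize_percentile()` subtracts each array's 75th percentile of log2
intensity, using the linear-interpolation order-statistic estimator
(R's `quantile` type 7) — a convention that had to be fixed for
bit-for-bit reproducibility. The operation is idempotent and invariant
to per-array additive offsets.

`select_de()` computes per-probe unpaired t-tests, Welch
(unequal-variance) form by default with the pooled form behind
`var_equal = TRUE`, selecting probes at `p < 0.03`. Degenerate probes
(zero variance in both groups) get `p = 1` at equal means. When one
group has a single array — a design that does occur with one array per
siRNA against a handful of controls — Welch is undefined; the package
borrows the larger group's variance on that group's degrees of freedom
and warns. At the 3-vs-5 array design the Welch test is known to be
slightly conservative (true size ≈ 0.028 at nominal 0.03 under
Gaussian noise); the calibration test allows ±0.005 around the nominal
level to cover this finite-sample size plus Monte-Carlo error, a band
declared before the calibration was run. Multi-probe genes are
collapsed to the most significant probe (`collapse_probes()`), ties
broken by larger absolute fold then probe id.

`shortest_paths_network()` takes a directed interaction graph (SIF-like
TSV: source, effect, target) and returns the union over targets of
*all* shortest directed paths — ties retained — from the seed gene to
each target and from each target back to the seed, since signalling
flows both into and out of a knocked-down hub; undirected and
single-orientation modes are flags. Whether the original
commercial implementation capped path length is not documentable, so
`max_len` is exposed and defaults to none. `merge_networks()` labels
each edge `A_specific` / `B_specific` / `common` by membership and
overlays per-condition log2 folds on nodes, marking a node only when
its absolute linear fold is at least `min_fold` (default 2,
inclusive). Output goes to SIF-like TSV, a node table, and GraphML.

## Problem sizes and numerical choices in the test suite

The suite's simulation sizes are chosen to give tight Monte-Carlo
error at interactive runtimes: 10⁴ control wells for moment recovery
(3 standard errors), 1000 null genes for the false-call bound, 200
seeds for power, 60 common-random-number replicates per shift for
monotonicity, 500 null matrices × 200 probes for DE calibration, 100
random instances each for the brute-force equivalences (m-of-n rule
and shortest-path subnetworks against independent loop/DFS oracles),
and 20 replicates for the synthetic knockdown recovery, whose expected
level is $2^{-1.15} \approx 45\%$ of control. Seeds are fixed inside
the tests; the acceptance script derives all of its seeds from a single
`--seed` argument.

## Known limitations

- The classifier consumes marker hits and a proliferation class; it
  does not test marker differences statistically (`t.test` is there for
  annotation if wanted) and does not model dose–response.
- Gene-level proliferation averages over all library siRNAs, active or
  not; with partially active genes the mixture can straddle a boundary.
- The interaction-graph content is entirely user-supplied; the package
  ships no interactome and performs no identifier mapping beyond a
  case-collision warning.
- B-score/median-polish normalisation and redundant-siRNA activity
  scoring are deliberately out of scope; per-plate control anchoring is
  the only plate correction implemented.
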