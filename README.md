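# senescreen

Decision machinery for high-content RNAi screens that score cellular
**senescence**. Image-based siRNA screens read out senescence through a
panel of per-well phenotypes — nuclear area, senescence-associated
β-galactosidase (SAβGal), p21 nuclear intensity, 53BP1 foci, endpoint
cell number, and secreted SASP cytokines — and turn them into hit lists
with a small set of control-anchored decision rules. `senescreen`
implements those rules as tested, reusable functions, together with a
synthetic screen generator with the same statistical structure, so that
every stage can be exercised and calibrated without raw imaging data.

## The rules

All thresholds are anchored to the scrambled (non-targeting) controls of
each plate, with mean *μ* and sample SD *σ* computed per plate and
marker, so additive plate effects cancel:

- **Primary hit** (per siRNA): mean nuclear area `> μ + k·σ` for
  `k ∈ {1,2,3}` **and** mean object count `< μ − 1·σ` of the same
  controls. The largest `k` passed gives the per-gene **confidence
  ranking**, rendered as canonical labels such as
  `"2 siRNA at 3 x SD; 1 siRNA at 2 x SD"`.
- **Validated hit** (per gene × cell line × marker): a unit (siRNA or
  well) passes an experiment when its value exceeds `μ + 3σ`
  (strict `>` for biomarkers, `≥` for cytokine induction); an
  experiment passes when ≥ ⌈2/3 · units⌉ pass; the gene is a hit when
  ≥ ⌈2/3 · experiments⌉ pass.
- **Proliferation class** from endpoint cell number as % of seeding
  density: `< 100%` toxic, `100–150%` cytostasis (no growth),
  `> 150%` growth.
- **Senescence response**: *complete* = nuclear-area hit ∧ SAβGal hit ∧
  cytostasis; *none* = no marker hit ∧ growth; everything else
  *partial* — summarised per genotype across an isogenic cell-line
  panel.
- **Network stage**: per-array 75th-percentile normalisation of log2
  expression, unpaired (Welch) t-test selection at `p < 0.03`, then the
  union of all shortest directed paths between a seed gene and the
  selected genes on a user-supplied interaction graph; two condition
  networks are merged with edge-origin labels and a ≥ 2-fold
  expression overlay on nodes.

## Worked example

```r
library(senescreen)

profiles <- rbind(
  effect_profile("ECT2",  c(nuclear_area = 5, sabgal = 5),   proliferation_pct = 120),
  effect_profile("ALDOA", c(nuclear_area = 4, sabgal = 4.5), proliferation_pct = 130),
  effect_profile("CIT",   c(nuclear_area = 4, sabgal = 0),   proliferation_pct = 200))
cfg   <- screen_config(profiles = profiles, n_null_genes = 2, seed = 1)
wells <- simulate_screen(cfg)      # 171 wells: 5 genes x 3 siRNA x 3 wells x 3 experiments + controls
scr   <- senescence_screen(wells)
scr
#> Senescence screen analysis
#>   171 wells, 1 cell line(s), 5 gene(s)
#>   rule: unit value > control mean + 3 SD (plate-anchored), >= 0.667 of sirnas in >= 0.667 of experiments
#>   biomarker hits: 5 of 20 gene x line x marker calls
#>   cytokine hits: 0 of 45 calls
#>   responses: 2 complete, 1 partial, 2 none
summary(scr)
#> Genotype panel summary
#>  cell_line senescence_response partial_senescence_response               none
#>     HCT116         ALDOA, ECT2                         CIT NULL0001, NULL0002
```

The two simulated strong inducers (nuclear area and SAβGal shifted
+4–5 control SDs with arrested proliferation at 120–130% of seeding)
come out as *complete* senescence responses; `CIT`, which raises
nuclear area but not SAβGal and keeps growing (its endpoint count is
~199% of seeding), is a *partial* response; the null genes are *none*:

```r
subset(scr$responses, gene == "CIT")
#>   gene cell_line nuclear_area_hit sabgal_hit prolif_class pct_of_seeding response
#> 2  CIT    HCT116             TRUE      FALSE       growth       199.4099  partial
```

`plot(scr)` draws the hit/miss heat-map with per-experiment pass counts;
`run_pipeline(config, out_dir)` chains simulate → call → classify →
summarise → network from a YAML configuration and writes every table
(see `inst/scripts/senescreen.R` for a command-line wrapper).

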