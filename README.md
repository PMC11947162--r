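# ferrospread

Quantification and simulation of contact-dependent ferroptosis propagation
in cell monolayers.

Ferroptosis — iron-dependent cell death driven by phospholipid peroxidation —
can spread from a dying cell to the cells touching it. In the assay this
package targets, an optogenetic degrader of GPX4 is activated by light in a
chosen subset of transfected cells; those cells die within minutes
(blebbing at 13–20 min, mean 17), and death then propagates outward to
non-transfected "bystander" neighbours, visible as travelling waves of
C11-BODIPY oxidation followed by DRAQ7-positive nuclei. ferrospread provides,
for experimentalists and image analysts working with such data:

* **per-cell quantification** of multi-channel time-lapse stacks:
  segmentation, background-corrected intensity traces, transfected/bystander
  classification, DRAQ7 death calling, and the ratiometric oxidation score
  `G/(G + R)` (oxidized fraction of the probe, in [0, 1]);
* **spatial statistics** on dead-cell point patterns: the Hopkins
  cluster-tendency statistic
  `H = Σuᵢᵈ / (Σuᵢᵈ + Σwᵢᵈ)` (≈ 0.5 under complete spatial randomness, → 1
  for clustered death), cross-population nearest-neighbour distances, and a
  geometry-preserving permutation null for "are dead bystanders closer to
  dead transfected cells than chance?";
* **population kinetics**: %positive curves with fixed initial denominators,
  the %AUC summary (area under the curve normalized to the maximal
  attainable area), time-to-event summaries, one-way ANOVA + Tukey HSD;
* **chain-binomial inference** of the per-contact spread probability `p`
  from an event table and contact graph, where a cell with `k` newly dead
  contact neighbours converts with probability `1 − (1 − p)ᵏ` per step;
* **lipidomics normalisation**: internal-standard ratios, optional
  per-µg-protein scaling, replicate-paired illuminated/control fold changes;
* a **synthetic-data generator** for all of the above — monolayer geometry,
  contact graphs, propagation event tables with pharmacological modifiers
  (Fer-1, iron chelation, contact ablation, bilayer bridging), rendered
  4-channel TIFF stacks, GUV oxidation-transfer traces, and lipidomics
  tables — with known ground truth at every stage.

## Worked example

Simulate the default assay (500 µm field, 50% confluency of ~23 µm cells,
5 opto-activated cells, 6 h window), then ask whether death propagated:

```r
library(ferrospread)

cfg    <- simulation_config(seed = 42)
cells  <- generate_monolayer(cfg)
graph  <- build_contact_graph(cells)
events <- simulate_propagation(cells, graph, cfg)
table(events$cause)
#>       none       opto propagated
#>        258          5         47

report <- propagation_test(events, cells, seed = 1)
report
#> propagation report: verdict = propagating
#>   Hopkins H = 0.913 +/- 0.077; median cross-NN = 30.4 um; permutation p = 0.001

fit <- fit_spread_probability(events, graph)
fit
#> chain-binomial spread fit: p_hat = 0.602 (46 conversions / 81 trials)

times  <- seq(0, cfg$t_end, by = 10)
curves <- population_curves(events$draq7_time, cells$population, times)
pct_auc(curves)
#>    population  pct_auc span_min
#> 1   bystander 3.967335      360
#> 2 transfected 8.525414      360
```

Reading the output: 47 of 305 non-activated cells died by propagation; the
dead-cell pattern is strongly clustered (Hopkins 0.91 versus ≈ 0.5 for
random death) and dead bystanders sit a median 30 µm — just over one cell
diameter — from the nearest dead transfected cell, far closer than the
permutation null allows (p = 0.001), so the composite verdict is
"propagating". The estimator recovers the generator's per-contact spread
probability (true 0.6, estimated 0.60 here). The %AUC values summarize each
population's death kinetics on a 0–100 scale over the 6 h window.

The full imaging path works the same way from rendered stacks:
`render_frames()` → `segment_cells()` → `extract_timecourses()` →
`classify_populations()` / `call_death()` → the statistics above. See the
methods vignette (`vignettes/ferrospread-methods.Rmd`) for the models,
defaults and their rationale.

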