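---
title: "Models and methods behind ferrospread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ferrospread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ferrospread analyses optogenetic monolayer assays in which ferroptosis is
triggered in a selected subset of transfected cells and death subsequently
spreads to touching neighbours ("bystanders"). Because the raw imaging data
of such experiments are rarely deposited, the package pairs every analysis
stage with a synthetic generator that produces the same data structures with
known ground truth. This vignette explains the models, the defaults, and the
choices made where the design was genuinely open.

## The propagation model

Cells are hard discs placed by random sequential adsorption (RSA) in a
square field until a target area fraction (confluency) is reached; discs may
overlap by at most `overlap_tolerance` (default 10%) of their summed radii,
reflecting the slight squishing of adherent cells. Two cells are in contact
when their centre distance is at most $\kappa\,(d_i+d_j)/2$. With
$\kappa = 1$ this is disc tangency; the default $\kappa = 1.5$ accounts for
lamellipodia and spread cell borders reaching beyond the equivalent-circle
disc, and yields a mean contact degree of about 3.7 at 50% confluency —
enough connectivity for contained, cluster-forming spread rather than
isolated deaths or immediate field-wide percolation.

Death propagates on this contact graph by a discrete-time chain-binomial
process with step $dt$ (default 2 min, a typical imaging cadence — the same
clock the estimator assumes):

* at $t=0$, every illuminated transfected cell converts; its time from
  activation to morphological death (blebbing) is truncated-normal with mean
  17 min, SD 2, on [13, 20] min — the single-cell range reported for
  optogenetic GPX4 depletion;
* at each step, an alive unconverted cell with $k$ contact neighbours that
  blebbed during the step converts with probability $1-(1-p_\mathrm{eff})^k$,
  where $p_\mathrm{eff} = p_\mathrm{spread}\cdot
  \mathrm{iron}\cdot\mathrm{fer1}(t)\cdot\mathrm{contacts}$;
* a converted bystander shows lipid-peroxidation onset after a lognormal
  delay (meanlog $\ln 30$, sdlog 0.4 — median 30 min) and blebs a further
  $\mathcal N(60, 15^2)$ min (truncated at 0) later. Only the ordering of
  these events is established experimentally; the delay distributions are
  package defaults chosen to put bystander death on the hours scale of the
  published kinetics, not measured values;
* DRAQ7 (nuclear membrane-rupture dye) turns positive a fixed
  `draq7_lag` = 4 min after blebbing;
* an optional per-minute background hazard (default 0) models
  photo-toxicity; it is compounded per step as $1-(1-h)^{dt}$.

Events whose oxidation onset falls beyond the assay window ($t_\mathrm{end}$,
default 360 min) are censored to `NA` and reported as unobserved.

Modifiers map to the assay's interventions: Fer-1 multiplies
$p_\mathrm{eff}$ by `fer1_efficacy` from `fer1_time` on (it blocks *new*
conversions; whether a radical-trapping antioxidant also rescues
already-oxidized bystanders is unknown, and the model deliberately leaves
them to die); `iron_factor` scales $p_\mathrm{eff}$ (extracellular iron
chelation); `contacts_enabled = FALSE` removes the junctional channel
(α-catenin loss, calcium depletion). The bilayer channel — spread along a
supported lipid bilayer bridging non-touching cells — is *not* gated by
`contacts_enabled` and uses a linear distance decay of the conversion
probability out to `bilayer_range`; the linear form is a modelling choice,
as only the existence of acceleration, not its functional form, is
established.

The default `p_spread` is 0.6 per newly dead contact per step. With the
default geometry this produces, in 6 h, a few dozen propagated deaths in
contiguous patches around the activated cells — large enough for spatial
statistics, small enough that the field does not saturate.

## Rendering and quantification

The renderer draws each cell as an isotropic Gaussian blob whose width is
the stain extent convolved with the point-spread function,
$\sigma = \sqrt{(f_c d)^2 + (\mathrm{psf}\cdot\mathrm{px})^2}$. The width
fraction $f_c$ is per channel: the transfection marker and the C11-BODIPY
membrane probe fill the cell ($f_c = 1/4$), while DRAQ7 is confined to the
nucleus ($f_c = 1/8$). The nuclear width matters: with a whole-cell DRAQ7
blob, dead neighbours bleed measurable signal into an alive cell's trace and
trigger premature death calls. After oxidation onset the green (oxidized)
amplitude rises as $b + (1-b)(1-e^{-(t-t_0)/\tau})$ (baseline $b = 0.1$,
$\tau = 20$ min) and the red (reduced) amplitude falls in mirror image, so
green + red is conserved per cell up to noise.

Segmentation is single-reference-frame: Gaussian smoothing, Otsu
thresholding, and a watershed on the distance transform to split touching
cells, with an area filter (100–1800 µm² at the defaults). Labels are static
— adherent cells barely move on the analysis timescale, and tracking is out
of scope. A contrast guard returns an empty label map when the Otsu classes
are separated by less than 4 background SDs; thresholding pure noise yields
a separation near 2.7 regardless of the noise level, so this cleanly rejects
signal-free frames without rejecting dim real ones.

Per-cell traces are mean intensities over label pixels (mean, not sum, *is*
the cell-size correction: intensity per pixel) minus a local background — the
median of a 3-px dilation annulus excluding all labelled pixels, falling
back to the global background median when the annulus is empty. Death is
called at the first frame whose corrected DRAQ7 value reaches the threshold
and stays there for `persistence` (default 2) consecutive frames; the
default threshold is the pre-activation mean plus five SDs. A consequence of
the persistence rule is that deaths within the last `persistence − 1` frames
cannot be confirmed and are censored.

The oxidation ratio is $G/(G+R)$ — the oxidized fraction of the probe,
bounded in [0, 1], with $G+R=0$ entries flagged `NA` rather than zeroed. An
unbounded variant $(G+R)/G$ of the same monotone quantity is exposed via
`formula = "total_over_green"` for comparability with reports that state the
ratio that way; the bounded fraction is the default because it is the form
consistent with "normalizing green with green + red".

## Spatial statistics

The Hopkins statistic compares distances from random locations to the
nearest event ($u_i$) with distances from sampled events to their nearest
neighbour ($w_i$): $H = \sum u_i^d / (\sum u_i^d + \sum w_i^d)$, reported as
mean ± SD over replicates (default $m = \max(5, 0.1n)$, $d = 2$, 100
replicates). $H \approx 0.5$ indicates spatial randomness, values near 1
clustering, values below 0.5 regularity. The sampling window defaults to the
bounding box of the *full* cell population, not the dead cells: the field of
view is the sampling frame, and a window shrunk to the dead-cell hull would
bias $H$ upward. Note that even a genuinely random pattern's *conditional*
Hopkins mean varies by roughly ±0.03 from pattern to pattern at $n = 200$;
calibration statements are therefore about averages over patterns.

Nearest-neighbour distances (within- or cross-population) are raw
centroid-to-centroid Euclidean lengths with no edge correction — distances
from near-boundary points carry the usual outward bias, which cancels in the
permutation comparison below. Ties resolve to the lowest index for
determinism.

The permutation null holds the monolayer geometry fixed and resamples
*which* cells died within each population, recomputing the median
cross-population nearest-neighbour distance per replicate; the p-value uses
the add-one rule $(1 + \#\{\mathrm{null} \le \mathrm{obs}\})/(R+1)$. The
composite `propagation_test()` verdict is "propagating" when this p-value is
below α (default 0.05) *and* the Hopkins mean exceeds 0.5, "random" when the
p-value is not significant, "inconclusive" otherwise.

## Kinetics

Percent-positive curves divide cumulative deaths by the *initial* population
size (denominators fixed at $t_0$; curves are non-decreasing and bounded by
100). The %AUC summary is the trapezoidal area under the curve divided by
the maximal attainable area (a curve pinned at 100%), times 100 — so a
saturated death curve scores 100, no death 0, a linear ramp 50. This
normalisation is the package's definition; it is stated prominently because
published "%AUC" panels do not define one. An object-count-per-confluency
mode is provided for nuclear-count readouts; its units are arbitrary.
Time-to-event summaries report mean/min/max of uncensored times only and
count censored cells separately — no imputation, no survival modelling.
Group comparison is a standard one-way ANOVA with Tukey HSD, with
numerically zero within-group variance flagged rather than reported as an F
statistic.

## Chain-binomial estimation

`fit_spread_probability()` inverts the propagation model from an event table
and contact graph alone. The difficulty is that conversion is unobservable —
only the oxidation onset, which lags conversion by a positive delay. The
likelihood therefore brackets, for each converted cell, all exposures within
the delay window $[w_{lo}, w_{hi}]$ (default [8, 110] min, the 0.1–99.9%
range of the default lognormal delay) before onset into a single
"at least one of these converted me" term $1-(1-p)^K$; exposures older than
$w_{hi}$ are escapes; exposures more recent than $w_{lo}$ are ignored as
almost surely post-conversion. For never-converted cells, an exposure near
the end of the assay might have converted the cell without the onset being
visible yet; such escape terms are weighted by a linear approximation of the
delay CDF between the window bounds. Without this weighting the estimator is
visibly biased (downward when late exposures count as full escapes, upward
when they are dropped). The maximum is found by a 1001-point grid refined
with golden-section search; degenerate data give exact boundary estimates 0
and 1.

Two caveats are documented deliberately. First, the window approximation
leaves a small upward systematic (about +0.03 at the defaults) that does not
shrink with field size — across-seed variability does, but the bias is
attribution-limited, not data-limited. Second, the underlying assay never
measures a per-contact transmission probability; this estimator is an
artifact-level formalization of "death spreads to touching neighbours", not
a reproduction of a published analysis.

## Vesicle transfer model

The two-compartment GUV model is
$\dot x_d = k_\mathrm{act}(1-x_d)$,
$\dot x_a = \mathrm{contact}\cdot k_0\,[\mathrm{Fe}]\,x_d(1-x_a)$,
with oxidized fractions mapped to probe ratios through
$r = b + (1-b)x$. It is integrated with `deSolve` (lsoda, tolerances
$10^{-10}$); the donor admits the closed form $1-e^{-k_\mathrm{act}t}$ used
as an oracle. Without contact or without iron the acceptor's derivative is
identically zero and its trace stays exactly at baseline — the qualitative
signature of iron-dependent, contact-dependent transfer.

## Lipidomics

Normalized ratios are peak area / matched internal-standard area, divided by
protein content (per µg) for oxidized phospholipid panels and not for fatty
acids. Fold changes are illuminated/control per replicate — replicate-paired,
not pooled-control, which is the stricter reading of "for the individual
replicates" — and summarized by the arithmetic mean (a geometric option
exists). The internal-standard matching (PC species to the PC standard, PE
to PE, and so on) is supplied as a configurable map since no such table is
standard.

## What the generator does and does not emulate

The synthetic data reproduce the statistical structure the analyses assume:
disc geometry with contact-scaled adjacency, chain-binomial spread with
delayed observable onset, channel dynamics with conserved ratiometric
probes, additive Gaussian read noise, and multiplicative lipidomics noise.
They do *not* emulate cell migration or division, irregular cell shapes,
uneven illumination or flat-field artifacts, probe photobleaching, or 3-D
tissue geometry. A pipeline that passes the round-trip tests is therefore
validated for its arithmetic and logic, not against the full messiness of
real microscopy. Published Hopkins values from the original assay (clustered
0.67 versus random 0.43) are not recomputable without the raw images; note
that 0.43 sits below the CSR expectation of 0.5, consistent with the mild
regularity a monolayer imposes on nucleus positions, which the
permutation-based comparison is insensitive to.

## Problem sizes used by the test suite

Unit tests run on 250 µm fields (~75 cells). The acceptance-style checks use
the defaults (500 µm, ~310 cells) with 50 replicates for the paired spatial
comparison and the %AUC ordering, 20 seeds at 650 µm (~510 cells) for
parameter recovery, and 300 µm fields for the imaging round trip; these
sizes give stable statistics at interactive runtimes and are the same sizes
`scripts/acceptance.R` reports.
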