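---
title: "gelscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gelscreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelscreen)
```

gelscreen implements an image-based screening pipeline for hydrogel
biodegradation on a millifluidic chip: dye-stained gel discs sit in
perfused circular wells, a fixed camera takes top-down time-lapse images,
and the software turns those images into per-disc degradation curves,
endpoint degradation rates and — from the chip eluate — release profiles of
entrapped compounds. Because laboratory image sets are rarely shareable,
the package also contains a ground-truthed scene simulator so that every
analysis stage can be exercised and validated end to end. This vignette
explains the models, the tunable parameters and the choices made where the
design was genuinely open.

## The erosion model behind the simulator

The simulator treats each disc as a cylinder of initial radius $r_0$
(default 2 mm) and thickness $h_0$ (default 1 mm) that loses material from
its rim. In the perfused chip the degrading enzyme reaches the disc mainly
at its exposed circumference, and top-down observation shows shrinking
outlines rather than thinning, so erosion acts on the radius only and the
thickness is held constant:

$$ r(t) = \max\{0,\; r_0 - k\,C\,t \}, \qquad
   m(t) = \pi r(t)^2 h_0 \rho, $$

where $C$ is the enzyme concentration (µg/mL), $k$ the erosion coefficient
(`erode_coeff`, mm·h⁻¹ per µg/mL) and $\rho$ an arbitrary density scale.
Linear decay at constant speed is the simplest form consistent with the
endpoint-rate analysis the pipeline performs; the proportionality between
erosion speed and enzyme concentration is likewise a modeling choice — real
dose–response curves are only known to be monotone — and is therefore a
single exposed parameter rather than a hard-coded law. The default
`erode_coeff = 1/600` is anchored to the one quantitative observation
available for the chip: a 2 mm disc under the 100 µg/mL enzyme condition
disappears in roughly 12 hours.

At high enzyme doses real gels sometimes fail abruptly instead of eroding
smoothly. The simulator reproduces this as a single all-or-nothing event:
once the remaining area fraction drops below `disintegrate_frac` (default
0.25), each time step triggers complete loss with probability
`disintegrate_prob`. One event per disc, gated on late-stage fragility, is
deliberately minimal — enough to exercise the event-flagging code without
pretending to model fracture mechanics.

Replicate wells at the same dose receive a lognormal jitter on
`erode_coeff` (`rate_cv`, default 5% in the full-experiment configuration)
so that biological replicates are not numerically identical; without it,
between-replicate statistics (ANOVA on rates) would be degenerate, which no
real data set is.

## The release model

Cumulative release of the entrapped compound (PVA in the motivating
application) is a two-term mixture:

$$ q(t) = L\left[\, b\,(1 - e^{-t/\tau})
        \;+\; (1-b)\,\Bigl(1 - \tfrac{r(t)^2}{r_0^2}\Bigr) \right], $$

with load $L$ (`pva_load`, default 943 µg = disc volume × 7.5% w/v), burst
fraction $b$ (`burst_frac`, default 0.3) and burst time constant $\tau$
(`burst_tau`, default 1 h). The first term is passive diffusion of compound
near the surface — it is why release is observed even with no enzyme at all
— and the second couples the remainder of the load to the eroded area
fraction, so faster-degrading discs release faster. Both functional forms
are package inventions: they reproduce the qualitative phenomenology (an
early burst visible at a 1 h sample; degradation-coupled sustained release)
and give closed-form ground truth for testing, nothing more. The default
$\tau = 1$ h makes the burst essentially complete by the first eluate
sample.

Eluate measurement is simulated as a closed recirculating reservoir
(default 20 mL): concentration = cumulative release / reservoir volume,
mapped through a linear standard curve and perturbed with Gaussian
absorbance noise (sd 0.005 AU). The small sampled volumes (tens of µL) are
neglected in the mass balance. The synthetic 630-nm calibration (slope
0.02 AU per µg/mL, blank 0.05 AU, standards 0–50 µg/mL) was chosen once so
that the working range covers the concentrations the default experiment
produces, with sensitivity typical of colorimetric PVA assays.

## Rendering and the rasterization rule

Frames are drawn at `px_per_mm` (default 15) with three flat colors plus
noise: a dark chip background, a pale dye-tinted medium filling each well
(RGB 230,170,175 — red in hue but low in saturation), and a strongly
stained disc (RGB 200,30,40). A pixel belongs to a disc iff its integer
center coordinate lies inside the closed circle; this exact rule is shared
with the test oracle, so "segmentation equals rasterization" is a
well-defined equality, not an approximation. Additive Gaussian pixel noise
(sd 5 of 255 by default) and Poisson-count debris specks of disc-colored
pixels at non-well locations emulate sensor noise and the gel fragments
that wash down the channels. Kinetics are simulated on a fine grid (60 s,
the acquisition cadence of the real system) while frames are rendered only
every `frame_interval` minutes (default 30 in the full-experiment
configuration), so ground truth is always sharper than what the camera
sees — as in a real experiment.

What the generator does *not* emulate: uneven illumination, white-balance
drift, specular highlights, perspective or lens distortion, discs that
drift within a well, and partial-transparency edges. Tests passing on
synthetic frames therefore validate the algorithmic chain (gating,
grouping, tracking, rate arithmetic, calibration algebra), not robustness
to real-camera artifacts; on real images the HSV gate will need tuning
per lighting setup.

## Segmentation choices

The stained-gel gate works in HSV space: hue in a window that may wrap
through 0° (default 340°–20°), saturation ≥ 0.35, value ≥ 0.15. A pure hue
threshold cannot work here because the perfusion medium is dyed too — disc
and medium share the red hue and differ mainly in saturation. The
saturation floor is therefore the discriminating criterion, and the value
floor suppresses dark chip pixels whose hue is noise. Whether to threshold
in RGB or HSV space was an open choice; HSV was selected because it makes
"same color, different intensity" separable with two scalar floors.

Debris suppression is a minimum-region-size filter (`min_region_px`,
default 5 px): every 8-connected foreground region smaller than the
threshold is deleted. A size filter, unlike morphological opening, keeps
the surviving mask an exact subset of the thresholded pixels, which
preserves the segmentation-equals-rasterization property on clean frames
and makes the filter idempotent. The threshold couples to rate estimation:
a disc is "completely degraded" when its cleaned area reaches zero, so the
filter sets the detection floor. At 5 px the floor is exactly the
one-pixel rasterized disc (radius < 1 px ≈ 0.067 mm at 15 px/mm, about 3%
of $r_0$), which keeps endpoint rates of completing discs within 5% of
truth while still removing the isolated pixels that camera noise pushes
through the gate.

Pixel grouping is 8-connected component labeling with labels assigned in
raster-scan order of first encounter (implemented in C++; the test suite
checks it against an independent pure-R flood fill). 8-connectivity was
chosen so that fragments of a disintegrating disc that touch only at
corners remain one region. Regions are credited to the well whose circle
contains their centroid, fragments within a well are summed (the disc, not
the fragment, is the unit of interest), and regions whose centroid lies in
no well — debris flowing in the channels — are discarded. Centroid
containment is the simplest deterministic rule for a fixed chip geometry;
an overlap-fraction rule would behave identically here because wells are
far apart relative to disc size.

## Rates, events and statistics

The endpoint pseudorate assumes linear degradation and uses only two
numbers per trace: `rate = 100 / t_complete` %/h when the disc fully
degrades, else `rate = 100·(A(0) − A(T))/A(0)/T` over the run length $T$,
floored at zero. An ordinary least-squares slope (`regression_rate()`) is
available as a smoother alternative but is not the reported estimator.
Disintegration events are flagged when a single-frame drop reaches
`drop_frac` (default 0.3) of the *initial* area — normalizing by the
initial rather than the current area keeps late-stage noise on a nearly
gone disc from raising spurious events. Note the interaction with the
simulator's gate: an event armed at `disintegrate_frac = 0.25` produces
drops of at most ~25% of initial, below the default 0.3 flag; detecting
simulated disintegration therefore uses a higher gate or a lower flag —
both are exposed parameters.

Validation statistics are deliberately standard: Pearson correlation with
the t-transform p-value, one-way fixed-effects ANOVA, Tukey HSD on the
studentized range (Tukey–Kramer for unequal n), stars at p < 0.05 and
p < 0.005. For the eluate validation the package correlates *percent
degraded* (100 − area%) against cumulative eluate gel, because disc size
against a cumulative quantity is negatively sloped by construction; the
degraded-fraction convention yields the positive correlation conventionally
reported. The mass validation pairs final-frame measured area against
final disc mass, one pair per well.

## Numerical and reproducibility choices

* All randomness flows from explicit integer seeds through
  `withr::with_seed()`; no function leaves the global RNG state altered.
  `run_experiment()` derives fixed per-stage seed offsets from one master
  seed, and two runs with the same configuration are byte-identical in all
  CSV/JSON outputs.
* Times are hours in kinetics and traces, minutes in frame metadata
  (matching acquisition timestamps); concentrations are µg/mL; image
  colors are 8-bit.
* Completion is the first frame with zero cleaned area and all later
  frames zero; a disc whose area reappears after zero is an anomaly —
  completion is left unset and a warning raised rather than silently
  accepting either reading.
* Degenerate inputs are rejected with messages naming the offending well:
  zero initial area (nothing to normalize by), single-frame traces (no
  elapsed time), zero-variance margins in correlation, all-identical
  standard concentrations, zero-slope curves.
* The default full-experiment problem size — 8 wells, 20 h, kinetics at
  60 s, frames every 30 min at 15 px/mm — was chosen so a complete
  simulate–segment–track–quantify–assay–report cycle runs in seconds on a
  laptop while every quantity of interest (completion times, rates, burst,
  correlations) remains comfortably above its resolution floor.

## Known limitations

Only surface area is measured: thickness changes are invisible from the
top view, so mass inferred from area underestimates degradation for
materials that thin substantially. The segmentation gate assumes a stable
color cast; it has no illumination correction. The simulator's linear
dose–response and two-term release model are conveniences, not mechanistic
claims — fitting mechanistic release models (e.g. surface-erosion models of
the Hopfenberg family) to the release profiles this package produces is
out of scope. Well assignment assumes discs do not migrate between wells,
which the chip geometry guarantees but free-floating fragments may violate
transiently; such fragments are counted wherever their region centroid
lands.
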