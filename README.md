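# gelscreen

Image-based screening of hydrogel biodegradation and therapeutic release.

Biodegradable hydrogels (e.g. gelatin methacrylate, GelMA) are candidate
ocular drug-delivery vehicles: as enzymes in the tear film degrade the gel,
an entrapped therapeutic is released. The conventional way to measure
degradation — drying and weighing gels at a handful of time points — is
destructive, laborious, and blind to fast events such as sudden
disintegration. An alternative is to perfuse dye-stained gel discs in the
wells of a millifluidic chip, photograph them continuously from above, and
measure degradation as the loss of stained area over time, while assaying
the chip eluate for released compounds.

gelscreen implements that analysis chain in R, plus a ground-truthed
simulator so the whole pipeline can be validated without laboratory data:

- **scene simulation** — surface-erosion kinetics
  (`r(t) = max(0, r0 − k·C·t)`, mass `∝ r²`, optional abrupt
  disintegration), two-term release (burst + degradation-coupled), and a
  frame renderer with noise and flowing debris (`simulate_kinetics()`,
  `render_frames()`, `simulate_eluates()`)
- **segmentation** — HSV color gate (hue window with wraparound,
  saturation/value floors) and minimum-region-size debris filtering
  (`make_mask()`, `clean_mask()`)
- **labeling & tracking** — 8-connected component labeling in raster
  order, centroid-based well assignment, per-well area traces normalized
  to the initial area (`label_regions()`, `assign_to_wells()`,
  `build_traces()`, `trace_frames()`)
- **quantification** — endpoint degradation pseudorate, in percent of
  initial surface area per hour: `rate = 100/t_complete` for discs that
  fully degrade, else `100·(A(0) − A(T))/A(0)/T`; single-frame
  disintegration-event flags (`pseudorate()`, `flag_disintegration()`)
- **assay** — linear absorbance standard curve (OLS), inversion with
  extrapolation flags, closed-reservoir cumulative release profiles
  (`fit_standard_curve()`, `invert_curve()`, `release_profile()`)
- **statistics & report** — Pearson validation correlations, one-way
  ANOVA with Tukey HSD (stars at p < 0.05 / p < 0.005), figures and a
  machine-readable summary (`pearson_r()`, `compare_groups()`,
  `build_report()`)

## Worked example

A complete synthetic experiment — 8 wells at enzyme concentrations
0/50/100/200 µg/mL (two replicates each), 2 mm discs, 20 h, frames every
30 min — runs from one configuration object:

```r
library(gelscreen)
res <- run_experiment(default_config(seed = 7), out_dir = "run7")
res$rates
#>   well_id rate_pct_per_h complete t_complete_h n_events condition
#> 1      W1       0.000000    FALSE           NA        0         0
#> 2      W2       0.000000    FALSE           NA        0         0
#> 3      W3       4.743090    FALSE           NA        0        50
#> 4      W4       4.757178    FALSE           NA        0        50
#> 5      W5       9.090909     TRUE         11.0        0       100
#> 6      W6       8.000000     TRUE         12.5        0       100
#> 7      W7      18.181818     TRUE          5.5        0       200
#> 8      W8      16.666667     TRUE          6.0        0       200
```

Reading: control discs do not degrade (0 %/h); 50 µg/mL discs lose about
4.75% of their initial area per hour and survive past 20 h; at 100 µg/mL
discs fully degrade in 11–12.5 h (rate = 100/t_complete); at 200 µg/mL in
5.5–6 h. Replicates differ because the simulator jitters per-disc erosion
speed (5% CV), as biological replicates do. The output directory contains
the rendered frames, the tidy `traces.csv` / `rates.csv` /
`release_*.csv` tables, figures, and `summary.json` with the ANOVA
(`F = 249.8, p = 5.28e-05` for this seed) and the validation correlations
(measured area vs. true mass `r = 0.9999996`; percent degraded vs. eluate
gel `r = 0.9998`).

A command-line front end with `simulate` / `segment` / `quantify` /
`assay` / `report` / `run-all` subcommands is installed at
`system.file("cli/gelscreen", package = "gelscreen")` and reads the same
YAML configuration (`read_config()`).

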