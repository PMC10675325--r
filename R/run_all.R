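#' Default end-to-end experiment configuration
#'
#' One nested list drives the whole pipeline; [run_experiment()] consumes it
#' and the CLI reads the same structure from YAML. Defaults reproduce the
#' standard chip study: an 8-well chip with enzyme at 0/50/100/200 ug/mL
#' (two replicate wells each), 2 mm x 1 mm discs, a 20 h time course, and
#' eluate sampling at 0, 1, 2, 3 and 17 h against a linear 630-nm standard
#' curve. Kinetics run on a 60 s grid (the acquisition cadence) while frames
#' are rendered every 30 min at 15 px/mm, a desk-scale problem size that
#' keeps a full run in seconds. The 5 px speckle filter puts the
#' completion-detection floor at a rasterized disc radius of one pixel
#' (0.067 mm here), about 3% of the initial radius.
#'
#' @param seed Master integer seed; stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    wells = list(enzyme_conc = c(0, 50, 100, 200), replicates = 2,
                 erode_coeff = 1 / 600, disintegrate_frac = 0.25,
                 disintegrate_prob = 0, rate_cv = 0.05),
    disc = list(radius0 = 2, thickness0 = 1, density_scale = 1,
                pva_load = 943, burst_frac = 0.3, burst_tau = 1),
    kinetics = list(duration = 20, step = 1 / 60),
    render = list(px_per_mm = 15, well_radius_mm = 5, frame_interval_min = 30,
                  noise_sd = 5, debris_rate = 1, debris_size_px = 20),
    gate = list(hue_lo = 340, hue_hi = 20, sat_min = 0.35, val_min = 0.15),
    min_region_px = 5,
    drop_frac = 0.3,
    assay = list(
      standards_conc = c(0, 5, 10, 20, 30, 40, 50),
      pva_slope = 0.02, pva_intercept = 0.05,
      gel_slope = 1.0, gel_intercept = 0.04,
      gel_standards_conc = c(0, 0.1, 0.2, 0.4, 0.6, 0.8),
      sample_times = c(0, 1, 2, 3, 17),
      reservoir_vol = 20, absorbance_noise_sd = 0.005
    )
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a run configuration from YAML
#'
#' Fields present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

# Noise-free standards on the configured line; the synthetic calibration is
# exact by construction, measurement error enters through the eluate reads.
config_curve <- function(slope, intercept, conc) {
  fit_standard_curve(conc, slope * conc + intercept)
}

#' Run the full synthetic screening experiment
#'
#' Chains every stage: simulate kinetics, render time-lapse frames, segment
#' and track discs, estimate pseudorates, simulate and quantify eluates
#' (released PVA and degraded gel), pair the visual measurements against the
#' ground-truth mass and the eluate gel, and build the report bundle. All
#' stage outputs are written under `out_dir`; the run is deterministic given
#' `config$seed`.
#'
#' @param config Configuration list from [default_config()] or
#'   [read_config()].
#' @param out_dir Output directory.
#' @param keep_frames Write rendered frames to disk (`TRUE`, default) —
#'   needed when you want to re-run segmentation on files; the analysis
#'   itself streams frames either way.
#' @return Invisibly, a list with `truth`, `traces`, `rates`, `release_pva`,
#'   `release_gel`, `pairs` and the report `summary`.
#' @export
run_experiment <- function(config = default_config(), out_dir,
                           keep_frames = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  wells <- default_wells(
    enzyme_conc = config$wells$enzyme_conc,
    replicates = config$wells$replicates,
    erode_coeff = config$wells$erode_coeff,
    disintegrate_frac = config$wells$disintegrate_frac,
    disintegrate_prob = config$wells$disintegrate_prob,
    rate_cv = config$wells$rate_cv %||% 0,
    seed = seed + 4L
  )
  disc <- do.call(disc_spec, config$disc)
  truth <- simulate_kinetics(wells, disc, duration = config$kinetics$duration,
                             step = config$kinetics$step, seed = seed)
  write_truth_csv(truth, file.path(out_dir, "truth.csv"))

  cfg <- render_config(px_per_mm = config$render$px_per_mm,
                       frame_interval = config$render$frame_interval_min,
                       noise_sd = config$render$noise_sd,
                       debris_rate = config$render$debris_rate,
                       debris_size_px = config$render$debris_size_px,
                       seed = seed + 1L)
  layout <- row_layout(colnames(truth$radius),
                       well_radius_mm = config$render$well_radius_mm,
                       px_per_mm = config$render$px_per_mm)
  write_layout_csv(layout, file.path(out_dir, "layout.csv"))

  frames_dir <- file.path(out_dir, "frames")
  rendered <- render_frames(truth, layout, cfg,
                            dir = if (keep_frames) frames_dir else NULL)

  gate <- do.call(color_gate, config$gate)
  source <- if (keep_frames) frames_dir else rendered$frames
  traces <- trace_frames(source, layout, gate,
                         min_region_px = config$min_region_px)
  utils::write.csv(traces_to_df(traces), file.path(out_dir, "traces.csv"),
                   row.names = FALSE, quote = FALSE)

  rates <- rate_table(traces, drop_frac = config$drop_frac)
  conc <- vapply(wells, `[[`, numeric(1), "enzyme_conc")
  rates$condition <- conc[match(rates$well_id,
                                vapply(wells, `[[`, character(1), "well_id"))]
  utils::write.csv(rates, file.path(out_dir, "rates.csv"),
                   row.names = FALSE, quote = FALSE)

  ac <- config$assay
  pva_curve <- config_curve(ac$pva_slope, ac$pva_intercept, ac$standards_conc)
  gel_curve <- config_curve(ac$gel_slope, ac$gel_intercept,
                            ac$gel_standards_conc)
  elu_pva <- simulate_eluates(truth, pva_curve, times = ac$sample_times,
                              analyte = "pva",
                              reservoir_vol = ac$reservoir_vol,
                              noise_sd = ac$absorbance_noise_sd,
                              seed = seed + 2L)
  elu_gel <- simulate_eluates(truth, gel_curve, times = ac$sample_times,
                              analyte = "gel",
                              reservoir_vol = ac$reservoir_vol,
                              noise_sd = ac$absorbance_noise_sd,
                              seed = seed + 3L)
  release_pva <- suppressWarnings(
    release_profile(elu_pva, pva_curve, ac$reservoir_vol))
  release_gel <- suppressWarnings(
    release_profile(elu_gel, gel_curve, ac$reservoir_vol))
  utils::write.csv(release_pva, file.path(out_dir, "release_pva.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(release_gel, file.path(out_dir, "release_gel.csv"),
                   row.names = FALSE, quote = FALSE)

  pairs <- validation_pairs(truth, traces, release_gel)
  summary <- build_report(traces, rates, eluates = release_pva,
                          pairs = pairs, out_dir = out_dir)

  invisible(list(truth = truth, traces = traces, rates = rates,
                 release_pva = release_pva, release_gel = release_gel,
                 pairs = pairs, summary = summary))
}

#' Pair visual measurements with reference measures for validation
#'
#' Two pairings mirror the method validations: (1) final-frame measured disc
#' area (px) against final ground-truth disc mass, one pair per well (the
#' mass-loss comparison); (2) per-timepoint percent degraded
#' (`100 - area_pct`) against eluate-measured degraded gel, pooled over
#' wells and sampling times (the eluate comparison — degraded fraction is
#' used so the expected correlation is positive).
#'
#' @param truth A `sim_truth`.
#' @param traces List of `disc_trace`.
#' @param release_gel Gel release profile from [release_profile()].
#' @return Named list of data.frames with columns `x`, `y`.
#' @export
validation_pairs <- function(truth, traces, release_gel = NULL) {
  ids <- vapply(traces, `[[`, character(1), "well_id")
  final_area <- vapply(traces, function(tr)
    tr$area_px[length(tr$area_px)], numeric(1))
  final_mass <- truth$mass[nrow(truth$mass), ids]
  mass_pairs <- data.frame(x = final_area, y = unname(final_mass))
  attr(mass_pairs, "xlab") <- "Final disc area (px)"
  attr(mass_pairs, "ylab") <- "Final disc mass (truth units)"
  pairs <- list(area_vs_mass = mass_pairs)

  if (!is.null(release_gel) && nrow(release_gel) > 0) {
    deg <- do.call(rbind, lapply(traces, function(tr) {
      rg <- release_gel[release_gel$well_id == tr$well_id, ]
      if (!nrow(rg)) return(NULL)
      pct <- stats::approx(tr$times, tr$area_pct, xout = rg$time_h,
                           rule = 2)$y
      data.frame(x = 100 - pct, y = rg$cum_mass_ug)
    }))
    if (!is.null(deg) && nrow(deg) >= 3) {
      attr(deg, "xlab") <- "Degraded area (% of initial)"
      attr(deg, "ylab") <- "Eluate gel (cumulative units)"
      pairs$degradation_vs_eluate_gel <- deg
    }
  }
  pairs
}
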