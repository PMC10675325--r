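#' Define one well condition for a simulated degradation run
#'
#' A well condition couples an enzyme concentration (an MMP9 analog, the dose
#' variable of the experiment) to the parameters of the surface-erosion model:
#' the radial erosion speed is `erode_coeff * enzyme_conc` in mm/h, and an
#' optional abrupt-disintegration event can fire once the remaining area
#' fraction drops below `disintegrate_frac`.
#'
#' @param well_id Identifier for the well (character scalar).
#' @param enzyme_conc Enzyme concentration in ug/mL; must be >= 0.
#' @param erode_coeff Radial erosion speed per unit enzyme concentration, in
#'   mm/h per (ug/mL). The default `1/600` makes a 2 mm disc at 100 ug/mL
#'   erode to nothing in 12 h.
#' @param disintegrate_frac Area fraction (of initial) below which abrupt
#'   disintegration becomes possible; in \[0, 1\].
#' @param disintegrate_prob Per-timestep probability of disintegration once
#'   armed; in \[0, 1\]. Zero disables disintegration.
#' @return A `well_condition` object (a named list).
#' @seealso [simulate_kinetics()]
#' @export
well_condition <- function(well_id, enzyme_conc,
                           erode_coeff = 1 / 600,
                           disintegrate_frac = 0.25,
                           disintegrate_prob = 0) {
  stopifnot(length(well_id) == 1L)
  if (enzyme_conc < 0) stop("enzyme_conc must be >= 0")
  if (erode_coeff < 0) stop("erode_coeff must be >= 0")
  if (disintegrate_frac < 0 || disintegrate_frac > 1)
    stop("disintegrate_frac must lie in [0, 1]")
  if (disintegrate_prob < 0 || disintegrate_prob > 1)
    stop("disintegrate_prob must lie in [0, 1]")
  structure(
    list(well_id = as.character(well_id), enzyme_conc = enzyme_conc,
         erode_coeff = erode_coeff, disintegrate_frac = disintegrate_frac,
         disintegrate_prob = disintegrate_prob),
    class = "well_condition"
  )
}

#' Geometry and release parameters of a hydrogel disc
#'
#' Defaults match the cast discs used on the chip: radius 2 mm, thickness
#' 1 mm, loaded with 7.5% w/v PVA (943 ug for this volume). The release model
#' splits the load into an early diffusive burst (fraction `burst_frac`,
#' time constant `burst_tau`) and a degradation-coupled remainder released in
#' proportion to the eroded cross-section area.
#'
#' @param radius0 Initial disc radius, mm (> 0).
#' @param thickness0 Disc thickness, mm (> 0); held constant during erosion.
#' @param density_scale Mass units per mm^3 (arbitrary but fixed scale).
#' @param pva_load Total releasable PVA, ug.
#' @param burst_frac Fraction of the load released by the burst term, \[0, 1\].
#' @param burst_tau Burst time constant, h (> 0).
#' @return A `disc_spec` object.
#' @export
disc_spec <- function(radius0 = 2, thickness0 = 1, density_scale = 1,
                      pva_load = 943, burst_frac = 0.3, burst_tau = 1) {
  if (radius0 <= 0) stop("radius0 must be > 0")
  if (thickness0 <= 0) stop("thickness0 must be > 0")
  if (burst_frac < 0 || burst_frac > 1) stop("burst_frac must lie in [0, 1]")
  if (burst_tau <= 0) stop("burst_tau must be > 0")
  structure(
    list(radius0 = radius0, thickness0 = thickness0,
         density_scale = density_scale, pva_load = pva_load,
         burst_frac = burst_frac, burst_tau = burst_tau),
    class = "disc_spec"
  )
}

#' Standard eight-well chip conditions
#'
#' Convenience constructor for the default study layout: the four enzyme
#' concentrations of the chip experiment (0, 50, 100, 200 ug/mL) with
#' `replicates` wells each. Disintegration is enabled only at the highest
#' concentration, where rapid, irregular break-up is observed.
#'
#' Replicate wells emulate biological variability through a lognormal jitter
#' of the erosion coefficient (`rate_cv`, coefficient of variation): two
#' discs under the same enzyme dose never degrade at exactly the same speed.
#' Set `rate_cv = 0` for idealized identical replicates.
#'
#' @param enzyme_conc Vector of enzyme concentrations, ug/mL.
#' @param replicates Wells per concentration.
#' @param disintegrate_prob Per-step disintegration probability applied to the
#'   highest concentration only.
#' @param erode_coeff Mean erosion coefficient (see [well_condition()]).
#' @param rate_cv Between-replicate coefficient of variation of the erosion
#'   coefficient (>= 0).
#' @param seed Integer seed for the replicate jitter.
#' @param ... Further arguments passed to [well_condition()].
#' @return List of `well_condition` objects.
#' @export
default_wells <- function(enzyme_conc = c(0, 50, 100, 200), replicates = 2,
                          disintegrate_prob = 0, erode_coeff = 1 / 600,
                          rate_cv = 0, seed = 1L, ...) {
  if (rate_cv < 0) stop("rate_cv must be >= 0")
  conc <- rep(enzyme_conc, each = replicates)
  ids <- sprintf("W%d", seq_along(conc))
  mult <- rep(1, length(conc))
  if (rate_cv > 0) {
    sdlog <- sqrt(log(1 + rate_cv^2))
    mult <- withr::with_seed(as.integer(seed),
      stats::rlnorm(length(conc), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  lapply(seq_along(conc), function(i) {
    p <- if (conc[i] == max(conc) && max(conc) > 0) disintegrate_prob else 0
    well_condition(ids[i], conc[i], erode_coeff = erode_coeff * mult[i],
                   disintegrate_prob = p, ...)
  })
}

#' Simulate surface-erosion kinetics for a set of wells
#'
#' Radial surface-erosion model: each disc's radius decreases linearly at
#' `erode_coeff * enzyme_conc` mm/h while its thickness stays constant
#' (erosion in the chip acts on the rim, not the faces), so
#' `mass(t) = pi * r(t)^2 * thickness0 * density_scale`. Once the remaining
#' area fraction falls below a well's `disintegrate_frac`, an abrupt
#' disintegration event may fire with probability `disintegrate_prob` per
#' step; after the event the radius is 0 at all later times. Cumulative PVA
#' release is `pva_load * (burst_frac * (1 - exp(-t / burst_tau)) +
#' (1 - burst_frac) * (1 - r(t)^2 / radius0^2))`: an early diffusive burst
#' plus a degradation-coupled term. All randomness flows from `seed`.
#'
#' @param wells List of [well_condition()] objects.
#' @param disc A [disc_spec()].
#' @param duration Total simulated time, h (> 0).
#' @param step Time step, h (> 0).
#' @param seed Integer seed; the run is deterministic given it.
#' @return A `sim_truth` object: list with `times` (h), matrices
#'   `radius` (mm), `area_mm2`, `mass`, `cum_pva` (ug), `cum_gel`
#'   (time x well, columns named by well id), named vectors `t_complete` and
#'   `t_disintegrate` (h, `NA` where the event never occurs), plus the inputs.
#' @examples
#' tr <- simulate_kinetics(list(well_condition("A", 100)), disc_spec(),
#'                         duration = 20, step = 0.5, seed = 1)
#' tr$t_complete
#' @export
simulate_kinetics <- function(wells, disc, duration, step, seed = 1L) {
  if (!is.list(wells) || !length(wells) ||
      !all(vapply(wells, inherits, logical(1), "well_condition")))
    stop("wells must be a non-empty list of well_condition objects")
  stopifnot(inherits(disc, "disc_spec"))
  if (duration <= 0) stop("duration must be > 0 (hours)")
  if (step <= 0) stop("step must be > 0 (hours)")

  times <- seq(0, duration, by = step)
  if (times[length(times)] < duration) times <- c(times, duration)
  nt <- length(times)
  ids <- vapply(wells, `[[`, character(1), "well_id")
  if (anyDuplicated(ids)) stop("well ids must be unique")

  r0 <- disc$radius0
  radius <- matrix(0, nt, length(wells), dimnames = list(NULL, ids))
  t_dis <- stats::setNames(rep(NA_real_, length(wells)), ids)

  withr::with_seed(as.integer(seed), {
    for (w in seq_along(wells)) {
      wc <- wells[[w]]
      r <- pmax(0, r0 - wc$erode_coeff * wc$enzyme_conc * times)
      if (wc$disintegrate_prob > 0) {
        for (k in seq_len(nt)) {
          frac <- (r[k] / r0)^2
          if (r[k] > 0 && frac < wc$disintegrate_frac) {
            if (stats::runif(1) < wc$disintegrate_prob) {
              r[k:nt] <- 0
              t_dis[w] <- times[k]
              break
            }
          }
        }
      }
      radius[, w] <- r
    }
  })

  area <- pi * radius^2
  mass <- area * disc$thickness0 * disc$density_scale
  frac_remaining <- (radius / r0)^2
  cum_pva <- disc$pva_load *
    (disc$burst_frac * (1 - exp(-times / disc$burst_tau)) +
       (1 - disc$burst_frac) * (1 - frac_remaining))
  cum_gel <- sweep(-mass, 2, mass[1, ], `+`)
  t_complete <- apply(radius, 2, function(r) {
    i <- which(r == 0)
    if (length(i)) times[i[1]] else NA_real_
  })

  structure(
    list(times = times, radius = radius, area_mm2 = area, mass = mass,
         cum_pva = cum_pva, cum_gel = cum_gel,
         t_complete = t_complete, t_disintegrate = t_dis,
         wells = wells, disc = disc, seed = as.integer(seed)),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d wells, %d timepoints over %.3g h (seed %d)\n",
              ncol(x$radius), length(x$times), max(x$times), x$seed))
  done <- sum(!is.na(x$t_complete))
  cat(sprintf("  completed: %d/%d wells; disintegrated: %d\n",
              done, ncol(x$radius), sum(!is.na(x$t_disintegrate))))
  invisible(x)
}

#' Rendering configuration for synthetic time-lapse frames
#'
#' Colors emulate the chip as imaged: discs stained with red food dye
#' (saturated red), flow medium also dye-tinted (pale red, low saturation so
#' an HSV gate can separate it from gel), and the chip body a dark gray.
#'
#' @param px_per_mm Spatial scale, pixels per mm (> 0).
#' @param frame_interval Time between frames, minutes (> 0).
#' @param image_size `c(width, height)` in pixels, or `NULL` to size the
#'   image from the well layout at render time.
#' @param disc_color,media_color,background_color RGB triples, 0-255.
#' @param noise_sd Additive Gaussian pixel noise sd, 8-bit intensity units.
#' @param debris_rate Expected number of debris specks per frame (Poisson).
#' @param debris_size_px Maximum pixels per debris speck.
#' @param seed Integer seed for noise and debris.
#' @return A `render_config` object.
#' @export
render_config <- function(px_per_mm = 15, frame_interval = 1,
                          image_size = NULL,
                          disc_color = c(200, 30, 40),
                          media_color = c(230, 170, 175),
                          background_color = c(60, 60, 60),
                          noise_sd = 5, debris_rate = 1,
                          debris_size_px = 20, seed = 1L) {
  if (px_per_mm <= 0) stop("px_per_mm must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0 (minutes)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (debris_rate < 0) stop("debris_rate must be >= 0")
  chk_col <- function(x) length(x) == 3 && all(x >= 0 & x <= 255)
  if (!chk_col(disc_color) || !chk_col(media_color) || !chk_col(background_color))
    stop("colors must be RGB triples in [0, 255]")
  structure(
    list(px_per_mm = px_per_mm, frame_interval = frame_interval,
         image_size = image_size, disc_color = disc_color,
         media_color = media_color, background_color = background_color,
         noise_sd = noise_sd, debris_rate = debris_rate,
         debris_size_px = debris_size_px, seed = as.integer(seed)),
    class = "render_config"
  )
}

# Rasterization rule shared with the analysis oracle: a pixel belongs to a
# circle iff its center (integer coordinates (col, row)) lies within it.
in_circle <- function(nr, nc, cx, cy, r) {
  dx2 <- (seq_len(nc) - cx)^2
  dy2 <- (seq_len(nr) - cy)^2
  outer(dy2, dx2, `+`) <= r^2
}

blank_frame <- function(nr, nc, color) {
  px <- array(0L, dim = c(nr, nc, 3L))
  for (ch in 1:3) px[, , ch] <- as.integer(color[ch])
  px
}

paint_circle <- function(px, cx, cy, r, color) {
  sel <- in_circle(dim(px)[1], dim(px)[2], cx, cy, r)
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[sel] <- as.integer(color[ch])
    px[, , ch] <- plane
  }
  px
}

# Compact blob of <= n_px pixels around (cx, cy): nearest pixel centers first.
debris_offsets <- function(n_px) {
  rmax <- ceiling(sqrt(n_px)) + 1
  g <- expand.grid(dx = -rmax:rmax, dy = -rmax:rmax)
  g <- g[order(g$dx^2 + g$dy^2, abs(g$dx), abs(g$dy)), ]
  g[seq_len(min(n_px, nrow(g))), ]
}

#' Render a simulated run into time-lapse frames
#'
#' Draws, for every simulated timepoint, the chip background, each well's
#' medium-filled circle and (while alive) its disc as a filled circle of the
#' true radius, then adds Poisson-count debris specks at random non-well
#' locations and clipped additive Gaussian noise. Deterministic given
#' `cfg$seed`. Either returns the frames in memory or streams them to `dir`
#' as 8-bit RGB PNGs with a `manifest.csv` (`filename,time_min`).
#'
#' The kinetics grid and the camera cadence are decoupled: a frame is
#' emitted at every simulated time that falls on a multiple of
#' `cfg$frame_interval` (the kinetics step is typically finer, so ground
#' truth is known more precisely than the camera samples it, as in a real
#' experiment).
#'
#' @param truth A `sim_truth` from [simulate_kinetics()].
#' @param layout A [well_layout()]; one well per truth column, matched by id.
#' @param cfg A [render_config()].
#' @param dir Output directory; if `NULL`, frames are returned in memory.
#' @return Invisibly, a list with `manifest` (data.frame `filename`,
#'   `time_min`) and `frames` (list of `frame_image`, or `NULL` when written
#'   to `dir`).
#' @export
render_frames <- function(truth, layout, cfg = render_config(), dir = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(layout, "well_layout"),
            inherits(cfg, "render_config"))
  ids <- colnames(truth$radius)
  if (!all(ids %in% layout$wells$well_id))
    stop("layout is missing wells: ",
         paste(setdiff(ids, layout$wells$well_id), collapse = ", "))
  wl <- layout$wells[match(ids, layout$wells$well_id), ]

  size <- cfg$image_size
  if (is.null(size)) {
    size <- c(ceiling(max(wl$cx_px + wl$r_px)) + 10L,
              ceiling(max(wl$cy_px + wl$r_px)) + 10L)
  }
  nc <- as.integer(size[1]); nr <- as.integer(size[2])
  if (any(wl$cx_px - wl$r_px < 1 | wl$cx_px + wl$r_px > nc |
          wl$cy_px - wl$r_px < 1 | wl$cy_px + wl$r_px > nr))
    stop("well layout does not fit inside image_size at this scale")
  tm <- truth$times * 60
  phase <- tm / cfg$frame_interval
  sel <- which(abs(phase - round(phase)) < 1e-6)
  if (length(sel) < 1) stop("no simulated time falls on the frame interval")
  r_px <- truth$radius[sel, , drop = FALSE] * cfg$px_per_mm
  over <- r_px[1, ] > wl$r_px
  if (any(over))
    stop("disc radius exceeds well radius for well(s): ",
         paste(ids[over], collapse = ", "))

  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- length(sel)
  manifest <- data.frame(
    filename = sprintf("frame_%04d.png", seq_len(nt)),
    time_min = tm[sel]
  )
  keep <- is.null(dir)
  frames <- if (keep) vector("list", nt) else NULL

  base <- blank_frame(nr, nc, cfg$background_color)
  for (w in seq_len(nrow(wl)))
    base <- paint_circle(base, wl$cx_px[w], wl$cy_px[w], wl$r_px[w],
                         cfg$media_color)
  well_dist_ok <- function(x, y, margin) {
    all((x - wl$cx_px)^2 + (y - wl$cy_px)^2 > (wl$r_px + margin)^2)
  }

  withr::with_seed(cfg$seed, {
    for (k in seq_len(nt)) {
      px <- base
      for (w in seq_len(nrow(wl))) {
        if (r_px[k, w] > 0)
          px <- paint_circle(px, wl$cx_px[w], wl$cy_px[w], r_px[k, w],
                             cfg$disc_color)
      }
      n_debris <- stats::rpois(1, cfg$debris_rate)
      if (n_debris > 0 && cfg$debris_size_px > 0) {
        margin <- ceiling(sqrt(cfg$debris_size_px)) + 2
        for (d in seq_len(n_debris)) {
          for (try in 1:50) {
            cx <- sample.int(nc, 1); cy <- sample.int(nr, 1)
            if (well_dist_ok(cx, cy, margin)) break
            cx <- NA
          }
          if (is.na(cx)) next
          off <- debris_offsets(sample.int(cfg$debris_size_px, 1))
          xs <- cx + off$dx; ys <- cy + off$dy
          ok <- xs >= 1 & xs <= nc & ys >= 1 & ys <= nr
          idx <- cbind(ys[ok], xs[ok])
          for (ch in 1:3) {
            plane <- px[, , ch]
            plane[idx] <- as.integer(cfg$disc_color[ch])
            px[, , ch] <- plane
          }
        }
      }
      if (cfg$noise_sd > 0) {
        noise <- stats::rnorm(length(px), sd = cfg$noise_sd)
        px <- array(pmin(255L, pmax(0L, as.integer(round(px + noise)))),
                    dim = dim(px))
      }
      fr <- frame_image(px, time = manifest$time_min[k],
                        source_name = manifest$filename[k])
      if (keep) frames[[k]] <- fr
      else png::writePNG(fr$pixels / 255, file.path(dir, manifest$filename[k]))
    }
  })
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest, frames = frames))
}

#' Write ground-truth kinetics to CSV
#'
#' Long-format export with header
#' `well_id,time_h,radius_mm,area_mm2,mass,cum_pva_ug,cum_gel`.
#'
#' @param truth A `sim_truth`.
#' @param path Output CSV path.
#' @return The data.frame written, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  ids <- colnames(truth$radius)
  df <- do.call(rbind, lapply(seq_along(ids), function(w) {
    data.frame(well_id = ids[w], time_h = truth$times,
               radius_mm = truth$radius[, w], area_mm2 = truth$area_mm2[, w],
               mass = truth$mass[, w], cum_pva_ug = truth$cum_pva[, w],
               cum_gel = truth$cum_gel[, w])
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Simulate eluate absorbance readings from ground-truth release
#'
#' Emulates sampling the recirculating reservoir at the scheduled times and
#' reading each sample's 630-nm absorbance against the supplied standard
#' curve: concentration is cumulative released analyte divided by reservoir
#' volume (closed reservoir; the small sampled volume is neglected), mapped
#' through the curve and perturbed with Gaussian absorbance noise.
#'
#' @param truth A `sim_truth`.
#' @param curve A [fit_standard_curve()] result (or `standard_curve` list).
#' @param times Sampling schedule, h; the default is the experiment's
#'   0, 1, 2, 3 and 17 h.
#' @param analyte `"pva"` (released PVA, ug) or `"gel"` (degraded gel mass).
#' @param reservoir_vol Reservoir volume, mL.
#' @param noise_sd Absorbance noise sd.
#' @param seed Integer seed.
#' @return data.frame `well_id,time_h,absorbance`.
#' @export
simulate_eluates <- function(truth, curve, times = c(0, 1, 2, 3, 17),
                             analyte = c("pva", "gel"), reservoir_vol = 20,
                             noise_sd = 0.005, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  analyte <- match.arg(analyte)
  if (reservoir_vol <= 0) stop("reservoir_vol must be > 0 (mL)")
  if (max(times) > max(truth$times))
    stop("sampling times extend beyond the simulated duration")
  released <- if (analyte == "pva") truth$cum_pva else truth$cum_gel
  ids <- colnames(released)
  df <- do.call(rbind, lapply(seq_along(ids), function(w) {
    cum <- stats::approx(truth$times, released[, w], xout = times)$y
    data.frame(well_id = ids[w], time_h = times,
               conc = cum / reservoir_vol)
  }))
  withr::with_seed(as.integer(seed), {
    df$absorbance <- curve$slope * df$conc + curve$intercept +
      stats::rnorm(nrow(df), sd = noise_sd)
  })
  df[c("well_id", "time_h", "absorbance")]
}
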