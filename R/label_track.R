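#' Group mask pixels into 8-connected regions
#'
#' Two foreground pixels share a label iff they are connected under
#' 8-connectivity (edge or corner adjacency). Labels are assigned in
#' raster-scan order of first encounter, so the labeling is deterministic:
#' region 1 is the first region met scanning rows top-to-bottom, columns
#' left-to-right.
#'
#' @param mask A `binary_mask` or plain 0/1 integer matrix.
#' @return A `region_labeling`: list with `label_map` (integer matrix,
#'   0 = background) and `regions`, a data.frame sorted by label with columns
#'   `label`, `pixel_count`, `centroid_x`, `centroid_y` (fractional pixel
#'   coordinates: x = column, y = row), `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
label_regions <- function(mask) {
  m <- unclass(mask)
  lab <- cc_label_8(matrix(as.integer(m), nrow(m), ncol(m)))
  k <- max(lab)
  if (k == 0) {
    regions <- data.frame(label = integer(0), pixel_count = integer(0),
                          centroid_x = numeric(0), centroid_y = numeric(0),
                          xmin = integer(0), xmax = integer(0),
                          ymin = integer(0), ymax = integer(0))
  } else {
    idx <- which(lab > 0)
    l <- lab[idx]
    ys <- ((idx - 1) %% nrow(lab)) + 1
    xs <- ((idx - 1) %/% nrow(lab)) + 1
    regions <- data.frame(
      label = seq_len(k),
      pixel_count = as.integer(tabulate(l, nbins = k)),
      centroid_x = as.vector(tapply(xs, l, mean)),
      centroid_y = as.vector(tapply(ys, l, mean)),
      xmin = as.integer(tapply(xs, l, min)),
      xmax = as.integer(tapply(xs, l, max)),
      ymin = as.integer(tapply(ys, l, min)),
      ymax = as.integer(tapply(ys, l, max))
    )
  }
  structure(list(label_map = lab, regions = regions),
            class = "region_labeling")
}

#' @export
print.region_labeling <- function(x, ...) {
  cat(sprintf("<region_labeling> %d region(s), %d foreground px\n",
              nrow(x$regions), sum(x$regions$pixel_count)))
  invisible(x)
}

#' Define the chip's well geometry in pixel coordinates
#'
#' @param wells data.frame with columns `well_id`, `cx_px`, `cy_px`, `r_px`
#'   (center coordinates and radius in pixels). Well circles must be pairwise
#'   disjoint.
#' @return A `well_layout` object.
#' @export
well_layout <- function(wells) {
  need <- c("well_id", "cx_px", "cy_px", "r_px")
  if (!is.data.frame(wells) || !all(need %in% names(wells)))
    stop("wells must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(wells) < 1) stop("at least one well is required")
  if (anyDuplicated(wells$well_id)) stop("well ids must be unique")
  if (any(wells$r_px <= 0)) stop("well radii must be > 0")
  n <- nrow(wells)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      d <- sqrt((wells$cx_px[i] - wells$cx_px[j])^2 +
                (wells$cy_px[i] - wells$cy_px[j])^2)
      if (d < wells$r_px[i] + wells$r_px[j])
        stop("well circles overlap: ", wells$well_id[i], " and ",
             wells$well_id[j])
    }
  }
  wells$well_id <- as.character(wells$well_id)
  structure(list(wells = wells, n_wells = n), class = "well_layout")
}

#' Lay wells out in a single row (the 8-chamber chip pattern)
#'
#' @param well_ids Well identifiers, left to right.
#' @param well_radius_mm Chamber radius in mm (chip default 5 mm).
#' @param px_per_mm Pixels per mm; must match the render scale.
#' @param gap_px Pixel gap between adjacent well circles and to the borders.
#' @return A [well_layout()].
#' @export
row_layout <- function(well_ids, well_radius_mm = 5, px_per_mm = 15,
                       gap_px = 10) {
  r <- well_radius_mm * px_per_mm
  n <- length(well_ids)
  cx <- gap_px + r + (seq_len(n) - 1) * (2 * r + gap_px)
  well_layout(data.frame(well_id = well_ids, cx_px = cx,
                         cy_px = gap_px + r, r_px = r))
}

#' Read/write a well layout as CSV (`well_id,cx_px,cy_px,r_px`)
#'
#' @param path CSV path.
#' @return `read_layout_csv`: a [well_layout()]. `write_layout_csv`: `path`,
#'   invisibly.
#' @export
read_layout_csv <- function(path) well_layout(utils::read.csv(path))

#' @rdname read_layout_csv
#' @param layout A [well_layout()].
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(layout$wells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign labeled regions to wells and total their pixel areas
#'
#' Each region goes to the well whose circle contains its centroid; regions
#' whose centroid falls in no well are treated as channel debris and
#' discarded. A well's area is the sum over all its assigned regions, so a
#' disc fragmenting during disintegration still contributes its full visible
#' area. Wells with no region get area 0.
#'
#' @param labeling A [label_regions()] result.
#' @param layout A [well_layout()].
#' @return Named numeric vector of pixel areas, one entry per layout well.
#' @export
assign_to_wells <- function(labeling, layout) {
  stopifnot(inherits(labeling, "region_labeling"),
            inherits(layout, "well_layout"))
  wl <- layout$wells
  areas <- stats::setNames(numeric(nrow(wl)), wl$well_id)
  reg <- labeling$regions
  if (nrow(reg) == 0) return(areas)
  for (i in seq_len(nrow(reg))) {
    d2 <- (reg$centroid_x[i] - wl$cx_px)^2 + (reg$centroid_y[i] - wl$cy_px)^2
    hit <- which(d2 <= wl$r_px^2)
    if (length(hit))
      areas[hit[1]] <- areas[hit[1]] + reg$pixel_count[i]
  }
  areas
}

#' Build per-well area traces from a frame sequence's well areas
#'
#' Normalizes each well's pixel area to its first-frame value (the initial
#' surface area) and finds the completion time: the first time with zero area
#' after which the area stays zero. A disc that "reappears" (area > 0 after a
#' zero) keeps `complete_at = NA` and raises a warning, since that pattern
#' indicates a segmentation anomaly rather than regrowth.
#'
#' @param times_h Frame times in hours; strictly increasing, length >= 2.
#' @param areas Numeric matrix, one row per frame, one named column per well
#'   (as from stacking [assign_to_wells()] results).
#' @return List of `disc_trace` objects: each has `well_id`, `times` (h),
#'   `area_px`, `area_pct` (100 at time 0), `complete_at` (h, `NA` if never).
#' @export
build_traces <- function(times_h, areas) {
  areas <- as.matrix(areas)
  if (length(times_h) < 2) stop("at least two frames are required")
  if (any(diff(times_h) <= 0)) stop("frame times must be strictly increasing")
  if (nrow(areas) != length(times_h))
    stop("areas must have one row per frame time")
  if (is.null(colnames(areas))) stop("areas columns must be named by well")
  zero0 <- colnames(areas)[areas[1, ] <= 0]
  if (length(zero0))
    stop("zero initial area for well(s) ", paste(zero0, collapse = ", "),
         ": cannot normalize to the initial surface area")
  lapply(colnames(areas), function(id) {
    a <- areas[, id]
    zero <- which(a == 0)
    complete_at <- NA_real_
    if (length(zero)) {
      first <- zero[1]
      if (all(a[first:length(a)] == 0)) {
        complete_at <- times_h[first]
      } else {
        warning("well ", id, ": area reappears after reaching zero; ",
                "completion left unset (anomaly)")
      }
    }
    structure(list(well_id = id, times = times_h, area_px = a,
                   area_pct = 100 * a / a[1], complete_at = complete_at),
              class = "disc_trace")
  })
}

#' @export
print.disc_trace <- function(x, ...) {
  cat(sprintf("<disc_trace> well %s: %d frames over %.3g h, final %.1f%%%s\n",
              x$well_id, length(x$times), max(x$times),
              x$area_pct[length(x$area_pct)],
              if (is.na(x$complete_at)) ""
              else sprintf(", complete at %.3g h", x$complete_at)))
  invisible(x)
}

#' Tidy data.frame view of disc traces
#'
#' @param traces List of `disc_trace` objects.
#' @return data.frame `well_id,time_h,area_px,area_pct`.
#' @export
traces_to_df <- function(traces) {
  do.call(rbind, lapply(traces, function(tr)
    data.frame(well_id = tr$well_id, time_h = tr$times,
               area_px = tr$area_px, area_pct = tr$area_pct)))
}

#' Run the per-frame analysis chain over a frame sequence
#'
#' For each frame: color-gate ([make_mask()]), suppress debris-sized regions
#' ([clean_mask()]), group pixels ([label_regions()]) and assign regions to
#' wells ([assign_to_wells()]); then assemble per-well traces
#' ([build_traces()]). Frames can be given in memory or as a rendered
#' directory with a manifest, in which case they are streamed one at a time.
#'
#' @param frames List of [frame_image()] objects, or a directory path
#'   containing frames plus `manifest.csv`.
#' @param layout A [well_layout()].
#' @param gate A [color_gate()].
#' @param min_region_px Debris filter threshold, px (see [clean_mask()]).
#' @return List of `disc_trace` objects.
#' @export
trace_frames <- function(frames, layout, gate = color_gate(),
                         min_region_px = 5) {
  if (is.character(frames)) {
    dir <- frames
    man <- utils::read.csv(file.path(dir, "manifest.csv"))
    times_h <- man$time_min / 60
    rows <- lapply(seq_len(nrow(man)), function(i) {
      fr <- read_frame(file.path(dir, man$filename[i]),
                       time = man$time_min[i])
      frame_well_areas(fr, layout, gate, min_region_px)
    })
    areas <- do.call(rbind, rows)
  } else {
    times_h <- vapply(frames, `[[`, numeric(1), "time") / 60
    areas <- do.call(rbind, lapply(frames, frame_well_areas,
                                   layout = layout, gate = gate,
                                   min_region_px = min_region_px))
  }
  colnames(areas) <- layout$wells$well_id
  build_traces(times_h, areas)
}

frame_well_areas <- function(frame, layout, gate, min_region_px) {
  mask <- clean_mask(make_mask(frame, gate), min_region_px)
  assign_to_wells(label_regions(mask), layout)
}
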