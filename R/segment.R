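#' Construct a timestamped RGB frame
#'
#' @param pixels H x W x 3 array of 8-bit channel values (0-255).
#' @param time Acquisition time, minutes since experiment start (>= 0).
#' @param source_name Text label, typically the source filename.
#' @return A `frame_image` object.
#' @export
frame_image <- function(pixels, time = 0, source_name = "") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (any(pixels < 0) || any(pixels > 255))
    stop("channel values must lie in [0, 255]")
  if (time < 0) stop("time must be >= 0 (minutes)")
  structure(list(pixels = pixels, time = time,
                 source_name = as.character(source_name)),
            class = "frame_image")
}

#' @export
print.frame_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<frame_image> %dx%d px, t = %g min (%s)\n",
              d[2], d[1], x$time, x$source_name))
  invisible(x)
}

#' Read a frame from a PNG or TIFF file
#'
#' @param path Image path (`.png`, `.tif`/`.tiff`).
#' @param time Acquisition time in minutes.
#' @return A [frame_image()].
#' @export
read_frame <- function(path, time = 0) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF frames requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported frame format '.", ext, "' (PNG or TIFF expected)")
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  frame_image(array(as.integer(round(img * 255)), dim = dim(img)),
              time = time, source_name = basename(path))
}

#' Read a rendered frame sequence via its manifest
#'
#' @param dir Directory holding frames and a `manifest.csv`
#'   (`filename,time_min`).
#' @return List of [frame_image()] in manifest order.
#' @export
read_frame_sequence <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(man)), function(i)
    read_frame(file.path(dir, man$filename[i]), time = man$time_min[i]))
}

#' HSV color gate for stained-gel pixels
#'
#' The stained gel is identified in HSV space: hue must fall in a window
#' (which may wrap through 0 degrees, as red does) and saturation and value
#' must clear floor thresholds. The saturation floor is what separates the
#' strongly stained gel from the dye-tinted flow medium, which shares the red
#' hue but at much lower saturation.
#'
#' @param hue_lo,hue_hi Hue window in degrees, \[0, 360); `hue_lo > hue_hi`
#'   means the window wraps through 0. Defaults 340-20 degrees (red).
#' @param sat_min Minimum saturation, \[0, 1\].
#' @param val_min Minimum value (brightness), \[0, 1\].
#' @return A `color_gate` object.
#' @export
color_gate <- function(hue_lo = 340, hue_hi = 20,
                       sat_min = 0.35, val_min = 0.15) {
  if (sat_min < 0 || sat_min > 1 || val_min < 0 || val_min > 1)
    stop("sat_min and val_min must lie in [0, 1]")
  if (hue_lo < 0 || hue_lo >= 360 || hue_hi < 0 || hue_hi >= 360)
    stop("hue bounds must lie in [0, 360)")
  structure(list(hue_lo = hue_lo, hue_hi = hue_hi,
                 sat_min = sat_min, val_min = val_min),
            class = "color_gate")
}

#' Threshold a frame into a binary stained-gel mask
#'
#' Converts every pixel to HSV (standard hexcone formulas via
#' [grDevices::rgb2hsv()]; achromatic pixels get hue 0 but are rejected by
#' any positive saturation floor) and sets the mask to 1 where the hue lies
#' in the gate window (with wraparound) and saturation and value clear their
#' floors. Pure function of its inputs.
#'
#' @param frame A [frame_image()].
#' @param gate A [color_gate()].
#' @return A `binary_mask`: integer H x W matrix over \{0, 1\} carrying the
#'   frame's `time` and `source_name` as attributes.
#' @export
make_mask <- function(frame, gate = color_gate()) {
  stopifnot(inherits(frame, "frame_image"), inherits(gate, "color_gate"))
  d <- dim(frame$pixels)
  hsv <- grDevices::rgb2hsv(
    r = as.vector(frame$pixels[, , 1]),
    g = as.vector(frame$pixels[, , 2]),
    b = as.vector(frame$pixels[, , 3]),
    maxColorValue = 255
  )
  hue <- hsv[1, ] * 360
  in_hue <- if (gate$hue_lo <= gate$hue_hi)
    hue >= gate$hue_lo & hue <= gate$hue_hi
  else
    hue >= gate$hue_lo | hue <= gate$hue_hi
  keep <- in_hue & hsv[2, ] >= gate$sat_min & hsv[3, ] >= gate$val_min
  mask <- matrix(as.integer(keep), d[1], d[2])
  attr(mask, "time") <- frame$time
  attr(mask, "source_name") <- frame$source_name
  class(mask) <- c("binary_mask", class(mask))
  mask
}

#' Remove small connected regions from a mask
#'
#' Debris suppression: every 8-connected region of foreground pixels smaller
#' than `min_region_px` is zeroed; larger regions pass unchanged, so the
#' output is a pure subset of the input and the operation is idempotent.
#'
#' @param mask A `binary_mask` (or plain 0/1 integer matrix).
#' @param min_region_px Minimum surviving region size in pixels (>= 0).
#' @return Cleaned `binary_mask` with the input's attributes.
#' @export
clean_mask <- function(mask, min_region_px = 5) {
  if (min_region_px < 0) stop("min_region_px must be >= 0")
  if (min_region_px == 0) return(mask)
  m <- unclass(mask)
  lab <- cc_label_8(matrix(as.integer(m), nrow(m), ncol(m)))
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes < min_region_px)
    if (length(drop)) m[matrix(lab %in% drop, nrow(m))] <- 0L
  }
  attributes(m) <- attributes(mask)
  m
}

#' Write a mask as an 8-bit PNG (0/255) for visual inspection
#'
#' @param mask A `binary_mask`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(unclass(mask)), nrow(mask)), path)
  invisible(path)
}
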