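#' Fit a linear absorbance standard curve
#'
#' Ordinary least-squares fit of absorbance on concentration for a set of
#' standards of known concentration, as used to calibrate the 630-nm
#' colorimetric PVA assay. The valid range is the span of the standard
#' concentrations; inversions outside it are flagged as extrapolations.
#'
#' @param conc Standard concentrations, ug/mL (>= 3 values, >= 2 distinct),
#'   or a data.frame with columns `conc_ug_ml` and `absorbance`.
#' @param absorbance Measured absorbances (same length as `conc`).
#' @return A `standard_curve`: list with `slope` (AU per ug/mL), `intercept`
#'   (AU, the blank), `r_squared`, `valid_range` (`c(min, max)` ug/mL) and
#'   `n`.
#' @export
fit_standard_curve <- function(conc, absorbance = NULL) {
  if (is.data.frame(conc)) {
    absorbance <- conc$absorbance
    conc <- conc$conc_ug_ml
  }
  if (length(conc) != length(absorbance))
    stop("conc and absorbance must have equal length")
  if (length(conc) < 2) stop("at least two standards are required")
  if (length(unique(conc)) < 2)
    stop("all standard concentrations are identical: degenerate design")
  fit <- stats::lm(absorbance ~ conc)
  co <- unname(stats::coef(fit))
  r2 <- if (stats::var(absorbance) == 0) 1
        else unname(stats::cor(conc, absorbance))^2
  structure(
    list(slope = co[2], intercept = co[1], r_squared = r2,
         valid_range = range(conc), n = length(conc)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> A = %.4g * C + %.4g (R^2 = %.4f, %d standards, %g-%g ug/mL)\n",
    x$slope, x$intercept, x$r_squared, x$n, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Predicted absorbance at given concentrations
#'
#' @param object A `standard_curve`.
#' @param conc Concentrations, ug/mL.
#' @param ... Unused.
#' @return Numeric vector of absorbances.
#' @export
predict.standard_curve <- function(object, conc, ...) {
  object$slope * conc + object$intercept
}

#' Invert a standard curve: absorbance to concentration
#'
#' `conc = (absorbance - intercept) / slope`, clamped below at 0. The
#' extrapolation flag marks readings whose unclamped concentration falls
#' outside the curve's valid range.
#'
#' @param curve A [fit_standard_curve()] result with nonzero slope.
#' @param absorbance Absorbance value(s).
#' @return data.frame `conc_ug_ml,extrapolated` with one row per reading.
#' @export
invert_curve <- function(curve, absorbance) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0)
    stop("standard curve slope is zero: concentration is not identifiable")
  raw <- (absorbance - curve$intercept) / curve$slope
  data.frame(
    conc_ug_ml = pmax(0, raw),
    extrapolated = raw < curve$valid_range[1] | raw > curve$valid_range[2]
  )
}

#' Convert eluate absorbances into a cumulative release profile
#'
#' Concentrations come from [invert_curve()]; cumulative released mass is
#' concentration times reservoir volume, the mass balance of a closed
#' recirculating reservoir (inlet and outlet both connect to the source
#' vial; the small sampled volumes are neglected). Monotonicity is not
#' enforced — measurement noise can make the series dip — but a warning is
#' raised when it does.
#'
#' @param eluates data.frame `well_id,time_h,absorbance`, times strictly
#'   increasing within each well.
#' @param curve A [fit_standard_curve()] result.
#' @param reservoir_vol Reservoir volume, mL (> 0).
#' @return data.frame `well_id,time_h,conc_ug_ml,cum_mass_ug,extrapolated`.
#' @export
release_profile <- function(eluates, curve, reservoir_vol = 20) {
  need <- c("well_id", "time_h", "absorbance")
  if (!is.data.frame(eluates) || !all(need %in% names(eluates)))
    stop("eluates must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (reservoir_vol <= 0) stop("reservoir_vol must be > 0 (mL)")
  out <- do.call(rbind, lapply(split(eluates, eluates$well_id), function(d) {
    d <- d[order(d$time_h), ]
    if (any(diff(d$time_h) <= 0))
      stop("sampling times must be strictly increasing (well ",
           d$well_id[1], ")")
    inv <- invert_curve(curve, d$absorbance)
    cum <- inv$conc_ug_ml * reservoir_vol
    if (any(diff(cum) < 0))
      warning("well ", d$well_id[1],
              ": non-monotone cumulative release (measurement noise?)")
    data.frame(well_id = d$well_id, time_h = d$time_h,
               conc_ug_ml = inv$conc_ug_ml, cum_mass_ug = cum,
               extrapolated = inv$extrapolated)
  }))
  rownames(out) <- NULL
  out
}
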