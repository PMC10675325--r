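#' Endpoint degradation pseudorate of a disc trace
#'
#' The pseudorate assumes linear degradation and uses only the endpoints of
#' the trace: if the disc reaches complete degradation, the rate is
#' `100 / complete_at` percent of initial area per hour; otherwise it is the
#' percent of initial area lost between the first and the last frame divided
#' by the elapsed time, floored at 0 if the area grew.
#'
#' @param trace A `disc_trace` from [build_traces()].
#' @return A `rate_estimate`: list with `well_id`, `rate` (%/h), `basis`
#'   (named vector `t_start`, `t_end`, `A_start`, `A_end` in px) and
#'   `complete` (logical).
#' @examples
#' tr <- build_traces(c(0, 5, 10, 15),
#'                    cbind(A = c(1000, 500, 0, 0)))[[1]]
#' pseudorate(tr)$rate  # 100 / 10 = 10 %/h
#' @export
pseudorate <- function(trace) {
  stopifnot(inherits(trace, "disc_trace"))
  n <- length(trace$times)
  if (n < 2) stop("pseudorate needs at least two frames (no elapsed time)")
  a0 <- trace$area_px[1]
  if (a0 <= 0) stop("initial area must be > 0")
  if (!is.na(trace$complete_at)) {
    rate <- 100 / trace$complete_at
    basis <- c(t_start = trace$times[1], t_end = trace$complete_at,
               A_start = a0, A_end = 0)
    complete <- TRUE
  } else {
    tt <- trace$times[n]
    rate <- max(0, 100 * (a0 - trace$area_px[n]) / a0 / tt)
    basis <- c(t_start = trace$times[1], t_end = tt,
               A_start = a0, A_end = trace$area_px[n])
    complete <- FALSE
  }
  structure(list(well_id = trace$well_id, rate = rate, basis = basis,
                 complete = complete),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> well %s: %.3g %%/h (%s)\n", x$well_id, x$rate,
              if (x$complete) sprintf("complete at %.3g h", x$basis["t_end"])
              else "incomplete over the run"))
  invisible(x)
}

#' Regression-slope degradation rate (alternative estimator)
#'
#' Least-squares slope of `area_pct` against time, sign-flipped so loss is
#' positive, floored at 0. This is not the endpoint pseudorate used for
#' reporting; it is offered as a smoother alternative when traces are noisy.
#'
#' @param trace A `disc_trace`.
#' @return Rate in %/h (numeric scalar).
#' @export
regression_rate <- function(trace) {
  stopifnot(inherits(trace, "disc_trace"))
  if (length(trace$times) < 2) stop("need at least two frames")
  max(0, -unname(stats::coef(stats::lm(trace$area_pct ~ trace$times))[2]))
}

#' Flag abrupt disintegration events in a trace
#'
#' An event is recorded at frame i when the single-frame area drop, as a
#' fraction of the *initial* area, reaches `drop_frac`:
#' `(A(t[i-1]) - A(t[i])) / A(0) >= drop_frac`.
#'
#' @param trace A `disc_trace`.
#' @param drop_frac Threshold fraction in (0, 1\]; default 0.3.
#' @return data.frame `time_h,drop_frac_of_initial`, sorted by time
#'   (zero rows when nothing is flagged).
#' @export
flag_disintegration <- function(trace, drop_frac = 0.3) {
  stopifnot(inherits(trace, "disc_trace"))
  if (drop_frac <= 0 || drop_frac > 1) stop("drop_frac must lie in (0, 1]")
  a0 <- trace$area_px[1]
  drops <- -diff(trace$area_px) / a0
  hit <- which(drops >= drop_frac) + 1L
  data.frame(time_h = trace$times[hit],
             drop_frac_of_initial = drops[hit - 1L])
}

#' Summarize rates and events over a set of traces
#'
#' @param traces List of `disc_trace` objects.
#' @param drop_frac Disintegration-flag threshold (see
#'   [flag_disintegration()]).
#' @return data.frame
#'   `well_id,rate_pct_per_h,complete,t_complete_h,n_events`.
#' @export
rate_table <- function(traces, drop_frac = 0.3) {
  do.call(rbind, lapply(traces, function(tr) {
    est <- pseudorate(tr)
    ev <- flag_disintegration(tr, drop_frac)
    data.frame(well_id = tr$well_id, rate_pct_per_h = est$rate,
               complete = est$complete,
               t_complete_h = if (est$complete) tr$complete_at else NA_real_,
               n_events = nrow(ev))
  }))
}
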