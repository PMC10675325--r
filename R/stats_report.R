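#' Pearson correlation between a visual measure and a reference measure
#'
#' Thin, validated wrapper around [stats::cor.test()] for the method
#' validation: visual disc area against dry mass, or percent degraded against
#' eluate gel. Requires at least 3 complete pairs and nonzero variance in
#' both margins; the p-value is the usual two-sided t-transform with n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (the paired measurements).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("pairs must be complete (no missing values)")
  if (length(x) < 3) stop("at least 3 pairs are required")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in one margin: correlation is undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Significance stars at the study's thresholds
#'
#' @param p P-value(s).
#' @return Character vector: `"**"` for p < 0.005, `"*"` for p < 0.05,
#'   `"ns"` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.005, "**", ifelse(p < 0.05, "*", "ns"))
}

#' Compare degradation rates across conditions (one-way ANOVA + Tukey HSD)
#'
#' Fixed-effects one-way ANOVA over condition groups followed by Tukey's
#' honest significant difference for all pairwise contrasts (studentized
#' range; the Tukey-Kramer adjustment applies automatically for unequal
#' group sizes). Significance stars use the study's thresholds (0.05, 0.005).
#'
#' @param values Replicate rate values, %/h.
#' @param group Condition label per value (coerced to factor); >= 2 groups
#'   with >= 2 replicates each.
#' @return A `group_comparison`: list with `anova_F`, `anova_p`, `pairwise`
#'   (data.frame `group_a,group_b,diff,p_adj,stars`) and `groups`
#'   (data.frame `group,n,mean,sd`).
#' @export
compare_groups <- function(values, group) {
  if (length(values) != length(group))
    stop("values and group must have equal length")
  group <- factor(group)
  n_per <- table(group)
  if (length(n_per) < 2) stop("at least 2 groups are required")
  if (any(n_per < 2))
    stop("every group needs >= 2 replicates (offending: ",
         paste(names(n_per)[n_per < 2], collapse = ", "), ")")
  if (stats::var(values) == 0)
    stop("all values are identical: ANOVA is undefined (zero variance)")
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pairwise <- data.frame(
    group_a = pairs[, 1], group_b = pairs[, 2],
    diff = unname(tk[, "diff"]), p_adj = unname(tk[, "p adj"]),
    stars = significance_stars(unname(tk[, "p adj"]))
  )
  groups <- data.frame(
    group = levels(group), n = as.integer(n_per),
    mean = as.vector(tapply(values, group, mean)),
    sd = as.vector(tapply(values, group, stats::sd))
  )
  structure(
    list(anova_F = tab[["F value"]][1], anova_p = tab[["Pr(>F)"]][1],
         pairwise = pairwise, groups = groups),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> one-way ANOVA: F = %.4g, p = %.3g %s\n",
              x$anova_F, x$anova_p, significance_stars(x$anova_p)))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

signif3 <- function(p) signif(p, 3)

#' Assemble the run report: figures, summary table and machine summary
#'
#' Emits per-well area-vs-time curves, a rate-vs-condition plot with Tukey
#' significance stars (when a condition column is present and testable),
#' cumulative-release curves, and a scatter with best-fit line and annotated
#' Pearson r for each paired validation. Alongside the figures it writes
#' `summary.csv` (the rate table) and `summary.json` (rates, correlations
#' and ANOVA results, p-values to 3 significant figures). Output is
#' deterministic given identical inputs.
#'
#' @param traces List of `disc_trace` objects.
#' @param rates Rate table from [rate_table()], optionally with an added
#'   `condition` column (e.g. enzyme concentration) for group comparison.
#' @param eluates Optional release profile from [release_profile()].
#' @param pairs Optional named list of paired validations; each element is a
#'   data.frame with columns `x`, `y` (and optionally `xlab`, `ylab`
#'   attributes).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
build_report <- function(traces, rates, eluates = NULL, pairs = NULL,
                         out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  df <- traces_to_df(traces)

  p1 <- ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$area_pct,
                                         color = .data$well_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Disc area (% of initial)",
                  color = "Well") +
    ggplot2::theme_minimal()
  save_plot(p1, file.path(out_dir, "area_vs_time.png"), width = 6, height = 4)

  summary <- list(rates = rates)

  cmp <- NULL
  if ("condition" %in% names(rates)) {
    tab <- table(rates$condition)
    if (length(tab) >= 2 && all(tab >= 2) &&
        stats::var(rates$rate_pct_per_h) > 0) {
      cmp <- compare_groups(rates$rate_pct_per_h, rates$condition)
      summary$anova <- list(F = cmp$anova_F, p = signif3(cmp$anova_p),
                            stars = significance_stars(cmp$anova_p))
      summary$tukey <- transform(cmp$pairwise, p_adj = signif3(p_adj))
    }
    p2 <- ggplot2::ggplot(rates,
            ggplot2::aes(factor(.data$condition), .data$rate_pct_per_h)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                            linewidth = 0.3) +
      ggplot2::labs(x = "Condition (enzyme, ug/mL)",
                    y = "Pseudorate (%/h)") +
      ggplot2::theme_minimal()
    save_plot(p2, file.path(out_dir, "rate_vs_condition.png"),
              width = 5, height = 4)
  }

  if (!is.null(eluates) && nrow(eluates) > 0) {
    p3 <- ggplot2::ggplot(eluates, ggplot2::aes(.data$time_h,
                                                .data$cum_mass_ug,
                                                color = .data$well_id)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "Time (h)", y = "Cumulative release (ug)",
                    color = "Well") +
      ggplot2::theme_minimal()
    save_plot(p3, file.path(out_dir, "release_curves.png"),
              width = 6, height = 4)
  }

  if (!is.null(pairs)) {
    summary$correlations <- list()
    for (nm in names(pairs)) {
      d <- pairs[[nm]]
      pr <- pearson_r(d$x, d$y)
      summary$correlations[[nm]] <-
        list(r = pr$r, p = signif3(pr$p), n = pr$n)
      p4 <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
        ggplot2::geom_point() +
        ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                             color = "red", linetype = "dashed") +
        ggplot2::annotate("text", x = min(d$x), y = max(d$y), hjust = 0,
                          label = sprintf("R = %.2f", pr$r)) +
        ggplot2::labs(x = attr(d, "xlab") %||% "x",
                      y = attr(d, "ylab") %||% "y", title = nm) +
        ggplot2::theme_minimal()
      save_plot(p4, file.path(out_dir, paste0("scatter_", nm, ".png")),
                width = 4.5, height = 4)
    }
  }

  utils::write.csv(rates, file.path(out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

save_plot <- function(p, path, width, height) {
  grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  on.exit(grDevices::dev.off())
  print(p)
}
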