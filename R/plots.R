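# All plot builders follow the same contract: construct a ggplot, write it to
# `path` when given (PNG or SVG by file extension), and return (invisibly) a
# list with the plot object and the numeric data behind every layer, so tests
# can check the plotted values without pixel inspection.

save_plot <- function(plot, path, width = 7, height = 5, dpi = 150) {
  if (is.null(path)) return(invisible(NULL))
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
                png = grDevices::png,
                svg = grDevices::svg,
                stop("unsupported image format: ", ext,
                     " (use .png or .svg)", call. = FALSE))
  if (ext == "png") {
    dev(path, width = width, height = height, units = "in", res = dpi)
  } else {
    dev(path, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}

#' Histogram with fitted mixture overlay
#'
#' Histogram of the marker with the fitted two-component mixture density
#' (weighted components and their sum) overlaid and an optional vertical
#' line at the chosen cutoff.
#'
#' @param dataset A [marker_dataset()] or numeric vector.
#' @param fit A [fit_mixture()] result.
#' @param cutoff Optional cutoff to mark; `NULL` omits the line.
#' @param path Optional output file (`.png` or `.svg`).
#' @param bins Number of histogram bins, default 30.
#' @return Invisibly, a list with `plot` (ggplot), `density` (the curve data
#'   from [mixture_density()]) and `cutoff`.
#' @export
plot_histogram_mixture <- function(dataset, fit, cutoff = NULL, path = NULL,
                                   bins = 30) {
  x <- if (inherits(dataset, "marker_dataset")) dataset$marker else dataset
  stopifnot(inherits(fit, "mixture_fit"))
  grid_x <- seq(min(x), max(x), length.out = 512)
  dens <- mixture_density(fit, grid_x)
  df <- data.frame(marker = x)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$marker)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = dens, ggplot2::aes(x = .data$x, y = .data$mixture),
                       colour = "red", linewidth = 1) +
    ggplot2::geom_line(data = dens, ggplot2::aes(x = .data$x, y = .data$component1),
                       colour = "red", linetype = "dashed") +
    ggplot2::geom_line(data = dens, ggplot2::aes(x = .data$x, y = .data$component2),
                       colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "marker", y = "density")
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = "dotted")
  }
  save_plot(p, path)
  invisible(list(plot = p, density = dens, cutoff = cutoff))
}

#' Overview plot of an effect size across all candidate cutoffs
#'
#' The per-cutoff effect size (odds ratio, hazard ratio, or restricted-mean
#' survival-time difference) with its confidence band, a vertical line at the
#' selected cutoff, and a rug of the observed marker values. Ratio effects
#' (OR/HR) are drawn on a log axis with a reference line at 1; the survival
#' difference is on a linear axis with a reference at 0.
#'
#' @param scan A [binary_scan()] (for `effect = "or"`) or [survival_scan()]
#'   (for `"hr"` / `"survdiff"`).
#' @param effect `"or"`, `"hr"` or `"survdiff"`.
#' @param selected_cutoff Optional cutoff to mark.
#' @param path Optional output file (`.png` or `.svg`).
#' @return Invisibly, a list with `plot` and `data` (columns `cutoff`,
#'   `estimate`, `low`, `high`, taken from the scan unchanged).
#' @export
plot_scan_overview <- function(scan, effect = c("or", "hr", "survdiff"),
                               selected_cutoff = NULL, path = NULL) {
  effect <- match.arg(effect)
  if (is.null(scan) || nrow(scan) == 0) stop("empty scan", call. = FALSE)
  cols <- switch(effect,
                 or = c("or", "or_low", "or_high"),
                 hr = c("hr", "hr_low", "hr_high"),
                 survdiff = c("rmst_diff", "rmst_diff_low", "rmst_diff_high"))
  if (!all(cols %in% names(scan))) {
    stop("scan does not carry effect ", sQuote(effect), call. = FALSE)
  }
  dat <- data.frame(cutoff = scan$cutoff,
                    estimate = scan[[cols[1]]],
                    low = scan[[cols[2]]],
                    high = scan[[cols[3]]])
  marker <- attr(scan, "marker")
  ratio <- effect %in% c("or", "hr")
  if (ratio) {
    # unbounded CIs (boundary fits, zero-cell corrections) would destroy the
    # log axis; clip the band to the finite range for display only
    finite_rng <- range(dat$estimate[is.finite(dat$estimate) & dat$estimate > 0])
    dat$low_plot <- pmax(dat$low, finite_rng[1] / 10, na.rm = TRUE)
    dat$high_plot <- pmin(dat$high, finite_rng[2] * 10, na.rm = TRUE)
  } else {
    dat$low_plot <- dat$low
    dat$high_plot <- dat$high
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$cutoff, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$low_plot, ymax = .data$high_plot),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "blue") +
    ggplot2::geom_hline(yintercept = if (ratio) 1 else 0, linetype = "dashed") +
    ggplot2::labs(x = "cutoff",
                  y = switch(effect, or = "odds ratio (95% CI)",
                             hr = "hazard ratio (95% CI)",
                             survdiff = "difference in mean survival time (95% CI)"))
  if (ratio) p <- p + ggplot2::scale_y_log10()
  if (!is.null(marker)) {
    p <- p + ggplot2::geom_rug(data = data.frame(m = marker),
                               ggplot2::aes(x = .data$m), inherit.aes = FALSE,
                               sides = "b", alpha = 0.4)
  }
  if (!is.null(selected_cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = selected_cutoff, linetype = "dotted")
  }
  save_plot(p, path)
  invisible(list(plot = p, data = dat[, c("cutoff", "estimate", "low", "high")]))
}

#' ROC curve plot
#'
#' Staircase ROC with the chance diagonal and, optionally, the point of the
#' selected cutoff highlighted.
#'
#' @param roc A [roc_curve()].
#' @param selected_cutoff Optional cutoff whose ROC point is highlighted.
#' @param path Optional output file.
#' @return Invisibly, a list with `plot`, `data` (the curve points) and
#'   `selected` (the highlighted point, if any).
#' @export
plot_roc <- function(roc, selected_cutoff = NULL, path = NULL) {
  stopifnot(inherits(roc, "roc_curve"))
  dat <- as.data.frame(roc)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_step(colour = "blue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", attr(roc, "auc")))
  sel <- NULL
  if (!is.null(selected_cutoff)) {
    hit <- which(!is.na(dat$cutoff) & dat$cutoff == selected_cutoff)
    if (length(hit)) {
      sel <- dat[hit[1], ]
      p <- p + ggplot2::geom_point(data = sel, colour = "red", size = 3)
    }
  }
  save_plot(p, path)
  invisible(list(plot = p, data = dat, selected = sel))
}

#' Waterfall plot of per-patient marker values
#'
#' Sorted per-patient bars of the marker value, colored by the dichotomized
#' group (or by outcome when present), with a horizontal line at the cutoff.
#'
#' @param dataset A [marker_dataset()].
#' @param cutoff The cutoff to display.
#' @param path Optional output file.
#' @param color_by `"group"` (default) or `"outcome"` (requires an outcome).
#' @return Invisibly, a list with `plot` and `data` (sorted bar values with
#'   the coloring variable).
#' @export
plot_waterfall <- function(dataset, cutoff, path = NULL,
                           color_by = c("group", "outcome")) {
  color_by <- match.arg(color_by)
  stopifnot(inherits(dataset, "marker_dataset"))
  if (color_by == "outcome" && is.null(dataset$outcome)) {
    stop("color_by = 'outcome' requires an outcome variable", call. = FALSE)
  }
  ord <- order(dataset$marker, decreasing = TRUE)
  dat <- data.frame(
    rank = seq_along(ord),
    marker = dataset$marker[ord],
    fill = if (color_by == "group") dichotomize(dataset$marker[ord], cutoff)
           else dataset$outcome[ord]
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$marker,
                                         fill = .data$fill)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dotted") +
    ggplot2::labs(x = "patients (sorted)", y = "marker", fill = color_by)
  save_plot(p, path)
  invisible(list(plot = p, data = dat))
}

#' Kaplan-Meier plot of the dichotomized cohort
#'
#' Survival curves of the high and low marker groups with the two-group
#' log-rank p-value in the title.
#'
#' @param dataset A [marker_dataset()] with survival variables.
#' @param cutoff The cutoff defining the groups.
#' @param path Optional output file.
#' @return Invisibly, a list with `plot`, `data` (the plotted step
#'   coordinates per group) and `p_logrank`.
#' @export
plot_km <- function(dataset, cutoff, path = NULL) {
  stopifnot(inherits(dataset, "marker_dataset"))
  keep <- survival_complete(dataset)
  time <- dataset$time[keep]; event <- dataset$event[keep]
  grp <- dichotomize(dataset$marker[keep], cutoff)
  if (nlevels(droplevels(grp)) != 2) {
    stop("cutoff leaves one group empty; no Kaplan-Meier comparison possible",
         call. = FALSE)
  }
  p_lr <- if (sum(event) == 0) 1 else logrank_p(time, event, grp)
  steps <- do.call(rbind, lapply(levels(grp), function(g) {
    km <- km_estimate(time[grp == g], event[grp == g])
    tt <- c(0, rep(km$event_times, each = 2), km$max_time)
    ss <- c(1, 1, rep(km$survival, each = 2))
    data.frame(group = g, time = tt, survival = ss[seq_along(tt)])
  }))
  p <- ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival,
                                           colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival",
                  title = sprintf("log-rank p = %.2g", p_lr))
  save_plot(p, path)
  invisible(list(plot = p, data = steps, p_logrank = p_lr))
}
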