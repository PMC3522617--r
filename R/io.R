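#' Load a patient table from a tab-separated file
#'
#' Reads a tab-separated table (rows = patients, columns = variables, header
#' row required, "." decimal) and assembles a [marker_dataset()] from the
#' named columns. Table size is soft-limited to 5000 data rows and 50
#' columns; set `enforce_limits = FALSE` to lift both.
#'
#' @param path Path to the TSV file.
#' @param marker Name of the biomarker column (must coerce to numeric).
#' @param outcome Optional name of a binary outcome column.
#' @param time,event Optional names of the survival time and event columns.
#' @param positive_level Outcome level treated as positive (see
#'   [marker_dataset()]).
#' @param id Optional name of an identifier column.
#' @param enforce_limits Enforce the 5000-row / 50-column limits
#'   (default TRUE).
#' @return A [marker_dataset()] with attribute `"columns"` (the full column
#'   inventory of the file) and attribute `"drop_log"` (per-variable counts
#'   of unusable rows).
#' @export
load_table <- function(path, marker, outcome = NULL, time = NULL, event = NULL,
                       positive_level = NULL, id = NULL,
                       enforce_limits = TRUE) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (enforce_limits) {
    if (nrow(df) > 5000) {
      stop("table has ", nrow(df),
           " data rows, exceeding the 5000-row limit (use enforce_limits = FALSE to override)",
           call. = FALSE)
    }
    if (ncol(df) > 50) {
      stop("table has ", ncol(df),
           " columns, exceeding the 50-column limit (use enforce_limits = FALSE to override)",
           call. = FALSE)
    }
  }
  get_col <- function(nm, what) {
    if (is.null(nm)) return(NULL)
    if (!nm %in% names(df)) {
      stop(sprintf("%s column %s not found; available columns: %s",
                   what, sQuote(nm), paste(sQuote(names(df)), collapse = ", ")),
           call. = FALSE)
    }
    df[[nm]]
  }
  num_col <- function(nm, what) {
    x <- get_col(nm, what)
    if (is.null(x)) return(NULL)
    xn <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(xn))
    if (length(bad)) {
      stop(sprintf("%s column %s is not numeric in data row(s) %s",
                   what, sQuote(nm),
                   paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
    }
    xn
  }

  mk <- num_col(marker, "marker")
  tm <- num_col(time, "time")
  ev <- num_col(event, "event")
  oc <- get_col(outcome, "outcome")
  ids <- get_col(id, "id")

  ds <- marker_dataset(mk, outcome = oc, time = tm, event = ev, ids = ids,
                       positive_level = positive_level)
  drop_log <- c(marker = sum(is.na(mk)))
  if (!is.null(oc)) drop_log["outcome"] <- sum(is.na(ds$outcome))
  if (!is.null(tm)) drop_log["survival"] <- sum(is.na(ds$time))
  attr(ds, "columns") <- names(df)
  attr(ds, "drop_log") <- drop_log
  ds
}

#' Run a full cutoff analysis and write a result bundle
#'
#' The controller behind the command-line interface: dispatches to the
#' configured cutoff-determination method, computes the at-cutoff statistics
#' and the per-candidate scan, and (optionally) writes `results.json`,
#' `scan.tsv`, the requested plots and `run.log` into an output directory.
#' Two runs with the same configuration and seed produce identical result
#' and scan files.
#'
#' @param dataset A [marker_dataset()], e.g. from [load_table()].
#' @param method One of `"mixture"`, `"binary_significance"`,
#'   `"roc_euclidean"`, `"roc_manhattan"`, `"min_sensitivity"`,
#'   `"min_specificity"`, `"survival_significance"`, `"manual"`.
#' @param value Manual cutoff (required for `method = "manual"`).
#' @param threshold Required sensitivity/specificity level for the
#'   constrained methods, default 0.9.
#' @param orientation Passed to the binary-outcome machinery.
#' @param min_group Minimum group size for the candidate grid.
#' @param alpha Significance level for [proportion_significant()].
#' @param seed Seed for the mixture fit's random restarts.
#' @param out_dir Output directory; `NULL` (default) skips file output.
#' @param plots Character vector of plot kinds to write (any of
#'   `"histogram_mixture"`, `"or_overview"`, `"hr_overview"`,
#'   `"survdiff_overview"`, `"roc"`, `"waterfall"`, `"km"`), or `"all"`.
#'   Ignored when `out_dir` is `NULL`.
#' @param format Image format for plots, `"png"` or `"svg"`.
#' @return A list of class `markercut_run`: `result` (a `cutoff_result`),
#'   `scans` (whatever scans the method and data support),
#'   `proportion_significant` (named vector, one entry per available scan),
#'   `mixture_fit` (when computed), `files` (paths written).
#' @export
run_markercut <- function(dataset, method, value = NULL, threshold = 0.9,
                          orientation = "auto", min_group = 1, alpha = 0.05,
                          seed = 1, out_dir = NULL, plots = "all",
                          format = "png") {
  method <- match.arg(method, c(
    "mixture", "binary_significance", "roc_euclidean", "roc_manhattan",
    "min_sensitivity", "min_specificity", "survival_significance", "manual"
  ))
  stopifnot(inherits(dataset, "marker_dataset"))

  needs_outcome <- method %in% c("binary_significance", "roc_euclidean",
                                 "roc_manhattan", "min_sensitivity",
                                 "min_specificity")
  if (needs_outcome && is.null(dataset$outcome)) {
    stop("method ", sQuote(method), " requires a binary outcome column",
         call. = FALSE)
  }
  if (method == "survival_significance" && is.null(dataset$time)) {
    stop("method 'survival_significance' requires time and event columns",
         call. = FALSE)
  }
  if (method == "manual" && (is.null(value) || !is.numeric(value))) {
    stop("method 'manual' requires a numeric cutoff `value`", call. = FALSE)
  }

  grid <- candidate_cutoffs(dataset, min_group = min_group)
  fit <- NULL

  result <- switch(
    method,
    mixture = {
      fit <- fit_mixture(dataset, seed = seed)
      cut <- mixture_cutoff(fit)
      new_cutoff_result(as.numeric(cut), "mixture",
                        statistics = list(pi1 = fit$pi1, pi2 = fit$pi2,
                                          mu1 = fit$mu1, mu2 = fit$mu2,
                                          sigma1 = fit$sigma1,
                                          sigma2 = fit$sigma2,
                                          loglik = fit$loglik,
                                          in_interval = attr(cut, "in_interval")))
    },
    binary_significance = optimize_binary_significance(dataset, grid, orientation),
    roc_euclidean = optimize_roc(binary_scan(dataset, grid, orientation), "euclidean"),
    roc_manhattan = optimize_roc(binary_scan(dataset, grid, orientation), "manhattan"),
    min_sensitivity = constrained_cutoff(binary_scan(dataset, grid, orientation),
                                         "sensitivity", threshold),
    min_specificity = constrained_cutoff(binary_scan(dataset, grid, orientation),
                                         "specificity", threshold),
    survival_significance = optimize_survival_significance(dataset, grid),
    manual = new_cutoff_result(value, "manual")
  )

  # always attach every scan the data support, evaluated at the chosen cutoff
  scans <- list()
  if (!is.null(dataset$outcome)) {
    scans$binary <- if (inherits(result$scan, "binary_scan")) result$scan
                    else binary_scan(dataset, grid, orientation)
  }
  if (!is.null(dataset$time)) {
    scans$survival <- if (inherits(result$scan, "survival_scan")) result$scan
                      else survival_scan(dataset, grid)
  }
  result$statistics <- utils::modifyList(
    at_cutoff_all(dataset, result$cutoff, scans, orientation),
    result$statistics %||% list()
  )
  prop <- vapply(scans, proportion_significant, numeric(1), alpha = alpha)

  run <- structure(
    list(result = result, scans = scans, proportion_significant = prop,
         mixture_fit = fit, grid = grid, alpha = alpha, seed = seed,
         files = character()),
    class = "markercut_run"
  )
  if (!is.null(out_dir)) {
    run$files <- write_run_bundle(run, dataset, out_dir, plots, format)
  }
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# At-cutoff statistics for an arbitrary cutoff (manual / mixture methods):
# binary table stats and survival stats, whichever the data support.
at_cutoff_all <- function(dataset, cutoff, scans, orientation = "auto") {
  out <- list()
  if (!is.null(dataset$outcome)) {
    orient <- if (!is.null(scans$binary)) attr(scans$binary, "orientation")
              else if (orientation == "auto") auto_orientation(dataset)
              else orientation
    tab <- confusion_at(dataset, cutoff, orient)
    orr <- odds_ratio(tab)
    sci <- wilson_ci(tab$tp, max(tab$tp + tab$fn, 1))
    pci <- wilson_ci(tab$tn, max(tab$tn + tab$fp, 1))
    out <- c(out, list(
      or = orr$or, or_low = orr$ci_low, or_high = orr$ci_high,
      p_fisher = fisher_p(tab),
      sensitivity = tab$tp / (tab$tp + tab$fn),
      sens_low = sci[["low"]], sens_high = sci[["high"]],
      specificity = tab$tn / (tab$tn + tab$fp),
      spec_low = pci[["low"]], spec_high = pci[["high"]],
      orientation = orient
    ))
  }
  if (!is.null(dataset$time)) {
    keep <- survival_complete(dataset)
    grp <- dichotomize(dataset$marker[keep], cutoff)
    if (nlevels(droplevels(grp)) == 2 && sum(dataset$event[keep]) > 0) {
      cx <- suppressWarnings(cox_hr(dataset$time[keep], dataset$event[keep], grp))
      out <- c(out, list(
        hr = cx$hr, hr_low = cx$ci_low, hr_high = cx$ci_high,
        p_logrank = logrank_p(dataset$time[keep], dataset$event[keep], grp),
        p_wald = cx$p_wald
      ))
    }
  }
  out
}

write_run_bundle <- function(run, dataset, out_dir, plots, format) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()

  res <- run$result
  summary <- list(
    method = res$method,
    cutoff = res$cutoff,
    n = dataset$n,
    n_dropped_marker = dataset$n_dropped,
    statistics = res$statistics[!vapply(res$statistics, is.null, logical(1))],
    proportion_significant = as.list(run$proportion_significant),
    alpha = run$alpha,
    seed = run$seed,
    n_candidates = length(run$grid$cutoffs),
    warnings = res$warnings
  )
  json_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, json_path)

  for (nm in names(run$scans)) {
    scan_path <- file.path(out_dir, paste0("scan_", nm, ".tsv"))
    utils::write.table(as.data.frame(run$scans[[nm]]), scan_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, scan_path)
  }

  plot_dir <- file.path(out_dir, "plots")
  files <- c(files, write_run_plots(run, dataset, plot_dir, plots, format))

  log_path <- file.path(out_dir, "run.log")
  writeLines(c(
    paste0("markercut ", as.character(utils::packageVersion("markercut"))),
    paste0("method: ", res$method),
    paste0("cutoff: ", format(res$cutoff, digits = 10)),
    paste0("seed: ", run$seed),
    paste0("n: ", dataset$n,
           " (", dataset$n_dropped, " rows dropped: missing marker)"),
    paste0("candidates: ", length(run$grid$cutoffs),
           " (min_group ", run$grid$min_group, ")"),
    if (length(res$warnings)) paste0("warning: ", res$warnings) else character()
  ), log_path)
  files <- c(files, log_path)
  run$files <- files
  files
}

write_run_plots <- function(run, dataset, plot_dir, plots, format) {
  all_kinds <- c("histogram_mixture", "or_overview", "hr_overview",
                 "survdiff_overview", "roc", "waterfall", "km")
  if (length(plots) == 0) return(character())
  if (identical(plots, "all")) {
    plots <- all_kinds
  } else {
    plots <- match.arg(plots, all_kinds, several.ok = TRUE)
  }
  # drop kinds the data or method cannot support
  if (is.null(dataset$outcome)) plots <- setdiff(plots, c("or_overview", "roc"))
  if (is.null(dataset$time)) {
    plots <- setdiff(plots, c("hr_overview", "survdiff_overview", "km"))
  }
  if (length(plots) == 0) return(character())
  dir.create(plot_dir, recursive = TRUE, showWarnings = FALSE)

  cut <- run$result$cutoff
  files <- character()
  path_for <- function(kind) file.path(plot_dir, paste0(kind, ".", format))
  for (kind in plots) {
    p <- path_for(kind)
    res <- switch(
      kind,
      histogram_mixture = {
        fit <- run$mixture_fit %||% fit_mixture(dataset, seed = run$seed)
        plot_histogram_mixture(dataset, fit, cutoff = cut, path = p)
      },
      or_overview = plot_scan_overview(run$scans$binary, "or",
                                       selected_cutoff = cut, path = p),
      hr_overview = plot_scan_overview(run$scans$survival, "hr",
                                       selected_cutoff = cut, path = p),
      survdiff_overview = plot_scan_overview(run$scans$survival, "survdiff",
                                             selected_cutoff = cut, path = p),
      roc = plot_roc(roc_curve(run$scans$binary), selected_cutoff = cut,
                     path = p),
      waterfall = plot_waterfall(dataset, cutoff = cut, path = p),
      km = plot_km(dataset, cutoff = cut, path = p)
    )
    files <- c(files, p)
  }
  files
}

#' @export
print.markercut_run <- function(x, ...) {
  print(x$result)
  if (length(x$proportion_significant)) {
    for (nm in names(x$proportion_significant)) {
      cat(sprintf("  proportion of significant cutoffs (%s scan, alpha = %g): %.1f%%\n",
                  nm, x$alpha, 100 * x$proportion_significant[[nm]]))
    }
  }
  if (length(x$files)) cat("  files:", length(x$files), "written\n")
  invisible(x)
}
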