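#' Assemble a marker dataset
#'
#' Bundles a per-patient biomarker measurement with an optional binary outcome
#' and an optional right-censored survival pair. Rows with a missing marker
#' value are dropped globally and counted; rows missing only the outcome (or
#' only the survival pair) are retained and dropped lazily by the analyses
#' that need those variables.
#'
#' @param marker Numeric vector of biomarker values (metric or ordinal score).
#' @param outcome Optional binary outcome, one value per patient. Any vector
#'   with exactly two observed levels is accepted; `positive_level` names the
#'   level treated as "positive".
#' @param time Optional non-negative survival times. Requires `event`.
#' @param event Optional event indicator (1 = event observed, 0 = censored).
#'   Logical vectors are accepted.
#' @param ids Optional patient identifiers.
#' @param positive_level Which outcome level is "positive". Defaults to the
#'   larger level (numerically, or lexicographically for character levels)
#'   with a message, mirroring the common convention that the higher code is
#'   the event of interest.
#'
#' @return An object of class `marker_dataset`: a list with elements
#'   `marker`, `outcome` (factor with levels `c("negative", "positive")` or
#'   `NULL`), `time`, `event`, `ids`, `n`, and `n_dropped` (rows lost to
#'   missing marker values).
#' @examples
#' d <- marker_dataset(c(1.2, 3.4, 2.2, 5.0), outcome = c(0, 1, 0, 1))
#' d$n
#' @export
marker_dataset <- function(marker, outcome = NULL, time = NULL, event = NULL,
                           ids = NULL, positive_level = NULL) {
  if (!is.numeric(marker)) {
    stop("`marker` must be numeric", call. = FALSE)
  }
  n_in <- length(marker)
  if (!is.null(time) && is.null(event)) {
    stop("`event` is required when `time` is given", call. = FALSE)
  }
  if (is.null(time) && !is.null(event)) {
    stop("`time` is required when `event` is given", call. = FALSE)
  }
  check_len <- function(x, what) {
    if (!is.null(x) && length(x) != n_in) {
      stop(sprintf("`%s` must have the same length as `marker`", what),
           call. = FALSE)
    }
  }
  check_len(outcome, "outcome")
  check_len(time, "time")
  check_len(event, "event")
  check_len(ids, "ids")

  keep <- !is.na(marker)
  n_dropped <- sum(!keep)
  marker <- marker[keep]
  if (!is.null(outcome)) outcome <- outcome[keep]
  if (!is.null(time)) time <- time[keep]
  if (!is.null(event)) event <- event[keep]
  if (!is.null(ids)) ids <- ids[keep]

  if (length(unique(marker)) < 2) {
    stop("no cutoff definable: fewer than 2 distinct marker values",
         call. = FALSE)
  }

  if (!is.null(outcome)) {
    outcome <- encode_outcome(outcome, positive_level)
  }

  if (!is.null(time)) {
    time <- as.numeric(time)
    if (any(time < 0, na.rm = TRUE)) {
      stop("survival times must be non-negative", call. = FALSE)
    }
    if (is.logical(event)) event <- as.integer(event)
    event <- as.integer(event)
    bad <- stats::na.omit(setdiff(unique(event), c(0L, 1L)))
    if (length(bad)) {
      stop("`event` must be binary (1 = event, 0 = censored)", call. = FALSE)
    }
    # a time without an event status (or vice versa) counts as missing
    miss <- is.na(time) != is.na(event)
    time[miss] <- NA_real_
    event[miss] <- NA_integer_
  }

  structure(
    list(marker = marker, outcome = outcome, time = time, event = event,
         ids = ids, n = length(marker), n_dropped = n_dropped),
    class = "marker_dataset"
  )
}

# Map an arbitrary two-level vector onto factor(negative, positive).
encode_outcome <- function(outcome, positive_level = NULL) {
  obs <- outcome[!is.na(outcome)]
  lev <- unique(obs)
  if (length(lev) != 2) {
    stop("`outcome` must have exactly two observed levels, found ",
         length(lev), call. = FALSE)
  }
  lev <- sort(lev)
  if (is.null(positive_level)) {
    positive_level <- lev[2]
    message("positive outcome level not given; using the larger level ",
            sQuote(positive_level))
  }
  if (!positive_level %in% lev) {
    stop(sprintf("positive level %s not found among outcome levels (%s)",
                 sQuote(positive_level), paste(sQuote(lev), collapse = ", ")),
         call. = FALSE)
  }
  factor(ifelse(is.na(outcome), NA,
                ifelse(outcome == positive_level, "positive", "negative")),
         levels = c("negative", "positive"))
}

#' @export
print.marker_dataset <- function(x, ...) {
  cat("<marker_dataset> n =", x$n)
  if (x$n_dropped > 0) cat(sprintf(" (%d rows dropped: missing marker)", x$n_dropped))
  cat("\n  marker: range", format(min(x$marker)), "..", format(max(x$marker)),
      sprintf("(%d distinct)", length(unique(x$marker))), "\n")
  if (!is.null(x$outcome)) {
    tab <- table(x$outcome)
    cat("  outcome:", tab[["positive"]], "positive /", tab[["negative"]],
        "negative\n")
  }
  if (!is.null(x$time)) {
    cat("  survival:", sum(x$event == 1, na.rm = TRUE), "events /",
        sum(x$event == 0, na.rm = TRUE), "censored\n")
  }
  invisible(x)
}

#' Candidate cutoff grid
#'
#' Enumerates every distinct observed marker value `v` such that splitting the
#' cohort into `low = {marker < v}` and `high = {marker >= v}` leaves both
#' groups with at least `min_group` patients. The global minimum is never a
#' candidate (it would leave the low group empty). Candidates are the observed
#' values themselves, so reported cutoffs stay interpretable on the marker's
#' scale.
#'
#' @param dataset A [marker_dataset()].
#' @param min_group Minimum size of each group (default 1). Larger values
#'   stabilize logistic and Cox fits at the grid edges.
#' @return An object of class `candidate_grid`: a list with `cutoffs`
#'   (strictly increasing), `n_low`, `n_high`, and `min_group`.
#' @examples
#' d <- marker_dataset(c(1, 2, 2, 3))
#' candidate_cutoffs(d)$cutoffs
#' @export
candidate_cutoffs <- function(dataset, min_group = 1) {
  stopifnot(inherits(dataset, "marker_dataset"))
  if (min_group < 1) stop("`min_group` must be >= 1", call. = FALSE)
  x <- dataset$marker
  vals <- sort(unique(x))
  if (length(vals) < 2) stop("no cutoff definable", call. = FALSE)
  n_low <- vapply(vals, function(v) sum(x < v), integer(1))
  n_high <- length(x) - n_low
  keep <- n_low >= min_group & n_high >= min_group
  if (!any(keep)) stop("min_group too large: no candidate cutoff leaves both groups with >= ",
                       min_group, " patients", call. = FALSE)
  structure(
    list(cutoffs = vals[keep], n_low = n_low[keep], n_high = n_high[keep],
         min_group = as.integer(min_group)),
    class = "candidate_grid"
  )
}

#' @export
print.candidate_grid <- function(x, ...) {
  cat("<candidate_grid>", length(x$cutoffs), "candidates in [",
      format(min(x$cutoffs)), ",", format(max(x$cutoffs)), "], min_group =",
      x$min_group, "\n")
  invisible(x)
}

#' Dichotomize a marker at a cutoff
#'
#' Patients with `marker >= cutoff` form the "high" group (the marker-positive
#' reference group in all downstream effect sizes); the rest are "low". A
#' marker exactly equal to the cutoff belongs to the high group.
#'
#' @param dataset A [marker_dataset()] or a numeric vector.
#' @param cutoff Numeric scalar.
#' @return Factor with levels `c("low", "high")`.
#' @examples
#' dichotomize(c(1, 2, 3), 2)
#' @export
dichotomize <- function(dataset, cutoff) {
  x <- if (inherits(dataset, "marker_dataset")) dataset$marker else dataset
  stopifnot(is.numeric(x), is.numeric(cutoff), length(cutoff) == 1)
  factor(ifelse(x >= cutoff, "high", "low"), levels = c("low", "high"))
}

# Construct the shared result container. `cutoff` need not belong to the grid
# for the mixture and manual methods.
new_cutoff_result <- function(cutoff, method, statistics = list(),
                              scan = NULL, warnings = character()) {
  method <- match.arg(method, c(
    "mixture", "binary_significance", "roc_euclidean", "roc_manhattan",
    "min_sensitivity", "min_specificity", "survival_significance", "manual"
  ))
  structure(
    list(cutoff = cutoff, method = method, statistics = statistics,
         scan = scan, warnings = warnings),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat("<cutoff_result> method =", x$method, " cutoff =", format(x$cutoff), "\n")
  s <- x$statistics
  fmt <- function(v) formatC(v, digits = 4, format = "g")
  if (!is.null(s$or)) {
    cat(sprintf("  OR = %s (%s-%s), Fisher p = %s\n",
                fmt(s$or), fmt(s$or_low), fmt(s$or_high), fmt(s$p_fisher)))
  }
  if (!is.null(s$hr)) {
    cat(sprintf("  HR = %s (%s-%s), log-rank p = %s\n",
                fmt(s$hr), fmt(s$hr_low), fmt(s$hr_high), fmt(s$p_logrank)))
  }
  if (!is.null(s$sensitivity)) {
    cat(sprintf("  sensitivity = %s (%s-%s), specificity = %s (%s-%s)\n",
                fmt(s$sensitivity), fmt(s$sens_low), fmt(s$sens_high),
                fmt(s$specificity), fmt(s$spec_low), fmt(s$spec_high)))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# Rows usable for binary-outcome analyses.
binary_complete <- function(dataset) {
  if (is.null(dataset$outcome)) {
    stop("this analysis requires a binary outcome variable", call. = FALSE)
  }
  !is.na(dataset$outcome)
}

# Rows usable for survival analyses.
survival_complete <- function(dataset) {
  if (is.null(dataset$time)) {
    stop("this analysis requires survival time and event variables",
         call. = FALSE)
  }
  !is.na(dataset$time) & !is.na(dataset$event)
}
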