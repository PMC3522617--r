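#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the step function in a
#' plain list, restricted to the event times (the survival estimate only
#' drops there).
#'
#' @param times Non-negative survival times.
#' @param events Event indicator (1 = event, 0 = censored).
#' @return An object of class `km_curve`: `event_times` (distinct times with
#'   at least one event, ascending), `survival` (estimate just after each
#'   event time), `n_risk`, `n_event`, `max_time` (largest observed time,
#'   event or censored), `n`.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$survival
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events))
  keep <- !is.na(times) & !is.na(events)
  times <- times[keep]; events <- as.integer(events[keep])
  if (length(times) == 0) stop("no observations for Kaplan-Meier estimate", call. = FALSE)
  if (any(times < 0)) stop("survival times must be non-negative", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  has_event <- fit$n.event > 0
  structure(
    list(event_times = fit$time[has_event],
         survival = fit$surv[has_event],
         n_risk = fit$n.risk[has_event],
         n_event = fit$n.event[has_event],
         max_time = max(times),
         n = length(times)),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n =", x$n, ",", sum(x$n_event), "events at",
      length(x$event_times), "distinct times, max observed time",
      format(x$max_time), "\n")
  invisible(x)
}

# S(t) of a km_curve at arbitrary times (right-continuous step function).
km_survival_at <- function(curve, t) {
  if (length(curve$event_times) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, curve$event_times)
  c(1, curve$survival)[idx + 1]
}

#' Two-group log-rank test p-value
#'
#' Standard 1-df log-rank chi-square via [survival::survdiff()].
#'
#' @param times,events Survival data.
#' @param groups Two-level grouping (e.g. the output of [dichotomize()]).
#' @return Two-sided p-value. If no events occurred at all, returns 1 with a
#'   warning.
#' @export
logrank_p <- function(times, events, groups) {
  keep <- !is.na(times) & !is.na(events)
  times <- times[keep]; events <- as.integer(events[keep]); groups <- groups[keep]
  if (length(unique(groups[!is.na(groups)])) != 2) {
    stop("log-rank test needs exactly two non-empty groups", call. = FALSE)
  }
  if (sum(events) == 0) {
    warning("no events observed; log-rank p set to 1", call. = FALSE)
    return(1)
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
}

#' Cox proportional-hazards ratio for a two-group split
#'
#' Univariate Cox partial-likelihood fit of the high-vs-low indicator with
#' Efron tie handling (switchable) via [survival::coxph()]; returns the
#' hazard ratio of the high group relative to the low group with a Wald
#' confidence interval. When all events fall into one group the partial
#' likelihood is monotone and the estimate diverges; the result is then
#' flagged (`boundary = TRUE`) with an unbounded confidence interval.
#'
#' @param times,events Survival data.
#' @param groups Factor with levels `c("low", "high")` (or any two-level
#'   grouping; the second level is the numerator).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param level Confidence level, default 0.95.
#' @return List with `hr`, `ci_low`, `ci_high`, `p_wald`, `boundary`.
#' @export
cox_hr <- function(times, events, groups, ties = c("efron", "breslow"),
                   level = 0.95) {
  ties <- match.arg(ties)
  keep <- !is.na(times) & !is.na(events) & !is.na(groups)
  times <- times[keep]; events <- as.integer(events[keep])
  groups <- factor(groups[keep])
  if (nlevels(groups) != 2) stop("Cox fit needs exactly two groups", call. = FALSE)
  if (sum(events) < 1) stop("Cox fit needs at least one event", call. = FALSE)

  boundary <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ groups, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        boundary <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(unname(fit$var[1, 1]))
  # monotone likelihood: events confined to one group
  ev_by_group <- tapply(events, groups, sum)
  if (any(ev_by_group == 0)) boundary <- TRUE
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(hr = exp(beta),
       ci_low = if (boundary) 0 else exp(beta - z * se),
       ci_high = if (boundary) Inf else exp(beta + z * se),
       p_wald = 2 * stats::pnorm(-abs(beta / se)),
       boundary = boundary)
}

#' Restricted mean survival time (area under the Kaplan-Meier curve)
#'
#' Integrates the KM step function from 0 to `tau`. With no censoring and
#' `tau` equal to the largest observed time this is exactly the sample mean
#' of the survival times. If `tau` exceeds the largest observed time the
#' curve is extended flat at its last value and the result flagged.
#'
#' @param curve A [km_estimate()] result.
#' @param tau Upper integration limit (> 0). Defaults to the curve's
#'   `max_time`.
#' @return RMST (numeric scalar) with attributes `"se"` (Greenwood-type
#'   asymptotic standard error) and `"extrapolated"`.
#' @export
rmst <- function(curve, tau = curve$max_time) {
  stopifnot(inherits(curve, "km_curve"), tau > 0)
  extrapolated <- tau > curve$max_time
  if (extrapolated) {
    warning("tau exceeds the largest observed time; survival held constant beyond it",
            call. = FALSE)
  }
  t_ev <- curve$event_times
  s <- curve$survival
  in_win <- t_ev <= tau
  t_w <- t_ev[in_win]
  s_w <- s[in_win]
  # left-continuous step integral: S = 1 on [0, t1), s_i on [t_i, t_{i+1})
  knots <- c(0, t_w, tau)
  heights <- c(1, s_w)
  area <- sum(diff(knots) * heights)

  # Greenwood-type variance: sum over event times of
  # A_i^2 * d_i / (n_i (n_i - d_i)), A_i = area under S from t_i to tau
  d <- curve$n_event[in_win]
  nr <- curve$n_risk[in_win]
  if (length(t_w) > 0) {
    area_from <- rev(cumsum(rev(diff(c(t_w, tau)) * s_w)))
    denom <- nr * (nr - d)
    term <- ifelse(denom > 0, area_from^2 * d / denom, 0)
    v <- sum(term)
  } else {
    v <- 0
  }
  structure(area, se = sqrt(v), extrapolated = extrapolated)
}

#' Per-candidate survival scan: HR, log-rank p and RMST difference
#'
#' For each candidate cutoff, dichotomizes the marker, fits a univariate Cox
#' model (hazard ratio of high vs low with Wald CI), computes the two-group
#' log-rank p-value, and the difference in restricted mean survival time
#' (high minus low) at the uniform horizon `tau` = largest observed time in
#' the full dataset, with an asymptotic CI treating the two arms as
#' independent.
#'
#' @param dataset A [marker_dataset()] with survival variables.
#' @param grid Optional [candidate_cutoffs()] grid (built with
#'   `min_group = 1` when omitted).
#' @param ties Tie handling passed to [cox_hr()].
#' @return A `survival_scan`: a [tibble::tibble] with one row per candidate
#'   and columns `cutoff`, `n_low`, `n_high`, `hr`, `hr_low`, `hr_high`, `p`
#'   (log-rank), `p_wald`, `rmst_high`, `rmst_low`, `rmst_diff`,
#'   `rmst_diff_low`, `rmst_diff_high`, `boundary`. The horizon is attached
#'   as attribute `"tau"`.
#' @export
survival_scan <- function(dataset, grid = NULL, ties = "efron") {
  keep <- survival_complete(dataset)
  sub <- marker_dataset(dataset$marker[keep],
                        time = dataset$time[keep],
                        event = dataset$event[keep])
  if (is.null(grid)) grid <- candidate_cutoffs(sub)
  tau <- max(sub$time)
  z <- stats::qnorm(0.975)

  rows <- lapply(seq_along(grid$cutoffs), function(i) {
    v <- grid$cutoffs[i]
    grp <- dichotomize(sub$marker, v)
    hi <- grp == "high"
    cx <- suppressWarnings(cox_hr(sub$time, sub$event, grp, ties = ties))
    p_lr <- if (sum(sub$event) == 0) 1 else logrank_p(sub$time, sub$event, grp)
    # the uniform tau routinely exceeds one arm's own maximum time; the flat
    # extension is by design here, so the per-arm extrapolation warning is
    # silenced
    r_hi <- suppressWarnings(rmst(km_estimate(sub$time[hi], sub$event[hi]), tau))
    r_lo <- suppressWarnings(rmst(km_estimate(sub$time[!hi], sub$event[!hi]), tau))
    dd <- as.numeric(r_hi) - as.numeric(r_lo)
    se <- sqrt(attr(r_hi, "se")^2 + attr(r_lo, "se")^2)
    tibble::tibble(
      cutoff = v,
      hr = cx$hr, hr_low = cx$ci_low, hr_high = cx$ci_high,
      p = p_lr, p_wald = cx$p_wald,
      rmst_high = as.numeric(r_hi), rmst_low = as.numeric(r_lo),
      rmst_diff = dd, rmst_diff_low = dd - z * se, rmst_diff_high = dd + z * se,
      boundary = cx$boundary
    )
  })
  scan <- do.call(rbind, rows)
  scan <- tibble::add_column(scan, n_low = grid$n_low, n_high = grid$n_high,
                             .after = "cutoff")
  attr(scan, "tau") <- tau
  attr(scan, "marker") <- sub$marker
  class(scan) <- c("survival_scan", class(scan))
  scan
}

#' Per-candidate restricted-mean-survival-time differences
#'
#' Convenience view of [survival_scan()] restricted to the RMST columns —
#' the data behind the survival-difference overview plot.
#'
#' @inheritParams survival_scan
#' @return A [tibble::tibble] with columns `cutoff`, `rmst_high`, `rmst_low`,
#'   `rmst_diff`, `rmst_diff_low`, `rmst_diff_high`.
#' @export
survival_difference_scan <- function(dataset, grid = NULL) {
  scan <- survival_scan(dataset, grid)
  out <- scan[, c("cutoff", "rmst_high", "rmst_low", "rmst_diff",
                  "rmst_diff_low", "rmst_diff_high")]
  attr(out, "tau") <- attr(scan, "tau")
  out
}

#' Cutoff minimizing the log-rank p-value
#'
#' Scans all candidate cutoffs and selects the split with the most
#' significant two-group log-rank test (minimal p-value; ties go to the
#' lowest cutoff). As with every minimal-p selection the reported p-value is
#' anti-conservative under the null; the per-cutoff scan and
#' [proportion_significant()] help judge robustness.
#'
#' @inheritParams survival_scan
#' @return A `cutoff_result` whose `statistics` carry the at-cutoff HR with
#'   CI, log-rank p and RMST difference; `$scan` holds the full
#'   [survival_scan()].
#' @export
optimize_survival_significance <- function(dataset, grid = NULL, ties = "efron") {
  keep <- survival_complete(dataset)
  if (sum(dataset$event[keep], na.rm = TRUE) == 0) {
    stop("no events observed; survival-based optimization impossible", call. = FALSE)
  }
  scan <- survival_scan(dataset, grid, ties = ties)
  idx <- which_min_first(scan$p)
  r <- scan[idx, ]
  new_cutoff_result(r$cutoff, "survival_significance",
                    statistics = list(hr = r$hr, hr_low = r$hr_low,
                                      hr_high = r$hr_high,
                                      p_logrank = r$p, p_wald = r$p_wald,
                                      rmst_diff = r$rmst_diff,
                                      rmst_diff_low = r$rmst_diff_low,
                                      rmst_diff_high = r$rmst_diff_high,
                                      tau = attr(scan, "tau")),
                    scan = scan)
}
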