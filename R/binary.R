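#' Confusion table of the dichotomized marker against the outcome
#'
#' Cross-tabulates the dichotomized marker against the binary outcome. Under
#' the default `high_positive` orientation the high group predicts a positive
#' outcome, so `tp` counts high/positive patients; `low_positive` swaps the
#' prediction direction.
#'
#' @param dataset A [marker_dataset()] with an outcome.
#' @param cutoff Numeric cutoff (marker >= cutoff is "high").
#' @param orientation `"high_positive"` (default) or `"low_positive"`.
#' @return An object of class `confusion_table` with integer fields `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
confusion_at <- function(dataset, cutoff,
                         orientation = c("high_positive", "low_positive")) {
  orientation <- match.arg(orientation)
  keep <- binary_complete(dataset)
  grp <- dichotomize(dataset$marker[keep], cutoff)
  out <- dataset$outcome[keep]
  pred_pos <- if (orientation == "high_positive") grp == "high" else grp == "low"
  obs_pos <- out == "positive"
  structure(
    list(tp = sum(pred_pos & obs_pos), fp = sum(pred_pos & !obs_pos),
         tn = sum(!pred_pos & !obs_pos), fn = sum(!pred_pos & obs_pos),
         orientation = orientation),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              observed = c("positive", "negative")))
  cat("<confusion_table> orientation:", x$orientation, "\n")
  print(m)
  invisible(x)
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$tp, tab$fn, tab$fp, tab$tn), 2, 2)
}

#' Two-sided Fisher exact p-value of a confusion table
#'
#' Standard two-sided Fisher exact test by summation of hypergeometric table
#' probabilities no larger than the observed table's. Degenerate margins give
#' p = 1.
#'
#' @param table A [confusion_at()] result (or a list with `tp`, `fp`, `tn`,
#'   `fn`).
#' @return p-value in \[0, 1\].
#' @export
fisher_p <- function(table) {
  m <- as_matrix_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Odds ratio with Wald confidence interval
#'
#' The cross-product odds ratio `(tp * tn) / (fp * fn)` — the maximum
#' likelihood estimate of the logistic-regression odds ratio for a single
#' binary predictor — with the 95% Wald interval
#' `exp(log(OR) +/- z * sqrt(1/tp + 1/fp + 1/tn + 1/fn))`. Any zero cell
#' triggers the Haldane–Anscombe correction (0.5 added to every cell), which
#' is flagged in the result.
#'
#' @param table A [confusion_at()] result.
#' @param level Confidence level, default 0.95.
#' @return List with `or`, `ci_low`, `ci_high`, `p_wald`, `corrected`.
#' @export
odds_ratio <- function(table, level = 0.95) {
  a <- table$tp; b <- table$fp; c <- table$fn; d <- table$tn
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       p_wald = 2 * stats::pnorm(-abs(log(or) / se)),
       corrected = corrected)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,trials Non-negative integers with
#'   `0 <= successes <= trials`, `trials >= 1`.
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' wilson_ci(0, 10) # lower bound is exactly 0
#' @export
wilson_ci <- function(successes, trials, level = 0.95) {
  if (trials < 1) stop("`trials` must be >= 1", call. = FALSE)
  stopifnot(successes >= 0, successes <= trials)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  center <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Per-candidate scan against a binary outcome
#'
#' Evaluates every candidate cutoff against the binary outcome: confusion
#' counts, odds ratio with Wald CI, two-sided Fisher p, and sensitivity /
#' specificity with Wilson CIs. This is the table behind the OR overview plot
#' and the input to all binary-outcome optimizers.
#'
#' @param dataset A [marker_dataset()] with an outcome.
#' @param grid A [candidate_cutoffs()] grid; built with `min_group = 1` when
#'   omitted.
#' @param orientation `"auto"` (default; picks the direction with empirical
#'   AUC >= 0.5), `"high_positive"` or `"low_positive"`.
#' @return A `binary_scan`: a [tibble::tibble] with one row per candidate and
#'   columns `cutoff`, `n_low`, `n_high`, `tp`, `fp`, `tn`, `fn`, `or`,
#'   `or_low`, `or_high`, `p`, `sensitivity`, `sens_low`, `sens_high`,
#'   `specificity`, `spec_low`, `spec_high`, `youden`. The orientation used
#'   is attached as attribute `"orientation"`.
#' @export
binary_scan <- function(dataset, grid = NULL,
                        orientation = c("auto", "high_positive", "low_positive")) {
  orientation <- match.arg(orientation)
  keep <- binary_complete(dataset)
  sub <- marker_dataset(dataset$marker[keep],
                        outcome = dataset$outcome[keep],
                        positive_level = "positive")
  if (is.null(grid)) grid <- candidate_cutoffs(sub)
  if (orientation == "auto") orientation <- auto_orientation(sub)

  rows <- lapply(grid$cutoffs, function(v) {
    tab <- confusion_at(sub, v, orientation)
    orr <- odds_ratio(tab)
    sens <- tab$tp / (tab$tp + tab$fn)
    spec <- tab$tn / (tab$tn + tab$fp)
    sci <- wilson_ci(tab$tp, tab$tp + tab$fn)
    pci <- wilson_ci(tab$tn, tab$tn + tab$fp)
    tibble::tibble(
      cutoff = v, tp = tab$tp, fp = tab$fp, tn = tab$tn, fn = tab$fn,
      or = orr$or, or_low = orr$ci_low, or_high = orr$ci_high,
      or_corrected = orr$corrected,
      p = fisher_p(tab),
      sensitivity = sens, sens_low = sci[["low"]], sens_high = sci[["high"]],
      specificity = spec, spec_low = pci[["low"]], spec_high = pci[["high"]],
      youden = sens + spec - 1
    )
  })
  scan <- do.call(rbind, rows)
  scan <- tibble::add_column(scan, n_low = grid$n_low, n_high = grid$n_high,
                             .after = "cutoff")
  attr(scan, "orientation") <- orientation
  attr(scan, "marker") <- sub$marker
  class(scan) <- c("binary_scan", class(scan))
  scan
}

# Direction with empirical AUC >= 0.5: high marker predicts positive if the
# rank-sum AUC of marker vs outcome is at least 1/2.
auto_orientation <- function(dataset) {
  keep <- binary_complete(dataset)
  x <- dataset$marker[keep]
  pos <- dataset$outcome[keep] == "positive"
  if (!any(pos) || all(pos)) return("high_positive")
  r <- rank(x)
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  if (auc >= 0.5) "high_positive" else "low_positive"
}

#' Cutoff minimizing the Fisher exact p-value
#'
#' Scans all candidate cutoffs and selects the split most significantly
#' associated with the binary outcome by the two-sided Fisher exact test
#' (the minimal p-value approach; ties go to the lowest cutoff). Note the
#' selected p-value is not corrected for the multiplicity of candidate
#' cutoffs and is anti-conservative; inspect the full scan (and
#' [proportion_significant()]) to judge robustness.
#'
#' @inheritParams binary_scan
#' @return A `cutoff_result` whose `statistics` carry the at-cutoff OR,
#'   Fisher p, and sensitivity/specificity with Wilson CIs; `$scan` holds
#'   the full [binary_scan()].
#' @export
optimize_binary_significance <- function(dataset, grid = NULL,
                                         orientation = "auto") {
  scan <- binary_scan(dataset, grid, orientation)
  idx <- which_min_first(scan$p)
  warn <- character()
  if (all(scan$p >= 1 - 1e-12)) {
    warn <- "all candidate splits have Fisher p = 1; outcome looks independent of the marker"
    warning(warn, call. = FALSE)
  }
  new_cutoff_result(scan$cutoff[idx], "binary_significance",
                    statistics = at_cutoff_stats(scan, idx),
                    scan = scan, warnings = warn)
}

at_cutoff_stats <- function(scan, idx) {
  r <- scan[idx, ]
  list(or = r$or, or_low = r$or_low, or_high = r$or_high,
       p_fisher = r$p,
       sensitivity = r$sensitivity, sens_low = r$sens_low, sens_high = r$sens_high,
       specificity = r$specificity, spec_low = r$spec_low, spec_high = r$spec_high,
       youden = r$youden,
       orientation = attr(scan, "orientation"))
}

#' Empirical ROC curve over the candidate grid
#'
#' One `(1 - specificity, sensitivity)` point per candidate cutoff plus the
#' trivial endpoints (0, 0) and (1, 1).
#'
#' @inheritParams binary_scan
#' @return A `roc_curve`: a [tibble::tibble] with columns `cutoff` (`NA` for
#'   the endpoints), `fpr`, `sensitivity`, ordered by increasing `fpr`;
#'   empirical `auc` and the orientation are attached as attributes.
#' @export
roc_curve <- function(dataset, grid = NULL, orientation = "auto") {
  scan <- if (inherits(dataset, "binary_scan")) dataset
          else binary_scan(dataset, grid, orientation)
  pts <- tibble::tibble(
    cutoff = c(NA, scan$cutoff, NA),
    fpr = c(1, 1 - scan$specificity, 0),
    sensitivity = c(1, scan$sensitivity, 0)
  )
  pts <- pts[order(pts$fpr, pts$sensitivity), ]
  # trapezoidal AUC over the (sorted) staircase
  auc <- sum(diff(pts$fpr) * (utils::head(pts$sensitivity, -1) +
                              utils::tail(pts$sensitivity, -1)) / 2)
  attr(pts, "auc") <- auc
  attr(pts, "orientation") <- attr(scan, "orientation")
  class(pts) <- c("roc_curve", class(pts))
  pts
}

#' ROC-distance cutoff optimization
#'
#' Selects the candidate whose ROC point is closest to the top-left corner
#' (perfect classification): `metric = "euclidean"` minimizes
#' \eqn{\sqrt{(1 - sens)^2 + (1 - spec)^2}}; `metric = "manhattan"` minimizes
#' \eqn{(1 - sens) + (1 - spec)}, which is equivalent to maximizing Youden's
#' \eqn{J = sens + spec - 1}. Ties go to the lowest cutoff.
#'
#' @param roc A [roc_curve()] or a [binary_scan()].
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return A `cutoff_result` (method `roc_euclidean` or `roc_manhattan`) with
#'   the at-cutoff distance and Youden's J in `statistics`.
#' @export
optimize_roc <- function(roc, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (inherits(roc, "binary_scan")) {
    scan <- roc
    pts <- tibble::tibble(cutoff = scan$cutoff,
                          fpr = 1 - scan$specificity,
                          sensitivity = scan$sensitivity)
  } else {
    stopifnot(inherits(roc, "roc_curve"))
    scan <- NULL
    pts <- roc[!is.na(roc$cutoff), ]
  }
  if (nrow(pts) == 0) stop("empty ROC curve", call. = FALSE)
  dist <- if (metric == "euclidean") {
    sqrt((1 - pts$sensitivity)^2 + pts$fpr^2)
  } else {
    (1 - pts$sensitivity) + pts$fpr
  }
  ord <- order(pts$cutoff)
  idx <- ord[which_min_first(dist[ord])]
  stats <- list(distance = dist[idx], metric = metric,
                sensitivity = pts$sensitivity[idx],
                specificity = 1 - pts$fpr[idx],
                youden = pts$sensitivity[idx] - pts$fpr[idx])
  if (!is.null(scan)) {
    i2 <- which(scan$cutoff == pts$cutoff[idx])[1]
    stats <- utils::modifyList(at_cutoff_stats(scan, i2),
                               stats[c("distance", "metric")])
  }
  new_cutoff_result(pts$cutoff[idx],
                    if (metric == "euclidean") "roc_euclidean" else "roc_manhattan",
                    statistics = stats, scan = scan)
}

#' Cutoff with guaranteed minimum sensitivity or specificity
#'
#' Among the candidates whose constrained measure strictly exceeds
#' `threshold`, returns the one that maximizes the complementary measure.
#' Under the usual `high_positive` orientation this is the largest qualifying
#' cutoff for a sensitivity constraint and the smallest for a specificity
#' constraint — the maximally stringent cutoff that still meets the
#' guarantee.
#'
#' @param scan A [binary_scan()].
#' @param constraint `"sensitivity"` or `"specificity"`.
#' @param threshold Required level in (0, 1), e.g. 0.9.
#' @return A `cutoff_result` (method `min_sensitivity` or `min_specificity`).
#' @export
constrained_cutoff <- function(scan, constraint = c("sensitivity", "specificity"),
                               threshold) {
  constraint <- match.arg(constraint)
  stopifnot(inherits(scan, "binary_scan"),
            is.numeric(threshold), threshold > 0, threshold < 1)
  measure <- scan[[constraint]]
  complement <- if (constraint == "sensitivity") scan$specificity else scan$sensitivity
  ok <- which(measure > threshold)
  if (length(ok) == 0) {
    stop(sprintf("no cutoff satisfies constraint: %s > %g", constraint, threshold),
         call. = FALSE)
  }
  best <- max(complement[ok])
  cand <- ok[complement[ok] == best]
  # stringency tie-break: highest cutoff for sensitivity, lowest for specificity
  idx <- if (constraint == "sensitivity") cand[length(cand)] else cand[1]
  new_cutoff_result(scan$cutoff[idx],
                    if (constraint == "sensitivity") "min_sensitivity" else "min_specificity",
                    statistics = c(at_cutoff_stats(scan, idx),
                                   list(constraint = constraint, threshold = threshold)),
                    scan = scan)
}

#' Proportion of candidate cutoffs with a significant split
#'
#' The fraction of candidate cutoffs whose per-cutoff p-value falls below
#' `alpha` — a robustness diagnostic: a dichotomization whose significance
#' survives across most of the marker's range is less likely to be a
#' minimal-p artifact.
#'
#' @param scan A [binary_scan()] or [survival_scan()] (any data frame with a
#'   `p` column).
#' @param alpha Significance level, default 0.05.
#' @return Fraction in \[0, 1\].
#' @export
proportion_significant <- function(scan, alpha = 0.05) {
  p <- scan$p
  if (is.null(p) || length(p) == 0) stop("scan has no p-values", call. = FALSE)
  mean(p < alpha)
}

#' Equivocal-zone construction from paired sensitivity/specificity cutoffs
#'
#' Runs [constrained_cutoff()] twice to obtain a lower cutoff guaranteeing
#' sensitivity above `sens_threshold` and an upper cutoff guaranteeing
#' specificity above `spec_threshold`. Markers at or above the upper cutoff
#' test positive, markers below the lower cutoff test negative, and markers
#' in `[lower, upper)` are reported as equivocal. Sensitivity and specificity
#' of the resulting three-way test are re-estimated on the non-equivocal
#' samples.
#'
#' @param dataset A [marker_dataset()] with an outcome.
#' @param grid Optional [candidate_cutoffs()] grid.
#' @param sens_threshold,spec_threshold Required levels in (0, 1),
#'   default 0.9 each.
#' @param orientation Passed to [binary_scan()].
#' @return List with `lower`, `upper`, `fraction_equivocal`,
#'   `sensitivity_reliable`, `specificity_reliable` (computed on the
#'   non-equivocal samples), and `inverted` (TRUE with a warning when the
#'   constraints produce `lower >= upper`).
#' @export
equivocal_zone <- function(dataset, grid = NULL, sens_threshold = 0.9,
                           spec_threshold = 0.9, orientation = "auto") {
  scan <- binary_scan(dataset, grid, orientation)
  lower <- constrained_cutoff(scan, "sensitivity", sens_threshold)$cutoff
  upper <- constrained_cutoff(scan, "specificity", spec_threshold)$cutoff
  inverted <- lower > upper
  if (inverted) {
    warning("constraints produce an inverted zone (lower ", format(lower),
            " > upper ", format(upper), ")", call. = FALSE)
  }
  keep <- binary_complete(dataset)
  x <- dataset$marker[keep]
  out <- dataset$outcome[keep]
  # the zone [lower, upper) is empty when the constraints invert; samples in
  # the overlap then satisfy both guarantees and stay reliable
  equivocal <- x >= lower & x < upper
  rel_x <- x[!equivocal]
  rel_out <- out[!equivocal]
  pred_pos <- rel_x >= upper
  obs_pos <- rel_out == "positive"
  list(lower = lower, upper = upper,
       fraction_equivocal = mean(equivocal),
       sensitivity_reliable = if (any(obs_pos)) mean(pred_pos[obs_pos]) else NA_real_,
       specificity_reliable = if (any(!obs_pos)) mean(!pred_pos[!obs_pos]) else NA_real_,
       inverted = inverted)
}
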