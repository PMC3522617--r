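#' Draw a bimodal marker from a two-component Gaussian mixture
#'
#' The default parameters emulate a log2-scale gene-expression marker with a
#' pronounced bimodal shape: component means 5 and 10, unit SDs, equal
#' weights — the structure the mixture-based cutoff method assumes.
#'
#' @param n Number of patients.
#' @param pi1 Weight of the first (lower) component, strictly inside (0, 1).
#' @param mu Length-2 vector of component means.
#' @param sigma Length-2 vector of component SDs (> 0).
#' @param seed Integer seed (required for reproducibility).
#' @return Numeric vector of length `n`.
#' @examples
#' x <- gen_bimodal_marker(200, seed = 42)
#' @export
gen_bimodal_marker <- function(n, pi1 = 0.5, mu = c(5, 10), sigma = c(1, 1),
                               seed) {
  stopifnot(n >= 1, length(mu) == 2, length(sigma) == 2, all(sigma > 0))
  if (pi1 <= 0 || pi1 >= 1) {
    stop("`pi1` must be strictly inside (0, 1): both components must be present",
         call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  with_preserved_seed(seed, {
    comp <- stats::rbinom(n, 1, 1 - pi1) + 1
    stats::rnorm(n, mu[comp], sigma[comp])
  })
}

#' Generate a binary outcome linked to the marker
#'
#' Two link choices: a logistic link
#' \eqn{P(positive) = expit(intercept + slope \cdot marker)}, or a step link
#' where the outcome is positive iff the marker is at or above a true
#' changepoint, with each label independently flipped with probability
#' `flip_prob` (misclassification noise).
#'
#' @param marker Numeric marker values.
#' @param link `"logistic"` or `"step"`.
#' @param intercept,slope Logistic-link coefficients.
#' @param changepoint,flip_prob Step-link parameters; `flip_prob` in
#'   \[0, 0.5).
#' @param seed Integer seed (required).
#' @return Integer vector (1 = positive, 0 = negative).
#' @export
gen_binary_outcome <- function(marker, link = c("logistic", "step"),
                               intercept = -15, slope = 2,
                               changepoint = 7.5, flip_prob = 0.1, seed) {
  link <- match.arg(link)
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  n <- length(marker)
  with_preserved_seed(seed, {
    if (link == "logistic") {
      p <- stats::plogis(intercept + slope * marker)
      stats::rbinom(n, 1, p)
    } else {
      stopifnot(flip_prob >= 0, flip_prob < 0.5)
      y <- as.integer(marker >= changepoint)
      flip <- stats::rbinom(n, 1, flip_prob) == 1
      ifelse(flip, 1L - y, y)
    }
  })
}

#' Generate right-censored survival with a proportional-hazards cutoff effect
#'
#' Event times are exponential with baseline rate `baseline_rate`, multiplied
#' by `hr` for patients with `marker >= changepoint` (so `hr < 1` means
#' better survival in the high group). Censoring times are independent
#' exponentials whose rate is solved numerically so that the expected
#' censoring fraction matches `censoring`; observed time is the minimum of
#' the two.
#'
#' @param marker Numeric marker values.
#' @param changepoint True cutoff at which the hazard changes.
#' @param hr True hazard ratio (high vs low), > 0.
#' @param baseline_rate Exponential event rate of the low group, > 0.
#' @param censoring Target censoring fraction in \[0, 1).
#' @param seed Integer seed (required).
#' @return A list with numeric `time` and integer `event`
#'   (1 = event, 0 = censored).
#' @export
gen_survival <- function(marker, changepoint = 7.5, hr = 0.5,
                         baseline_rate = 0.1, censoring = 0.3, seed) {
  stopifnot(hr > 0, baseline_rate > 0, censoring >= 0, censoring < 1)
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  n <- length(marker)
  rate <- ifelse(marker >= changepoint, baseline_rate * hr, baseline_rate)
  with_preserved_seed(seed, {
    t_event <- stats::rexp(n, rate)
    if (censoring == 0) {
      list(time = t_event, event = rep(1L, n))
    } else {
      # P(C < T) for exponentials: mu / (lambda_i + mu), averaged over patients
      cens_rate <- stats::uniroot(
        function(mu) mean(mu / (rate + mu)) - censoring,
        lower = 1e-10, upper = 1e6 * baseline_rate, tol = 1e-12
      )$root
      t_cens <- stats::rexp(n, cens_rate)
      list(time = pmin(t_event, t_cens),
           event = as.integer(t_event <= t_cens))
    }
  })
}

#' Simulate a complete marker dataset
#'
#' Bundles the three generators into one cohort with the structure every
#' cutoff method assumes: a bimodal marker, a binary outcome tied to it, and
#' right-censored survival with a proportional-hazards effect of the
#' dichotomized marker. The defaults mirror a 286-patient breast-cancer-style
#' cohort on a log2 expression scale (bimodal marker with modes near 5 and
#' 10, strong outcome concordance, HR 0.5 at the distribution's midpoint,
#' 30% censoring).
#'
#' @param n Cohort size, default 286.
#' @param seed Integer seed (required). Sub-seeds for the three generators
#'   are derived deterministically from it.
#' @param pi1,mu,sigma Mixture parameters, see [gen_bimodal_marker()].
#' @param link,intercept,slope,changepoint,flip_prob Outcome parameters, see
#'   [gen_binary_outcome()].
#' @param hr,baseline_rate,censoring Survival parameters, see
#'   [gen_survival()].
#' @param outcome,surv Set FALSE to omit the outcome or survival variables.
#' @return A [marker_dataset()].
#' @examples
#' d <- simulate_marker_dataset(100, seed = 7)
#' @export
simulate_marker_dataset <- function(n = 286, seed,
                                    pi1 = 0.5, mu = c(5, 10), sigma = c(1, 1),
                                    link = "logistic", intercept = -15,
                                    slope = 2, changepoint = 7.5,
                                    flip_prob = 0.1,
                                    hr = 0.5, baseline_rate = 0.1,
                                    censoring = 0.3,
                                    outcome = TRUE, surv = TRUE) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  s <- derive_seeds(seed, 3)
  x <- gen_bimodal_marker(n, pi1 = pi1, mu = mu, sigma = sigma, seed = s[1])
  y <- if (outcome) {
    gen_binary_outcome(x, link = link, intercept = intercept, slope = slope,
                       changepoint = changepoint, flip_prob = flip_prob,
                       seed = s[2])
  } else NULL
  sv <- if (surv) {
    gen_survival(x, changepoint = changepoint, hr = hr,
                 baseline_rate = baseline_rate, censoring = censoring,
                 seed = s[3])
  } else NULL
  suppressMessages(marker_dataset(
    x, outcome = y, time = sv$time, event = sv$event,
    ids = sprintf("P%04d", seq_len(n)), positive_level = if (outcome) 1 else NULL
  ))
}

# Deterministic 32-bit sub-seeds from a master seed.
derive_seeds <- function(seed, k) {
  with_preserved_seed(seed, sample.int(.Machine$integer.max, k))
}

#' Write a simulated cohort as a tab-separated fixture
#'
#' Serializes a [marker_dataset()] in the input dialect of [load_table()]:
#' one header row, one row per patient, tab-separated, "." decimal.
#'
#' @param dataset A [marker_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "marker_dataset"))
  df <- data.frame(
    id = if (is.null(dataset$ids)) seq_len(dataset$n) else dataset$ids,
    marker = dataset$marker
  )
  if (!is.null(dataset$outcome)) {
    df$outcome <- as.integer(dataset$outcome == "positive")
  }
  if (!is.null(dataset$time)) {
    df$time <- dataset$time
    df$event <- dataset$event
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
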