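# Independent brute-force oracles, deliberately written with plain loops and
# none of the package's scan machinery.

# every observed value that leaves both groups non-empty (min_group 1)
oracle_candidates <- function(x, min_group = 1) {
  vals <- sort(unique(x))
  ok <- logical(length(vals))
  for (i in seq_along(vals)) {
    ok[i] <- sum(x < vals[i]) >= min_group && sum(x >= vals[i]) >= min_group
  }
  vals[ok]
}

# per-candidate Fisher p / sensitivity / specificity, high predicts positive
oracle_binary_table <- function(x, y_pos) {
  cand <- oracle_candidates(x)
  out <- data.frame(cutoff = cand, p = NA_real_, sens = NA_real_, spec = NA_real_)
  for (i in seq_along(cand)) {
    hi <- x >= cand[i]
    tp <- sum(hi & y_pos); fn <- sum(!hi & y_pos)
    fp <- sum(hi & !y_pos); tn <- sum(!hi & !y_pos)
    m <- matrix(c(tp, fn, fp, tn), 2)
    out$p[i] <- if (any(rowSums(m) == 0) || any(colSums(m) == 0)) 1
                else stats::fisher.test(m)$p.value
    out$sens[i] <- tp / (tp + fn)
    out$spec[i] <- tn / (tn + fp)
  }
  out
}

# per-candidate log-rank p by direct survdiff calls
oracle_logrank_scan <- function(x, time, event) {
  cand <- oracle_candidates(x)
  p <- numeric(length(cand))
  for (i in seq_along(cand)) {
    g <- factor(x >= cand[i])
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    p[i] <- stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
  }
  data.frame(cutoff = cand, p = p)
}

# textbook log-rank from the O/E/V sums, no survival-package code
hand_logrank <- function(time, event, group) {
  g2 <- group == levels(factor(group))[2]
  ts <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n2 <- sum(at_risk & g2)
    d <- sum(time == t & event == 1)
    d2 <- sum(time == t & event == 1 & g2)
    o <- o + d2
    e <- e + d * n2 / n
    if (n > 1) v <- v + d * (n2 / n) * (1 - n2 / n) * (n - d) / (n - 1)
  }
  chisq <- (o - e)^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Cox partial log-likelihood for a binary covariate, no ties assumed
hand_cox_loglik <- function(beta, time, event, z) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * z[i] - log(sum(exp(beta * z[risk])))
  }
  ll
}

# small random instance with a binary outcome
rand_binary_instance <- function(seed, n = NULL) {
  set.seed(seed)
  n <- n %||% sample(10:60, 1)
  x <- round(rnorm(n), 1)
  while (length(unique(x)) < 2) x <- round(rnorm(n), 1)
  y <- rbinom(n, 1, plogis(0.8 * x))
  if (length(unique(y)) < 2) y[sample(n, 2)] <- c(0, 1)
  list(x = x, y = y)
}

# small random survival instance
rand_surv_instance <- function(seed, n = NULL) {
  set.seed(seed)
  n <- n %||% sample(20:60, 1)
  x <- round(rnorm(n), 1)
  while (length(unique(x)) < 2) x <- round(rnorm(x), 1)
  rate <- ifelse(x >= 0, 0.5, 1)
  t_ev <- rexp(n, rate)
  t_c <- rexp(n, 0.3)
  list(x = x, time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

quiet_dataset <- function(...) suppressMessages(marker_dataset(...))
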