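# Run `expr` under `set.seed(seed)` (when non-NULL) and restore the caller's
# RNG state afterwards, so library calls never perturb user simulations.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Lowest-cutoff tie-break used by every optimizer: index of the first
# minimum of `crit` in grid order.
which_min_first <- function(crit) {
  which(crit == min(crit))[1]
}
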