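# Closed-form logistic growth, the immune-free limit of the tumor subsystem.
logistic_solution <- function(x0, alpha, K, t) {
  K / (1 + (K / x0 - 1) * exp(-alpha * t))
}

# Draw a random parameter set within the admissible ranges, on each
# parameter's sampling scale. delta_t is kept away from 0 so that the
# tumor-free T level stays finite.
random_params <- function(min_delta_t = 1e-3) {
  rngs <- param_ranges()
  v <- purrr::pmap_dbl(rngs, function(parameter, low, high, baseline, scale) {
    if (scale == "log") {
      exp(stats::runif(1, log(low), log(high)))
    } else {
      stats::runif(1, low, high)
    }
  })
  names(v) <- rngs$parameter
  v[["delta_t"]] <- max(v[["delta_t"]], min_delta_t)
  validate_params(v)
}

# Day-`day` percent volume reduction from checkpoint blockade at (p1, p2),
# used as an independent check of grid_response / p2_threshold_for_reduction.
reduction_at <- function(p1, p2, day = 25, pars = baseline_params()) {
  pars[["p_1"]] <- p1
  pars[["p_2"]] <- p2
  v <- vapply(c("active", "blocked"), function(mode) {
    volume_at(integrate_tumor(pars, mode = mode, t_end = day, times = day), day)
  }, numeric(1))
  1 - v[["blocked"]] / v[["active"]]
}
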