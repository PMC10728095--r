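# Canonical parameter order shared with the C++ right-hand side.
.par_order <- c(
  "alpha_n", "alpha_m", "K", "delta_ns", "delta_ms", "delta_nf", "delta_mf",
  "kappa_0", "kappa_1", "kappa_2", "delta_t", "mu", "delta_n", "delta_m",
  "p_1", "p_2", "alpha_nt", "alpha_mt", "rho_p", "rho_l", "eps_c", "mu_PA",
  "k_TQ"
)

.par_baseline <- c(
  alpha_n  = 0.337,     alpha_m  = 0.337,     K        = 5e9,
  delta_ns = 4,         delta_ms = 4,         delta_nf = 2.5e-7,
  delta_mf = 2.5e-7,    kappa_0  = 2e7,       kappa_1  = 0.5,
  kappa_2  = 2.019e7,   delta_t  = 0.0412,    mu       = 2e4,
  delta_n  = 3.422e-10, delta_m  = 3.422e-10, p_1      = 0.92,
  p_2      = 0.33,      alpha_nt = 0.15,      alpha_mt = 0.15,
  rho_p    = 1.259e-11, rho_l    = 2.510e-11, eps_c    = 10,
  mu_PA    = 8.945,     k_TQ     = 1.296e-9
)

.par_low <- c(
  alpha_n = 0.05, alpha_m = 0.05, K = 3e9, delta_ns = 1, delta_ms = 1,
  delta_nf = 1e-8, delta_mf = 1e-8, kappa_0 = 1e6, kappa_1 = 0.01,
  kappa_2 = 1e6, delta_t = 0, mu = 5e3, delta_n = 1e-11, delta_m = 1e-11,
  p_1 = 0, p_2 = 0, alpha_nt = 0, alpha_mt = 0, rho_p = 1e-12, rho_l = 1e-12,
  eps_c = 1, mu_PA = 6.45, k_TQ = 1e-10
)

.par_high <- c(
  alpha_n = 0.6, alpha_m = 0.6, K = 6e9, delta_ns = 12, delta_ms = 12,
  delta_nf = 1e-6, delta_mf = 1e-6, kappa_0 = 1e8, kappa_1 = 1,
  kappa_2 = 1e8, delta_t = 0.5, mu = 1.5e5, delta_n = 1e-9, delta_m = 1e-9,
  p_1 = 1, p_2 = 1, alpha_nt = 0.5, alpha_mt = 0.5, rho_p = 1e-10,
  rho_l = 2e-10, eps_c = 50, mu_PA = 273, k_TQ = 1e-8
)

# Parameters whose admissible range spans >= 2 orders of magnitude are
# sampled log-uniformly in the virtual cohort; mu (1.5 decades) is also
# log-sampled so that recruitment strength is not concentrated in its top
# decade.
.par_scale <- ifelse(.par_low > 0 & .par_high / pmax(.par_low, .Machine$double.xmin) >= 100,
  "log", "linear"
)
names(.par_scale) <- names(.par_low)
.par_scale["mu"] <- "log"

#' Baseline model parameters
#'
#' Returns the full parameter set of the tumor-immune model at its baseline
#' (mouse-calibrated) values. The model tracks high-antigen tumor cells (N),
#' low-antigen tumor cells (M) and cytotoxic T cells (T); parameters cover
#' logistic tumor growth, the fast (perforin/granzyme, mass-action) and slow
#' (FasL, saturating) CTL killing channels, T-cell recruitment, antigen-driven
#' T-cell proliferation, and the PD-1/PD-L1 checkpoint suppression factor.
#'
#' @param ... named overrides of individual parameters, e.g. `p_1 = 1`.
#'   Unknown names are an error.
#' @return An object of class `ctl_params`: a named numeric vector with one
#'   entry per model parameter.
#' @examples
#' p <- baseline_params(p_2 = 0.5)
#' p[["p_2"]]
#' @export
baseline_params <- function(...) {
  over <- c(...)
  pars <- .par_baseline
  if (length(over)) {
    bad <- setdiff(names(over), .par_order)
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    pars[names(over)] <- as.numeric(over)
  }
  validate_params(pars)
}

#' Validate a parameter vector
#'
#' Checks completeness, positivity (all rates and concentrations must be
#' positive; `delta_t` may be zero at the lower end of its admissible range)
#' and that the fast-kill probabilities lie in \[0, 1\].
#'
#' @param pars named numeric vector with one entry per model parameter.
#' @return The validated vector with class `ctl_params`.
#' @export
validate_params <- function(pars) {
  pars <- unclass(pars)
  missing <- setdiff(.par_order, names(pars))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(pars), .par_order)
  if (length(extra)) {
    stop("unknown parameter(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  pars <- pars[.par_order]
  if (anyNA(pars) || any(!is.finite(pars))) {
    stop("parameters must be finite and non-missing", call. = FALSE)
  }
  probs <- c("p_1", "p_2")
  if (any(pars[probs] < 0 | pars[probs] > 1)) {
    stop("p_1 and p_2 must lie in [0, 1]", call. = FALSE)
  }
  # delta_t, mu, alpha_nt, alpha_mt may be zero (immune-free / no-recruitment
  # limits used by the analytical oracles); everything else must be positive
  strict <- setdiff(.par_order, c(probs, "delta_t", "mu", "alpha_nt", "alpha_mt"))
  if (any(pars[strict] <= 0)) {
    stop("all rate and concentration parameters must be strictly positive",
      call. = FALSE
    )
  }
  if (any(pars[c("delta_t", "mu", "alpha_nt", "alpha_mt")] < 0)) {
    stop("delta_t, mu, alpha_nt, alpha_mt must be non-negative", call. = FALSE)
  }
  structure(pars, class = "ctl_params")
}

#' Admissible parameter ranges
#'
#' The sampling range of every model parameter, together with the sampling
#' scale used by the virtual cohort (log-uniform for ranges spanning at least
#' two orders of magnitude, linear otherwise).
#'
#' @return A tibble with columns `parameter`, `low`, `high`, `baseline`,
#'   `scale`.
#' @export
param_ranges <- function() {
  tibble::tibble(
    parameter = .par_order,
    low = unname(.par_low[.par_order]),
    high = unname(.par_high[.par_order]),
    baseline = unname(.par_baseline[.par_order]),
    scale = unname(.par_scale[.par_order])
  )
}

#' Range of a single parameter
#'
#' @param name parameter name, e.g. `"mu"`.
#' @return Numeric vector `c(low, high)`.
#' @export
range_of <- function(name) {
  if (!name %in% .par_order) stop("unknown parameter: ", name, call. = FALSE)
  c(low = unname(.par_low[name]), high = unname(.par_high[name]))
}

#' @export
print.ctl_params <- function(x, ...) {
  cat("<ctl_params> tumor-immune model parameters\n")
  print(format(unclass(x), digits = 4), quote = FALSE)
  invisible(x)
}

#' Read / write a parameter configuration file
#'
#' A configuration file is a flat JSON object with one key per model
#' parameter. Unknown keys are an error; missing keys fall back to baseline
#' with a message naming each defaulted parameter.
#'
#' @param path file path.
#' @return `read_params()` returns a `ctl_params` vector; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- unlist(raw)
  bad <- setdiff(names(raw), .par_order)
  if (length(bad)) {
    stop("unknown parameter key(s) in config: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  missing <- setdiff(.par_order, names(raw))
  if (length(missing)) {
    message(
      "config omits ", length(missing), " parameter(s), using baseline: ",
      paste(missing, collapse = ", ")
    )
  }
  pars <- .par_baseline
  pars[names(raw)] <- as.numeric(raw)
  validate_params(pars)
}

#' @rdname read_params
#' @param pars a `ctl_params` vector.
#' @export
write_params <- function(pars, path) {
  pars <- validate_params(pars)
  jsonlite::write_json(as.list(unclass(pars)), path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
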