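# Non-parameter dimensions sampled for each virtual mouse. The initial
# tumor is fixed at 1 mm^3 (the standard inoculum); its phenotype split and
# the initial immune-to-tumor cell ratio are part of the hypercube.
.init_dims <- function(spec) {
  tibble::tibble(
    parameter = c("init_low_fraction", "init_T_ratio"),
    low = c(spec$init_low_fraction_range[1], spec$init_T_ratio_range[1]),
    high = c(spec$init_low_fraction_range[2], spec$init_T_ratio_range[2]),
    scale = c("linear", "log")
  )
}

#' Specify a virtual cohort
#'
#' A cohort is defined by its size, a seed, the per-parameter sampling
#' ranges (defaulting to the model's admissible ranges, log-uniform where
#' the range spans at least two decades), a fixed 1 mm^3 initial tumor, and
#' sampled initial composition and immune-to-tumor ratio.
#'
#' @param n cohort size.
#' @param seed RNG seed (mandatory: cohorts must be reproducible).
#' @param ranges tibble of parameter sampling ranges as from
#'   [param_ranges()]; must stay within the admissible bounds.
#' @param init_tumor_mm3 initial tumor volume (mm^3), fixed per mouse.
#' @param init_low_fraction_range range of the initial low-antigen fraction
#'   (sampled uniformly).
#' @param init_T_ratio_range range of the initial T-cell to tumor-cell ratio
#'   (sampled log-uniformly).
#' @return A `ctl_cohort_spec` list.
#' @export
cohort_spec <- function(n = 30000, seed = 1, ranges = param_ranges(),
                        init_tumor_mm3 = 1,
                        init_low_fraction_range = c(0, 1),
                        init_T_ratio_range = c(0.01, 1)) {
  if (n < 1) stop("cohort size must be at least 1", call. = FALSE)
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  full <- param_ranges()
  chk <- dplyr::left_join(ranges, full,
    by = "parameter",
    suffix = c("", "_adm")
  )
  if (any(chk$low < chk$low_adm - 1e-12 * abs(chk$low_adm)) ||
    any(chk$high > chk$high_adm + 1e-12 * abs(chk$high_adm))) {
    stop("sampling ranges must lie within the admissible parameter ranges",
      call. = FALSE
    )
  }
  structure(
    list(
      n = as.integer(n), seed = as.integer(seed), ranges = ranges,
      init_tumor_mm3 = init_tumor_mm3,
      init_low_fraction_range = init_low_fraction_range,
      init_T_ratio_range = init_T_ratio_range
    ),
    class = "ctl_cohort_spec"
  )
}

# One Latin hypercube dimension: exactly one draw per equal-probability
# stratum on the sampling scale.
.lhs_dim <- function(n, low, high, scale) {
  if (low == high) {
    message("degenerate range [", low, ", ", high, "]: dimension held constant")
    return(rep(low, n))
  }
  u <- (sample.int(n) - stats::runif(n)) / n
  if (scale == "log") {
    exp(log(low) + u * (log(high) - log(low)))
  } else {
    low + u * (high - low)
  }
}

#' Sample a Latin hypercube virtual cohort
#'
#' Draws `spec$n` virtual mice by Latin hypercube sampling over all model
#' parameters plus the initial low-antigen fraction and initial
#' immune-to-tumor cell ratio: in every dimension exactly one mouse falls in
#' each of the `n` equal-probability strata of the sampling scale.
#' Deterministic for a fixed seed.
#'
#' @param spec a `ctl_cohort_spec`.
#' @return Tibble with one row per mouse: `id`, every model parameter,
#'   `init_low_fraction`, `init_T_ratio`, `init_tumor_mm3`.
#' @export
sample_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "ctl_cohort_spec"))
  dims <- dplyr::bind_rows(
    spec$ranges[, c("parameter", "low", "high", "scale")],
    .init_dims(spec)
  )
  cols <- .with_seed(spec$seed, {
    purrr::pmap(
      dims,
      function(parameter, low, high, scale) .lhs_dim(spec$n, low, high, scale)
    )
  })
  names(cols) <- dims$parameter
  out <- tibble::as_tibble(cols)
  out <- dplyr::mutate(out,
    id = dplyr::row_number(),
    init_tumor_mm3 = spec$init_tumor_mm3, .before = 1
  )
  attr(out, "spec") <- spec
  out
}

#' Simulate a virtual cohort under one or both checkpoint modes
#'
#' Integrates every mouse from its own parameters and initial conditions and
#' records tumor volume, composition and the clinical outcome at each
#' readout day. Integration failures are flagged and excluded from
#' probabilities; more than 1% failures aborts (a solver misconfiguration,
#' not biology).
#'
#' @param cohort tibble from [sample_cohort()].
#' @param modes checkpoint modes to run.
#' @param days readout days.
#' @param rtol,atol solver tolerances (slightly looser than single-run
#'   defaults; cohort-level fractions are insensitive to this, see the
#'   package vignette).
#' @return Tibble of class `ctl_cohort_result`: one row per mouse, mode and
#'   day with `volume_mm3`, `low_antigen_fraction`, `outcome`, `clamped`,
#'   `ok`.
#' @export
run_cohort <- function(cohort, modes = c("active", "blocked"),
                       days = c(25, 150), rtol = 1e-6, atol = 1e-2) {
  modes <- match.arg(modes, several.ok = TRUE)
  days <- sort(days)
  n <- nrow(cohort)
  par_mat <- as.matrix(cohort[, .par_order])
  t_out <- c(0, days)
  clamp_cells <- mm3_to_cells(.detection_mm3)
  n_days <- length(days)
  res <- vector("list", length(modes))
  names(res) <- modes
  n_failed <- 0L
  for (mode in modes) {
    blocked <- mode == "blocked"
    vol <- matrix(NA_real_, n, n_days)
    frac <- matrix(NA_real_, n, n_days)
    clam <- matrix(NA, n, n_days)
    ok <- rep(TRUE, n)
    for (i in seq_len(n)) {
      cells <- mm3_to_cells(cohort$init_tumor_mm3[i])
      y0 <- c(
        (1 - cohort$init_low_fraction[i]) * cells,
        cohort$init_low_fraction[i] * cells,
        cohort$init_T_ratio[i] * cells
      )
      r <- integrate_cpp(par_mat[i, ], y0,
        blocked = blocked, t_out = t_out,
        rtol = rtol, atol = atol, clamp_cells = clamp_cells
      )
      if (r$status != 0) {
        ok[i] <- FALSE
        n_failed <- n_failed + 1L
        next
      }
      st <- r$states[-1, , drop = FALSE]
      tot <- st[, 1] + st[, 2]
      v <- tot / .cells_per_mm3
      cl <- !is.na(r$clamped_at) & days >= r$clamped_at
      v[cl] <- .detection_mm3
      vol[i, ] <- v
      frac[i, ] <- ifelse(tot > 0, st[, 2] / tot, NA_real_)
      clam[i, ] <- cl
    }
    res[[mode]] <- tibble::tibble(
      id = rep(cohort$id, each = n_days),
      mode = mode,
      day = rep(days, n),
      volume_mm3 = as.vector(t(vol)),
      low_antigen_fraction = as.vector(t(frac)),
      clamped = as.vector(t(clam)),
      ok = rep(ok, each = n_days)
    )
  }
  out <- dplyr::bind_rows(res)
  # a clamped run crossed below the detection limit: clinically eliminated,
  # even though its reported volume is held at exactly 0.1 mm^3
  out$outcome <- classify_clinical(pmax(out$volume_mm3, 0))
  out$outcome[out$clamped %in% TRUE] <- "clinical_elimination"
  out$outcome[!out$ok] <- NA
  frac_failed <- n_failed / (n * length(modes))
  if (frac_failed > 0.01) {
    stop(sprintf(
      "%.1f%% of cohort integrations failed; check solver settings",
      100 * frac_failed
    ), call. = FALSE)
  }
  if (n_failed > 0) {
    message(n_failed, " integration(s) failed and are excluded")
  }
  attr(out, "n") <- n
  attr(out, "n_failed") <- n_failed
  class(out) <- c("ctl_cohort_result", class(out))
  out
}

#' Clinical outcome probabilities in a cohort
#'
#' Fractions of the (non-failed) cohort in each clinical outcome, with
#' binomial standard errors.
#'
#' @param result a `ctl_cohort_result`.
#' @param modes,days optional filters.
#' @return Tibble with `mode`, `day`, `outcome`, `n`, `p`, `se`.
#' @export
outcome_probabilities <- function(result, modes = NULL, days = NULL) {
  df <- dplyr::filter(result, .data$ok)
  if (!is.null(modes)) df <- dplyr::filter(df, .data$mode %in% modes)
  if (!is.null(days)) df <- dplyr::filter(df, .data$day %in% days)
  if (!nrow(df)) stop("no rows selected", call. = FALSE)
  df |>
    dplyr::count(.data$mode, .data$day, .data$outcome, .drop = FALSE) |>
    dplyr::group_by(.data$mode, .data$day) |>
    dplyr::mutate(
      p = .data$n / sum(.data$n),
      se = sqrt(.data$p * (1 - .data$p) / sum(.data$n))
    ) |>
    dplyr::ungroup()
}

.dim_range <- function(cohort, parameter) {
  spec <- attr(cohort, "spec")
  dims <- dplyr::bind_rows(
    param_ranges()[, c("parameter", "low", "high", "scale")],
    if (!is.null(spec)) .init_dims(spec)
  )
  row <- dims[dims$parameter == parameter, ]
  if (!nrow(row)) stop("unknown cohort dimension: ", parameter, call. = FALSE)
  row
}

#' Outcome probabilities across bins of one parameter
#'
#' Splits the cohort into `n_bins` equal-width bins of a sampled parameter
#' (width measured on its sampling scale) and reports the outcome
#' probabilities within each bin.
#'
#' @param result a `ctl_cohort_result`.
#' @param cohort the sampled cohort the result came from.
#' @param parameter cohort dimension to bin, e.g. `"alpha_nt"`.
#' @param mode,day which run to summarise.
#' @param n_bins number of bins (>= 2).
#' @return Tibble with `bin`, `bin_low`, `bin_high`, `outcome`, `n`, `p`.
#' @export
binned_outcome_rates <- function(result, cohort, parameter, mode, day,
                                 n_bins = 5) {
  if (n_bins < 2) stop("need at least 2 bins", call. = FALSE)
  rng <- .dim_range(cohort, parameter)
  edges <- if (rng$scale == "log") {
    exp(seq(log(rng$low), log(rng$high), length.out = n_bins + 1))
  } else {
    seq(rng$low, rng$high, length.out = n_bins + 1)
  }
  df <- dplyr::filter(result, .data$ok, .data$mode == !!mode, .data$day == !!day)
  df <- dplyr::left_join(df, cohort[, c("id", parameter)], by = "id")
  df$bin <- cut(df[[parameter]], edges, include.lowest = TRUE, labels = FALSE)
  out <- df |>
    dplyr::count(.data$bin, .data$outcome, .drop = FALSE) |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(p = .data$n / sum(.data$n)) |> # NaN marks an empty bin
    dplyr::ungroup() |>
    dplyr::mutate(p = ifelse(is.nan(.data$p), NA_real_, .data$p)) |>
    dplyr::mutate(
      bin_low = edges[.data$bin], bin_high = edges[.data$bin + 1],
      parameter = parameter, .before = 1
    )
  out
}

#' Parameter distribution conditioned on outcome
#'
#' For each clinical outcome with at least 10 mice, the median, quartiles
#' and a kernel density sketch (128-point grid) of one sampled parameter --
#' the tabular counterpart of an outcome-stratified violin plot.
#'
#' @inheritParams binned_outcome_rates
#' @return List with `summary` (median/quartiles per outcome) and `density`
#'   (outcome, x, density) tibbles.
#' @export
outcome_conditioned_summary <- function(result, cohort, parameter, mode, day) {
  rng <- .dim_range(cohort, parameter)
  df <- dplyr::filter(result, .data$ok, .data$mode == !!mode, .data$day == !!day)
  df <- dplyr::left_join(df, cohort[, c("id", parameter)], by = "id")
  kept <- df |>
    dplyr::group_by(.data$outcome) |>
    dplyr::filter(dplyr::n() >= 10) |>
    dplyr::ungroup()
  dropped <- setdiff(levels(df$outcome), unique(as.character(kept$outcome)))
  if (length(dropped)) {
    message(
      "outcome(s) with < 10 mice omitted: ",
      paste(dropped, collapse = ", ")
    )
  }
  x <- kept[[parameter]]
  summary <- kept |>
    dplyr::group_by(.data$outcome) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data[[parameter]]),
      q1 = stats::quantile(.data[[parameter]], 0.25),
      q3 = stats::quantile(.data[[parameter]], 0.75),
      .groups = "drop"
    ) |>
    dplyr::mutate(parameter = parameter, .before = 1)
  density <- kept |>
    dplyr::group_by(.data$outcome) |>
    dplyr::group_modify(function(g, key) {
      d <- stats::density(g[[parameter]],
        n = 128, from = rng$low,
        to = rng$high
      )
      tibble::tibble(x = d$x, density = d$y)
    }) |>
    dplyr::ungroup()
  list(summary = summary, density = density)
}
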