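# Detection limit of small-animal imaging: tumors below 0.1 mm^3 are
# clinically undetectable; simulations clamp there.
.detection_mm3 <- 0.1
.escape_mm3 <- 500

#' Homeostatic T-cell level
#'
#' The tumor-free steady state of the T compartment, `mu / delta_t`. Used as
#' the default initial T-cell count for figure-style simulations.
#'
#' @param pars a `ctl_params` vector.
#' @return T-cell count (cells).
#' @export
homeostatic_T <- function(pars) {
  pars <- validate_params(pars)
  if (pars[["delta_t"]] <= 0) {
    stop("homeostatic T level undefined for delta_t <= 0", call. = FALSE)
  }
  unname(pars[["mu"]] / pars[["delta_t"]])
}

#' Default inoculum state
#'
#' A 1 mm^3 tumor (1e6 cells) split 50/50 between the high- and low-antigen
#' phenotypes. By default no tumor-specific CTLs are present at inoculation
#' (`T_0 = 0`): effectors arrive through the recruitment term `mu`. Pass
#' `T_0 = homeostatic_T(pars)` to start from the tumor-free immune
#' steady state instead.
#'
#' @param pars a `ctl_params` vector.
#' @param volume_mm3 initial tumor volume.
#' @param low_fraction initial low-antigen fraction of the tumor.
#' @param T_0 initial CTL count.
#' @return A state vector as produced by [system_state()].
#' @export
inoculum_state <- function(pars, volume_mm3 = 1, low_fraction = 0.5, T_0 = 0) {
  cells <- mm3_to_cells(volume_mm3)
  system_state(
    N = (1 - low_fraction) * cells, M = low_fraction * cells,
    T_ = T_0
  )
}

#' Integrate the tumor-immune model
#'
#' Adaptive Dormand-Prince 5(4) integration of the three-compartment system.
#' When `clamp = TRUE` the run carries a terminal-style event: the first time
#' total tumor volume falls to the 0.1 mm^3 detection limit, N and M are
#' frozen (total reported as exactly 0.1 mm^3 from then on) while T continues
#' to relax; the trajectory records the clamp day.
#'
#' @param pars a `ctl_params` vector.
#' @param init state vector `c(N, M, T)`; default [inoculum_state()].
#' @param mode `"active"` or `"blocked"` checkpoint.
#' @param t_end horizon in days.
#' @param times output times; defaults to ~301 points plus days 25 and 150
#'   when within the horizon. Always includes 0 and `t_end`.
#' @param clamp apply the clinical detection-limit clamp?
#' @param rtol,atol solver relative / absolute (cells) tolerances.
#' @return A tibble of class `ctl_trajectory` with columns `time`, `N`, `M`,
#'   `T`, `volume_mm3`, `low_antigen_fraction`, `clamped`; attributes
#'   `clamped_at`, `mode`, `pars`.
#' @examples
#' p <- baseline_params()
#' tr <- integrate_tumor(p, mode = "blocked", t_end = 25)
#' volume_at(tr, 25)
#' @export
integrate_tumor <- function(pars, init = NULL, mode = c("active", "blocked"),
                            t_end = 150, times = NULL, clamp = TRUE,
                            rtol = 1e-8, atol = 1e-2) {
  mode <- .match_mode(mode)
  pars <- validate_params(pars)
  if (is.null(init)) init <- inoculum_state(pars)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (any(init[c("N", "M", "T")] < 0)) {
    stop("initial state must be non-negative", call. = FALSE)
  }
  if (is.null(times)) {
    times <- sort(unique(c(seq(0, t_end, length.out = 301), 25, 150)))
    times <- times[times <= t_end]
  } else {
    times <- sort(unique(c(0, times, t_end)))
    if (any(times < 0)) stop("output times must be non-negative", call. = FALSE)
  }
  res <- integrate_cpp(
    unclass(pars), unname(init[c("N", "M", "T")]),
    blocked = (mode == "blocked"), t_out = times, rtol = rtol, atol = atol,
    clamp_cells = if (clamp) mm3_to_cells(.detection_mm3) else -1
  )
  if (res$status != 0) {
    stop(structure(
      class = c("ctldyn_integration_error", "error", "condition"),
      list(
        message = sprintf(
          "integration failed at t = %.4g (last state N = %.4g, M = %.4g, T = %.4g)",
          res$t_last, res$y_last[1], res$y_last[2], res$y_last[3]
        ),
        call = sys.call(-1), t_last = res$t_last, y_last = res$y_last
      )
    ))
  }
  st <- res$states
  clamped_at <- res$clamped_at
  is_clamped <- !is.na(clamped_at) & times >= clamped_at
  vol <- cells_to_mm3(st[, 1] + st[, 2])
  vol[is_clamped] <- .detection_mm3
  tot <- st[, 1] + st[, 2]
  out <- tibble::tibble(
    time = times, N = st[, 1], M = st[, 2], T = st[, 3],
    volume_mm3 = vol,
    low_antigen_fraction = ifelse(tot > 0, st[, 2] / tot, NA_real_),
    clamped = is_clamped
  )
  attr(out, "clamped_at") <- clamped_at
  attr(out, "mode") <- mode
  attr(out, "pars") <- pars
  class(out) <- c("ctl_trajectory", class(out))
  out
}

#' Read a trajectory at a given day
#'
#' Exact lookup when the day is a stored sample (all requested days are);
#' linear interpolation between neighbouring samples otherwise.
#'
#' @param traj a `ctl_trajectory`.
#' @param day day to read.
#' @param what column to read.
#' @return Numeric scalar.
#' @export
volume_at <- function(traj, day, what = "volume_mm3") {
  i <- which(abs(traj$time - day) <= 1e-9 * max(1, day))
  if (length(i)) {
    return(traj[[what]][i[1]])
  }
  if (day < min(traj$time) || day > max(traj$time)) {
    stop("day outside the integrated horizon", call. = FALSE)
  }
  stats::approx(traj$time, traj[[what]], xout = day)$y
}

#' Classify a tumor volume at a clinical timepoint
#'
#' Clinical elimination below the 0.1 mm^3 imaging detection limit, dormancy
#' in \[0.1, 500\] mm^3, escape above 500 mm^3.
#'
#' @param volume_mm3 tumor volume(s) in mm^3.
#' @return Factor with levels `clinical_elimination`, `dormancy`, `escape`.
#' @export
classify_clinical <- function(volume_mm3) {
  if (any(volume_mm3 < 0, na.rm = TRUE)) {
    stop("tumor volume must be non-negative", call. = FALSE)
  }
  lab <- ifelse(volume_mm3 < .detection_mm3, "clinical_elimination",
    ifelse(volume_mm3 <= .escape_mm3, "dormancy", "escape")
  )
  factor(lab, levels = c("clinical_elimination", "dormancy", "escape"))
}

#' Low-antigen fraction of a tumor
#'
#' @param state a state vector `c(N, M, T)` or anything with named entries
#'   `N` and `M`.
#' @return `M / (N + M)`, or `NA` for an empty tumor.
#' @export
low_antigen_fraction <- function(state) {
  N <- state[["N"]]
  M <- state[["M"]]
  if (N + M <= 0) {
    return(NA_real_)
  }
  unname(M / (N + M))
}

#' Checkpoint response over a (p1, p2) grid
#'
#' Simulates every combination of fast-kill probabilities under both an
#' active and a blocked checkpoint from the standard 1 mm^3 / 50-50
#' inoculum, and records tumor volume, composition and the blockade-induced
#' percent volume reduction `1 - V_blocked / V_active` at each requested day.
#'
#' @param pars a `ctl_params` vector (p_1, p_2 entries are overridden).
#' @param p1_values,p2_values grids of fast-kill probabilities in \[0, 1\].
#' @param days readout days.
#' @return Tibble of class `ctl_grid` with columns `p1`, `p2`, `day`, `mode`,
#'   `volume_mm3`, `low_antigen_fraction`, `percent_reduction`, `clamped`,
#'   `failed`.
#' @export
grid_response <- function(pars = baseline_params(),
                          p1_values = seq(0, 1, by = 0.1),
                          p2_values = seq(0, 1, by = 0.1),
                          days = c(25, 150)) {
  if (any(c(p1_values, p2_values) < 0 | c(p1_values, p2_values) > 1)) {
    stop("p1 and p2 grids must lie in [0, 1]", call. = FALSE)
  }
  pars <- validate_params(pars)
  t_end <- max(days)
  cells <- expand.grid(p1 = p1_values, p2 = p2_values, KEEP.OUT.ATTRS = FALSE)
  rows <- purrr::pmap(cells, function(p1, p2) {
    pij <- pars
    pij[["p_1"]] <- p1
    pij[["p_2"]] <- p2
    run <- function(mode) {
      tryCatch(
        integrate_tumor(pij, mode = mode, t_end = t_end, times = days),
        ctldyn_integration_error = function(e) NULL
      )
    }
    tr <- list(active = run("active"), blocked = run("blocked"))
    purrr::map_dfr(days, function(d) {
      v <- purrr::map_dbl(tr, function(x) if (is.null(x)) NA_real_ else volume_at(x, d))
      f <- purrr::map_dbl(tr, function(x) {
        if (is.null(x)) NA_real_ else volume_at(x, d, "low_antigen_fraction")
      })
      cl <- purrr::map_lgl(tr, function(x) {
        if (is.null(x)) NA else volume_at(x, d, "clamped") > 0
      })
      red <- if (all(is.finite(v))) 1 - v[["blocked"]] / v[["active"]] else NA_real_
      tibble::tibble(
        p1 = p1, p2 = p2, day = d, mode = c("active", "blocked"),
        volume_mm3 = unname(v), low_antigen_fraction = unname(f),
        percent_reduction = red, clamped = unname(cl),
        failed = purrr::map_lgl(tr, is.null)
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ctl_grid", class(out))
  out
}

#' Smallest p2 achieving a target blockade reduction
#'
#' For a fixed `p1`, finds by bisection the smallest low-antigen fast-kill
#' probability `p2` such that checkpoint blockade reduces the day-`day` tumor
#' volume by at least `target` relative to the active checkpoint. Percent
#' reduction is checked for monotonicity in `p2` on a coarse grid first.
#'
#' @param p1 fixed high-antigen fast-kill probability.
#' @param target target fractional reduction in (0, 1), e.g. 0.75.
#' @param pars a `ctl_params` vector.
#' @param day readout day.
#' @param tol bisection tolerance on p2.
#' @return The threshold `p2` in \[0, 1\], or `NA` if the target is
#'   unattainable at `p2 = 1`.
#' @export
p2_threshold_for_reduction <- function(p1, target = 0.75,
                                       pars = baseline_params(), day = 25,
                                       tol = 1e-3) {
  if (target < 0 || target >= 1) stop("target must be in [0, 1)", call. = FALSE)
  pars <- validate_params(pars)
  red <- function(p2) {
    pij <- pars
    pij[["p_1"]] <- p1
    pij[["p_2"]] <- p2
    v <- vapply(c("active", "blocked"), function(mode) {
      volume_at(integrate_tumor(pij, mode = mode, t_end = day, times = day), day)
    }, numeric(1))
    1 - v[["blocked"]] / v[["active"]]
  }
  coarse_p <- seq(0, 1, by = 0.25)
  coarse <- vapply(coarse_p, red, numeric(1))
  if (any(diff(coarse) < -0.02)) {
    stop("percent reduction is not monotone in p2 here; use grid_response()",
      call. = FALSE
    )
  }
  if (coarse[1] >= target) {
    return(0)
  }
  if (coarse[length(coarse)] < target) {
    return(NA_real_)
  }
  lo <- 0
  hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (red(mid) >= target) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
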