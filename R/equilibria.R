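# Steady-state (bifurcation) outcome thresholds, in cells: a persistent
# steady state below 500 mm^3 is dormancy, at/above it escape; elimination
# is an exactly tumor-free state. These are distinct from the *clinical*
# thresholds of classify_clinical(), which include the 0.1 mm^3 detection
# limit.
.escape_cells <- 5e8
.zero_cells <- 0.5
.tol_eig <- 1e-8

# T-cell level at equilibrium given the tumor burden: the T equation is
# linear in T, so T* = mu / (delta_t + delta_n*N + delta_m*M - prolif).
# A non-positive denominator means no finite positive T equilibrium exists
# for that tumor burden (NA), except when mu = 0 where T* = 0 always solves.
.T_of <- function(p, N, M) {
  denom <- p$delta_t + p$delta_n * N + p$delta_m * M -
    p$alpha_nt * N / (p$kappa_2 + N) - p$alpha_mt * M / (p$kappa_2 + M)
  if (p$mu == 0) {
    return(0)
  }
  if (denom <= 0) {
    return(NA_real_)
  }
  p$mu / denom
}

.F_of <- function(p, N, M, T_, mode) {
  if (mode == "blocked") {
    return(1)
  }
  1 / (1 + p$rho_p * T_ * p$rho_l * (T_ + p$eps_c * (N + M)) / p$k_TQ)
}

.kill_per_capita <- function(p, T_, fast_rate, slow_rate, prob, tumor = 0) {
  prob * fast_rate * T_ +
    (1 - prob) * slow_rate * T_ / (p$kappa_0 + tumor + p$kappa_1 * T_)
}

# Per-capita net growth of each tumor phenotype at its own-boundary branch
.g_N <- function(p, N, M, mode) {
  T_ <- .T_of(p, N, M)
  if (is.na(T_)) {
    return(NA_real_)
  }
  F_ <- .F_of(p, N, M, T_, mode)
  p$alpha_n * (1 - (N + M) / p$K) -
    F_ * .kill_per_capita(p, T_, p$delta_nf, p$delta_ns, p$p_1, N + M)
}

.g_M <- function(p, N, M, mode) {
  T_ <- .T_of(p, N, M)
  if (is.na(T_)) {
    return(NA_real_)
  }
  F_ <- .F_of(p, N, M, T_, mode)
  p$alpha_m * (1 - (N + M) / p$K) -
    F_ * .kill_per_capita(p, T_, p$delta_mf, p$delta_ms, p$p_2, N + M)
}

.make_equilibrium <- function(pars, state, mode, branch) {
  y <- unname(state)
  res <- max(abs(.rhs_smooth(pars, y, mode)))
  J <- numDeriv::jacobian(function(x) .rhs_smooth(pars, x, mode), y)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  stability <- if (all(re < -.tol_eig)) {
    "stable"
  } else if (any(re > .tol_eig)) {
    "unstable"
  } else {
    "marginal"
  }
  list(
    state = c(N = y[1], M = y[2], T = y[3]), residual = res,
    eigenvalues = ev, stability = stability, branch = branch
  )
}

#' Tumor-free equilibrium
#'
#' The model always has the tumor-free state `(0, 0, mu/delta_t)`. Its
#' Jacobian is triangular there, so the eigenvalues are available in closed
#' form: `-delta_t` for the T direction and, for each phenotype, its
#' intrinsic growth rate minus the checkpoint-scaled per-capita kill rate at
#' the homeostatic T level. The sign of the tumor eigenvalues decides whether
#' a small inoculum can invade.
#'
#' @param pars a `ctl_params` vector.
#' @param mode `"active"` or `"blocked"`.
#' @return An equilibrium: list with `state`, `residual`, `eigenvalues`,
#'   `stability`, `branch`.
#' @export
tumor_free_equilibrium <- function(pars, mode = c("active", "blocked")) {
  mode <- .match_mode(mode)
  pars <- validate_params(pars)
  p <- as.list(unclass(pars))
  if (p$delta_t <= 0 && p$mu > 0) {
    stop("tumor-free equilibrium requires delta_t > 0", call. = FALSE)
  }
  T_star <- if (p$mu == 0) 0 else p$mu / p$delta_t
  F_star <- .F_of(p, 0, 0, T_star, mode)
  lam_N <- p$alpha_n - F_star * .kill_per_capita(p, T_star, p$delta_nf, p$delta_ns, p$p_1)
  lam_M <- p$alpha_m - F_star * .kill_per_capita(p, T_star, p$delta_mf, p$delta_ms, p$p_2)
  lam_T <- -p$delta_t
  ev <- c(lam_N, lam_M, lam_T)
  re <- ev
  stability <- if (all(re < -.tol_eig)) {
    "stable"
  } else if (any(re > .tol_eig)) {
    "unstable"
  } else {
    "marginal"
  }
  list(
    state = c(N = 0, M = 0, T = T_star),
    residual = max(abs(.rhs_smooth(pars, c(0, 0, T_star), mode))),
    eigenvalues = as.complex(ev), stability = stability, branch = "tumor_free"
  )
}

# All roots of a scalar function over a log-spaced grid of N, by sign-change
# bracketing plus Newton polishing. Returns the tumor burden at each root.
#
# The domain has forbidden segments (no finite T equilibrium, fun = NA); as
# the burden approaches such a boundary the T level diverges and fun can
# plunge, hiding a root between the last finite grid point and the
# singularity. Those boundary brackets are refined by bisection on the
# domain indicator before root bracketing.
.scan_roots <- function(fun, n_points, upper) {
  xs <- 10^seq(0, log10(upper), length.out = n_points)
  vals <- vapply(xs, fun, numeric(1))
  # tighten each finite<->NA bracket onto the domain boundary
  extra_x <- numeric(0)
  extra_v <- numeric(0)
  for (i in seq_len(length(xs) - 1)) {
    if (is.na(vals[i]) == is.na(vals[i + 1])) next
    lo <- xs[i]
    hi <- xs[i + 1]
    lo_fin <- !is.na(vals[i])
    for (k in 1:60) {
      mid <- sqrt(lo * hi)
      mid_na <- is.na(fun(mid))
      if (mid_na == lo_fin) hi <- mid else lo <- mid # shrink towards boundary
    }
    xb <- if (lo_fin) lo else hi # innermost point still inside the domain
    vb <- fun(xb)
    if (!is.na(vb)) {
      extra_x <- c(extra_x, xb)
      extra_v <- c(extra_v, vb)
    }
  }
  if (length(extra_x)) {
    ord <- order(c(xs, extra_x))
    vals <- c(vals, extra_v)[ord]
    xs <- c(xs, extra_x)[ord]
  }
  roots <- numeric(0)
  for (i in seq_len(length(xs) - 1)) {
    v1 <- vals[i]
    v2 <- vals[i + 1]
    if (is.na(v1) || is.na(v2)) next
    if (v1 == 0) roots <- c(roots, xs[i])
    if (v1 * v2 < 0) {
      r <- tryCatch(
        stats::uniroot(fun, c(xs[i], xs[i + 1]), tol = 1e-12 * xs[i + 1])$root,
        error = function(e) NA_real_
      )
      if (!is.na(r)) {
        # polish: secant refinement on the per-capita growth rate
        for (k in 1:8) {
          fr <- fun(r)
          if (!is.finite(fr) || abs(fr) < 1e-14) break
          h <- r * 1e-7
          df <- (fun(r + h) - fun(r - h)) / (2 * h)
          if (!is.finite(df) || df == 0) break
          step <- fr / df
          if (!is.finite(step)) break
          r <- max(r - step, .Machine$double.eps)
        }
        roots <- c(roots, r)
      }
    }
  }
  roots
}

#' Find all equilibria of the model
#'
#' Exploits the model structure rather than blind multistart: on each
#' invariant boundary branch (`N = 0`, `M = 0`) the T equation is solved in
#' closed form given the tumor burden, reducing the branch to a scalar
#' root-find that is scanned exhaustively on a log grid of `n_starts` points
#' up to `10 * K`. Interior (both phenotypes positive) equilibria, which
#' exist only when the two per-capita kill rates balance, are searched by
#' seeded multistart Newton iteration. The tumor-free state is always
#' included.
#'
#' @param pars a `ctl_params` vector.
#' @param mode `"active"` or `"blocked"`.
#' @param n_starts scan resolution per boundary branch and number of interior
#'   Newton starts.
#' @param seed seed for the interior-branch starts.
#' @param interior search for interior equilibria?
#' @return An object of class `ctl_equilibria`: list of equilibria, with the
#'   call metadata in attributes. Use [tidy()] for a tabular view.
#' @export
find_equilibria <- function(pars, mode = c("active", "blocked"),
                            n_starts = 400, seed = 1, interior = TRUE) {
  mode <- .match_mode(mode)
  pars <- validate_params(pars)
  p <- as.list(unclass(pars))
  upper <- 10 * p$K
  eqs <- list(tumor_free_equilibrium(pars, mode))

  roots_N <- .scan_roots(function(N) .g_N(p, N, 0, mode), n_starts, upper)
  for (N in roots_N) {
    T_ <- .T_of(p, N, 0)
    if (!is.na(T_) && T_ >= 0) {
      eqs <- c(eqs, list(.make_equilibrium(pars, c(N, 0, T_), mode, "N_only")))
    }
  }
  roots_M <- .scan_roots(function(M) .g_M(p, 0, M, mode), n_starts, upper)
  for (M in roots_M) {
    T_ <- .T_of(p, 0, M)
    if (!is.na(T_) && T_ >= 0) {
      eqs <- c(eqs, list(.make_equilibrium(pars, c(0, M, T_), mode, "M_only")))
    }
  }

  if (interior) {
    eqs <- c(eqs, .interior_equilibria(pars, p, mode, n_starts, seed))
  }

  # drop non-converged roots, deduplicate at relative distance 1e-6
  eqs <- purrr::keep(eqs, function(e) {
    e$residual <= 1e-6 * max(1, sqrt(sum(e$state^2)))
  })
  kept <- list()
  for (e in eqs) {
    dup <- purrr::some(kept, function(k) {
      sc <- max(1, sqrt(sum(k$state^2)))
      sqrt(sum((k$state - e$state)^2)) / sc < 1e-6
    })
    if (!dup) kept <- c(kept, list(e))
  }
  structure(kept,
    class = "ctl_equilibria", mode = mode, pars = pars,
    n_starts = n_starts, seed = seed
  )
}

.interior_equilibria <- function(pars, p, mode, n_starts, seed) {
  fn <- function(x) {
    N <- exp(x[1])
    M <- exp(x[2])
    c(.g_N(p, N, M, mode), .g_M(p, N, M, mode))
  }
  out <- list()
  rng <- .with_seed(seed, matrix(stats::runif(2 * n_starts), ncol = 2))
  lo <- 0
  hi <- log(10 * p$K)
  for (i in seq_len(nrow(rng))) {
    x <- lo + rng[i, ] * (hi - lo)
    ok <- TRUE
    for (it in 1:50) {
      f <- fn(x)
      if (anyNA(f) || any(!is.finite(f))) {
        ok <- FALSE
        break
      }
      if (max(abs(f)) < 1e-13) break
      J <- tryCatch(numDeriv::jacobian(fn, x), error = function(e) NULL)
      if (is.null(J) || anyNA(J) || any(!is.finite(J)) || abs(det(J)) < 1e-300 ||
        1 / kappa(J) < 1e-14) {
        ok <- FALSE
        break
      }
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step)) {
        ok <- FALSE
        break
      }
      step <- pmin(pmax(step, -2), 2) # damp
      x <- x - step
      if (x[1] > hi + 5 || x[2] > hi + 5 || x[1] < -40 || x[2] < -40) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    f <- fn(x)
    if (anyNA(f) || max(abs(f)) > 1e-10) next
    N <- exp(x[1])
    M <- exp(x[2])
    if (N < .zero_cells || M < .zero_cells) next
    T_ <- .T_of(p, N, M)
    if (is.na(T_) || T_ < 0) next
    out <- c(out, list(.make_equilibrium(pars, c(N, M, T_), mode, "interior")))
  }
  out
}

.steady_label <- function(total_cells) {
  if (total_cells <= .zero_cells) {
    "elimination"
  } else if (total_cells < .escape_cells) {
    "dormancy"
  } else {
    "escape"
  }
}

#' Classify the long-run outcome structure of a parameter set
#'
#' Maps every *stable* equilibrium to a steady-state outcome (elimination:
#' no tumor; dormancy: below 500 mm^3; escape: at/above 500 mm^3). The
#' outcome set is their union; the regime is bistable when two different
#' outcomes coexist. The composition of the persistent state records which
#' phenotype survives (the model's persistent states are single-phenotype).
#'
#' @inheritParams find_equilibria
#' @param probe_cycles also integrate from each unstable persistent
#'   equilibrium (nudged by 1%) to detect stable limit cycles -- oscillatory
#'   dormancy -- that equilibrium enumeration cannot represent.
#' @param fallback what to do when no stable equilibrium is found:
#'   `"error"`, or `"simulate"` to label outcomes from long-run integration
#'   over a grid of initial conditions.
#' @return A list with `outcomes` (character subset of elimination /
#'   dormancy / escape), `bistable`, `composition` (`high_antigen_dominant`,
#'   `low_antigen_dominant` or `none`), and the underlying `equilibria`.
#' @export
classify_steady_state <- function(pars, mode = c("active", "blocked"),
                                  n_starts = 400, seed = 1, interior = TRUE,
                                  probe_cycles = TRUE,
                                  fallback = c("error", "simulate")) {
  mode <- .match_mode(mode)
  fallback <- match.arg(fallback)
  eqs <- find_equilibria(pars, mode,
    n_starts = n_starts, seed = seed,
    interior = interior
  )
  stable <- purrr::keep(eqs, function(e) e$stability == "stable")
  if (!length(stable)) {
    if (fallback == "error") {
      stop("no stable equilibrium found; rerun with fallback = \"simulate\"",
        call. = FALSE
      )
    }
    labs <- simulate_outcomes(pars, mode)
    return(list(
      outcomes = labs, bistable = length(labs) >= 2,
      composition = "none", equilibria = eqs, method = "simulation"
    ))
  }
  totals <- purrr::map_dbl(stable, function(e) e$state[["N"]] + e$state[["M"]])
  outcomes <- unique(purrr::map_chr(totals, .steady_label))
  # probe for attractors invisible to equilibrium enumeration (stable limit
  # cycles around unstable persistent states, i.e. relapsing-remitting
  # dormancy): integrate from each unstable persistent equilibrium, nudged
  # off its stable manifold
  if (probe_cycles) {
    unstable_pers <- purrr::keep(eqs, function(e) {
      e$stability != "stable" && e$state[["N"]] + e$state[["M"]] > .zero_cells
    })
    for (e in unstable_pers) {
      y0 <- pmax(unname(e$state) * 1.01, c(0, 0, 1))
      lab <- .longrun_label(pars, mode, y0, 2000)
      if (!is.na(lab) && !lab %in% outcomes) outcomes <- c(outcomes, lab)
    }
  }
  persistent <- purrr::keep(stable, function(e) {
    e$state[["N"]] + e$state[["M"]] > .zero_cells
  })
  composition <- "none"
  if (length(persistent)) {
    tot <- purrr::map_dbl(persistent, function(e) e$state[["N"]] + e$state[["M"]])
    top <- persistent[[which.max(tot)]]
    composition <- if (top$state[["M"]] <= .zero_cells && top$state[["N"]] > .zero_cells) {
      "high_antigen_dominant"
    } else if (top$state[["N"]] <= .zero_cells && top$state[["M"]] > .zero_cells) {
      "low_antigen_dominant"
    } else {
      "mixed"
    }
  }
  list(
    outcomes = sort(outcomes), bistable = length(outcomes) >= 2,
    composition = composition, equilibria = eqs, method = "equilibria"
  )
}

#' Long-run outcomes by brute-force simulation
#'
#' Integrates (without the clinical clamp) from a log-spaced grid of initial
#' conditions and labels each end state by the steady-state thresholds. Runs
#' are extended when the tumor is still visibly moving at the horizon.
#'
#' @inheritParams find_equilibria
#' @param t_end base horizon (days); extended up to 3x when unconverged.
#' @param n_grid points per axis of the (N, M, T) initial-condition grid.
#' @return Character vector: the set of observed outcome labels.
#' @export
simulate_outcomes <- function(pars, mode = c("active", "blocked"),
                              t_end = 2000, n_grid = 3) {
  mode <- .match_mode(mode)
  pars <- validate_params(pars)
  tums <- 10^seq(4, log10(pars[["K"]]), length.out = n_grid)
  ts <- 10^seq(4, 7, length.out = n_grid)
  grid <- expand.grid(N0 = tums, M0 = tums, T0 = ts, KEEP.OUT.ATTRS = FALSE)
  labs <- purrr::pmap_chr(grid, function(N0, M0, T0) {
    .longrun_label(pars, mode, c(N0, M0, T0), t_end)
  })
  sort(unique(labs[!is.na(labs)]))
}

# Integrate in segments until the total tumor burden is stationary (fixed
# point or bounded oscillation) or has escaped; a run that is still in
# transit after all segments -- e.g. creeping through a fold ghost at
# ~1e-5/day -- gets no label (NA) rather than a wrong one.
#
# Between segments the tumor compartments are floored at a quasi-extinction
# level (1e-6 cells): the continuum model never reaches zero in finite time,
# but in double precision a deep crash underflows to exactly 0 and would be
# absorbed there, mislabelling a regrowing (invasion-unstable) tumor as
# eliminated. A truly eliminated tumor is pushed back to the floor and still
# ends below the extinction scale.
.longrun_label <- function(pars, mode, y0, t_end) {
  y <- y0
  mean_prev <- y[1] + y[2]
  seg_times <- seq(0, t_end, length.out = 101) # whole-segment sampling
  for (seg in 1:6) {
    y[1] <- max(y[1], 1e-6)
    y[2] <- max(y[2], 1e-6)
    tr <- tryCatch(
      integrate_tumor(pars,
        init = system_state(y[1], y[2], y[3]), mode = mode,
        t_end = t_end, times = seg_times, clamp = FALSE
      ),
      ctldyn_integration_error = function(e) NULL
    )
    if (is.null(tr)) {
      return(NA_character_)
    }
    n <- nrow(tr)
    y <- c(tr$N[n], tr$M[n], tr$T[n])
    # averaging the whole segment makes the criterion phase-robust for
    # long-period limit cycles
    mean_tot <- mean(tr$N + tr$M)
    if (mean_tot >= .escape_cells && mean_tot >= mean_prev) {
      return(.steady_label(mean_tot))
    }
    # below the extinction scale the absolute criterion is vacuous, so also
    # demand the burden is not growing in relative terms: a marginally
    # invasion-unstable tumor creeping up from the floor (e.g. 200x per
    # segment while still < 1 cell) is in transit, not eliminated
    settled <- seg > 1 &&
      abs(mean_tot - mean_prev) <= 1e-2 * max(mean_tot, 1) &&
      (mean_tot > 100 || mean_tot <= 1.5 * mean_prev)
    if (settled) {
      return(.steady_label(if (mean_tot <= 100) 0 else mean_tot))
    }
    mean_prev <- mean_tot
  }
  NA_character_
}

#' Bifurcation sweep over a parameter plane
#'
#' Classifies the steady-state outcome structure on a grid over two
#' parameters, optionally repeated for slices of a third parameter, with all
#' other parameters fixed. Per-point failures are recorded, not fatal.
#'
#' @param pars a `ctl_params` vector supplying the off-plane values.
#' @param param1,param2 parameter names.
#' @param values1,values2 grids for the two parameters.
#' @param slice_param,slice_values optional third parameter and its values.
#' @param mode checkpoint mode (the reference analysis is `"blocked"`).
#' @param n_starts scan resolution per grid point.
#' @param interior search interior equilibria at each point? Off by default:
#'   interior states require exact balance of the two phenotypes' kill terms
#'   and do not arise on the planes swept here.
#' @return Tibble of class `ctl_sweep`: one row per grid point with
#'   `outcome_set` (e.g. `"dormancy+escape"`), `bistable`, `composition`.
#' @export
bifurcation_sweep <- function(pars = baseline_params(), param1, values1,
                              param2, values2, slice_param = NULL,
                              slice_values = NULL,
                              mode = c("blocked", "active"), n_starts = 100,
                              interior = FALSE) {
  mode <- match.arg(mode)
  pars <- validate_params(pars)
  for (nm in c(param1, param2, slice_param)) {
    if (!nm %in% .par_order) stop("unknown parameter: ", nm, call. = FALSE)
  }
  if (is.null(slice_param)) slice_values <- NA_real_
  grid <- expand.grid(
    v1 = values1, v2 = values2, slice = slice_values,
    KEEP.OUT.ATTRS = FALSE
  )
  rows <- purrr::pmap(grid, function(v1, v2, slice) {
    pg <- pars
    pg[[param1]] <- v1
    pg[[param2]] <- v2
    if (!is.null(slice_param)) pg[[slice_param]] <- slice
    cls <- tryCatch(
      classify_steady_state(pg, mode,
        n_starts = n_starts, interior = interior,
        fallback = "simulate"
      ),
      error = function(e) NULL
    )
    tibble::tibble(
      param1 = param1, value1 = v1, param2 = param2, value2 = v2,
      slice_param = if (is.null(slice_param)) NA_character_ else slice_param,
      slice = slice,
      outcome_set = if (is.null(cls)) NA_character_ else paste(cls$outcomes, collapse = "+"),
      bistable = if (is.null(cls)) NA else cls$bistable,
      composition = if (is.null(cls)) NA_character_ else cls$composition,
      failed = is.null(cls)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ctl_sweep", class(out))
  out
}

#' Summarise a bifurcation sweep as region areas
#'
#' @param sweep a `ctl_sweep` tibble.
#' @return Tibble with the fraction of each slice's plane per outcome set.
#' @export
sweep_region_areas <- function(sweep) {
  dplyr::count(
    dplyr::group_by(sweep, .data$slice, .data$outcome_set),
    name = "n_points"
  ) |>
    dplyr::group_by(.data$slice) |>
    dplyr::mutate(fraction = .data$n_points / sum(.data$n_points)) |>
    dplyr::ungroup()
}
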