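# Package-wide volume convention: 1 mm^3 of tumor tissue = 1e6 cells, which
# places the carrying capacity K = 5e9 cells at 5000 mm^3.
.cells_per_mm3 <- 1e6

#' Convert tumor volume to cell count (and back)
#'
#' The package uses the standard solid-tumor convention of 1e6 cells per
#' cubic millimetre throughout, so the 0.1 mm^3 clinical detection limit is
#' 1e5 cells and the baseline carrying capacity (5e9 cells) is 5000 mm^3.
#'
#' @param volume_mm3 tumor volume in mm^3 (non-negative).
#' @param cells tumor cell count (non-negative).
#' @return A numeric vector of cells (`mm3_to_cells`) or mm^3
#'   (`cells_to_mm3`).
#' @examples
#' mm3_to_cells(1) # 1e6
#' cells_to_mm3(5e9) # 5000
#' @export
mm3_to_cells <- function(volume_mm3) {
  if (any(volume_mm3 < 0, na.rm = TRUE)) {
    stop("tumor volume must be non-negative", call. = FALSE)
  }
  volume_mm3 * .cells_per_mm3
}

#' @rdname mm3_to_cells
#' @export
cells_to_mm3 <- function(cells) {
  if (any(cells < 0, na.rm = TRUE)) {
    stop("cell count must be non-negative", call. = FALSE)
  }
  cells / .cells_per_mm3
}

#' Construct a model state
#'
#' @param N high-antigen tumor cells.
#' @param M low-antigen tumor cells.
#' @param T_ cytotoxic T cells.
#' @param t time in days.
#' @return Named numeric vector `c(N, M, T)` with attribute `t`.
#' @export
system_state <- function(N, M, T_, t = 0) {
  if (any(c(N, M, T_) < 0) || t < 0) {
    stop("cell counts and time must be non-negative", call. = FALSE)
  }
  structure(c(N = N, M = M, T = T_), t = t)
}

.match_mode <- function(mode) {
  match.arg(mode, c("active", "blocked"))
}

#' PD-1/PD-L1 checkpoint suppression factor
#'
#' Total PD-1 is carried by T cells (`P = rho_p * T`) and total PD-L1 by both
#' T cells and tumor cells, the latter weighted by the expression ratio
#' `eps_c` (`L = rho_l * (T + eps_c * (N + M))`). The checkpoint complex
#' `Q = P * L` suppresses T-cell cytotoxicity through
#' `F = 1 / (1 + Q / k_TQ)`, so `0 < F <= 1`. A blocked checkpoint (perfect
#' PD-1/PD-L1 blockade) sets `F = 1` identically.
#'
#' @param pars a `ctl_params` vector.
#' @param state a state vector `c(N, M, T)` (see [system_state()]).
#' @param mode `"active"` or `"blocked"`.
#' @return The scalar suppression factor in (0, 1].
#' @export
checkpoint_factor <- function(pars, state, mode = c("active", "blocked")) {
  mode <- .match_mode(mode)
  if (mode == "blocked") {
    return(1)
  }
  pars <- validate_params(pars)
  P <- pars[["rho_p"]] * state[["T"]]
  L <- pars[["rho_l"]] * (state[["T"]] + pars[["eps_c"]] * (state[["N"]] + state[["M"]]))
  unname(1 / (1 + P * L / pars[["k_TQ"]]))
}

#' Saturating slow-kill (FasL) functional response
#'
#' Per-capita tumor cell death rate from the slow, death-receptor-mediated
#' channel: a multi-prey Beddington-DeAngelis response
#' `delta_s * T / (kappa_0 + tumor + kappa_1 * T)`, where `tumor` is the
#' total tumor burden competing for CTL engagement. It is monotone in the
#' number of effectors, saturates (at `delta_s / kappa_1` for a vanishing
#' tumor) as T grows, and is diluted by a large tumor burden -- a CTL
#' handling one tumor cell is unavailable to kill another.
#'
#' @param T_ number of cytotoxic T cells.
#' @param delta_s maximal slow-kill rate (per day).
#' @param kappa_0 half-saturation constant (cells).
#' @param kappa_1 effector-saturation coefficient (dimensionless).
#' @param tumor total tumor burden `N + M` (cells); 0 gives the pure
#'   effector-saturation limit.
#' @return Per-capita kill rate (per day).
#' @export
slow_kill_rate <- function(T_, delta_s, kappa_0, kappa_1, tumor = 0) {
  if (any(T_ < 0)) stop("T must be non-negative", call. = FALSE)
  if (kappa_0 == 0 && kappa_1 == 0 && all(tumor == 0)) {
    stop("kappa_0 and kappa_1 cannot both be zero", call. = FALSE)
  }
  ifelse(T_ == 0, 0, delta_s * T_ / (kappa_0 + tumor + kappa_1 * T_))
}

#' Right-hand side of the tumor-immune ODE system
#'
#' Tumor phenotypes share a logistic niche of capacity `K` and are killed by
#' CTLs through a probabilistic mixture of the fast (mass-action,
#' perforin/granzyme) and slow (saturating, FasL) channels; the checkpoint
#' factor `F` multiplies both kill terms. T cells are recruited at constant
#' rate `mu`, proliferate in response to each antigen class with Michaelis-
#' Menten saturation, die at rate `delta_t` and are exhausted by tumor
#' contact at rates `delta_n`, `delta_m`.
#'
#' @inheritParams checkpoint_factor
#' @return Named numeric vector of derivatives `c(dN, dM, dT)` in cells/day.
#' @export
tumor_rhs <- function(pars, state, mode = c("active", "blocked")) {
  mode <- .match_mode(mode)
  pars <- validate_params(pars)
  y <- unname(state[c("N", "M", "T")])
  if (anyNA(y) || any(!is.finite(y))) {
    stop("state contains NaN/Inf", call. = FALSE)
  }
  d <- rhs_cpp(y, unclass(pars), mode == "blocked")
  c(dN = d[1], dM = d[2], dT = d[3])
}

# Smooth (unclipped) right-hand side used for finite-difference Jacobians:
# central differences at boundary equilibria (N = 0 or M = 0) need the
# analytic continuation to slightly negative states, which the integration
# kernel deliberately floors at zero.
.rhs_smooth <- function(pars, y, mode) {
  p <- as.list(unclass(pars))
  N <- y[1]
  M <- y[2]
  T_ <- y[3]
  F_ <- if (mode == "blocked") {
    1
  } else {
    1 / (1 + p$rho_p * T_ * p$rho_l * (T_ + p$eps_c * (N + M)) / p$k_TQ)
  }
  crowd <- 1 - (N + M) / p$K
  sk <- function(delta_s) delta_s * T_ / (p$kappa_0 + N + M + p$kappa_1 * T_)
  killN <- p$p_1 * p$delta_nf * T_ + (1 - p$p_1) * sk(p$delta_ns)
  killM <- p$p_2 * p$delta_mf * T_ + (1 - p$p_2) * sk(p$delta_ms)
  c(
    p$alpha_n * N * crowd - F_ * killN * N,
    p$alpha_m * M * crowd - F_ * killM * M,
    p$mu + (p$alpha_nt * N / (p$kappa_2 + N) + p$alpha_mt * M / (p$kappa_2 + M)) * T_ -
      p$delta_t * T_ - p$delta_n * N * T_ - p$delta_m * M * T_
  )
}

# Pure-R reference implementation of the same right-hand side, used in the
# test suite to pin the compiled kernel to the documented formulas.
tumor_rhs_r <- function(pars, state, mode = c("active", "blocked")) {
  mode <- .match_mode(mode)
  pars <- as.list(validate_params(pars))
  N <- state[["N"]]
  M <- state[["M"]]
  T_ <- state[["T"]]
  F_ <- checkpoint_factor(validate_params(unlist(pars)), state, mode)
  crowd <- 1 - (N + M) / pars$K
  killN <- pars$p_1 * pars$delta_nf * T_ +
    (1 - pars$p_1) * slow_kill_rate(T_, pars$delta_ns, pars$kappa_0, pars$kappa_1, N + M)
  killM <- pars$p_2 * pars$delta_mf * T_ +
    (1 - pars$p_2) * slow_kill_rate(T_, pars$delta_ms, pars$kappa_0, pars$kappa_1, N + M)
  c(
    dN = pars$alpha_n * N * crowd - F_ * killN * N,
    dM = pars$alpha_m * M * crowd - F_ * killM * M,
    dT = pars$mu +
      (pars$alpha_nt * N / (pars$kappa_2 + N) +
        pars$alpha_mt * M / (pars$kappa_2 + M)) * T_ -
      pars$delta_t * T_ - pars$delta_n * N * T_ - pars$delta_m * M * T_
  )
}
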