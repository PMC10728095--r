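#' Tidy an equilibrium set
#'
#' @param x a `ctl_equilibria` object from [find_equilibria()].
#' @param ... unused.
#' @return One row per equilibrium: branch, state, total volume, leading
#'   eigenvalue real part, stability.
#' @export
tidy.ctl_equilibria <- function(x, ...) {
  purrr::map_dfr(x, function(e) {
    tibble::tibble(
      branch = e$branch,
      N = e$state[["N"]], M = e$state[["M"]], T = e$state[["T"]],
      total_mm3 = cells_to_mm3(e$state[["N"]] + e$state[["M"]]),
      max_re_eigenvalue = max(Re(e$eigenvalues)),
      stability = e$stability,
      residual = e$residual
    )
  })
}

#' @rdname tidy.ctl_equilibria
#' @export
glance.ctl_equilibria <- function(x, ...) {
  td <- tidy.ctl_equilibria(x)
  stable <- td[td$stability == "stable", ]
  outs <- if (nrow(stable)) {
    sort(unique(vapply(
      mm3_to_cells(stable$total_mm3), .steady_label,
      character(1)
    )))
  } else {
    character(0)
  }
  tibble::tibble(
    mode = attr(x, "mode"),
    n_equilibria = nrow(td),
    n_stable = nrow(stable),
    outcome_set = paste(outs, collapse = "+"),
    bistable = length(outs) >= 2
  )
}

#' Tidy a sensitivity report
#'
#' @param x a `ctl_sensitivity` object.
#' @param ... unused.
#' @export
tidy.ctl_sensitivity <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.ctl_sensitivity
#' @export
glance.ctl_sensitivity <- function(x, ...) {
  tibble::tibble(
    mode = attr(x, "mode"), metric = attr(x, "metric"),
    n = attr(x, "n"), seed = attr(x, "seed"),
    n_significant = sum(x$significant, na.rm = TRUE)
  )
}
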