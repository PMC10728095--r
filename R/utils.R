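# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

# Derive a reproducible per-stage substream seed from a global seed, keeping
# the result a valid 32-bit integer.
.substream_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, sweep = 202L, cohort = 303L, sensitivity = 404L,
    extra = 505L
  )
  off <- offsets[[stage]]
  as.integer((as.double(seed) * 1009 + off) %% 2147483647)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
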