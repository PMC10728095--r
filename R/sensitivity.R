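#' Partial rank correlation coefficients
#'
#' Rank-transforms every input column and the output, then computes each
#' input's partial correlation with the output controlling for all other
#' inputs (correlation of the two residual vectors after regressing out the
#' other inputs' ranks). Significance uses the standard t approximation
#' with n - 2 - k degrees of freedom (k inputs controlled for), with
#' Benjamini-Hochberg correction across inputs.
#'
#' @param X data frame or matrix of sampled inputs (rows >= inputs + 2).
#' @param y output vector.
#' @param fdr false-discovery rate for the `significant` flag.
#' @return Tibble with `parameter`, `prcc`, `statistic`, `p_value`,
#'   `p_adjusted`, `significant`, `rank` (1 = largest |PRCC|). Constant
#'   columns get `NA` coefficients.
#' @examples
#' set.seed(1)
#' X <- data.frame(x1 = runif(200), x2 = runif(200))
#' prcc(X, 5 * X$x1 + rnorm(200, sd = 0.1))
#' @export
prcc <- function(X, y, fdr = 0.05) {
  X <- as.data.frame(X)
  n <- nrow(X)
  if (length(y) != n) stop("y must match rows of X", call. = FALSE)
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  const <- vapply(X, function(col) length(unique(col)) < 2, logical(1))
  Xv <- X[, !const, drop = FALSE]
  k <- ncol(Xv)
  if (n < k + 3) stop("need at least inputs + 3 rows", call. = FALSE)
  R <- apply(as.matrix(Xv), 2, rank)
  ry <- rank(y)
  out <- purrr::map_dfr(seq_len(k), function(j) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    qz <- qr(Z)
    rx <- qr.resid(qz, R[, j])
    rr <- qr.resid(qz, ry)
    r <- suppressWarnings(stats::cor(rx, rr))
    df <- n - 2 - (k - 1)
    tstat <- r * sqrt(df / (1 - r^2))
    tibble::tibble(
      parameter = colnames(R)[j], prcc = r, statistic = tstat,
      p_value = 2 * stats::pt(-abs(tstat), df)
    )
  })
  if (any(const)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      parameter = names(const)[const], prcc = NA_real_,
      statistic = NA_real_, p_value = NA_real_
    ))
  }
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < fdr
  out$rank <- rank(-abs(out$prcc), na.last = "keep", ties.method = "first")
  dplyr::arrange(out, .data$rank)
}

#' Global sensitivity of day-25 tumor state
#'
#' Latin-hypercube samples all model parameters (plus the sampled initial
#' conditions), simulates each draw to day 25 under the requested checkpoint
#' mode, and computes PRCC of a day-25 metric against every sampled
#' dimension.
#'
#' @param mode `"active"` or `"blocked"`.
#' @param n number of hypercube samples (>= 500).
#' @param seed RNG seed.
#' @param metric `"day25_volume"` or `"day25_low_fraction"`.
#' @param fdr false-discovery rate for significance flags.
#' @return Object of class `ctl_sensitivity`: the PRCC tibble with run
#'   metadata in attributes; use [tidy()] / [glance()].
#' @export
global_sensitivity <- function(mode = c("active", "blocked"), n = 2000,
                               seed = 1,
                               metric = c("day25_volume", "day25_low_fraction"),
                               fdr = 0.05) {
  mode <- .match_mode(mode)
  metric <- match.arg(metric)
  if (n < 500) stop("n must be at least 500", call. = FALSE)
  cohort <- sample_cohort(cohort_spec(n = n, seed = seed))
  result <- run_cohort(cohort, modes = mode, days = 25)
  y <- if (metric == "day25_volume") {
    result$volume_mm3
  } else {
    result$low_antigen_fraction
  }
  y[!result$ok] <- NA
  dims <- setdiff(names(cohort), c("id", "init_tumor_mm3"))
  out <- prcc(cohort[, dims], y[match(cohort$id, result$id)], fdr = fdr)
  structure(out,
    class = c("ctl_sensitivity", class(out)),
    mode = mode, metric = metric, n = n, seed = seed
  )
}
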