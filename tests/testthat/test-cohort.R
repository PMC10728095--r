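test_that("Latin hypercube places one draw per stratum in every dimension", {
  spec <- cohort_spec(n = 100, seed = 21)
  co <- sample_cohort(spec)
  expect_equal(nrow(co), 100)
  dims <- param_ranges()
  for (j in seq_len(nrow(dims))) {
    x <- co[[dims$parameter[j]]]
    u <- if (dims$scale[j] == "log") {
      (log(x) - log(dims$low[j])) / (log(dims$high[j]) - log(dims$low[j]))
    } else {
      (x - dims$low[j]) / (dims$high[j] - dims$low[j])
    }
    counts <- table(cut(u, breaks = seq(0, 1, length.out = 101)))
    expect_true(all(counts == 1), label = dims$parameter[j])
  }
  # sampled initial conditions follow the same stratification
  counts <- table(cut(co$init_low_fraction, seq(0, 1, length.out = 101)))
  expect_true(all(counts == 1))
  r <- (log(co$init_T_ratio) - log(0.01)) / (log(1) - log(0.01))
  expect_true(all(table(cut(r, seq(0, 1, length.out = 101))) == 1))
})

test_that("cohort sampling is seed-deterministic", {
  a <- sample_cohort(cohort_spec(n = 50, seed = 9))
  b <- sample_cohort(cohort_spec(n = 50, seed = 9))
  c <- sample_cohort(cohort_spec(n = 50, seed = 10))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$mu, c$mu))
})

test_that("marginals are uniform on the sampling scale (KS bound)", {
  co <- sample_cohort(cohort_spec(n = 1000, seed = 4))
  dims <- param_ranges()
  for (j in seq_len(nrow(dims))) {
    x <- co[[dims$parameter[j]]]
    u <- if (dims$scale[j] == "log") {
      (log(x) - log(dims$low[j])) / (log(dims$high[j]) - log(dims$low[j]))
    } else {
      (x - dims$low[j]) / (dims$high[j] - dims$low[j])
    }
    ks <- max(abs(sort(u) - (seq_along(u) - 0.5) / length(u)))
    expect_lt(ks, 2 / sqrt(1000))
  }
})

test_that("degenerate sampling ranges are held constant with a notice", {
  rngs <- param_ranges()
  rngs$low[rngs$parameter == "K"] <- 5e9
  rngs$high[rngs$parameter == "K"] <- 5e9
  expect_message(
    co <- sample_cohort(cohort_spec(n = 20, seed = 1, ranges = rngs)),
    "constant"
  )
  expect_true(all(co$K == 5e9))
  # out-of-bounds ranges rejected
  rngs$high[rngs$parameter == "K"] <- 1e10
  expect_error(cohort_spec(ranges = rngs), "admissible")
})

test_that("a cohort of identical mice shares a single outcome", {
  co <- sample_cohort(cohort_spec(n = 5, seed = 2))
  base <- baseline_params()
  for (nm in names(base)) co[[nm]] <- base[[nm]]
  co$init_low_fraction <- 0.5
  co$init_T_ratio <- 0.4854
  res <- run_cohort(co, modes = "blocked", days = 25)
  expect_equal(length(unique(res$outcome)), 1)
  expect_equal(length(unique(res$volume_mm3)), 1)
})

test_that("outcome probabilities count correctly and normalize", {
  fake <- tibble::tibble(
    id = 1:100, mode = "blocked", day = 25,
    volume_mm3 = c(rep(0.05, 16), rep(10, 48), rep(1000, 36)),
    low_antigen_fraction = 0.5,
    clamped = c(rep(TRUE, 16), rep(FALSE, 84)),
    ok = TRUE,
    outcome = classify_clinical(c(rep(0.05, 16), rep(10, 48), rep(1000, 36)))
  )
  pr <- outcome_probabilities(fake)
  expect_equal(pr$p, c(0.16, 0.48, 0.36))
  expect_equal(pr$se, sqrt(pr$p * (1 - pr$p) / 100))
  expect_equal(sum(pr$p), 1, tolerance = 1e-12)
})

test_that("blockade improves outcomes in a small cohort at both endpoints", {
  co <- sample_cohort(cohort_spec(n = 400, seed = 31))
  res <- run_cohort(co)
  pr <- outcome_probabilities(res)
  get <- function(m, d, o) pr$p[pr$mode == m & pr$day == d & pr$outcome == o]
  for (d in c(25, 150)) {
    expect_gt(
      get("blocked", d, "clinical_elimination"),
      get("active", d, "clinical_elimination")
    )
    expect_lt(get("blocked", d, "escape"), get("active", d, "escape"))
  }
})

test_that("binned outcome rates partition the cohort and normalize", {
  co <- sample_cohort(cohort_spec(n = 400, seed = 31))
  res <- run_cohort(co, modes = "blocked", days = 150)
  rates <- binned_outcome_rates(res, co, "alpha_nt", "blocked", 150, n_bins = 5)
  expect_equal(unique(rates$bin), 1:5)
  sums <- tapply(rates$p, rates$bin, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(sum(rates$n), 400)
  # equal-width bins over the declared range [0, 0.5]
  expect_equal(min(rates$bin_low), 0)
  expect_equal(max(rates$bin_high), 0.5)
})

test_that("outcome-conditioned summaries expose favorable-immune shifts", {
  co <- sample_cohort(cohort_spec(n = 1500, seed = 8))
  res <- run_cohort(co, modes = "blocked", days = 150)
  s <- outcome_conditioned_summary(res, co, "mu", "blocked", 150)
  med <- function(o) s$summary$median[s$summary$outcome == o]
  expect_gt(med("clinical_elimination"), med("escape"))
  sa <- outcome_conditioned_summary(res, co, "alpha_nt", "blocked", 150)
  expect_lt(
    sa$summary$median[sa$summary$outcome == "escape"],
    sa$summary$median[sa$summary$outcome == "clinical_elimination"]
  )
  expect_equal(length(unique(s$density$x)), 128)
})
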