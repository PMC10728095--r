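test_that("tumor-free equilibrium: closed form and stability limits", {
  p <- baseline_params()
  tf <- tumor_free_equilibrium(p, "blocked")
  expect_equal(tf$state[["T"]], 2e4 / 0.0412, tolerance = 1e-12) # ~4.854e5
  expect_equal(unname(Re(tf$eigenvalues[3])), -0.0412)
  # without recruitment the naked tumor-free state is invadable
  tf0 <- tumor_free_equilibrium(baseline_params(mu = 0), "blocked")
  expect_equal(tf0$state[["T"]], 0)
  expect_equal(unname(Re(tf0$eigenvalues[1])), 0.337)
  expect_equal(tf0$stability, "unstable")
})

test_that("closed-form eigenvalues match finite-difference Jacobians", {
  set.seed(99)
  for (i in 1:8) {
    p <- random_params()
    for (mode in c("active", "blocked")) {
      tf <- tumor_free_equilibrium(p, mode)
      J <- numDeriv::jacobian(
        function(y) ctldyn:::.rhs_smooth(p, y, mode),
        unname(tf$state)
      )
      ev_num <- sort(Re(eigen(J, only.values = TRUE)$values))
      ev_cf <- sort(Re(tf$eigenvalues))
      expect_equal(ev_cf, ev_num, tolerance = 1e-8)
    }
  }
})

test_that("baseline blocked world: escape to capacity, low-antigen tumor", {
  e <- find_equilibria(baseline_params(), "blocked")
  td <- tidy(e)
  expect_true("tumor_free" %in% td$branch)
  stable <- td[td$stability == "stable", ]
  expect_equal(nrow(stable), 1)
  expect_gte(stable$total_mm3, 500) # escape
  expect_equal(stable$N, 0) # only low-antigen cells persist (p1 > p2)
  expect_gt(stable$M, 0)
  cls <- classify_steady_state(baseline_params(), "blocked")
  expect_equal(cls$outcomes, "escape")
  expect_false(cls$bistable)
  expect_equal(cls$composition, "low_antigen_dominant")
})

test_that("equilibrium finding is reproducible and residual-tight", {
  p <- baseline_params()
  a <- tidy(find_equilibria(p, "blocked", seed = 3))
  b <- tidy(find_equilibria(p, "blocked", seed = 3))
  expect_identical(a, b)
  e <- find_equilibria(p, "blocked")
  for (eq in e) {
    expect_lte(eq$residual, 1e-6 * max(1, sqrt(sum(eq$state^2))))
  }
})

test_that("immune-free limit recovers the logistic equilibria", {
  p <- baseline_params(mu = 0)
  td <- tidy(find_equilibria(p, "blocked"))
  expect_true(any(td$branch == "tumor_free" & td$T == 0))
  expect_true(any(abs(td$N - 5e9) / 5e9 < 1e-6 & td$M == 0))
  expect_true(any(abs(td$M - 5e9) / 5e9 < 1e-6 & td$N == 0))
})

test_that("stable equilibria attract nearby states", {
  e <- find_equilibria(baseline_params(), "blocked")
  stable <- purrr::keep(e, function(x) x$stability == "stable")
  expect_gte(length(stable), 1)
  for (eq in stable) {
    y0 <- unname(eq$state) * 1.01
    tr <- integrate_tumor(baseline_params(),
      init = system_state(y0[1], y0[2], y0[3]), mode = "blocked",
      t_end = 2000, times = 2000, clamp = FALSE
    )
    yT <- c(tr$N[nrow(tr)], tr$M[nrow(tr)], tr$T[nrow(tr)])
    expect_lt(
      sqrt(sum((yT - unname(eq$state))^2)) / sqrt(sum(eq$state^2)),
      1e-3
    )
  }
})

test_that("steady-state classification mirrors under phenotype swap", {
  a <- classify_steady_state(baseline_params(), "blocked")
  b <- classify_steady_state(baseline_params(p_1 = 0.33, p_2 = 0.92), "blocked")
  expect_equal(a$outcomes, b$outcomes)
  expect_equal(a$composition, "low_antigen_dominant")
  expect_equal(b$composition, "high_antigen_dominant")
})

test_that("therapy-style parameter shifts open dormancy and elimination", {
  # cytokine-like boost of alpha_mt: dormancy becomes possible
  up <- classify_steady_state(baseline_params(alpha_mt = 0.55), "blocked")
  expect_true("dormancy" %in% up$outcomes)
  expect_true(up$bistable)
  # adoptive-transfer-like boost of mu: elimination-or-escape bistability
  mu_up <- classify_steady_state(baseline_params(mu = 8e4), "blocked")
  expect_true(all(c("elimination", "escape") %in% mu_up$outcomes))
})

test_that("bifurcation sweep emits a long-format region map", {
  sw <- bifurcation_sweep(baseline_params(),
    param1 = "p_1", values1 = c(0.2, 0.8),
    param2 = "p_2", values2 = c(0.2, 0.8),
    mode = "blocked", n_starts = 150
  )
  expect_s3_class(sw, "ctl_sweep")
  expect_equal(nrow(sw), 4)
  expect_true(all(!sw$failed))
  expect_true(all(grepl("escape|dormancy|elimination", sw$outcome_set)))
  # swap symmetry on the anti-diagonal with composition flipped
  a <- sw[sw$value1 == 0.8 & sw$value2 == 0.2, ]
  b <- sw[sw$value1 == 0.2 & sw$value2 == 0.8, ]
  expect_equal(a$outcome_set, b$outcome_set)
  areas <- sweep_region_areas(sw)
  expect_equal(sum(areas$fraction), 1)
})
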