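test_that("immune-free integration matches the closed-form logistic", {
  p <- baseline_params(mu = 0)
  tr <- integrate_tumor(p,
    init = system_state(5e5, 5e5, 0), mode = "blocked",
    t_end = 150, clamp = FALSE
  )
  expected <- logistic_solution(1e6, 0.337, 5e9, tr$time)
  expect_equal(tr$N + tr$M, expected, tolerance = 1e-6)
  # phenotype split stays 50/50 with equal growth rates
  expect_equal(tr$low_antigen_fraction, rep(0.5, nrow(tr)), tolerance = 1e-9)
})

test_that("clinical clamp freezes reported volume at the detection limit", {
  p <- baseline_params()
  # already undetectable at t = 0
  tr0 <- integrate_tumor(p,
    init = system_state(2.5e4, 2.5e4, 1e5), mode = "active", t_end = 10
  )
  expect_equal(attr(tr0, "clamped_at"), 0)
  expect_true(all(tr0$volume_mm3 == 0.1))
  expect_true(all(tr0$clamped))
  # crossing mid-run: blocked baseline with homeostatic effectors eliminates
  tr <- integrate_tumor(p,
    init = inoculum_state(p, T_0 = homeostatic_T(p)),
    mode = "blocked", t_end = 150
  )
  ca <- attr(tr, "clamped_at")
  expect_false(is.na(ca))
  expect_gt(ca, 0)
  after <- tr$volume_mm3[tr$time >= ca]
  expect_true(all(after == 0.1)) # absorbing
  expect_true(all(tr$volume_mm3[tr$time < ca] > 0.1))
  # T keeps relaxing toward homeostasis after the clamp
  expect_gt(tr$T[nrow(tr)], 0)
})

test_that("trajectories stay non-negative and finite across random worlds", {
  set.seed(123)
  for (i in 1:12) {
    p <- random_params()
    tr <- integrate_tumor(p,
      init = system_state(1e6 * runif(1), 1e6 * runif(1), 1e6 * runif(1)),
      mode = sample(c("active", "blocked"), 1), t_end = 150
    )
    expect_true(all(is.finite(c(tr$N, tr$M, tr$T))))
    expect_true(all(tr$N >= 0 & tr$M >= 0 & tr$T >= 0))
  }
})

test_that("stored-step readout is consistent across output resolutions", {
  p <- baseline_params()
  coarse <- integrate_tumor(p, mode = "blocked", t_end = 40, times = c(25, 40))
  dense <- integrate_tumor(p,
    mode = "blocked", t_end = 40,
    times = seq(0, 40, by = 0.25)
  )
  expect_equal(volume_at(coarse, 25), volume_at(dense, 25), tolerance = 1e-6)
  expect_equal(volume_at(coarse, 25, "low_antigen_fraction"),
    volume_at(dense, 25, "low_antigen_fraction"),
    tolerance = 1e-6
  )
})

test_that("integration is deterministic and tolerance-robust", {
  p <- baseline_params()
  a <- integrate_tumor(p, mode = "blocked", t_end = 150)
  b <- integrate_tumor(p, mode = "blocked", t_end = 150)
  expect_identical(a$volume_mm3, b$volume_mm3)
  tight <- integrate_tumor(p, mode = "blocked", t_end = 150, rtol = 1e-9)
  expect_equal(volume_at(a, 25), volume_at(tight, 25), tolerance = 1e-4)
  expect_equal(volume_at(a, 150), volume_at(tight, 150), tolerance = 1e-4)
})

test_that("trajectory-level phenotype swap symmetry", {
  p <- baseline_params() # p_1 != p_2, so the swap is non-trivial
  swapped <- p
  swapped[["p_1"]] <- p[["p_2"]]
  swapped[["p_2"]] <- p[["p_1"]]
  init <- system_state(7e5, 3e5, 0)
  init_sw <- system_state(3e5, 7e5, 0)
  for (mode in c("active", "blocked")) {
    a <- integrate_tumor(p, init = init, mode = mode, t_end = 60, clamp = FALSE)
    b <- integrate_tumor(swapped, init = init_sw, mode = mode, t_end = 60, clamp = FALSE)
    expect_equal(a$N, b$M, tolerance = 1e-6)
    expect_equal(a$M, b$N, tolerance = 1e-6)
    expect_equal(a$T, b$T, tolerance = 1e-6)
  }
})

test_that("invalid inputs are rejected cleanly", {
  p <- baseline_params()
  expect_error(integrate_tumor(p, t_end = -5), "positive")
  expect_error(
    integrate_tumor(p, init = c(N = -1, M = 0, T = 0)),
    "non-negative"
  )
  expect_error(system_state(-1, 0, 0), "non-negative")
})
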