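test_that("volume convention converts exactly and inverts", {
  expect_identical(mm3_to_cells(0), 0)
  expect_identical(mm3_to_cells(1), 1e6)
  expect_identical(cells_to_mm3(5e9), 5000) # carrying capacity = 5000 mm^3
  x <- c(0.1, 1, 500, 5000)
  expect_equal(cells_to_mm3(mm3_to_cells(x)), x)
  expect_error(mm3_to_cells(-1), "non-negative")
  expect_error(cells_to_mm3(-1), "non-negative")
})

test_that("checkpoint factor is 1 when blocked, in (0,1] when active", {
  p <- baseline_params()
  st <- system_state(5e5, 5e5, 4.854e5)
  expect_identical(checkpoint_factor(p, st, "blocked"), 1)
  # direct arithmetic: P = rho_p T, L = rho_l (T + eps_c (N+M)), Q = P L
  P <- 1.259e-11 * 4.854e5
  L <- 2.510e-11 * (4.854e5 + 10 * 1e6)
  expect_equal(checkpoint_factor(p, st, "active"), 1 / (1 + P * L / 1.296e-9),
    tolerance = 1e-12
  )
  expect_equal(checkpoint_factor(p, st, "active"), 0.45, tolerance = 0.02)
  # no PD-1 -> no suppression
  expect_equal(checkpoint_factor(baseline_params(rho_p = 1e-300), st, "active"),
    1,
    tolerance = 1e-6
  )
  set.seed(1)
  for (i in 1:20) {
    st <- system_state(runif(1, 0, 1e9), runif(1, 0, 1e9), runif(1, 0, 1e8))
    f <- checkpoint_factor(p, st, "active")
    expect_true(f > 0 && f <= 1)
    if (st[["T"]] > 0) expect_lt(f, 1) # strict suppression whenever T > 0
  }
})

test_that("slow-kill response: zero at T=0, half-saturation, effector limit", {
  expect_identical(slow_kill_rate(0, 4, 2e7, 0.5), 0)
  expect_equal(slow_kill_rate(2e7, 4, 2e7, 1), 2) # T = kappa_0, kappa_1 = 1
  expect_equal(slow_kill_rate(1e18, 4, 2e7, 0.5), 8, tolerance = 1e-6)
  # monotone non-decreasing in T, diluted by tumor burden
  ts <- 10^seq(0, 9, length.out = 50)
  r <- slow_kill_rate(ts, 4, 2e7, 0.5)
  expect_true(all(diff(r) >= 0))
  expect_lt(
    slow_kill_rate(1e6, 4, 2e7, 0.5, tumor = 1e9),
    slow_kill_rate(1e6, 4, 2e7, 0.5, tumor = 0)
  )
  expect_error(slow_kill_rate(1, 4, 0, 0), "cannot both be zero")
})

test_that("compiled right-hand side agrees with the R reference formulas", {
  set.seed(42)
  for (i in 1:25) {
    p <- random_params()
    st <- system_state(
      10^runif(1, 0, 9.8), 10^runif(1, 0, 9.8),
      10^runif(1, 0, 8)
    )
    for (mode in c("active", "blocked")) {
      expect_equal(tumor_rhs(p, st, mode), ctldyn:::tumor_rhs_r(p, st, mode),
        tolerance = 1e-12
      )
    }
  }
})

test_that("right-hand side limits: empty tumor, no effectors, homeostasis", {
  p <- baseline_params()
  # no tumor: T relaxes to mu/delta_t, tumor stays empty
  d <- tumor_rhs(p, system_state(0, 0, 1e5), "active")
  expect_identical(unname(d[c("dN", "dM")]), c(0, 0))
  expect_equal(unname(d[["dT"]]), 2e4 - 0.0412 * 1e5)
  expect_equal(
    unname(tumor_rhs(p, system_state(0, 0, homeostatic_T(p)), "blocked")[["dT"]]),
    0,
    tolerance = 1e-9
  )
  # no effectors: pure logistic growth of the total burden
  st <- system_state(2e8, 3e8, 0)
  d <- tumor_rhs(p, st, "blocked")
  expect_equal(
    unname(d[["dN"]] + d[["dM"]]),
    0.337 * 5e8 * (1 - 5e8 / 5e9),
    tolerance = 1e-12
  )
})

test_that("phenotype-swap symmetry of the right-hand side", {
  set.seed(7)
  for (i in 1:10) {
    p <- random_params()
    swapped <- p
    swapped[["alpha_n"]] <- p[["alpha_m"]]
    swapped[["alpha_m"]] <- p[["alpha_n"]]
    swapped[["delta_ns"]] <- p[["delta_ms"]]
    swapped[["delta_ms"]] <- p[["delta_ns"]]
    swapped[["delta_nf"]] <- p[["delta_mf"]]
    swapped[["delta_mf"]] <- p[["delta_nf"]]
    swapped[["delta_n"]] <- p[["delta_m"]]
    swapped[["delta_m"]] <- p[["delta_n"]]
    swapped[["p_1"]] <- p[["p_2"]]
    swapped[["p_2"]] <- p[["p_1"]]
    swapped[["alpha_nt"]] <- p[["alpha_mt"]]
    swapped[["alpha_mt"]] <- p[["alpha_nt"]]
    st <- system_state(3e6, 8e8, 2e6)
    st_sw <- system_state(8e8, 3e6, 2e6)
    for (mode in c("active", "blocked")) {
      d <- tumor_rhs(p, st, mode)
      d_sw <- tumor_rhs(swapped, st_sw, mode)
      expect_equal(unname(d[["dN"]]), unname(d_sw[["dM"]]), tolerance = 1e-12)
      expect_equal(unname(d[["dM"]]), unname(d_sw[["dN"]]), tolerance = 1e-12)
      expect_equal(unname(d[["dT"]]), unname(d_sw[["dT"]]), tolerance = 1e-12)
    }
  }
})
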