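test_that("survival time is a refined first passage of the critical volume", {
  p <- nominal_params()
  st <- survival_settings(n_crit = 8000, t_max = 100)
  r <- survival_time(p, small_tumor(), u = 0, v = 0, st)
  expect_true(r$reached)
  expect_gt(r$t_s, 0)
  # refinement consistency: total volume at the reported time is on the level set
  tr <- simulate_tumor(p, small_tumor(), dose_schedule(0, 0, r$t_s + 1),
                       t_span = c(0, r$t_s), rel_tol = 1e-10)
  n <- nrow(tr$states)
  expect_lt(abs(tr$states[n, 1] + tr$states[n, 2] - 8000), 1e-3)
})

test_that("an initial volume at the threshold gives zero survival time", {
  r <- survival_time(nominal_params(), tumor_state(8000, 1, 5000), 0, 0,
                     survival_settings(n_crit = 8000))
  expect_equal(r$t_s, 0)
  expect_true(r$reached)
})

test_that("the sentinel is returned iff the volume stays subcritical up to the cap", {
  p <- nominal_params()
  st <- survival_settings(n_crit = 8000, t_max = 8)
  r <- survival_time(p, small_tumor(), 0, 0, st)
  expect_false(r$reached)
  expect_true(is.infinite(r$t_s))
  tr <- simulate_tumor(p, small_tumor(), dose_schedule(0, 0, 8),
                       rel_tol = 1e-8)
  expect_lt(max(tr$states[, 1] + tr$states[, 2]), 8000)
})

test_that("dose sweep preserves grid order and reduces to a single call", {
  p <- nominal_params()
  st <- survival_settings(t_max = 150)
  g <- c(0.4, 0, 0.1)
  sw <- dose_sweep(p, small_tumor(), g, v = 0.5, st)
  expect_equal(sw$u, g)
  one <- dose_sweep(p, small_tumor(), 0.1, v = 0.5, st)
  expect_equal(one$t_s, survival_time(p, small_tumor(), 0.1, 0.5, st)$t_s)
  expect_equal(sw$t_s[3], one$t_s)
})

test_that("survival peaks at an intermediate dose below 25% of MTD", {
  p <- nominal_params()
  st <- survival_settings(t_max = 300)
  g <- seq(0, 0.6, by = 0.05)
  sw <- dose_sweep(p, small_tumor(), g, v = 0.5, st)
  i <- which.max(sw$t_s)
  expect_gt(i, 1)                 # interior maximum
  expect_lt(i, length(g))
  expect_lt(sw$u[i], 0.25)
})

test_that("grid refinement moves the optimum by less than one coarse cell", {
  p <- nominal_params()
  st <- survival_settings(t_max = 300)
  coarse <- seq(0, 0.6, length.out = 13)   # spacing 0.05
  fine <- seq(0, 0.6, length.out = 25)
  oc <- optimal_constant_dose(p, small_tumor(), 0.5, st, coarse,
                              refine_tol = 1e-3)
  of <- optimal_constant_dose(p, small_tumor(), 0.5, st, fine,
                              refine_tol = 1e-3)
  expect_lt(abs(oc$u_star - of$u_star), 0.05)
})

test_that("a drug with no target is dosed at zero", {
  p <- model_params(beta1 = 0, beta = 0)  # chemo hits neither cells nor vessels
  oc <- optimal_constant_dose(p, small_tumor(), v = 0.5,
                              survival_settings(t_max = 200),
                              u_grid = seq(0, 1, length.out = 6))
  expect_equal(oc$u_star, 0)
})

test_that("lower mutation rate toward resistance lengthens survival and lowers the dose", {
  st <- survival_settings(t_max = 400)
  g <- seq(0, 0.6, length.out = 16)
  r_lo <- optimal_constant_dose(model_params(tau1 = 2e-6), small_tumor(),
                                0.5, st, g, refine_tol = 5e-3)
  r_hi <- optimal_constant_dose(model_params(tau1 = 2e-3), small_tumor(),
                                0.5, st, g, refine_tol = 5e-3)
  expect_gt(r_lo$t_s_star, r_hi$t_s_star)
  expect_lt(r_lo$u_star, r_hi$u_star)
})

test_that("heatmap cells agree with direct calls and flag sentinels categorically", {
  p <- nominal_params()
  st <- survival_settings(t_max = 60)
  hm <- dose_heatmap(p, small_tumor(), u_grid = c(0, 0.5), v_grid = c(0, 1),
                     settings = st)
  expect_equal(dim(hm$t_s), c(2, 2))
  expect_equal(hm$t_s[1, 1],
               survival_time(p, small_tumor(), 0, 0, st)$t_s)
  # strong combined therapy keeps the tumor subcritical past this short cap
  expect_true(any(is.infinite(hm$t_s)))
  expect_equal(is.infinite(hm$t_s), !hm$reached)
  finite <- hm$t_s[is.finite(hm$t_s)]
  expect_true(all(finite > 0))
})

test_that("mutation sweep reduces to the single-pair optimum on a 1x1 grid", {
  p <- nominal_params()
  st <- survival_settings(t_max = 200)
  g <- seq(0, 0.6, length.out = 9)
  ms <- mutation_sweep(p, small_tumor(), 0.5, tau1_grid = 2e-5,
                       tau2_grid = 1e-5, settings = st, u_grid = g,
                       refine_tol = 5e-3)
  oc <- optimal_constant_dose(p, small_tumor(), 0.5, st, g,
                              refine_tol = 5e-3)
  expect_equal(nrow(ms), 1L)
  expect_equal(ms$t_s_max, oc$t_s_star)
  expect_equal(ms$u_star, oc$u_star)
})
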