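test_that("transcription dimensions, bounds and first Euler step are exact", {
  p <- nominal_params()
  set <- transcription_settings(n_nodes = 2, horizon = 14)
  nlp <- transcribe(p, small_tumor(), objective_weights(), v = 0.5, set)
  expect_equal(nlp$n_controls, 2L)
  expect_equal(nlp$n_state_nodes, 3L)
  expect_equal(nlp$n_eq_constraints, 6L)
  expect_equal(nlp$u_lower, c(0, 0))
  expect_equal(nlp$u_upper, c(1, 1))
  h <- 7
  X <- nlp$rollout(c(0.25, 0.6))
  step1 <- c(280, 20, 650) + h * rhs_oracle(c(280, 20, 650), 0.25, 0.5, p)
  expect_equal(unname(X[2, ]), step1, tolerance = 1e-12)
  expect_equal(unname(X[3, ]),
               step1 + h * rhs_oracle(step1, 0.6, 0.5, p), tolerance = 1e-12)
  # the Euler defect of a rollout is identically zero
  expect_lt(max(abs(nlp$euler_residual(X, c(0.25, 0.6)))), 1e-10)
})

test_that("adjoint gradient matches central finite differences", {
  nlp <- transcribe(sensitive_params(), small_tumor(), objective_weights(),
                    v = 0.5, transcription_settings(n_nodes = 50))
  u <- seq(0.2, 0.9, length.out = 50)
  g <- nlp$gradient(u)
  for (k in c(1, 17, 50)) {
    e <- 1e-6
    up <- u; up[k] <- up[k] + e
    um <- u; um[k] <- um[k] - e
    expect_equal(g[k], (nlp$objective(up) - nlp$objective(um)) / (2 * e),
                 tolerance = 1e-5)
  }
})

test_that("degenerate weight settings have known optima", {
  p <- nominal_params()
  set <- transcription_settings(n_nodes = 50)
  # all weights zero: any feasible control is optimal and J = 0
  w0 <- objective_weights(0, 0, 0, 0, 0, 10, 0)
  s0 <- solve_ocp(transcribe(p, small_tumor(), w0, 0.5, set))
  expect_equal(s0$objective$total, 0)
  # drug that only costs: theta > 0 with no cell kill and no tumor weight
  pz <- model_params(beta1 = 0, beta = 0)
  wz <- objective_weights(0, 0, 0, 0, 0, 10, theta = 1)
  sz <- solve_ocp(transcribe(pz, small_tumor(), wz, 0.5, set))
  expect_lt(max(sz$control), 1e-8)
})

test_that("average dose and protocol classification follow their definitions", {
  expect_equal(average_dose(rep(1, 40)), 100)
  expect_equal(average_dose(rep(0, 40)), 0)
  expect_equal(average_dose(cbind(c(2, 6), c(1, 0.25))), 100 * (2 + 1.5) / 8)
  expect_equal(classify_protocol(100)$label, "full-dose")
  expect_equal(classify_protocol(52.51)$label, "intermediate-dose")
  expect_equal(classify_protocol(90)$label, "intermediate-dose")  # strict rule
  expect_equal(classify_protocol(90.01)$label, "full-dose")
})

test_that("singular-arc extraction finds interior runs and ignores bang-bang", {
  sol <- list(control = c(rep(1, 10), rep(0, 10)),
              times = seq(0, 14, length.out = 21))
  expect_false(extract_singular(sol)$has_singular)
  u <- c(rep(1, 5), seq(0.6, 0.3, length.out = 8), rep(1, 7))
  sol2 <- list(control = u, times = seq(0, 14, length.out = 21))
  sg <- extract_singular(sol2)
  expect_true(sg$has_singular)
  expect_equal(length(sg$segments), 1L)
  expect_equal(sg$segments[[1]]$start, sol2$times[6])
  expect_equal(sg$mean_dose_pct, 100 * mean(u[6:13]))
  # runs shorter than min_len are not singular arcs
  u3 <- c(rep(1, 9), 0.5, 0.5, rep(1, 9))
  expect_false(extract_singular(list(control = u3,
                                     times = seq(0, 14, length.out = 21)))$has_singular)
  expect_error(extract_singular(sol, lo = 0.9, hi = 0.1), "lo < hi")
})

test_that("forward Euler converges at first order to the RK45 trajectory", {
  p <- sensitive_params()
  sched <- dose_schedule(0.4, 0.5, 14)
  ref <- simulate_tumor(p, small_tumor(), sched, rel_tol = 1e-10)
  final_ref <- ref$states[nrow(ref$states), ]
  errs <- vapply(c(100, 200, 400), function(M) {
    nlp <- transcribe(p, small_tumor(), objective_weights(), 0.5,
                      transcription_settings(n_nodes = M))
    X <- nlp$rollout(rep(0.4, M))
    max(abs(X[M + 1, ] - final_ref) / final_ref)
  }, numeric(1))
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.25)
  expect_equal(errs[2] / errs[3], 2, tolerance = 0.25)
})

test_that("the solver beats exhaustive 3-segment bang-bang controls on a coarse grid", {
  p <- sensitive_params()
  w <- objective_weights()
  set <- transcription_settings(n_nodes = 20)
  nlp <- transcribe(p, small_tumor(), w, 0.5, set)
  sol <- solve_ocp(nlp)
  best <- Inf
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    for (i in 0:20) for (j in i:20) {
      u <- c(rep(a, i), rep(b, j - i), rep(cc, 20 - j))
      best <- min(best, nlp$objective(u))
    }
  }
  expect_lte(sol$objective$total, best * (1 + 1e-6))
})

test_that("the optimum beats MTD and the constant mean dose, and is feasible", {
  p <- sensitive_params()
  w <- objective_weights()
  nlp <- transcribe(p, small_tumor(), w, 0.5,
                    transcription_settings(n_nodes = 100))
  sol <- solve_ocp(nlp)
  expect_lte(sol$objective$total, nlp$objective(rep(1, 100)))
  expect_lte(sol$objective$total,
             nlp$objective(rep(mean(sol$control), 100)))
  expect_lt(max(abs(nlp$euler_residual(sol$states, sol$control))), 1e-8)
  expect_true(all(sol$control >= 0 & sol$control <= 1))
  # bang-singular-bang structure: full dose at both ends, interior arc between
  expect_gt(sol$control[1], 0.99)
  expect_gt(sol$control[100], 0.99)
  expect_true(sol$singular$has_singular)
})

test_that("a single window reduces to one solve and windows chain their states", {
  p <- sensitive_params()
  w <- objective_weights()
  set <- transcription_settings(n_nodes = 60)
  mw1 <- multiwindow_optimize(p, small_tumor(), w, 0.5, set, n_windows = 1)
  direct <- solve_ocp(transcribe(p, small_tumor(), w, 0.5, set))
  expect_equal(mw1$control, direct$control, tolerance = 1e-6)
  expect_equal(mw1$average_dose_pct, direct$average_dose_pct,
               tolerance = 1e-6)
  mw2 <- multiwindow_optimize(p, small_tumor(), w, 0.5, set, n_windows = 2)
  expect_equal(length(mw2$control), 120L)
  expect_equal(mw2$average_dose_pct,
               mean(mw2$window_average_dose_pct), tolerance = 1e-9)
  # window 2 starts where the continuous simulation of window 1 ends
  tr1 <- simulate_tumor(p, small_tumor(),
                        dose_schedule(mw2$windows[[1]]$control, 0.5, 14,
                                      breaks = mw2$windows[[1]]$times),
                        rel_tol = 1e-8)
  expect_equal(unname(mw2$windows[[2]]$states[1, ]),
               unname(tr1$states[nrow(tr1$states), ]), tolerance = 1e-6)
})

test_that("protocol comparison reports the four protocols with coherent doses", {
  p <- sensitive_params()
  cp <- compare_protocols(p, large_tumor(), objective_weights(), 0.5,
                          transcription_settings(n_nodes = 60), n_windows = 2)
  expect_equal(cp$table$protocol,
               c("optimal", "mtd", "mean_dose", "oc_then_mtd"))
  expect_equal(cp$table$average_dose_pct[2], 100)
  expect_equal(cp$table$average_dose_pct[1], cp$table$average_dose_pct[3],
               tolerance = 1e-9)
  expect_true(all(cp$table$volume_final > 0))
  # MTD drives the resistant fraction to near fixation by mid-therapy
  expect_gt(cp$table$resistant_frac_w1[2], 0.99)
})
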