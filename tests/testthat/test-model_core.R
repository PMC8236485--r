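test_that("vector field matches a hand evaluation of each term", {
  p <- nominal_params()
  s <- small_tumor()
  f <- tumor_rhs(s, u = 0.25, v = 0.5, p)
  expect_equal(unname(f), rhs_oracle(as.numeric(s), 0.25, 0.5, p),
               tolerance = 1e-12)
  # per-term decomposition of the K equation at this operating point
  N <- 300
  expect_equal(unname(f["K"]),
               -p$mu * 650 + p$b * N - p$d * N^(2 / 3) * 650 -
                 p$beta * 650 * 0.25 - p$gamma * 650 * 0.5,
               tolerance = 1e-12)
  # logarithm vanishes when total volume equals carrying capacity
  p0 <- model_params(tau1 = 0, tau2 = 0)
  f0 <- tumor_rhs(tumor_state(100, 100, 200), 0, 0, p0)
  expect_equal(unname(f0[c("N1", "N2")]), c(0, 0))
})

test_that("non-positive states are rejected (logarithm undefined)", {
  expect_error(tumor_state(-1, 20, 650), "strictly positive")
  expect_error(tumor_state(280, 0, 650), "strictly positive")
  expect_error(tumor_rhs(c(280, 20, -5), 0, 0, nominal_params()),
               "strictly positive")
  expect_error(tumor_rhs(small_tumor(), 1.5, 0, nominal_params()), "0, 1")
})

test_that("analytic Jacobian matches central finite differences", {
  p <- sensitive_params()
  s <- c(350, 120, 900)
  J <- tumor_jacobian(s, 0.4, 0.7, p)
  Jfd <- matrix(0, 3, 3)
  for (j in 1:3) {
    h <- 1e-5 * s[j]
    sp <- s; sm <- s
    sp[j] <- sp[j] + h; sm[j] <- sm[j] - h
    Jfd[, j] <- (rhs_oracle(sp, 0.4, 0.7, p) - rhs_oracle(sm, 0.4, 0.7, p)) /
      (2 * h)
  }
  expect_equal(unname(unclass(J)), Jfd, tolerance = 1e-6)
})

test_that("simulation matches the Gompertz closed form with frozen vasculature", {
  # single compartment, no mutation, no therapy, K frozen:
  # N1(t) = K^(1 - exp(-lambda t)) * N1(0)^(exp(-lambda t))
  p <- model_params(lambda1 = 0.192, lambda2 = 0, tau1 = 0, tau2 = 0,
                    mu = 0, b = 0, d = 0, beta1 = 0, beta = 0, gamma = 0)
  K <- 650; N10 <- 50
  tr <- simulate_tumor(p, tumor_state(N10, 1e-9 + 1e-10, K),
                       dose_schedule(0, 0, 20), rel_tol = 1e-10)
  e <- exp(-0.192 * tr$times)
  closed <- K^(1 - e) * N10^e
  expect_lt(max(abs(tr$states[, 1] - closed) / closed), 1e-5)
})

test_that("mutation exchange conserves total volume when growth and kill are off", {
  p <- model_params(lambda1 = 0, lambda2 = 0, tau1 = 3e-3, tau2 = 7e-4,
                    mu = 0, b = 0, d = 0, beta1 = 0, beta = 0, gamma = 0)
  tr <- simulate_tumor(p, tumor_state(200, 100, 500),
                       dose_schedule(0, 0, 50), rel_tol = 1e-10)
  tot <- tr$states[, 1] + tr$states[, 2]
  expect_lt(max(abs(tot - 300)) / 300, 1e-7)
})

test_that("states stay strictly positive under randomized schedules", {
  set.seed(42)
  p <- nominal_params()
  for (i in 1:8) {
    brk <- sort(c(0, runif(3, 0.5, 29.5), 30))
    sched <- dose_schedule(u = runif(4), v = runif(1), horizon = 30,
                           breaks = brk)
    tr <- simulate_tumor(p, small_tumor(), sched)
    expect_true(all(tr$states > 0))
  }
})

test_that("halving the rate constants doubles event times (time rescaling)", {
  p1 <- model_params(lambda1 = 0.192, lambda2 = 0, tau1 = 0, tau2 = 0,
                     mu = 0, b = 0, d = 0, beta1 = 0, beta = 0, gamma = 0)
  p2 <- model_params(lambda1 = 0.096, lambda2 = 0, tau1 = 0, tau2 = 0,
                     mu = 0, b = 0, d = 0, beta1 = 0, beta = 0, gamma = 0)
  s <- tumor_state(100, 1e-9, 650)
  t1 <- as.numeric(doubling_time_numeric(p1, s))
  t2 <- as.numeric(doubling_time_numeric(p2, s))
  expect_equal(t2 / t1, 2, tolerance = 1e-4)
  # full system: doubling every rate constant halves the doubling time
  pf <- nominal_params()
  ph <- model_params(lambda1 = 2 * pf$lambda1, lambda2 = 2 * pf$lambda2,
                     tau1 = 2 * pf$tau1, tau2 = 2 * pf$tau2, mu = 2 * pf$mu,
                     b = 2 * pf$b, d = 2 * pf$d, beta1 = pf$beta1,
                     beta = pf$beta, gamma = pf$gamma)
  expect_equal(as.numeric(doubling_time_numeric(ph, small_tumor())) /
                 as.numeric(doubling_time_numeric(pf, small_tumor())),
               0.5, tolerance = 1e-4)
})

test_that("doubling time is flagged not-reached from the saturating volume", {
  p <- nominal_params()
  sat <- find_steady_state(p, 0, 0, tumor_state(6000, 12000, 17000))$state
  td <- doubling_time_numeric(p, sat, cap = 20)
  expect_true(is.na(td))
  expect_false(attr(td, "reached"))
})

test_that("closed-form doubling time evaluates and scales as ln2/(lambda ln ratio)", {
  expect_equal(doubling_time_formula(0.192, 17000, 300),
               log(2) / (0.192 * (log(17000) - log(300))))
  expect_equal(doubling_time_formula(1, 2, 1), 1)          # reduces to ln2/ln2
  expect_equal(doubling_time_formula(0.5, 900, 30),
               2 * doubling_time_formula(1, 900, 30))      # T ~ 1/lambda
  expect_error(doubling_time_formula(0.2, 300, 300), "n_sat")
})

test_that("zero-length span returns the initial point unchanged", {
  tr <- simulate_tumor(nominal_params(), small_tumor(),
                       dose_schedule(0.3, 0.5, 10), t_span = c(0, 0))
  expect_equal(length(tr$times), 1L)
  expect_equal(unname(tr$states[1, ]), c(280, 20, 650))
})

test_that("untreated steady state matches the closed-form saturating volume", {
  # no mutation, single-compartment branch: N = K = ((b - mu)/d)^{3/2}
  p <- model_params(tau1 = 0, tau2 = 0)
  ss <- find_steady_state(p, 0, 0, tumor_state(17000, 1e-7, 17000))
  n_sat <- ((p$b - p$mu) / p$d)^1.5
  expect_equal(unname(ss$state[1] + ss$state[2]), n_sat, tolerance = 1e-6)
  expect_lt(ss$residual_norm, 1e-9)
})

test_that("treated steady state is attracting, resistant-dominated, and consistent with simulation", {
  p <- nominal_params()
  ss <- find_steady_state(p, 0.25, 0.5, tumor_state(100, 4000, 3000))
  expect_lt(ss$residual_norm, 1e-9)
  expect_true(ss$stable)
  expect_gt(ss$state[2], ss$state[1])  # resistant tumor at equilibrium
  # trajectories started near the steady state stay in a shrinking neighborhood
  s0 <- tumor_state(ss$state[1] * 1.05, ss$state[2] * 1.05, ss$state[3] * 1.05)
  tr <- simulate_tumor(p, s0, dose_schedule(0.25, 0.5, 400), rel_tol = 1e-8)
  dev <- abs(sweep(tr$states, 2, as.numeric(ss$state), `/`) - 1)
  n <- nrow(dev)
  expect_lt(max(dev[n, ]), max(dev[1, ]))
  expect_lt(max(dev[n, ]), 0.01)
})
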