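#' Right-hand side of the tumor-angiogenesis system
#'
#' Evaluates the vector field of the heterogeneous model
#' \deqn{\dot N_1 = -\lambda_1 N_1 \ln\frac{N_1+N_2}{K} - \tau_1 N_1 + \tau_2 N_2 - \beta_1 N_1 u}
#' \deqn{\dot N_2 = -\lambda_2 N_2 \ln\frac{N_1+N_2}{K} + \tau_1 N_1 - \tau_2 N_2}
#' \deqn{\dot K = -\mu K + b(N_1+N_2) - d (N_1+N_2)^{2/3} K - \beta K u - \gamma K v}
#' Sensitive cells are killed by chemotherapy under the log-kill hypothesis;
#' the vasculature is hit by both agents; mutation exchanges cells between the
#' two compartments at constant per-cell rates.
#'
#' @param state A `tumor_state` (or numeric triple), strictly positive.
#' @param u Chemotherapy dose in [0, 1] (fraction of MTD).
#' @param v Anti-angiogenic dose in [0, 1].
#' @param params A `model_params` object.
#' @return Named numeric rates `(N1, N2, K)` in mm^3/day.
#' @export
#' @examples
#' tumor_rhs(tumor_state(280, 20, 650), u = 0.25, v = 0.5, model_params())
tumor_rhs <- function(state, u, v, params) {
  s <- as_tumor_state(state)
  if (u < 0 || u > 1 || v < 0 || v > 1)
    stop("doses u and v must lie in [0, 1]", call. = FALSE)
  f <- rhs_cpp(param_vec(params), as.numeric(s), u, v)
  names(f) <- c("N1", "N2", "K")
  f
}

#' Analytic Jacobian of the vector field
#'
#' @inheritParams tumor_rhs
#' @return 3x3 matrix of partial derivatives with respect to `(N1, N2, K)`.
#' @export
tumor_jacobian <- function(state, u, v, params) {
  s <- as_tumor_state(state)
  J <- jac_cpp(param_vec(params), as.numeric(s), u, v)
  dimnames(J) <- list(c("N1", "N2", "K"), c("N1", "N2", "K"))
  J
}

# deSolve-facing RHS closure for a fixed (u, v)
desolve_rhs <- function(params) {
  pv <- param_vec(params)
  function(t, y, parms) {
    list(rhs_cpp(pv, y, parms[["u"]], parms[["v"]]))
  }
}

# integrate one constant-control segment with RK45, returning states at `times`
integrate_segment <- function(params, y0, u, v, times, rel_tol = 1e-6,
                              abs_tol = 1e-8) {
  out <- deSolve::ode(y = c(N1 = y0[1], N2 = y0[2], K = y0[3]),
                      times = times, func = desolve_rhs(params),
                      parms = c(u = u, v = v), method = "ode45",
                      rtol = rel_tol, atol = abs_tol)
  m <- unclass(out)
  if (nrow(m) < length(times))
    stop("integration failed before t = ", max(times),
         " (state likely left the positive orthant)", call. = FALSE)
  if (any(m[, 2:4] <= -1e-12))
    stop("integration left the positive orthant beyond tolerance", call. = FALSE)
  m
}

#' Simulate the model under a dose schedule
#'
#' Adaptive Runge-Kutta (4,5) integration. Piecewise-constant chemotherapy is
#' applied left-continuously and the integrator is restarted at every control
#' breakpoint, so control discontinuities never fall inside an adaptive step.
#'
#' @param params A `model_params` object.
#' @param initial Initial `tumor_state`.
#' @param schedule A `dose_schedule`.
#' @param t_span Integration interval `c(t0, t1)` within the schedule horizon;
#'   defaults to the full horizon. A zero-length span returns a single-point
#'   trajectory.
#' @param rel_tol Relative integration tolerance (default 1e-6).
#' @param n_out Approximate number of output points over the span.
#' @return A `tumor_trajectory`: list with `times`, `states` (matrix with
#'   columns N1, N2, K), `u` (control at each output time) and `v`.
#' @export
#' @examples
#' tr <- simulate_tumor(model_params(), tumor_state(280, 20, 650),
#'                      dose_schedule(u = 0.25, v = 0.5, horizon = 30))
#' tail(tr$states, 1)
simulate_tumor <- function(params, initial, schedule,
                           t_span = c(0, schedule$horizon),
                           rel_tol = 1e-6, n_out = 800) {
  init <- as_tumor_state(initial)
  stopifnot(inherits(schedule, "dose_schedule"))
  t0 <- t_span[1]; t1 <- t_span[2]
  if (t1 < t0) stop("'t_span' must be non-decreasing", call. = FALSE)
  if (t1 == t0) {
    tr <- list(times = t0,
               states = matrix(as.numeric(init), 1, 3,
                               dimnames = list(NULL, c("N1", "N2", "K"))),
               u = schedule_u_at(schedule, t0), v = schedule$v)
    return(structure(tr, class = "tumor_trajectory"))
  }
  brk <- schedule$breaks
  cut_pts <- sort(unique(c(t0, t1, brk[brk > t0 & brk < t1])))
  times_all <- numeric(0); states_all <- NULL; u_all <- numeric(0)
  y <- as.numeric(init)
  for (i in seq_len(length(cut_pts) - 1L)) {
    a <- cut_pts[i]; b <- cut_pts[i + 1L]
    useg <- schedule_u_at(schedule, a)
    npt <- max(2L, ceiling(n_out * (b - a) / (t1 - t0)))
    tt <- seq(a, b, length.out = npt)
    m <- integrate_segment(params, y, useg, schedule$v, tt, rel_tol)
    y <- as.numeric(m[nrow(m), 2:4])
    keep <- if (i == 1L) seq_len(nrow(m)) else 2:nrow(m)
    times_all <- c(times_all, m[keep, 1])
    states_all <- rbind(states_all, m[keep, 2:4, drop = FALSE])
    u_all <- c(u_all, rep(useg, length(keep)))
  }
  colnames(states_all) <- c("N1", "N2", "K")
  structure(list(times = times_all, states = states_all, u = u_all,
                 v = schedule$v),
            class = "tumor_trajectory")
}

#' @export
print.tumor_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Tumor trajectory: %d points on [%.4g, %.4g] days\n",
              n, x$times[1], x$times[n]))
  cat(sprintf("  final state: N1 = %.4g, N2 = %.4g, K = %.4g mm^3 (total %.4g)\n",
              x$states[n, 1], x$states[n, 2], x$states[n, 3],
              x$states[n, 1] + x$states[n, 2]))
  invisible(x)
}

# First time total volume N1+N2 crosses `threshold` from below, under constant
# (u, v). Coarse RK45 scan brackets the crossing; bisection (re-integrating
# from the stored bracket-left state) refines it to `tol` days.
# Returns NA_real_ if no crossing by t_max.
first_passage_time <- function(params, initial, u, v, threshold, t_max,
                               tol = 1e-6, rel_tol = 1e-8) {
  y <- as.numeric(as_tumor_state(initial))
  if (sum(y[1:2]) >= threshold) return(0)
  chunk <- max(t_max / 50, 1e-3)
  step <- max(min(chunk / 80, 0.25), tol)
  t_now <- 0
  while (t_now < t_max) {
    t_end <- min(t_now + chunk, t_max)
    tt <- seq(t_now, t_end, by = step)
    if (tt[length(tt)] < t_end) tt <- c(tt, t_end)
    m <- integrate_segment(params, y, u, v, tt, rel_tol)
    tot <- m[, 2] + m[, 3]
    idx <- which(tot >= threshold)
    if (length(idx) > 0) {
      i <- idx[1]
      if (i == 1L) return(unname(t_now))  # boundary case: already at threshold
      ta <- unname(m[i - 1L, 1]); tb <- unname(m[i, 1])
      ya <- as.numeric(m[i - 1L, 2:4])
      # bisection on the bracket; each probe integrates from (ta, ya)
      while (tb - ta > tol) {
        tm <- 0.5 * (ta + tb)
        mm <- integrate_segment(params, ya, u, v, c(ta, tm), rel_tol)
        ym <- as.numeric(mm[nrow(mm), 2:4])
        if (ym[1] + ym[2] >= threshold) {
          tb <- tm
        } else {
          ta <- tm; ya <- ym
        }
      }
      return(unname(0.5 * (ta + tb)))
    }
    y <- as.numeric(m[nrow(m), 2:4])
    t_now <- t_end
  }
  NA_real_
}

#' Numerical tumor doubling time
#'
#' First time the untreated total volume N1+N2 reaches twice its initial
#' value, located by event detection with bisection refinement to 1e-6 day.
#'
#' @param params A `model_params` object.
#' @param initial Initial `tumor_state`.
#' @param cap Search cap (days); beyond it the doubling is reported as not
#'   reached (e.g. when starting at the saturating volume).
#' @return Doubling time in hours, or `NA` with attribute `reached = FALSE`
#'   when the volume never doubles within `cap`.
#' @export
#' @examples
#' doubling_time_numeric(model_params(), tumor_state(280, 20, 650))
doubling_time_numeric <- function(params, initial, cap = 100) {
  init <- as_tumor_state(initial)
  target <- 2 * total_volume(init)
  t_d <- first_passage_time(params, init, u = 0, v = 0, threshold = target,
                            t_max = cap)
  if (is.na(t_d)) return(structure(NA_real_, reached = FALSE))
  structure(t_d * 24, reached = TRUE)
}

#' Closed-form Gompertz doubling time
#'
#' \deqn{T = \frac{\ln 2}{\lambda(\ln N_{sat} - \ln N_{init})}}
#' i.e. ln 2 divided by the instantaneous per-volume growth rate of a
#' Gompertz tumor of size `n_init` saturating at `n_sat`.
#'
#' @param lam Growth rate (1/day).
#' @param n_sat Saturating volume (mm^3).
#' @param n_init Initial volume (mm^3), with `n_sat > n_init > 0`.
#' @return Doubling time in days.
#' @export
#' @examples
#' doubling_time_formula(0.192, 17000, 300)
doubling_time_formula <- function(lam, n_sat, n_init) {
  if (lam <= 0) stop("'lam' must be positive", call. = FALSE)
  if (n_init <= 0 || n_sat <= n_init)
    stop("need n_sat > n_init > 0", call. = FALSE)
  log(2) / (lam * (log(n_sat) - log(n_init)))
}

#' Steady state of the system under constant dosing
#'
#' Finds a root of the vector field by Levenberg-Marquardt least squares in
#' log-coordinates (which keeps all components strictly positive), with the
#' analytic Jacobian, then reports the eigenvalues of the
#' central-finite-difference Jacobian and a stability flag. For biologically
#' relevant doses the system has an attracting positive steady state; under
#' sustained chemotherapy it is dominated by the resistant compartment.
#'
#' @param params A `model_params` object.
#' @param u,v Constant doses in [0, 1].
#' @param guess Strictly positive initial `tumor_state` guess.
#' @param tol Residual tolerance (max |rhs|, mm^3/day).
#' @return A `steady_state_report`: list with `state`, `residual_norm`,
#'   `eigenvalues`, `stable`.
#' @export
#' @examples
#' find_steady_state(model_params(), u = 0.25, v = 0.5,
#'                   guess = tumor_state(100, 4000, 3000))
find_steady_state <- function(params, u, v, guess, tol = 1e-9) {
  g <- as_tumor_state(guess)
  pv <- param_vec(params)
  # Solve for per-capita rates rhs(x)/x = 0 in z = log(x): this removes the
  # spurious root at the origin (where all extensive rates vanish) and is
  # well scaled across the three components.
  resid <- function(z) rhs_cpp(pv, exp(z), u, v) / exp(z)
  jac_z <- function(z) {
    x <- exp(z)
    f <- rhs_cpp(pv, x, u, v)
    J <- jac_cpp(pv, x, u, v)
    # d(f_i/x_i)/dz_j = (x_j/x_i) J_ij - delta_ij f_i/x_i
    Jz <- sweep(sweep(J, 2, x, `*`), 1, x, `/`)
    Jz - diag(f / x)
  }
  fit <- minpack.lm::nls.lm(par = log(as.numeric(g)), fn = resid, jac = jac_z,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-15, ptol = 1e-15,
                              maxiter = 1000, maxfev = 100000))
  z <- fit$par
  for (i in 1:100) {  # Newton polish with capped log-steps
    r <- resid(z)
    if (max(abs(r)) < 1e-13) break
    dz <- tryCatch(solve(jac_z(z), -r), error = function(e) NULL)
    if (is.null(dz)) break
    z <- z + pmin(pmax(dz, -1), 1)
  }
  r <- rhs_cpp(pv, exp(z), u, v)
  if (max(abs(r)) >= tol)
    stop("steady-state solver did not converge; last residual ",
         format(max(abs(r))), call. = FALSE)
  x_star <- exp(z)
  # central finite-difference Jacobian at the root
  Jn <- matrix(0, 3, 3)
  hstep <- pmax(1e-6 * abs(x_star), 1e-9)
  for (j in 1:3) {
    xp <- x_star; xm <- x_star
    xp[j] <- xp[j] + hstep[j]; xm[j] <- xm[j] - hstep[j]
    Jn[, j] <- (rhs_cpp(pv, xp, u, v) - rhs_cpp(pv, xm, u, v)) / (2 * hstep[j])
  }
  ev <- eigen(Jn, only.values = TRUE)$values
  structure(list(state = tumor_state(x_star[1], x_star[2], x_star[3]),
                 residual_norm = max(abs(r)),
                 eigenvalues = ev,
                 stable = all(Re(ev) < 0)),
            class = "steady_state_report")
}

#' @export
print.steady_state_report <- function(x, ...) {
  s <- x$state
  cat(sprintf("Steady state: N1 = %.6g, N2 = %.6g, K = %.6g mm^3 (total %.6g)\n",
              s[1], s[2], s[3], s[1] + s[2]))
  cat(sprintf("  residual %.3g; %s (max Re(eig) = %.3g)\n", x$residual_norm,
              if (x$stable) "attracting" else "unstable",
              max(Re(x$eigenvalues))))
  invisible(x)
}
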