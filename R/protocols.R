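#' Piecewise-constant suboptimal protocol from an optimal schedule
#'
#' Builds the clinically realizable four-phase approximation
#' MTD / c1 / c2 / MTD of a bang-singular-bang optimal schedule. The switch
#' times (t1, t2, t3) and interior levels (c1, c2) are initialized from the
#' detected singular arc (its boundaries, midpoint and segment means) and then
#' refined by Nelder-Mead on the continuous-time objective (RK45 simulation
#' plus trapezoid quadrature), since the deployed protocol runs in continuous
#' time. With `levels = "mean"` the interior levels are frozen at the segment
#' means of the optimal control and only the switch times move.
#'
#' @param solution A solved `ocp_solution` with a detected singular arc.
#' @param params,initial,weights,v The problem the solution came from.
#' @param levels "optimize" (default) refines c1, c2 together with the switch
#'   times; "mean" keeps them at the singular-segment means.
#' @param maxit Nelder-Mead iteration cap.
#' @return A `piecewise_protocol`: `switch_times` (t1 < t2 < t3),
#'   `levels` (c(1, c1, c2, 1)), `objective` (continuous-time
#'   `objective_value`), `objective_euler` (same protocol scored with the
#'   solver's own forward-Euler/left-rectangle quadrature),
#'   `average_dose_pct`, and `gap_pct` (relative objective excess over the
#'   reference solution, Euler quadrature on both sides).
#' @export
approximate_piecewise <- function(solution, params, initial, weights, v,
                                  levels = c("optimize", "mean"),
                                  maxit = 400) {
  levels <- match.arg(levels)
  sing <- extract_singular(solution)
  if (!sing$has_singular)
    stop("no singular arc detected; the reference solution looks full-dose",
         call. = FALSE)
  init <- as_tumor_state(initial)
  horizon <- solution$horizon
  seg <- sing$segments[[1]]
  last <- sing$segments[[length(sing$segments)]]
  t1_0 <- seg$start
  t3_0 <- last$end
  t2_0 <- 0.5 * (t1_0 + t3_0)
  u <- solution$control; tt <- solution$times
  mids <- 0.5 * (tt[-length(tt)] + tt[-1])
  seg_mean <- function(a, b) {
    sel <- mids >= a & mids < b
    if (!any(sel)) return(mean(u))
    mean(u[sel])
  }
  c1_0 <- seg_mean(t1_0, t2_0)
  c2_0 <- seg_mean(t2_0, t3_0)

  protocol_objective <- function(t1, t2, t3, c1, c2) {
    sched <- dose_schedule(u = c(1, c1, c2, 1), v = v, horizon = horizon,
                           breaks = c(0, t1, t2, t3, horizon))
    tr <- simulate_tumor(params, init, sched, rel_tol = 1e-8, n_out = 1400)
    evaluate_objective(tr, weights, quadrature = "trapezoid")$total
  }
  eps_t <- 1e-3
  score <- function(par) {
    if (levels == "optimize") {
      t1 <- par[1]; t2 <- par[2]; t3 <- par[3]; c1 <- par[4]; c2 <- par[5]
    } else {
      t1 <- par[1]; t2 <- par[2]; t3 <- par[3]; c1 <- c1_0; c2 <- c2_0
    }
    if (!(t1 > eps_t && t2 > t1 + eps_t && t3 > t2 + eps_t &&
          t3 < horizon - eps_t && c1 >= 0 && c1 <= 1 && c2 >= 0 && c2 <= 1))
      return(1e12)
    protocol_objective(t1, t2, t3, c1, c2)
  }
  par0 <- if (levels == "optimize") c(t1_0, t2_0, t3_0, c1_0, c2_0)
          else c(t1_0, t2_0, t3_0)
  j0 <- score(par0)
  fit <- stats::optim(par0, score, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  # restart once from the incumbent; Nelder-Mead benefits from a fresh simplex
  fit2 <- stats::optim(fit$par, score, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-10))
  if (fit2$value <= fit$value) fit <- fit2
  if (fit$value > j0) fit <- list(par = par0, value = j0)
  p <- fit$par
  t123 <- p[1:3]
  cc <- if (levels == "optimize") p[4:5] else c(c1_0, c2_0)

  sched <- dose_schedule(u = c(1, cc[1], cc[2], 1), v = v, horizon = horizon,
                         breaks = c(0, t123, horizon))
  tr <- simulate_tumor(params, init, sched, rel_tol = 1e-8, n_out = 1400)
  obj_cont <- evaluate_objective(tr, weights, quadrature = "trapezoid")

  # score the same protocol with the solver's own quadrature for the gap
  nlp <- solution$nlp
  if (is.null(nlp))
    nlp <- transcribe(params, init, weights, v,
                      transcription_settings(n_nodes = length(u),
                                             horizon = horizon))
  u_grid <- schedule_u_at(sched, nlp$times[-length(nlp$times)])
  og <- nlp$objgrad(u_grid)
  obj_euler <- objective_value_from_parts(og$terminal_part,
                                          og$running_tumor_part,
                                          og$resistance_part, og$dose_part)
  dur <- diff(c(0, t123, horizon))
  avg <- 100 * sum(dur * c(1, cc[1], cc[2], 1)) / horizon
  structure(list(switch_times = t123,
                 levels = c(1, cc[1], cc[2], 1),
                 objective = obj_cont,
                 objective_euler = obj_euler,
                 average_dose_pct = avg,
                 gap_pct = suboptimality_gap(obj_euler, solution$objective),
                 schedule = sched,
                 trajectory = tr),
            class = "piecewise_protocol")
}

#' @export
print.piecewise_protocol <- function(x, ...) {
  cat(sprintf("Piecewise protocol MTD/%.3g/%.3g/MTD, switches at (%.3g, %.3g, %.3g) days\n",
              x$levels[2], x$levels[3],
              x$switch_times[1], x$switch_times[2], x$switch_times[3]))
  cat(sprintf("  average dose %.4g%% of MTD; objective gap %.4g%%\n",
              x$average_dose_pct, x$gap_pct))
  invisible(x)
}

#' Relative suboptimality gap in percent
#'
#' `100 * (J_sub - J_opt) / J_opt`.
#'
#' @param j_sub,j_opt Objective values (`objective_value` or bare numbers);
#'   `j_opt` must be positive.
#' @return Percentage excess (can be slightly negative when the suboptimal
#'   family stumbles on a marginally better point).
#' @export
suboptimality_gap <- function(j_sub, j_opt) {
  a <- if (inherits(j_sub, "objective_value")) j_sub$total else as.numeric(j_sub)
  b <- if (inherits(j_opt, "objective_value")) j_opt$total else as.numeric(j_opt)
  if (b <= 0) stop("reference objective must be positive", call. = FALSE)
  100 * (a - b) / b
}

#' Resistant-vs-sensitive phase-plane data
#'
#' Projects a trajectory onto the (N1, N2) plane, labeling each point by its
#' control regime (full dose, interior/singular, off) and reporting crossings
#' of the diagonal N2 = N1 (the boundary where the tumor switches from
#' majority-sensitive to majority-resistant).
#'
#' @param traj A `tumor_trajectory` with control annotations.
#' @param lo,hi Interior-dose thresholds used for regime labels.
#' @return List with `path` (data frame `t, N1, N2, regime`) and
#'   `diagonal_crossings` (times where N2 - N1 changes sign).
#' @export
resistance_phase_data <- function(traj, lo = 0.02, hi = 0.98) {
  n <- length(traj$times)
  if (n == 0)
    return(list(path = data.frame(t = numeric(0), N1 = numeric(0),
                                  N2 = numeric(0), regime = character(0)),
                diagonal_crossings = numeric(0)))
  uu <- if (is.null(traj$u)) rep(0, n) else traj$u
  regime <- ifelse(uu >= hi, "full",
                   ifelse(uu > lo, "singular", "off"))
  path <- data.frame(t = traj$times, N1 = traj$states[, 1],
                     N2 = traj$states[, 2], regime = regime)
  dsign <- sign(path$N2 - path$N1)
  flips <- which(dsign[-1] * dsign[-n] < 0)
  crossings <- vapply(flips, function(i) {
    d1 <- path$N2[i] - path$N1[i]; d2 <- path$N2[i + 1] - path$N1[i + 1]
    path$t[i] + (path$t[i + 1] - path$t[i]) * d1 / (d1 - d2)
  }, numeric(1))
  list(path = path, diagonal_crossings = crossings)
}
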