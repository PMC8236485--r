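#' Transcribe the scheduling problem into a finite NLP
#'
#' Direct transcription ("first discretize, then optimize") of the 14-day
#' chemotherapy-scheduling problem: forward Euler on a regular grid of
#' `n_nodes` intervals, control bounds 0 <= u_k <= 1, state floor 1e-9 mm^3,
#' and the treatment objective with left-rectangle quadrature (the rule
#' conjugate to forward Euler). The state variables are eliminated through the
#' Euler recursion, so the returned NLP is the reduced problem in the control
#' values only; its minimizers coincide with those of the full
#' state-and-control transcription. Exact gradients come from the hand-coded
#' discrete adjoint of the analytic Jacobian.
#'
#' @param params A `model_params` object.
#' @param initial Initial `tumor_state`.
#' @param weights An `objective_weights` object.
#' @param v Constant anti-angiogenic dose in [0, 1].
#' @param settings A `transcription_settings` object.
#' @return An `ocp_nlp`: list with the problem dimensions (`n_controls`,
#'   `n_state_nodes`, `n_eq_constraints` = 3 * n_nodes of the full
#'   transcription), the grid (`h`, `times`), bounds, and closures
#'   `objective(u)`, `gradient(u)`, `rollout(u)` and
#'   `euler_residual(states, u)` (defect of a state sequence against the
#'   Euler recursion).
#' @export
transcribe <- function(params, initial, weights, v,
                       settings = transcription_settings()) {
  stopifnot(inherits(settings, "transcription_settings"))
  init <- as_tumor_state(initial)
  pv <- param_vec(params)
  wv <- weight_vec(weights)
  M <- settings$n_nodes
  h <- settings$horizon / M
  x0 <- as.numeric(init)
  nlp <- list(
    n_controls = M,
    n_state_nodes = M + 1L,
    n_eq_constraints = 3L * M,
    h = h,
    times = seq(0, settings$horizon, length.out = M + 1L),
    horizon = settings$horizon,
    u_lower = rep(0, M), u_upper = rep(1, M),
    state_floor = 1e-9,
    v = v,
    params = params, weights = weights, initial = init,
    settings = settings,
    objective = function(u) euler_objgrad(pv, x0, u, v, h, wv, FALSE)$objective,
    gradient = function(u) euler_objgrad(pv, x0, u, v, h, wv, TRUE)$gradient,
    objgrad = function(u) euler_objgrad(pv, x0, u, v, h, wv, TRUE),
    rollout = function(u) euler_rollout(pv, x0, u, v, h),
    euler_residual = function(states, u) {
      f <- t(vapply(seq_len(M), function(k)
        rhs_cpp(pv, pmax(states[k, ], 1e-12), u[k], v), numeric(3)))
      states[-1, , drop = FALSE] - states[-(M + 1L), , drop = FALSE] - h * f
    })
  structure(nlp, class = "ocp_nlp")
}

#' Solve the transcribed scheduling problem
#'
#' Minimizes the reduced transcription with projected quasi-Newton (L-BFGS-B)
#' under the control box constraints, using exact adjoint gradients, from
#' every constant seed in `settings$multistart`. The best objective wins;
#' ties (within 1e-9 relative) break toward the lower average dose.
#'
#' @param nlp An `ocp_nlp` from [transcribe()].
#' @param settings Optional `transcription_settings` overriding the one
#'   stored in the NLP (e.g. a different multistart set).
#' @return An `ocp_solution`: list with `control` (length M), `times`
#'   (M+1 node times), `states` (Euler state sequence), `objective`
#'   (`objective_value` under the NLP's own left-rectangle quadrature),
#'   `average_dose_pct`, `singular` segments, `v`, and per-start diagnostics
#'   in `starts`.
#' @export
#' @examples
#' \donttest{
#' nlp <- transcribe(model_params(), tumor_state(280, 20, 650),
#'                   objective_weights(), v = 0.5)
#' sol <- solve_ocp(nlp)
#' sol$average_dose_pct
#' }
solve_ocp <- function(nlp, settings = NULL) {
  stopifnot(inherits(nlp, "ocp_nlp"))
  if (is.null(settings)) settings <- nlp$settings
  M <- nlp$n_controls
  runs <- lapply(settings$multistart, function(u0) {
    fit <- stats::optim(rep(u0, M), fn = nlp$objective, gr = nlp$gradient,
                        method = "L-BFGS-B", lower = 0, upper = 1,
                        control = list(maxit = settings$maxit,
                                       factr = 10,
                                       pgtol = settings$nlp_tol,
                                       lmm = 20))
    list(seed = u0, value = fit$value, par = fit$par,
         convergence = fit$convergence, message = fit$message)
  })
  vals <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(vals)))
    stop("optimizer failed on all starts", call. = FALSE)
  best_val <- min(vals)
  near <- which(vals <= best_val * (1 + 1e-9) + 1e-12)
  avg <- vapply(near, function(i) mean(runs[[i]]$par), numeric(1))
  i_best <- near[which.min(avg)]
  u_opt <- pmin(pmax(runs[[i_best]]$par, 0), 1)  # clip round-off at bounds
  og <- nlp$objgrad(u_opt)
  obj <- objective_value_from_parts(og$terminal_part, og$running_tumor_part,
                                    og$resistance_part, og$dose_part)
  sol <- structure(list(
    control = u_opt,
    times = nlp$times,
    states = og$states,
    objective = obj,
    v = nlp$v,
    horizon = nlp$horizon,
    average_dose_pct = mean(u_opt) * 100,
    solver_status = runs[[i_best]]$convergence,
    starts = data.frame(seed = vapply(runs, `[[`, numeric(1), "seed"),
                        objective = vals,
                        convergence = vapply(runs, `[[`, numeric(1),
                                             "convergence")),
    nlp = nlp), class = "ocp_solution")
  sol$singular <- extract_singular(sol)
  sol
}

#' @export
print.ocp_solution <- function(x, ...) {
  cat(sprintf("Optimal chemotherapy schedule over %.4g days (v = %.4g):\n",
              x$horizon, x$v))
  cat(sprintf("  J = %.6g; average dose %.4g%% of MTD\n",
              x$objective$total, x$average_dose_pct))
  if (length(x$singular$segments) > 0) {
    seg <- x$singular$segments[[1]]
    cat(sprintf("  singular arc: first interior entry at t = %.3g days; mean singular dose %.4g%%\n",
                seg$start, x$singular$mean_dose_pct))
  } else {
    cat("  no interior (singular) arc: bang-bang control\n")
  }
  invisible(x)
}

#' Time-averaged dose as a percentage of MTD
#'
#' @param control Control values on a uniform grid, or a two-column matrix /
#'   data frame of `(duration, level)` segments.
#' @param horizon Unused for the uniform-grid form (kept for symmetry).
#' @return Time-average of the control times 100.
#' @export
average_dose <- function(control, horizon = NULL) {
  if (is.matrix(control) || is.data.frame(control)) {
    dur <- control[, 1]; lev <- control[, 2]
    return(100 * sum(dur * lev) / sum(dur))
  }
  100 * mean(control)
}

#' Extract singular (interior-dose) arcs from a solved schedule
#'
#' Maximal runs of at least `min_len` consecutive grid nodes whose dose lies
#' strictly between `lo` and `hi` (away from both control bounds), and the
#' mean dose over their union. For the nominal problem the optimal schedule
#' is bang-singular-bang: full dose, one long interior arc, full dose.
#'
#' @param solution An `ocp_solution` (or a list with `control` and `times`).
#' @param lo,hi Interior thresholds, `lo < hi` (defaults 0.02 / 0.98).
#' @param min_len Minimum run length in nodes.
#' @return List with `segments` (each `start`, `end` in days, `mean`) and
#'   `mean_dose_pct` (`NA` and a `has_singular = FALSE` flag when no interior
#'   run exists).
#' @export
extract_singular <- function(solution, lo = 0.02, hi = 0.98, min_len = 3L) {
  if (lo >= hi) stop("need lo < hi", call. = FALSE)
  u <- solution$control
  tt <- solution$times
  interior <- u > lo & u < hi
  r <- rle(interior)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  sel <- logical(length(u))
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= min_len) {
      ks <- starts[i]:ends[i]
      sel[ks] <- TRUE
      segs[[length(segs) + 1L]] <-
        list(start = tt[starts[i]], end = tt[ends[i] + 1L],
             mean = mean(u[ks]))
    }
  }
  list(segments = segs,
       has_singular = length(segs) > 0,
       mean_dose_pct = if (any(sel)) 100 * mean(u[sel]) else NA_real_)
}

#' Classify a schedule as full-dose or intermediate-dose
#'
#' A protocol is full-dose when its time-averaged dose strictly exceeds 90%
#' of MTD; otherwise it is intermediate-dose.
#'
#' @param solution An `ocp_solution`, or anything with an `average_dose_pct`
#'   field, or a bare average-dose percentage.
#' @return List with `label` ("full-dose" / "intermediate-dose") and
#'   `average_dose_pct`.
#' @export
classify_protocol <- function(solution) {
  avg <- if (is.numeric(solution) && length(solution) == 1L) solution
         else solution$average_dose_pct
  list(label = if (avg > 90) "full-dose" else "intermediate-dose",
       average_dose_pct = avg)
}

# continuous-time trajectory of a solved (grid) control: RK45 with restarts
# at every grid node, using the node-wise piecewise-constant control
solution_schedule <- function(solution) {
  dose_schedule(u = solution$control, v = solution$v,
                horizon = solution$horizon, breaks = solution$times)
}

#' Sequential multi-window optimization
#'
#' Solves `n_windows` consecutive scheduling windows (receding horizon): the
#' terminal state of the continuous-time simulation of window k's optimal
#' schedule is the initial state of window k+1.
#'
#' @param params,initial,weights,v As in [transcribe()].
#' @param window A `transcription_settings` describing one window.
#' @param n_windows Number of consecutive windows (>= 1).
#' @return List with `windows` (per-window `ocp_solution`s), concatenated
#'   `control` and `times`, `window_average_dose_pct`, overall
#'   `average_dose_pct`, and the continuous-time `trajectory` over all
#'   windows.
#' @export
multiwindow_optimize <- function(params, initial, weights, v,
                                 window = transcription_settings(),
                                 n_windows = 2) {
  if (n_windows < 1) stop("'n_windows' must be >= 1", call. = FALSE)
  state <- as_tumor_state(initial)
  sols <- vector("list", n_windows)
  ctrl <- numeric(0); times <- numeric(0)
  traj_t <- numeric(0); traj_s <- NULL; traj_u <- numeric(0)
  offset <- 0
  for (w in seq_len(n_windows)) {
    nlp <- transcribe(params, state, weights, v, window)
    sol <- tryCatch(solve_ocp(nlp),
                    error = function(e)
                      stop("window ", w, " failed: ", conditionMessage(e),
                           call. = FALSE))
    sols[[w]] <- sol
    tr <- simulate_tumor(params, state, solution_schedule(sol),
                         rel_tol = 1e-8)
    state <- tumor_state(tr$states[nrow(tr$states), 1],
                         tr$states[nrow(tr$states), 2],
                         tr$states[nrow(tr$states), 3])
    ctrl <- c(ctrl, sol$control)
    times <- c(times, offset + sol$times[-length(sol$times)])
    keep <- if (w == 1L) seq_along(tr$times) else -1L
    traj_t <- c(traj_t, offset + tr$times[keep])
    traj_s <- rbind(traj_s, tr$states[keep, , drop = FALSE])
    traj_u <- c(traj_u, tr$u[keep])
    offset <- offset + window$horizon
  }
  times <- c(times, offset)
  traj <- structure(list(times = traj_t, states = traj_s, u = traj_u, v = v),
                    class = "tumor_trajectory")
  list(windows = sols,
       control = ctrl,
       times = times,
       window_average_dose_pct = vapply(sols, function(s) s$average_dose_pct,
                                        numeric(1)),
       average_dose_pct = mean(ctrl) * 100,
       trajectory = traj)
}

#' Compare the optimal schedule with reference protocols
#'
#' Simulates four protocols over `n_windows` consecutive windows from the
#' same initial state and reports, per protocol, the total volume at the end
#' of the first window and at the end of therapy, the per-window tumor
#' minima, and the resistant fraction at both time points:
#' \itemize{
#'   \item \code{optimal}: the resistance-penalizing optimal schedule in
#'     every window;
#'   \item \code{mtd}: maximum tolerated dose throughout (u = 1);
#'   \item \code{mean_dose}: the constant dose equal to the optimal
#'     schedule's overall average;
#'   \item \code{oc_then_mtd}: the optimal schedule in the first window, MTD
#'     in the remaining ones.
#' }
#'
#' @inheritParams multiwindow_optimize
#' @return List with `table` (one row per protocol) and `trajectories`.
#' @export
compare_protocols <- function(params, initial, weights, v,
                              window = transcription_settings(),
                              n_windows = 2) {
  opt <- multiwindow_optimize(params, initial, weights, v, window, n_windows)
  horizon <- window$horizon * n_windows
  mean_u <- mean(opt$control)
  schedules <- list(
    optimal = dose_schedule(u = opt$control, v = v, horizon = horizon,
                            breaks = opt$times),
    mtd = dose_schedule(u = 1, v = v, horizon = horizon),
    mean_dose = dose_schedule(u = mean_u, v = v, horizon = horizon),
    oc_then_mtd = dose_schedule(
      u = c(opt$windows[[1]]$control,
            rep(1, (n_windows - 1) * window$n_nodes)),
      v = v, horizon = horizon,
      breaks = seq(0, horizon, length.out = n_windows * window$n_nodes + 1)))
  trajs <- lapply(schedules, function(s)
    simulate_tumor(params, initial, s, rel_tol = 1e-8,
                   n_out = 400 * n_windows))
  summarize <- function(tr) {
    tot <- tr$states[, 1] + tr$states[, 2]
    rfrac <- tr$states[, 2] / tot
    i_mid <- which.min(abs(tr$times - window$horizon))
    n <- length(tr$times)
    win_min <- vapply(seq_len(n_windows), function(w) {
      sel <- tr$times >= (w - 1) * window$horizon &
             tr$times <= w * window$horizon
      min(tot[sel])
    }, numeric(1))
    c(volume_day_w1 = tot[i_mid], volume_final = tot[n],
      resistant_frac_w1 = rfrac[i_mid], resistant_frac_final = rfrac[n],
      min_volume = min(tot), setNames(win_min, paste0("min_window", seq_len(n_windows))))
  }
  tab <- as.data.frame(t(vapply(trajs, summarize,
                                numeric(5 + n_windows))))
  tab <- cbind(protocol = rownames(tab),
               average_dose_pct = c(opt$average_dose_pct, 100, mean_u * 100,
                                    average_dose(schedules$oc_then_mtd$u)),
               tab)
  rownames(tab) <- NULL
  list(table = tab, trajectories = trajs, optimal = opt)
}
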