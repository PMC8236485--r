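#' Survival time under constant dosing
#'
#' First-passage time of the total tumor volume N1+N2 to the critical (fatal)
#' volume under constant chemotherapy dose `u` and anti-angiogenic dose `v`.
#' The crossing is bracketed on an adaptive RK45 scan and refined by bisection
#' to 1e-6 day. If the volume stays below the critical level up to
#' `settings$t_max` the treatment holds the tumor indefinitely and the
#' survival time is reported as infinite.
#'
#' @param params A `model_params` object.
#' @param initial Initial `tumor_state`.
#' @param u,v Constant doses in [0, 1].
#' @param settings A `survival_settings` object (critical volume, time cap).
#' @return A `survival_result`: list with `t_s` (days; `Inf` when never
#'   reached) and `reached` flag. An initial volume already at or above the
#'   critical level gives `t_s = 0`.
#' @export
#' @examples
#' \donttest{
#' survival_time(model_params(), tumor_state(280, 20, 650),
#'               u = 0.2192, v = 0.5, survival_settings())
#' }
survival_time <- function(params, initial, u, v,
                          settings = survival_settings()) {
  stopifnot(inherits(settings, "survival_settings"))
  init <- as_tumor_state(initial)
  if (total_volume(init) >= settings$n_crit)
    return(structure(list(t_s = 0, reached = TRUE), class = "survival_result"))
  t_s <- first_passage_time(params, init, u, v, settings$n_crit,
                            settings$t_max)
  if (is.na(t_s))
    return(structure(list(t_s = Inf, reached = FALSE),
                     class = "survival_result"))
  structure(list(t_s = t_s, reached = TRUE), class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("Survival time: %.4g days\n", x$t_s))
  } else {
    cat("Survival time: infinite (critical volume never reached)\n")
  }
  invisible(x)
}

#' Survival-time sweep over chemotherapy doses
#'
#' @param params A `model_params` object.
#' @param initial Initial `tumor_state`.
#' @param u_grid Non-empty vector of chemotherapy doses in [0, 1].
#' @param v Fixed anti-angiogenic dose.
#' @param settings A `survival_settings` object.
#' @return Data frame `(u, t_s, reached)` in grid order; failed cells carry
#'   `NA` with `reached = NA`.
#' @export
dose_sweep <- function(params, initial, u_grid, v,
                       settings = survival_settings()) {
  if (length(u_grid) == 0) stop("'u_grid' must be non-empty", call. = FALSE)
  res <- lapply(u_grid, function(u) {
    tryCatch(survival_time(params, initial, u, v, settings),
             error = function(e) list(t_s = NA_real_, reached = NA))
  })
  data.frame(u = u_grid,
             t_s = vapply(res, function(r) r$t_s, numeric(1)),
             reached = vapply(res, function(r) as.logical(r$reached),
                              logical(1)))
}

#' Optimal constant chemotherapy dose for survival
#'
#' Maximizes the survival time over constant chemotherapy doses at fixed
#' anti-angiogenic dose: a coarse grid scan locates the best cell, then
#' golden-section search refines the interior maximum. If some dose holds the
#' tumor below the critical volume indefinitely, the smallest such dose on the
#' grid is reported with infinite survival.
#'
#' @param params,initial,v,settings As in [survival_time()].
#' @param u_grid Coarse scan grid (default 41 points on [0, 1]).
#' @param refine_tol Width tolerance of the golden-section bracket in `u`.
#' @return List with `u_star`, `t_s_star` and the scan table `sweep`.
#' @export
optimal_constant_dose <- function(params, initial, v,
                                  settings = survival_settings(),
                                  u_grid = seq(0, 1, length.out = 41),
                                  refine_tol = 1e-4) {
  sw <- dose_sweep(params, initial, u_grid, v, settings)
  ok <- !is.na(sw$t_s)
  if (!any(ok)) stop("all sweep cells failed", call. = FALSE)
  if (any(is.infinite(sw$t_s[ok]))) {
    u_inf <- min(sw$u[ok & is.infinite(sw$t_s)])
    return(list(u_star = u_inf, t_s_star = Inf, sweep = sw))
  }
  # best grid cell; near-ties (within 1e-3 day, e.g. a dose with no effect)
  # break to the smallest dose
  tie_tol <- 1e-3
  t_best <- max(sw$t_s[ok])
  i_best <- which(ok & sw$t_s >= t_best - tie_tol)[1]
  # golden-section on [u[i-1], u[i+1]] around the best cell
  lo <- sw$u[max(i_best - 1L, 1L)]
  hi <- sw$u[min(i_best + 1L, nrow(sw))]
  f <- function(u) {
    r <- survival_time(params, initial, u, v, settings)
    if (!r$reached) Inf else r$t_s
  }
  if (hi - lo < refine_tol) {
    return(list(u_star = sw$u[i_best], t_s_star = sw$t_s[i_best], sweep = sw))
  }
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > refine_tol) {
    if (f1 >= f2) {  # maximize; ties keep the lower-dose side
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
    if (is.infinite(f1) || is.infinite(f2)) break
  }
  u_star <- if (f1 >= f2) x1 else x2
  t_star <- max(f1, f2)
  # refinement must not lose the grid best; near-ties break to the lower dose
  if (t_star < sw$t_s[i_best] ||
      (t_star <= sw$t_s[i_best] + tie_tol && sw$u[i_best] < u_star)) {
    u_star <- sw$u[i_best]; t_star <- max(t_star, sw$t_s[i_best])
  }
  list(u_star = u_star, t_s_star = t_star, sweep = sw)
}

#' Survival-time heatmap over (u, v) dose combinations
#'
#' @param params,initial,settings As in [survival_time()].
#' @param u_grid,v_grid Non-empty dose grids in [0, 1].
#' @return List with `t_s` matrix (rows = v, columns = u), `reached` logical
#'   matrix, and the grids. Cells where the critical volume is never reached
#'   carry `Inf` ("infinity" category).
#' @export
dose_heatmap <- function(params, initial,
                         u_grid = seq(0, 1, length.out = 101),
                         v_grid = seq(0, 1, length.out = 101),
                         settings = survival_settings()) {
  if (length(u_grid) == 0 || length(v_grid) == 0)
    stop("dose grids must be non-empty", call. = FALSE)
  ts_mat <- matrix(NA_real_, length(v_grid), length(u_grid))
  rc_mat <- matrix(NA, length(v_grid), length(u_grid))
  for (i in seq_along(v_grid)) {
    sw <- dose_sweep(params, initial, u_grid, v_grid[i], settings)
    ts_mat[i, ] <- sw$t_s
    rc_mat[i, ] <- sw$reached
  }
  structure(list(t_s = ts_mat, reached = rc_mat,
                 u_grid = u_grid, v_grid = v_grid),
            class = "dose_heatmap")
}

#' Mutation-rate sweep of the optimal constant dose
#'
#' For each pair of mutation rates (tau1, tau2) on the given grids, overrides
#' the rates in `params` and records the maximal survival time and the
#' constant chemotherapy dose attaining it (anti-angiogenic dose fixed).
#' Grids are typically logarithmically spaced over [1e-5, 1e-2].
#'
#' @param params,initial,v,settings As in [optimal_constant_dose()].
#' @param tau1_grid,tau2_grid Mutation-rate grids (1/day).
#' @param u_grid Scan grid passed to [optimal_constant_dose()].
#' @param refine_tol Dose refinement tolerance.
#' @return Data frame `(tau1, tau2, t_s_max, u_star)` in row-major
#'   (tau2-fastest) order.
#' @export
mutation_sweep <- function(params, initial, v, tau1_grid, tau2_grid,
                           settings = survival_settings(),
                           u_grid = seq(0, 1, length.out = 41),
                           refine_tol = 1e-3) {
  grid <- expand.grid(tau2 = tau2_grid, tau1 = tau1_grid)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$tau1 <- grid$tau1[i]; p$tau2 <- grid$tau2[i]
    p <- do.call(model_params, unclass(p))
    tryCatch({
      r <- optimal_constant_dose(p, initial, v, settings, u_grid, refine_tol)
      c(t_s_max = r$t_s_star, u_star = r$u_star)
    }, error = function(e) c(t_s_max = NA_real_, u_star = NA_real_))
  })
  out <- do.call(rbind, out)
  data.frame(tau1 = grid$tau1, tau2 = grid$tau2,
             t_s_max = out[, "t_s_max"], u_star = out[, "u_star"])
}
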