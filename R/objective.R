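#' Smoothed resistance penalty
#'
#' \deqn{f(N_1, N_2) = \frac{\xi}{2}\left(1 + \tanh\frac{N_2 - N_1}{\epsilon}\right)}
#' A smoothed Heaviside step charging (approximately) `xi` whenever resistant
#' cells outnumber sensitive ones, and (approximately) 0 otherwise; `epsilon`
#' controls the steepness of the transition around N1 = N2.
#'
#' @param n1,n2 Sensitive / resistant volumes (mm^3); vectorized.
#' @param xi Penalty amplitude.
#' @param epsilon Slope margin (mm^3), positive.
#' @return Penalty value(s) in (0, xi).
#' @export
#' @examples
#' resistance_penalty(300, 280, xi = 1000, epsilon = 10)
resistance_penalty <- function(n1, n2, xi = 1000, epsilon = 10) {
  if (epsilon <= 0) stop("'epsilon' must be positive", call. = FALSE)
  0.5 * xi * (1 + tanh((n2 - n1) / epsilon))
}

#' Evaluate the treatment objective on a trajectory
#'
#' Computes
#' \deqn{J = \omega_1 N_1(T) + \omega_2 N_2(T) + \int_0^T (\eta_1 N_1 + \eta_2 N_2 +
#'   f(N_1, N_2) + \theta u)\, dt}
#' on a stored trajectory. The running integral uses composite trapezoid on
#' the trajectory's own time grid ("trapezoid", for RK45 output) or a
#' left-rectangle rule ("left", matching the forward-Euler transcription used
#' by the optimal-control solver).
#'
#' @param traj A `tumor_trajectory` (needs `u` attached when `theta > 0`).
#' @param weights An `objective_weights` object.
#' @param quadrature "trapezoid" or "left".
#' @return An `objective_value`: list with `total`, `terminal_part`,
#'   `running_tumor_part`, `resistance_part`, `dose_part`.
#' @export
evaluate_objective <- function(traj, weights,
                               quadrature = c("trapezoid", "left")) {
  quadrature <- match.arg(quadrature)
  stopifnot(inherits(weights, "objective_weights"))
  tt <- traj$times
  S <- traj$states
  n <- length(tt)
  if (is.null(traj$u) && weights$theta > 0)
    stop("trajectory has no control attached but theta > 0", call. = FALSE)
  uu <- if (is.null(traj$u)) rep(0, n) else traj$u
  terminal <- weights$omega1 * S[n, 1] + weights$omega2 * S[n, 2]
  g_tumor <- weights$eta1 * S[, 1] + weights$eta2 * S[, 2]
  g_resist <- resistance_penalty(S[, 1], S[, 2], weights$xi, weights$epsilon)
  g_dose <- weights$theta * uu
  quad <- function(g) {
    if (n < 2) return(0)
    dt <- diff(tt)
    if (quadrature == "trapezoid") {
      sum(dt * (g[-n] + g[-1]) / 2)
    } else {
      sum(dt * g[-n])
    }
  }
  parts <- c(terminal_part = terminal,
             running_tumor_part = quad(g_tumor),
             resistance_part = quad(g_resist),
             dose_part = quad(g_dose))
  structure(c(list(total = sum(parts)), as.list(parts)),
            class = "objective_value")
}

#' @export
print.objective_value <- function(x, ...) {
  cat(sprintf("J = %.6g  (terminal %.6g + running tumor %.6g + resistance %.6g + dose %.6g)\n",
              x$total, x$terminal_part, x$running_tumor_part,
              x$resistance_part, x$dose_part))
  invisible(x)
}

# build an objective_value from the parts the transcription kernel returns
objective_value_from_parts <- function(terminal, running_tumor, resistance, dose) {
  structure(list(total = terminal + running_tumor + resistance + dose,
                 terminal_part = terminal,
                 running_tumor_part = running_tumor,
                 resistance_part = resistance,
                 dose_part = dose),
            class = "objective_value")
}
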