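#' Model parameters of the heterogeneous tumor-angiogenesis system
#'
#' Constructs and validates the full set of rate constants of the
#' sensitive/resistant Hahnfeldt-type model. Defaults are the nominal values
#' used throughout the package: a fast-growing, initially mostly sensitive
#' tumor whose vasculature saturates near 17,000 mm^3 in the absence of
#' therapy.
#'
#' @param lambda1 Proliferation rate of chemotherapy-sensitive cells (1/day).
#' @param lambda2 Proliferation rate of resistant cells (1/day).
#' @param tau1 Mutation rate sensitive -> resistant (1/day).
#' @param tau2 Back-mutation rate resistant -> sensitive (1/day).
#' @param mu Natural death rate of endothelial cells (1/day).
#' @param b Vascular stimulation rate by tumor cells (1/day).
#' @param d Vascular inhibition rate by tumor cells (1/(day * mm^2)).
#' @param beta1 Log-kill sensitivity of sensitive cells to chemotherapy
#'   (1/(day * unit dose)).
#' @param beta Sensitivity of the vasculature to chemotherapy
#'   (1/(day * unit dose)).
#' @param gamma Sensitivity of the vasculature to the anti-angiogenic agent
#'   (1/(day * unit dose)).
#' @return An object of class `model_params` (a validated named list).
#' @export
#' @examples
#' p <- model_params()
#' p$lambda1
model_params <- function(lambda1 = 0.192, lambda2 = 0.096,
                         tau1 = 2e-5, tau2 = 1e-5,
                         mu = 0, b = 5.85, d = 8.73e-3,
                         beta1 = 0.3, beta = 0.1, gamma = 2) {
  p <- list(lambda1 = lambda1, lambda2 = lambda2, tau1 = tau1, tau2 = tau2,
            mu = mu, b = b, d = d, beta1 = beta1, beta = beta, gamma = gamma)
  for (nm in names(p)) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (val < 0)
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  # the biological regime has lambda1 > 0, d > 0 and b > mu (positive
  # untreated saturating volume ((b - mu)/d)^{3/2}); degenerate zero settings
  # are allowed so closed-form limits (frozen vasculature, pure mutation
  # exchange) remain constructible for diagnostics
  if (p$d > 0 && p$b > 0 && p$b <= p$mu)
    stop("'b' must exceed 'mu' (needed for a positive untreated saturating volume)",
         call. = FALSE)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Tumor-angiogenesis model parameters (1/day unless noted):\n")
  print(unlist(x))
  invisible(x)
}

# internal: pack into the vector layout the C++ kernels expect
param_vec <- function(params) {
  stopifnot(inherits(params, "model_params"))
  c(params$lambda1, params$lambda2, params$tau1, params$tau2,
    params$mu, params$b, params$d, params$beta1, params$beta, params$gamma)
}

#' Tumor state (sensitive, resistant, carrying capacity)
#'
#' @param N1 Sensitive tumor volume (mm^3), strictly positive.
#' @param N2 Resistant tumor volume (mm^3), strictly positive.
#' @param K Vascular carrying capacity (mm^3), strictly positive.
#' @return A named numeric vector of class `tumor_state`.
#' @export
#' @examples
#' tumor_state(280, 20, 650)
tumor_state <- function(N1, N2, K) {
  x <- c(N1 = as.numeric(N1), N2 = as.numeric(N2), K = as.numeric(K))
  if (any(!is.finite(x)) || any(x <= 0))
    stop("tumor state components N1, N2, K must be strictly positive ",
         "(the Gompertz logarithm is undefined otherwise)", call. = FALSE)
  structure(x, class = c("tumor_state", "numeric"))
}

as_tumor_state <- function(x) {
  if (inherits(x, "tumor_state")) return(x)
  x <- as.numeric(x)
  if (length(x) != 3L) stop("a tumor state has exactly 3 components", call. = FALSE)
  tumor_state(x[1], x[2], x[3])
}

#' Total tumor volume of a state
#' @param state A `tumor_state` or numeric triple `(N1, N2, K)`.
#' @return N1 + N2 (mm^3).
#' @export
total_volume <- function(state) {
  s <- as_tumor_state(state)
  unname(s[1] + s[2])
}

#' Dose schedule: piecewise-constant chemotherapy plus constant anti-angiogenic
#'
#' The chemotherapy dose u(t) is either a single constant or a
#' piecewise-constant step function given by break times and per-interval
#' values; the anti-angiogenic dose v is constant throughout. Doses are
#' dimensionless fractions of the maximum tolerated dose (MTD) in [0, 1].
#'
#' @param u Either a single value in [0, 1] or a numeric vector of
#'   per-interval values (length `length(breaks) - 1`).
#' @param v Constant anti-angiogenic dose in [0, 1].
#' @param horizon Schedule duration (days).
#' @param breaks Strictly increasing break times spanning `[0, horizon]`;
#'   required when `u` has more than one value.
#' @return An object of class `dose_schedule`.
#' @export
#' @examples
#' dose_schedule(u = 0.25, v = 0.5, horizon = 14)
#' dose_schedule(u = c(1, 0.3, 1), v = 0.5, horizon = 14,
#'               breaks = c(0, 4, 10, 14))
dose_schedule <- function(u, v = 0, horizon, breaks = NULL) {
  if (!is.numeric(horizon) || horizon <= 0) stop("'horizon' must be positive", call. = FALSE)
  u <- as.numeric(u)
  if (any(u < 0 | u > 1)) stop("chemotherapy dose u must lie in [0, 1]", call. = FALSE)
  if (length(v) != 1L || v < 0 || v > 1) stop("anti-angiogenic dose v must lie in [0, 1]", call. = FALSE)
  if (length(u) == 1L && is.null(breaks)) breaks <- c(0, horizon)
  if (is.null(breaks)) stop("'breaks' required for a piecewise u", call. = FALSE)
  breaks <- as.numeric(breaks)
  if (length(breaks) != length(u) + 1L)
    stop("need length(breaks) == length(u) + 1", call. = FALSE)
  if (any(diff(breaks) <= 0)) stop("'breaks' must be strictly increasing", call. = FALSE)
  if (abs(breaks[1]) > 1e-12 || abs(breaks[length(breaks)] - horizon) > 1e-9)
    stop("'breaks' must span [0, horizon]", call. = FALSE)
  structure(list(u = u, v = v, horizon = horizon, breaks = breaks),
            class = "dose_schedule")
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf("Dose schedule over %.4g days: v = %.4g (constant), u in %d piece(s)\n",
              x$horizon, x$v, length(x$u)))
  invisible(x)
}

# u value at time t (left-continuous step function; u[i] on [breaks[i], breaks[i+1]))
schedule_u_at <- function(schedule, t) {
  idx <- findInterval(t, schedule$breaks, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(schedule$u))
  schedule$u[idx]
}

#' Objective-functional weights
#'
#' Weights of the treatment objective
#' \deqn{J(u) = \omega_1 N_1(T) + \omega_2 N_2(T) + \int_0^T \big(\eta_1 N_1 +
#'   \eta_2 N_2 + \tfrac{\xi}{2}(1 + \tanh((N_2 - N_1)/\epsilon)) + \theta u\big) dt.}
#' The tanh term is a smoothed step that charges the full penalty `xi` whenever
#' the resistant compartment outnumbers the sensitive one; `epsilon` (mm^3)
#' sets the width of the transition around N1 = N2.
#'
#' @param omega1,omega2 Terminal weights on sensitive / resistant volume.
#' @param eta1,eta2 Running weights on sensitive / resistant volume.
#' @param xi Amplitude of the resistance penalty.
#' @param epsilon Slope margin of the resistance penalty (mm^3), positive.
#' @param theta Running penalty on the administered dose (1/unit dose).
#' @return An object of class `objective_weights`.
#' @export
objective_weights <- function(omega1 = 5, omega2 = 25, eta1 = 1, eta2 = 5,
                              xi = 1000, epsilon = 10, theta = 0) {
  w <- list(omega1 = omega1, omega2 = omega2, eta1 = eta1, eta2 = eta2,
            xi = xi, epsilon = epsilon, theta = theta)
  for (nm in names(w)) {
    val <- w[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val < 0)
      stop("weight '", nm, "' must be a single finite non-negative number",
           call. = FALSE)
  }
  if (w$epsilon <= 0) stop("'epsilon' must be positive", call. = FALSE)
  structure(w, class = "objective_weights")
}

weight_vec <- function(weights) {
  stopifnot(inherits(weights, "objective_weights"))
  c(weights$omega1, weights$omega2, weights$eta1, weights$eta2,
    weights$xi, weights$epsilon, weights$theta)
}

#' Survival-analysis settings
#'
#' @param n_crit Critical (fatal) tumor volume (mm^3).
#' @param t_max Simulation cap defining the "never reached" sentinel (days).
#' @return An object of class `survival_settings`.
#' @export
survival_settings <- function(n_crit = 8000, t_max = 1000) {
  if (n_crit <= 0) stop("'n_crit' must be positive", call. = FALSE)
  if (t_max <= 0) stop("'t_max' must be positive", call. = FALSE)
  structure(list(n_crit = n_crit, t_max = t_max), class = "survival_settings")
}

#' Direct-transcription settings for the optimal-control solver
#'
#' @param n_nodes Number of forward-Euler intervals over the horizon
#'   (default 400; increasing it further does not change the solution).
#' @param horizon Treatment window length T (days).
#' @param nlp_tol Optimizer convergence tolerance on the projected gradient.
#' @param multistart Constant control seeds; the best-objective solution wins,
#'   ties broken toward the lower average dose.
#' @param maxit Iteration cap per start.
#' @return An object of class `transcription_settings`.
#' @export
transcription_settings <- function(n_nodes = 400, horizon = 14,
                                   nlp_tol = 1e-12,
                                   multistart = c(0, 0.5, 1),
                                   maxit = 5000) {
  if (n_nodes < 2) stop("'n_nodes' must be at least 2", call. = FALSE)
  if (horizon <= 0) stop("'horizon' must be positive", call. = FALSE)
  if (nlp_tol <= 0) stop("'nlp_tol' must be positive", call. = FALSE)
  if (any(multistart < 0 | multistart > 1))
    stop("'multistart' seeds must lie in [0, 1]", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes), horizon = horizon,
                 nlp_tol = nlp_tol, multistart = multistart,
                 maxit = as.integer(maxit)),
            class = "transcription_settings")
}
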