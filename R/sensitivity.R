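#' Design of the mutation-rate robustness study
#'
#' Random pairs of mutation rates (tau1, tau2) are drawn over `tau_range`
#' (log-uniform by default, matching the log10-plane on which the resulting
#' classification is read) and the scheduling problem re-solved for each pair
#' under a set of (beta1, beta, v) treatment-sensitivity scenarios.
#'
#' @param n_samples Number of (tau1, tau2) pairs per scenario (default 400).
#' @param tau_range Sampling interval for both rates (1/day).
#' @param sampling "log-uniform" (default) or "uniform".
#' @param seed Integer seed recorded in all outputs.
#' @param scenarios List of scenarios, each `list(beta1 =, beta =, v =)`.
#'   Defaults to the four combinations of (0.6, 0.2) / (0.3, 0.1)
#'   chemo-sensitivity pairs with v = 0.5 / 1.
#' @return A `sensitivity_design`.
#' @export
sensitivity_design <- function(n_samples = 400, tau_range = c(1e-5, 5e-2),
                               sampling = c("log-uniform", "uniform"),
                               seed = 1L,
                               scenarios = NULL) {
  sampling <- match.arg(sampling)
  if (n_samples < 1) stop("'n_samples' must be >= 1", call. = FALSE)
  if (tau_range[1] <= 0 || tau_range[2] >= 1 || tau_range[1] > tau_range[2])
    stop("'tau_range' must lie within (0, 1) and be non-decreasing", call. = FALSE)
  if (is.null(scenarios))
    scenarios <- list(
      list(beta1 = 0.6, beta = 0.2, v = 0.5),
      list(beta1 = 0.6, beta = 0.2, v = 1),
      list(beta1 = 0.3, beta = 0.1, v = 0.5),
      list(beta1 = 0.3, beta = 0.1, v = 1))
  structure(list(n_samples = as.integer(n_samples), tau_range = tau_range,
                 sampling = sampling, seed = as.integer(seed),
                 scenarios = scenarios),
            class = "sensitivity_design")
}

#' Draw the mutation-rate sample
#'
#' @param design A `sensitivity_design`.
#' @return Data frame `(tau1, tau2)` with `design$n_samples` rows;
#'   reproducible for a fixed seed.
#' @export
sample_mutation_rates <- function(design) {
  stopifnot(inherits(design, "sensitivity_design"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(design$seed)
  n <- design$n_samples
  r <- design$tau_range
  draw <- function() {
    if (design$sampling == "log-uniform") {
      if (r[1] == r[2]) rep(r[1], n)
      else 10^stats::runif(n, log10(r[1]), log10(r[2]))
    } else {
      stats::runif(n, r[1], r[2])
    }
  }
  data.frame(tau1 = draw(), tau2 = draw())
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Run the mutation-rate sensitivity study
#'
#' For every sampled (tau1, tau2) pair and every scenario, overrides the
#' mutation and chemo-sensitivity parameters, solves the scheduling problem,
#' and records the average dose and the full-dose/intermediate-dose label.
#' Per-sample solver failures are recorded with a status label rather than
#' resampled, so the sample size stays interpretable.
#'
#' @param params Baseline `model_params` (mutation rates and beta1/beta are
#'   overridden per sample/scenario).
#' @param initial Initial `tumor_state`.
#' @param weights An `objective_weights` object.
#' @param design A `sensitivity_design`.
#' @param settings `transcription_settings` for the per-sample solves; the
#'   default trims the multistart to c(0.5, 1) to bound runtime.
#' @param scenario_index Optional subset of scenarios to run.
#' @return A `sensitivity_result`: list of per-scenario entries, each with
#'   `scenario`, `samples` (tau1, tau2, avg_dose_pct, class, status) and
#'   `controls` (samples x nodes matrix of optimal controls); plus `design`.
#' @export
run_sensitivity <- function(params, initial, weights, design,
                            settings = transcription_settings(
                              multistart = c(0.5, 1)),
                            scenario_index = seq_along(design$scenarios)) {
  stopifnot(inherits(design, "sensitivity_design"))
  taus <- sample_mutation_rates(design)
  out <- lapply(scenario_index, function(si) {
    sc <- design$scenarios[[si]]
    ctrl <- matrix(NA_real_, design$n_samples, settings$n_nodes)
    avg <- rep(NA_real_, design$n_samples)
    status <- rep("ok", design$n_samples)
    for (i in seq_len(design$n_samples)) {
      p <- params
      p$tau1 <- taus$tau1[i]; p$tau2 <- taus$tau2[i]
      p$beta1 <- sc$beta1; p$beta <- sc$beta
      p <- do.call(model_params, unclass(p))
      sol <- tryCatch(
        solve_ocp(transcribe(p, initial, weights, sc$v, settings)),
        error = function(e) NULL)
      if (is.null(sol)) {
        status[i] <- "failed"
      } else {
        ctrl[i, ] <- sol$control
        avg[i] <- sol$average_dose_pct
      }
    }
    n_fail <- sum(status != "ok")
    if (n_fail > 0.1 * design$n_samples)
      warning(sprintf("scenario %d: %d/%d solves failed", si, n_fail,
                      design$n_samples))
    cls <- ifelse(is.na(avg), NA_character_,
                  ifelse(avg > 90, "full-dose", "intermediate-dose"))
    list(scenario = sc,
         samples = data.frame(tau1 = taus$tau1, tau2 = taus$tau2,
                              avg_dose_pct = avg, class = cls,
                              status = status),
         controls = ctrl,
         times = seq(0, settings$horizon, length.out = settings$n_nodes + 1))
  })
  structure(list(scenarios = out, design = design), class = "sensitivity_result")
}

#' Pointwise percentile curves of the optimal control
#'
#' Empirical percentiles of the optimal dose across samples, at every control
#' node (linear-interpolation quantile convention).
#'
#' @param result One scenario entry of a `sensitivity_result` (list with
#'   `controls` and `times`), or a `sensitivity_result` whose first scenario
#'   is used.
#' @param percentiles Percentile levels in [0, 100].
#' @return Data frame `t, percentile, u` in long format.
#' @export
percentile_curves <- function(result, percentiles = c(0, 10, 25, 50, 75, 90, 100)) {
  if (inherits(result, "sensitivity_result")) result <- result$scenarios[[1]]
  ctrl <- result$controls
  ok <- stats::complete.cases(ctrl)
  if (!any(ok)) stop("no successful solves in this scenario", call. = FALSE)
  ctrl <- ctrl[ok, , drop = FALSE]
  t_mid <- result$times[-length(result$times)]
  out <- lapply(percentiles, function(p) {
    data.frame(t = t_mid,
               percentile = p,
               u = apply(ctrl, 2, stats::quantile, probs = p / 100,
                         type = 7, names = FALSE))
  })
  do.call(rbind, out)
}

#' Full/intermediate classification on the log10 mutation-rate plane
#'
#' @param result One scenario entry of a `sensitivity_result` (or the result
#'   itself, first scenario).
#' @return Data frame `log10_tau1, log10_tau2, class, avg_dose_pct` with one
#'   row per successfully solved sample.
#' @export
classify_map <- function(result) {
  if (inherits(result, "sensitivity_result")) result <- result$scenarios[[1]]
  s <- result$samples
  ok <- s$status == "ok"
  data.frame(log10_tau1 = log10(s$tau1[ok]),
             log10_tau2 = log10(s$tau2[ok]),
             class = s$class[ok],
             avg_dose_pct = s$avg_dose_pct[ok])
}
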