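# shared fixtures: nominal parameterization and standard initial states

nominal_params <- function(...) model_params(...)

# chemo-sensitivity pair under which the short-horizon schedule develops the
# bang-singular-bang structure (resistance takeover reachable in 14 days)
sensitive_params <- function(...) model_params(beta1 = 0.6, beta = 0.2, ...)

small_tumor <- function() tumor_state(280, 20, 650)
large_tumor <- function() tumor_state(5900, 2000, 10000)

# hand-written vector field used as an independent oracle against the
# compiled implementation
rhs_oracle <- function(s, u, v, p) {
  N <- s[1] + s[2]
  lg <- log(N / s[3])
  c(-p$lambda1 * s[1] * lg - p$tau1 * s[1] + p$tau2 * s[2] - p$beta1 * s[1] * u,
    -p$lambda2 * s[2] * lg + p$tau1 * s[1] - p$tau2 * s[2],
    -p$mu * s[3] + p$b * N - p$d * N^(2 / 3) * s[3] - p$beta * s[3] * u -
      p$gamma * s[3] * v)
}

# build a synthetic trajectory object without integrating
make_trajectory <- function(times, N1, N2, K, u = NULL, v = 0) {
  structure(list(times = times,
                 states = cbind(N1 = N1, N2 = N2, K = K),
                 u = u, v = v),
            class = "tumor_trajectory")
}
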