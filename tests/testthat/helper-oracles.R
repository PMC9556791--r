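# Independent oracle implementations used only by tests. These are coded
# separately from the package internals (different structure, direct
# transcription of the underlying physics) so that agreement is a genuine
# dual-route check.

# spectral density J(omega; tau) = tau / (1 + (omega tau)^2)
oracle_spectral_density <- function(omega, tau) tau / (1 + (omega * tau)^2)

# full two-timescale CSA relaxation rates, re-coded from the spectral
# density up rather than from the package's pooled expression
oracle_rates <- function(tau_f, tau_s, omega, sigma_ppm, eta, S) {
  sig <- sigma_ppm * 1e-6
  amp <- omega^2 * sig^2 * (1 + eta^2 / 3)
  j <- S^2 * oracle_spectral_density(omega, tau_s) +
    (1 - S^2) * oracle_spectral_density(omega, tau_f)
  secular <- S^2 * tau_s + (1 - S^2) * tau_f
  c(R1 = 2 / 15 * amp * j,
    R2 = 1 / 15 * amp * j + 4 / 45 * amp * secular)
}

# Monte Carlo powder average of cos(x * P2(cos theta)) over a uniform sphere
oracle_powder_mc <- function(x, n = 1e4, seed = 42) {
  set.seed(seed)
  u <- stats::runif(n, -1, 1)
  p2 <- (3 * u^2 - 1) / 2
  vapply(x, function(xx) mean(cos(xx * p2)), numeric(1))
}

# brute-force REDOR powder integration over (beta, gamma)
oracle_redor_powder <- function(lambda, n = 600) {
  gl <- pracma::gaussLegendre(n, -1, 1)
  gam <- seq(0, 2 * pi, length.out = 2049)[-1]
  sb <- sqrt(pmax(0, 1 - gl$x^2))
  geom <- outer(gl$x * sb, sin(gam))
  vapply(lambda, function(l)
    1 - sum(gl$w * rowMeans(cos(4 * sqrt(2) * l * geom))) / 2,
    numeric(1))
}

# brute-force rectangular window sum over a spectrum2d, point by point
oracle_window_sum <- function(spec, center, half_width = c(0.75, 0.75)) {
  total <- 0
  for (i in seq_along(spec$axis_f1))
    for (j in seq_along(spec$axis_f2)) {
      if (abs(spec$axis_f1[i] - center[1]) <= half_width[1] + 1e-12 &&
          abs(spec$axis_f2[j] - center[2]) <= half_width[2] + 1e-12)
        total <- total + spec$intensity[i, j]
    }
  total
}

# default study spin parameters, shared across tests
study_params <- spin_system_params()

# forward-simulate T1/T2 from the SIMPLIFIED equations and return the decay
# time constants (used for exact algebraic round-trip tests)
simplified_forward <- function(tau_f, tau_s, params) {
  sig <- params$csa_sigma
  A <- 1 + params$eta^2 / 3
  S2 <- params$order_param^2
  w <- params$larmor_omega
  R1 <- (2 / 15) * sig^2 * A * (1 - S2) / tau_f
  R2 <- (1 / 15) * sig^2 * A * (1 - S2) / tau_f +
    (4 / 45) * w^2 * sig^2 * A * (S2 * tau_s + (1 - S2) * tau_f)
  list(T1 = 1 / R1, T2 = 1 / R2)
}

# wrap plain T1/T2 numbers as minimal exponential_fit objects
as_fit <- function(kind, tau, sigma_tau = 0, label = "oracle") {
  structure(list(I0 = 100, beta = if (kind == "T1") 2 else NA_real_,
                 tau = tau, sigma_tau = sigma_tau, rate = 1 / tau,
                 residual_rms = 0, kind = kind, label = label,
                 temperature = 280, fit = NULL),
            class = "exponential_fit")
}
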