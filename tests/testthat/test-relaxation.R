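test_that("noiseless exponential decays are recovered exactly", {
  t2 <- seq(0.005, 0.3, length.out = 8)
  s2 <- relaxation_series("T2", t2, 100 * exp(-t2 / 0.050))
  f2 <- fit_exponential_decay(s2)
  expect_equal(f2$tau, 0.050, tolerance = 1e-6)
  expect_lt(f2$residual_rms, 1e-6)
  expect_equal(f2$rate * f2$tau, 1)

  t1 <- seq(0.05, 5, length.out = 9)
  s1 <- relaxation_series("T1", t1, 80 - 2 * 80 * exp(-t1 / 1.2))
  f1 <- fit_exponential_decay(s1)
  expect_equal(f1$tau, 1.2, tolerance = 1e-6)
  expect_equal(f1$beta, 2, tolerance = 1e-4)
  f1b <- fit_exponential_decay(s1, fix_beta = 2)
  expect_equal(f1b$tau, 1.2, tolerance = 1e-6)
})

test_that("series constructor enforces its invariants", {
  expect_error(relaxation_series("T2", c(0, 1, 2), c(1, 2, 3)), "4 points")
  expect_error(relaxation_series("T2", c(0, 1, 1, 2), 1:4), "increasing")
  expect_error(relaxation_series("T2", c(-1, 0, 1, 2), 1:4), "non-negative")
  expect_error(relaxation_series("T2", 0:3, 1:3), "equal length")
})

test_that("fitted sigma_tau matches Monte Carlo scatter for noisy T2 decays", {
  true_tau <- 0.050
  t <- seq(0.004, 0.25, length.out = 10)
  clean <- 100 * exp(-t / true_tau)
  set.seed(101)
  taus <- sigmas <- numeric(200)
  for (i in 1:200) {
    y <- clean + rnorm(length(t), 0, 2)  # 2 % of max signal
    f <- fit_exponential_decay(relaxation_series("T2", t, pmax(y, 0.01)))
    taus[i] <- f$tau; sigmas[i] <- f$sigma_tau
  }
  expect_lt(abs(mean(taus) - true_tau) / true_tau, 0.01)
  expect_lt(abs(sd(taus) - mean(sigmas)) / sd(taus), 0.20)
})

test_that("full rate model matches an independently coded oracle", {
  p <- study_params
  set.seed(7)
  for (i in 1:100) {
    tf <- runif(1, 0.5e-9, 5e-9)
    ts <- runif(1, 0.5e-6, 20e-6)
    got <- full_rate_model(tf, ts, p)
    want <- oracle_rates(tf, ts, p$larmor_omega, p$csa_ppm, p$eta,
                         p$order_param)
    expect_equal(got$R1, want[["R1"]], tolerance = 1e-12)
    expect_equal(got$R2, want[["R2"]], tolerance = 1e-12)
  }
  # rates vanish with the motion: both linear in tau in the extreme
  # narrowing limit
  lim <- full_rate_model(1e-22, 1e-22, p)
  expect_lt(lim$R1, 1e-11)
  expect_lt(lim$R2, 1e-11)
  expect_equal(full_rate_model(2e-22, 2e-22, p)$R1 / lim$R1, 2,
               tolerance = 1e-9)
})

test_that("slow-motion spectral-density term of R1 is negligible", {
  # magnitude argument licensing the simplified inversion: at tau_s = 4 us
  # the slow term of R1 is ~1e-15-scale while the fast term dominates
  p <- study_params
  w <- p$larmor_omega
  slow_j <- p$order_param^2 * 4e-6 / (1 + (w * 4e-6)^2)
  fast_j <- (1 - p$order_param^2) * 1.5e-9 / (1 + (w * 1.5e-9)^2)
  expect_lt(slow_j, 1e-14)
  expect_gt(fast_j / slow_j, 1e4)
})

test_that("simplified inversion round-trips its own forward model exactly", {
  p <- study_params
  for (tf in c(1.3e-9, 1.8e-9, 2.1e-9)) {
    for (ts in c(1e-6, 4e-6, 12e-6)) {
      fwd <- simplified_forward(tf, ts, p)
      inv <- invert_simplified(as_fit("T1", fwd$T1), as_fit("T2", fwd$T2), p)
      expect_equal(inv$tau_f, tf, tolerance = 1e-10)
      expect_equal(inv$tau_s, ts, tolerance = 1e-10)
    }
  }
})

test_that("inverting full-model data bounds the approximation error", {
  p <- study_params
  for (tf in c(1.3e-9, 1.8e-9, 2.1e-9)) {
    rates <- full_rate_model(tf, 4e-6, p)
    inv <- invert_simplified(as_fit("T1", 1 / rates$R1),
                             as_fit("T2", 1 / rates$R2), p)
    expect_lt(abs(inv$tau_f - tf) / tf, 0.35)
    expect_lt(abs(inv$tau_s - 4e-6) / 4e-6, 0.15)
    expect_true(inv$valid || inv$validity_metric > 10)
  }
})

test_that("Larmor frequency cancels from the tau_f inversion but not tau_s", {
  p1 <- spin_system_params(larmor_mhz = 242)
  p2 <- spin_system_params(larmor_mhz = 484)
  f1 <- as_fit("T1", 0.5); f2 <- as_fit("T2", 0.001)
  a <- invert_simplified(f1, f2, p1)
  b <- invert_simplified(f1, f2, p2)
  expect_equal(a$tau_f, b$tau_f, tolerance = 1e-12)
  expect_gt(abs(a$tau_s - b$tau_s) / a$tau_s, 0.1)
})

test_that("inconsistent T2 (tau_s <= 0) is flagged but still reported", {
  p <- study_params
  fwd <- simplified_forward(1.8e-9, 4e-6, p)
  # T2 too long: secular term would have to be negative
  expect_warning(
    inv <- invert_simplified(as_fit("T1", fwd$T1),
                             as_fit("T2", fwd$T1 * 0.9), p),
    "non-positive")
  expect_false(inv$valid)
  expect_false(inv$consistent)
  expect_true(is.finite(inv$tau_s))
  expect_error(invert_simplified(as_fit("T1", 0.5), as_fit("T2", 0.6), p),
               "T2 < T1")
})

test_that("propagation constants reproduce the published closed forms", {
  pc <- propagation_constants(study_params)
  expect_equal(pc$C1, 8.74e9, tolerance = 1e-3)
  expect_equal(pc$C2, 4.29e-9, tolerance = 1e-3)
  # self-consistent C1 carries the (1 - S^2) factor of the inversion slope
  pcs <- propagation_constants(study_params, mode = "self_consistent")
  expect_equal(pcs$C1 / pc$C1, 1 - study_params$order_param^2,
               tolerance = 1e-6)
  expect_equal(pcs$C2, pc$C2)
})

test_that("C1-C4 match finite-difference derivatives of the inversion", {
  p <- study_params
  pc <- propagation_constants(p, mode = "self_consistent")
  w2 <- p$larmor_omega^2
  T1 <- 0.5; T2 <- 0.0011
  inv0 <- invert_simplified(as_fit("T1", T1), as_fit("T2", T2), p)
  h <- 1e-7
  dtf_dT1 <- (invert_simplified(as_fit("T1", T1 + h), as_fit("T2", T2),
                                p)$tau_f - inv0$tau_f) / h
  dts_dT1 <- (invert_simplified(as_fit("T1", T1 + h), as_fit("T2", T2),
                                p)$tau_s - inv0$tau_s) / h
  dts_dT2 <- (invert_simplified(as_fit("T1", T1), as_fit("T2", T2 + 1e-9),
                                p)$tau_s - inv0$tau_s) / 1e-9
  expect_equal(dtf_dT1, pc$C1 / w2, tolerance = 1e-4)
  expect_equal(dts_dT1, pc$C3 / T1^2 - pc$C4, tolerance = 1e-4)
  expect_equal(dts_dT2, -pc$C2 / T2^2, tolerance = 1e-4)
})

test_that("uncertainty propagation reduces correctly in single-error cases", {
  pc <- propagation_constants(study_params)
  T1 <- 0.5; T2 <- 0.0011
  zero <- propagate_uncertainty(as_fit("T1", T1, 0), as_fit("T2", T2, 0), pc)
  expect_equal(zero$sigma_tau_f, 0)
  expect_equal(zero$sigma_tau_s, 0)
  only_t2 <- propagate_uncertainty(as_fit("T1", T1, 0),
                                   as_fit("T2", T2, 3e-5), pc)
  expect_equal(only_t2$sigma_tau_s, (pc$C2 / T2^2) * 3e-5)
  expect_error(propagate_uncertainty(as_fit("T1", 0), as_fit("T2", T2), pc),
               "positive")
})

test_that("analytic propagation agrees with Monte Carlo within 15 %", {
  p <- study_params
  pc <- propagation_constants(p, mode = "self_consistent")
  fwd <- simplified_forward(1.8e-9, 4e-6, p)
  relsd <- 0.03
  s1 <- relsd * fwd$T1; s2 <- relsd * fwd$T2
  ana <- propagate_uncertainty(as_fit("T1", fwd$T1, s1),
                               as_fit("T2", fwd$T2, s2), pc)
  set.seed(11)
  n <- 4000
  tf <- ts <- numeric(n)
  for (i in seq_len(n)) {
    inv <- invert_simplified(as_fit("T1", rnorm(1, fwd$T1, s1)),
                             as_fit("T2", rnorm(1, fwd$T2, s2)), p)
    tf[i] <- inv$tau_f; ts[i] <- inv$tau_s
  }
  expect_lt(abs(sd(tf) - ana$sigma_tau_f) / sd(tf), 0.15)
  expect_lt(abs(sd(ts) - ana$sigma_tau_s) / sd(ts), 0.15)
})

test_that("delta correlation times combine differences in quadrature", {
  mk <- function(tf, ts, sf, ss) structure(
    list(tau_f = tf, tau_s = ts, sigma_tau_f = sf, sigma_tau_s = ss,
         validity_metric = 5, valid = TRUE, consistent = TRUE,
         temperature = 280, label = ""), class = "correlation_result")
  same <- delta_correlation_times(mk(2e-9, 4e-6, 1e-10, 1e-7),
                                  mk(2e-9, 4e-6, 1e-10, 1e-7))
  expect_equal(same$delta_tau_f, 0)
  expect_equal(same$delta_tau_s, 0)
  d <- delta_correlation_times(mk(2.0e-9, 4e-6, 0.1e-9, 1e-7),
                               mk(1.5e-9, 4e-6, 0.1e-9, 1e-7))
  expect_equal(d$delta_tau_f, 0.5e-9)
  expect_equal(d$sigma_delta_f, sqrt(2) * 0.1e-9, tolerance = 1e-6)
  a <- mk(2e-9, 4e-6, 1e-10, 1e-7); b <- mk(2e-9, 4e-6, 1e-10, 1e-7)
  b$temperature <- 296
  expect_error(delta_correlation_times(a, b), "temperatures differ")
})
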