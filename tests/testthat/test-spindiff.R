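make_peak_spectrum <- function(noise_sd = 0, seed = 1) {
  peaks <- data.frame(
    f1 = c(50, 20, 50), f2 = c(50, 20, 20),
    volume = c(100, 80, 30), width = c(0.35, 0.35, 0.35),
    type = c("diagonal", "diagonal", "intrastrand"))
  gen_spectrum2d(peaks, noise_sd = noise_sd, seed = seed)$nondiluted
}

test_that("peak volume integration is exact, linear and window-faithful", {
  spec <- make_peak_spectrum()
  expect_equal(integrate_peak_volume(spec, c(40, 40))$volume, 0)
  # a unit-volume Gaussian fully inside the window integrates to ~1
  v <- integrate_peak_volume(spec, c(50, 50), c(2, 2))$volume
  expect_equal(v, 100, tolerance = 0.01)
  # brute-force point-by-point reference on overlapping windows: same
  # points selected, identical up to floating summation order
  for (ctr in list(c(50, 50), c(50.5, 49.6), c(20, 20.7))) {
    expect_equal(integrate_peak_volume(spec, ctr)$volume,
                 oracle_window_sum(spec, ctr), tolerance = 1e-13)
  }
  # linearity: volume(aX + bY) = a vol(X) + b vol(Y)
  s2 <- spec; s2$intensity <- 2 * spec$intensity + 5
  va <- integrate_peak_volume(spec, c(50, 50))
  vb <- integrate_peak_volume(s2, c(50, 50))
  expect_equal(vb$volume, 2 * va$volume + 5 * va$n_points)
  expect_error(integrate_peak_volume(spec, c(10.1, 50)), "f1")
})

test_that("ascending ppm axes are normalized to the descending convention", {
  m <- matrix(1:12, 3, 4)
  sp <- spectrum2d(c(1, 2, 3), c(10, 20, 30, 40), m)
  expect_equal(sp$axis_f1, c(3, 2, 1))
  expect_equal(sp$axis_f2, c(40, 30, 20, 10))
  expect_equal(sp$intensity[1, 1], m[3, 4])
  # round trip: a window volume is invariant under axis orientation
  spd <- spectrum2d(c(3, 2, 1), c(40, 30, 20, 10), m[3:1, 4:1])
  expect_equal(sp$intensity, spd$intensity)
})

test_that("spectral noise estimate is seeded, deterministic and calibrated", {
  set.seed(5)
  n1 <- n2 <- 200
  ax <- seq(70, 10, by = -0.15)
  peaks <- list(c(50, 50), c(20, 20))
  sigma <- 0.7
  # same seed, same spectrum -> identical regions and noise_sd
  sp <- spectrum2d(ax, ax, matrix(rnorm(length(ax)^2, 0, sigma), length(ax)))
  a <- estimate_spectral_noise(sp, peaks, seed = 7)
  b <- estimate_spectral_noise(sp, peaks, seed = 7)
  expect_identical(a$regions, b$regions)
  expect_identical(a$noise_sd, b$noise_sd)
  # zero spectrum -> zero noise
  z <- spectrum2d(ax, ax, matrix(0, length(ax), length(ax)))
  expect_equal(estimate_spectral_noise(z, peaks, seed = 1)$noise_sd, 0)
  # sampling-theory calibration: SD of an m-point window sum ~ sigma*sqrt(m)
  m_pts <- integrate_peak_volume(sp, c(40, 40))$n_points
  ests <- vapply(1:50, function(s) {
    spi <- spectrum2d(ax, ax, matrix(rnorm(length(ax)^2, 0, sigma),
                                     length(ax)))
    estimate_spectral_noise(spi, peaks, seed = s)$noise_sd
  }, numeric(1))
  expect_lt(abs(mean(ests) - sigma * sqrt(m_pts)) / (sigma * sqrt(m_pts)),
            0.25)
  # impossible placement errors out with advice
  tiny <- spectrum2d(seq(12, 10, by = -0.1), seq(12, 10, by = -0.1),
                     matrix(0, 21, 21))
  expect_error(estimate_spectral_noise(tiny, peaks, n_regions = 10),
               "smaller window|fewer regions")
})

test_that("reduction statistic: identity, arithmetic and scale invariance", {
  # same crosspeak/diagonal ratio in both spectra -> 100 % (intrastrand-like)
  q <- dilution_quartet(10, 100, 5, 50)
  expect_equal(reduction_statistic(q)$reduction, 100)
  expect_equal(reduction_statistic(q)$contact_class, "intrastrand")
  # worked arithmetic
  q2 <- dilution_quartet(10, 100, 2.5, 50)
  expect_equal(reduction_statistic(q2)$reduction, 50)
  # scale invariance under common scaling of either spectrum's volumes
  q3 <- dilution_quartet(10 * 3, 100 * 3, 2.5, 50)
  q4 <- dilution_quartet(10, 100, 2.5 * 0.2, 50 * 0.2)
  expect_equal(reduction_statistic(q3)$reduction, 50)
  expect_equal(reduction_statistic(q4)$reduction, 50)
  expect_error(dilution_quartet(10, 0, 5, 50), "positive")
})

test_that("reduction uncertainty agrees with Monte Carlo resampling", {
  q <- dilution_quartet(40, 400, 12, 210, delta_n = 3, delta_d = 2)
  ana <- reduction_statistic(q)
  set.seed(23)
  n <- 1e5
  draws <- (pmax(rnorm(n, q$v1_d, q$delta_d), 1e-9) /
              pmax(rnorm(n, q$v0_d, q$delta_d), 1e-9)) /
    (pmax(rnorm(n, q$v1_n, q$delta_n), 1e-9) /
       pmax(rnorm(n, q$v0_n, q$delta_n), 1e-9)) * 100
  expect_lt(abs(sd(draws) - ana$uncertainty) / sd(draws), 0.15)
})

test_that("classification demotes to ambiguous on large uncertainty", {
  q <- dilution_quartet(10, 100, 8, 100, delta_n = 0.1, delta_d = 0.1)
  expect_equal(reduction_statistic(q)$contact_class, "intrastrand")
  qq <- dilution_quartet(10, 100, 8, 100, delta_n = 4, delta_d = 4)
  expect_equal(reduction_statistic(qq)$contact_class, "ambiguous")
  q3 <- dilution_quartet(10, 100, 2, 100, delta_n = 0.1, delta_d = 0.1)
  expect_equal(reduction_statistic(q3)$contact_class, "interstrand")
})

test_that("dilution expectation: closed form p^2 and Monte Carlo agree", {
  expect_equal(dilution_expectation(1)$expected, 100)
  expect_equal(dilution_expectation(0.5)$expected, 25)
  mc <- dilution_expectation(0.5, mc_pairs = 1e6, seed = 3)
  expect_lt(abs(mc$mc_estimate - 25), 0.1)
  # closed form across p
  for (p in c(0.2, 0.7)) expect_equal(dilution_expectation(p)$expected,
                                      100 * p^2)
  expect_error(dilution_expectation(0), "p > 0")
})

test_that("secondary shift deviations follow the beta-strand pattern", {
  rc <- random_coil_shifts()
  ala <- rc[rc$residue == "A", ]
  rec <- data.frame(residue = c("A", "A", "G", "X"),
                    delta_ca = c(ala$ca, ala$ca - 2, 45.1, 55),
                    delta_cb = c(ala$cb, ala$cb + 2, NA, 30))
  expect_warning(out <- secondary_shift_deviation(rec), "absent")
  # shifts equal to random coil: deviation 0, inside the undetermined band
  expect_equal(out$deviation[1], 0)
  expect_equal(out$call[1], "undetermined")
  # canonical beta pattern: Ca down, Cb up -> +4 ppm, beta
  expect_equal(out$deviation[2], 4)
  expect_equal(out$call[2], "beta")
  # glycine has no Cb: undetermined, no crash
  expect_equal(out$call[3], "undetermined")
  expect_equal(out$call[4], "undetermined")
  # helix-like pattern calls non_beta
  rec2 <- data.frame(residue = "A", delta_ca = ala$ca + 2,
                     delta_cb = ala$cb - 1)
  expect_equal(secondary_shift_deviation(rec2)$call, "non_beta")
})

test_that("analytic peak-list volumes match grid integration", {
  peaks <- data.frame(f1 = c(50, 20), f2 = c(50, 20),
                      volume = c(100, 80), width = 0.35,
                      type = "diagonal")
  spec <- gen_spectrum2d(peaks, noise_sd = 0, seed = 1)$nondiluted
  for (ctr in list(c(50, 50), c(20, 20), c(49.8, 50.4))) {
    # discretisation of the window edges on the 0.15 ppm grid limits the
    # agreement to a couple of percent
    expect_equal(peaklist_volume(peaks, ctr),
                 integrate_peak_volume(spec, ctr)$volume,
                 tolerance = 0.02)
  }
  # a window enclosing everything returns the total volume exactly
  expect_equal(peaklist_volume(peaks, c(35, 35), c(100, 100)), 180,
               tolerance = 1e-9)
})

test_that("end-to-end dilution pipeline classifies contacts correctly", {
  # synthetic spectra with known intrastrand/interstrand crosspeaks at
  # SNR >= 20, full pipeline: integrate -> noise -> reduction -> class
  peaks <- data.frame(
    f1 = c(55, 25, 40, 55, 40, 25),
    f2 = c(55, 25, 40, 25, 55, 40),
    volume = c(200, 200, 200, 40, 40, 40),
    width = 0.35,
    type = c("diagonal", "diagonal", "diagonal",
             "intrastrand", "interstrand", "interstrand"))
  n_ok <- 0; n_tot <- 0
  for (s in 1:8) {
    # peak height ~ vol/(2 pi w^2) * step^2 on the grid; noise for SNR ~ 20
    pair <- gen_spectrum2d(peaks, dilution_p = 0.5, noise_sd = 0.008,
                           seed = s)
    xw <- peaks[peaks$type != "diagonal", ]
    nz_n <- estimate_spectral_noise(pair$nondiluted,
                                    peaks[, c("f1", "f2")], seed = s)
    nz_d <- estimate_spectral_noise(pair$diluted,
                                    peaks[, c("f1", "f2")], seed = s + 500)
    for (i in seq_len(nrow(xw))) {
      diag_ctr <- c(xw$f1[i], xw$f1[i])
      q <- dilution_quartet(
        integrate_peak_volume(pair$nondiluted, c(xw$f1[i], xw$f2[i]))$volume,
        integrate_peak_volume(pair$nondiluted, diag_ctr)$volume,
        integrate_peak_volume(pair$diluted, c(xw$f1[i], xw$f2[i]))$volume,
        integrate_peak_volume(pair$diluted, diag_ctr)$volume,
        delta_n = nz_n$noise_sd, delta_d = nz_d$noise_sd)
      got <- reduction_statistic(q)$contact_class
      n_tot <- n_tot + 1
      if (got == xw$type[i]) n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok / n_tot, 0.9)
})
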