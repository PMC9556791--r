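# run expr with a local RNG seed, restoring the caller's RNG state
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Generate paired sample/control relaxation decay sets
#'
#' Forward-simulates 31P T1 inversion-recovery and T2 echo decays from the
#' FULL quadratic rate model (so the simplified inversion is genuinely
#' exercised, approximation error included), for a peptide-containing
#' sample and a peptide-free control with their own ground-truth
#' correlation times. Delays span the respective relaxation times
#' geometrically; Gaussian noise is added relative to the maximum signal.
#'
#' @param tau_f_sample,tau_s_sample ground-truth correlation times of the
#'   sample, s (physical ranges roughly 0.5-5 ns and 0.5-20 us).
#' @param tau_f_control,tau_s_control same for the control.
#' @param params a [spin_system_params()].
#' @param n_delays points per decay.
#' @param noise_sd Gaussian noise SD as a fraction of the maximum signal
#'   (default 0.02, mimicking typical spectral scatter).
#' @param temperature K, carried as metadata.
#' @param seed integer seed; same seed, same output.
#' @return list with `sample` and `control`, each a list of
#'   [relaxation_series()] `t1` and `t2`, plus `truth` (the generator
#'   parameters and the full-model T1/T2 values).
#' @export
gen_relaxation_set <- function(tau_f_sample = 1.8e-9, tau_s_sample = 4e-6,
                               tau_f_control = 1.5e-9, tau_s_control = 4e-6,
                               params = spin_system_params(),
                               n_delays = 10, noise_sd = 0.02,
                               temperature = 280, seed = 1L) {
  stopifnot(tau_f_sample > 0, tau_s_sample > 0,
            tau_f_control > 0, tau_s_control > 0)
  make_one <- function(tau_f, tau_s, label, seeds) {
    rates <- full_rate_model(tau_f, tau_s, params)
    T1 <- 1 / rates$R1; T2 <- 1 / rates$R2
    d1 <- T1 * seq(0.05, 3, length.out = n_delays)
    d2 <- T2 * seq(0.05, 3, length.out = n_delays)
    y1 <- 100 * (1 - 2 * exp(-d1 / T1))
    y2 <- 100 * exp(-d2 / T2)
    if (noise_sd > 0) {
      y1 <- y1 + with_seed_local(seeds[1], stats::rnorm(n_delays, 0, noise_sd * 100))
      y2 <- y2 + with_seed_local(seeds[2], stats::rnorm(n_delays, 0, noise_sd * 100))
      y2 <- pmax(y2, 1e-3)  # keep log-linear initialisation defined
    }
    list(t1 = relaxation_series("T1", d1, y1, temperature, paste0(label, "/T1")),
         t2 = relaxation_series("T2", d2, y2, temperature, paste0(label, "/T2")),
         T1 = T1, T2 = T2)
  }
  base <- as.integer(seed) %% 500000000L
  smp <- make_one(tau_f_sample, tau_s_sample, "sample",
                  c(base * 4L + 1L, base * 4L + 2L))
  ctl <- make_one(tau_f_control, tau_s_control, "control",
                  c(base * 4L + 3L, base * 4L + 4L))
  list(sample = smp[c("t1", "t2")], control = ctl[c("t1", "t2")],
       truth = list(tau_f_sample = tau_f_sample, tau_s_sample = tau_s_sample,
                    tau_f_control = tau_f_control,
                    tau_s_control = tau_s_control,
                    T1_sample = smp$T1, T2_sample = smp$T2,
                    T1_control = ctl$T1, T2_control = ctl$T2,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate a noisy dephasing curve with known ground truth
#'
#' Runs the corresponding simulator ([simulate_pithirds_decay()] or
#' [simulate_redor_buildup()]) and adds i.i.d. Gaussian noise.
#'
#' @param r true internuclear distance, Angstrom.
#' @param experiment `"PITHIRDS_CT"` or `"REDOR"`.
#' @param noise_sd per-point Gaussian noise SD on the normalized signal.
#' @param seed integer seed.
#' @param ... passed to the simulator (e.g. `times`, `kappa`,
#'   `n_rotor_periods`, `rotor_period`).
#' @return a [dephasing_curve()] with `sigma` set to `noise_sd` and the
#'   true `r` recorded.
#' @export
gen_dephasing <- function(r, experiment = c("PITHIRDS_CT", "REDOR"),
                          noise_sd = 0.02, seed = 1L, ...) {
  experiment <- match.arg(experiment)
  clean <- if (experiment == "PITHIRDS_CT") simulate_pithirds_decay(r, ...)
           else simulate_redor_buildup(r, ...)
  noisy <- clean$signal +
    with_seed_local(seed, stats::rnorm(length(clean$signal), 0, noise_sd))
  out <- dephasing_curve(experiment, clean$times, noisy,
                         sigma = rep(max(noise_sd, 1e-12),
                                     length(clean$times)),
                         r = r)
  out
}

#' Generate a non-diluted / diluted pair of 2D spin-diffusion spectra
#'
#' Builds Gaussian peaks (diagonal references plus crosspeaks, each with a
#' centre, integrated volume and per-axis widths) on a ppm grid, then
#' produces the 1:1 isotope-diluted counterpart by scaling every
#' label-derived signal by the labeled fraction `p` and interstrand
#' crosspeaks by an additional factor `p^2`; the crosspeak-to-diagonal
#' volume ratio therefore reduces by `p^2` for interstrand contacts
#' (the ~25 % expectation at p = 0.5) and is unchanged for intrastrand
#' contacts. Additive Gaussian noise is drawn independently for the two
#' spectra.
#'
#' @param peaks data frame with columns `f1`, `f2` (ppm centres), `volume`
#'   (integrated), `width` (Gaussian SD, ppm), `type` (one of `"diagonal"`,
#'   `"intrastrand"`, `"interstrand"`).
#' @param dilution_p labeled fraction in the diluted sample (default 0.5).
#' @param ppm_range,ppm_step grid specification (shared by both axes).
#' @param noise_sd additive noise SD per grid point.
#' @param seed integer seed.
#' @return list with `nondiluted` and `diluted` [spectrum2d()] objects and
#'   `truth` (peaks table, `dilution_p`, `noise_sd`, `seed`).
#' @export
gen_spectrum2d <- function(peaks, dilution_p = 0.5,
                           ppm_range = c(10, 70), ppm_step = 0.15,
                           noise_sd = 0, seed = 1L) {
  stopifnot(is.data.frame(peaks),
            all(c("f1", "f2", "volume", "width", "type") %in% names(peaks)),
            all(peaks$type %in% c("diagonal", "intrastrand", "interstrand")),
            dilution_p > 0, dilution_p <= 1)
  ax <- seq(ppm_range[2], ppm_range[1], by = -ppm_step)  # descending
  if (any(peaks$f1 < min(ax) | peaks$f1 > max(ax) |
            peaks$f2 < min(ax) | peaks$f2 > max(ax)))
    stop("peak centres must lie inside the ppm grid")
  build <- function(scales, noise_seed) {
    m <- matrix(0, length(ax), length(ax))
    for (i in seq_len(nrow(peaks))) {
      g1 <- stats::dnorm(ax, peaks$f1[i], peaks$width[i])
      g2 <- stats::dnorm(ax, peaks$f2[i], peaks$width[i])
      # discrete unit-volume normalisation on the grid
      m <- m + scales[i] * peaks$volume[i] *
        outer(g1 / sum(g1), g2 / sum(g2))
    }
    if (noise_sd > 0)
      m <- m + with_seed_local(noise_seed,
        matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m)))
    m
  }
  p <- dilution_p
  dil_scale <- ifelse(peaks$type == "interstrand", p * p^2, p)
  base <- as.integer(seed) %% 500000000L
  list(nondiluted = spectrum2d(ax, ax,
                               build(rep(1, nrow(peaks)), base * 2L + 1L),
                               label = "nondiluted"),
       diluted = spectrum2d(ax, ax, build(dil_scale, base * 2L + 2L),
                            label = "diluted"),
       truth = list(peaks = peaks, dilution_p = dilution_p,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate mass-per-length measurements from a multiples-of-u mixture
#'
#' Draws MPL values from a Gaussian mixture with means at integer multiples
#' of the unit MPL `u`, emulating fields of fibrils bundling one, two,
#' three, ... filaments.
#'
#' @param u unit MPL, kDa/nm (default 18.8).
#' @param weights mixture weights over k = 1..K (normalised internally).
#' @param width shared Gaussian SD, kDa/nm.
#' @param n number of measurements.
#' @param seed integer seed.
#' @return numeric vector of MPL values with attribute `truth`.
#' @export
gen_mpl_sample <- function(u = 18.8, weights = c(0, 0.5, 0.5), width = 3,
                           n = 500, seed = 1L) {
  stopifnot(u > 0, width >= 0, n > 0, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  vals <- with_seed_local(seed, {
    k <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    stats::rnorm(n, k * u, width)
  })
  attr(vals, "truth") <- list(u = u, weights = weights, width = width,
                              n = n, seed = seed)
  vals
}

#' Generate a ThT fluorescence trace with known lag period
#'
#' Logistic growth with \eqn{t_{1/2} = \mathrm{lag} + 2/k} (the tangent
#' lag convention used by [fit_tht_kinetics()]) plus Gaussian noise.
#'
#' @param lag ground-truth lag period, h.
#' @param k growth rate, 1/h.
#' @param F0 baseline fluorescence.
#' @param A amplitude.
#' @param noise_sd Gaussian noise SD as a fraction of `A`.
#' @param t_max,n_points time grid (hours).
#' @param seed integer seed.
#' @return a [tht_trace()]; ground truth in attribute `truth`.
#' @export
gen_tht_trace <- function(lag = 28.5, k = 0.5, F0 = 100, A = 1000,
                          noise_sd = 0.02, t_max = NULL, n_points = 60,
                          seed = 1L) {
  stopifnot(k > 0, A > 0, n_points >= 10)
  t_half <- lag + 2 / k
  if (is.null(t_max)) t_max <- t_half + 6 / k
  tt <- seq(0, t_max, length.out = n_points)
  f <- F0 + A / (1 + exp(-k * (tt - t_half)))
  if (noise_sd > 0)
    f <- f + with_seed_local(seed, stats::rnorm(n_points, 0, noise_sd * A))
  out <- tht_trace(tt, f, replicate_id = sprintf("sim-seed%d", seed))
  attr(out, "truth") <- list(lag = lag, k = k, F0 = F0, A = A,
                             t_half = t_half, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Preset generator truths for the study conditions
#'
#' Named parameter presets for [gen_tht_trace()] carrying the best-fit lag
#' periods of the four fibrillation conditions (aqueous buffer and synaptic
#' plasma membranes from 3-, 12- and 18-month animals). Presets are data
#' for demonstrations and ordering checks, not assertions about new
#' measurements.
#'
#' @return data frame with columns `preset`, `lag_h`, `lag_se_h`.
#' @export
tht_presets <- function() {
  data.frame(
    preset = c("aqueous", "rSPM-3mo", "rSPM-12mo", "rSPM-18mo"),
    lag_h = c(28.5, 39.4, 37.2, 40.5),
    lag_se_h = c(1.4, 1.8, 1.8, 1.7),
    stringsAsFactors = FALSE
  )
}
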