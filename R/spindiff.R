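#' Construct a 2D spectrum
#'
#' Container for a 2D 13C-13C spin-diffusion spectrum: two ppm axes and an
#' intensity matrix with `length(axis_f1)` rows and `length(axis_f2)`
#' columns. Axes may be supplied ascending or descending; they are
#' normalized internally to the NMR convention (descending ppm), reordering
#' the matrix accordingly.
#'
#' @param axis_f1,axis_f2 ppm grids, strictly monotone.
#' @param intensity numeric matrix, rows indexed by `axis_f1`.
#' @param label free text.
#' @return object of class `spectrum2d`.
#' @export
spectrum2d <- function(axis_f1, axis_f2, intensity, label = "") {
  stopifnot(is.matrix(intensity),
            nrow(intensity) == length(axis_f1),
            ncol(intensity) == length(axis_f2))
  d1 <- diff(axis_f1); d2 <- diff(axis_f2)
  if (!(all(d1 > 0) || all(d1 < 0)) || !(all(d2 > 0) || all(d2 < 0)))
    stop("ppm axes must be strictly monotone")
  if (all(d1 > 0)) { axis_f1 <- rev(axis_f1); intensity <- intensity[nrow(intensity):1, , drop = FALSE] }
  if (all(d2 > 0)) { axis_f2 <- rev(axis_f2); intensity <- intensity[, ncol(intensity):1, drop = FALSE] }
  structure(list(axis_f1 = axis_f1, axis_f2 = axis_f2,
                 intensity = intensity, label = label),
            class = "spectrum2d")
}

#' Integrate a rectangular peak volume
#'
#' Sums the intensity over all grid points inside a rectangular ppm window
#' (inclusive on both edges) centred on the peak. The default half-widths of
#' 0.75 ppm per side give the standard 1.5 x 1.5 ppm integration region.
#'
#' @param spec a [spectrum2d()].
#' @param center length-2 numeric, (f1 ppm, f2 ppm).
#' @param half_width length-2 (or scalar) half-widths in ppm per axis.
#' @param noise_sd optional noise SD attached to the result.
#' @return object of class `volume_result`: `center`, `half_width`,
#'   `volume`, `noise_sd`, `n_points`.
#' @export
integrate_peak_volume <- function(spec, center, half_width = c(0.75, 0.75),
                                  noise_sd = NA_real_) {
  stopifnot(inherits(spec, "spectrum2d"), length(center) == 2)
  half_width <- rep_len(half_width, 2L)
  lo <- center - half_width; hi <- center + half_width
  for (ax in 1:2) {
    axis <- if (ax == 1) spec$axis_f1 else spec$axis_f2
    if (lo[ax] < min(axis) || hi[ax] > max(axis))
      stop("integration window [", lo[ax], ", ", hi[ax],
           "] ppm exceeds the f", ax, " axis range [",
           min(axis), ", ", max(axis), "]")
  }
  i1 <- which(spec$axis_f1 >= lo[1] & spec$axis_f1 <= hi[1])
  i2 <- which(spec$axis_f2 >= lo[2] & spec$axis_f2 <= hi[2])
  structure(list(center = center, half_width = half_width,
                 volume = sum(spec$intensity[i1, i2]),
                 noise_sd = noise_sd,
                 n_points = length(i1) * length(i2)),
            class = "volume_result")
}

#' Analytic window volume from a Gaussian peak list
#'
#' When peak parameters rather than a full spectrum grid are available,
#' the volume of a rectangular window is computed exactly from the
#' bivariate Gaussian integrals: each peak contributes
#' `volume * P(f1 in window) * P(f2 in window)`. This exact path enables
#' fully analytic tests of the downstream dilution statistics.
#'
#' @param peaks data frame with columns `f1`, `f2` (centres, ppm),
#'   `volume`, `width` (Gaussian SD, ppm).
#' @param center,half_width window centre and per-axis half-widths, ppm.
#' @return integrated volume (numeric).
#' @export
peaklist_volume <- function(peaks, center, half_width = c(0.75, 0.75)) {
  stopifnot(is.data.frame(peaks),
            all(c("f1", "f2", "volume", "width") %in% names(peaks)),
            length(center) == 2)
  half_width <- rep_len(half_width, 2L)
  p1 <- stats::pnorm(center[1] + half_width[1], peaks$f1, peaks$width) -
    stats::pnorm(center[1] - half_width[1], peaks$f1, peaks$width)
  p2 <- stats::pnorm(center[2] + half_width[2], peaks$f2, peaks$width) -
    stats::pnorm(center[2] - half_width[2], peaks$f2, peaks$width)
  sum(peaks$volume * p1 * p2)
}

#' Estimate the spectral noise from peak-free regions
#'
#' Places `n_regions` disjoint rectangular windows (same size as the peak
#' integration window) on peak-free parts of the spectrum, integrates each,
#' and returns the SD of the volumes. Candidate positions are drawn without
#' replacement on a coarse grid of non-overlapping window tiles, excluding
#' any tile that comes within `exclusion` ppm of a listed peak; the draw is
#' seeded, so the same seed on the same spectrum reproduces identical
#' regions.
#'
#' @param spec a [spectrum2d()].
#' @param peaks list (or 2-column matrix) of peak centres (f1, f2) in ppm
#'   to avoid.
#' @param n_regions number of noise windows (default 10).
#' @param half_width window half-widths, ppm (default 0.75, i.e. 1.5 x 1.5).
#' @param exclusion extra clearance around peak centres, ppm.
#' @param seed integer seed for the placement.
#' @return list with `noise_sd`, `regions` (matrix of window centres),
#'   `seed`.
#' @export
estimate_spectral_noise <- function(spec, peaks, n_regions = 10,
                                    half_width = c(0.75, 0.75),
                                    exclusion = 2, seed = 1L) {
  stopifnot(inherits(spec, "spectrum2d"))
  half_width <- rep_len(half_width, 2L)
  if (is.data.frame(peaks)) peaks <- as.matrix(peaks[, 1:2])
  else if (is.list(peaks)) peaks <- do.call(rbind, peaks)
  peaks <- matrix(as.numeric(peaks), ncol = 2)
  # coarse tiling by whole windows guarantees disjointness
  c1 <- seq(min(spec$axis_f1) + half_width[1],
            max(spec$axis_f1) - half_width[1], by = 2 * half_width[1])
  c2 <- seq(min(spec$axis_f2) + half_width[2],
            max(spec$axis_f2) - half_width[2], by = 2 * half_width[2])
  tiles <- as.matrix(expand.grid(f1 = c1, f2 = c2))
  if (nrow(peaks) > 0) {
    near <- apply(tiles, 1, function(ct)
      any(abs(peaks[, 1] - ct[1]) < half_width[1] + exclusion &
            abs(peaks[, 2] - ct[2]) < half_width[2] + exclusion))
    tiles <- tiles[!near, , drop = FALSE]
  }
  if (nrow(tiles) < n_regions)
    stop("cannot place ", n_regions, " disjoint peak-free windows; ",
         "only ", nrow(tiles), " candidate tiles available - ",
         "try a smaller window or fewer regions")
  idx <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    sample.int(nrow(tiles), n_regions)
  })
  regions <- tiles[idx, , drop = FALSE]
  vols <- apply(regions, 1, function(ct)
    integrate_peak_volume(spec, ct, half_width)$volume)
  list(noise_sd = stats::sd(vols), regions = regions, seed = seed)
}

#' Construct an isotope-dilution volume quartet
#'
#' The four integrated volumes behind the Reduction statistic: crosspeak and
#' diagonal-reference volumes in the non-diluted (`v1_n`, `v0_n`) and 1:1
#' isotope-diluted (`v1_d`, `v0_d`) spectra, with the respective spectral
#' noise SDs.
#'
#' @param v1_n,v0_n crosspeak and diagonal volumes, non-diluted spectrum.
#' @param v1_d,v0_d same for the diluted spectrum.
#' @param delta_n,delta_d spectral noise SDs of the two spectra.
#' @return object of class `dilution_quartet`.
#' @export
dilution_quartet <- function(v1_n, v0_n, v1_d, v0_d,
                             delta_n = 0, delta_d = 0) {
  if (v0_n <= 0 || v0_d <= 0)
    stop("diagonal reference volumes must be positive")
  structure(list(v1_n = v1_n, v0_n = v0_n, v1_d = v1_d, v0_d = v0_d,
                 delta_n = delta_n, delta_d = delta_d),
            class = "dilution_quartet")
}

#' Crosspeak reduction statistic under isotope dilution
#'
#' Quantifies how much a crosspeak loses intensity, relative to its diagonal
#' spin reservoir, upon 1:1 isotope dilution:
#' \deqn{\mathrm{Reduction} = \frac{V_{1,d}/V_{0,d}}{V_{1,n}/V_{0,n}}
#'   \times 100\,\%}
#' Intrastrand (intramolecular) contacts survive dilution (~100 %), while
#' interstrand contacts, which need two neighbouring labeled molecules,
#' drop to ~25 % at 1:1 dilution. The uncertainty is the first-order
#' propagation over the four volumes with their spectral noises. The call
#' compares `reduction` against the thresholds (intrastrand at >= 75 %,
#' interstrand at <= 50 % by default, ambiguous between); a call is demoted
#' to ambiguous when the `reduction` +/- `uncertainty` interval straddles
#' the opposite threshold.
#'
#' @param q a [dilution_quartet()].
#' @param thresholds named numeric `c(intrastrand = 75, interstrand = 50)`
#'   in percent.
#' @return object of class `reduction_result`: `reduction` (%),
#'   `uncertainty` (%), `contact_class`.
#' @export
reduction_statistic <- function(q, thresholds = c(intrastrand = 75,
                                                  interstrand = 50)) {
  stopifnot(inherits(q, "dilution_quartet"))
  red <- (q$v1_d / q$v0_d) / (q$v1_n / q$v0_n) * 100
  unc <- 100 * sqrt(
    (q$v1_d / (q$v0_d * q$v1_n))^2 * q$delta_n^2 +
      (q$v0_n / (q$v0_d * q$v1_n))^2 * q$delta_d^2 +
      (q$v1_d * q$v0_n / (q$v0_d * q$v1_n^2))^2 * q$delta_n^2 +
      (q$v1_d * q$v0_n / (q$v1_n * q$v0_d^2))^2 * q$delta_d^2)
  # point classification, demoted to ambiguous when the +/- uncertainty
  # interval straddles the opposite threshold
  cls <- if (red >= thresholds[["intrastrand"]]) {
    if (red - unc <= thresholds[["interstrand"]]) "ambiguous" else "intrastrand"
  } else if (red <= thresholds[["interstrand"]]) {
    if (red + unc >= thresholds[["intrastrand"]]) "ambiguous" else "interstrand"
  } else "ambiguous"
  structure(list(reduction = red, uncertainty = unc, contact_class = cls),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("Crosspeak reduction: %.1f %% +/- %.1f %% -> %s\n",
              x$reduction, x$uncertainty, x$contact_class))
  invisible(x)
}

#' Expected interstrand crosspeak retention under isotope dilution
#'
#' Under independent Bernoulli labeling of strands with probability `p`, an
#' interstrand crosspeak requires both members of a neighbouring-strand pair
#' to be labeled, so its expected intensity relative to the fully labeled
#' sample is \eqn{p^2 \times 100\,\%} (25 % at 1:1 dilution). Optionally
#' confirms the closed form by a seeded Monte Carlo over a one-dimensional
#' strand lattice.
#'
#' @param p label fraction, 0 < p <= 1.
#' @param model only `"pair_product"` is implemented.
#' @param mc_pairs if > 0, also run a Monte Carlo with this many
#'   nearest-neighbour pairs (a lattice of `mc_pairs + 1` strands).
#' @param seed seed for the Monte Carlo.
#' @return list with `expected` (%), and when `mc_pairs > 0` also
#'   `mc_estimate` (%) and `mc_pairs`.
#' @export
dilution_expectation <- function(p, model = "pair_product",
                                 mc_pairs = 0, seed = 1L) {
  model <- match.arg(model, "pair_product")
  stopifnot(p > 0, p <= 1)
  out <- list(expected = 100 * p^2)
  if (mc_pairs > 0) {
    mc <- local({
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
      lab <- stats::rbinom(mc_pairs + 1, 1, p)
      mean(lab[-1] * lab[-length(lab)])
    })
    out$mc_estimate <- 100 * mc
    out$mc_pairs <- mc_pairs
  }
  out
}

#' Secondary chemical-shift deviations
#'
#' Computes, per residue, the beta-strand indicator
#' \deqn{\Delta\delta C_\beta - \Delta\delta C_\alpha =
#'   (\delta C_\beta^{obs} - \delta C_\beta^{rc}) -
#'   (\delta C_\alpha^{obs} - \delta C_\alpha^{rc})}
#' against a bundled random-coil 13C shift reference. Positive deviations
#' indicate beta-strand secondary structure. Calls: `beta` when the
#' deviation exceeds `threshold + band`, `non_beta` below
#' `threshold - band`, `undetermined` inside the band or when either shift
#' (or the reference entry) is missing - glycine, having no C-beta, is
#' always undetermined.
#'
#' @param records data frame with columns `residue` (one-letter code),
#'   `delta_ca`, `delta_cb` (observed shifts, ppm; NA allowed) and
#'   optionally `index`.
#' @param random_coil data frame with columns `residue`, `ca`, `cb`
#'   (defaults to the bundled reference, [random_coil_shifts()]).
#' @param threshold centre of the call boundary, ppm (default 0).
#' @param band half-width of the undetermined band, ppm (default 0.5).
#' @return the input data frame with added columns `deviation` (ppm) and
#'   `call`.
#' @export
secondary_shift_deviation <- function(records,
                                      random_coil = random_coil_shifts(),
                                      threshold = 0, band = 0.5) {
  stopifnot(is.data.frame(records),
            all(c("residue", "delta_ca", "delta_cb") %in% names(records)))
  m <- match(toupper(records$residue), toupper(random_coil$residue))
  if (anyNA(m))
    warning("residue(s) absent from random-coil table: ",
            paste(unique(records$residue[is.na(m)]), collapse = ", "),
            "; marked undetermined")
  rc_ca <- random_coil$ca[m]
  rc_cb <- random_coil$cb[m]
  dev <- (records$delta_cb - rc_cb) - (records$delta_ca - rc_ca)
  call <- ifelse(is.na(dev), "undetermined",
                 ifelse(dev > threshold + band, "beta",
                        ifelse(dev < threshold - band, "non_beta",
                               "undetermined")))
  records$deviation <- dev
  records$call <- call
  records
}

#' Random-coil 13C chemical shifts
#'
#' Loads the bundled random-coil reference table (Wishart-style random-coil
#' Ca/Cb/C' shifts for the 20 standard amino acids, ppm, DSS-referenced).
#' Glycine has no C-beta (NA).
#'
#' @return data frame with columns `residue` (one-letter code), `aa`
#'   (three-letter), `ca`, `cb`, `co`.
#' @export
random_coil_shifts <- function() {
  path <- system.file("extdata", "random_coil_shifts_13c.csv",
                      package = "fibrilquant", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
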