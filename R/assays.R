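#' Construct a thioflavin-T kinetics trace
#'
#' @param times measurement times, hours, increasing, >= 10 points.
#' @param fluorescence ThT fluorescence, arbitrary units.
#' @param replicate_id optional identifier.
#' @return object of class `tht_trace`.
#' @export
tht_trace <- function(times, fluorescence, replicate_id = "") {
  stopifnot(length(times) >= 10, length(times) == length(fluorescence))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times),
                 fluorescence = as.numeric(fluorescence),
                 replicate_id = replicate_id),
            class = "tht_trace")
}

#' Fit ThT fibrillation kinetics and extract the lag period
#'
#' Fits the logistic growth model
#' \deqn{F(t) = F_0 + \frac{A}{1 + e^{-k (t - t_{1/2})}}}
#' by least squares and reports the lag period under the tangent-intercept
#' convention \deqn{\mathrm{lag} = t_{1/2} - 2/k,} i.e. the intercept of
#' the maximal-growth tangent with the baseline. The lag standard error
#' comes from the fit covariance via the delta method
#' (\eqn{\mathrm{Var}[lag] = \mathrm{Var}[t_{1/2}] + (2/k^2)^2
#' \mathrm{Var}[k] + 2\cdot(2/k^2)\mathrm{Cov}[t_{1/2},k]}).
#' An alternative `"amplitude10"` convention (time at 10 % of amplitude)
#' is available.
#'
#' A trace with a decreasing overall trend, or one that has not reached a
#' plateau, cannot anchor the sigmoid: the former is an error, the latter
#' returns the fit with `lag_lower_bound_only = TRUE`.
#'
#' @param trace a [tht_trace()].
#' @param lag_convention `"tangent"` (default) or `"amplitude10"`.
#' @return object of class `kinetics_fit`: `F0`, `A`, `k` (1/h), `t_half`
#'   (h), `lag` (h), `lag_se` (h), `lag_lower_bound_only`, `residual_rms`.
#' @export
fit_tht_kinetics <- function(trace, lag_convention = c("tangent",
                                                       "amplitude10")) {
  stopifnot(inherits(trace, "tht_trace"))
  lag_convention <- match.arg(lag_convention)
  t <- trace$times; y <- trace$fluorescence
  if (stats::coef(stats::lm(y ~ t))[[2]] < 0 &&
      y[length(y)] < mean(y[1:3]))
    stop("trace decreases overall; no sigmoidal growth to fit ",
         "(replicate '", trace$replicate_id, "')")
  F0g <- min(y); Ag <- diff(range(y))
  t_half_g <- t[which.min(abs(y - (F0g + Ag / 2)))]
  span <- diff(range(t))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ F0 + A / (1 + exp(-k * (t - t_half))),
                      start = list(F0 = F0g, A = Ag, k = 4 / span,
                                   t_half = t_half_g),
                      lower = c(F0 = -Inf, A = 1e-12, k = 1e-6,
                                t_half = min(t) - span),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("logistic fit failed: ", conditionMessage(fit))
  cf <- stats::coef(fit)
  k <- cf[["k"]]; t_half <- cf[["t_half"]]
  lag <- if (lag_convention == "tangent") t_half - 2 / k
         else t_half - log(9) / k  # F = F0 + 0.1 A
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  lag_se <- if (is.null(vc)) NA_real_ else {
    dk <- if (lag_convention == "tangent") 2 / k^2 else log(9) / k^2
    sqrt(max(0, vc["t_half", "t_half"] + dk^2 * vc["k", "k"] +
               2 * dk * vc["t_half", "k"]))
  }
  # plateau check: last point should be near F0 + A
  plateau <- y[length(y)] >= cf[["F0"]] + 0.9 * cf[["A"]] ||
    max(t) >= t_half + 2 / k
  structure(list(F0 = cf[["F0"]], A = cf[["A"]], k = k, t_half = t_half,
                 lag = lag, lag_se = lag_se,
                 lag_lower_bound_only = !plateau,
                 lag_convention = lag_convention,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 fit = fit),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("ThT kinetics fit: lag = %.1f h +/- %.1f h%s\n", x$lag,
              x$lag_se,
              if (x$lag_lower_bound_only) " (lower bound only)" else ""))
  cat(sprintf("  t_half = %.1f h, k = %.3f 1/h, A = %.3g, F0 = %.3g\n",
              x$t_half, x$k, x$A, x$F0))
  invisible(x)
}

#' Membrane-binding percentage from a BCA supernatant assay
#'
#' After co-incubation of peptide with membranes and ultracentrifugation,
#' the background-corrected supernatant concentration relative to the
#' initial peptide concentration is the free (unbound) fraction:
#' \deqn{\mathrm{free\%} = \frac{C_{sup,sample} - C_{sup,control}}
#'   {C_{initial}} \times 100.}
#' The `"bound"` convention (default) reports `100 - free%`, i.e. the
#' membrane-bound percentage; `"as_printed"` reports the supernatant ratio
#' itself, as sometimes typeset under a bound-percentage label. The two
#' always sum to 100.
#'
#' @param c_sup_sample supernatant concentration with peptide + membranes.
#' @param c_sup_control supernatant concentration of the membrane-only
#'   control (background).
#' @param c_initial initial peptide concentration (> 0). All in the same
#'   units.
#' @param convention `"bound"` (default) or `"as_printed"`.
#' @return object of class `assay_result` with `kind = "binding"`,
#'   `value` (%), `convention`.
#' @export
binding_percentage <- function(c_sup_sample, c_sup_control, c_initial,
                               convention = c("bound", "as_printed")) {
  convention <- match.arg(convention)
  stopifnot(c_initial > 0)
  corrected <- c_sup_sample - c_sup_control
  if (corrected < 0) {
    warning("negative background-corrected supernatant concentration; ",
            "clipped to 0")
    corrected <- 0
  }
  free_pct <- 100 * corrected / c_initial
  value <- if (convention == "bound") 100 - free_pct else free_pct
  structure(list(kind = "binding", value = value, uncertainty = NA_real_,
                 convention = convention),
            class = "assay_result")
}

#' Cell-viability percentage from an MTT assay
#'
#' \deqn{\mathrm{viability\%} = \frac{A_{sample} - A_{background}}
#'   {A_{control} - A_{background}} \times 100}
#' with absorbances at 570 nm. Values above 100 % are reported as-is.
#'
#' @param a_sample absorbance of cells treated with fibrils.
#' @param a_background absorbance of the solvent background.
#' @param a_control absorbance of untreated (membrane-only) cells; must
#'   exceed `a_background`.
#' @return object of class `assay_result` with `kind = "viability"`.
#' @export
viability_percentage <- function(a_sample, a_background, a_control) {
  if (a_control <= a_background)
    stop("control absorbance must exceed background")
  structure(list(kind = "viability",
                 value = 100 * (a_sample - a_background) /
                   (a_control - a_background),
                 uncertainty = NA_real_),
            class = "assay_result")
}

#' Fit a denaturation stability curve and its midpoint
#'
#' Fits the remaining-pellet fraction versus denaturant (GdnHCl)
#' concentration to a two-state sigmoid
#' \deqn{f(c) = \frac{1}{1 + e^{(c - C_{1/2})/w}}}
#' and reports the midpoint \eqn{C_{1/2}} with its standard error. A lower
#' \eqn{C_{1/2}} means the fibril dissolves at lower denaturant
#' concentration, i.e. is less stable. For degenerate step-like data
#' (perfect 1-to-0 transition) the midpoint is the centre of the step and
#' the width collapses to the floor.
#'
#' @param conc denaturant concentrations, M (>= 4 values).
#' @param fraction remaining fibril fraction, in \[0, 1.1\].
#' @return object of class `stability_fit`: `c_half` (M), `c_half_se` (M),
#'   `width` (M), `flagged` (TRUE when the data rise with concentration
#'   beyond noise), `fit` (may be NULL for the degenerate step case).
#' @export
stability_curve <- function(conc, fraction) {
  stopifnot(length(conc) >= 4, length(conc) == length(fraction),
            all(fraction >= -0.05), all(fraction <= 1.1))
  o <- order(conc); conc <- conc[o]; fraction <- fraction[o]
  flagged <- stats::coef(stats::lm(fraction ~ conc))[[2]] > 0
  if (flagged)
    warning("fraction rises with denaturant concentration; fit flagged")
  # midpoint initial guess: interpolated 0.5 crossing
  below <- which(fraction <= 0.5)
  c_half_g <- if (length(below) == 0 || below[1] == 1) stats::median(conc)
  else {
    i <- below[1]
    conc[i - 1] + (fraction[i - 1] - 0.5) * (conc[i] - conc[i - 1]) /
      (fraction[i - 1] - fraction[i])
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fraction ~ 1 / (1 + exp((conc - c_half) / w)),
                      start = list(c_half = c_half_g,
                                   w = diff(range(conc)) / 8),
                      lower = c(c_half = min(conc) - diff(range(conc)),
                                w = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate (e.g. perfect step): report the interpolated crossing
    return(structure(list(c_half = c_half_g, c_half_se = NA_real_,
                          width = NA_real_, flagged = flagged, fit = NULL),
                     class = "stability_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["c_half", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(c_half = cf[["c_half"]], c_half_se = se, width = cf[["w"]],
                 flagged = flagged, fit = fit),
            class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf("Denaturation midpoint C1/2 = %.2f M (se %.2g M)%s\n",
              x$c_half, x$c_half_se, if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

#' Two-group significance with star annotation
#'
#' Two-sided two-sample t-test (Welch by default) with the star mapping used
#' for figure annotation: `***` for p < 0.001, `**` for p < 0.01, `*` for
#' p < 0.1, empty otherwise (thresholds configurable). Two groups with zero
#' variance and equal means are reported as p = 1.
#'
#' @param group_a,group_b numeric vectors, each n >= 2.
#' @param var_equal `FALSE` (Welch, default) or `TRUE` (Student).
#' @param star_thresholds decreasing p-value cutoffs for `*`, `**`, `***`.
#' @return list with `t`, `df`, `p`, `stars`.
#' @export
group_significance <- function(group_a, group_b, var_equal = FALSE,
                               star_thresholds = c(0.1, 0.01, 0.001)) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2,
            length(star_thresholds) == 3, all(diff(star_thresholds) < 0))
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = NA_real_, p = 1, stars = ""))
    return(list(t = Inf, df = NA_real_, p = 0,
                stars = strrep("*", 3)))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  p <- tt$p.value
  stars <- if (p < star_thresholds[3]) "***"
    else if (p < star_thresholds[2]) "**"
    else if (p < star_thresholds[1]) "*"
    else ""
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = p,
       stars = stars)
}

#' BCA standard-curve helper
#'
#' Ordinary least-squares line through BSA standard absorbances, returning a
#' function that converts absorbance to concentration.
#'
#' @param absorbance,concentration standard-curve points.
#' @return list with `slope`, `intercept`, `r_squared`, and `predict(a)`.
#' @export
bca_standard_curve <- function(absorbance, concentration) {
  stopifnot(length(absorbance) == length(concentration),
            length(absorbance) >= 3)
  m <- stats::lm(concentration ~ absorbance)
  cf <- stats::coef(m)
  list(slope = cf[[2]], intercept = cf[[1]],
       r_squared = summary(m)$r.squared,
       predict = function(a) cf[[1]] + cf[[2]] * a)
}
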