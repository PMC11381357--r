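#' @title Fluorescence kinetics
#' @name kinetics
#' @description Standard-curve calibration, conversion of fluorescence traces
#'   to product concentration, second-order rate-constant fitting, the
#'   three-class rate classification, and Arrhenius analysis.
NULL

#' Fit a fluorescence standard curve
#'
#' Ordinary least-squares line intensity = slope * concentration + intercept
#' over the calibration dilution series.
#'
#' @param concs concentrations (nM), at least two distinct values.
#' @param intensities fluorescence intensities (a.u.).
#' @return list of class \code{calibration_curve} with \code{slope} (a.u./nM),
#'   \code{intercept} (a.u.) and \code{r_squared}.
#' @export
fit_standard_curve <- function(concs, intensities) {
  if (length(concs) != length(intensities))
    stop("concs and intensities differ in length", call. = FALSE)
  if (length(concs) < 2L || length(unique(concs)) < 2L)
    stop("need at least 2 distinct concentrations", call. = FALSE)
  fit <- stats::lm(intensities ~ concs)
  r2 <- if (stats::var(intensities) == 0) 1
        else suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2),
            class = "calibration_curve")
}

#' Construct a kinetic trace
#'
#' @param times time points (s), strictly increasing, starting at >= 0.
#' @param intensities fluorescence intensities (a.u.), same length.
#' @param temperature temperature (deg C).
#' @param sample_id identifier.
#' @return list of class \code{kinetic_trace}.
#' @export
kinetic_trace <- function(times, intensities, temperature = 25, sample_id = "s1") {
  if (length(times) != length(intensities))
    stop("times and intensities differ in length", call. = FALSE)
  if (length(times) > 0L) {
    if (times[1L] < 0) stop("times must start at >= 0", call. = FALSE)
    if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = as.numeric(times), intensities = as.numeric(intensities),
                 temperature = temperature, sample_id = as.character(sample_id)),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace %s: %d points, %.4g-%.4g s, %g degC>\n",
              x$sample_id, length(x$times), min(x$times), max(x$times),
              x$temperature))
  invisible(x)
}

#' Convert a fluorescence trace to product concentration
#'
#' Inverts the standard curve after background subtraction:
#' c = max(0, (I - background - intercept) / slope), converted from nM to M.
#'
#' @param trace a \code{kinetic_trace}.
#' @param calib a \code{calibration_curve} with positive slope.
#' @param background background intensity (a.u.) measured on the quenched
#'   substrate:incumbent duplex.
#' @return numeric vector of product concentrations (M), clipped at 0.
#' @export
trace_to_concentration <- function(trace, calib, background = 0) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (calib$slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  c_nM <- (trace$intensities - background - calib$intercept) / calib$slope
  pmax(c_nM, 0) * 1e-9
}

# Second-order equal-concentration product curve, c(t) = c0^2 k t / (1 + c0 k t)
second_order_conc <- function(t, k, c0) c0 * (k * c0 * t) / (1 + k * c0 * t)

#' Fit the second-order rate constant of a displacement trace
#'
#' Nonlinear least squares of the equal-initial-concentration irreversible
#' second-order law \eqn{c(t) = c_0^2 k t / (1 + c_0 k t)} to a product
#' concentration series. The initial guess comes from the time at which the
#' series crosses \eqn{c_0/2} (there \eqn{k = 1/(c_0 t_{1/2})}); if the trace
#' never crosses, a grid search over log10 k in [2, 8] seeds the optimizer.
#'
#' @param conc product concentrations (M).
#' @param times time points (s), same length.
#' @param c0 initial strand concentration (M).
#' @param f_star completion fraction defining time-to-equilibrium
#'   (default 0.95).
#' @param flat_frac traces never exceeding \code{flat_frac * c0} are reported
#'   as no-reaction with k = 0 (default 0.02).
#' @return list of class \code{rate_fit}: \code{k} (M^-1 s^-1), \code{c0},
#'   \code{sse}, \code{t_eq} (s), \code{rate_class}, \code{no_reaction},
#'   \code{converged}.
#' @export
fit_rate_constant <- function(conc, times, c0, f_star = 0.95, flat_frac = 0.02) {
  if (length(conc) != length(times))
    stop("conc and times differ in length", call. = FALSE)
  if (length(conc) < 5L) stop("need at least 5 points", call. = FALSE)
  if (c0 <= 0) stop("c0 must be positive", call. = FALSE)
  if (max(conc) < flat_frac * c0) {
    return(structure(list(k = 0, c0 = c0, sse = sum(conc^2), t_eq = Inf,
                          rate_class = 2L, no_reaction = TRUE, converged = TRUE),
                     class = "rate_fit"))
  }
  cross <- which(conc >= c0 / 2)
  k0 <- if (length(cross) > 0L && times[cross[1L]] > 0) {
    1 / (c0 * times[cross[1L]])
  } else {
    grid <- 10^seq(2, 8, by = 0.25)
    sse_g <- vapply(grid, function(k) sum((conc - second_order_conc(times, k, c0))^2),
                    numeric(1L))
    grid[which.min(sse_g)]
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(conc ~ second_order_conc(times, k, c0),
                      start = list(k = k0), lower = 0,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    k <- k0
    converged <- FALSE
  } else {
    k <- unname(stats::coef(fit)[["k"]])
    converged <- fit$convInfo$isConv
  }
  sse <- sum((conc - second_order_conc(times, k, c0))^2)
  t_eq <- if (k > 0) time_to_equilibrium(k, c0, f_star) else Inf
  structure(list(k = k, c0 = c0, sse = sse, t_eq = t_eq,
                 rate_class = classify_rate(t_eq), no_reaction = FALSE,
                 converged = converged),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit: k = %.4g M^-1 s^-1, t_eq = %.4g s, class %d%s>\n",
              x$k, x$t_eq, x$rate_class,
              if (x$no_reaction) ", no reaction" else ""))
  invisible(x)
}

#' Time to reach a completion fraction under second-order kinetics
#'
#' Solving \eqn{c(t)/c_0 = f^*} gives
#' \eqn{t_{eq} = f^* / ((1 - f^*) k c_0)}.
#'
#' @param k rate constant (M^-1 s^-1), > 0.
#' @param c0 initial concentration (M).
#' @param f_star completion fraction in (0, 1), default 0.95.
#' @return time in seconds.
#' @export
time_to_equilibrium <- function(k, c0, f_star = 0.95) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (f_star <= 0 || f_star >= 1) stop("f_star must be in (0, 1)", call. = FALSE)
  f_star / ((1 - f_star) * k * c0)
}

#' Assign the three-class rate label from time to equilibrium
#'
#' Class 0: t_eq < 1000 s (fast); class 1: 1000 s <= t_eq <= 3600 s; class 2:
#' t_eq > 3600 s (slow). Both boundary times belong to the closed middle
#' interval.
#'
#' @param t_eq time to equilibrium (s); may be vectorized, Inf allowed.
#' @param t_fast,t_slow class boundaries (s).
#' @return integer class labels 0, 1 or 2.
#' @export
classify_rate <- function(t_eq, t_fast = 1000, t_slow = 3600) {
  if (any(t_eq <= 0, na.rm = TRUE)) stop("t_eq must be positive", call. = FALSE)
  ifelse(t_eq < t_fast, 0L, ifelse(t_eq <= t_slow, 1L, 2L))
}

#' Arrhenius fit of rate constants across temperatures
#'
#' Least-squares line of ln k against 1/T (K); the apparent activation energy
#' is \eqn{E_a = -slope \cdot R} with R = 8.314 J/(mol K).
#'
#' @param k_by_temp named numeric vector: names are temperatures in deg C,
#'   values rate constants (M^-1 s^-1), all > 0; at least 2 temperatures.
#' @return list of class \code{arrhenius_fit}: \code{Ea} (J/mol), \code{lnA},
#'   \code{r_squared}, \code{n_temps}.
#' @export
arrhenius_fit <- function(k_by_temp) {
  if (length(k_by_temp) < 2L)
    stop("need rate constants at >= 2 temperatures", call. = FALSE)
  if (is.null(names(k_by_temp)))
    stop("k_by_temp must be named by temperature (deg C)", call. = FALSE)
  if (any(k_by_temp <= 0)) stop("all rate constants must be positive", call. = FALSE)
  TK <- as.numeric(names(k_by_temp)) + 273.15
  if (anyNA(TK)) stop("temperature names must be numeric deg C", call. = FALSE)
  x <- 1 / TK
  y <- log(k_by_temp)
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) < 1e-30) 1 else suppressWarnings(summary(fit)$r.squared)
  structure(list(Ea = -unname(stats::coef(fit)[2L]) * R_J,
                 lnA = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n_temps = length(k_by_temp)),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit: Ea = %.3g kJ/mol, lnA = %.3f, R^2 = %.4f (%d temps)>\n",
              x$Ea / 1000, x$lnA, x$r_squared, x$n_temps))
  invisible(x)
}

#' Geometric mean of replicate rate constants
#'
#' Replicate traces are fitted independently and combined on the log scale,
#' appropriate for rate constants spanning orders of magnitude.
#'
#' @param ks positive rate constants.
#' @return geometric mean.
#' @export
geometric_mean_k <- function(ks) {
  ks <- ks[is.finite(ks) & ks > 0]
  if (length(ks) == 0L) return(0)
  exp(mean(log(ks)))
}
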