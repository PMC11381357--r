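#' @title Synthetic TMSD study generator
#' @name synthetic_data
#' @description Generates displacement systems with random toeholds on a fixed
#'   branch-migration region, planted sequence-dependent rate constants, and
#'   simulated fluorescence traces (including four-temperature Arrhenius
#'   series), so every downstream stage can be exercised and validated without
#'   laboratory data.
NULL

# Arbitrary documented default 16-mer branch-migration region; replaceable via
# the config so a real study sequence can be substituted.
DEFAULT_BRANCH_SEQ <- "TCATTCAATACCCTAC"

#' Configuration of the synthetic study
#'
#' Defaults mirror the emulated experiment: 6-nt random toeholds on a fixed
#' 16-nt branch region, 50 nM strands after 1:1 mixing of 100 nM stocks,
#' second-order displacement kinetics read out as restored fluorescence, and
#' a 15/20/25/30 degC temperature series.
#'
#' @param n_systems number of systems to generate (>= 0).
#' @param toehold_len toehold length (default 6).
#' @param branch_seq fixed branch-migration sequence (default a documented
#'   arbitrary 16-mer).
#' @param seed master integer seed; all per-system streams derive from it.
#' @param planted_coeffs named numeric vector of log10-rate weights on
#'   features (names must be feature names); defaults plant the monotone
#'   X2/X5/X11 dependence: faster with more free H-bond sites (X2 up, X5 up),
#'   slower with more intramolecular bonds (X11 down).
#' @param planted_intercept baseline log10 k.
#' @param noise_sd_log10k Gaussian SD of log10 k around the planted model.
#' @param c0 strand concentration after mixing (M), default 5e-8 (50 nM).
#' @param calibration list(slope, intercept): a.u. per nM and a.u.
#' @param background background intensity (a.u.).
#' @param trace_noise_sd additive Gaussian intensity noise (a.u.).
#' @param dt sampling interval (s).
#' @param duration trace duration (s).
#' @param temps_C temperatures of the variable-temperature series (deg C).
#' @param Ea apparent activation energy (J/mol) for temperature series.
#' @param lnA Arrhenius prefactor (ln of M^-1 s^-1).
#' @return list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_systems = 100L, toehold_len = 6L,
                             branch_seq = DEFAULT_BRANCH_SEQ, seed = 1L,
                             planted_coeffs = c(X2 = 0.20, X5 = 0.10, X11 = -0.15),
                             planted_intercept = -0.4,
                             noise_sd_log10k = 0.3,
                             c0 = 5e-8,
                             calibration = list(slope = 12, intercept = 50),
                             background = 100, trace_noise_sd = 6,
                             dt = 1, duration = 7200,
                             temps_C = c(15, 20, 25, 30),
                             Ea = 6e4, lnA = 35.7) {
  n_systems <- as.integer(n_systems)
  if (n_systems < 0L) stop("n_systems must be >= 0", call. = FALSE)
  if (as.integer(toehold_len) < 1L) stop("toehold_len must be >= 1", call. = FALSE)
  branch_seq <- check_dna(branch_seq, "branch_seq")
  if (!is.null(planted_coeffs)) {
    bad <- setdiff(names(planted_coeffs), feature_names())
    if (length(bad) > 0L)
      stop("unknown feature name(s) in planted_coeffs: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (c0 <= 0) stop("c0 must be positive", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (duration < dt) stop("duration must be >= dt", call. = FALSE)
  if (length(temps_C) == 0L) stop("temps_C must be nonempty", call. = FALSE)
  if (Ea < 0) stop("Ea must be >= 0", call. = FALSE)
  structure(
    list(n_systems = n_systems, toehold_len = as.integer(toehold_len),
         branch_seq = branch_seq, seed = as.integer(seed),
         planted_coeffs = planted_coeffs,
         planted_intercept = planted_intercept,
         noise_sd_log10k = noise_sd_log10k, c0 = c0,
         calibration = calibration, background = background,
         trace_noise_sd = trace_noise_sd, dt = dt, duration = duration,
         temps_C = temps_C, Ea = Ea, lnA = lnA),
    class = "synthetic_config"
  )
}

# Independent per-system seeds drawn once from the master seed; drawing is
# sequential, so extending n_systems never perturbs earlier systems.
derive_seeds <- function(seed, n, salt = 0L) {
  if (n == 0L) return(integer(0))
  withr::with_seed(seed + salt, sample.int(.Machine$integer.max - 1L, n))
}

#' Generate random-toehold displacement systems
#'
#' Each invader is a uniformly random toehold (5' end) followed by the fixed
#' branch-migration region; substrate and incumbent follow from
#' complementarity. Deterministic given the config seed, with per-system
#' random streams so earlier systems are unchanged when more are added.
#'
#' @param cfg a \code{synthetic_config}.
#' @return list of \code{displacement_system}, ids "sys001", ...
#' @export
gen_systems <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_systems
  if (n == 0L) return(list())
  seeds <- derive_seeds(cfg$seed, n, salt = 0L)
  width <- max(3L, nchar(as.character(n)))
  lapply(seq_len(n), function(i) {
    th <- withr::with_seed(seeds[i],
      paste(sample(DNA_BASES, cfg$toehold_len, replace = TRUE), collapse = ""))
    displacement_system(paste0(th, cfg$branch_seq),
                        toehold_len = cfg$toehold_len,
                        id = sprintf("sys%0*d", width, i))
  })
}

#' Planted sequence-dependent rate constant
#'
#' Draws \eqn{\log_{10} k = \beta_0 + \sum_f \beta_f X_f + \epsilon} with
#' \eqn{\epsilon \sim N(0, \sigma)}, the planted monotone dependence used to
#' validate the downstream ranking and classification machinery.
#'
#' @param fv a \code{feature_vector} (or named numeric with the feature
#'   columns referenced by the planted coefficients).
#' @param cfg a \code{synthetic_config}.
#' @param seed optional seed for the noise draw; without one the current RNG
#'   stream is used.
#' @return rate constant k (M^-1 s^-1).
#' @export
planted_log_rate <- function(fv, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  lg <- cfg$planted_intercept
  if (length(cfg$planted_coeffs) > 0L) {
    miss <- setdiff(names(cfg$planted_coeffs), names(fv))
    if (length(miss) > 0L)
      stop("feature vector lacks: ", paste(miss, collapse = ", "), call. = FALSE)
    lg <- lg + sum(cfg$planted_coeffs * unclass(fv)[names(cfg$planted_coeffs)])
  }
  if (cfg$noise_sd_log10k > 0) {
    eps <- if (is.null(seed)) stats::rnorm(1L, 0, cfg$noise_sd_log10k)
           else withr::with_seed(seed, stats::rnorm(1L, 0, cfg$noise_sd_log10k))
    lg <- lg + eps
  }
  10^lg
}

#' Simulate a fluorescence displacement trace
#'
#' Product concentration follows the equal-concentration second-order law
#' \eqn{c(t) = c_0 (k c_0 t)/(1 + k c_0 t)}; intensity is
#' slope * c(nM) + intercept + background + Gaussian noise, sampled at
#' 0, dt, ..., duration.
#'
#' @param k rate constant (M^-1 s^-1), >= 0.
#' @param cfg a \code{synthetic_config}.
#' @param seed optional seed for the intensity noise.
#' @param temperature trace temperature label (deg C), default 25.
#' @param sample_id identifier.
#' @return a \code{kinetic_trace}.
#' @export
simulate_trace <- function(k, cfg, seed = NULL, temperature = 25,
                           sample_id = "s1") {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  times <- seq(0, cfg$duration, by = cfg$dt)
  conc <- second_order_conc(times, k, cfg$c0)
  I <- cfg$calibration$slope * conc * 1e9 + cfg$calibration$intercept +
    cfg$background
  if (cfg$trace_noise_sd > 0) {
    eps <- if (is.null(seed)) stats::rnorm(length(I), 0, cfg$trace_noise_sd)
           else withr::with_seed(seed, stats::rnorm(length(I), 0, cfg$trace_noise_sd))
    I <- I + eps
  }
  kinetic_trace(times, I, temperature = temperature, sample_id = sample_id)
}

#' Arrhenius rate constant at a temperature
#' @param temp_C temperature (deg C).
#' @param Ea activation energy (J/mol).
#' @param lnA Arrhenius prefactor.
#' @return k (M^-1 s^-1).
#' @export
arrhenius_k <- function(temp_C, Ea, lnA) exp(lnA - Ea / (R_J * (temp_C + 273.15)))

#' Simulate a variable-temperature trace series
#'
#' One trace per configured temperature with
#' \eqn{k(T) = \exp(\ln A - E_a / RT)}.
#'
#' @param cfg a \code{synthetic_config} (nonempty \code{temps_C},
#'   \code{Ea >= 0}).
#' @param seed seed for the per-temperature noise streams.
#' @param sample_id identifier.
#' @return named list of \code{kinetic_trace}, names the temperatures in degC.
#' @export
simulate_temperature_series <- function(cfg, seed = NULL, sample_id = "s1") {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (length(cfg$temps_C) == 0L) stop("temps_C must be nonempty", call. = FALSE)
  seeds <- if (is.null(seed)) rep(list(NULL), length(cfg$temps_C))
           else as.list(derive_seeds(seed, length(cfg$temps_C), salt = 7L))
  out <- lapply(seq_along(cfg$temps_C), function(i) {
    Tc <- cfg$temps_C[i]
    simulate_trace(arrhenius_k(Tc, cfg$Ea, cfg$lnA), cfg, seed = seeds[[i]],
                   temperature = Tc, sample_id = sample_id)
  })
  names(out) <- as.character(cfg$temps_C)
  out
}

#' Simulate the complete planted study
#'
#' Generates systems, features, planted rate constants and (optionally)
#' fluorescence traces in one call. The planted log10 k combines the feature
#' model and per-system noise; the rate class derives from the realized k via
#' the time-to-equilibrium thresholds.
#'
#' @param cfg a \code{synthetic_config}.
#' @param model an \code{energy_model} for featurization.
#' @param traces also simulate one 25 degC trace per system (default FALSE).
#' @return list with \code{systems}, \code{features} (data.frame),
#'   \code{rates} (data.frame: sample_id, k, log10_k, t_eq, rate_class) and
#'   optionally \code{traces} (list of \code{kinetic_trace}).
#' @export
simulate_study <- function(cfg, model = energy_model(), traces = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  systems <- gen_systems(cfg)
  if (length(systems) == 0L)
    return(list(systems = list(), features = NULL, rates = NULL))
  features <- featurize_systems(systems, model, c0 = cfg$c0)
  kseeds <- derive_seeds(cfg$seed, length(systems), salt = 1L)
  k <- vapply(seq_along(systems), function(i) {
    fv <- unlist(features[i, feature_names()])
    planted_log_rate(fv, cfg, seed = kseeds[i])
  }, numeric(1L))
  t_eq <- 0.95 / (0.05 * k * cfg$c0)
  rates <- data.frame(sample_id = features$sample_id, k = k,
                      log10_k = log10(k), t_eq = t_eq,
                      rate_class = classify_rate(t_eq),
                      stringsAsFactors = FALSE)
  out <- list(systems = systems, features = features, rates = rates)
  if (traces) {
    tseeds <- derive_seeds(cfg$seed, length(systems), salt = 2L)
    out$traces <- lapply(seq_along(systems), function(i)
      simulate_trace(k[i], cfg, seed = tseeds[i],
                     sample_id = features$sample_id[i]))
  }
  out
}
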