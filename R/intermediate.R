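#' @title Toehold intermediate model
#' @name intermediate
NULL

#' Two-state toehold-hybridization intermediate
#'
#' Models the three-strand intermediate of TMSD as an all-or-none duplex
#' between the invader's toehold and the substrate's single-stranded overhang.
#' The association constant is \eqn{K = \exp(-\Delta G^\circ / RT)} with the
#' duplex standard free energy from the nearest-neighbor model. For equal
#' strand concentrations \eqn{c_0} the bound fraction solves the mass-action
#' quadratic
#' \deqn{\theta = \frac{(1 + 2 K c_0) - \sqrt{1 + 4 K c_0}}{2 K c_0}.}
#' The per-base probability of an interstrand toehold pair discounts toehold
#' bases already occupied by intramolecular folding of the invader:
#' \eqn{p_{inter}(i) = \theta (1 - p_{intra}(i))}.
#'
#' @param system a \code{displacement_system}.
#' @param model an \code{energy_model}.
#' @param c0 strand concentration after mixing (M); default 5e-8 (50 nM).
#' @param ppm optional precomputed \code{pair_prob_matrix} of the invader; if
#'   missing it is computed under \code{model}.
#' @param K optional association constant override (M^-1); mainly for testing
#'   degenerate cases such as a non-complementary toehold (K = 0).
#' @return an object of class \code{intermediate_state}: list with
#'   \code{theta}, \code{interstrand_pair_prob} (per toehold base),
#'   \code{complex_conc} (M), \code{delta_g} (kcal/mol) and \code{K} (M^-1).
#' @export
intermediate_state <- function(system, model = energy_model(), c0 = 5e-8,
                               ppm = NULL, K = NULL) {
  stopifnot(inherits(system, "displacement_system"))
  if (c0 <= 0) stop("c0 must be positive", call. = FALSE)
  th <- toehold_seq(system)
  dg <- duplex_delta_g(th, model)
  if (is.null(K)) K <- exp(-dg / (R_KCAL * model$temperature_K))
  theta <- theta_two_state(K, c0)
  if (is.null(ppm)) ppm <- partition_pair_probabilities(system$invader$sequence, model)
  p_intra <- 1 - ppm$p_unpaired[toehold_idx(system)]
  structure(
    list(theta = theta,
         interstrand_pair_prob = theta * (1 - p_intra),
         complex_conc = theta * c0,
         delta_g = dg, K = K, c0 = c0),
    class = "intermediate_state"
  )
}

#' Bound fraction of an equal-concentration two-state duplex
#' @param K association constant (M^-1), >= 0.
#' @param c0 total concentration of each strand (M).
#' @return bound fraction in [0, 1].
#' @export
theta_two_state <- function(K, c0) {
  if (K < 0) stop("K must be >= 0", call. = FALSE)
  if (K == 0) return(0)
  x <- K * c0
  # numerically safe form of ((1 + 2x) - sqrt(1 + 4x)) / (2x)
  unname((1 + 2 * x - sqrt(1 + 4 * x)) / (2 * x))
}

#' @export
print.intermediate_state <- function(x, ...) {
  cat(sprintf("<intermediate_state: theta = %.4f, [complex] = %.3g M, dG = %.2f kcal/mol>\n",
              x$theta, x$complex_conc, x$delta_g))
  invisible(x)
}
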