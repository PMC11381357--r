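#' @title Nucleic-acid energy model
#' @name energy
NULL

# SantaLucia unified nearest-neighbor parameters for DNA/DNA duplexes.
# dH kcal/mol, dS cal/(mol K); keys are the top-strand dinucleotide 5'->3'
# (the bottom strand is its Watson-Crick complement). Symmetric steps are
# filled in by reverse-complement equivalence.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# Duplex initiation, per terminal pair.
INIT_DH <- c(GC = 0.1, AT = 2.3)
INIT_DS <- c(GC = -2.8, AT = 4.1)

R_KCAL <- 0.0019872  # kcal / (mol K)
R_J <- 8.314         # J / (mol K)

#' Construct the secondary-structure energy model
#'
#' A decomposable model of intramolecular folding used by the enumeration
#' oracle, the partition-function engine and the MFE solver. The free energy of
#' a nested Watson-Crick structure is
#' \deqn{E = \sum_{pairs} \delta_{pair} + \sum_{stacks} \Delta G_{stack}(T),}
#' i.e. a per-pair penalty (a coarse loop-entropy cost of constraining the
#' backbone) plus a sequence-dependent stabilizing stacking term for every two
#' adjacent pairs (i,j), (i+1,j-1), taken from the nearest-neighbor table at
#' the model temperature. The same nearest-neighbor table (plus duplex
#' initiation) supplies the standard free energy of the intermolecular toehold
#' duplex used for the intermediate state.
#'
#' @param temperature_C temperature in degrees Celsius (default 25, the
#'   reference condition bracketed by the variable-temperature kinetics runs).
#' @param pair_penalty free-energy cost (kcal/mol) per intramolecular base
#'   pair; default 1.0.
#' @param stacks optional named vector of stack free energies (kcal/mol) keyed
#'   by top-strand dinucleotide; defaults to the nearest-neighbor
#'   \eqn{\Delta H - T \Delta S} values at \code{temperature_C}. All entries
#'   must be <= 0 (the MFE recursion relies on stacking being stabilizing).
#' @param kT thermal energy in kcal/mol; defaults to \eqn{R T}.
#' @param min_loop minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @param duplex_init free-energy initiation penalty added per terminal pair of
#'   an intermolecular duplex; default the nearest-neighbor initiation terms.
#' @return an object of class \code{energy_model}.
#' @export
energy_model <- function(temperature_C = 25, pair_penalty = 1.0,
                         stacks = NULL, kT = NULL, min_loop = 3L,
                         duplex_init = NULL) {
  TK <- temperature_C + 273.15
  if (TK <= 0) stop("temperature below absolute zero", call. = FALSE)
  if (is.null(stacks)) {
    stacks <- NN_DH - TK * NN_DS / 1000
  } else if (length(stacks) == 1L && is.null(names(stacks))) {
    stacks <- stats::setNames(rep(stacks, length(NN_DH)), names(NN_DH))
  } else if (!all(names(NN_DH) %in% names(stacks))) {
    stop("stacks must be a scalar or a vector named by all 16 dinucleotides",
         call. = FALSE)
  }
  if (any(stacks > 1e-12))
    stop("stack free energies must be <= 0", call. = FALSE)
  if (is.null(kT)) kT <- R_KCAL * TK
  if (kT <= 0) stop("kT must be positive", call. = FALSE)
  min_loop <- as.integer(min_loop)
  if (min_loop < 0L) stop("min_loop must be >= 0", call. = FALSE)
  if (is.null(duplex_init)) duplex_init <- INIT_DH - TK * INIT_DS / 1000
  structure(
    list(temperature_K = TK, pair_penalty = pair_penalty, stacks = stacks,
         kT = kT, min_loop = min_loop, duplex_init = duplex_init),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model: T = %.2f K, kT = %.4f kcal/mol, pair penalty %.2f, min_loop %d>\n",
              x$temperature_K, x$kT, x$pair_penalty, x$min_loop))
  invisible(x)
}

#' Can two bases form a Watson-Crick pair?
#' @keywords internal
wc_pairable <- function(a, b) WC_PARTNER[a] == b

#' Energy of a given structure under the model
#'
#' @param chars character vector of bases.
#' @param pairs integer matrix with columns i, j (1-based, i < j), possibly
#'   zero rows.
#' @param model an \code{energy_model}.
#' @return structure free energy in model units (kcal/mol).
#' @keywords internal
structure_energy <- function(chars, pairs, model) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(0)
  e <- nrow(pairs) * model$pair_penalty
  # stack term for each pair (i,j) whose inward neighbor (i+1,j-1) is paired
  key <- paste0(pairs[, 1L], ":", pairs[, 2L])
  inward <- paste0(pairs[, 1L] + 1L, ":", pairs[, 2L] - 1L)
  stacked <- inward %in% key
  if (any(stacked)) {
    steps <- paste0(chars[pairs[stacked, 1L]], chars[pairs[stacked, 1L] + 1L])
    e <- e + sum(model$stacks[steps])
  }
  unname(e)
}

#' Standard free energy of an intermolecular Watson-Crick duplex
#'
#' Nearest-neighbor sum over the duplex stacks plus per-terminal initiation
#' penalties, for a fully complementary duplex given by its top strand.
#'
#' @param top_seq top-strand sequence 5'->3'; the bottom strand is assumed to
#'   be its full reverse complement.
#' @param model an \code{energy_model}.
#' @return duplex standard free energy (kcal/mol).
#' @export
duplex_delta_g <- function(top_seq, model = energy_model()) {
  s <- check_dna(top_seq, "duplex top strand")
  ch <- seq_chars(s)
  n <- length(ch)
  if (n < 2L) stop("duplex needs at least 2 base pairs", call. = FALSE)
  steps <- paste0(ch[-n], ch[-1L])
  dg <- sum((NN_DH - model$temperature_K * NN_DS / 1000)[steps])
  term <- ifelse(ch[c(1L, n)] %in% c("G", "C"), "GC", "AT")
  dg + sum(model$duplex_init[term])
}
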