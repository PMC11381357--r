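#' @title Sequence-structure feature construction
#' @name featurization
#' @description The 16 structural and thermodynamic variables X1-X16
#'   describing an invader strand and its toehold intermediate, the
#'   X2/X5/X11 ranking key, and the strand-design rule report.
NULL

#' Names of the 16 features, in fixed column order
#' @return character vector \code{c("X1", ..., "X16")}.
#' @export
feature_names <- function() paste0("X", 1:16)

FEATURE_LABELS <- c(
  X1 = "free bases in toehold",
  X2 = "free H-bond sites in toehold",
  X3 = "G/C count in toehold",
  X4 = "free bases in invader",
  X5 = "free H-bond sites in invader",
  X6 = "total H-bond capacity of toehold",
  X7 = "total H-bond capacity of invader",
  X8 = "free bases in branch region",
  X9 = "H-bond pairs in branch region",
  X10 = "ensemble free energy of invader",
  X11 = "ensemble H-bond count of invader",
  X12 = "bases in MFE hairpin loops",
  X13 = "pair count in MFE structure",
  X14 = "H-bonds in intermediate",
  X15 = "intermediate content",
  X16 = "intermediate duplex dG"
)

#' Hydrogen-bond capacity of a base
#'
#' The number of hydrogen bonds a base contributes in a Watson-Crick pair:
#' 2 for A/T, 3 for G/C.
#'
#' @param base character vector of bases.
#' @return integer vector of capacities.
#' @examples
#' hbond_capacity(c("A", "G"))  # 2 3
#' @export
hbond_capacity <- function(base) {
  base <- toupper(base)
  if (!all(base %in% DNA_BASES))
    stop("invalid base: ", paste(setdiff(base, DNA_BASES), collapse = ", "),
         call. = FALSE)
  unname(c(A = 2L, T = 2L, G = 3L, C = 3L)[base])
}

#' Compute the 16-variable feature vector of a displacement system
#'
#' All quantities are ensemble expectations under the invader's intramolecular
#' pair-probability matrix unless stated otherwise. Writing \eqn{p(i)} for the
#' probability that invader base i is intramolecularly paired, \eqn{h(i)} for
#' its hydrogen-bond capacity (2 for A/T, 3 for G/C) and \eqn{h_{pair}(i,j)}
#' for the bonds of pair (i,j):
#' \itemize{
#'   \item X1 free toehold bases, X2 free toehold H-bond sites, X3 toehold
#'     G/C count, X6 total toehold H-bond capacity;
#'   \item X4 free invader bases, X5 free invader H-bond sites, X7 total
#'     invader capacity, X10 ensemble free energy, X11 expected H-bond count
#'     \eqn{\sum_{i<j} p(i,j) h_{pair}(i,j)};
#'   \item X8 free branch-region bases, X9 expected pairs touching
#'     branch-region indices;
#'   \item X12 hairpin-loop bases and X13 pair count of the MFE structure;
#'   \item X14 expected interstrand toehold H-bonds, X15 intermediate
#'     concentration (M), X16 intermediate duplex standard free energy.
#' }
#' The conservation identity X5 = X7 - 2 X11 holds exactly because both sides
#' are linear in the same pair probabilities.
#'
#' @param system a \code{displacement_system}.
#' @param ppm invader \code{pair_prob_matrix} (length must equal the invader).
#' @param mfe invader MFE \code{secondary_structure}.
#' @param inter an \code{intermediate_state}.
#' @return named numeric vector of length 16 (class \code{feature_vector}).
#' @export
compute_features <- function(system, ppm, mfe, inter) {
  stopifnot(inherits(system, "displacement_system"),
            inherits(ppm, "pair_prob_matrix"),
            inherits(mfe, "secondary_structure"),
            inherits(inter, "intermediate_state"))
  ch <- seq_chars(system$invader$sequence)
  n <- length(ch)
  if (ppm$n != n) stop("pair-probability matrix length (", ppm$n,
                       ") does not match invader length (", n, ")",
                       call. = FALSE)
  if (mfe$n != n) stop("MFE structure length does not match invader", call. = FALSE)
  h <- hbond_capacity(ch)
  ti <- toehold_idx(system)
  bi <- setdiff(seq_len(n), ti)
  p_free <- ppm$p_unpaired
  # expected H-bond count over all pairs; h_pair(i,j) = h(i) = h(j) for WC
  # pairs (the symmetric mean also covers imported non-WC pairs gracefully)
  pu <- ppm$p * upper.tri(ppm$p)
  x11 <- sum(pu * (outer(h, h, "+") / 2))
  x9 <- sum(pu[bi, ]) + sum(pu[, bi]) - sum(pu[bi, bi])  # pairs touching branch, once
  fv <- c(
    X1 = sum(p_free[ti]),
    X2 = sum(h[ti] * p_free[ti]),
    X3 = sum(ch[ti] %in% c("G", "C")),
    X4 = sum(p_free),
    X5 = sum(h * p_free),
    X6 = sum(h[ti]),
    X7 = sum(h),
    X8 = sum(p_free[bi]),
    X9 = x9,
    X10 = ppm$free_energy,
    X11 = x11,
    X12 = hairpin_loop_bases(mfe),
    X13 = nrow(mfe$pairs),
    X14 = sum(h[ti] * inter$interstrand_pair_prob),
    X15 = inter$complex_conc,
    X16 = inter$delta_g
  )
  class(fv) <- c("feature_vector", class(fv))
  fv
}

#' Featurize a displacement system end-to-end
#'
#' Convenience wrapper computing the invader ensemble, MFE structure and
#' intermediate state under one model, then the feature vector.
#'
#' @param system a \code{displacement_system}.
#' @param model an \code{energy_model}.
#' @param c0 strand concentration (M) for the intermediate state.
#' @param ppm optional externally supplied \code{pair_prob_matrix} (e.g. from
#'   \code{\link{read_pair_probabilities}}) used in place of the built-in
#'   engine.
#' @return a \code{feature_vector}.
#' @export
featurize_system <- function(system, model = energy_model(), c0 = 5e-8,
                             ppm = NULL) {
  if (is.null(ppm)) {
    ppm <- partition_pair_probabilities(system$invader$sequence, model)
  } else if (is.na(ppm$free_energy)) {
    # imported matrices carry no ensemble energy; fall back to the builtin engine's
    builtin <- partition_pair_probabilities(system$invader$sequence, model)
    ppm$free_energy <- builtin$free_energy
  }
  mfe <- mfe_structure(system$invader$sequence, model)
  inter <- intermediate_state(system, model, c0 = c0, ppm = ppm)
  compute_features(system, ppm, mfe, inter)
}

#' Featurize a list of systems into a data frame
#'
#' @param systems list of \code{displacement_system}.
#' @param model an \code{energy_model}.
#' @param c0 strand concentration (M).
#' @return data.frame with columns \code{sample_id}, \code{X1} ... \code{X16}.
#' @export
featurize_systems <- function(systems, model = energy_model(), c0 = 5e-8) {
  stopifnot(length(systems) > 0L)
  mat <- t(vapply(systems, featurize_system, numeric(16L),
                  model = model, c0 = c0))
  df <- data.frame(sample_id = vapply(systems, function(s) s$id, character(1L)),
                   mat, stringsAsFactors = FALSE)
  names(df)[-1L] <- feature_names()
  df
}

#' Rank systems by the X2/X5/X11 key
#'
#' Scores each feature vector as z(X2) + z(X5) - z(X11), where z() is
#' standardization within the supplied set (a zero-variance feature
#' contributes 0), and orders descending: high free H-bond site counts in the
#' toehold (X2) and whole invader (X5) and a low intramolecular H-bond count
#' (X11) predict fast displacement. Ties keep input order and are flagged.
#'
#' @param features data.frame containing columns X2, X5, X11 and optionally
#'   \code{sample_id}, or a matrix with those columns.
#' @return data.frame ordered fastest-first with columns \code{sample_id},
#'   \code{score}, \code{rank}, \code{tied}.
#' @export
rank_by_key <- function(features) {
  features <- as.data.frame(features)
  if (nrow(features) == 0L) stop("empty feature set", call. = FALSE)
  need <- c("X2", "X5", "X11")
  if (!all(need %in% names(features)))
    stop("features must contain columns X2, X5, X11", call. = FALSE)
  zcol <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  score <- zcol(features$X2) + zcol(features$X5) - zcol(features$X11)
  id <- if ("sample_id" %in% names(features)) features$sample_id
        else as.character(seq_len(nrow(features)))
  ord <- order(-score)  # stable: ties keep input order
  out <- data.frame(sample_id = id[ord], score = score[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  out$tied <- duplicated(out$score) | duplicated(out$score, fromLast = TRUE)
  out
}

#' Strand-design rule report
#'
#' Checks an invader design against three rules for fast simple-TMSD systems:
#' (i) use the full configured toehold length; (ii) keep the toehold G/C
#' proportion high, providing more hydrogen-bonding sites; (iii) avoid
#' intrachain base pairs that occupy toehold bases.
#'
#' @param system a \code{displacement_system}.
#' @param fv its \code{feature_vector}.
#' @param mfe optional invader MFE structure (computed if missing) used for
#'   the occlusion rule.
#' @param model energy model used when \code{mfe} is missing.
#' @param max_toehold configured maximum useful toehold length (default 6).
#' @param min_gc_frac minimum toehold G/C proportion (default 0.5).
#' @param max_occluded maximum tolerated MFE-paired toehold bases (default 2).
#' @return list of class \code{design_rule_report} with per-rule \code{pass}
#'   flags and explanations.
#' @export
design_rule_report <- function(system, fv, mfe = NULL, model = energy_model(),
                               max_toehold = 6L, min_gc_frac = 0.5,
                               max_occluded = 2L) {
  stopifnot(inherits(system, "displacement_system"))
  if (is.null(mfe)) mfe <- mfe_structure(system$invader$sequence, model)
  ti <- toehold_idx(system)
  occluded <- sum(ti %in% c(mfe$pairs[, 1L], mfe$pairs[, 2L]))
  gc_frac <- unname(fv["X3"]) / system$toehold_len
  rules <- list(
    toehold_length = list(
      pass = system$toehold_len >= max_toehold,
      value = system$toehold_len,
      message = sprintf("toehold length %d vs configured maximum %d",
                        system$toehold_len, max_toehold)),
    gc_proportion = list(
      pass = gc_frac >= min_gc_frac,
      value = gc_frac,
      message = sprintf("toehold G/C proportion %.2f (threshold %.2f)",
                        gc_frac, min_gc_frac)),
    toehold_occlusion = list(
      pass = occluded <= max_occluded,
      value = occluded,
      message = sprintf("%d toehold base(s) paired in the MFE structure (max %d)",
                        occluded, max_occluded))
  )
  structure(list(sample_id = system$id, rules = rules,
                 all_pass = all(vapply(rules, `[[`, logical(1L), "pass"))),
            class = "design_rule_report")
}

#' @export
print.design_rule_report <- function(x, ...) {
  cat(sprintf("<design_rule_report %s: %s>\n", x$sample_id,
              if (x$all_pass) "all rules pass" else "flags raised"))
  for (nm in names(x$rules)) {
    r <- x$rules[[nm]]
    cat(sprintf("  [%s] %s: %s\n", if (r$pass) "ok" else "FLAG", nm, r$message))
  }
  invisible(x)
}
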