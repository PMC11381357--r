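#' @title Secondary-structure engine
#' @name structure_engine
#' @description Exhaustive enumeration of nested Watson-Crick structures (the
#'   testing oracle), the Boltzmann partition function with base-pair
#'   probabilities by inside-outside dynamic programming, and the
#'   minimum-free-energy (MFE) structure.
NULL

ENUM_CAP <- 22L

#' Construct a secondary structure object
#'
#' @param pairs integer matrix with columns \code{i}, \code{j} (1-based,
#'   i < j), zero rows for the open chain.
#' @param energy free energy in model units.
#' @param n sequence length.
#' @return an object of class \code{secondary_structure}.
#' @export
secondary_structure <- function(pairs, energy, n) {
  if (is.null(pairs) || length(pairs) == 0L)
    pairs <- matrix(integer(0), ncol = 2L)
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  if (nrow(pairs) > 1L) pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  structure(list(pairs = pairs, energy = energy, n = as.integer(n)),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure: %d nt, %d pairs, energy %.4f>\n%s\n",
              x$n, nrow(x$pairs), x$energy, dot_bracket(x)))
  invisible(x)
}

#' Dot-bracket representation of a secondary structure
#' @param struct a \code{secondary_structure}.
#' @return a dot-bracket string.
#' @export
dot_bracket <- function(struct) {
  db <- rep(".", struct$n)
  db[struct$pairs[, 1L]] <- "("
  db[struct$pairs[, 2L]] <- ")"
  paste(db, collapse = "")
}

#' Enumerate all nested Watson-Crick structures (testing oracle)
#'
#' Exhaustively lists every secondary structure of a short strand: Watson-Crick
#' pairs only, nested (no pseudoknots), hairpin loops of at least
#' \code{model$min_loop} unpaired bases. Intended as the brute-force oracle for
#' the dynamic-programming engine; refuses long strands.
#'
#' @param seq DNA sequence string.
#' @param model an \code{energy_model}.
#' @param cap maximum length accepted (default 22).
#' @return list of \code{secondary_structure}, energies included; the open
#'   chain is always present.
#' @export
enumerate_structures <- function(seq, model = energy_model(), cap = ENUM_CAP) {
  s <- check_dna(seq)
  ch <- seq_chars(s)
  n <- length(ch)
  if (n > cap) stop("enumeration capped at length ", cap, call. = FALSE)
  ml <- model$min_loop
  # recursive enumeration over intervals: structures(i, j) returns a list of
  # pair matrices for the subsequence [i, j]
  memo <- new.env(parent = emptyenv())
  structures <- function(i, j) {
    if (j - i < ml + 1L) return(list(matrix(integer(0), ncol = 2L)))
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- structures(i, j - 1L)  # j unpaired
    for (k in i:(j - ml - 1L)) {
      if (wc_pairable(ch[k], ch[j])) {
        left <- structures(i, k - 1L)
        inner <- structures(k + 1L, j - 1L)
        for (L in left) for (In in inner)
          out[[length(out) + 1L]] <- rbind(L, In, c(k, j))
      }
    }
    memo[[key]] <- out
    out
  }
  lapply(structures(1L, n), function(p)
    secondary_structure(p, structure_energy(ch, p, model), n))
}

# Precompute per-sequence tables shared by the DP routines: Boltzmann weight
# of each admissible pair and the stacking factor for each position.
dp_tables <- function(ch, model) {
  n <- length(ch)
  w <- matrix(0, n, n)
  pairable <- outer(ch, ch, function(a, b) WC_PARTNER[a] == b)
  wt <- exp(-model$pair_penalty / model$kT)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (j - i >= model$min_loop + 1L && pairable[i, j]) w[i, j] <- wt
  sfac <- c(exp(-model$stacks[paste0(ch[-n], ch[-1L])] / model$kT), 1)
  list(n = n, w = w, sfac = unname(sfac))
}

#' Equilibrium pair probabilities by inside-outside dynamic programming
#'
#' Computes the Boltzmann partition function over all nested Watson-Crick
#' structures of a single strand under the energy model, then base-pair
#' probabilities by propagating outside (adjoint) quantities back through the
#' same recursions. For short strands the result equals Boltzmann-weighted
#' averaging over \code{enumerate_structures} to numerical precision.
#'
#' @param seq DNA sequence string.
#' @param model an \code{energy_model}.
#' @return an object of class \code{pair_prob_matrix}: list with \code{n},
#'   symmetric matrix \code{p}, vector \code{p_unpaired}, \code{free_energy}
#'   (-kT log Z, model units) and \code{log_z}.
#' @export
partition_pair_probabilities <- function(seq, model = energy_model()) {
  s <- check_dna(seq)
  ch <- seq_chars(s)
  tb <- dp_tables(ch, model)
  n <- tb$n
  w <- tb$w
  sfac <- tb$sfac
  ml <- model$min_loop
  # inside: Q over [i,j] (empty interval = 1), Qb with (i,j) paired
  Q <- matrix(1, n, n)
  Qb <- matrix(0, n, n)
  Qget <- function(i, j) if (j < i) 1 else Q[i, j]
  for (len in seq_len(n)) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      if (w[i, j] > 0) {
        inner <- Qget(i + 1L, j - 1L)
        qb_in <- if (j - 1L > i + 1L) Qb[i + 1L, j - 1L] else 0
        Qb[i, j] <- w[i, j] * (inner + (sfac[i] - 1) * qb_in)
      }
      if (len == 1L) { Q[i, j] <- 1; next }
      acc <- Q[i, j - 1L]
      for (k in i:(j - 1L)) {
        if (Qb[k, j] == 0) next
        left <- if (k - 1L >= i) Q[i, k - 1L] else 1
        acc <- acc + left * Qb[k, j]
      }
      Q[i, j] <- acc
    }
  }
  Z <- Q[1L, n]
  # outside pass: adjoints of Q and Qb wrt Z, processed by decreasing length;
  # within a length class all Q pushes precede all Qb pushes so that adjoints
  # of equal-length Qb cells are complete before they are expanded.
  Qbar <- matrix(0, n, n)
  Qbbar <- matrix(0, n, n)
  Qbar[1L, n] <- 1
  for (len in rev(seq_len(n))) {
    starts <- seq_len(n - len + 1L)
    for (i in starts) {  # Q(i,j) pushes
      j <- i + len - 1L
      qb0 <- Qbar[i, j]
      if (qb0 == 0 || len == 1L) next
      Qbar[i, j - 1L] <- Qbar[i, j - 1L] + qb0
      for (k in i:(j - 1L)) {
        if (Qb[k, j] == 0) next
        if (k - 1L >= i) Qbar[i, k - 1L] <- Qbar[i, k - 1L] + qb0 * Qb[k, j]
        left <- if (k - 1L < i) 1 else Q[i, k - 1L]
        Qbbar[k, j] <- Qbbar[k, j] + qb0 * left
      }
    }
    for (i in starts) {  # Qb(i,j) pushes
      j <- i + len - 1L
      qbb <- Qbbar[i, j]
      if (qbb == 0 || Qb[i, j] == 0) next
      if (j - 1L >= i + 1L) {
        Qbar[i + 1L, j - 1L] <- Qbar[i + 1L, j - 1L] + qbb * w[i, j]
        if (j - 1L > i + 1L)
          Qbbar[i + 1L, j - 1L] <- Qbbar[i + 1L, j - 1L] +
            qbb * w[i, j] * (sfac[i] - 1)
      }
    }
  }
  p <- Qbbar * Qb / Z
  p <- p + t(p)
  p_unpaired <- pmin(pmax(1 - rowSums(p), 0), 1)
  structure(
    list(n = n, p = p, p_unpaired = p_unpaired,
         free_energy = -model$kT * log(Z), log_z = log(Z), sequence = s),
    class = "pair_prob_matrix"
  )
}

#' @export
print.pair_prob_matrix <- function(x, ...) {
  cat(sprintf("<pair_prob_matrix: %d nt, ensemble free energy %.4f>\n",
              x$n, x$free_energy))
  invisible(x)
}

#' Minimum-free-energy structure
#'
#' Finds the nested Watson-Crick structure of minimum free energy under the
#' energy model by dynamic programming over the same decomposition as the
#' partition function. Ties in energy are broken toward fewer pairs, then by a
#' deterministic traceback preferring 5'-most pairings (lexicographically
#' smallest pair list).
#'
#' @param seq DNA sequence string.
#' @param model an \code{energy_model}.
#' @return a \code{secondary_structure}.
#' @export
mfe_structure <- function(seq, model = energy_model()) {
  s <- check_dna(seq)
  ch <- seq_chars(s)
  n <- length(ch)
  ml <- model$min_loop
  pairable <- outer(ch, ch, function(a, b) WC_PARTNER[a] == b)
  stk <- c(unname(model$stacks[paste0(ch[-n], ch[-1L])]), 0)
  pe <- model$pair_penalty
  E <- matrix(0, n, n)     # min energy over [i,j]
  N <- matrix(0L, n, n)    # pair count of the optimum (secondary key)
  Eb <- matrix(Inf, n, n)  # min energy with (i,j) paired
  Nb <- matrix(0L, n, n)
  Eget <- function(i, j) if (j < i) 0 else E[i, j]
  Nget <- function(i, j) if (j < i) 0L else N[i, j]
  better <- function(e1, n1, e2, n2) {
    e1 < e2 - 1e-12 || (abs(e1 - e2) <= 1e-12 && n1 < n2)
  }
  for (len in seq_len(n)) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      if (len >= ml + 2L && pairable[i, j]) {
        # interior: general structure, or stacked on an inner (i+1,j-1) pair;
        # stack energies are <= 0 so the stacked branch dominates whenever the
        # general optimum itself pairs the inner ends
        e1 <- Eget(i + 1L, j - 1L); n1 <- Nget(i + 1L, j - 1L)
        eb <- pe + e1; nb <- n1 + 1L
        if (j - 1L > i + 1L && is.finite(Eb[i + 1L, j - 1L])) {
          e2 <- pe + stk[i] + Eb[i + 1L, j - 1L]; n2 <- Nb[i + 1L, j - 1L] + 1L
          if (better(e2, n2, eb, nb)) { eb <- e2; nb <- n2 }
        }
        Eb[i, j] <- eb; Nb[i, j] <- nb
      }
      if (len == 1L) next
      e <- E[i, j - 1L]; nn <- N[i, j - 1L]
      for (k in i:(j - 1L)) {
        if (!is.finite(Eb[k, j])) next
        ek <- Eget(i, k - 1L) + Eb[k, j]
        nk <- Nget(i, k - 1L) + Nb[k, j]
        if (better(ek, nk, e, nn)) { e <- ek; nn <- nk }
      }
      E[i, j] <- e; N[i, j] <- nn
    }
  }
  # traceback; candidate order (k ascending before "j unpaired") prefers
  # 5'-shifted pairings among exact ties
  pairs <- matrix(integer(0), ncol = 2L)
  trace_b <- function(i, j) {
    pairs <<- rbind(pairs, c(i, j))
    if (j - 1L < i + 1L) return(invisible())
    use_stack <- j - 1L > i + 1L && is.finite(Eb[i + 1L, j - 1L]) &&
      abs(Eb[i, j] - (pe + stk[i] + Eb[i + 1L, j - 1L])) <= 1e-12 &&
      Nb[i, j] == Nb[i + 1L, j - 1L] + 1L
    if (use_stack) trace_b(i + 1L, j - 1L) else trace(i + 1L, j - 1L)
  }
  trace <- function(i, j) {
    if (j <= i) return(invisible())
    for (k in i:(j - 1L)) {
      if (!is.finite(Eb[k, j])) next
      if (abs(E[i, j] - (Eget(i, k - 1L) + Eb[k, j])) <= 1e-12 &&
          N[i, j] == Nget(i, k - 1L) + Nb[k, j]) {
        trace(i, k - 1L)
        trace_b(k, j)
        return(invisible())
      }
    }
    trace(i, j - 1L)  # j unpaired
  }
  trace(1L, n)
  secondary_structure(pairs, if (n > 1L) E[1L, n] else 0, n)
}

#' Count the unpaired bases inside the hairpin loops of a structure
#'
#' A hairpin is a pair with no other pair nested inside it; all enclosed bases
#' are unpaired and counted.
#'
#' @param struct a \code{secondary_structure}.
#' @return total hairpin-loop base count.
#' @export
hairpin_loop_bases <- function(struct) {
  p <- struct$pairs
  if (nrow(p) == 0L) return(0L)
  total <- 0L
  for (r in seq_len(nrow(p))) {
    i <- p[r, 1L]; j <- p[r, 2L]
    inside <- p[, 1L] > i & p[, 2L] < j
    if (!any(inside)) total <- total + (j - i - 1L)
  }
  total
}
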