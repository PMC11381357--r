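#' @title Pair-probability file adapter
#' @name ppairs
#' @description Read and write the plain-text pair-probability format emitted
#'   by nucleic-acid thermodynamics tools ("ppairs"): a header line with the
#'   strand length n, then whitespace-separated records \code{i j p} with
#'   1-based indices; rows with \code{j = n + 1} carry the unpaired
#'   probability of base i.
NULL

#' Read a ppairs-style pair-probability file
#'
#' @param file path to a ppairs text file.
#' @param tol tolerance on row sums exceeding 1.
#' @return a \code{pair_prob_matrix}. Unpaired probabilities are taken from
#'   the \code{j = n + 1} rows when present, otherwise derived as
#'   \code{1 - rowSums(p)}.
#' @export
read_pair_probabilities <- function(file, tol = 1e-6) {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "%") & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty ppairs file: ", file, call. = FALSE)
  n <- suppressWarnings(as.integer(lines[[1L]]))
  if (is.na(n) || n <= 0L)
    stop("ppairs header must be the strand length, got: ", lines[[1L]],
         call. = FALSE)
  p <- matrix(0, n, n)
  p_unpaired <- rep(NA_real_, n)
  for (ln in lines[-1L]) {
    f <- strsplit(ln, "\\s+")[[1L]]
    if (length(f) != 3L) stop("malformed ppairs line: ", ln, call. = FALSE)
    i <- suppressWarnings(as.integer(f[[1L]]))
    j <- suppressWarnings(as.integer(f[[2L]]))
    pr <- suppressWarnings(as.numeric(f[[3L]]))
    if (anyNA(c(i, j, pr))) stop("malformed ppairs line: ", ln, call. = FALSE)
    if (pr < 0 || pr > 1)
      stop("probability outside [0, 1] in line: ", ln, call. = FALSE)
    if (i < 1L || i > n || j < 1L || j > n + 1L || i == j)
      stop("index out of range in line: ", ln, call. = FALSE)
    if (j == n + 1L) {
      p_unpaired[i] <- pr
    } else {
      p[i, j] <- pr
      p[j, i] <- pr
    }
  }
  rs <- rowSums(p)
  if (any(rs > 1 + tol))
    stop("pair probabilities of base ", which.max(rs), " sum to ",
         format(max(rs)), " > 1", call. = FALSE)
  derived <- pmin(pmax(1 - rs, 0), 1)
  if (anyNA(p_unpaired)) {
    p_unpaired[is.na(p_unpaired)] <- derived[is.na(p_unpaired)]
  } else if (any(abs(p_unpaired - derived) > 1e-3)) {
    warning("unpaired rows inconsistent with 1 - rowSums(p); keeping file values")
  }
  structure(list(n = n, p = p, p_unpaired = p_unpaired,
                 free_energy = NA_real_, log_z = NA_real_, sequence = NA_character_),
            class = "pair_prob_matrix")
}

#' Write a pair-probability matrix in ppairs format
#'
#' @param ppm a \code{pair_prob_matrix}.
#' @param file output path.
#' @param digits significant digits written (default 17, round-trip exact).
#' @return \code{file}, invisibly.
#' @export
write_pair_probabilities <- function(ppm, file, digits = 17L) {
  stopifnot(inherits(ppm, "pair_prob_matrix"))
  n <- ppm$n
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && ppm$p[i, j] > 0)
        writeLines(sprintf("%d %d %.*g", i, j, digits, ppm$p[i, j]), con)
    }
    writeLines(sprintf("%d %d %.*g", i, n + 1L, digits, ppm$p_unpaired[i]), con)
  }
  invisible(file)
}
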