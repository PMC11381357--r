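#' @title DNA strands and displacement systems
#' @name sequences
#' @description Constructors and validators for the strand-level objects used
#'   throughout the package: single DNA strands and three-strand
#'   toehold-mediated strand displacement (TMSD) systems.
NULL

DNA_BASES <- c("A", "C", "G", "T")
WC_PARTNER <- c(A = "T", C = "G", G = "C", T = "A")

#' Split a DNA sequence into a character vector of bases
#'
#' @param seq single character string over A/C/G/T, written 5'->3'.
#' @return character vector of single bases.
#' @keywords internal
seq_chars <- function(seq) {
  strsplit(toupper(seq), "", fixed = TRUE)[[1]]
}

#' Validate a DNA sequence
#'
#' @param seq candidate sequence string.
#' @param what label used in error messages.
#' @return the uppercased sequence, invisibly on success.
#' @keywords internal
check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop(what, " must be a single non-empty character string", call. = FALSE)
  s <- toupper(seq)
  bad <- setdiff(unique(seq_chars(s)), DNA_BASES)
  if (length(bad) > 0L)
    stop(what, " contains invalid bases: ", paste(bad, collapse = ", "),
         call. = FALSE)
  s
}

#' Reverse complement of a DNA sequence
#'
#' Standard Watson-Crick reverse complement (A<->T, G<->C), input and output
#' both written 5'->3'.
#'
#' @param seq a DNA sequence string over A/C/G/T.
#' @return the reverse-complement sequence string.
#' @examples
#' reverse_complement("ACGT")  # "ACGT" (palindrome)
#' reverse_complement("AAAA")  # "TTTT"
#' @export
reverse_complement <- function(seq) {
  s <- check_dna(seq)
  paste(rev(seq_chars(chartr("ACGT", "TGCA", s))), collapse = "")
}

#' Complement (same orientation) of a DNA sequence
#' @param seq a DNA sequence string.
#' @return base-wise Watson-Crick complement, not reversed.
#' @keywords internal
complement <- function(seq) {
  chartr("ACGT", "TGCA", check_dna(seq))
}

#' Construct a DNA strand
#'
#' @param id strand identifier.
#' @param sequence sequence string 5'->3' over A/C/G/T.
#' @param role one of "invader", "substrate", "incumbent".
#' @return an object of class \code{dna_strand}.
#' @export
dna_strand <- function(id, sequence, role = c("invader", "substrate", "incumbent")) {
  role <- match.arg(role)
  structure(
    list(id = as.character(id), sequence = check_dna(sequence, paste0("strand ", id)),
         role = role),
    class = "dna_strand"
  )
}

#' @export
print.dna_strand <- function(x, ...) {
  cat(sprintf("<dna_strand %s [%s], %d nt> %s\n", x$id, x$role,
              nchar(x$sequence), x$sequence))
  invisible(x)
}

#' Construct a three-strand TMSD displacement system
#'
#' A displacement system is defined by the 5'->3' invader sequence and the
#' toehold length. The substrate is the full reverse complement of the invader,
#' so its 3' end carries a single-stranded overhang (the toehold) complementary
#' to the invader's 5'-terminal \code{toehold_len} bases. The incumbent is
#' complementary to the branch-migration region only (the invader minus its
#' toehold), so the substrate:incumbent duplex leaves the toehold exposed.
#'
#' @param invader invader sequence (default geometry: 22 nt), 5'->3'.
#' @param toehold_len number of 5'-terminal invader bases forming the toehold
#'   (default 6).
#' @param id system identifier.
#' @param substrate,incumbent optional explicit sequences; when given they are
#'   validated against the invader-derived expectations.
#' @return an object of class \code{displacement_system} with elements
#'   \code{invader}, \code{substrate}, \code{incumbent} (each a
#'   \code{dna_strand}), \code{toehold_len} and \code{branch_len}.
#' @examples
#' sys <- displacement_system("GCGATTCATTCAATACCCTACG")
#' sys$incumbent$sequence
#' @export
displacement_system <- function(invader, toehold_len = 6L, id = "sys1",
                                substrate = NULL, incumbent = NULL) {
  inv <- check_dna(invader, "invader")
  toehold_len <- as.integer(toehold_len)
  if (toehold_len < 1L || toehold_len >= nchar(inv))
    stop("toehold_len must be in [1, invader length - 1]", call. = FALSE)
  branch_len <- nchar(inv) - toehold_len
  exp_sub <- reverse_complement(inv)
  branch_seq <- substr(inv, toehold_len + 1L, nchar(inv))
  # incumbent pairs the branch region: reverse complement so both strands are 5'->3'
  exp_inc <- reverse_complement(branch_seq)
  if (!is.null(substrate)) {
    substrate <- check_dna(substrate, "substrate")
    if (substrate != exp_sub) {
      bad <- which(seq_chars(substrate) != seq_chars(exp_sub))
      stop("substrate is not the reverse complement of the invader ",
           "(positions ", paste(utils::head(bad, 5L), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  if (!is.null(incumbent)) {
    incumbent <- check_dna(incumbent, "incumbent")
    if (incumbent != exp_inc) {
      bad <- which(seq_chars(incumbent) != seq_chars(exp_inc))
      stop("incumbent is not complementary to the branch-migration region ",
           "(positions ", paste(utils::head(bad, 5L), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  structure(
    list(
      id = as.character(id),
      invader = dna_strand(paste0(id, "_I"), inv, "invader"),
      substrate = dna_strand(paste0(id, "_F"), exp_sub, "substrate"),
      incumbent = dna_strand(paste0(id, "_Q"), exp_inc, "incumbent"),
      toehold_len = toehold_len,
      branch_len = branch_len
    ),
    class = "displacement_system"
  )
}

#' @export
print.displacement_system <- function(x, ...) {
  cat(sprintf("<displacement_system %s: toehold %d nt + branch %d nt>\n",
              x$id, x$toehold_len, x$branch_len))
  cat(sprintf("  invader   (I) 5'-%s-3'\n", x$invader$sequence))
  cat(sprintf("  substrate (F) 5'-%s-3'\n", x$substrate$sequence))
  cat(sprintf("  incumbent (Q) 5'-%s-3'\n", x$incumbent$sequence))
  invisible(x)
}

#' Toehold sequence of a displacement system
#' @param system a \code{displacement_system}.
#' @return the 5'-terminal toehold of the invader as a string.
#' @export
toehold_seq <- function(system) {
  stopifnot(inherits(system, "displacement_system"))
  substr(system$invader$sequence, 1L, system$toehold_len)
}

#' 0-based toehold index positions on the invader (returned 1-based for R)
#' @keywords internal
toehold_idx <- function(system) seq_len(system$toehold_len)
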