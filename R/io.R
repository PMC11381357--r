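#' @title File input/output
#' @name io
#' @description Readers and writers for the package's on-disk formats:
#'   sequence tables (CSV or FASTA triplets), kinetic trace CSVs, and feature
#'   tables.
NULL

#' Write displacement systems as CSV
#'
#' Columns: id, invader, substrate, incumbent, toehold_len.
#'
#' @param systems list of \code{displacement_system}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_sequences_csv <- function(systems, file) {
  df <- data.frame(
    id = vapply(systems, function(s) s$id, character(1L)),
    invader = vapply(systems, function(s) s$invader$sequence, character(1L)),
    substrate = vapply(systems, function(s) s$substrate$sequence, character(1L)),
    incumbent = vapply(systems, function(s) s$incumbent$sequence, character(1L)),
    toehold_len = vapply(systems, function(s) s$toehold_len, integer(1L)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write displacement systems as FASTA
#'
#' One record per strand, headers \code{<id>_I}, \code{<id>_F}, \code{<id>_Q}
#' for invader, substrate and incumbent.
#'
#' @param systems list of \code{displacement_system}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_sequences_fasta <- function(systems, file) {
  seqs <- unlist(lapply(systems, function(s)
    stats::setNames(c(s$invader$sequence, s$substrate$sequence,
                      s$incumbent$sequence),
                    c(s$invader$id, s$substrate$id, s$incumbent$id))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), file)
  invisible(file)
}

#' Load displacement systems from CSV or FASTA
#'
#' CSV files need columns id, invader, substrate, incumbent and optionally
#' toehold_len (default 6). FASTA files must contain, per system, records
#' \code{<id>_I}, \code{<id>_F} and \code{<id>_Q}. Complementarity is
#' validated per row; violations are reported with offending positions.
#'
#' @param path input file; format chosen by extension (.csv/.tsv vs
#'   .fa/.fasta).
#' @param toehold_len toehold length used when the file does not carry one.
#' @return list of \code{displacement_system}.
#' @export
load_sequences <- function(path, toehold_len = 6L) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fa", "fasta", "fna")) {
    ss <- Biostrings::readDNAStringSet(path)
    nm <- names(ss)
    ids <- unique(sub("_[IFQ]$", "", nm))
    systems <- lapply(ids, function(id) {
      need <- paste0(id, c("_I", "_F", "_Q"))
      if (!all(need %in% nm))
        stop("FASTA lacks records ", paste(setdiff(need, nm), collapse = ", "),
             call. = FALSE)
      displacement_system(as.character(ss[[paste0(id, "_I")]]),
                          toehold_len = toehold_len, id = id,
                          substrate = as.character(ss[[paste0(id, "_F")]]),
                          incumbent = as.character(ss[[paste0(id, "_Q")]]))
    })
    return(systems)
  }
  sep <- if (ext == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("id", "invader", "substrate", "incumbent")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("sequence table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"toehold_len" %in% names(df)) df$toehold_len <- toehold_len
  errs <- character(0)
  systems <- vector("list", nrow(df))
  for (r in seq_len(nrow(df))) {
    systems[[r]] <- tryCatch(
      displacement_system(df$invader[r], toehold_len = df$toehold_len[r],
                          id = df$id[r], substrate = df$substrate[r],
                          incumbent = df$incumbent[r]),
      error = function(e) {
        errs <<- c(errs, sprintf("row %d (%s): %s", r, df$id[r],
                                 conditionMessage(e)))
        NULL
      })
  }
  if (length(errs) > 0L)
    stop("invalid sequence rows:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  systems
}

#' Write kinetic traces as a long-format CSV
#'
#' Columns: time_s, intensity, temp_C, sample_id.
#'
#' @param traces list of \code{kinetic_trace}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_traces_csv <- function(traces, file) {
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(time_s = tr$times, intensity = tr$intensities,
               temp_C = tr$temperature, sample_id = tr$sample_id,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Load kinetic traces from a long-format CSV
#'
#' Rows are grouped by (sample_id, temp_C); within each group times must be
#' unique, and are sorted ascending, so row order in the file is irrelevant.
#'
#' @param path trace CSV with columns time_s, intensity, temp_C, sample_id.
#' @return list of \code{kinetic_trace}, named \code{<sample_id>@<temp_C>},
#'   ordered by sample then temperature.
#' @export
load_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "intensity", "temp_C", "sample_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("trace table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- interaction(df$sample_id, df$temp_C, drop = TRUE, sep = "@")
  groups <- split(df, key)
  ord <- order(vapply(groups, function(g) g$sample_id[1L], character(1L)),
               vapply(groups, function(g) g$temp_C[1L], numeric(1L)))
  out <- lapply(groups[ord], function(g) {
    if (anyDuplicated(g$time_s))
      stop("duplicate time point(s) for sample ", g$sample_id[1L], " at ",
           g$temp_C[1L], " degC", call. = FALSE)
    g <- g[order(g$time_s), , drop = FALSE]
    kinetic_trace(g$time_s, g$intensity, temperature = g$temp_C[1L],
                  sample_id = g$sample_id[1L])
  })
  names(out) <- names(groups)[ord]
  out
}
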