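# Sequence records, FASTA I/O and the pre-clustering filters.

# 20 standard residues plus the ambiguity letters X/B/Z and selenocysteine U.
AA_ALLOWED <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V", "X", "B", "Z", "U")

#' Construct a table of protein sequence records
#'
#' A set of sequences is represented as a plain `data.frame` with one row per
#' record and columns `seq_id`, `accession`, `annotation` and `residues`.
#' `seq_id` is an opaque stable identifier used throughout the clustering
#' pipeline; it defaults to the accession.
#'
#' @param accession Character vector of accessions (e.g. `"XP_452906.1"`).
#' @param residues Character vector of uppercase amino-acid strings. The 20
#'   standard letters plus `X`, `B`, `Z` and `U` are allowed.
#' @param annotation Free-text annotations (the remainder of a FASTA header).
#' @param seq_id Stable identifiers; defaults to `accession`.
#' @return A `data.frame` with columns `seq_id`, `accession`, `annotation`,
#'   `residues`.
#' @examples
#' seq_records("A1", "ACDEF", annotation = "toy protein")
#' @export
seq_records <- function(accession, residues, annotation = "",
                        seq_id = accession) {
  stopifnot(length(accession) == length(residues))
  validate_residues(residues)
  data.frame(seq_id = as.character(seq_id),
             accession = as.character(accession),
             annotation = rep_len(as.character(annotation), length(accession)),
             residues = toupper(as.character(residues)),
             stringsAsFactors = FALSE)
}

validate_residues <- function(residues, where = NULL) {
  bad <- grepl(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")),
               toupper(residues))
  if (any(bad)) {
    stop("illegal residue character in sequence",
         if (!is.null(where)) sprintf(" (line %d)", where[which(bad)[1]]),
         call. = FALSE)
  }
  if (any(!nzchar(residues))) {
    stop("empty sequence", call. = FALSE)
  }
  invisible(TRUE)
}

#' Parse FASTA text into sequence records
#'
#' Headers have the form `>accession annotation...`: the accession is the
#' first whitespace-delimited token after `>`, the annotation is the
#' remainder of the header line. Malformed input (text before the first
#' header, an entry with no sequence body, or an illegal residue letter)
#' raises an error naming the offending line.
#'
#' @param text A character scalar of FASTA text, or a character vector of
#'   lines.
#' @return A record `data.frame` (see [seq_records()]); empty input gives a
#'   zero-row table.
#' @seealso [read_fasta()] to read from a file, [write_fasta()].
#' @export
parse_fasta <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(seq_records(character(), character()))
  }
  is_hdr <- startsWith(trimws(lines), ">")
  if (!is_hdr[nonblank[1]]) {
    stop(sprintf("malformed FASTA: expected '>' header at line %d",
                 nonblank[1]), call. = FALSE)
  }
  hdr_idx <- which(is_hdr)
  acc <- character(length(hdr_idx))
  ann <- character(length(hdr_idx))
  seqs <- character(length(hdr_idx))
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (h in seq_along(hdr_idx)) {
    header <- sub("^>", "", trimws(lines[hdr_idx[h]]))
    if (!nzchar(header)) {
      stop(sprintf("malformed FASTA: empty header at line %d", hdr_idx[h]),
           call. = FALSE)
    }
    acc[h] <- sub("\\s.*$", "", header)
    ann[h] <- trimws(sub("^\\S+", "", header))
    body_lines <- lines[seq2(hdr_idx[h] + 1L, bounds[h + 1L] - 1L)]
    body_lineno <- seq2(hdr_idx[h] + 1L, bounds[h + 1L] - 1L)
    keep <- nzchar(trimws(body_lines))
    body_lines <- trimws(body_lines[keep])
    body_lineno <- body_lineno[keep]
    if (length(body_lines) == 0L) {
      stop(sprintf("malformed FASTA: entry '%s' has empty sequence body (line %d)",
                   acc[h], hdr_idx[h]), call. = FALSE)
    }
    for (k in seq_along(body_lines)) {
      validate_residues(toupper(body_lines[k]), where = body_lineno[k])
    }
    seqs[h] <- toupper(paste(body_lines, collapse = ""))
  }
  seq_records(acc, seqs, annotation = ann)
}

seq2 <- function(from, to) if (from > to) integer() else seq.int(from, to)

#' Read a FASTA file
#'
#' @param path Path to a protein multi-FASTA file.
#' @return A record `data.frame`; see [parse_fasta()] for the header
#'   conventions and error contract.
#' @export
read_fasta <- function(path) {
  parse_fasta(readLines(path, warn = FALSE))
}

#' Write sequence records as FASTA
#'
#' Writes standard FASTA with 60-column-wrapped sequence lines and headers
#' of the form `>accession annotation`. An empty record table writes
#' nothing.
#'
#' @param records A record `data.frame`.
#' @param path Output file path or connection.
#' @param width Sequence line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  out <- character(0)
  for (i in seq_len(nrow(records))) {
    hdr <- paste0(">", records$accession[i],
                  if (nzchar(records$annotation[i]))
                    paste0(" ", records$annotation[i]) else "")
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    out <- c(out, hdr, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(out, path)
  invisible(path)
}

#' Remove hypothetical proteins and duplicate sequences from a batch
#'
#' Applies the two pre-clustering filters used before batch clustering:
#' records whose annotation contains the phrase `"hypothetical protein"`
#' (case-insensitive substring match) are dropped first, then exact
#' duplicate residue strings are dropped keeping the first occurrence in
#' input order. Duplicate detection looks only at the residue string, never
#' at accession or annotation.
#'
#' @param records A record `data.frame`.
#' @return A list with elements `records` (the kept rows, input order
#'   preserved) and `report`, a `filter_report` with counts `n_input`,
#'   `n_hypothetical_removed`, `n_duplicates_removed`, `n_kept` which always
#'   satisfy `n_input = n_kept + n_hypothetical_removed +
#'   n_duplicates_removed`.
#' @examples
#' recs <- seq_records(c("A", "B", "C"), c("ACDEF", "ACDEF", "WYWYW"),
#'                     annotation = c("kinase", "kinase copy", "hypothetical protein X"))
#' filter_batch(recs)$report
#' @export
filter_batch <- function(records) {
  n_input <- nrow(records)
  hypo <- grepl("hypothetical protein", records$annotation, ignore.case = TRUE)
  kept <- records[!hypo, , drop = FALSE]
  dup <- duplicated(kept$residues)
  out <- kept[!dup, , drop = FALSE]
  rownames(out) <- NULL
  report <- structure(
    list(n_input = n_input,
         n_hypothetical_removed = sum(hypo),
         n_duplicates_removed = sum(dup),
         n_kept = nrow(out)),
    class = "filter_report")
  list(records = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d input, %d hypothetical removed, %d duplicates removed, %d kept\n",
              x$n_input, x$n_hypothetical_removed, x$n_duplicates_removed,
              x$n_kept))
  invisible(x)
}
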