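# Scoring parameters, semi-global alignment and the three alignment
# statistics attached to every evaluated sequence pair.

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format used by the NCBI `matrices`
#' distribution (comment lines starting with `#`, a header row of residue
#' letters, then one labelled row per residue).
#'
#' @param path Path to the matrix file.
#' @return An integer matrix with residue letters as dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  rn <- vapply(rows, `[`, "", 1L)
  m <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1])))
  dimnames(m) <- list(rn, hdr)
  if (!identical(rownames(m), colnames(m)) || !isSymmetric(unname(m))) {
    stop("substitution matrix must be symmetric with matching row/column labels")
  }
  m
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- read_score_matrix(
        system.file("extdata", "BLOSUM62.txt", package = "homoclust"))
    }
    cache
  }
})

#' Alignment scoring parameters
#'
#' Bundles a symmetric amino-acid substitution matrix with affine gap
#' penalties. A gap of length L costs `gap_open + L * gap_extend`; gaps at
#' either end of either sequence are free in semi-global mode.
#'
#' The default is BLOSUM62 with gap open 11 and gap extend 2. The extension
#' penalty is deliberately above the BLAST default of 1: when every
#' sequence pair is aligned (no exact-match candidate prefilter), an
#' extension cost of 1 lets unrelated sequences chain short high-scoring
#' segments with cheap long gaps into weak alignments spanning most of
#' their length, which corrupts the aligned-length statistic that the
#' similarity graph thresholds. With extension 2 such mosaic alignments
#' score below the short terminal-overlap optimum and the statistic stays
#' discriminative, while genuine homolog alignments (whose internal gaps
#' are short) are essentially unchanged. Both penalties are configurable.
#'
#' @param matrix Integer substitution matrix with residue dimnames; default
#'   is the bundled NCBI BLOSUM62.
#' @param gap_open Non-negative gap opening penalty.
#' @param gap_extend Non-negative gap extension penalty, at most `gap_open`.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(matrix = NULL, gap_open = 11L, gap_extend = 2L) {
  if (is.null(matrix)) matrix <- blosum62_matrix()
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            identical(rownames(matrix), colnames(matrix)))
  if (!isSymmetric(unname(matrix))) stop("substitution matrix must be symmetric")
  if (gap_open < 0 || gap_extend < 0 || gap_extend > gap_open) {
    stop("require 0 <= gap_extend <= gap_open")
  }
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat(sprintf("Scoring: %dx%d substitution matrix, gap open %d, gap extend %d\n",
              nrow(x$matrix), ncol(x$matrix), x$gap_open, x$gap_extend))
  invisible(x)
}

residue_indices <- function(seq, scoring) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, rownames(scoring$matrix))
  if (anyNA(idx)) {
    stop(sprintf("residue '%s' absent from the substitution matrix",
                 chars[which(is.na(idx))[1]]), call. = FALSE)
  }
  idx
}

#' Self-alignment score of a sequence
#'
#' The sum of diagonal substitution-matrix entries over the residues; the
#' denominator of the score-ratio alignment statistic.
#'
#' @param seq Residue string (non-empty).
#' @param scoring A [scoring_params()] object.
#' @return Integer score.
#' @examples
#' self_score("ACD")  # 4 + 9 + 6 = 19 under BLOSUM62
#' @export
self_score <- function(seq, scoring = scoring_params()) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("seq must be a non-empty residue string")
  }
  idx <- residue_indices(seq, scoring)
  sum(diag(scoring$matrix)[idx])
}

#' Semi-global pairwise alignment
#'
#' Optimal global alignment in which gaps at the beginning or end of either
#' sequence are free, with affine penalties for internal gaps. This mode
#' suits pairs whose lengths differ substantially or that overlap
#' end-to-start, since neither terminal overhang is penalized. The dynamic
#' program and its traceback are deterministic: ties are broken in the
#' order diagonal, then up, then left, and among equally scoring end cells
#' the one nearest the bottom-right corner wins.
#'
#' @param a,b Non-empty residue strings.
#' @param scoring A [scoring_params()] object.
#' @return An object of class `align_result`: list with `aligned_a`,
#'   `aligned_b` (gapped strings), `score`, `aligned_region_length` (number
#'   of columns between the first and last column pairing two residues,
#'   inclusive) and `n_exact_matches`.
#' @examples
#' semiglobal_align("ACDEFG", "CDEF")
#' @export
semiglobal_align <- function(a, b, scoring = scoring_params()) {
  a <- as_residue_string(a)
  b <- as_residue_string(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  res <- semiglobal_align_cpp(a, b,
                              residue_indices(a, scoring) - 1L,
                              residue_indices(b, scoring) - 1L,
                              scoring$matrix,
                              scoring$gap_open, scoring$gap_extend)
  structure(res, class = "align_result")
}

as_residue_string <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x$residues
  } else {
    as.character(x)
  }
}

#' @export
print.align_result <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score %d, aligned region %d, exact matches %d\n",
              x$score, x$aligned_region_length, x$n_exact_matches))
  invisible(x)
}

#' The three alignment statistics for a sequence pair
#'
#' From one semi-global alignment of the pair this computes
#' \describe{
#'   \item{`len_ratio`}{alignment length over the length of the longer
#'     input sequence (statistic 1, the similarity-graph edge weight);}
#'   \item{`match_ratio`}{number of exact matches over alignment length
#'     (statistic 2);}
#'   \item{`score_ratio`}{alignment score over the smaller of the two self
#'     scores (statistic 3).}
#' }
#' "Alignment length" is the number of columns between the first and last
#' column where both sequences place a residue, so terminal free-gap
#' overhangs are excluded and internal gaps are included. All three
#' statistics equal 1 for identical sequences and are invariant under
#' swapping the arguments: the pair is aligned in a canonical order
#' (longer sequence first; ties broken lexicographically) so that
#' co-optimal traceback choices cannot differ between `(a, b)` and
#' `(b, a)`.
#'
#' @param a,b Residue strings or single-row record data frames.
#' @param scoring A [scoring_params()] object.
#' @return An object of class `align_stats`: list with `len_ratio`,
#'   `match_ratio`, `score_ratio`, plus the underlying `score`.
#' @examples
#' align_stats("ACDEFG", "CDEF")  # len_ratio 4/6, match_ratio 1, score_ratio 1
#' @export
align_stats <- function(a, b, scoring = scoring_params()) {
  a <- as_residue_string(a)
  b <- as_residue_string(b)
  if (nchar(b) > nchar(a) ||
      (nchar(b) == nchar(a) && a != b &&
       sort(c(a, b), method = "radix")[1] == b)) {
    tmp <- a; a <- b; b <- tmp
  }
  aln <- semiglobal_align(a, b, scoring)
  len_ratio <- aln$aligned_region_length / max(nchar(a), nchar(b))
  match_ratio <- if (aln$aligned_region_length > 0) {
    aln$n_exact_matches / aln$aligned_region_length
  } else 0
  score_ratio <- aln$score / min(self_score(a, scoring), self_score(b, scoring))
  structure(list(len_ratio = len_ratio, match_ratio = match_ratio,
                 score_ratio = score_ratio, score = aln$score),
            class = "align_stats")
}

#' @export
print.align_stats <- function(x, ...) {
  cat(sprintf("len_ratio %.4f, match_ratio %.4f, score_ratio %.4f (score %d)\n",
              x$len_ratio, x$match_ratio, x$score_ratio, x$score))
  invisible(x)
}
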