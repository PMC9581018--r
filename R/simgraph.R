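# Similarity graph: vertices are sequences, edges connect pairs whose
# alignment-length ratio (statistic 1) exceeds the threshold.

#' Build the sequence similarity graph
#'
#' Evaluates [align_stats()] for every candidate unordered pair of records
#' and keeps an edge exactly when `len_ratio` is strictly greater than
#' `threshold` (default 0.80). The kept edge's weight is `len_ratio`; the
#' other two statistics are carried along on the edge table for inspection
#' but play no role downstream.
#'
#' By default only candidate pairs are aligned: two sequences are a
#' candidate pair when they share at least one exact k-mer (`prefilter_k =
#' 6`), the word-based candidate generation that graph-building alignment
#' engines use at scale. Without it, score-optimal semi-global alignment
#' occasionally produces long, barely positive alignments between entirely
#' unrelated sequences, whose aligned-length ratio then exceeds the
#' threshold and attaches spurious edges. Homologous pairs at any
#' plausible identity level share many exact 6-mers, so the rule costs no
#' genuine edges in practice; pairs where either sequence is shorter than
#' 30 residues are always aligned, and `prefilter_k = 0` disables the rule
#' entirely (literal all-pairs evaluation).
#'
#' @param records Filtered record `data.frame` (unique residue strings, no
#'   hypothetical proteins); at least one row.
#' @param scoring A [scoring_params()] object.
#' @param threshold Edge threshold in (0, 1); pairs must exceed it strictly.
#' @param prefilter_k Exact shared-word length for candidate generation;
#'   0 disables.
#' @return An object of class `sim_graph`: list with `ids` (vertex order =
#'   input order), `edges` (data frame `from`, `to`, `weight`,
#'   `match_ratio`, `score_ratio`, with `from`/`to` seq_ids and
#'   `from` < `to` in vertex order) and `threshold`.
#' @examples
#' recs <- seq_records(c("a", "b", "c"),
#'                     c("MKTAYIAKQR", "MKTAYIAKQA", "WWPHGGHHEE"))
#' build_graph(recs, threshold = 0.8)
#' @export
build_graph <- function(records, scoring = scoring_params(), threshold = 0.8,
                        prefilter_k = 6L) {
  if (nrow(records) < 1L) stop("need at least one record")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (anyDuplicated(records$seq_id)) stop("seq_ids must be unique")
  n <- nrow(records)
  from <- character(0); to <- character(0)
  w <- numeric(0); mr <- numeric(0); sr <- numeric(0)
  kmer_sets <- NULL
  if (prefilter_k > 0L && n >= 2L) {
    kmer_sets <- lapply(records$residues, function(s) {
      if (nchar(s) < 30L || nchar(s) < prefilter_k) return(NULL)
      unique(substring(s, seq_len(nchar(s) - prefilter_k + 1L),
                       seq_len(nchar(s) - prefilter_k + 1L) + prefilter_k - 1L))
    })
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (!is.null(kmer_sets) && !is.null(kmer_sets[[i]]) &&
            !is.null(kmer_sets[[j]]) &&
            !any(kmer_sets[[i]] %in% kmer_sets[[j]])) next
        st <- align_stats(records$residues[i], records$residues[j], scoring)
        if (st$len_ratio > threshold) {
          from <- c(from, records$seq_id[i])
          to <- c(to, records$seq_id[j])
          w <- c(w, st$len_ratio)
          mr <- c(mr, st$match_ratio)
          sr <- c(sr, st$score_ratio)
        }
      }
    }
  }
  structure(list(ids = records$seq_id,
                 edges = data.frame(from = from, to = to, weight = w,
                                    match_ratio = mr, score_ratio = sr,
                                    stringsAsFactors = FALSE),
                 threshold = threshold),
            class = "sim_graph")
}

#' Construct a similarity graph from an explicit edge list
#'
#' Mostly useful for tests and worked examples where edge weights are given
#' directly rather than computed from alignments.
#'
#' @param ids Ordered vertex identifiers.
#' @param edges Data frame with columns `from`, `to`, `weight` (ids).
#' @param threshold Threshold recorded on the graph.
#' @return A `sim_graph` object.
#' @export
sim_graph <- function(ids, edges = NULL, threshold = 0.8) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("vertex ids must be unique")
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!all(c(edges$from, edges$to) %in% ids)) stop("edge endpoint not in ids")
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  structure(list(ids = ids, edges = edges, threshold = threshold),
            class = "sim_graph")
}

#' @export
print.sim_graph <- function(x, ...) {
  cat(sprintf("Similarity graph: %d vertices, %d edges (threshold %.2f)\n",
              length(x$ids), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Convert a similarity graph (or SSN) to an igraph object
#'
#' @param x A `sim_graph` or `ssn` object.
#' @return An undirected weighted [igraph::graph] object.
#' @export
as_igraph <- function(x) UseMethod("as_igraph")

#' @export
as_igraph.sim_graph <- function(x) {
  g <- igraph::make_empty_graph(n = length(x$ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = x$ids)
  if (nrow(x$edges) > 0) {
    g <- igraph::add_edges(g, rbind(x$edges$from, x$edges$to),
                           weight = x$edges$weight)
  }
  g
}

#' Export a weighted edge list as TSV
#'
#' Writes three tab-separated columns `id_a`, `id_b`, `weight`.
#'
#' @param x A `sim_graph` or `ssn` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  edges <- x$edges
  weight_col <- if ("weight" %in% names(edges)) "weight" else "distance"
  out <- data.frame(id_a = edges$from, id_b = edges$to,
                    weight = edges[[weight_col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a graph in GraphML format
#'
#' @param x A `sim_graph` or `ssn` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(x, path) {
  igraph::write_graph(as_igraph(x), path, format = "graphml")
  invisible(path)
}
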