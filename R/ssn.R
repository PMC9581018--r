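# k-mer distances, distance matrices, and sequence similarity networks.

kmer_counts <- function(seq, k) {
  n <- nchar(seq)
  kmers <- substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  table(kmers)
}

#' k-mer distance between two unaligned sequences
#'
#' The fraction of k-length substrings the two sequences share, subtracted
#' from one: with \eqn{c_x(w)} the count of k-mer \eqn{w} in sequence
#' \eqn{x}, \deqn{d = 1 - \frac{\sum_w \min(c_a(w), c_b(w))}{\min(|a|,|b|) - k + 1}.}
#' The result lies in [0, 1]: 0 is a perfect match (identical sequences
#' give 0), 1 means no shared k-mers. This is the alignment-free distance
#' family used to build guide distance matrices from unaligned sequences.
#'
#' @param a,b Residue strings of length at least `k`.
#' @param k k-mer length (default 3).
#' @return The distance.
#' @examples
#' kmer_distance("AAAA", "AAAC", k = 2)  # 1/3
#' @export
kmer_distance <- function(a, b, k = 3L) {
  a <- as_residue_string(a); b <- as_residue_string(b)
  if (nchar(a) < k || nchar(b) < k) {
    stop(sprintf("sequences must be at least k = %d residues long", k))
  }
  ca <- kmer_counts(a, k); cb <- kmer_counts(b, k)
  shared <- intersect(names(ca), names(cb))
  f <- sum(pmin(ca[shared], cb[shared])) / (min(nchar(a), nchar(b)) - k + 1L)
  1 - f
}

#' Pairwise k-mer distance matrix
#'
#' @param records Record `data.frame` with at least two rows, all
#'   sequences of length at least `k`.
#' @param k k-mer length.
#' @return A symmetric numeric matrix with zero diagonal, dimnames =
#'   seq_ids.
#' @export
distance_matrix <- function(records, k = 3L) {
  if (nrow(records) < 2L) stop("need at least two records")
  n <- nrow(records)
  d <- matrix(0, n, n, dimnames = list(records$seq_id, records$seq_id))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- kmer_distance(records$residues[i],
                                          records$residues[j], k)
    }
  }
  d
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param path Output path.
#' @param digits Decimal places (default 6, the conventional display).
#' @return `path`, invisibly.
#' @export
write_phylip <- function(d, path, digits = 6L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(formatC(d[i, ], format = "f", digits = digits),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Build a sequence similarity network
#'
#' A fully connected weighted graph over the query plus at least two
#' selected sequences (typically chosen from a best-matching cluster's
#' FASTA headers), with k-mer distances as edge weights. The best match is
#' the non-query node at minimum distance from the query; 0 means the
#' sequences are identical. Validation flags on the selected records (a
#' `validated` column, if present) are carried onto the nodes. Node order
#' is deterministic: the query first, then the selection in input order.
#'
#' @param query A single-row record `data.frame` or residue string.
#' @param selected Record `data.frame` with at least two rows.
#' @param k k-mer length.
#' @return An object of class `ssn`: list with `nodes` (data frame
#'   `seq_id`, `accession`, `annotation`, `validated`, `is_query`),
#'   `edges` (data frame `from`, `to`, `distance`, all unordered pairs)
#'   and `best_match` (list `node_id`, `distance`).
#' @export
build_ssn <- function(query, selected, k = 3L) {
  if (nrow(selected) < 2L) stop("select at least two sequences for an SSN")
  if (!is.data.frame(query)) {
    query <- seq_records("query", as.character(query), annotation = "query sequence")
  }
  stopifnot(nrow(query) == 1L)
  validated <- if ("validated" %in% names(selected)) selected$validated else 0L
  validated <- rep_len(as.integer(validated), nrow(selected))
  nodes <- data.frame(seq_id = c(query$seq_id, selected$seq_id),
                      accession = c(query$accession, selected$accession),
                      annotation = c(query$annotation, selected$annotation),
                      validated = c(0L, as.integer(validated)),
                      is_query = c(TRUE, rep(FALSE, nrow(selected))),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$seq_id)) stop("duplicate seq_ids in SSN nodes")
  recs <- rbind(query[, c("seq_id", "accession", "annotation", "residues")],
                selected[, c("seq_id", "accession", "annotation", "residues")])
  d <- distance_matrix(recs, k)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  edges <- data.frame(from = rownames(d)[pairs[, 1]],
                      to = colnames(d)[pairs[, 2]],
                      distance = d[pairs],
                      stringsAsFactors = FALSE)
  qd <- d[1, -1]
  best <- which.min(qd)  # first minimum: selection input order breaks ties
  structure(list(nodes = nodes, edges = edges,
                 best_match = list(node_id = names(qd)[best],
                                   distance = unname(qd[best]))),
            class = "ssn")
}

#' @export
print.ssn <- function(x, ...) {
  cat(sprintf("SSN: %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  cat(sprintf("Best match: %s at distance %.6f%s\n", x$best_match$node_id,
              x$best_match$distance,
              if (x$best_match$distance == 0) " (identical sequences)" else ""))
  v <- x$nodes[x$nodes$validated == 1L, "seq_id"]
  if (length(v)) cat("Validated:", paste(v, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_igraph.ssn <- function(x) {
  g <- igraph::make_empty_graph(n = nrow(x$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = x$nodes$seq_id)
  g <- igraph::set_vertex_attr(g, "validated", value = x$nodes$validated)
  g <- igraph::set_vertex_attr(g, "is_query", value = x$nodes$is_query)
  if (nrow(x$edges) > 0) {
    g <- igraph::add_edges(g, rbind(x$edges$from, x$edges$to),
                           weight = x$edges$distance)
  }
  g
}
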