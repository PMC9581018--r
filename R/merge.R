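# Sub-cluster merging: resolve the final iteration's communities back
# through the trace into clusters over the original sequences.

find_provenance <- function(trace, iteration, id) {
  for (b in trace$iterations[[iteration]]) {
    p <- b$provenance[[id]]
    if (!is.null(p)) return(list(prov = p, batch = b))
  }
  NULL
}

#' Expand a sequence to the original sequences it represents
#'
#' A sequence entering iteration `iteration` stands for a set of original
#' (iteration-1 input) sequences: an original sequence stands for itself;
#' a singleton carried forward stands for whatever it stood for at the
#' iteration it came from; a sub-cluster representative stands for the
#' union of the expansions of all that sub-cluster's members. Duplicates
#' removed when batches were combined expand with the sequence that was
#' kept in their place.
#'
#' @param trace An `iteration_trace` from [run_iterations()].
#' @param iteration Iteration whose input `seq` belongs to.
#' @param seq A seq_id present at that iteration.
#' @return Character vector of original seq_ids (sorted).
#' @export
expand_member <- function(trace, iteration, seq) {
  hit <- find_provenance(trace, iteration, seq)
  if (is.null(hit)) {
    stop(sprintf("unknown sequence '%s' at iteration %d", seq, iteration))
  }
  out <- expand_via(trace, hit$prov, seq)
  # lineages of duplicates that this sequence absorbed at this iteration
  for (r in hit$batch$removed) {
    if (r$kept_by == seq) {
      out <- union(out, expand_via(trace, r$provenance, r$id))
    }
  }
  sort(out)
}

expand_via <- function(trace, prov, id) {
  switch(prov$kind,
    original = id,
    singleton = expand_member(trace, prov$iter, id),
    rep = {
      src <- trace$iterations[[prov$iter]][[prov$batch]]
      members <- src$result$subclusters[[prov$cluster]]
      out <- character(0)
      for (m in members) {
        out <- union(out, expand_member(trace, prov$iter,
                                        src$ids[m + 1L]))
      }
      out
    },
    stop("unknown provenance kind"))
}

#' Merge the iteration trace into final homologous clusters
#'
#' Starting from the final iteration's single batch, every sub-cluster is
#' expanded (the union of its members' expansions) into one homologous
#' cluster. Final-iteration singletons are expanded too: a singleton that
#' represents an earlier sub-cluster still yields a cluster — sequences
#' grouped at an earlier level stay together even if their representative
#' never clustered again — while an expansion of size one remains a
#' singleton. Clusters are indexed `0..n-1`, sub-cluster-derived clusters
#' first in final-iteration cluster order, then singleton-derived clusters.
#'
#' Together the clusters and singletons form an exact partition of the
#' sequences that entered iteration 1.
#'
#' @param trace An `iteration_trace` from [run_iterations()].
#' @return An object of class `cluster_set`: list with `clusters` (list of
#'   character vectors of original seq_ids, each of size >= 2) and
#'   `singletons` (character vector).
#' @export
merge_all <- function(trace) {
  if (is.null(trace$final_batch) ||
      is.null(trace$iterations[[length(trace$iterations)]][[trace$final_batch]])) {
    stop("incomplete trace: final iteration batch missing")
  }
  t_final <- length(trace$iterations)
  fb <- trace$iterations[[t_final]][[trace$final_batch]]
  res <- fb$result
  clusters <- list()
  singletons <- character(0)
  for (c in seq_along(res$subclusters)) {
    members <- res$subclusters[[c]]
    out <- character(0)
    for (m in members) {
      out <- union(out, expand_member(trace, t_final, res$ids[m + 1L]))
    }
    clusters[[length(clusters) + 1L]] <- sort(out)
  }
  for (s in res$singletons) {
    out <- expand_member(trace, t_final, res$ids[s + 1L])
    if (length(out) >= 2L) {
      clusters[[length(clusters) + 1L]] <- sort(out)
    } else {
      singletons <- c(singletons, out)
    }
  }
  cluster_set(clusters, singletons)
}

#' A small worked example of an iteration trace
#'
#' Eleven single-sequence batches (the first holding two sequences) run
#' through four iterations: batch outputs are grouped 1-2-3 / 4-5-6-7 /
#' 8-9-10-11 in iteration 2, the first two groups combine in iteration 3
#' while the third carries forward, and everything meets in one final
#' batch. Sequence `b1_s1` represents its iteration-1 sub-cluster
#' throughout; merging the trace yields a single homologous cluster of
#' seven sequences plus the five iteration-1 singletons that never
#' clustered.
#'
#' @return An `iteration_trace` suitable for [merge_all()] and
#'   [expand_member()].
#' @examples
#' merge_all(example_trace())
#' @export
example_trace <- function() {
  sing <- function(iter, batch) list(kind = "singleton", iter = iter,
                                     batch = batch)
  rep_ <- function(iter, batch, cluster) list(kind = "rep", iter = iter,
                                              batch = batch,
                                              cluster = cluster)
  orig <- list(kind = "original")
  iter1 <- list()
  iter1[["1"]] <- list(ids = c("b1_s1", "b1_s2"),
                       provenance = list(b1_s1 = orig, b1_s2 = orig),
                       result = batch_result(list(c(0L, 1L)), integer(),
                                             c("b1_s1", "b1_s2")))
  for (k in 2:11) {
    id <- sprintf("b%d_S1", k)
    if (k == 7) id <- "b7_s1"
    b <- list(ids = id, provenance = setNames(list(orig), id),
              result = batch_result(list(), 0L, id))
    iter1[[as.character(k)]] <- b
  }
  iter2 <- list(
    "1-2-3" = list(
      ids = c("b1_s1", "b2_S1", "b3_S1"),
      provenance = list(b1_s1 = rep_(1L, "1", 1L),
                        b2_S1 = sing(1L, "2"), b3_S1 = sing(1L, "3")),
      result = batch_result(list(c(0L, 1L)), 2L,
                            c("b1_s1", "b2_S1", "b3_S1"))),
    "4-5-6-7" = list(
      ids = c("b4_S1", "b5_S1", "b6_S1", "b7_s1"),
      provenance = list(b4_S1 = sing(1L, "4"), b5_S1 = sing(1L, "5"),
                        b6_S1 = sing(1L, "6"), b7_s1 = sing(1L, "7")),
      result = batch_result(list(c(0L, 3L)), c(1L, 2L),
                            c("b4_S1", "b5_S1", "b6_S1", "b7_s1"))),
    "8-9-10-11" = list(
      ids = c("b8_S1", "b9_S1", "b10_S1", "b11_S1"),
      provenance = list(b8_S1 = sing(1L, "8"), b9_S1 = sing(1L, "9"),
                        b10_S1 = sing(1L, "10"), b11_S1 = sing(1L, "11")),
      result = batch_result(list(c(0L, 1L)), c(2L, 3L),
                            c("b8_S1", "b9_S1", "b10_S1", "b11_S1"))))
  iter3 <- list(
    "1-2-3-4-5-6-7" = list(
      ids = c("b1_s1", "b3_S1", "b4_S1", "b5_S1", "b6_S1"),
      provenance = list(b1_s1 = rep_(2L, "1-2-3", 1L),
                        b3_S1 = sing(2L, "1-2-3"),
                        b4_S1 = rep_(2L, "4-5-6-7", 1L),
                        b5_S1 = sing(2L, "4-5-6-7"),
                        b6_S1 = sing(2L, "4-5-6-7")),
      result = batch_result(list(c(0L, 2L)), c(1L, 3L, 4L),
                            c("b1_s1", "b3_S1", "b4_S1", "b5_S1", "b6_S1"))))
  final_ids <- c("b1_s1", "b3_S1", "b5_S1", "b6_S1", "b8_S1", "b10_S1",
                 "b11_S1")
  iter4 <- list(
    "1-2-3-4-5-6-7-8-9-10-11" = list(
      ids = final_ids,
      provenance = list(b1_s1 = rep_(3L, "1-2-3-4-5-6-7", 1L),
                        b3_S1 = sing(3L, "1-2-3-4-5-6-7"),
                        b5_S1 = sing(3L, "1-2-3-4-5-6-7"),
                        b6_S1 = sing(3L, "1-2-3-4-5-6-7"),
                        b8_S1 = rep_(2L, "8-9-10-11", 1L),
                        b10_S1 = sing(2L, "8-9-10-11"),
                        b11_S1 = sing(2L, "8-9-10-11")),
      result = batch_result(list(c(0L, 4L)), c(1L, 2L, 3L, 5L, 6L),
                            final_ids)))
  iteration_trace(list(iter1, iter2, iter3, iter4),
                  original_ids = c("b1_s1", "b1_s2", "b2_S1", "b3_S1",
                                   "b4_S1", "b5_S1", "b6_S1", "b7_s1",
                                   "b8_S1", "b9_S1", "b10_S1", "b11_S1"),
                  final_batch = "1-2-3-4-5-6-7-8-9-10-11")
}

#' Construct a cluster set
#'
#' @param clusters List of character vectors of member seq_ids (each of
#'   size at least 2, mutually disjoint).
#' @param singletons Character vector of seq_ids in no cluster.
#' @return An object of class `cluster_set`.
#' @export
cluster_set <- function(clusters = list(), singletons = character()) {
  clusters <- lapply(clusters, as.character)
  singletons <- as.character(singletons)
  sizes <- lengths(clusters)
  if (any(sizes < 2L)) stop("every cluster must have at least 2 members")
  all <- c(unlist(clusters), singletons)
  if (anyDuplicated(all)) {
    stop("clusters and singletons must be disjoint")
  }
  structure(list(clusters = clusters, singletons = singletons),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("Cluster set: %d clusters (%d sequences), %d singletons\n",
              length(x$clusters), sum(sizes), length(x$singletons)))
  if (length(sizes)) {
    cat(sprintf("  cluster sizes: min %d, median %s, max %d\n",
                min(sizes), format(stats::median(sizes)), max(sizes)))
  }
  invisible(x)
}

#' Write a cluster set as JSON lines
#'
#' One record per cluster: `{"cluster_id": i, "member_ids": [...]}`;
#' singletons follow with `cluster_id` null.
#'
#' @param x A `cluster_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x$clusters)) {
    writeLines(jsonlite::toJSON(list(cluster_id = i - 1L,
                                     member_ids = x$clusters[[i]]),
                                auto_unbox = TRUE), con)
  }
  for (s in x$singletons) {
    writeLines(jsonlite::toJSON(list(cluster_id = NULL, member_ids = list(s)),
                                auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Read a cluster set from JSON lines
#'
#' @param path Path written by [write_clusters()].
#' @return A `cluster_set`.
#' @export
read_clusters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  clusters <- list()
  singletons <- character()
  for (l in lines) {
    rec <- jsonlite::fromJSON(l)
    if (is.null(rec$cluster_id)) {
      singletons <- c(singletons, unlist(rec$member_ids))
    } else {
      clusters[[rec$cluster_id + 1L]] <- unlist(rec$member_ids)
    }
  }
  cluster_set(clusters, singletons)
}
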