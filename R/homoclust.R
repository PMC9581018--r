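# Top-level interface: one call running the whole pipeline and returning a
# classed fit, in the style of the base clustering functions.

#' Cluster protein sequences into homologous families
#'
#' Runs the full pipeline: each input batch is filtered (hypothetical
#' proteins and exact duplicate sequences removed), clustered through the
#' iterative batch scheme — similarity graph from semi-global alignment
#' statistics, Louvain community detection, representatives carried into
#' the next iteration — and the resulting trace is merged back into final
#' homologous clusters and singletons.
#'
#' @param x A record `data.frame` (one batch), a list of record data
#'   frames (pre-split batches), or a path to a FASTA file.
#' @param batches When `x` is a single table/file, split it into this many
#'   consecutive batches of near-equal size (default 1).
#' @param schedule An [iteration_schedule()], or `NULL` for the default
#'   (all batch outputs combined into one final batch).
#' @param scoring A [scoring_params()] object.
#' @param threshold Similarity-graph edge threshold (default 0.8: an edge
#'   requires the aligned region to cover more than 80% of the longer
#'   sequence).
#' @param dedup Deduplicate exact residue strings when batches are
#'   combined between iterations (default TRUE).
#' @return An object of class `homoclust`: list with `clusters` (the final
#'   `cluster_set`), `members` (per-sequence membership table with
#'   `seq_id`, `accession`, `annotation`, `cluster_id`, `validated`),
#'   `trace` (the `iteration_trace`), `filter_reports`, `n_input`,
#'   `threshold` and `call`. Methods: `print`, `summary`, `predict` (best
#'   match of new query sequences against the fitted clusters), `plot`
#'   (cluster size distribution).
#' @examples
#' ds <- make_dataset(n_families = 3, family = family_spec(n_members = 3,
#'   seed_length = 60, rng_seed = 7), n_decoys = 1, rng_seed = 7)
#' fit <- homoclust(ds$records, batches = 2)
#' fit
#' summary(fit)
#' @export
homoclust <- function(x, batches = 1L, schedule = NULL,
                      scoring = scoring_params(), threshold = 0.8,
                      dedup = TRUE) {
  cl <- match.call()
  batch_list <- if (is.character(x) && length(x) == 1L) {
    split_batches(read_fasta(x), batches)
  } else if (is.data.frame(x)) {
    split_batches(x, batches)
  } else if (is.list(x)) {
    x
  } else {
    stop("x must be a record data.frame, a list of them, or a FASTA path")
  }
  n_input <- sum(vapply(batch_list, nrow, 1L))
  filtered <- lapply(batch_list, filter_batch)
  reports <- lapply(filtered, `[[`, "report")
  kept <- lapply(filtered, `[[`, "records")
  kept <- kept[vapply(kept, nrow, 1L) > 0L]
  if (length(kept) == 0L) stop("no sequences left after filtering")
  trace <- run_iterations(kept, schedule = schedule, scoring = scoring,
                          threshold = threshold, dedup = dedup)
  clusters <- merge_all(trace)
  records <- do.call(rbind, kept)
  rownames(records) <- NULL
  members <- membership_table(clusters, records)
  structure(list(clusters = clusters, members = members, trace = trace,
                 records = records, filter_reports = reports,
                 n_input = n_input, threshold = threshold,
                 scoring = scoring, call = cl),
            class = "homoclust")
}

split_batches <- function(records, batches) {
  batches <- as.integer(batches)
  stopifnot(batches >= 1L)
  if (batches == 1L) return(list(records))
  idx <- sort(rep_len(seq_len(batches), nrow(records)))
  lapply(split(seq_len(nrow(records)), idx), function(i) {
    out <- records[i, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

membership_table <- function(clusters, records) {
  ids <- c(unlist(clusters$clusters), clusters$singletons)
  cluster_id <- rep(NA_integer_, length(ids))
  off <- 0L
  for (i in seq_along(clusters$clusters)) {
    n <- length(clusters$clusters[[i]])
    cluster_id[off + seq_len(n)] <- i - 1L
    off <- off + n
  }
  rows <- match(ids, records$seq_id)
  data.frame(member_id = seq_along(ids), seq_id = ids,
             accession = records$accession[rows],
             annotation = records$annotation[rows],
             cluster_id = cluster_id, validated = 0L,
             stringsAsFactors = FALSE)
}

#' @export
print.homoclust <- function(x, ...) {
  sizes <- lengths(x$clusters$clusters)
  cat("Homologous clustering\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("%d input sequences, %d after filtering; threshold %.2f\n",
              x$n_input, nrow(x$members), x$threshold))
  cat(sprintf("%d homologous clusters (%d sequences), %d singletons\n",
              length(sizes), sum(sizes), length(x$clusters$singletons)))
  invisible(x)
}

#' @export
summary.homoclust <- function(object, ...) {
  sizes <- lengths(object$clusters$clusters)
  structure(list(n_input = object$n_input,
                 n_filtered = nrow(object$members),
                 n_clusters = length(sizes),
                 n_singletons = length(object$clusters$singletons),
                 sizes = sizes,
                 n_iterations = length(object$trace$iterations),
                 threshold = object$threshold),
            class = "summary.homoclust")
}

#' @export
print.summary.homoclust <- function(x, ...) {
  cat(sprintf("Homologous clustering: %d clusters, %d singletons over %d sequences (%d before filtering)\n",
              x$n_clusters, x$n_singletons, x$n_filtered, x$n_input))
  cat(sprintf("Iterations: %d; edge threshold: %.2f\n", x$n_iterations,
              x$threshold))
  if (length(x$sizes)) {
    cat("Cluster sizes:\n")
    print(summary(x$sizes))
  }
  invisible(x)
}

#' Query new sequences against a fitted clustering
#'
#' For each query record, finds the best-matching stored sequence by
#' semi-global alignment score and reports its cluster (see
#' [best_match()]).
#'
#' @param object A `homoclust` fit.
#' @param newdata A record `data.frame` of query sequences (or a residue
#'   string).
#' @param scoring Scoring parameters; defaults to those of the fit.
#' @param min_len_ratio Match floor passed to [best_match()].
#' @param ... Unused.
#' @return A list of `cluster_hit` objects (or `NULL` for unsuccessful
#'   queries), one per query row.
#' @export
predict.homoclust <- function(object, newdata, scoring = object$scoring,
                              min_len_ratio = 0.5, ...) {
  if (!is.data.frame(newdata)) {
    newdata <- seq_records("query", as.character(newdata))
  }
  db <- structure(list(path = NULL, members = object$members,
                       records = object$records[
                         match(object$members$seq_id,
                               object$records$seq_id), , drop = FALSE]),
                  class = "cluster_db")
  lapply(seq_len(nrow(newdata)), function(i) {
    best_match(db, newdata[i, , drop = FALSE], scoring, min_len_ratio)
  })
}

#' Plot the cluster size distribution of a fit
#'
#' @param x A `homoclust` fit.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the size table plotted.
#' @export
plot.homoclust <- function(x, ...) {
  sizes <- lengths(x$clusters$clusters)
  tab <- table(factor(c(sizes, rep(1L, length(x$clusters$singletons))),
                      levels = seq_len(max(c(sizes, 1L)))))
  graphics::barplot(tab, xlab = "cluster size (1 = singleton)",
                    ylab = "count", ...)
  invisible(tab)
}
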