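# Iterative batch clustering: label grammar, per-batch clustering,
# representative selection and the multi-iteration driver.

#' Batch letter codes
#'
#' Batches are designated by uppercase letters in input order: `A` ... `Z`
#' for the first 26, then base-26 letter strings (`AA`, `AB`, ...) beyond.
#' Sequences within a batch use the lowercase equivalent.
#'
#' @param batch_index 0-based batch index (vectorized).
#' @return Character vector of letter codes.
#' @examples
#' batch_letters(c(0, 10, 26))  # "A" "K" "AA"
#' @export
batch_letters <- function(batch_index) {
  vapply(as.integer(batch_index), function(i) {
    stopifnot(i >= 0)
    s <- ""
    repeat {
      s <- paste0(LETTERS[i %% 26L + 1L], s)
      i <- i %/% 26L - 1L
      if (i < 0) break
    }
    s
  }, "")
}

letters_to_index <- function(code) {
  chars <- strsplit(code, "", fixed = TRUE)[[1]]
  idx <- match(chars, LETTERS)
  if (anyNA(idx)) stop(sprintf("invalid batch letters '%s'", code))
  as.integer(sum(idx * 26^rev(seq_along(idx) - 1)) - 1)
}

#' Render / parse sub-cluster membership labels
#'
#' The label grammar identifies sequences within an iteration's batches.
#' A member of a sub-cluster is written `<BATCH>_<cluster>#<batch>_<seq>`,
#' e.g. `A_11#a_15`: the sequence with within-batch index 15 of batch 0
#' sits in that batch's sub-cluster 11 (all indices 0-based). A singleton
#' is written `S<batch>_<seq>#<batch>_<seq>`, e.g. `Sa_1#a_1`: the sequence
#' with index 1 of batch 0 clustered with no other sequence. Uppercase
#' letters name the batch; the lowercase equivalent prefixes sequence
#' indices. `parse_label()` is the exact inverse of `render_label()`.
#'
#' @param label A list with fields `kind` (`"member"` or `"singleton"`),
#'   `batch_index`, `seq_index`, and for members `cluster_index` (all
#'   0-based), as returned by `parse_label()`.
#' @param text A label string.
#' @return `render_label()`: the label string. `parse_label()`: the label
#'   list.
#' @examples
#' render_label(list(kind = "member", batch_index = 0,
#'                   cluster_index = 11, seq_index = 15))  # "A_11#a_15"
#' parse_label("Sa_1#a_1")
#' @export
render_label <- function(label) {
  stopifnot(label$kind %in% c("member", "singleton"),
            label$batch_index >= 0, label$seq_index >= 0)
  up <- batch_letters(label$batch_index)
  low <- tolower(up)
  if (label$kind == "member") {
    stopifnot(label$cluster_index >= 0)
    sprintf("%s_%d#%s_%d", up, label$cluster_index, low, label$seq_index)
  } else {
    sprintf("S%s_%d#%s_%d", low, label$seq_index, low, label$seq_index)
  }
}

#' @rdname render_label
#' @export
parse_label <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^([A-Z]+)_([0-9]+)#([a-z]+)_([0-9]+)$", text))[[1]]
  if (length(m)) {
    if (tolower(m[2]) != m[4]) stop(sprintf("malformed label '%s': batch letters disagree", text))
    return(list(kind = "member", batch_index = letters_to_index(m[2]),
                cluster_index = as.integer(m[3]), seq_index = as.integer(m[5])))
  }
  m <- regmatches(text, regexec("^S([a-z]+)_([0-9]+)#([a-z]+)_([0-9]+)$", text))[[1]]
  if (length(m)) {
    if (m[2] != m[4] || m[3] != m[5]) {
      stop(sprintf("malformed singleton label '%s'", text))
    }
    return(list(kind = "singleton",
                batch_index = letters_to_index(toupper(m[2])),
                seq_index = as.integer(m[3])))
  }
  stop(sprintf("malformed label '%s'", text))
}

#' Cluster one batch of sequences
#'
#' Builds the similarity graph over the batch and runs [louvain()].
#' Communities with at least two members become sub-clusters, ordered by
#' community index with members ordered by within-batch sequence index;
#' single-vertex communities become singletons.
#'
#' @param records Filtered record `data.frame` (the batch); non-empty.
#' @param scoring A [scoring_params()] object.
#' @param threshold Similarity-graph edge threshold.
#' @return An object of class `batch_result`: list with `subclusters`
#'   (list of integer vectors of 0-based within-batch sequence indices),
#'   `singletons` (integer vector of indices) and `ids` (the batch's
#'   seq_ids in input order). Every input sequence appears exactly once.
#' @export
cluster_batch <- function(records, scoring = scoring_params(),
                          threshold = 0.8) {
  if (nrow(records) == 0L) stop("empty batch")
  graph <- build_graph(records, scoring, threshold)
  part <- louvain(graph)
  batch_result_from_partition(part, records$seq_id)
}

#' Construct a batch clustering result
#'
#' Mostly useful for encoding traces by hand (worked examples, tests);
#' [cluster_batch()] produces these from data.
#'
#' @param subclusters List of integer vectors of 0-based within-batch
#'   sequence indices, each of length at least 2.
#' @param singletons Integer vector of 0-based indices.
#' @param ids The batch's seq_ids in input order.
#' @return A `batch_result`; sub-clusters and singletons must exactly
#'   partition the indices `0 .. length(ids)-1`.
#' @export
batch_result <- function(subclusters, singletons, ids) {
  subclusters <- lapply(subclusters, function(m) sort(as.integer(m)))
  singletons <- sort(as.integer(singletons))
  ids <- as.character(ids)
  if (any(lengths(subclusters) < 2L)) {
    stop("every sub-cluster needs at least 2 members")
  }
  covered <- c(unlist(subclusters), singletons)
  if (length(covered) != length(ids) ||
      !setequal(covered, seq_along(ids) - 1L) || anyDuplicated(covered)) {
    stop("sub-clusters and singletons must exactly partition the batch")
  }
  structure(list(subclusters = subclusters, singletons = singletons,
                 ids = ids),
            class = "batch_result")
}

#' Assemble an iteration trace by hand
#'
#' Builds the trace object that [run_iterations()] produces, from
#' explicitly given per-iteration batches; useful for encoding worked
#' examples and for testing [merge_all()] independently of the clustering
#' itself.
#'
#' @param iterations A list (one element per iteration) of named lists of
#'   batches. Each batch is a list with `name`, `ids` (input seq_ids),
#'   `provenance` (named list, one entry per id: `list(kind =
#'   "original")`, `list(kind = "singleton", iter =, batch =)` or
#'   `list(kind = "rep", iter =, batch =, cluster =)` with `cluster`
#'   1-based), `result` (a [batch_result()]) and optionally `removed`.
#' @param original_ids All seq_ids that entered iteration 1.
#' @param final_batch Name of the single final-iteration batch.
#' @return An `iteration_trace`.
#' @export
iteration_trace <- function(iterations, original_ids, final_batch) {
  for (t in seq_along(iterations)) {
    for (b in names(iterations[[t]])) {
      entry <- iterations[[t]][[b]]
      stopifnot(!is.null(entry$ids), !is.null(entry$provenance),
                inherits(entry$result, "batch_result"))
      if (!setequal(names(entry$provenance), entry$ids)) {
        stop(sprintf("provenance of batch '%s' must cover exactly its ids", b))
      }
      if (is.null(entry$removed)) iterations[[t]][[b]]$removed <- list()
      iterations[[t]][[b]]$name <- b
    }
  }
  last <- iterations[[length(iterations)]]
  if (is.null(last[[final_batch]])) {
    stop("final_batch must name a batch of the last iteration")
  }
  structure(list(iterations = iterations,
                 original_ids = as.character(original_ids),
                 final_batch = final_batch),
            class = "iteration_trace")
}

batch_result_from_partition <- function(part, ids) {
  mem <- unname(part$membership)
  subclusters <- list()
  singletons <- integer()
  for (c in sort(unique(mem))) {
    members <- which(mem == c) - 1L  # 0-based within-batch indices
    if (length(members) >= 2L) {
      subclusters[[length(subclusters) + 1L]] <- sort(members)
    } else {
      singletons <- c(singletons, members)
    }
  }
  structure(list(subclusters = subclusters,
                 singletons = sort(singletons),
                 ids = ids),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("Batch result: %d sequences, %d sub-clusters, %d singletons\n",
              length(x$ids), length(x$subclusters), length(x$singletons)))
  invisible(x)
}

#' Representative sequences of a batch result
#'
#' For each sub-cluster, the member with the smallest within-batch
#' sequence index (the "first sequence") represents the whole sub-cluster
#' in the next iteration; this makes the later sequence-to-cluster mapping
#' fast. Output is ordered by sub-cluster index.
#'
#' @param result A `batch_result`.
#' @param records The batch's record `data.frame` (same order as when
#'   clustered).
#' @return A record `data.frame` with one row per sub-cluster.
#' @export
representatives <- function(result, records) {
  idx <- vapply(result$subclusters, function(m) min(m) + 1L, 1L)
  out <- records[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define an iteration schedule
#'
#' An iteration schedule describes how batch outputs are regrouped between
#' clustering iterations. Iteration 1 always clusters each input batch
#' separately. Each later iteration is a list of groups; a group is a
#' character vector of batch names from the pool of not-yet-consumed batch
#' outputs, and the group's outputs are combined into one new batch named
#' by joining the component names with `-`. Outputs not consumed by any
#' group carry forward unchanged to later iterations. The last iteration
#' must leave exactly one batch, consuming everything outstanding.
#'
#' The production schedule in this lineage (11 initial batches, then
#' groups 1-2-3 / 4-5-6-7 / 8-9-10-11, then combining the first two while
#' the third carries forward, then one final batch) is expressed as
#' `iteration_schedule(list(c("1","2","3"), c("4","5","6","7"),
#' c("8","9","10","11")), list(c("1-2-3", "4-5-6-7")),
#' list(c("1-2-3-4-5-6-7", "8-9-10-11")))`.
#'
#' @param ... One list per iteration after the first; each a list of
#'   character vectors of batch names.
#' @return An object of class `iteration_schedule`.
#' @seealso [read_schedule()] to load a schedule from YAML or JSON.
#' @export
iteration_schedule <- function(...) {
  iters <- lapply(list(...), function(groups) {
    lapply(groups, as.character)
  })
  structure(list(iterations = iters), class = "iteration_schedule")
}

#' Read an iteration schedule from a YAML or JSON file
#'
#' The file holds a top-level key `iterations`: a list of iterations, each
#' a list of groups, each a list of batch names. See
#' [iteration_schedule()] for the grouping semantics.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` schedule file.
#' @return An `iteration_schedule` object.
#' @export
read_schedule <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$iterations)) stop("schedule file must define 'iterations'")
  do.call(iteration_schedule, lapply(cfg$iterations, function(groups) {
    lapply(groups, function(g) as.character(unlist(g)))
  }))
}

group_name <- function(parts) paste(parts, collapse = "-")

#' Run the full iterative clustering scheme
#'
#' Iteration 1 clusters each input batch independently. For each later
#' iteration, the outputs of the scheduled previous batches — the first
#' sequence of every sub-cluster as its representative, plus all
#' singletons — are concatenated into new batches, optionally deduplicated
#' (exact residue-string duplicates, first occurrence kept; removals are
#' recorded and the removed sequence's lineage follows the kept copy at
#' merge time), and clustered again. Batches not consumed by the
#' iteration's groups carry forward. The final iteration clusters a single
#' batch. The returned trace records, for every sequence entering an
#' iteration, exactly one provenance: either the representative of an
#' earlier sub-cluster or an earlier singleton.
#'
#' @param batches A list of filtered record `data.frame`s (the iteration-1
#'   batches), optionally named; unnamed batches are named `"1"`, `"2"`,
#'   ...
#' @param schedule An [iteration_schedule()]; `NULL` (the default) builds
#'   the trivial schedule that combines all batch outputs into one final
#'   batch (or, for a single input batch, stops after iteration 1).
#' @param scoring A [scoring_params()] object.
#' @param threshold Similarity-graph edge threshold.
#' @param dedup Remove exact duplicate residue strings when batches are
#'   combined (default TRUE).
#' @return An object of class `iteration_trace`; see [merge_all()] for the
#'   back-mapping that turns it into final homologous clusters.
#' @export
run_iterations <- function(batches, schedule = NULL,
                           scoring = scoring_params(), threshold = 0.8,
                           dedup = TRUE) {
  stopifnot(is.list(batches), length(batches) >= 1L)
  nm <- names(batches)
  if (is.null(nm)) nm <- as.character(seq_along(batches))
  all_ids <- unlist(lapply(batches, function(b) b$seq_id), use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("seq_ids must be unique across batches")
  if (is.null(schedule)) {
    schedule <- if (length(batches) == 1L) {
      iteration_schedule()
    } else {
      iteration_schedule(list(nm))
    }
  }

  record_of <- do.call(rbind, batches)
  rownames(record_of) <- NULL

  # iteration 1: cluster every input batch
  iter1 <- list()
  for (b in seq_along(batches)) {
    recs <- batches[[b]]
    prov <- setNames(rep(list(list(kind = "original")), nrow(recs)),
                     recs$seq_id)
    iter1[[nm[b]]] <- list(name = nm[b], ids = recs$seq_id,
                           provenance = prov, removed = list(),
                           result = cluster_batch(recs, scoring, threshold))
  }
  iterations <- list(iter1)

  # outstanding outputs: batch name -> list(iter, ids, provenance for next use)
  pool <- list()
  for (b in names(iter1)) pool[[b]] <- batch_output(iterations, 1L, b)

  for (t in seq_along(schedule$iterations)) {
    groups <- schedule$iterations[[t]]
    iter_t <- list()
    for (g in groups) {
      missing <- setdiff(g, names(pool))
      if (length(missing)) {
        stop(sprintf("schedule consumes unknown batch '%s'", missing[1]))
      }
      newname <- group_name(g)
      ids <- character(); prov <- list()
      for (src in g) {
        ids <- c(ids, pool[[src]]$ids)
        prov <- c(prov, pool[[src]]$provenance)
        pool[[src]] <- NULL
      }
      removed <- list()
      if (dedup) {
        res <- record_of$residues[match(ids, record_of$seq_id)]
        dup <- duplicated(res)
        if (any(dup)) {
          kept_of <- ids[match(res[dup], res)]
          for (d in seq_along(which(dup))) {
            rid <- ids[which(dup)[d]]
            removed[[length(removed) + 1L]] <-
              list(id = rid, kept_by = kept_of[d], provenance = prov[[rid]])
          }
          prov <- prov[ids[!dup]]
          ids <- ids[!dup]
        }
      }
      recs <- record_of[match(ids, record_of$seq_id), , drop = FALSE]
      rownames(recs) <- NULL
      iter_t[[newname]] <- list(name = newname, ids = ids, provenance = prov,
                                removed = removed,
                                result = cluster_batch(recs, scoring,
                                                       threshold))
    }
    iterations[[length(iterations) + 1L]] <- iter_t
    tt <- length(iterations)
    for (b in names(iter_t)) pool[[b]] <- batch_output(iterations, tt, b)
  }

  if (length(pool) != 1L) {
    stop(sprintf("schedule must end with exactly one batch (found %d)",
                 length(pool)))
  }
  structure(list(iterations = iterations,
                 original_ids = all_ids,
                 final_batch = names(pool)[1],
                 threshold = threshold),
            class = "iteration_trace")
}

# Outputs of a clustered batch: representatives (first member of each
# sub-cluster) then singletons, with provenance entries for the next
# iteration's input.
batch_output <- function(iterations, iter, batch) {
  entry <- iterations[[iter]][[batch]]
  res <- entry$result
  ids <- character(); prov <- list()
  for (c in seq_along(res$subclusters)) {
    rep_id <- res$ids[min(res$subclusters[[c]]) + 1L]
    ids <- c(ids, rep_id)
    prov[[rep_id]] <- list(kind = "rep", iter = iter, batch = batch,
                           cluster = c)
  }
  for (s in res$singletons) {
    sid <- res$ids[s + 1L]
    ids <- c(ids, sid)
    prov[[sid]] <- list(kind = "singleton", iter = iter, batch = batch)
  }
  list(iter = iter, ids = ids, provenance = prov[ids])
}

#' @export
print.iteration_trace <- function(x, ...) {
  cat(sprintf("Iteration trace: %d iterations over %d sequences\n",
              length(x$iterations), length(x$original_ids)))
  for (t in seq_along(x$iterations)) {
    for (b in x$iterations[[t]]) {
      cat(sprintf("  iter %d batch %-12s %6d seqs -> %d sub-clusters, %d singletons\n",
                  t, b$name, length(b$ids), length(b$result$subclusters),
                  length(b$result$singletons)))
    }
  }
  invisible(x)
}

#' Persist an iteration trace as JSON lines
#'
#' Writes one JSON object per clustered batch with the iteration number,
#' batch name, input ids, sub-cluster membership, singletons, provenance
#' and dedup removals.
#'
#' @param trace An `iteration_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_along(trace$iterations)) {
    for (b in trace$iterations[[t]]) {
      rec <- list(iteration = t, batch = b$name, ids = b$ids,
                  subclusters = b$result$subclusters,
                  singletons = b$result$singletons,
                  provenance = b$provenance,
                  removed = b$removed)
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}
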