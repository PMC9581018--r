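# Flat-file cluster membership store and best-match queries.
#
# The store is a directory holding `members.tsv` (one row per sequence:
# member_id, seq_id, accession, annotation, cluster_id, validated) and
# `sequences.fasta` with the residues. Validation flags start at 0 and are
# set to 1 once a sequence's functional annotation has experimental
# support.

#' Build and persist a cluster membership database
#'
#' @param clusters A `cluster_set` over the records' seq_ids.
#' @param records Record `data.frame` covering every cluster member and
#'   singleton.
#' @param path Directory to create/overwrite for the store.
#' @return An object of class `cluster_db`: list with `path`, `members`
#'   (the membership table) and `records`.
#' @examples
#' recs <- seq_records(c("a", "b", "c"), c("ACDEF", "ACDEY", "WWWWW"))
#' cs <- cluster_set(list(c("a", "b")), "c")
#' db <- build_db(cs, recs, tempfile())
#' db$members
#' @export
build_db <- function(clusters, records, path) {
  ids <- c(unlist(clusters$clusters), clusters$singletons)
  missing <- setdiff(ids, records$seq_id)
  if (length(missing)) {
    stop(sprintf("no record for cluster member '%s'", missing[1]))
  }
  cluster_id <- rep(NA_integer_, length(ids))
  off <- 0L
  for (i in seq_along(clusters$clusters)) {
    n <- length(clusters$clusters[[i]])
    cluster_id[off + seq_len(n)] <- i - 1L
    off <- off + n
  }
  rows <- match(ids, records$seq_id)
  members <- data.frame(member_id = seq_along(ids),
                        seq_id = ids,
                        accession = records$accession[rows],
                        annotation = records$annotation[rows],
                        cluster_id = cluster_id,
                        validated = 0L,
                        stringsAsFactors = FALSE)
  if (anyDuplicated(members$accession)) {
    stop("accessions must be unique in the membership database")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.table(members, file.path(path, "members.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(records[rows, , drop = FALSE], file.path(path, "sequences.fasta"))
  structure(list(path = path, members = members,
                 records = {
                   r <- records[rows, , drop = FALSE]; rownames(r) <- NULL; r
                 }),
            class = "cluster_db")
}

#' Load a cluster membership database
#'
#' @param path Directory written by [build_db()].
#' @return A `cluster_db` object with the same content.
#' @export
load_db <- function(path) {
  members <- read.delim(file.path(path, "members.tsv"), sep = "\t",
                        stringsAsFactors = FALSE,
                        colClasses = c(member_id = "integer",
                                       seq_id = "character",
                                       accession = "character",
                                       annotation = "character",
                                       cluster_id = "integer",
                                       validated = "integer"))
  members$annotation[is.na(members$annotation)] <- ""
  records <- read_fasta(file.path(path, "sequences.fasta"))
  records$seq_id <- members$seq_id  # FASTA headers carry accessions
  structure(list(path = path, members = members, records = records),
            class = "cluster_db")
}

#' Reconstruct the cluster set stored in a database
#'
#' @param db A `cluster_db`.
#' @return The `cluster_set` the store was built from.
#' @export
db_cluster_set <- function(db) {
  m <- db$members
  cl <- split(m$seq_id[!is.na(m$cluster_id)], m$cluster_id[!is.na(m$cluster_id)])
  cluster_set(unname(cl[order(as.integer(names(cl)))]),
              m$seq_id[is.na(m$cluster_id)])
}

#' @export
print.cluster_db <- function(x, ...) {
  ncl <- length(unique(x$members$cluster_id[!is.na(x$members$cluster_id)]))
  cat(sprintf("Cluster database at '%s': %d members, %d clusters, %d singletons, %d validated\n",
              x$path, nrow(x$members), ncl, sum(is.na(x$members$cluster_id)),
              sum(x$members$validated)))
  invisible(x)
}

#' Best-match cluster query
#'
#' Aligns the query against every stored sequence with
#' [semiglobal_align()] and ranks hits by alignment score, breaking ties
#' by higher `len_ratio` and then by accession order. If the top hit's
#' `len_ratio` reaches `min_len_ratio` the hit's whole cluster is
#' returned, with each member's FASTA header and validation flag; below
#' the floor the query is unsuccessful and `NULL` is returned.
#'
#' @param db A `cluster_db`.
#' @param query A single-row record `data.frame` or residue string.
#' @param scoring A [scoring_params()] object.
#' @param min_len_ratio Minimum `len_ratio` of the best hit for a match to
#'   count (default 0.5).
#' @return An object of class `cluster_hit` (fields `query_id`,
#'   `best_hit_accession`, `best_hit_score`, `best_hit_stats`,
#'   `cluster_id`, `cluster_headers`) or `NULL` when no hit qualifies.
#' @export
best_match <- function(db, query, scoring = scoring_params(),
                       min_len_ratio = 0.5) {
  if (nrow(db$members) == 0L) stop("empty database")
  qseq <- as_residue_string(query)
  qid <- if (is.data.frame(query)) query$seq_id else "query"
  n <- nrow(db$records)
  score <- integer(n); lr <- numeric(n)
  stats <- vector("list", n)
  for (i in seq_len(n)) {
    st <- align_stats(qseq, db$records$residues[i], scoring)
    score[i] <- st$score
    lr[i] <- st$len_ratio
    stats[[i]] <- st
  }
  ord <- order(-score, -lr, db$members$accession)
  top <- ord[1]
  if (lr[top] < min_len_ratio) return(NULL)
  cid <- db$members$cluster_id[top]
  rows <- if (is.na(cid)) top else which(db$members$cluster_id %in% cid)
  headers <- data.frame(accession = db$members$accession[rows],
                        annotation = db$members$annotation[rows],
                        validated = db$members$validated[rows],
                        stringsAsFactors = FALSE)
  structure(list(query_id = qid,
                 best_hit_accession = db$members$accession[top],
                 best_hit_score = score[top],
                 best_hit_stats = stats[[top]],
                 cluster_id = cid,
                 cluster_headers = headers),
            class = "cluster_hit")
}

#' @export
print.cluster_hit <- function(x, ...) {
  cat(sprintf("Query %s: best hit %s (score %d, len_ratio %.3f), cluster %s\n",
              x$query_id, x$best_hit_accession, x$best_hit_score,
              x$best_hit_stats$len_ratio,
              if (is.na(x$cluster_id)) "singleton" else x$cluster_id))
  for (i in seq_len(nrow(x$cluster_headers))) {
    cat(sprintf("  >%s %s%s\n", x$cluster_headers$accession[i],
                x$cluster_headers$annotation[i],
                if (x$cluster_headers$validated[i] == 1L) "  [VALIDATED]" else ""))
  }
  invisible(x)
}

#' Mark a sequence's annotation as experimentally validated
#'
#' Sets the validation flag of the given accession from 0 to 1 and
#' persists the change; calling it again is a no-op. In the production
#' setting this flag is flipped when a curated function publication is
#' found for the sequence.
#'
#' @param db A `cluster_db`.
#' @param accession An accession present in the database.
#' @return The updated `cluster_db` (reassign it: `db <-
#'   mark_validated(db, acc)`).
#' @export
mark_validated <- function(db, accession) {
  row <- which(db$members$accession == accession)
  if (length(row) != 1L) {
    stop(sprintf("unknown accession '%s'", accession))
  }
  db$members$validated[row] <- 1L
  write.table(db$members, file.path(db$path, "members.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  db
}
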