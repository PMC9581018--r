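# Independent oracles and small fixture builders used across the suite.

AA4 <- c("A", "C", "D", "E")
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_seq <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force semi-global alignment score: enumerate every monotone
# alignment (move strings over D = pair, U = consume a, L = consume b) and
# score it under the free-end-gap affine model: the first run, if it is a
# gap run, is free; the last run, if a gap run, is free; every other gap
# run of length L costs gap_open + L * gap_extend; D columns score by the
# substitution matrix. Completely independent of the dynamic program.
oracle_semiglobal_score <- function(a, b, scoring = scoring_params()) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- scoring$matrix
  go <- scoring$gap_open
  ge <- scoring$gap_extend
  best <- -Inf
  score_moves <- function(moves) {
    r <- rle(moves)
    s <- 0
    i <- 0L; j <- 0L
    for (k in seq_along(r$values)) {
      v <- r$values[k]; len <- r$lengths[k]
      if (v == "D") {
        for (t in seq_len(len)) {
          s <- s + m[A[i + t], B[j + t]]
        }
        i <- i + len; j <- j + len
      } else {
        terminal <- (k == 1L) || (k == length(r$values))
        if (!terminal) s <- s - go - len * ge
        if (v == "U") i <- i + len else j <- j + len
      }
    }
    s
  }
  rec <- function(i, j, moves) {
    if (i > length(A) && j > length(B)) {
      sc <- score_moves(moves)
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) rec(i + 1L, j + 1L, c(moves, "D"))
    if (i <= length(A)) rec(i + 1L, j, c(moves, "U"))
    if (j <= length(B)) rec(i, j + 1L, c(moves, "L"))
  }
  rec(1L, 1L, character())
  best
}

# All sequences over an alphabet up to a maximum length.
all_seqs_upto <- function(max_len, alphabet = AA4) {
  out <- character()
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

# Small unit-weight fixture graphs for community detection.
fixture_graphs <- function() {
  ug <- function(ids, from, to) {
    sim_graph(ids, data.frame(from = from, to = to, weight = 1))
  }
  list(
    two_triangles = ug(letters[1:6],
                       c("a", "a", "b", "d", "d", "e"),
                       c("b", "c", "c", "e", "f", "f")),
    path5 = ug(letters[1:5], letters[1:4], letters[2:5]),
    barbell = ug(letters[1:7],
                 c("a", "a", "b", "c", "d", "d", "e"),
                 c("b", "c", "c", "d", "e", "f", "f")),
    clique3_clique4 = ug(letters[1:7],
                         c("a", "a", "b", "d", "d", "d", "e", "e", "f"),
                         c("b", "c", "c", "e", "f", "g", "f", "g", "g")),
    star5 = ug(letters[1:5], rep("a", 4), letters[2:5])
  )
}

# Independent recursive expansion over a trace, structured differently
# from the package's implementation (iterative worklist over an explicit
# parent table instead of provenance-directed recursion).
oracle_expand <- function(trace, iteration, id) {
  # Build a table: for every (iter, id) input, the list of (iter', id')
  # pairs it directly stands for.
  children <- function(iter, id) {
    for (b in trace$iterations[[iter]]) {
      p <- b$provenance[[id]]
      if (is.null(p)) next
      kids <- list()
      if (p$kind == "original") {
        return(list())
      } else if (p$kind == "singleton") {
        kids <- list(list(iter = p$iter, id = id))
      } else {
        src <- trace$iterations[[p$iter]][[p$batch]]
        for (mm in src$result$subclusters[[p$cluster]]) {
          kids <- c(kids, list(list(iter = p$iter, id = src$ids[mm + 1L])))
        }
      }
      for (r in b$removed) {
        if (r$kept_by == id) {
          if (r$provenance$kind == "original") {
            kids <- c(kids, list(list(iter = 1L, id = r$id, leaf = TRUE)))
          } else if (r$provenance$kind == "singleton") {
            kids <- c(kids, list(list(iter = r$provenance$iter, id = r$id)))
          } else {
            src <- trace$iterations[[r$provenance$iter]][[r$provenance$batch]]
            for (mm in src$result$subclusters[[r$provenance$cluster]]) {
              kids <- c(kids, list(list(iter = r$provenance$iter,
                                        id = src$ids[mm + 1L])))
            }
          }
        }
      }
      return(kids)
    }
    stop(sprintf("oracle: unknown id %s at iteration %d", id, iteration))
  }
  seen <- character()
  work <- list(list(iter = iteration, id = id))
  leaves <- character()
  while (length(work)) {
    cur <- work[[1]]; work <- work[-1]
    key <- paste(cur$iter, cur$id)
    if (key %in% seen) next
    seen <- c(seen, key)
    kids <- if (isTRUE(cur$leaf)) list() else children(cur$iter, cur$id)
    if (length(kids) == 0L) {
      leaves <- union(leaves, cur$id)
    } else {
      work <- c(work, kids)
    }
  }
  sort(leaves)
}

# Normalize a cluster_set for comparison as sets of sets.
norm_cluster_set <- function(cs) {
  cl <- lapply(cs$clusters, sort)
  cl <- cl[order(vapply(cl, `[`, "", 1))]
  list(clusters = cl, singletons = sort(cs$singletons))
}
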