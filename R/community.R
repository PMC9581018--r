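# Weighted modularity and a deterministic sequential Louvain optimizer.

# Internal meta-graph representation used across Louvain levels:
# list(n, eu, ev, ew (inter-node edges, eu < ev, 1-based), self (per-node
# self-loop weight; a self loop of weight w contributes 2*w to the degree)).

graph_as_meta <- function(graph) {
  idx <- setNames(seq_along(graph$ids), graph$ids)
  list(n = length(graph$ids),
       eu = unname(idx[graph$edges$from]),
       ev = unname(idx[graph$edges$to]),
       ew = graph$edges$weight,
       self = numeric(length(graph$ids)))
}

meta_degrees <- function(mg) {
  k <- numeric(mg$n)
  if (length(mg$eu)) {
    for (e in seq_along(mg$eu)) {
      k[mg$eu[e]] <- k[mg$eu[e]] + mg$ew[e]
      k[mg$ev[e]] <- k[mg$ev[e]] + mg$ew[e]
    }
  }
  k + 2 * mg$self
}

#' Weighted modularity of a partition
#'
#' Computes \eqn{Q = \sum_c [w_{in}(c)/m - (d(c)/(2m))^2]} where \eqn{m} is
#' the total edge weight, \eqn{w_{in}(c)} the weight of edges inside
#' community \eqn{c} and \eqn{d(c)} the summed weighted degree of its
#' vertices: the fraction of edge weight falling within communities minus
#' the expectation under a degree-preserving random rewiring.
#'
#' @param graph A `sim_graph` with at least one edge.
#' @param membership Integer vector of 0-based community indices, one per
#'   graph vertex in vertex order (or named by vertex id).
#' @return The modularity value.
#' @examples
#' g <- sim_graph(c("a", "b"), data.frame(from = "a", to = "b", weight = 1))
#' graph_modularity(g, c(0, 1))  # -0.5
#' graph_modularity(g, c(0, 0))  #  0
#' @export
graph_modularity <- function(graph, membership) {
  membership <- align_membership(graph, membership)
  if (nrow(graph$edges) == 0L) {
    stop("modularity is undefined for an edgeless graph")
  }
  mg <- graph_as_meta(graph)
  m_tot <- sum(mg$ew)
  k <- meta_degrees(mg)
  intra <- sum(mg$ew[membership[mg$eu] == membership[mg$ev]])
  d_c <- tapply(k, membership, sum)
  intra / m_tot - sum((d_c / (2 * m_tot))^2)
}

align_membership <- function(graph, membership) {
  n <- length(graph$ids)
  if (!is.null(names(membership))) {
    if (!setequal(names(membership), graph$ids)) {
      stop("membership names do not match the graph's vertices")
    }
    membership <- membership[graph$ids]
  }
  if (length(membership) != n) {
    stop("membership must cover exactly the graph's vertices")
  }
  as.integer(membership)
}

#' Louvain community detection (sequential, deterministic)
#'
#' Two-phase Louvain modularity optimization. Phase 1 scans vertices in
#' ascending input order and moves each to the neighboring community with
#' the largest strictly positive modularity gain (ties broken by the
#' smallest community index; a vertex stays put on a tie with its current
#' community). Phase 2 aggregates communities into a meta-graph and the two
#' phases repeat. The algorithm stops when the modularity improvement of a
#' full level falls below `gain_threshold` (default `1e-6`, balancing
#' convergence speed against partition quality). The result is the
#' flattened vertex partition; modularity never decreases across levels.
#'
#' An edgeless graph yields every vertex in its own community.
#'
#' @param graph A `sim_graph`.
#' @param gain_threshold Positive per-level modularity improvement below
#'   which optimization stops.
#' @return An object of class `partition`: list with `membership` (0-based
#'   contiguous community indices named by vertex id, numbered by first
#'   occurrence in vertex order), `n_communities` and `modularity` (NA for
#'   an edgeless graph).
#' @examples
#' tri2 <- sim_graph(letters[1:6], data.frame(
#'   from = c("a", "a", "b", "d", "d", "e"),
#'   to   = c("b", "c", "c", "e", "f", "f"), weight = 1))
#' louvain(tri2)  # the two triangles, Q = 0.5
#' @export
louvain <- function(graph, gain_threshold = 1e-6) {
  stopifnot(gain_threshold > 0)
  n <- length(graph$ids)
  if (nrow(graph$edges) == 0L) {
    return(new_partition(setNames(seq_len(n) - 1L, graph$ids), NA_real_))
  }
  mg <- graph_as_meta(graph)
  vmap <- seq_len(n)  # original vertex -> current meta node
  q_prev <- graph_modularity(graph, vmap - 1L)  # singleton partition
  repeat {
    comm <- louvain_local_move(mg)
    flat <- comm[vmap]
    q_now <- graph_modularity(graph, flat - 1L)
    if (q_now < q_prev - 1e-12) {
      stop("internal error: modularity decreased across a level")
    }
    if (q_now - q_prev < gain_threshold) break
    q_prev <- q_now
    agg <- louvain_aggregate(mg, comm)
    mg <- agg$mg
    vmap <- agg$remap[flat]
    if (mg$n == 1L) break
  }
  # renumber contiguous 0-based by first occurrence in vertex order
  final <- comm[vmap]
  codes <- match(final, unique(final)) - 1L
  new_partition(setNames(codes, graph$ids),
                graph_modularity(graph, codes))
}

new_partition <- function(membership, q) {
  structure(list(membership = membership,
                 n_communities = length(unique(membership)),
                 modularity = q),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition: %d vertices in %d communities",
              length(x$membership), x$n_communities))
  if (!is.na(x$modularity)) cat(sprintf(", Q = %.6f", x$modularity))
  cat("\n")
  invisible(x)
}

# One full phase-1 local-moving pass over a meta-graph; returns the
# (non-contiguous) community index per meta node, sweeping until a full
# sweep makes no move.
louvain_local_move <- function(mg) {
  n <- mg$n
  m_tot <- sum(mg$ew) + sum(mg$self)
  # adjacency lists (inter-node edges only)
  nb <- vector("list", n)
  for (v in seq_len(n)) nb[[v]] <- list(to = integer(), w = numeric())
  if (length(mg$eu)) {
    for (e in seq_along(mg$eu)) {
      u <- mg$eu[e]; v <- mg$ev[e]; w <- mg$ew[e]
      nb[[u]]$to <- c(nb[[u]]$to, v); nb[[u]]$w <- c(nb[[u]]$w, w)
      nb[[v]]$to <- c(nb[[v]]$to, u); nb[[v]]$w <- c(nb[[v]]$w, w)
    }
  }
  k <- meta_degrees(mg)
  comm <- seq_len(n)
  sigma_tot <- k  # per community, indexed by community id = initial node
  repeat {
    moved <- FALSE
    for (v in seq_len(n)) {
      cur <- comm[v]
      # weight from v to each neighboring community
      if (length(nb[[v]]$to) == 0L) next
      ncomm <- comm[nb[[v]]$to]
      w_to <- tapply(nb[[v]]$w, ncomm, sum)
      cand <- as.integer(names(w_to))
      # remove v from its community
      sigma_tot[cur] <- sigma_tot[cur] - k[v]
      w_cur <- if (as.character(cur) %in% names(w_to)) w_to[[as.character(cur)]] else 0
      gain_stay <- w_cur / m_tot - k[v] * sigma_tot[cur] / (2 * m_tot^2)
      best_c <- cur
      best_gain <- gain_stay
      ord <- order(cand)
      for (c in cand[ord]) {
        if (c == cur) next
        g <- w_to[[as.character(c)]] / m_tot -
          k[v] * sigma_tot[c] / (2 * m_tot^2)
        if (g > best_gain + 1e-12) { best_gain <- g; best_c <- c }
      }
      sigma_tot[best_c] <- sigma_tot[best_c] + k[v]
      if (best_c != cur) { comm[v] <- best_c; moved <- TRUE }
    }
    if (!moved) break
  }
  comm
}

# Phase 2: aggregate communities into a new meta-graph. Returns the new
# graph and `remap`, mapping old meta-node community ids to new node ids.
louvain_aggregate <- function(mg, comm) {
  labels <- unique(comm[order(seq_along(comm))])  # by first occurrence
  remap_comm <- setNames(seq_along(labels), labels)
  node_of <- remap_comm[as.character(comm)]
  nn <- length(labels)
  self <- numeric(nn)
  for (v in seq_len(mg$n)) self[node_of[v]] <- self[node_of[v]] + mg$self[v]
  acc <- new.env(parent = emptyenv())
  if (length(mg$eu)) {
    for (e in seq_along(mg$eu)) {
      cu <- node_of[mg$eu[e]]; cv <- node_of[mg$ev[e]]
      if (cu == cv) {
        self[cu] <- self[cu] + mg$ew[e]
      } else {
        key <- paste(min(cu, cv), max(cu, cv))
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + mg$ew[e]
      }
    }
  }
  keys <- ls(acc)
  if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
    eu <- as.integer(parts[, 1]); ev <- as.integer(parts[, 2])
    ew <- vapply(keys, function(k) acc[[k]], 0)
    o <- order(eu, ev)
    eu <- eu[o]; ev <- ev[o]; ew <- unname(ew[o])
  } else {
    eu <- integer(); ev <- integer(); ew <- numeric()
  }
  # remap for flattening: community id (old labelling) -> new node id
  remap <- integer(max(comm))
  remap[as.integer(names(remap_comm))] <- remap_comm
  list(mg = list(n = nn, eu = eu, ev = ev, ew = ew, self = self),
       remap = remap)
}

#' Exhaustive maximum-modularity partition
#'
#' Enumerates every set partition of the vertices and returns the one with
#' maximal modularity. Only feasible for small graphs (Bell(12) is already
#' over four million); used as the optimality reference for [louvain()] on
#' fixture graphs.
#'
#' @param graph A `sim_graph` with at least one edge and at most ~10
#'   vertices.
#' @return A `partition` object with the optimal modularity.
#' @export
exhaustive_modularity <- function(graph) {
  n <- length(graph$ids)
  if (n > 12L) stop("exhaustive search is limited to small graphs")
  if (nrow(graph$edges) == 0L) stop("modularity is undefined for an edgeless graph")
  best_q <- -Inf
  best <- NULL
  codes <- integer(n)
  recurse <- function(i, k) {
    if (i > n) {
      q <- graph_modularity(graph, codes)
      if (q > best_q) { best_q <<- q; best <<- codes }
      return(invisible())
    }
    for (c in 0:k) {
      codes[i] <<- c
      recurse(i + 1L, max(k, c + 1L))
    }
  }
  recurse(1L, 0L)
  new_partition(setNames(best, graph$ids), best_q)
}

#' Write a partition as a TSV table
#'
#' @param partition A `partition` object.
#' @param path Output path; columns `seq_id`, `community`.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  write.table(data.frame(seq_id = names(partition$membership),
                         community = unname(partition$membership)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
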