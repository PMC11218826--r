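# Thresholded structure-similarity networks, weighted modularity, Louvain
# community detection and sequence-vs-structure cross-tabulation.

#' Build a thresholded similarity graph from a pairwise score list
#'
#' Keeps an undirected weighted edge for every pair with score at least `tau`
#' (the boundary is kept). Nodes appearing only in sub-threshold pairs remain
#' in the node set as isolates.
#'
#' @param scores data frame with columns `id_a`, `id_b`, `score`; scores must
#'   lie in \code{[0, 1]}; each unordered pair at most once (exact duplicates
#'   are collapsed, conflicting duplicates are an error); no self-pairs.
#' @param tau similarity threshold (default 0.5).
#' @param nodes optional character vector of additional node ids to retain.
#' @return object of class `sim_graph`: list with `nodes`, `edges` (data
#'   frame `a`, `b`, `weight`), `tau`.
#' @export
build_graph <- function(scores, tau = 0.5, nodes = NULL) {
  need <- c("id_a", "id_b", "score")
  if (!all(need %in% names(scores)))
    stop_data("scores must have columns ", paste(need, collapse = ", "))
  if (any(is.na(scores$score)) || any(scores$score < 0 | scores$score > 1))
    stop_data("scores must lie in [0, 1]")
  if (any(scores$id_a == scores$id_b))
    stop_data("self-pairs are not allowed")
  a <- pmin(scores$id_a, scores$id_b)
  b <- pmax(scores$id_a, scores$id_b)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(scores$score, key, function(s) diff(range(s)))
    if (any(agg > 1e-12))
      stop_data("duplicate pair(s) with conflicting scores")
    first <- !duplicated(key)
    a <- a[first]; b <- b[first]
    scores <- scores[first, , drop = FALSE]
  }
  all_nodes <- sort(unique(c(scores$id_a, scores$id_b, nodes)))
  keep <- scores$score >= tau
  structure(list(nodes = all_nodes,
                 edges = data.frame(a = a[keep], b = b[keep],
                                    weight = scores$score[keep],
                                    stringsAsFactors = FALSE),
                 tau = tau),
            class = "sim_graph")
}

#' @export
print.sim_graph <- function(x, ...) {
  cat(sprintf("similarity graph: %d nodes, %d edges (tau = %g)\n",
              length(x$nodes), nrow(x$edges), x$tau))
  invisible(x)
}

graph_weight_option <- function(graph, weighted) {
  e <- graph$edges
  if (!weighted && nrow(e)) e$weight <- 1
  e
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' Q = sum over communities c of (w_in_c / m - resolution * (K_c / 2m)^2),
#' with m the total edge weight, w_in_c the weight inside c and K_c the
#' summed weighted degree of c. An edgeless graph has Q = 0 by convention.
#'
#' @param graph a [build_graph()] result.
#' @param membership named vector mapping every node to a community id.
#' @param resolution resolution parameter (1 = classic modularity).
#' @param weighted use edge weights (default) or treat all edges as weight 1.
#' @return modularity Q in \code{[-0.5, 1]}.
#' @export
modularity_q <- function(graph, membership, resolution = 1.0, weighted = TRUE) {
  miss <- setdiff(graph$nodes, names(membership))
  if (length(miss))
    stop_data("partition misses node(s): ", paste(utils::head(miss, 5), collapse = ", "))
  e <- graph_weight_option(graph, weighted)
  if (!nrow(e)) return(0)
  m <- sum(e$weight)
  ca <- membership[e$a]; cb <- membership[e$b]
  w_in <- tapply(e$weight[ca == cb], ca[ca == cb], sum)
  deg <- tapply(c(e$weight, e$weight), c(e$a, e$b), sum)
  K <- tapply(unname(deg), membership[names(deg)], sum)
  q <- sum(w_in) / m - resolution * sum((K / (2 * m))^2)
  unname(q)
}

# one pass of Louvain local moving on an aggregated weighted graph;
# adj: list per node of c(neighbour -> weight); self: self-loop weight.
# Starts from comm_init (default all-singletons) and also considers moving a
# node out into a fresh singleton community (gain 0 reference), so the result
# is a node-level local optimum of modularity.
louvain_local_move <- function(n, adj, self_w, node_deg, m, order_idx,
                               resolution, comm_init = seq_len(n)) {
  comm <- match(comm_init, unique(comm_init))
  tot <- rep(0, n)                  # summed degree per community id
  for (i in seq_len(n)) tot[comm[i]] <- tot[comm[i]] + node_deg[i]
  improved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in order_idx) {
      ci <- comm[i]
      nb <- adj[[i]]
      # weight from i to each neighbouring community
      if (length(nb)) {
        ncomm <- comm[as.integer(names(nb))]
        w_to <- tapply(nb, ncomm, sum)
      } else w_to <- numeric(0)
      tot[ci] <- tot[ci] - node_deg[i]
      w_own <- if (as.character(ci) %in% names(w_to)) w_to[[as.character(ci)]] else 0
      base_gain <- w_own / m - resolution * tot[ci] * node_deg[i] / (2 * m^2)
      best_c <- ci; best_gain <- base_gain
      for (cn in names(w_to)) {
        cc <- as.integer(cn)
        if (cc == ci) next
        gain <- w_to[[cn]] / m - resolution * tot[cc] * node_deg[i] / (2 * m^2)
        if (gain > best_gain + 1e-12 ||
            (abs(gain - best_gain) <= 1e-12 && cc < best_c)) {
          best_gain <- gain; best_c <- cc
        }
      }
      if (best_gain < -1e-12 && tot[ci] > 0) {
        # splitting out into a fresh singleton beats every neighbour
        empty <- which(tot == 0)
        if (length(empty)) { best_c <- empty[1]; best_gain <- 0 }
      }
      tot[best_c] <- tot[best_c] + node_deg[i]
      if (best_c != ci) { comm[i] <- best_c; moved <- TRUE; improved_any <- TRUE }
    }
    if (!moved) break
  }
  list(comm = comm, improved = improved_any)
}

build_adj <- function(n, ea, eb, ew) {
  adj <- vector("list", n)
  for (k in seq_along(ew)) {
    adj[[ea[k]]] <- c(adj[[ea[k]]], stats::setNames(ew[k], eb[k]))
    adj[[eb[k]]] <- c(adj[[eb[k]]], stats::setNames(ew[k], ea[k]))
  }
  lapply(adj, function(v) {
    if (is.null(v)) return(numeric(0))
    tapply(v, names(v), sum)
  })
}

louvain_once <- function(graph, order_nodes, resolution, weighted,
                         shuffle = FALSE) {
  nodes <- graph$nodes
  e <- graph_weight_option(graph, weighted)
  if (!nrow(e))
    return(stats::setNames(seq_along(nodes), nodes))
  m <- sum(e$weight)

  # current aggregated graph state
  idx <- stats::setNames(seq_along(nodes), nodes)
  ea0 <- idx[e$a]; eb0 <- idx[e$b]; ew0 <- e$weight
  ea <- ea0; eb <- eb0; ew <- ew0
  n <- length(nodes)
  self_w <- rep(0, n)
  membership <- seq_len(n)          # node -> current aggregated community
  level_order <- match(order_nodes, nodes)

  repeat {
    adj <- build_adj(n, ea, eb, ew)
    node_deg <- vapply(seq_len(n), function(i) sum(adj[[i]]) + 2 * self_w[i],
                       numeric(1))
    ord <- if (!is.null(level_order)) level_order
           else if (shuffle) sample.int(n) else seq_len(n)
    res <- louvain_local_move(n, adj, self_w, node_deg, m, ord, resolution)
    if (!res$improved) break
    # aggregate: communities become nodes
    new_id <- match(res$comm, sort(unique(res$comm)))
    membership <- new_id[membership]
    n2 <- max(new_id)
    # self-loops: internal weight of each community
    self2 <- rep(0, n2)
    for (i in seq_len(n)) self2[new_id[i]] <- self2[new_id[i]] + self_w[i]
    same <- new_id[ea] == new_id[eb]
    if (any(same)) {
      add <- tapply(ew[same], new_id[ea[same]], sum)
      self2[as.integer(names(add))] <- self2[as.integer(names(add))] + add
    }
    keep <- !same
    ea2 <- new_id[ea[keep]]; eb2 <- new_id[eb[keep]]; ew2 <- ew[keep]
    if (length(ew2)) {
      key <- paste(pmin(ea2, eb2), pmax(ea2, eb2))
      agg <- tapply(ew2, key, sum)
      parts <- do.call(rbind, strsplit(names(agg), " "))
      ea <- as.integer(parts[, 1]); eb <- as.integer(parts[, 2])
      ew <- unname(agg)
    } else { ea <- integer(0); eb <- integer(0); ew <- numeric(0) }
    self_w <- self2
    n <- n2
    level_order <- NULL             # deeper levels use natural order
    if (!length(ew)) break
  }
  # refinement: node-level local moves on the original graph starting from
  # the aggregated partition, so single nodes can still leave or split out
  n0 <- length(nodes)
  adj0 <- build_adj(n0, ea0, eb0, ew0)
  deg0 <- vapply(seq_len(n0), function(i) sum(adj0[[i]]), numeric(1))
  res <- louvain_local_move(n0, adj0, rep(0, n0), deg0, m,
                            match(order_nodes, nodes), resolution,
                            comm_init = membership)
  stats::setNames(res$comm, nodes)
}

#' Louvain community detection on a similarity graph
#'
#' Two-phase Louvain modularity optimisation (local moving to a fixed point,
#' then community aggregation, repeated until no further improvement) on the
#' weighted graph. Node processing order is sorted ids for the first restart
#' and a seeded shuffle for the remaining restarts; the best-Q partition is
#' returned, so the result is deterministic for a fixed seed. Singleton
#' communities are allowed; an empty graph yields the all-singletons
#' partition with Q = 0.
#'
#' @param graph a [build_graph()] result.
#' @param seed integer seed controlling the restart shuffles.
#' @param resolution resolution parameter (default 1.0, classic modularity).
#' @param n_restarts local-optimisation restarts (default 10); the first uses
#'   sorted-id node order, the rest seeded shuffles at every level, and a
#'   node-level refinement pass follows each run.
#' @param weighted use edge weights in the objective (default TRUE).
#' @return object of class `partition`: list with `membership` (named integer
#'   vector with consecutive community ids), `Q`, `n_communities`.
#' @export
louvain <- function(graph, seed = 1L, resolution = 1.0, n_restarts = 10L,
                    weighted = TRUE) {
  nodes <- graph$nodes
  if (!length(nodes))
    return(structure(list(membership = stats::setNames(integer(0), character(0)),
                          Q = 0, n_communities = 0L), class = "partition"))
  best <- NULL; best_q <- -Inf
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    ord <- if (r == 1) sort(nodes) else sample(nodes)
    mem <- louvain_once(graph, ord, resolution, weighted, shuffle = r > 1)
    q <- modularity_q(graph, mem, resolution = resolution, weighted = weighted)
    if (q > best_q + 1e-12) { best_q <- q; best <- mem }
  }
  best <- stats::setNames(match(best, unique(best[sort(names(best))])), names(best))
  structure(list(membership = best, Q = best_q,
                 n_communities = length(unique(best))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d communities, Q = %.4f\n", x$n_communities, x$Q))
  invisible(x)
}

#' Filter communities by size
#'
#' Communities below `min_size` members are dropped from the community tally;
#' those with at least `major_min` members form the major set.
#'
#' @param partition a [louvain()] result (or any list with a `membership`
#'   named vector).
#' @param min_size minimum members for a community to be counted (default 2).
#' @param major_min minimum members for a major community (default 20).
#' @return list with `sizes` (named vector), `kept` and `major` community
#'   ids, `n_communities`, `n_major`.
#' @export
filter_communities <- function(partition, min_size = 2, major_min = 20) {
  mem <- partition$membership
  sizes <- table(mem)
  kept <- names(sizes)[sizes >= min_size]
  major <- names(sizes)[sizes >= major_min]
  list(sizes = sizes, kept = kept, major = major,
       n_communities = length(kept), n_major = length(major))
}

#' Cross-tabulate sequence groups against structure communities
#'
#' Cell (r, c) counts the members shared between sequence group r and
#' structure community c over the ids present in both assignments; ids
#' missing from either side are excluded and reported.
#'
#' @param og_assignment named vector: member id -> sequence-group id.
#' @param af_partition named vector: member id -> structure-community id.
#' @return list with `matrix` (groups x communities count matrix),
#'   `only_og`, `only_af` (ids present on one side only).
#' @export
crosstab <- function(og_assignment, af_partition) {
  common <- intersect(names(og_assignment), names(af_partition))
  only_og <- setdiff(names(og_assignment), common)
  only_af <- setdiff(names(af_partition), common)
  mat <- if (length(common)) {
    as.matrix(table(og = as.character(og_assignment[common]),
                    af = as.character(af_partition[common])))
  } else matrix(integer(0), 0, 0)
  list(matrix = mat, only_og = only_og, only_af = only_af)
}
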