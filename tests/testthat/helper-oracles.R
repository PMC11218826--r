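# Independent oracles used across the suite: brute-force enumerators and
# closed forms, kept deliberately separate from the package's own code paths.

# ---- long-branch flagging oracle -------------------------------------------
# Enumerate every branch of the tree and apply the two predicates directly:
# absolute (length >= abs) and relative (length >= rel AND >= ratio x the
# longest sister branch at the parent node).
oracle_flag_branches <- function(tree, abs_cutoff = 1.0, rel_cutoff = 0.5,
                                 rel_ratio = 10) {
  if (length(tree$tip.label) >= 3 && ape::is.rooted(tree))
    tree <- ape::unroot(tree)
  flags <- logical(nrow(tree$edge))
  for (i in seq_len(nrow(tree$edge))) {
    len <- tree$edge.length[i]
    sis <- setdiff(which(tree$edge[, 1] == tree$edge[i, 1]), i)
    sl <- if (length(sis)) max(tree$edge.length[sis]) else NA
    flags[i] <- (len >= abs_cutoff) ||
      (!is.na(sl) && len >= rel_cutoff && len >= rel_ratio * sl)
  }
  flags
}

# terminal tips flagged by the oracle
oracle_flagged_tips <- function(tree, ...) {
  if (length(tree$tip.label) >= 3 && ape::is.rooted(tree))
    tree <- ape::unroot(tree)
  flags <- oracle_flag_branches(tree, ...)
  child <- tree$edge[, 2]
  tree$tip.label[child[flags & child <= length(tree$tip.label)]]
}

random_tree <- function(n, mean_len = 0.3) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / mean_len)
  tr
}

# ---- exhaustive global alignment oracle ------------------------------------
# Enumerates ALL global alignments of two short sequences under BLOSUM62 with
# affine gaps (a gap of length L costs open + L * extend) by plain recursion.
oracle_align_score <- function(a, b, open = 11, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    # state: 0 = match, 1 = gap in b (a consumed), 2 = gap in a
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb))
      best <- max(best, S[ca[i], cb[j]] + rec(i + 1, j + 1, 0))
    if (i <= length(ca)) {
      cost <- if (state == 1) extend else open + extend
      best <- max(best, -cost + rec(i + 1, j, 1))
    }
    if (j <= length(cb)) {
      cost <- if (state == 2) extend else open + extend
      best <- max(best, -cost + rec(i, j + 1, 2))
    }
    best
  }
  rec(1, 1, 0)
}

# ---- profile-HMM path enumeration oracle -----------------------------------
# Enumerates every glocal alignment of the profile to every substring of the
# sequence; returns the max (viterbi) and log2-sum (forward) of path scores.
oracle_hmm_scores <- function(hmm, seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  M <- hmm$M
  ridx <- match(chars, AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                                        "M","N","P","Q","R","S","T","V","W","Y"))
  emis <- function(j, i) if (is.na(ridx[i])) 0 else hmm$emissions[j, ridx[i]]
  scores <- numeric(0)
  # walk(j, i, state, sc): at profile position j having consumed residue i
  walk <- function(j, i, state, sc) {
    if (j == M) { scores[[length(scores) + 1]] <<- sc; return(invisible()) }
    tj <- hmm$transitions[[j + 1]]
    # inserts at junction j (0 or more), then M/D at j+1
    advance <- function(i2, from, sc2) {
      if (i2 < L)
        walk(j + 1, i2 + 1, "M", sc2 + tj[from, "M"] + emis(j + 1, i2 + 1))
      walk(j + 1, i2, "D", sc2 + tj[from, "D"])
    }
    advance(i, state, sc)
    if (i < L) {
      sc2 <- sc + tj[state, "I"]
      i2 <- i + 1
      repeat {
        advance(i2, "I", sc2)
        if (i2 >= L) break
        sc2 <- sc2 + tj["I", "I"]
        i2 <- i2 + 1
      }
    }
  }
  t0 <- hmm$transitions[[1]]
  for (s in 0:L) {                     # flank prefix length
    if (s < L) walk(1, s + 1, "M", t0["B", "M"] + emis(1, s + 1))
    walk(1, s, "D", t0["B", "D"])
  }
  scores <- unlist(scores)
  mx <- max(scores)
  list(viterbi = mx, forward = mx + log2(sum(2 ^ (scores - mx))))
}

random_hmm <- function(M, n_train = 8, mut = 0.3) {
  cons <- paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                         "M","N","P","Q","R","S","T","V","W","Y"),
                       M, replace = TRUE), collapse = "")
  seqs <- plant_motif(stats::setNames(
    vapply(seq_len(n_train), function(i) cons, character(1)),
    paste0("s", seq_len(n_train))), cons, mut)
  # sprinkle gaps to exercise delete/insert transitions
  seqs <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[stats::runif(length(ch)) < 0.15] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  build_profile(seqs)
}

# ---- modularity / partition enumeration ------------------------------------
# All set partitions of n elements (restricted-growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(code, mx) {
    k <- length(code)
    if (k == n) { out[[length(out) + 1]] <<- code; return(invisible()) }
    for (v in seq_len(mx + 1)) rec(c(code, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

# direct double-sum modularity of a membership vector on an adjacency matrix
oracle_modularity <- function(A, comm) {
  m <- sum(A) / 2
  if (m == 0) return(0)
  k <- rowSums(A)
  B <- A - outer(k, k) / (2 * m)
  sum(B[outer(comm, comm, "==")]) / (2 * m)
}

oracle_max_modularity <- function(A) {
  n <- nrow(A)
  best <- -Inf
  for (p in all_partitions(n)) best <- max(best, oracle_modularity(A, p))
  best
}

random_graph <- function(n, p_edge = 0.4) {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  w <- stats::runif(sum(keep), 0.5, 1)
  edges <- data.frame(id_a = ids[pairs[1, keep]], id_b = ids[pairs[2, keep]],
                      score = w, stringsAsFactors = FALSE)
  list(edges = edges, ids = ids)
}

graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges))
    for (k in seq_len(nrow(graph$edges))) {
      a <- graph$edges$a[k]; b <- graph$edges$b[k]
      A[a, b] <- A[b, a] <- graph$edges$weight[k]
    }
  A
}

# ---- hypergeometric tail / BH ----------------------------------------------
oracle_hyper_upper <- function(k, K, N, n) {
  # P(X >= k) for X ~ Hypergeom(N, K, n), by direct summation
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
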