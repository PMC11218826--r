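# Iterative homolog-tree cleaning: column-occupancy filtering, distance
# trees, and long-branch removal by absolute and sister-relative cutoffs.

#' Trimming policy for long-branch cleaning
#'
#' @param abs_cutoff absolute removal cutoff in substitutions/site: any branch
#'   at least this long is flagged (default 1.0).
#' @param rel_cutoff relative-rule minimum length (default 0.5).
#' @param rel_ratio relative-rule multiplier: a branch is flagged when it is at
#'   least `rel_cutoff` long AND at least `rel_ratio` times its sister branch
#'   (default 10).
#' @param rounds maximum cleaning iterations (default 13).
#' @param occupancy_min minimum fraction of non-gap characters for an
#'   alignment column to survive filtering (default 0.10).
#' @param terminal_only_final restrict the final extra trimming pass to
#'   terminal branches (default TRUE).
#' @param internal_during_rounds apply the rules to internal branches during
#'   the cleaning rounds (default TRUE); terminal branches are always
#'   considered.
#' @return a validated list of class `trim_policy`.
#' @export
trim_policy <- function(abs_cutoff = 1.0, rel_cutoff = 0.5, rel_ratio = 10,
                        rounds = 13L, occupancy_min = 0.10,
                        terminal_only_final = TRUE,
                        internal_during_rounds = TRUE) {
  if (!(abs_cutoff > rel_cutoff && rel_cutoff > 0))
    stop_config("need abs_cutoff > rel_cutoff > 0")
  if (rel_ratio <= 1) stop_config("rel_ratio must exceed 1")
  rounds <- check_count(rounds, "rounds")
  if (!(occupancy_min > 0 && occupancy_min <= 1))
    stop_config("occupancy_min must be in (0, 1]")
  structure(list(abs_cutoff = abs_cutoff, rel_cutoff = rel_cutoff,
                 rel_ratio = rel_ratio, rounds = rounds,
                 occupancy_min = occupancy_min,
                 terminal_only_final = isTRUE(terminal_only_final),
                 internal_during_rounds = isTRUE(internal_during_rounds)),
            class = "trim_policy")
}

as_msa_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  if (!length(msa)) stop_data("empty alignment")
  if (length(unique(nchar(msa))) != 1)
    stop_data("ragged alignment: rows differ in length")
  m <- do.call(rbind, strsplit(msa, ""))
  rownames(m) <- names(msa)
  m
}

#' Filter alignment columns by occupancy
#'
#' Keeps exactly the columns whose fraction of non-gap characters is at least
#' `occupancy_min` (the boundary is kept). Row order is preserved; rows that
#' become all-gap are removed.
#'
#' @param msa named character vector of equal-length aligned sequences
#'   (gap characters `-` and `.`).
#' @param occupancy_min minimum non-gap fraction per column (default 0.10).
#' @return filtered alignment as a named character vector.
#' @export
filter_columns <- function(msa, occupancy_min = 0.10) {
  m <- as_msa_matrix(msa)
  res <- matrix(!(m %in% GAP_CHARS), nrow(m))
  keep <- colMeans(res) >= occupancy_min
  m2 <- m[, keep, drop = FALSE]
  rows <- rowSums(res[, keep, drop = FALSE]) > 0
  m2 <- m2[rows, , drop = FALSE]
  stats::setNames(apply(m2, 1, paste, collapse = ""), rownames(m2))
}

#' Uncorrected p-distances from an alignment
#'
#' Pairwise proportion of mismatching residues over columns holding a residue
#' in both sequences; pairs with no comparable column get distance 1.
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @return symmetric distance matrix with zero diagonal.
#' @export
p_distance <- function(msa) {
  m <- as_msa_matrix(msa)
  n <- nrow(m)
  res <- !(matrix(m %in% GAP_CHARS, n))
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- res[i, ] & res[j, ]
    d[i, j] <- d[j, i] <-
      if (any(both)) mean(m[i, both] != m[j, both]) else 1
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around the standard neighbor-joining algorithm; negative
#' estimated branch lengths are clamped to zero. Three-taxon matrices are
#' resolved by the closed-form star lengths.
#'
#' @param d symmetric numeric matrix with zero diagonal and at least 3 taxa,
#'   with dimnames giving taxon labels.
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop_data("need at least 3 taxa")
  if (any(abs(d - t(d)) > 1e-8)) stop_data("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop_data("distance matrix must have zero diagonal")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) == 3) {
    a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    c_ <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    nwk <- sprintf("(%s:%.12f,%s:%.12f,%s:%.12f);", labs[1], max(a, 0),
                   labs[2], max(b, 0), labs[3], max(c_, 0))
    return(ape::read.tree(text = nwk))
  }
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# descendant tip labels below the child node of an edge
tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    nd <- todo[1]; todo <- todo[-1]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- c(tips, ch[ch <= ntip])
    todo <- c(todo, ch[ch > ntip])
  }
  tree$tip.label[tips]
}

#' Flag long branches in a single pass
#'
#' Evaluates the absolute and relative removal rules on every branch of the
#' input tree at once: absolute, branch length `>= abs_cutoff`; relative,
#' length `>= rel_cutoff` and `>= rel_ratio` times the sister branch (stem of
#' the sibling subtree at the parent; at polytomies the longest sister). A
#' degree-2 root is merged away first. Flags are not re-evaluated after
#' removals — cascades belong to [iterative_clean()].
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param policy a [trim_policy()].
#' @return data frame with one row per edge of the (unrooted) tree: `edge`,
#'   `child`, `terminal`, `label` (tip label or NA), `branch_length`,
#'   `sister_length`, `abs_flag`, `rel_flag`.
#' @export
flag_long_branches <- function(tree, policy = trim_policy()) {
  if (is.null(tree$edge.length)) stop_data("tree must have branch lengths")
  if (length(tree$tip.label) >= 3 && ape::is.rooted(tree))
    tree <- ape::unroot(tree)
  len <- tree$edge.length
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  ntip <- length(tree$tip.label)
  sister_len <- vapply(seq_along(len), function(i) {
    sis <- which(parent == parent[i])
    sis <- setdiff(sis, i)
    if (length(sis)) max(len[sis]) else NA_real_
  }, numeric(1))
  abs_flag <- len >= policy$abs_cutoff
  rel_flag <- len >= policy$rel_cutoff & !is.na(sister_len) &
    len >= policy$rel_ratio * sister_len
  data.frame(edge = seq_along(len), child = child,
             terminal = child <= ntip,
             label = ifelse(child <= ntip, tree$tip.label[child], NA_character_),
             branch_length = len, sister_length = sister_len,
             abs_flag = abs_flag, rel_flag = rel_flag,
             stringsAsFactors = FALSE)
}

#' Remove long branches from a tree
#'
#' Flags, in a single pass over the input tree, every branch that is (i) at
#' least `abs_cutoff` substitutions/site long, or (ii) at least `rel_cutoff`
#' long and at least `rel_ratio` times as long as its sister branch (the stem
#' of the sibling subtree at the parent node; at polytomies the longest
#' sister, so only unambiguous outliers fire). Flagged terminal branches lose
#' their tip (degree-2 nodes are suppressed with branch lengths summed);
#' flagged internal branches — considered only when `terminal_only` is FALSE
#' — split the tree, and only the larger tip set is retained (ties keep the
#' side with the lexicographically smallest tip). Flags are not re-evaluated
#' within a pass; cascading effects are the iterative loop's job. A degree-2
#' root is merged away before evaluation, so rooted and unrooted inputs give
#' the same answer.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param policy a [trim_policy()].
#' @param terminal_only ignore internal-branch flags (default FALSE).
#' @return list with `tree` (trimmed tree, or NULL when fewer than 3 tips
#'   survive), `removed_tips`, and `log` (one row per flagged branch with the
#'   rule that fired).
#' @export
trim_long_branches <- function(tree, policy = trim_policy(),
                               terminal_only = FALSE) {
  if (is.null(tree$edge.length)) stop_data("tree must have branch lengths")
  if (length(tree$tip.label) >= 3 && ape::is.rooted(tree))
    tree <- ape::unroot(tree)
  fl <- flag_long_branches(tree, policy)
  fl$flag <- fl$abs_flag | fl$rel_flag
  act <- fl[fl$flag & (fl$terminal | !terminal_only), , drop = FALSE]

  removed <- character(0)
  removed <- c(removed, act$label[act$terminal])
  all_tips <- tree$tip.label
  for (i in which(!act$terminal)) {
    below <- tips_below(tree, act$child[i])
    other <- setdiff(all_tips, below)
    drop_side <-
      if (length(below) < length(other)) below
      else if (length(below) > length(other)) other
      else if (min(below) < min(other)) other else below
    removed <- union(removed, drop_side)
  }
  removed <- intersect(all_tips, removed)

  log <- fl[fl$flag, c("label", "terminal", "branch_length", "sister_length",
                       "abs_flag", "rel_flag"), drop = FALSE]
  log$rule <- ifelse(log$abs_flag & log$rel_flag, "both",
                     ifelse(log$abs_flag, "absolute", "relative"))
  log$applied <- log$terminal | !terminal_only
  rownames(log) <- NULL

  surv <- setdiff(all_tips, removed)
  new_tree <- if (length(removed) == 0) tree
              else if (length(surv) >= 3) ape::drop.tip(tree, removed)
              else NULL
  list(tree = new_tree, removed_tips = removed, log = log)
}

#' Iterative homolog cleaning
#'
#' Runs the cleaning loop align -> occupancy filter -> tree -> long-branch
#' trim for up to `policy$rounds` iterations or until a fixed point (a round
#' with no removals), whichever comes first, then applies one extra trimming
#' pass restricted to terminal branches when `policy$terminal_only_final` is
#' set. The aligner defaults to pass-through (input treated as pre-aligned)
#' and the tree builder to neighbor joining on p-distances; both are
#' pluggable so an external aligner or maximum-likelihood inference can be
#' swapped in.
#'
#' @param x either a named character vector of (pre-aligned) sequences, or an
#'   `ape::phylo` tree to be cleaned directly (no re-alignment between
#'   rounds).
#' @param policy a [trim_policy()].
#' @param aligner function(seqs) -> aligned seqs; NULL = pass-through.
#' @param treebuilder function(msa) -> phylo; NULL = NJ on p-distances.
#' @return list with `surviving` (ids), `log` (per-branch removal log with a
#'   `round` column; the final pass is round `"final"`), `rounds_run`, and
#'   `status` (`"ok"`, `"fixed_point"` or `"too_few_survivors"`).
#' @export
iterative_clean <- function(x, policy = trim_policy(), aligner = NULL,
                            treebuilder = NULL) {
  tree_mode <- inherits(x, "phylo")
  if (!tree_mode && is.null(treebuilder))
    treebuilder <- function(msa) nj_tree(p_distance(msa))
  seqs <- if (tree_mode) NULL else x
  surv <- if (tree_mode) x$tip.label else names(seqs)
  cur_tree <- if (tree_mode) x else NULL
  logs <- list()
  status <- "ok"
  r <- 0L
  while (r < policy$rounds) {
    r <- r + 1L
    if (length(surv) < 4) { status <- "too_few_survivors"; r <- r - 1L; break }
    if (tree_mode) {
      tr <- ape::keep.tip(cur_tree, surv)
    } else {
      aln <- if (is.null(aligner)) seqs[surv] else aligner(seqs[surv])
      aln <- filter_columns(aln, policy$occupancy_min)
      if (length(aln) < 4) { status <- "too_few_survivors"; r <- r - 1L; break }
      tr <- treebuilder(aln)
    }
    res <- trim_long_branches(tr, policy,
                              terminal_only = !policy$internal_during_rounds)
    if (!length(res$removed_tips)) { status <- "fixed_point"; break }
    lg <- res$log[res$log$applied, , drop = FALSE]
    if (nrow(lg)) { lg$round <- r; logs[[length(logs) + 1L]] <- lg }
    surv <- setdiff(surv, res$removed_tips)
  }

  # final extra pass with the same cutoffs, terminal branches only by default
  if (status != "too_few_survivors" && length(surv) >= 4) {
    tr <- if (tree_mode) ape::keep.tip(cur_tree, surv) else {
      aln <- if (is.null(aligner)) seqs[surv] else aligner(seqs[surv])
      aln <- filter_columns(aln, policy$occupancy_min)
      if (length(aln) >= 4) treebuilder(aln) else NULL
    }
    if (!is.null(tr)) {
      res <- trim_long_branches(tr, policy,
                                terminal_only = policy$terminal_only_final)
      if (length(res$removed_tips)) {
        lg <- res$log[res$log$applied, , drop = FALSE]
        lg$round <- "final"
        logs[[length(logs) + 1L]] <- lg
        surv <- setdiff(surv, res$removed_tips)
      }
    }
  }
  if (length(surv) < 4 && status == "ok") status <- "too_few_survivors"
  if (status == "too_few_survivors")
    warning("fewer than 4 sequences survive cleaning")
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(label = character(), terminal = logical(),
               branch_length = numeric(), sister_length = numeric(),
               abs_flag = logical(), rel_flag = logical(),
               rule = character(), applied = logical(), round = character(),
               stringsAsFactors = FALSE)
  rownames(log) <- NULL
  list(surviving = surv, log = log, rounds_run = r, status = status)
}
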