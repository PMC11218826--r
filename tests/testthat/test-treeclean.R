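# Occupancy filtering, NJ trees and the long-branch cleaning loop.

test_that("occupancy filter keeps the exact boundary and drops all-gap columns", {
  rows <- c("A--A", "A--A", "A--A", "A--A", "A--A",
            "A--A", "A--A", "A--A", "A--A", "AC-A")
  msa <- stats::setNames(rows, paste0("s", 1:10))
  out <- filter_columns(msa, 0.10)
  # column 2 has occupancy exactly 0.10 -> kept; column 3 all-gap -> dropped
  expect_equal(unname(nchar(out[1])), 3L)
  expect_equal(unname(out[["s10"]]), "ACA")
  expect_error(filter_columns(c(a = "AC", b = "A")), "ragged")
})

test_that("occupancy filter matches a per-column recount and is idempotent", {
  set.seed(19)
  for (i in 1:10) {
    n <- sample(5:12, 1); L <- sample(10:30, 1)
    m <- matrix(sample(c("A", "C", "D", "-"), n * L, replace = TRUE,
                       prob = c(0.2, 0.2, 0.2, 0.4)), n, L)
    msa <- stats::setNames(apply(m, 1, paste, collapse = ""), paste0("s", 1:n))
    out <- filter_columns(msa, 0.3)
    keep <- colMeans(m != "-") >= 0.3
    kept_rows <- rowSums(m[, keep, drop = FALSE] != "-") > 0
    expected <- apply(m[kept_rows, keep, drop = FALSE], 1, paste, collapse = "")
    expect_equal(unname(out), unname(expected))
    expect_equal(filter_columns(out, 0.3), out)      # idempotent
  }
})

test_that("neighbor joining recovers additive distances exactly", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
    d <- ape::cophenetic.phylo(tr)
    d <- d[order(rownames(d)), order(colnames(d))]
    nj <- nj_tree(d)
    d2 <- ape::cophenetic.phylo(nj)[rownames(d), colnames(d)]
    expect_lt(max(abs(d - d2)), 1e-9)
  }
  # 3 taxa: closed-form star lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(d3)
  d3b <- ape::cophenetic.phylo(tr3)[rownames(d3), colnames(d3)]
  expect_equal(unname(d3b), unname(d3), tolerance = 1e-9)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "3 taxa")
  bad <- d3; bad[1, 2] <- 9
  expect_error(nj_tree(bad), "symmetric")
})

test_that("absolute and relative trimming rules fire as specified", {
  t1 <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:1.2,D:0.1):0.05);")
  r1 <- trim_long_branches(t1)
  expect_equal(r1$removed_tips, "C")
  expect_true(r1$log$abs_flag[r1$log$label == "C"])  # absolute rule fires

  # absolute rule alone (sister too long for the relative rule)
  t1b <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:1.2,D:0.3):0.05);")
  r1b <- trim_long_branches(t1b)
  expect_equal(r1b$log$rule[r1b$log$label == "C"], "absolute")

  t2 <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:0.55,D:0.05):0.05);")
  r2 <- trim_long_branches(t2)
  expect_equal(r2$removed_tips, "C")
  expect_equal(r2$log$rule[r2$log$label == "C"], "relative")

  # 45x sister but below the 0.5 floor: retained
  t3 <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:0.45,D:0.01):0.05);")
  expect_length(trim_long_branches(t3)$removed_tips, 0)
})

test_that("single-pass flags equal the brute-force enumeration oracle", {
  set.seed(31)
  for (i in 1:50) {
    tr <- random_tree(sample(5:25, 1))
    res <- trim_long_branches(tr, terminal_only = TRUE)
    expect_setequal(res$removed_tips, oracle_flagged_tips(tr))
  }
})

test_that("surviving tips are invariant to tip-label permutation", {
  set.seed(37)
  tr <- random_tree(15)
  res1 <- trim_long_branches(tr)
  perm <- sample(tr$tip.label)
  tr2 <- tr
  tr2$tip.label <- perm[match(tr$tip.label, sort(tr$tip.label))]
  # relabel consistently: map old label -> new label, compare via the map
  lab_map <- stats::setNames(tr2$tip.label, tr$tip.label)
  res2 <- trim_long_branches(tr2)
  expect_setequal(res2$removed_tips, unname(lab_map[res1$removed_tips]))
})

test_that("tip removal alone preserves distances among survivors", {
  set.seed(41)
  tr <- random_tree(12)
  res <- trim_long_branches(tr, terminal_only = TRUE)
  if (length(res$removed_tips) && !is.null(res$tree)) {
    keep <- res$tree$tip.label
    d_before <- ape::cophenetic.phylo(tr)[keep, keep]
    d_after <- ape::cophenetic.phylo(res$tree)[keep, keep]
    expect_equal(d_before, d_after, tolerance = 1e-12)
  }
  # degenerate: no branch above any cutoff -> nothing removed
  small <- ape::read.tree(text = "((A:0.1,B:0.12):0.05,(C:0.08,D:0.1):0.04);")
  expect_length(trim_long_branches(small)$removed_tips, 0)
})

test_that("iterative cleaning reaches a fixed point and respects the round cap", {
  small <- ape::read.tree(text = "((A:0.1,B:0.12):0.05,(C:0.08,D:0.1):0.04);")
  res <- iterative_clean(small)
  expect_equal(res$status, "fixed_point")
  expect_equal(res$rounds_run, 1L)
  expect_equal(nrow(res$log), 0L)
  expect_setequal(res$surviving, c("A", "B", "C", "D"))

  # log rounds bounded by rounds + 1 (the final pass)
  cfg <- sim_config(seed = 43, n_taxa = 25, long_branch_fraction = 0.2)
  tr <- gen_tree_with_outliers(cfg)
  res2 <- iterative_clean(tr$tree, trim_policy(rounds = 13))
  expect_lte(length(unique(res2$log$round)), 14)
})

test_that("iterative cleaning removes planted outliers and spares baseline tips", {
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, n_taxa = 30, long_branch_fraction = 0.2)
    tr <- gen_tree_with_outliers(cfg)
    planted <- tr$truth$tip[tr$truth$is_planted_outlier]
    res <- iterative_clean(tr$tree)
    removed <- setdiff(tr$truth$tip, res$surviving)
    expect_setequal(removed, planted)
  }
})

test_that("sequence-mode cleaning runs the full align-filter-tree-trim loop", {
  set.seed(47)
  proto <- random_protein(60)
  seqs <- plant_motif(stats::setNames(rep(proto, 8), paste0("s", 1:8)),
                      proto, 0.1)
  # one divergent sequence: mutate nearly every position
  seqs["s8"] <- plant_motif(seqs["s8"], random_protein(60), 0.95)
  res <- iterative_clean(seqs, trim_policy(abs_cutoff = 0.6, rel_cutoff = 0.3,
                                           rel_ratio = 5, rounds = 5))
  expect_true(!("s8" %in% res$surviving) || res$status == "fixed_point")
  expect_true(all(res$surviving %in% names(seqs)))
})

test_that("cleaning warns when too few sequences survive", {
  tiny <- ape::read.tree(text = "((A:2.0,B:2.0):0.1,(C:2.0,D:2.0):0.1);")
  expect_warning(res <- iterative_clean(tiny), "fewer than 4")
  expect_equal(res$status, "too_few_survivors")
})
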