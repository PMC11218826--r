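# Generators: determinism, planted-signal validity, label completeness.

test_that("configuration validation rejects malformed inputs", {
  expect_error(sim_config(n_taxa = 0), "n_taxa")
  expect_error(sim_config(motif_mut_rate = 1.5), "probability")
  expect_error(sim_config(architecture_mix = c(TIR = 0.5, CC = 0.4)), "sum to 1")
  expect_error(sim_config(architecture_mix = c(FOO = 1)), "unknown")
  expect_error(sim_config(within_mu = 0.3, between_mu = 0.4), "exceed")
})

test_that("all generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42, proteins_per_species = 20, n_orthogroups = 50)
  expect_identical(gen_proteome(cfg), gen_proteome(cfg))
  t1 <- gen_tree_with_outliers(cfg); t2 <- gen_tree_with_outliers(cfg)
  expect_identical(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
  expect_identical(t1$truth, t2$truth)
  expect_identical(gen_tm_matrix(cfg), gen_tm_matrix(cfg))
  expect_identical(gen_deg_tables(cfg), gen_deg_tables(cfg))
})

test_that("proteome honours the architecture mix and labels every protein", {
  cfg <- sim_config(seed = 1, n_species = 1, proteins_per_species = 50,
                    architecture_mix = c(TIR = 1))
  p <- gen_proteome(cfg)
  expect_equal(nrow(p$truth), 50)
  expect_true(all(p$truth$label == "TIR"))
  expect_setequal(p$truth$protein_id, names(p$seqs))

  # two-class mix: counts within 3 sigma of the binomial expectation
  cfg2 <- sim_config(seed = 7, n_species = 1, proteins_per_species = 2000,
                     architecture_mix = c(CC = 0.5, TIR = 0.5))
  p2 <- gen_proteome(cfg2)
  n_cc <- sum(p2$truth$label == "CC")
  expect_lt(abs(n_cc - 1000), 3 * sqrt(2000 * 0.25))
})

test_that("generated domain hits are ordered and non-overlapping", {
  p <- gen_proteome(sim_config(seed = 3, proteins_per_species = 40))
  for (id in unique(p$hits$protein_id)) {
    h <- p$hits[p$hits$protein_id == id, ]
    h <- h[order(h$start), ]
    expect_true(all(h$start <= h$end))
    if (nrow(h) > 1) expect_true(all(h$start[-1] > h$end[-nrow(h)]))
  }
})

test_that("plant_motif writes the motif with the expected mutation load", {
  seqs <- stats::setNames(vapply(1:500, function(i) random_protein(40),
                                 character(1)), paste0("s", 1:500))
  cons <- "MAEPLVAKVGELAKRAG"          # 17-mer

  set.seed(1)
  exact <- plant_motif(seqs[1:5], cons, 0)
  expect_true(all(substr(exact, 1, 17) == cons))
  expect_true(all(substr(exact, 18, 40) == substr(seqs[1:5], 18, 40)))

  set.seed(2)
  full <- plant_motif(seqs[1:20], cons, 1)
  mm <- vapply(full, function(s)
    sum(strsplit(substr(s, 1, 17), "")[[1]] ==
          strsplit(cons, "")[[1]]), numeric(1))
  expect_true(all(mm == 0))            # substitutions never keep the letter

  set.seed(3)
  mut <- plant_motif(seqs, cons, 0.2)
  mm <- vapply(mut, function(s)
    sum(strsplit(substr(s, 1, 17), "")[[1]] !=
          strsplit(cons, "")[[1]]), numeric(1))
  expect_lt(abs(mean(mm) - 3.4), 3 * sqrt(17 * 0.2 * 0.8 / 500))
  expect_error(plant_motif(seqs, "", 0.1), "non-empty")
  expect_error(plant_motif(stats::setNames("ACD", "x"), cons, 0.1), "longer")
})

test_that("planted tree outliers are exactly the tips satisfying the rules", {
  cfg <- sim_config(seed = 11, n_taxa = 20, long_branch_fraction = 0.2)
  tr <- gen_tree_with_outliers(cfg)
  planted <- tr$truth$tip[tr$truth$is_planted_outlier]
  expect_length(planted, 4)
  flagged <- oracle_flagged_tips(tr$tree)
  expect_setequal(flagged, planted)

  none <- gen_tree_with_outliers(sim_config(seed = 12, n_taxa = 20,
                                            long_branch_fraction = 0))
  expect_false(any(none$truth$is_planted_outlier))
  expect_length(oracle_flagged_tips(none$tree), 0)
  expect_length(trim_long_branches(none$tree)$removed_tips, 0)
})

test_that("similarity matrix separates planted communities", {
  cfg <- sim_config(seed = 5, n_structures = 60, n_communities = 3,
                    within_mu = 0.8, between_mu = 0.2)
  tm <- gen_tm_matrix(cfg)
  expect_equal(nrow(tm$edges), choose(60, 2))
  expect_true(all(tm$edges$score >= 0 & tm$edges$score <= 1))
  comm <- stats::setNames(tm$truth$community, tm$truth$id)
  same <- comm[tm$edges$id_a] == comm[tm$edges$id_b]
  expect_gt(mean(tm$edges$score[same]), mean(tm$edges$score[!same]))

  one <- gen_tm_matrix(sim_config(seed = 5, n_structures = 20,
                                  n_communities = 1, between_mu = 0.1))
  expect_true(all(one$truth$community == 1))
  expect_gt(min(one$edges$score), 0.5)
})

test_that("DEG tables realise the planted concordance exactly at the extremes", {
  for (pc in c(0, 1)) {
    cfg <- sim_config(seed = 9, n_orthogroups = 100, planted_concordance = pc)
    d <- gen_deg_tables(cfg)
    mp <- map_orthologs(filter_degs(d$deg_a), filter_degs(d$deg_b), d$orthomap)
    cc <- concordance(mp$shared)
    expect_equal(unname(cc$fraction), pc)
  }
})

test_that("non-DEG genes can never pass the significance cutoff", {
  d <- gen_deg_tables(sim_config(seed = 13, n_orthogroups = 200))
  fa <- filter_degs(d$deg_a)
  deg_ogs <- d$truth$orthogroup[d$truth$status %in%
                                  c("concordant", "discordant", "a_only", "mixed")]
  mapped <- d$orthomap[d$orthomap$species == "A", ]
  deg_genes_truth <- mapped$gene[mapped$orthogroup %in% deg_ogs]
  called <- fa$gene[fa$direction != "none"]
  unmapped <- setdiff(called, mapped$gene)    # deliberate unmapped spike-ins
  expect_true(all(setdiff(called, unmapped) %in% deg_genes_truth))
})

test_that("simulate_dataset writes a complete, re-readable bundle", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 2, proteins_per_species = 10, n_taxa = 8,
                    n_structures = 12, n_orthogroups = 30)
  paths <- simulate_dataset(cfg, dir, n_motif_align = 10, n_scan = 5)
  for (f in paths) expect_true(file.exists(f))
  expect_length(read_fasta(paths$proteome), 30)
  expect_equal(length(ape::read.tree(paths$tree)$tip.label), 8)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_named(truth, c("proteome", "tree", "communities", "orthogroups"))
})
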