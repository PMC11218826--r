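# End-to-end synthetic pipeline: simulate one dataset and run every analysis
# stage against its ground truth.

#' Run the full desk-scale analysis pipeline on one synthetic dataset
#'
#' Simulates a dataset under `cfg` (written to `out_dir`), then runs the six
#' analysis stages from the files on disk: NLR classification + inventory,
#' N-terminal-domain sequence clustering, iterative long-branch tree
#' cleaning, structure-similarity network + Louvain communities +
#' sequence/structure cross-tab, profile-HMM motif scanning, and
#' cross-species DEG concordance. Returns recovery metrics against the
#' generator's truth labels.
#'
#' @param out_dir directory for the simulated files and stage outputs.
#' @param seed integer seed (used for the configuration and Louvain).
#' @param cfg optional [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param n_cluster_seqs number of N-terminal-domain sequences drawn for the
#'   clustering stage (kept modest: clustering is quadratic in the worst
#'   case).
#' @return named list of stage summaries and recovery metrics.
#' @export
run_pipeline <- function(out_dir, seed = 1L, cfg = NULL, n_cluster_seqs = 40L) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed)
  paths <- simulate_dataset(cfg, out_dir)
  truth <- lapply(jsonlite::read_json(paths$truth, simplifyVector = TRUE),
                  as.data.frame, stringsAsFactors = FALSE)

  # 1. classification -------------------------------------------------------
  hits <- read_tsv(paths$hits)
  species <- read_tsv(paths$species)
  ann <- classify_nlr(hits)
  pt <- truth$proteome
  ann_full <- merge(pt, ann, by = "protein_id", all.x = TRUE,
                    suffixes = c(".truth", ""))
  ann_full$category[is.na(ann_full$category)] <- "none"
  cat_ok <- ann_full$category == ann_full$category.truth
  sub_ok <- ifelse(ann_full$category.truth %in% c("NLR", "degenerate-NLR"),
                   ann_full$subtype == ann_full$subtype.truth, TRUE)
  id_ok <- (ann_full$n_integrated > 0) == ann_full$has_integrated
  id_ok[is.na(id_ok)] <- ann_full$has_integrated[is.na(id_ok)] == FALSE
  inv <- nlr_inventory(ann, species)
  write_tsv(ann, file.path(out_dir, "annotations.tsv"))
  write_tsv(inv, file.path(out_dir, "inventory.tsv"))
  classification <- list(
    n = nrow(ann_full),
    category_accuracy = mean(cat_ok),
    subtype_accuracy = mean(sub_ok[ann_full$category.truth %in%
                                     c("NLR", "degenerate-NLR")]),
    id_flag_accuracy = mean(id_ok),
    inventory = inv)

  # 2. sequence clustering ---------------------------------------------------
  set.seed(cfg$seed + 91L)
  fam_seed <- replicate(3, random_protein(120))
  n_per <- ceiling(n_cluster_seqs / 3)
  clseqs <- unlist(lapply(1:3, function(f) {
    nm <- sprintf("f%d_m%02d", f, seq_len(n_per))
    plant_motif(stats::setNames(rep(fam_seed[f], n_per), nm), fam_seed[f], 0.2)
  }))
  clseqs <- clseqs[seq_len(min(length(clseqs), n_cluster_seqs))]
  cl <- greedy_cluster(clseqs)
  fam_truth <- sub("_.*", "", cl$member)
  purity <- mean(vapply(split(fam_truth, cl$cluster), function(f)
    max(table(f)) / length(f), numeric(1)))
  clustering <- list(n_seqs = length(clseqs),
                     n_clusters = length(unique(cl$cluster)),
                     mean_cluster_purity = purity)
  write_tsv(cl, file.path(out_dir, "clusters.tsv"))

  # 3. tree cleaning ---------------------------------------------------------
  tree <- ape::read.tree(paths$tree)
  res <- iterative_clean(tree, trim_policy())
  tt <- truth$tree
  planted <- tt$tip[tt$is_planted_outlier]
  removed <- setdiff(tt$tip, res$surviving)
  treeclean <- list(
    n_tips = nrow(tt), n_planted = length(planted),
    planted_recall = if (length(planted))
      mean(planted %in% removed) else NA_real_,
    baseline_removed = length(setdiff(removed, planted)),
    rounds_run = res$rounds_run, status = res$status)
  write_tsv(res$log, file.path(out_dir, "treeclean_log.tsv"))

  # 4. structure network -----------------------------------------------------
  edges <- read_tsv(paths$tm_edges)
  g <- build_graph(edges, tau = 0.5)
  part <- louvain(g, seed = cfg$seed)
  ct <- truth$communities
  ari <- if (requireNamespace("mclust", quietly = TRUE))
    mclust::adjustedRandIndex(part$membership[ct$id], ct$community) else NA_real_
  fc <- filter_communities(part)
  og_truth <- stats::setNames(paste0("OG", ct$community), ct$id)
  xt <- crosstab(og_truth, part$membership)
  structnet <- list(n_nodes = length(g$nodes), n_edges = nrow(g$edges),
                    modularity = part$Q,
                    n_communities = fc$n_communities, n_major = fc$n_major,
                    ari_vs_truth = ari,
                    crosstab = xt$matrix)
  write_tsv(data.frame(id = names(part$membership),
                       community = unname(part$membership)),
            file.path(out_dir, "communities.tsv"))

  # 5. motif profiling -------------------------------------------------------
  aln <- read_fasta(paths$motif_alignment)
  hmm <- build_profile(aln)
  pos <- read_fasta(paths$motif_positive)
  neg <- read_fasta(paths$motif_negative)
  scan <- scan_and_summarize(hmm, list(planted = pos, background = neg))
  sc_pos <- scan$hits$bitscore[scan$hits$set == "planted"]
  sc_neg <- scan$hits$bitscore[scan$hits$set == "background"]
  auroc <- mean(outer(sc_pos, sc_neg, ">") + 0.5 * outer(sc_pos, sc_neg, "=="))
  motif <- list(consensus = hmm$consensus, M = hmm$M,
                mean_planted = mean(sc_pos), mean_background = mean(sc_neg),
                auroc = auroc, summary = scan$summary)
  write_tsv(scan$hits, file.path(out_dir, "motif_hits.tsv"))

  # 6. cross-species concordance --------------------------------------------
  deg_a <- filter_degs(read_tsv(paths$deg_a))
  deg_b <- filter_degs(read_tsv(paths$deg_b))
  orthomap <- read_tsv(paths$orthomap)
  mp <- map_orthologs(deg_a, deg_b, orthomap)
  cc <- concordance(mp$shared)
  ot <- truth$orthogroups
  planted_frac <- mean(ot$status[ot$status %in% c("concordant", "discordant")] ==
                         "concordant")
  xspecies <- list(n_shared = cc$total, quadrants = cc$quadrants,
                   concordance = cc$fraction,
                   planted_concordance = planted_frac,
                   n_mixed = length(mp$mixed),
                   n_unmapped = lengths(mp$unmapped))
  write_tsv(mp$shared, file.path(out_dir, "concordance_quadrants.tsv"))

  list(config = cfg, classification = classification, clustering = clustering,
       treeclean = treeclean, structnet = structnet, motif = motif,
       xspecies = xspecies)
}
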