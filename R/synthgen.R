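# Synthetic-data generation: seeded proteomes, trees, similarity matrices and
# DEG tables with ground-truth labels for every downstream stage.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators, including the
#' random seed, and validates the whole set once. All generators are pure
#' functions of this object: the same configuration always yields byte-identical
#' output.
#'
#' @param seed integer random seed.
#' @param n_species number of species in the synthetic proteome.
#' @param proteins_per_species proteins generated per species.
#' @param architecture_mix named numeric vector of label probabilities summing
#'   to 1. Valid labels: the NLR subtypes `TIR`, `CC`, `CC_R`, `CC_CblN`,
#'   `Hyd`, `Pkn`, `NL` plus the non-NLR classes `degenerate`, `assoc_RPW8`,
#'   `assoc_TX`, `assoc_CCX`, `assoc_MLKL`, `none`.
#' @param id_fraction fraction of NLRs carrying an extra integrated
#'   (non-canonical) domain at the N- or C-terminus.
#' @param motif_consensus amino-acid consensus string planted at the N-terminus
#'   of motif-positive sequences. The default is a synthetic MAEPL-style
#'   17-mer.
#' @param motif_mut_rate per-position substitution probability applied when
#'   planting the motif.
#' @param n_taxa tips of the synthetic phylogeny.
#' @param long_branch_fraction fraction of tips planted as long-branch
#'   outliers.
#' @param n_structures structure models in the similarity matrix.
#' @param n_communities planted communities in the similarity matrix.
#' @param within_mu,between_mu mean pairwise similarity within and between
#'   planted communities (within must exceed between).
#' @param sim_sigma standard deviation of the truncated-normal similarity
#'   noise.
#' @param n_orthogroups orthogroups shared by the two synthetic species.
#' @param deg_fraction fraction of orthogroups differentially expressed in
#'   both species.
#' @param planted_concordance probability that a both-species DEG orthogroup
#'   is regulated in the same direction in the two species.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 3L,
                       proteins_per_species = 200L,
                       architecture_mix = c(TIR = 0.22, CC = 0.26, CC_R = 0.08,
                                            CC_CblN = 0.08, Hyd = 0.04, Pkn = 0.04,
                                            NL = 0.12, degenerate = 0.04,
                                            assoc_RPW8 = 0.02, assoc_TX = 0.02,
                                            assoc_CCX = 0.02, assoc_MLKL = 0.02,
                                            none = 0.04),
                       id_fraction = 0.10,
                       motif_consensus = "MAEPLVAKVGELAKRAG",
                       motif_mut_rate = 0.10,
                       n_taxa = 30L,
                       long_branch_fraction = 0.20,
                       n_structures = 100L,
                       n_communities = 4L,
                       within_mu = 0.80,
                       between_mu = 0.20,
                       sim_sigma = 0.05,
                       n_orthogroups = 600L,
                       deg_fraction = 2 / 3,
                       planted_concordance = 0.62) {
  cfg <- list(
    seed = check_count(seed, "seed"),
    n_species = check_count(n_species, "n_species"),
    proteins_per_species = check_count(proteins_per_species, "proteins_per_species"),
    architecture_mix = architecture_mix,
    id_fraction = check_prob(id_fraction, "id_fraction"),
    motif_consensus = motif_consensus,
    motif_mut_rate = check_prob(motif_mut_rate, "motif_mut_rate"),
    n_taxa = check_count(n_taxa, "n_taxa"),
    long_branch_fraction = check_prob(long_branch_fraction, "long_branch_fraction"),
    n_structures = check_count(n_structures, "n_structures"),
    n_communities = check_count(n_communities, "n_communities"),
    within_mu = check_prob(within_mu, "within_mu"),
    between_mu = check_prob(between_mu, "between_mu"),
    sim_sigma = check_prob(sim_sigma, "sim_sigma"),
    n_orthogroups = check_count(n_orthogroups, "n_orthogroups"),
    deg_fraction = check_prob(deg_fraction, "deg_fraction"),
    planted_concordance = check_prob(planted_concordance, "planted_concordance")
  )
  mix <- cfg$architecture_mix
  if (is.null(names(mix)) || any(!nzchar(names(mix))))
    stop_config("architecture_mix must be a named probability vector")
  bad <- setdiff(names(mix), SYNTH_LABELS)
  if (length(bad))
    stop_config("unknown architecture_mix label(s): ", paste(bad, collapse = ", "))
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
    stop_config("architecture_mix probabilities must be >= 0 and sum to 1")
  if (!nzchar(cfg$motif_consensus))
    stop_config("motif_consensus must be non-empty")
  check_protein(cfg$motif_consensus, "motif_consensus")
  if (cfg$within_mu <= cfg$between_mu)
    stop_config("within_mu must exceed between_mu")
  structure(cfg, class = "sim_config")
}

SYNTH_LABELS <- c("TIR", "CC", "CC_R", "CC_CblN", "Hyd", "Pkn", "NL",
                  "degenerate", "assoc_RPW8", "assoc_TX", "assoc_CCX",
                  "assoc_MLKL", "none")

# NTD domain planted for each NLR subtype (NL has none)
NTD_FOR_SUBTYPE <- c(TIR = "TIR", CC = "CC", CC_R = "RPW8", CC_CblN = "CblN",
                     Hyd = "Hydrolase", Pkn = "Kinase")

INTEGRATED_POOL <- c("WRKY", "Zf-BED", "TRX", "Jacalin", "B3", "BRX")

check_cfg <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop_config("cfg must be a sim_config object")
  cfg
}

#' Generate a synthetic multi-species proteome with planted architectures
#'
#' Draws a truth label for every protein from `architecture_mix`, lays out the
#' corresponding domain architecture as non-overlapping, N-to-C ordered hits
#' (NTD, NB-ARC or P-loop, LRR as appropriate), optionally attaches an
#' integrated non-canonical domain at the N- or C-terminus of an NLR, and
#' emits random amino-acid sequences of matching length.
#'
#' @param cfg a [sim_config()].
#' @return list with `seqs` (named character vector), `hits` (data frame
#'   `protein_id`, `domain`, `start`, `end`, `score`), `species` (data frame
#'   `protein_id`, `species`), and `truth` (data frame with one row per
#'   protein: label, category, subtype, associated class, integrated-domain
#'   flag and terminus).
#' @export
gen_proteome <- function(cfg) {
  check_cfg(cfg)
  set.seed(cfg$seed + 11L)
  n <- cfg$n_species * cfg$proteins_per_species
  species <- rep(sprintf("sp%02d", seq_len(cfg$n_species)),
                 each = cfg$proteins_per_species)
  ids <- sprintf("%s_p%04d", species, sequence(rep(cfg$proteins_per_species,
                                                   cfg$n_species)))
  labels <- sample(names(cfg$architecture_mix), n, replace = TRUE,
                   prob = cfg$architecture_mix)

  hit_list <- vector("list", n)
  truth <- data.frame(protein_id = ids, species = species, label = labels,
                      category = NA_character_, subtype = NA_character_,
                      associated_class = NA_character_,
                      has_integrated = FALSE, id_domain = NA_character_,
                      id_terminus = NA_character_,
                      stringsAsFactors = FALSE)
  seqs <- character(n)

  for (k in seq_len(n)) {
    lay <- layout_for_label(labels[k], cfg$id_fraction)
    seqs[k] <- random_protein(lay$protein_length)
    if (nrow(lay$hits)) lay$hits$protein_id <- ids[k]
    hit_list[[k]] <- lay$hits
    truth$category[k] <- lay$category
    truth$subtype[k] <- lay$subtype
    truth$associated_class[k] <- lay$associated_class
    truth$has_integrated[k] <- lay$has_integrated
    truth$id_domain[k] <- lay$id_domain
    truth$id_terminus[k] <- lay$id_terminus
  }
  names(seqs) <- ids
  hits <- do.call(rbind, hit_list[vapply(hit_list, nrow, 1L) > 0])
  hits <- hits[, c("protein_id", "domain", "start", "end", "score")]
  rownames(hits) <- NULL
  list(seqs = seqs, hits = hits,
       species = data.frame(protein_id = ids, species = species,
                            stringsAsFactors = FALSE),
       truth = truth)
}

# Domain layout for one truth label. Coordinates are 1-based inclusive,
# jittered, strictly non-overlapping and ordered N -> C.
layout_for_label <- function(label, id_fraction) {
  seg <- function(domain, start, len, score) {
    data.frame(domain = domain, start = start, end = start + len - 1L,
               score = score, stringsAsFactors = FALSE)
  }
  rows <- list()
  pos <- sample(3:12, 1L)
  category <- "none"; subtype <- NA_character_; assoc <- NA_character_
  has_id <- FALSE; id_dom <- NA_character_; id_term <- NA_character_

  add <- function(domain, len_range, score_range) {
    len <- sample(len_range[1]:len_range[2], 1L)
    s <- seg(domain, pos, len, round(stats::runif(1, score_range[1], score_range[2]), 1))
    pos <<- s$end + sample(20:60, 1L)
    rows[[length(rows) + 1L]] <<- s
  }

  is_nlr_subtype <- label %in% c(names(NTD_FOR_SUBTYPE), "NL")
  if (is_nlr_subtype && stats::runif(1) < id_fraction) {
    has_id <- TRUE
    id_dom <- sample(INTEGRATED_POOL, 1L)
    id_term <- sample(c("N", "C"), 1L)
  }

  if (has_id && id_term == "N") add(paste0("OTHER:", id_dom), c(50, 90), c(20, 60))
  if (label %in% names(NTD_FOR_SUBTYPE))
    add(NTD_FOR_SUBTYPE[[label]], c(90, 150), c(40, 100))

  if (is_nlr_subtype) {
    add("NB-ARC", c(270, 330), c(150, 350))
    add("LRR", c(180, 300), c(60, 200))
    category <- "NLR"; subtype <- label
  } else if (label == "degenerate") {
    # partial NB-ARC features: bare P-loop, with an LRR tail
    add("P-loop", c(40, 70), c(30, 80))
    add("LRR", c(150, 250), c(50, 150))
    category <- "degenerate-NLR"; subtype <- "NL"
  } else if (label == "assoc_RPW8") {
    add("RPW8", c(90, 140), c(40, 90))
    category <- "NLR-associated"; assoc <- "RPW8"
  } else if (label == "assoc_TX") {
    add("TIR", c(90, 150), c(40, 100))
    add("Hydrolase", c(120, 200), c(40, 100))
    category <- "NLR-associated"; assoc <- "TX"
  } else if (label == "assoc_CCX") {
    add("CC", c(90, 150), c(40, 100))
    add("Hydrolase", c(120, 200), c(40, 100))
    category <- "NLR-associated"; assoc <- "CC-X"
  } else if (label == "assoc_MLKL") {
    add("MLKL", c(120, 180), c(40, 100))
    category <- "NLR-associated"; assoc <- "MLKL"
  } else if (label == "none") {
    if (stats::runif(1) < 0.5) add("LRR", c(150, 300), c(40, 120))
  }

  if (has_id && id_term == "C") add(paste0("OTHER:", id_dom), c(50, 90), c(20, 60))

  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(domain = character(), start = integer(), end = integer(),
               score = numeric(), stringsAsFactors = FALSE)
  list(hits = hits, protein_length = pos + sample(10:50, 1L),
       category = category, subtype = subtype, associated_class = assoc,
       has_integrated = has_id, id_domain = id_dom, id_terminus = id_term)
}

#' Plant a motif at the N-terminus of sequences
#'
#' Overwrites positions `1..nchar(consensus)` of each sequence with a mutated
#' copy of the consensus: each position is substituted, with probability
#' `mut_rate`, by a residue drawn uniformly from the 19 alternatives. The
#' remainder of each sequence is untouched.
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param consensus non-empty consensus string; must be no longer than the
#'   shortest sequence.
#' @param mut_rate per-position substitution probability.
#' @return sequences of identical lengths with the motif planted at position 1.
#' @export
plant_motif <- function(seqs, consensus, mut_rate) {
  if (!nzchar(consensus)) stop_data("consensus must be non-empty")
  check_protein(consensus, "consensus")
  mut_rate <- check_prob(mut_rate, "mut_rate")
  L <- nchar(consensus)
  if (any(nchar(seqs) < L))
    stop_data("consensus is longer than the shortest sequence")
  cons <- strsplit(consensus, "")[[1]]
  vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    motif <- cons
    hit <- stats::runif(L) < mut_rate
    if (any(hit))
      motif[hit] <- vapply(which(hit), function(i)
        sample(setdiff(AA_ALPHABET, cons[i]), 1L), character(1))
    chars[seq_len(L)] <- motif
    paste(chars, collapse = "")
  }, character(1))
}

#' Generate a random unrooted tree with planted long-branch outliers
#'
#' Builds a random topology by successive random tip attachment starting from
#' a three-tip star, so every internal node has degree three and no degree-two
#' root exists. Baseline branch lengths are exponential (mean 0.1) truncated
#' below the relative trim cutoff (0.5 substitutions/site), which guarantees
#' that no baseline branch can satisfy either removal predicate and the truth
#' labels are exact. Planted outlier tips (no two sharing a parent node) get
#' either an absolute-rule length (>= 1.0) or a relative-rule length in
#' [0.55, 0.95) with every sister branch forced to 1/20 of it.
#'
#' @param cfg a [sim_config()] (uses `n_taxa`, `long_branch_fraction`, `seed`).
#' @return list with `tree` (an `ape::phylo`) and `truth` (data frame `tip`,
#'   `is_planted_outlier`, `rule` in absolute/relative/NA).
#' @export
gen_tree_with_outliers <- function(cfg) {
  check_cfg(cfg)
  if (cfg$n_taxa < 4) stop_config("n_taxa must be >= 4")
  set.seed(cfg$seed + 23L)
  n <- cfg$n_taxa

  # node arrays; 1 = central (degree-3+) origin node, never carries an edge
  parent <- c(NA_integer_, 1L, 1L, 1L)
  is_tip <- c(FALSE, TRUE, TRUE, TRUE)
  # successive random attachment: bisect the edge above a random non-origin node
  while (sum(is_tip) < n) {
    cand <- which(!is.na(parent))
    c_node <- cand[sample.int(length(cand), 1L)]
    m <- length(parent) + 1L
    parent[m] <- parent[c_node]; is_tip[m] <- FALSE
    parent[c_node] <- m
    t_node <- length(parent) + 1L
    parent[t_node] <- m; is_tip[t_node] <- TRUE
  }
  tips <- which(is_tip)
  tip_lab <- sprintf("t%03d", seq_along(tips))
  names(tip_lab) <- tips

  # baseline lengths: exp(rate 10) truncated to < rel cutoff 0.5
  rate <- 10
  n_nodes <- length(parent)
  edge_len <- rep(NA_real_, n_nodes)
  has_edge <- !is.na(parent)
  u <- stats::runif(sum(has_edge)) * stats::pexp(0.5, rate)
  edge_len[has_edge] <- stats::qexp(u, rate)

  # choose planted tips, no two sharing a parent
  n_out <- round(cfg$long_branch_fraction * n)
  planted <- integer(0)
  pool <- sample(tips)
  for (tp in pool) {
    if (length(planted) >= n_out) break
    if (!(parent[tp] %in% parent[planted])) planted <- c(planted, tp)
  }
  rule <- character(0)
  for (tp in planted) {
    r <- sample(c("absolute", "relative"), 1L)
    if (r == "absolute") {
      edge_len[tp] <- 1.0 + stats::rexp(1, 2)
    } else {
      len <- stats::runif(1, 0.55, 0.95)
      edge_len[tp] <- len
      sisters <- setdiff(which(!is.na(parent) & parent == parent[tp]), tp)
      edge_len[sisters] <- len / 20
    }
    rule <- c(rule, r)
  }

  nwk <- paste0(newick_from_arrays(1L, parent, is_tip, edge_len, tip_lab), ";")
  tree <- ape::read.tree(text = nwk)
  truth <- data.frame(tip = tip_lab[as.character(tips)],
                      is_planted_outlier = tips %in% planted,
                      rule = NA_character_, stringsAsFactors = FALSE)
  truth$rule[match(tip_lab[as.character(planted)], truth$tip)] <- rule
  list(tree = tree, truth = truth)
}

newick_from_arrays <- function(node, parent, is_tip, edge_len, tip_lab) {
  children <- which(!is.na(parent) & parent == node)
  inner <- vapply(children, function(ch) {
    lab <- if (is_tip[ch]) tip_lab[[as.character(ch)]]
           else newick_from_arrays(ch, parent, is_tip, edge_len, tip_lab)
    sprintf("%s:%.10f", lab, edge_len[ch])
  }, character(1))
  paste0("(", paste(inner, collapse = ","), ")")
}

#' Generate an all-vs-all structure-similarity edge list with planted
#' communities
#'
#' Assigns each structure model to one of `n_communities` planted communities
#' and draws pairwise normalized similarity scores from a truncated normal on
#' \code{[0, 1]}: mean `within_mu` for same-community pairs, `between_mu`
#' otherwise, common sd `sim_sigma`. Self-pairs are omitted; each unordered
#' pair appears once.
#'
#' @param cfg a [sim_config()].
#' @return list with `edges` (data frame `id_a`, `id_b`, `score`) and `truth`
#'   (data frame `id`, `community`).
#' @export
gen_tm_matrix <- function(cfg) {
  check_cfg(cfg)
  set.seed(cfg$seed + 37L)
  n <- cfg$n_structures
  ids <- sprintf("af%04d", seq_len(n))
  comm <- sample(rep_len(seq_len(cfg$n_communities), n))
  pairs <- utils::combn(n, 2)
  same <- comm[pairs[1, ]] == comm[pairs[2, ]]
  mu <- ifelse(same, cfg$within_mu, cfg$between_mu)
  lo <- stats::pnorm(0, mu, cfg$sim_sigma)
  hi <- stats::pnorm(1, mu, cfg$sim_sigma)
  score <- stats::qnorm(lo + stats::runif(ncol(pairs)) * (hi - lo), mu, cfg$sim_sigma)
  list(edges = data.frame(id_a = ids[pairs[1, ]], id_b = ids[pairs[2, ]],
                          score = score, stringsAsFactors = FALSE),
       truth = data.frame(id = ids, community = comm, stringsAsFactors = FALSE))
}

#' Generate two-species DEG tables with a planted concordance fraction
#'
#' Builds an orthogroup map shared by two species (one gene per species per
#' orthogroup, plus a few deliberately mixed and unmapped genes), plants a
#' fraction `deg_fraction` of orthogroups as differentially expressed in both
#' species, and gives each such orthogroup a concordant direction pair with
#' probability `planted_concordance`. DEG genes get |log2FC| > 2 and adjusted
#' p log-uniform in [1e-10, 1e-4]; all other genes get adjusted p log-uniform
#' in [1e-2, 1], so no non-DEG gene can pass the 1e-3 cutoff.
#'
#' @param cfg a [sim_config()].
#' @return list with `deg_a`, `deg_b` (data frames `gene`, `log2fc`, `padj`),
#'   `orthomap` (data frame `gene`, `species`, `orthogroup`) and `truth`
#'   (data frame `orthogroup`, `status`, `dir_a`, `dir_b`).
#' @export
gen_deg_tables <- function(cfg) {
  check_cfg(cfg)
  set.seed(cfg$seed + 53L)
  n_og <- cfg$n_orthogroups
  ogs <- sprintf("OG%05d", seq_len(n_og))
  gene_a <- sprintf("spA_g%05d", seq_len(n_og))
  gene_b <- sprintf("spB_g%05d", seq_len(n_og))

  n_shared <- round(cfg$deg_fraction * n_og)
  shared <- sort(sample.int(n_og, n_shared))
  rest <- setdiff(seq_len(n_og), shared)
  n_mixed <- min(length(rest), max(0L, round(0.02 * n_og)))
  mixed <- if (n_mixed) sort(sample(rest, n_mixed)) else integer(0)
  rest <- setdiff(rest, mixed)
  n_aonly <- floor(length(rest) * 0.2)
  n_bonly <- floor(length(rest) * 0.2)
  a_only <- if (n_aonly) sort(sample(rest, n_aonly)) else integer(0)
  rest2 <- setdiff(rest, a_only)
  b_only <- if (n_bonly) sort(sample(rest2, n_bonly)) else integer(0)

  status <- rep("none", n_og)
  dir_a <- rep(NA_character_, n_og)
  dir_b <- rep(NA_character_, n_og)
  conc <- stats::runif(n_shared) < cfg$planted_concordance
  d_a <- sample(c("up", "down"), n_shared, replace = TRUE)
  d_b <- ifelse(conc, d_a, ifelse(d_a == "up", "down", "up"))
  status[shared] <- ifelse(conc, "concordant", "discordant")
  dir_a[shared] <- d_a
  dir_b[shared] <- d_b
  status[mixed] <- "mixed"
  dir_b[mixed] <- sample(c("up", "down"), n_mixed, replace = TRUE)
  status[a_only] <- "a_only"
  dir_a[a_only] <- sample(c("up", "down"), n_aonly, replace = TRUE)
  status[b_only] <- "b_only"
  dir_b[b_only] <- sample(c("up", "down"), n_bonly, replace = TRUE)

  deg_lfc <- function(dir, n) ifelse(dir == "up", 1, -1) * (2 + stats::rexp(n, 1))
  deg_p <- function(n) 10 ^ stats::runif(n, -10, -4)
  null_lfc <- function(n) stats::runif(n, -3, 3)
  null_p <- function(n) 10 ^ stats::runif(n, -2, 0)

  mk_table <- function(genes, dirs) {
    is_deg <- !is.na(dirs)
    lfc <- null_lfc(length(genes)); p <- null_p(length(genes))
    lfc[is_deg] <- deg_lfc(dirs[is_deg], sum(is_deg))
    p[is_deg] <- deg_p(sum(is_deg))
    data.frame(gene = genes, log2fc = lfc, padj = p, stringsAsFactors = FALSE)
  }
  deg_a <- mk_table(gene_a, dir_a)
  deg_b <- mk_table(gene_b, dir_b)

  orthomap <- data.frame(
    gene = c(gene_a, gene_b),
    species = rep(c("A", "B"), each = n_og),
    orthogroup = c(ogs, ogs), stringsAsFactors = FALSE)

  # mixed orthogroups: a second species-A member with the opposite direction
  if (n_mixed) {
    extra_gene <- sprintf("spA_x%05d", seq_len(n_mixed))
    d1 <- sample(c("up", "down"), n_mixed, replace = TRUE)
    d2 <- ifelse(d1 == "up", "down", "up")
    deg_a <- rbind(deg_a,
                   data.frame(gene = extra_gene, log2fc = deg_lfc(d2, n_mixed),
                              padj = deg_p(n_mixed), stringsAsFactors = FALSE))
    deg_a$log2fc[match(gene_a[mixed], deg_a$gene)] <- deg_lfc(d1, n_mixed)
    deg_a$padj[match(gene_a[mixed], deg_a$gene)] <- deg_p(n_mixed)
    deg_b$log2fc[match(gene_b[mixed], deg_b$gene)] <- deg_lfc(dir_b[mixed], n_mixed)
    deg_b$padj[match(gene_b[mixed], deg_b$gene)] <- deg_p(n_mixed)
    orthomap <- rbind(orthomap,
                      data.frame(gene = extra_gene, species = "A",
                                 orthogroup = ogs[mixed], stringsAsFactors = FALSE))
  }

  # a handful of significant genes absent from the orthogroup map
  n_unm <- 5L
  unm_a <- sprintf("spA_u%03d", seq_len(n_unm))
  unm_b <- sprintf("spB_u%03d", seq_len(n_unm))
  du <- sample(c("up", "down"), n_unm, replace = TRUE)
  deg_a <- rbind(deg_a, data.frame(gene = unm_a, log2fc = deg_lfc(du, n_unm),
                                   padj = deg_p(n_unm), stringsAsFactors = FALSE))
  deg_b <- rbind(deg_b, data.frame(gene = unm_b, log2fc = deg_lfc(du, n_unm),
                                   padj = deg_p(n_unm), stringsAsFactors = FALSE))

  list(deg_a = deg_a, deg_b = deg_b, orthomap = orthomap,
       truth = data.frame(orthogroup = ogs, status = status,
                          dir_a = dir_a, dir_b = dir_b, stringsAsFactors = FALSE))
}

#' Write a complete synthetic dataset to disk
#'
#' Runs every generator under one configuration and writes the standard-format
#' files each analysis stage reads: proteome FASTA and domain-hit/species TSVs,
#' a newick tree, a similarity edge-list TSV, a motif alignment FASTA plus
#' motif-positive/negative scan sets, the two DEG TSVs and the orthogroup map,
#' and a JSON file of all truth labels.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param n_motif_align sequences in the motif training alignment.
#' @param n_scan sequences per motif scan set (positive and negative).
#' @param scan_len length of the scan-set sequences.
#' @return (invisibly) a named list of the written paths.
#' @export
simulate_dataset <- function(cfg, out_dir, n_motif_align = 60L, n_scan = 200L,
                             scan_len = 150L) {
  check_cfg(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  prot <- gen_proteome(cfg)
  write_fasta(prot$seqs, p("proteome.fa"))
  write_tsv(prot$hits, p("domain_hits.tsv"))
  write_tsv(prot$species, p("species.tsv"))

  tr <- gen_tree_with_outliers(cfg)
  ape::write.tree(tr$tree, p("tree.nwk"))

  tm <- gen_tm_matrix(cfg)
  tm$edges$score <- round(tm$edges$score, 6)
  write_tsv(tm$edges, p("tm_edges.tsv"))

  set.seed(cfg$seed + 71L)
  L <- nchar(cfg$motif_consensus)
  aln <- plant_motif(stats::setNames(replicate(n_motif_align, random_protein(L)),
                                     sprintf("aln%03d", seq_len(n_motif_align))),
                     cfg$motif_consensus, cfg$motif_mut_rate)
  write_fasta(aln, p("motif_alignment.fa"))
  pos <- plant_motif(stats::setNames(replicate(n_scan, random_protein(scan_len)),
                                     sprintf("pos%04d", seq_len(n_scan))),
                     cfg$motif_consensus, cfg$motif_mut_rate)
  neg <- stats::setNames(replicate(n_scan, random_protein(scan_len)),
                         sprintf("neg%04d", seq_len(n_scan)))
  write_fasta(pos, p("motif_positive.fa"))
  write_fasta(neg, p("motif_negative.fa"))

  dg <- gen_deg_tables(cfg)
  write_tsv(dg$deg_a, p("deg_a.tsv"))
  write_tsv(dg$deg_b, p("deg_b.tsv"))
  write_tsv(dg$orthomap, p("orthomap.tsv"))

  truth <- list(proteome = prot$truth, tree = tr$truth,
                communities = tm$truth, orthogroups = dg$truth)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       na = "null", digits = NA)

  invisible(list(proteome = p("proteome.fa"), hits = p("domain_hits.tsv"),
                 species = p("species.tsv"), tree = p("tree.nwk"),
                 tm_edges = p("tm_edges.tsv"),
                 motif_alignment = p("motif_alignment.fa"),
                 motif_positive = p("motif_positive.fa"),
                 motif_negative = p("motif_negative.fa"),
                 deg_a = p("deg_a.tsv"), deg_b = p("deg_b.tsv"),
                 orthomap = p("orthomap.tsv"), truth = p("truth.json")))
}
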