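# Cross-species orthologous DEG concordance and enrichment.

#' Assign differential-expression directions under strict cutoffs
#'
#' A gene is `up` when log2FC >= `lfc_min` and adjusted p <= `p_max`, `down`
#' symmetrically, and `none` otherwise. With `strict = TRUE` the inequalities
#' become strict (matching the "< 1e-3" figure-legend form rather than the
#' "<= 1e-3" methods form). Missing or NaN adjusted p-values are treated as
#' non-significant and counted in the `n_na_padj` attribute.
#'
#' @param table data frame with columns `gene`, `log2fc`, `padj`.
#' @param lfc_min minimum |log2 fold change| (default 2).
#' @param p_max maximum adjusted p (default 1e-3).
#' @param strict use strict inequalities (default FALSE).
#' @return the input with a `direction` column; genes with direction `none`
#'   stay in the table as the background universe.
#' @export
filter_degs <- function(table, lfc_min = 2, p_max = 1e-3, strict = FALSE) {
  need <- c("gene", "log2fc", "padj")
  if (!all(need %in% names(table)))
    stop_data("DEG table must have columns ", paste(need, collapse = ", "))
  p <- table$padj
  na_p <- is.na(p) | is.nan(p)
  p[na_p] <- 1
  ge <- if (strict) `>` else `>=`
  le <- if (strict) `<` else `<=`
  dir <- ifelse(ge(table$log2fc, lfc_min) & le(p, p_max), "up",
                ifelse(ge(-table$log2fc, lfc_min) & le(p, p_max), "down",
                       "none"))
  out <- table
  out$direction <- dir
  attr(out, "n_na_padj") <- sum(na_p)
  out
}

#' Map two species' DEGs onto shared orthogroups
#'
#' Collapses each species' significant genes to the orthogroup level: an
#' orthogroup's per-species direction is the unanimous direction of its DEG
#' members (`mode = "unanimity"`, default) or the majority direction with
#' ties mixed (`mode = "majority"`); orthogroups whose members conflict are
#' reported as mixed and excluded from the quadrant table. Only orthogroups
#' with a DEG in both species are kept. With `level = "gene"` every cross-
#' species DEG pair within an orthogroup becomes one row instead.
#'
#' @param degs_a,degs_b outputs of [filter_degs()] for the two species.
#' @param orthomap data frame with columns `gene`, `species`, `orthogroup`.
#' @param level `"orthogroup"` (default) or `"gene"`.
#' @param mode conflict resolution within a species: `"unanimity"` (default)
#'   or `"majority"`.
#' @return list with `shared` (data frame `orthogroup`, `dir_a`, `dir_b`;
#'   gene-level adds `gene_a`, `gene_b`), `mixed` (orthogroup ids excluded
#'   for within-species conflict), `unmapped` (list of DEG genes absent from
#'   the orthomap, per species), `level`, `mode`.
#' @export
map_orthologs <- function(degs_a, degs_b, orthomap,
                          level = c("orthogroup", "gene"),
                          mode = c("unanimity", "majority")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  if (!all(c("gene", "species", "orthogroup") %in% names(orthomap)))
    stop_data("orthomap must have columns gene, species, orthogroup")
  sp <- sort(unique(orthomap$species))
  if (length(sp) != 2)
    stop_data("orthomap must cover exactly two species, found ", length(sp))

  deg_genes <- function(d) d$gene[d$direction != "none"]
  dir_of <- function(d) stats::setNames(d$direction, d$gene)
  ga <- deg_genes(degs_a); gb <- deg_genes(degs_b)
  map_a <- orthomap[orthomap$species == sp[1], ]
  map_b <- orthomap[orthomap$species == sp[2], ]
  unmapped <- list(a = setdiff(ga, map_a$gene), b = setdiff(gb, map_b$gene))

  og_dirs <- function(genes, map, dirs) {
    m <- map[map$gene %in% genes, , drop = FALSE]
    split(data.frame(gene = m$gene, dir = dirs[m$gene],
                     stringsAsFactors = FALSE), m$orthogroup)
  }
  da <- og_dirs(ga, map_a, dir_of(degs_a))
  db <- og_dirs(gb, map_b, dir_of(degs_b))
  shared_ogs <- intersect(names(da), names(db))

  if (level == "gene") {
    rows <- lapply(shared_ogs, function(og) {
      expand.grid(gene_a = da[[og]]$gene, gene_b = db[[og]]$gene,
                  stringsAsFactors = FALSE) |>
        transform(orthogroup = og)
    })
    shared <- do.call(rbind, rows)
    if (is.null(shared)) shared <- data.frame(gene_a = character(),
                                              gene_b = character(),
                                              orthogroup = character())
    shared$dir_a <- dir_of(degs_a)[shared$gene_a]
    shared$dir_b <- dir_of(degs_b)[shared$gene_b]
    shared <- shared[, c("orthogroup", "gene_a", "gene_b", "dir_a", "dir_b")]
    rownames(shared) <- NULL
    return(list(shared = shared, mixed = character(0), unmapped = unmapped,
                level = level, mode = mode))
  }

  collapse <- function(d) {
    tab <- table(d$dir)
    if (mode == "unanimity") {
      if (length(tab) == 1) names(tab) else "mixed"
    } else {
      mx <- tab[tab == max(tab)]
      if (length(mx) == 1) names(mx) else "mixed"
    }
  }
  dir_a <- vapply(da[shared_ogs], collapse, character(1))
  dir_b <- vapply(db[shared_ogs], collapse, character(1))
  mixed <- shared_ogs[dir_a == "mixed" | dir_b == "mixed"]
  keep <- !(shared_ogs %in% mixed)
  shared <- data.frame(orthogroup = shared_ogs[keep],
                       dir_a = unname(dir_a[keep]),
                       dir_b = unname(dir_b[keep]),
                       stringsAsFactors = FALSE)
  list(shared = shared, mixed = mixed, unmapped = unmapped,
       level = level, mode = mode)
}

#' Directional concordance quadrants
#'
#' Counts the up/up, down/down, up/down and down/up quadrants of a shared
#' orthogroup (or gene-pair) table and the concordance fraction
#' (up/up + down/down) / total.
#'
#' @param shared the `shared` element of [map_orthologs()] (columns `dir_a`,
#'   `dir_b`).
#' @return list with `quadrants` (named counts `uu`, `dd`, `ud`, `du`),
#'   `total`, `fraction` (NaN with a warning when the table is empty).
#' @export
concordance <- function(shared) {
  if (is.list(shared) && !is.data.frame(shared) && !is.null(shared$shared))
    shared <- shared$shared
  n <- nrow(shared)
  q <- c(uu = sum(shared$dir_a == "up" & shared$dir_b == "up"),
         dd = sum(shared$dir_a == "down" & shared$dir_b == "down"),
         ud = sum(shared$dir_a == "up" & shared$dir_b == "down"),
         du = sum(shared$dir_a == "down" & shared$dir_b == "up"))
  total <- sum(q)
  if (total == 0) {
    warning("empty shared table: concordance undefined")
    return(list(quadrants = q, total = 0L, fraction = NaN))
  }
  list(quadrants = q, total = total,
       fraction = unname((q["uu"] + q["dd"]) / total))
}

#' Per-sector functional enrichment (Fisher / Benjamini-Hochberg)
#'
#' For each sector gene set and annotation term, tests over-representation of
#' the term among sector genes against the universe with the hypergeometric
#' upper tail (one-sided Fisher exact test; `alternative = "two.sided"`
#' switches to the minimum-likelihood two-sided test). P-values are BH-
#' adjusted across terms within each sector, flagged significant at
#' FDR <= `fdr_max`.
#'
#' @param sectors named list of gene sets.
#' @param annotation named list: term -> gene set.
#' @param universe background gene universe (must contain all sector genes).
#' @param fdr_max significance cutoff on the adjusted p (default 0.05).
#' @param alternative `"greater"` (default, over-representation) or
#'   `"two.sided"`.
#' @return data frame with one row per (sector, term): overlap and margin
#'   counts, `p`, `fdr`, `significant`. Terms with no gene in the universe
#'   are skipped.
#' @export
sector_enrichment <- function(sectors, annotation, universe, fdr_max = 0.05,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  bad <- setdiff(unique(unlist(sectors)), universe)
  if (length(bad))
    stop_data("sector gene(s) outside the universe: ",
              paste(utils::head(bad, 5), collapse = ", "))
  N <- length(universe)
  out <- list()
  for (sec in names(sectors)) {
    genes <- intersect(unique(sectors[[sec]]), universe)
    n <- length(genes)
    rows <- list()
    for (term in names(annotation)) {
      term_genes <- intersect(unique(annotation[[term]]), universe)
      K <- length(term_genes)
      if (K == 0) next
      k <- length(intersect(genes, term_genes))
      p <- if (alternative == "greater") {
        stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      } else {
        stats::fisher.test(matrix(c(k, n - k, K - k, N - K - n + k), 2))$p.value
      }
      rows[[length(rows) + 1L]] <-
        data.frame(sector = sec, term = term, overlap = k, term_size = K,
                   sector_size = n, universe_size = N, p = p,
                   stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    d <- do.call(rbind, rows)
    d$fdr <- stats::p.adjust(d$p, method = "BH")
    d$significant <- d$fdr <= fdr_max
    out[[sec]] <- d
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sector = character(), term = character(), overlap = integer(),
               term_size = integer(), sector_size = integer(),
               universe_size = integer(), p = numeric(), fdr = numeric(),
               significant = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Venn-style overlap counts of DEG sets
#'
#' Counts every membership region of two or more gene sets over one species'
#' universe.
#'
#' @param sets named list of gene sets (2 or more).
#' @return list with `regions` (data frame `pattern`, `count`; pattern like
#'   `A&B`) and `pairwise` (data frame `set_a`, `set_b`, `size_a`, `size_b`,
#'   `intersection`).
#' @export
deg_overlap <- function(sets) {
  if (length(sets) < 2) stop_data("need at least two sets")
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  regions <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(regions) <- c("pattern", "count")
  pairs <- utils::combn(names(sets), 2)
  pairwise <- data.frame(
    set_a = pairs[1, ], set_b = pairs[2, ],
    size_a = vapply(pairs[1, ], function(s) length(unique(sets[[s]])), 1L),
    size_b = vapply(pairs[2, ], function(s) length(unique(sets[[s]])), 1L),
    intersection = vapply(seq_len(ncol(pairs)), function(i)
      length(intersect(sets[[pairs[1, i]]], sets[[pairs[2, i]]])), 1L),
    stringsAsFactors = FALSE)
  list(regions = regions, pairwise = pairwise)
}
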