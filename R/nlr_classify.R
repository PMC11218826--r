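# Domain-architecture classification of NLR-related proteins from
# per-protein domain-hit tables.

CANONICAL_DOMAINS <- c("NB-ARC", "P-loop", "TIR", "CC", "RPW8", "CblN",
                       "Kinase", "Hydrolase", "LRR", "MLKL")

NTD_DOMAINS <- c("TIR", "CC", "RPW8", "CblN", "Kinase", "Hydrolase")

SUBTYPE_FOR_NTD <- c(TIR = "TIR", CC = "CC", RPW8 = "CC_R", CblN = "CC_CblN",
                     Hydrolase = "Hyd", Kinase = "Pkn")

is_known_domain <- function(x) x %in% CANONICAL_DOMAINS | startsWith(x, "OTHER:")

# Resolve overlapping hits on one protein: keep the higher-scoring hit;
# ties broken by length (longer wins), then by start (N-terminal-most wins).
resolve_overlaps <- function(hits) {
  if (nrow(hits) < 2) return(hits)
  len <- hits$end - hits$start + 1L
  ord <- order(-hits$score, -len, hits$start)
  kept <- integer(0)
  for (i in ord) {
    clash <- any(hits$start[i] <= hits$end[kept] & hits$end[i] >= hits$start[kept])
    if (!clash) kept <- c(kept, i)
  }
  hits[sort(kept), , drop = FALSE]
}

classify_one <- function(hits, protein_length, resolve = TRUE) {
  if (nrow(hits)) {
    bad <- unique(hits$domain[!is_known_domain(hits$domain)])
    if (length(bad))
      stop_data("unknown domain label(s): ", paste(bad, collapse = ", "))
    if (any(hits$start < 1 | hits$start > hits$end))
      stop_data("invalid hit coordinates (need 1 <= start <= end)")
    if (!is.null(protein_length) && any(hits$end > protein_length))
      stop_data("hit end exceeds protein length")
    hits <- hits[order(hits$start), , drop = FALSE]
    if (resolve) {
      hits <- resolve_overlaps(hits)
    } else if (nrow(hits) > 1) {
      canon <- hits[hits$domain %in% CANONICAL_DOMAINS, , drop = FALSE]
      if (nrow(canon) > 1 &&
          any(canon$start[-1] <= canon$end[-nrow(canon)]))
        stop_data("overlapping canonical hits after resolution")
    }
  }
  out <- list(category = "none", subtype = NA_character_,
              associated_class = NA_character_,
              integrated = character(0))
  dom <- hits$domain

  anchor <- NULL
  if ("NB-ARC" %in% dom) {
    nb <- hits[dom == "NB-ARC", , drop = FALSE]
    anchor <- nb[which.max(nb$score), , drop = FALSE]
    out$category <- "NLR"
  } else if ("P-loop" %in% dom) {
    pl <- hits[dom == "P-loop", , drop = FALSE]
    anchor <- pl[which.max(pl$score), , drop = FALSE]
    out$category <- "degenerate-NLR"
  } else {
    # NLR-associated patterns, checked in a fixed precedence order
    if ("RPW8" %in% dom) {
      out$category <- "NLR-associated"; out$associated_class <- "RPW8"
    } else if ("MLKL" %in% dom) {
      out$category <- "NLR-associated"; out$associated_class <- "MLKL"
    } else if (all(c("TIR", "Hydrolase") %in% dom)) {
      out$category <- "NLR-associated"; out$associated_class <- "TX"
    } else if (all(c("CC", "Hydrolase") %in% dom)) {
      out$category <- "NLR-associated"; out$associated_class <- "CC-X"
    }
    return(out)
  }

  # subtype: highest-scoring canonical NTD entirely N-terminal of the anchor
  # (hit.end < anchor.start); score ties broken by anchor proximity
  ntd <- hits[dom %in% NTD_DOMAINS & hits$end < anchor$start, , drop = FALSE]
  if (nrow(ntd)) {
    best <- ntd[order(-ntd$score, -ntd$end)[1], , drop = FALSE]
    out$subtype <- SUBTYPE_FOR_NTD[[best$domain]]
  } else if (any(dom == "LRR" & hits$start > anchor$end)) {
    out$subtype <- "NL"
  } else {
    out$subtype <- "other"
  }

  idh <- hits[startsWith(dom, "OTHER:"), , drop = FALSE]
  if (nrow(idh)) {
    term <- ifelse(idh$end < anchor$start, "N", "C")
    out$integrated <- paste0(sub("^OTHER:", "", idh$domain), "@", term)
  }
  out
}

#' Classify proteins into NLR categories and subtypes from domain hits
#'
#' A protein with a full NB-ARC hit is an `NLR`; a P-loop hit without NB-ARC
#' marks a `degenerate-NLR`; proteins with neither are `NLR-associated` when
#' they match one of the RPW8, MLKL, TIR+hydrolase (TX) or CC+hydrolase (CC-X)
#' patterns, and `none` otherwise. For (degenerate) NLRs the subtype is taken
#' from the highest-scoring canonical N-terminal domain lying entirely
#' N-terminal of the NB-ARC (or P-loop) start — TIR, CC, CC_R (RPW8),
#' CC_CblN, Hyd, Pkn — falling back to `NL` when only an LRR follows the
#' NB-ARC and to `other` otherwise. Non-canonical (`OTHER:<name>`) hits are
#' inventoried as integrated domains with an N/C terminus flag relative to the
#' NB-ARC.
#'
#' Overlapping hits are resolved before classification: the higher-scoring hit
#' wins, ties go to the longer then the more N-terminal hit.
#'
#' @param hits data frame with columns `protein_id`, `domain`, `start`, `end`,
#'   `score`; coordinates 1-based inclusive.
#' @param protein_lengths optional named vector of protein lengths used to
#'   validate coordinates. Proteins listed here but absent from `hits` are
#'   classified as `none`.
#' @param resolve resolve overlapping hits (default). With `resolve = FALSE`,
#'   overlapping canonical hits raise a data error.
#' @return data frame with one row per protein: `protein_id`, `category`,
#'   `subtype`, `associated_class`, `integrated_domains` (comma-separated
#'   `<name>@<N|C>`), `n_integrated`.
#' @export
classify_nlr <- function(hits, protein_lengths = NULL, resolve = TRUE) {
  need <- c("protein_id", "domain", "start", "end", "score")
  if (!all(need %in% names(hits)))
    stop_data("hits must have columns ", paste(need, collapse = ", "))
  ids <- unique(c(hits$protein_id, names(protein_lengths)))
  rows <- lapply(ids, function(id) {
    h <- hits[hits$protein_id == id, , drop = FALSE]
    ann <- classify_one(h, protein_lengths[[id]], resolve = resolve)
    data.frame(protein_id = id, category = ann$category,
               subtype = ann$subtype,
               associated_class = ann$associated_class,
               integrated_domains = paste(ann$integrated, collapse = ","),
               n_integrated = length(ann$integrated),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-species inventory of NLR-related loci
#'
#' Tabulates, per species: total NLR-related loci (any category other than
#' `none`), counts per subtype for NLRs and degenerate NLRs, NLR-associated
#' counts, and the number of receptors carrying at least one integrated
#' domain (NLR-IDs).
#'
#' @param annotations output of [classify_nlr()].
#' @param species_map data frame with columns `protein_id`, `species`; must
#'   cover every annotated protein.
#' @return data frame with one row per species and columns `species`,
#'   `total_loci`, one column per subtype (`TIR`, `CC`, `CC_R`, `CC_CblN`,
#'   `Hyd`, `Pkn`, `NL`, `other`), `associated`, `degenerate`, `nlr_id`.
#' @export
nlr_inventory <- function(annotations, species_map) {
  miss <- setdiff(annotations$protein_id, species_map$protein_id)
  if (length(miss))
    stop_data("protein(s) without species assignment: ",
              paste(utils::head(miss, 5), collapse = ", "))
  sp <- species_map$species[match(annotations$protein_id, species_map$protein_id)]
  subtype_levels <- c("TIR", "CC", "CC_R", "CC_CblN", "Hyd", "Pkn", "NL", "other")
  species_levels <- sort(unique(species_map$species))
  rows <- lapply(species_levels, function(s) {
    a <- annotations[sp == s, , drop = FALSE]
    st <- table(factor(a$subtype[a$category %in% c("NLR", "degenerate-NLR")],
                       levels = subtype_levels))
    data.frame(species = s,
               total_loci = sum(a$category != "none"),
               as.list(as.integer(st)) |> stats::setNames(subtype_levels),
               associated = sum(a$category == "NLR-associated"),
               degenerate = sum(a$category == "degenerate-NLR"),
               nlr_id = sum(a$n_integrated > 0 &
                            a$category %in% c("NLR", "degenerate-NLR")),
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
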