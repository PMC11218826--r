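# Greedy identity/coverage clustering of N-terminal domain sequences.

#' Optimal global pairwise alignment with identity and coverage
#'
#' Aligns two protein sequences globally under BLOSUM62 with affine gap
#' penalties (open 11, extend 1; a gap of length L costs 11 + L). Identity is
#' the fraction of identical residue pairs over alignment columns holding a
#' residue in both sequences; coverage of each sequence is the fraction of its
#' residues aligned to a residue of the other.
#'
#' @param a,b protein sequences over the 20 canonical amino acids.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b` (gapped strings), `identity`, `coverage_a`, `coverage_b`,
#'   `score`.
#' @export
global_align <- function(a, b, gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop_data("sequences must be non-empty")
  check_protein(a, "a"); check_protein(b, "b")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  pa <- as.character(Biostrings::alignedPattern(al))
  pb <- as.character(Biostrings::alignedSubject(al))
  stats <- alignment_stats(pa, pb, nchar(a), nchar(b))
  structure(c(list(aligned_a = pa, aligned_b = pb,
                   score = Biostrings::score(al)), stats),
            class = "pairwise_alignment")
}

alignment_stats <- function(pa, pb, len_a, len_b) {
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  both <- !(ca %in% GAP_CHARS) & !(cb %in% GAP_CHARS)
  n_both <- sum(both)
  list(identity = if (n_both) sum(ca[both] == cb[both]) / n_both else 0,
       coverage_a = n_both / len_a,
       coverage_b = n_both / len_b)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment: score %.1f, identity %.3f, coverage %.3f / %.3f\n",
              x$score, x$identity, x$coverage_a, x$coverage_b))
  invisible(x)
}

#' Greedy centroid clustering by identity and coverage thresholds
#'
#' Processes sequences longest-first (ties broken lexicographically by name)
#' and assigns each to the first existing centroid it matches at
#' `identity >= id_min` with coverage `>= cov_min`, opening a new cluster
#' otherwise — the transparent stand-in for the 50%/50% sequence-grouping
#' step of the survey pipeline.
#'
#' @param seqs named character vector of protein sequences.
#' @param id_min minimum pairwise identity (default 0.5).
#' @param cov_min minimum coverage (default 0.5).
#' @param coverage_mode `"both"` (default) requires both sequences' coverages
#'   to pass; `"either"` requires at least one.
#' @return data frame with columns `member`, `cluster`, `centroid`; cluster
#'   ids are `G0001`, ... in centroid creation order.
#' @export
greedy_cluster <- function(seqs, id_min = 0.5, cov_min = 0.5,
                           coverage_mode = c("both", "either")) {
  coverage_mode <- match.arg(coverage_mode)
  if (!length(seqs)) stop_data("need at least one sequence")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_data("sequences must have unique names")
  ord <- order(-nchar(seqs), names(seqs))
  centroids <- character(0)      # names of centroid sequences, creation order
  assign <- character(length(seqs)); names(assign) <- names(seqs)
  for (i in ord) {
    nm <- names(seqs)[i]
    hit <- NA_character_
    for (cen in centroids) {
      al <- global_align(seqs[[cen]], seqs[[i]])
      cov_ok <- switch(coverage_mode,
                       both = al$coverage_a >= cov_min && al$coverage_b >= cov_min,
                       either = al$coverage_a >= cov_min || al$coverage_b >= cov_min)
      if (al$identity >= id_min && cov_ok) { hit <- cen; break }
    }
    if (is.na(hit)) {
      centroids <- c(centroids, nm)
      hit <- nm
    }
    assign[nm] <- hit
  }
  cluster_id <- stats::setNames(sprintf("G%04d", seq_along(centroids)), centroids)
  data.frame(member = names(assign),
             cluster = unname(cluster_id[assign]),
             centroid = unname(assign),
             stringsAsFactors = FALSE)
}

#' Flag major sequence groups
#'
#' A cluster is "major" when it holds at least `min_loci` members spanning at
#' least `min_species` species.
#'
#' @param assignment output of [greedy_cluster()].
#' @param species_map data frame with columns `protein_id`, `species` covering
#'   every member.
#' @param min_loci minimum cluster size (default 30).
#' @param min_species minimum number of distinct species (default 3).
#' @return character vector of major cluster ids.
#' @export
major_groups <- function(assignment, species_map, min_loci = 30, min_species = 3) {
  miss <- setdiff(assignment$member, species_map$protein_id)
  if (length(miss))
    stop_data("member(s) without species: ", paste(utils::head(miss, 5), collapse = ", "))
  sp <- species_map$species[match(assignment$member, species_map$protein_id)]
  by_cluster <- split(sp, assignment$cluster)
  keep <- vapply(by_cluster, function(s)
    length(s) >= min_loci && length(unique(s)) >= min_species, logical(1))
  names(by_cluster)[keep]
}
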