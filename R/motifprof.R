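# Profile HMM for short N-terminal motifs (MAEPL/MADA style): build from a
# curated alignment, score proteome sequences in bits.
#
# Model: match states M1..Mm over alignment columns whose occupancy reaches
# the match threshold; delete states D1..Dm; insert states I1..I(m-1) between
# consecutive match columns, emitting at background (log-odds 0). Begin goes
# to M1 or D1; Mm and Dm exit to End with probability 1. The profile is
# aligned glocally: the whole profile against any substring of the target
# sequence, with flanking residues cost-free (local in sequence). Bit scores
# are log2 odds against the background null.

ROBINSON_BG <- c(A = 0.0780, C = 0.0192, D = 0.0536, E = 0.0629, F = 0.0387,
                 G = 0.0738, H = 0.0219, I = 0.0514, K = 0.0570, L = 0.0901,
                 M = 0.0224, N = 0.0448, P = 0.0520, Q = 0.0426, R = 0.0512,
                 S = 0.0712, T = 0.0585, V = 0.0644, W = 0.0133, Y = 0.0321)

#' Build a profile HMM from a motif alignment
#'
#' Columns whose non-gap fraction is at least `match_occupancy` become match
#' states. Match emission probabilities are pseudocount-smoothed frequencies,
#' `(counts + pseudocount * background) / (n + pseudocount)` with `n` the
#' residues observed in the column, converted to log-odds bits against the
#' background. Transition probabilities among match/insert/delete states are
#' estimated from the observed gap structure with Laplace (+1) smoothing.
#'
#' @param alignment named character vector of at least 2 equal-length aligned
#'   sequences (gaps `-` or `.`).
#' @param match_occupancy minimum non-gap column fraction for a match state
#'   (default 0.5).
#' @param pseudocount total pseudocount weight added to each match column
#'   (default 1).
#' @param background `"uniform"` (each residue 1/20) or `"robinson"`
#'   (Robinson-Robinson frequencies), or a named numeric vector over the 20
#'   residues summing to 1.
#' @return object of class `profile_hmm`: list with `M` (match-state count),
#'   `emissions` (M x 20 log-odds bits), `emis_prob` (M x 20 probabilities),
#'   `transitions` (list of per-junction log2 transition matrices; junction 0
#'   is Begin), `background`, `match_cols`, `consensus`.
#' @export
build_profile <- function(alignment, match_occupancy = 0.5, pseudocount = 1,
                          background = c("uniform", "robinson")) {
  m <- as_msa_matrix(alignment)
  if (nrow(m) < 2) stop_data("need at least 2 aligned sequences")
  if (is.character(background)) {
    background <- match.arg(background)
    bg <- if (background == "uniform")
      stats::setNames(rep(1 / 20, 20), AA_ALPHABET) else ROBINSON_BG
  } else {
    bg <- background[AA_ALPHABET]
    if (any(is.na(bg)) || abs(sum(bg) - 1) > 1e-6)
      stop_config("background must cover the 20 residues and sum to 1")
  }
  res <- matrix(!(m %in% GAP_CHARS), nrow(m))
  occ <- colMeans(res)
  match_cols <- which(occ >= match_occupancy)
  M <- length(match_cols)
  if (M == 0) stop_data("no column reaches the match occupancy threshold")

  emis_prob <- matrix(0, M, 20, dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(M)) {
    col <- m[, match_cols[j]]
    col <- col[!(col %in% GAP_CHARS)]
    cnt <- table(factor(col, levels = AA_ALPHABET))
    emis_prob[j, ] <- (as.numeric(cnt) + pseudocount * bg) /
      (length(col) + pseudocount)
  }
  emissions <- log2(sweep(emis_prob, 2, bg, "/"))

  # transition counts from the gap structure; junction 0 = Begin -> {M1, D1}
  trans <- vector("list", M)        # trans[[j]] = junction j-1
  cnt0 <- matrix(1, 1, 2, dimnames = list("B", c("M", "D")))   # Laplace
  states <- ifelse(res[, match_cols, drop = FALSE], "M", "D")
  n_ins <- matrix(0L, nrow(m), max(M - 1, 0))
  if (M > 1) {
    for (j in seq_len(M - 1)) {
      lo <- match_cols[j]; hi <- match_cols[j + 1]
      if (hi > lo + 1)
        n_ins[, j] <- rowSums(res[, (lo + 1):(hi - 1), drop = FALSE])
    }
  }
  for (k in seq_len(nrow(m))) cnt0[1, states[k, 1]] <- cnt0[1, states[k, 1]] + 1
  trans[[1]] <- log2(cnt0 / sum(cnt0))
  if (M > 1) {
    for (j in seq_len(M - 1)) {
      cj <- matrix(1, 3, 3, dimnames = list(c("M", "I", "D"), c("M", "I", "D")))
      for (k in seq_len(nrow(m))) {
        from <- states[k, j]; to <- states[k, j + 1]; ni <- n_ins[k, j]
        if (ni == 0) {
          cj[from, to] <- cj[from, to] + 1
        } else {
          cj[from, "I"] <- cj[from, "I"] + 1
          cj["I", "I"] <- cj["I", "I"] + ni - 1
          cj["I", to] <- cj["I", to] + 1
        }
      }
      trans[[j + 1]] <- log2(cj / rowSums(cj))
    }
  }
  consensus <- AA_ALPHABET[apply(emis_prob, 1, which.max)]
  structure(list(M = M, emissions = emissions, emis_prob = emis_prob,
                 transitions = trans, background = bg,
                 match_cols = match_cols,
                 match_occupancy = match_occupancy,
                 consensus = paste(consensus, collapse = "")),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile HMM: %d match states, consensus %s\n", x$M, x$consensus))
  invisible(x)
}

l2se <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(-Inf)
  mx <- max(x)
  mx + log2(sum(2 ^ (x - mx)))
}

#' Score a sequence against a profile HMM
#'
#' Dynamic programming over the glocal profile alignment: the full profile is
#' matched against any substring of the sequence, flanking residues free.
#' `"viterbi"` reports the best single alignment's bit score and its 1-based
#' start position; `"forward"` reports the log-sum over all alignments (always
#' at least the Viterbi score). Residues outside the 20-letter alphabet are
#' scored as background (log-odds 0) and counted in `n_unknown`.
#'
#' @param hmm a [build_profile()] result.
#' @param seq amino-acid sequence (length >= 1).
#' @param mode `"viterbi"` (default) or `"forward"`.
#' @return object of class `motif_hit`: list with `score` (bits), `start`
#'   (Viterbi only), `mode`, `n_unknown`.
#' @export
score_sequence <- function(hmm, seq, mode = c("viterbi", "forward")) {
  mode <- match.arg(mode)
  if (!nzchar(seq)) stop_data("sequence must be non-empty")
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  M <- hmm$M
  ridx <- match(chars, AA_ALPHABET)
  n_unknown <- sum(is.na(ridx))
  # emission log-odds per (match state, residue); unknown residue -> 0
  E <- matrix(0, M, L)
  known <- !is.na(ridx)
  if (any(known)) E[, known] <- hmm$emissions[, ridx[known], drop = FALSE]

  tr <- hmm$transitions
  comb <- if (mode == "viterbi") function(a, b, c) pmax(a, b, c)
          else function(a, b, c) {
            mx <- pmax(a, b, c)
            out <- mx + log2(2^(a - mx) + 2^(b - mx) + 2^(c - mx))
            out[!is.finite(mx)] <- -Inf
            out
          }

  VM <- matrix(-Inf, M, L + 1)      # [j, i+1]: ends at Mj emitting residue i
  VI <- matrix(-Inf, M, L + 1)      # ends at Ij emitting residue i (j < M)
  VD <- matrix(-Inf, M, L + 1)      # ends at Dj, i residues consumed

  t0 <- tr[[1]]
  VM[1, 2:(L + 1)] <- E[1, ] + t0["B", "M"]       # flank prefix free
  VD[1, ] <- t0["B", "D"]
  if (M > 1) {
    for (j in seq_len(M - 1)) {
      tj <- tr[[j + 1]]
      # insert run at junction j (after Mj/Dj), scan over positions
      A <- comb(VM[j, seq_len(L)] + tj["M", "I"],
                VD[j, seq_len(L)] + tj["D", "I"], rep(-Inf, L))
      tII <- tj["I", "I"]
      ks <- seq_len(L)
      B <- A - tII * ks
      if (mode == "viterbi") {
        VI[j, 2:(L + 1)] <- cummax(B) + tII * ks
      } else {
        mB <- max(B[is.finite(B)], -Inf)
        if (is.finite(mB)) {
          cs <- cumsum(2 ^ (B - mB))
          VI[j, 2:(L + 1)] <- ifelse(cs > 0, mB + log2(cs) + tII * ks, -Inf)
        }
      }
      VM[j + 1, 2:(L + 1)] <- E[j + 1, ] +
        comb(VM[j, seq_len(L)] + tj["M", "M"],
             VI[j, seq_len(L)] + tj["I", "M"],
             VD[j, seq_len(L)] + tj["D", "M"])
      VD[j + 1, ] <- comb(VM[j, ] + tj["M", "D"],
                          VI[j, ] + tj["I", "D"],
                          VD[j, ] + tj["D", "D"])
    }
  }
  ends <- c(VM[M, ], VD[M, ])       # Mm/Dm -> End with probability 1
  score <- if (mode == "viterbi") max(ends) else l2se(ends)
  start <- NA_integer_
  if (mode == "viterbi" && is.finite(score))
    start <- viterbi_start(hmm, E, VM, VI, VD, score)
  structure(list(score = unname(score), start = start, mode = mode,
                 n_unknown = n_unknown), class = "motif_hit")
}

# trace the Viterbi path back to Begin and return the index of the first
# emitted residue (NA for an all-delete path)
viterbi_start <- function(hmm, E, VM, VI, VD, score) {
  M <- hmm$M; L <- ncol(E)
  tol <- 1e-9
  hit <- which(abs(VM[M, ] - score) < tol)
  st <- "M"
  if (!length(hit)) { hit <- which(abs(VD[M, ] - score) < tol); st <- "D" }
  i <- hit[length(hit)] - 1L        # residues consumed
  j <- M
  first_emit <- if (st == "M") i else NA_integer_
  val <- score
  while (!(j == 1 && st %in% c("M", "D"))) {
    tj <- hmm$transitions[[j]]      # junction j-1 (from states at j-1)
    if (st == "M") {
      target <- val - E[j, i]
      i2 <- i - 1L
      if (abs(VM[j - 1, i2 + 1] + tj["M", "M"] - target) < tol) {
        st <- "M"; j <- j - 1L; i <- i2
      } else if (abs(VI[j - 1, i2 + 1] + tj["I", "M"] - target) < tol) {
        st <- "I"; j <- j - 1L; i <- i2
      } else {
        st <- "D"; j <- j - 1L; i <- i2
      }
    } else if (st == "D") {
      if (abs(VM[j - 1, i + 1] + tj["M", "D"] - val) < tol) {
        st <- "M"; j <- j - 1L
      } else if (abs(VI[j - 1, i + 1] + tj["I", "D"] - val) < tol) {
        st <- "I"; j <- j - 1L
      } else {
        st <- "D"; j <- j - 1L
      }
    } else {                        # insert I_j, emitted residue i
      first_emit <- i
      tjj <- hmm$transitions[[j + 1]]
      i2 <- i - 1L
      if (abs(VM[j, i2 + 1] + tjj["M", "I"] - val) < tol) {
        st <- "M"
      } else if (abs(VI[j, i2 + 1] + tjj["I", "I"] - val) < tol) {
        st <- "I"
      } else {
        st <- "D"
      }
      i <- i2
      if (st == "M") first_emit <- i
      val <- VM_VI_VD(VM, VI, VD, st, j, i)
      next
    }
    if (st == "M") first_emit <- i
    val <- VM_VI_VD(VM, VI, VD, st, j, i)
  }
  if (st == "M") first_emit <- i
  if (is.na(first_emit)) NA_integer_ else as.integer(first_emit)
}

VM_VI_VD <- function(VM, VI, VD, st, j, i) {
  switch(st, M = VM[j, i + 1], I = VI[j, i + 1], D = VD[j, i + 1])
}

#' Scan labelled sequence sets and summarise motif scores
#'
#' Scores every sequence of every set against the profile and reports
#' per-set mean and median bit scores, optionally restricting scoring to an
#' N-terminal window.
#'
#' @param hmm a [build_profile()] result.
#' @param sets named list of named character vectors (one per proteome set).
#' @param mode `"viterbi"` or `"forward"`.
#' @param nterm_window optional integer: score only the first this-many
#'   residues of each sequence.
#' @return list with `hits` (data frame `set`, `id`, `bitscore`, `start`)
#'   and `summary` (data frame `set`, `n`, `mean`, `median`).
#' @export
scan_and_summarize <- function(hmm, sets, mode = "viterbi",
                               nterm_window = NULL) {
  if (!length(sets)) stop_data("need at least one sequence set")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  rows <- list()
  for (nm in names(sets)) {
    seqs <- sets[[nm]]
    if (!length(seqs)) {
      warning("empty sequence set: ", nm)
      next
    }
    if (!is.null(nterm_window))
      seqs <- vapply(seqs, substr, character(1), 1L, nterm_window)
    for (id in names(seqs)) {
      h <- score_sequence(hmm, seqs[[id]], mode)
      rows[[length(rows) + 1L]] <-
        data.frame(set = nm, id = id, bitscore = h$score, start = h$start,
                   stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(), id = character(), bitscore = numeric(),
               start = integer(), stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(split(hits, hits$set), function(d)
    data.frame(set = d$set[1], n = nrow(d), mean = mean(d$bitscore),
               median = stats::median(d$bitscore), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(hits = hits, summary = summary)
}

#' Per-column residue counts, frequencies and consensus of an alignment
#'
#' @param alignment named character vector of equal-length aligned sequences.
#' @return list with `counts` (20 x ncol), `freqs` (columns sum to 1 over
#'   residues present; all-gap columns are all-zero), and `consensus`
#'   (argmax residue per column, ties alphabetical; all-gap columns excluded).
#' @export
consensus_counts <- function(alignment) {
  m <- as_msa_matrix(alignment)
  counts <- apply(m, 2, function(col) {
    col <- col[!(col %in% GAP_CHARS)]
    as.integer(table(factor(col, levels = AA_ALPHABET)))
  })
  rownames(counts) <- AA_ALPHABET
  tot <- colSums(counts)
  freqs <- sweep(counts, 2, pmax(tot, 1), "/")
  nonempty <- tot > 0
  consensus <- paste(AA_ALPHABET[apply(counts[, nonempty, drop = FALSE], 2,
                                       which.max)], collapse = "")
  list(counts = counts, freqs = freqs, consensus = consensus)
}
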