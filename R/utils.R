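# Shared helpers: amino-acid alphabet, validation, file IO.

#' The 20 canonical amino-acid one-letter codes
#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHARS <- c("-", ".")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("nlrmacro_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("nlrmacro_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop_config(name, " must be a single integer >= 1, got ", deparse(x))
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(name, " must be a probability in [0, 1], got ", deparse(x))
  as.numeric(x)
}

#' Validate a protein sequence over the canonical alphabet
#' @keywords internal
check_protein <- function(seq, name = "sequence") {
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stop_data(name, " contains invalid residue(s): ", paste(bad, collapse = ", "))
  invisible(seq)
}

random_protein <- function(len, alphabet = AA_ALPHABET) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

#' Read a FASTA file into a named character vector
#'
#' @param path path to an (uncompressed) amino-acid FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
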