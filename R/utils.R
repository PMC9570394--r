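DNA_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T, case-insensitive;
#'   other IUPAC codes are complemented where defined, otherwise kept).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  flipped <- chartr("ACGTacgtRYKMrykm", "TGCAtgcaYRMKyrmk", x)
  vapply(
    strsplit(flipped, "", fixed = TRUE),
    function(s) paste(rev(s), collapse = ""),
    character(1)
  )
}

# TRUE where the (a, b) base pair is a transition (A<->G or C<->T)
is_transition <- function(a, b) {
  (a %in% PURINES & b %in% PURINES) | (a %in% PYRIMIDINES & b %in% PYRIMIDINES)
}

random_dna <- function(n_seq, length, bases = DNA_BASES) {
  vapply(
    seq_len(n_seq),
    function(i) paste(sample(bases, length, replace = TRUE), collapse = ""),
    character(1)
  )
}

# Run code under a fixed seed when one is given, leaving the caller's RNG
# stream untouched; with seed = NULL the current stream is consumed.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Character alignment matrix (taxa x sites) from equal-length sequences
aln_matrix <- function(seqs) {
  stopifnot(length(seqs) >= 2)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    abort("sequences must be aligned to equal length")
  }
  m <- do.call(rbind, strsplit(toupper(unname(seqs)), "", fixed = TRUE))
  rownames(m) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  m
}

substitute_base <- function(seq, column0, base) {
  # column0 is a 0-based offset into seq
  substr(seq, column0 + 1, column0 + 1) <- base
  seq
}
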