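## Shared constants and small helpers.

#' The 20-residue amino acid alphabet
#'
#' Single-letter codes in fixed alphabetical order. All positional matrices in
#' the package use this column order.
#'
#' @return Character vector of length 20.
#' @export
aminoAcids <- function() AA20

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## One canonical codon per fixed residue (template-encoded constant flanks).
CANONICAL_CODON <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCG", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT")

## All 32 NNK codons (N = A/C/G/T at positions 1-2, K = G/T at position 3).
nnkCodons <- function() {
  n <- c("A", "C", "G", "T")
  as.vector(outer(outer(n, n, paste0), c("G", "T"), paste0))
}

#' Expected residue frequencies of an NNK-randomized position
#'
#' Exact enumeration of the 32 NNK codons: each residue's frequency is its
#' codon count / 32, conditional on not drawing the amber stop (TAG), which is
#' removed downstream by the stop-codon filter.
#'
#' @param includeStop If `TRUE`, return the unconditional 21-entry vector
#'   including the amber stop (`*`).
#' @return Named numeric vector summing to 1.
#' @export
nnkFrequencies <- function(includeStop = FALSE) {
  cod <- nnkCodons()
  aa <- vapply(cod, function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(x))), character(1))
  tab <- table(aa) / length(cod)
  out <- structure(as.numeric(tab), names = names(tab))
  if (!includeStop) {
    out <- out[names(out) != "*"]
    out <- out / sum(out)
  }
  out[order(names(out))]
}

#' Average UniProt amino acid frequencies
#'
#' Background residue frequencies averaged over UniProtKB/Swiss-Prot, used for
#' logos of external peptide sets and for generating random calibration
#' peptides.
#'
#' @return Named numeric vector over [aminoAcids()], summing to 1.
#' @export
uniprotFrequencies <- function() {
  f <- c(A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86, G = 7.07,
         H = 2.27, I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06,
         P = 4.70, Q = 3.93, R = 5.53, S = 6.56, T = 5.34, V = 6.87,
         W = 1.08, Y = 2.92)
  f / sum(f)
}

#' Generate random peptides from a residue frequency background
#'
#' Draws unique peptides of a single length with i.i.d. residues. Used for
#' percent-rank calibration and algorithm-motif generation (the 50,000 random
#' 15mer convention).
#'
#' @param n Number of unique peptides.
#' @param length Peptide length.
#' @param freqs Residue background; defaults to [uniprotFrequencies()].
#' @param seed Integer seed; the draw is reproducible.
#' @return Character vector of `n` unique peptides.
#' @export
randomPeptides <- function(n, length = 15L, freqs = uniprotFrequencies(),
                           seed = 1L) {
  stopifnot(n >= 1, length >= 1)
  withr_seed(seed)
  aa <- names(freqs)
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    m <- matrix(sample(aa, (need + 16L) * length, replace = TRUE, prob = freqs),
                ncol = length)
    out <- unique(c(out, apply(m, 1L, paste0, collapse = "")))
  }
  out[seq_len(n)]
}

## set.seed without clobbering the caller's RNG stream
withr_seed <- function(seed) {
  seed <- as.integer(seed)
  set.seed(seed)
  invisible(seed)
}

## split equal-length strings into an n x L character matrix
peptideMatrix <- function(x) {
  L <- unique(nchar(x))
  if (length(L) != 1L) stop("ragged peptide set")
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         ncol = L, byrow = TRUE)
}

## Hamming distance between one string and a vector of equal-length strings
hammingTo <- function(s, xs) {
  sm <- strsplit(s, "")[[1]]
  m <- peptideMatrix(xs)
  rowSums(m != matrix(sm, nrow = nrow(m), ncol = length(sm), byrow = TRUE))
}

## derive a fresh sub-seed from a base seed (kept below 2^31)
deriveSeed <- function(seed, k) {
  (as.integer(seed) * 48271 + as.integer(k) * 16807) %% 2147483399L + 1L
}
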