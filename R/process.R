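## Read filtering, tiered Hamming-distance error collapse, translation.

#' Filter merged amplicon reads into per-round count tables
#'
#' Implements the full filter cascade. A read is kept iff it
#' (a) has exactly the expected length, (b) exactly matches the constant
#' DNA context (which contains the 3C-site-encoding and polymorphic
#' segments), (c) carries a known round barcode (the read is assigned to
#' that round), (d) has no peptide-encoding base with a Phred-33 score
#' below 20, and (e) matches the NNK codon pattern (K = G or T) at every
#' randomized codon. Kept reads contribute their peptide-encoding DNA to
#' the round's count map. Reads failing the barcode match are counted in
#' the attrition report, not silently dropped.
#'
#' @param reads A [SimulatedReadSet-class], a list of them, a FASTQ path (or
#'   vector of paths), or a list with elements `dna` and `qual`.
#' @param design The [LibraryDesign-class] to match against.
#' @return Named list (`r0`, `r1`, ...) of [RawCountTable-class], with an
#'   `"attrition"` attribute recording per-stage read losses.
#' @export
setGeneric("filterReads", function(reads, design)
  standardGeneric("filterReads"))

#' @rdname filterReads
setMethod("filterReads", "SimulatedReadSet", function(reads, design) {
  filterReadVectors(readSequences(reads), readQualities(reads), design)
})

#' @rdname filterReads
setMethod("filterReads", "list", function(reads, design) {
  if (all(c("dna", "qual") %in% names(reads)))
    return(filterReadVectors(reads$dna, reads$qual, design))
  dna <- unlist(lapply(reads, function(r)
    if (is(r, "SimulatedReadSet")) readSequences(r) else r$dna),
    use.names = FALSE)
  qual <- unlist(lapply(reads, function(r)
    if (is(r, "SimulatedReadSet")) readQualities(r) else r$qual),
    use.names = FALSE)
  filterReadVectors(dna, qual, design)
})

#' @rdname filterReads
setMethod("filterReads", "character", function(reads, design) {
  parts <- lapply(reads, readFastqReads)
  filterReadVectors(unlist(lapply(parts, `[[`, "dna")),
                    unlist(lapply(parts, `[[`, "qual")), design)
})

filterReadVectors <- function(dna, qual, design) {
  if (length(dna) != length(qual) || any(nchar(dna) != nchar(qual)))
    stop("malformed FASTQ record")
  attrition <- list(input = length(dna))

  expLen <- readLength(design)
  ok <- nchar(dna) == expLen
  attrition$length <- sum(!ok)
  dna <- dna[ok]; qual <- qual[ok]

  bcLen <- nchar(design@barcodes[[1L]])
  c5 <- design@constant5Dna
  c3 <- design@constant3Dna
  pepLen <- 3L * peptideLength(design)
  pepFrom <- bcLen + nchar(c5) + 1L
  pepTo <- pepFrom + pepLen - 1L

  ok <- substr(dna, bcLen + 1L, bcLen + nchar(c5)) == c5 &
    substr(dna, pepTo + 1L, expLen) == c3
  attrition$constant <- sum(!ok)
  dna <- dna[ok]; qual <- qual[ok]

  round <- match(substr(dna, 1L, bcLen), design@barcodes)
  ok <- !is.na(round)
  attrition$barcode <- sum(!ok)
  dna <- dna[ok]; qual <- qual[ok]; round <- round[ok]

  ## Phred-33 < 20 anywhere in the peptide-encoding region
  pepQual <- substr(qual, pepFrom, pepTo)
  ok <- !grepl("[\x21-\x34]", pepQual)
  attrition$quality <- sum(!ok)
  dna <- dna[ok]; round <- round[ok]

  ## NNK pattern: randomized codons must end in G or T
  pepDna <- substr(dna, pepFrom, pepTo)
  randFrom <- 3L * nchar(design@flank5Aa)
  ok <- rep(TRUE, length(pepDna))
  for (j in seq_len(design@nRandom)) {
    b <- substr(pepDna, randFrom + 3L * j, randFrom + 3L * j)
    ok <- ok & (b == "G" | b == "T")
  }
  attrition$nnk <- sum(!ok)
  pepDna <- pepDna[ok]; round <- round[ok]
  attrition$kept <- length(pepDna)

  rounds <- sort(unique(round))
  out <- lapply(rounds, function(r) {
    tab <- table(pepDna[round == r])
    new("RawCountTable", round = r - 1L,
        counts = structure(as.integer(tab), names = names(tab)))
  })
  names(out) <- names(design@barcodes)[rounds]
  structure(out, attrition = attrition)
}

#' Collapse likely PCR/sequencing error sequences within a round
#'
#' Accounts for errors propagated from high-prevalence peptides: a sequence
#' is discarded iff a sufficiently more prevalent comparison sequence sits
#' within a tiered Hamming radius -- distance <= 1 from any more prevalent
#' sequence, distance <= 2 from one at least 100-fold more prevalent, or
#' distance <= 3 from one at least 10,000-fold more prevalent, strictly
#' within the same round. Sequences are processed in descending count order
#' (ties broken lexicographically); by default only retained sequences act
#' as comparators (`compare = "retained"`), with the stricter all-comparators
#' variant available as `compare = "all"`.
#'
#' @param table A [RawCountTable-class] for one round.
#' @param compare `"retained"` (greedy, default) or `"all"`.
#' @return The collapsed [RawCountTable-class].
#' @export
collapseErrors <- function(table, compare = c("retained", "all")) {
  compare <- match.arg(compare)
  counts <- table@counts
  if (length(counts) < 2L) return(table)
  ord <- order(-counts, names(counts), method = "radix")
  keep <- collapse_greedy_cpp(names(counts)[ord], as.numeric(counts[ord]),
                              compare == "retained")
  kept <- counts[ord][keep]
  kept <- kept[order(names(kept), method = "radix")]
  new("RawCountTable", round = table@round, counts = kept)
}

#' Translate collapsed count tables into a peptide table
#'
#' Standard-genetic-code translation of the peptide-encoding DNA; sequences
#' encoding a stop are dropped, synonymous DNA variants of one peptide are
#' merged with read counts summed, and each peptide's final round of
#' observation is recorded.
#'
#' @param tables Named list of [RawCountTable-class] (rounds `r0 ... rR`, as
#'   returned by [filterReads()], usually after [collapseErrors()]).
#' @param design The [LibraryDesign-class].
#' @return A [PeptideTable-class].
#' @export
translateAndTabulate <- function(tables, design) {
  rounds <- vapply(tables, function(t) t@round, integer(1))
  nR <- max(rounds) + 1L
  allDna <- unique(unlist(lapply(tables, function(t) names(t@counts)),
                          use.names = FALSE))
  if (!length(allDna)) stop("no peptides")
  if (any(nchar(allDna) %% 3L != 0L)) stop("frame error")
  pep <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(allDna), no.init.codon = TRUE))
  names(pep) <- allDna
  counts <- matrix(0L, length(allDna), nR,
                   dimnames = list(allDna, paste0("r", seq_len(nR) - 1L)))
  for (t in tables)
    counts[names(t@counts), t@round + 1L] <- t@counts
  keep <- !grepl("*", pep, fixed = TRUE)
  counts <- counts[keep, , drop = FALSE]
  pep <- pep[keep]
  merged <- rowsum(counts, group = pep)
  storage.mode(merged) <- "integer"
  fr <- apply(merged > 0L, 1L, function(p) max(which(p)) - 1L)
  peps <- rownames(merged)
  rownames(merged) <- NULL
  new("PeptideTable", peptide = peps, readCounts = merged,
      finalRound = as.integer(fr), design = designName(design))
}

#' Extract the randomized residues of peptides under a design
#'
#' @param peptides Full-length peptides.
#' @param design The [LibraryDesign-class].
#' @return Character vector of the NNK-randomized stretch of each peptide.
#' @export
randomizedRegion <- function(peptides, design) {
  rr <- randomizedRange(design)
  substr(peptides, rr[1L], rr[2L])
}
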