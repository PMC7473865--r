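## Library designs.

C3_SITE_DNA <- "CTGGAAGTTCTGTTTCAGGGTCCG"  # encodes LEVLFQ/GP

DEFAULT_BARCODES <- c(r0 = "ACGTAC", r1 = "TGCAGT", r2 = "GATCCA",
                      r3 = "CTAGGT", r4 = "AGCTTG", r5 = "TCGAAC")

#' Construct a library design
#'
#' Most users want [builtinDesign()]; this constructor exists for custom
#' libraries (different flanks, barcodes or constant regions).
#'
#' @param name Design label.
#' @param flank5Aa,flank3Aa Fixed flanking residues.
#' @param nRandom Number of NNK-randomized residues (9 or 13).
#' @param coreStart 1-based start of the designed 9mer core in the peptide.
#' @param constant5Dna,constant3Dna Constant DNA around the peptide-encoding
#'   region; one of them must contain the 3C-site-encoding sequence.
#' @param barcodes Named character vector of per-round inline barcodes.
#' @return A [LibraryDesign-class].
#' @export
libraryDesign <- function(name, flank5Aa, nRandom, flank3Aa, coreStart,
                          constant5Dna, constant3Dna,
                          barcodes = DEFAULT_BARCODES) {
  new("LibraryDesign", name = name, flank5Aa = flank5Aa,
      nRandom = as.integer(nRandom), flank3Aa = flank3Aa,
      coreStart = as.integer(coreStart), constant5Dna = constant5Dna,
      constant3Dna = constant3Dna, barcodes = barcodes)
}

#' Built-in library designs
#'
#' The three library templates used throughout the package:
#' \describe{
#'   \item{`dr401_9mer`, `dr402_9mer`}{randomized 9mers with fixed flanks,
#'     peptide template `AA-X9-WEEG` (15 aa). The constant flanks constrain
#'     binding to a single register, so the designed 9mer core is exactly the
#'     randomized stretch (positions 3-11).}
#'   \item{`dr401_13mer`}{randomized 13mers, template `A-X13-G` (15 aa). The
#'     designed core is the central 9mer window (positions 4-12), leaving
#'     randomized flanking positions P(-2), P(-1), P10 and P11 around it.}
#' }
#' The constant DNA context carries the 3C-protease-site-encoding sequence
#' and a short polymorphic segment that distinguishes the DR401 and DR402
#' constructs, mirroring the amplicon layout the read filter matches against.
#'
#' @param name One of `dr401_9mer`, `dr401_13mer`, `dr402_9mer`.
#' @return A [LibraryDesign-class].
#' @examples
#' builtinDesign("dr401_9mer")
#' @export
builtinDesign <- function(name) {
  allele_tag <- c(dr401 = "AAGGACCTG", dr402 = "AAGGAGATC")
  const5 <- "GCTAGCGGAGGC"
  const3 <- function(allele)
    paste0("GGAGGTTCT", C3_SITE_DNA, allele_tag[[allele]])
  switch(name,
    dr401_9mer = libraryDesign("dr401_9mer", "AA", 9L, "WEEG", 3L,
                               const5, const3("dr401")),
    dr402_9mer = libraryDesign("dr402_9mer", "AA", 9L, "WEEG", 3L,
                               const5, const3("dr402")),
    dr401_13mer = libraryDesign("dr401_13mer", "A", 13L, "G", 4L,
                                const5, const3("dr401")),
    stop("unknown builtin design"))
}

## DNA encoding of the fixed flanks (single canonical codon per residue)
flankDna <- function(aa) {
  if (!nchar(aa)) return("")
  paste0(CANONICAL_CODON[strsplit(aa, "")[[1]]], collapse = "")
}

## expected read length for a design (barcode + constants + peptide dna)
readLength <- function(design) {
  nchar(design@barcodes[[1]]) + nchar(design@constant5Dna) +
    3L * peptideLength(design) + nchar(design@constant3Dna)
}

## permissible true core starts: 9mer windows fully inside the randomized
## stretch (for 9mer designs this is the single designed register)
permissibleCoreStarts <- function(design) {
  rr <- randomizedRange(design)
  if (design@nRandom == 9L) return(design@coreStart)
  seq.int(rr[1L], rr[2L] - 8L)
}
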