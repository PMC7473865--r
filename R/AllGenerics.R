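## Generics and accessors. Slots are never accessed directly by user code.

#' @rdname PeptideTable-class
#' @param object,x A package object.
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))
#' @rdname PeptideTable-class
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))
#' @rdname PeptideTable-class
#' @export
setGeneric("finalRound", function(x) standardGeneric("finalRound"))
#' @rdname LibraryDesign-class
#' @param x A package object.
#' @export
setGeneric("designName", function(x) standardGeneric("designName"))
#' @rdname LibraryDesign-class
#' @export
setGeneric("peptideLength", function(x) standardGeneric("peptideLength"))
#' @rdname LibraryDesign-class
#' @export
setGeneric("coreStart", function(x) standardGeneric("coreStart"))
#' @rdname LibraryDesign-class
#' @export
setGeneric("randomizedRange", function(x) standardGeneric("randomizedRange"))
#' @rdname FrequencyMatrix-class
#' @param x A package object.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname EnrichmentMatrix-class
#' @param x A package object.
#' @export
setGeneric("log2fc", function(x) standardGeneric("log2fc"))
#' @rdname EnrichmentMatrix-class
#' @export
setGeneric("pvalues", function(x) standardGeneric("pvalues"))
#' @rdname PSSM-class
#' @param x A package object.
#' @export
setGeneric("pssmScores", function(x) standardGeneric("pssmScores"))
#' @rdname GibbsSolution-class
#' @param x A package object.
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname GibbsSolution-class
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))
#' @rdname GibbsSolution-class
#' @export
setGeneric("kldByK", function(x) standardGeneric("kldByK"))
#' @rdname GibbsSolution-class
#' @export
setGeneric("outliers", function(x) standardGeneric("outliers"))
#' @rdname SimulatedReadSet-class
#' @param x A package object.
#' @export
setGeneric("readTruth", function(x) standardGeneric("readTruth"))
#' @rdname SimulatedReadSet-class
#' @export
setGeneric("readSequences", function(x) standardGeneric("readSequences"))
#' @rdname SimulatedReadSet-class
#' @export
setGeneric("readQualities", function(x) standardGeneric("readQualities"))
#' @rdname SimulatedReadSet-class
#' @export
setGeneric("selectionRound", function(x) standardGeneric("selectionRound"))

setMethod("peptides", "PeptideTable", function(x) x@peptide)
setMethod("readCounts", "PeptideTable", function(x) {
  m <- x@readCounts
  rownames(m) <- x@peptide
  m
})
setMethod("finalRound", "PeptideTable", function(x)
  structure(x@finalRound, names = x@peptide))
setMethod("designName", "PeptideTable", function(x) x@design)

setMethod("designName", "LibraryDesign", function(x) x@name)
setMethod("peptideLength", "LibraryDesign", function(x)
  nchar(x@flank5Aa) + x@nRandom + nchar(x@flank3Aa))
setMethod("coreStart", "LibraryDesign", function(x) x@coreStart)
setMethod("randomizedRange", "LibraryDesign", function(x)
  c(nchar(x@flank5Aa) + 1L, nchar(x@flank5Aa) + x@nRandom))

setMethod("frequencies", "FrequencyMatrix", function(x) x@freq)
setMethod("frequencies", "EnrichmentMatrix", function(x) x@reference@freq)
setMethod("log2fc", "EnrichmentMatrix", function(x) x@log2fc)
setMethod("pvalues", "EnrichmentMatrix", function(x) x@pvals)
setMethod("pssmScores", "PSSM", function(x) x@scores)

setMethod("assignments", "GibbsSolution", function(x) x@assignments)
setMethod("chosenK", "GibbsSolution", function(x) x@chosenK)
setMethod("kldByK", "GibbsSolution", function(x) x@kldByK)
setMethod("outliers", "GibbsSolution", function(x) x@outliers)

setMethod("readTruth", "SimulatedReadSet", function(x) x@truth)
setMethod("readSequences", "SimulatedReadSet", function(x) x@dna)
setMethod("readQualities", "SimulatedReadSet", function(x) x@qual)
setMethod("selectionRound", "SimulatedReadSet", function(x) x@round)

setMethod("show", "LibraryDesign", function(object) {
  cat("LibraryDesign '", object@name, "': ",
      object@flank5Aa, strrep("X", object@nRandom), object@flank3Aa,
      " (", peptideLength(object), " aa, core at ", object@coreStart, "-",
      object@coreStart + 8L, ", ", length(object@barcodes),
      " round barcodes)\n", sep = "")
})

setMethod("show", "SimulatedReadSet", function(object) {
  cat("SimulatedReadSet: round", object@round, "with",
      length(object@dna), "reads,", length(unique(object@dna)),
      "unique;", sum(object@truth$binder %in% TRUE),
      "truth binder entries\n")
})

setMethod("show", "RawCountTable", function(object) {
  cat("RawCountTable: round", object@round, "-",
      length(object@counts), "unique sequences,",
      sum(object@counts), "reads\n")
})

setMethod("show", "PeptideTable", function(object) {
  cat("PeptideTable (", object@design, "): ", length(object@peptide),
      " unique peptides over rounds ",
      paste(colnames(object@readCounts), collapse = ", "), "\n", sep = "")
  if (length(object@peptide)) {
    tab <- table(factor(object@finalRound,
                        levels = 0:(ncol(object@readCounts) - 1L)))
    cat("  final round: ",
        paste0("r", names(tab), "=", as.integer(tab), collapse = " "), "\n")
  }
})

setMethod("show", "FrequencyMatrix", function(object) {
  cat("FrequencyMatrix:", nrow(object@freq), "positions x 20 residues,",
      object@nPeptides, "unique peptides\n")
})

setMethod("show", "EnrichmentMatrix", function(object) {
  cat("EnrichmentMatrix: round", object@round, "vs unselected;",
      nrow(object@log2fc), "positions; log2fc range [",
      sprintf("%.2f, %.2f", min(object@log2fc), max(object@log2fc)), "];",
      if (length(object@pvals))
        paste(sum(object@pvals < 0.05), "cells significant (adj. p < 0.05)")
      else "no significance computed", "\n")
})

setMethod("show", "PSSM", function(object) {
  cat("PSSM: 9 positions x 20 residues (log2 enrichment, round",
      object@sourceRound, ")\n")
})

setMethod("show", "GibbsSolution", function(object) {
  cat("GibbsSolution: chosen k =", object@chosenK, "over k in {",
      paste(names(object@kldByK), collapse = ", "), "};",
      nrow(object@assignments), "peptides,",
      length(object@outliers), "outliers\n")
})

setMethod("show", "PredictorEnsemble", function(object) {
  cat("PredictorEnsemble:", length(object@members), "members (",
      paste(object@encoding, collapse = "+"), "encoding;",
      if (object@usePFR) "with" else "no", "PFR features);",
      if (length(object@calibration))
        paste0("calibrated on ", length(object@calibration), " peptides")
      else "uncalibrated", "\n")
})

setMethod("show", "BenchmarkSet", function(object) {
  cat("BenchmarkSet:", length(object@positives), "positives,",
      length(object@decoys), "decoys (", object@ratio, ")\n")
})
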