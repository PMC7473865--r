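#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib mhc2display, .registration = TRUE
NULL

#' LibraryDesign: template of one randomized peptide library
#'
#' Describes the fixed flanking residues, the NNK-randomized stretch, the
#' designed 9mer core placement, and the constant DNA context (including the
#' 3C-protease-site-encoding sequence and an allele-identifying polymorphic
#' segment) plus the per-round inline barcodes used for demultiplexing.
#'
#' All positions are 1-based: `coreStart` is the index of the first residue of
#' the designed 9mer core within the full peptide.
#'
#' @slot name Design label.
#' @slot flank5Aa,flank3Aa Fixed N-/C-terminal residues of the peptide.
#' @slot nRandom Number of NNK-randomized residues (9 or 13).
#' @slot coreStart 1-based start of the designed 9mer core.
#' @slot constant5Dna,constant3Dna Constant nucleotide context around the
#'   peptide-encoding region.
#' @slot barcodes Named character vector, round label (e.g. `"r0"`) to inline
#'   barcode nucleotides.
#' @exportClass LibraryDesign
setClass("LibraryDesign", representation(
  name = "character", flank5Aa = "character", nRandom = "integer",
  flank3Aa = "character", coreStart = "integer",
  constant5Dna = "character", constant3Dna = "character",
  barcodes = "character"))

setValidity("LibraryDesign", function(object) {
  len <- nchar(object@flank5Aa) + object@nRandom + nchar(object@flank3Aa)
  msg <- character(0)
  if (!object@nRandom %in% c(9L, 13L))
    msg <- c(msg, "nRandom must be 9 or 13")
  if (object@coreStart + 8L > len)
    msg <- c(msg, "core must fit within the peptide")
  if (object@coreStart < 1L) msg <- c(msg, "coreStart must be >= 1")
  if (anyDuplicated(object@barcodes))
    msg <- c(msg, "barcodes must be unique across rounds")
  if (!grepl("CTGGAAGTTCTGTTTCAGGGTCCG", object@constant3Dna, fixed = TRUE) &&
      !grepl("CTGGAAGTTCTGTTTCAGGGTCCG", object@constant5Dna, fixed = TRUE))
    msg <- c(msg, "constant DNA must contain the 3C-site-encoding sequence")
  if (length(msg)) msg else TRUE
})

#' GroundTruthModel: planted selection model for simulations
#'
#' @slot pssm 9 x 20 matrix of per-position residue scores on the
#'   log2-enrichment scale (positions in rows, residues in [aminoAcids()]
#'   order). The additive score of a 9mer core under this matrix drives
#'   retention during simulated selection.
#' @slot stringency Per-round logistic slopes, strictly positive and
#'   non-decreasing (later rounds at least as stringent).
#' @slot threshold Logistic midpoint: cores scoring at the threshold are
#'   retained with probability 1/2.
#' @slot registerMixture Named probability vector over permissible 1-based
#'   core starts (13mer designs); a single entry for 9mer designs.
#' @exportClass GroundTruthModel
setClass("GroundTruthModel", representation(
  pssm = "matrix", stringency = "numeric", threshold = "numeric",
  registerMixture = "numeric"))

setValidity("GroundTruthModel", function(object) {
  msg <- character(0)
  if (!all(dim(object@pssm) == c(9L, 20L)))
    msg <- c(msg, "pssm must be 9 x 20")
  if (any(object@stringency < 0) || any(diff(object@stringency) < 0))
    msg <- c(msg, "stringency must be non-negative and non-decreasing")
  if (abs(sum(object@registerMixture) - 1) > 1e-8)
    msg <- c(msg, "registerMixture must sum to 1")
  if (length(msg)) msg else TRUE
})

#' SimulatedReadSet: reads from one simulated selection round
#'
#' @slot round Selection round (0 = unselected library).
#' @slot dna,qual Parallel character vectors of read sequences and Phred-33
#'   quality strings.
#' @slot truth data.frame keyed by `dna` with the error-free parent, the true
#'   peptide, its true core start and binder flag.
#' @exportClass SimulatedReadSet
setClass("SimulatedReadSet", representation(
  round = "integer", dna = "character", qual = "character",
  truth = "data.frame"))

setValidity("SimulatedReadSet", function(object) {
  msg <- character(0)
  if (length(object@dna) != length(object@qual))
    msg <- c(msg, "dna and qual must be parallel")
  if (length(object@dna) && any(nchar(object@dna) != nchar(object@qual)))
    msg <- c(msg, "per-read sequence and quality lengths must match")
  if (!all(unique(object@dna) %in% object@truth$dna))
    msg <- c(msg, "truth must cover every emitted read")
  if (length(msg)) msg else TRUE
})

#' RawCountTable: per-round unique peptide-encoding DNA counts
#'
#' @slot round Selection round the counts belong to.
#' @slot counts Named integer vector, peptide-encoding DNA to read count.
#' @exportClass RawCountTable
setClass("RawCountTable", representation(round = "integer",
                                         counts = "integer"))

setValidity("RawCountTable", function(object) {
  msg <- character(0)
  if (length(object@counts)) {
    if (length(unique(nchar(names(object@counts)))) > 1L)
      msg <- c(msg, "all dna keys must have identical length")
    if (any(object@counts < 1L)) msg <- c(msg, "counts must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' PeptideTable: unique peptides with per-round read counts
#'
#' @slot peptide Unique peptide sequences (no stop symbol).
#' @slot readCounts Integer matrix, one row per peptide, columns `r0 ... rR`.
#' @slot finalRound Highest round in which each peptide was observed.
#' @slot design Name of the [LibraryDesign-class] the table derives from.
#' @exportClass PeptideTable
setClass("PeptideTable", representation(
  peptide = "character", readCounts = "matrix", finalRound = "integer",
  design = "character"))

setValidity("PeptideTable", function(object) {
  msg <- character(0)
  if (nrow(object@readCounts) != length(object@peptide))
    msg <- c(msg, "readCounts rows must match peptides")
  if (length(object@finalRound) != length(object@peptide))
    msg <- c(msg, "finalRound must match peptides")
  if (any(grepl("*", object@peptide, fixed = TRUE)))
    msg <- c(msg, "peptides must not contain a stop symbol")
  if (length(object@peptide)) {
    fr <- apply(object@readCounts > 0L, 1L, function(p) max(which(p)) - 1L)
    if (!identical(as.integer(fr), object@finalRound))
      msg <- c(msg, "finalRound inconsistent with per-round presence")
  }
  if (length(msg)) msg else TRUE
})

#' FrequencyMatrix: positional residue percentages
#'
#' @slot freq Position x 20 matrix of percentages; each row sums to 100.
#' @slot nPeptides Number of unique peptides the matrix summarizes.
#' @exportClass FrequencyMatrix
setClass("FrequencyMatrix", representation(freq = "matrix",
                                           nPeptides = "integer"))

setValidity("FrequencyMatrix", function(object) {
  msg <- character(0)
  if (ncol(object@freq) != 20L) msg <- c(msg, "freq must have 20 columns")
  if (any(object@freq < 0)) msg <- c(msg, "frequencies must be >= 0")
  if (any(abs(rowSums(object@freq) - 100) > 1e-6))
    msg <- c(msg, "each position must sum to 100%")
  if (length(msg)) msg else TRUE
})

#' EnrichmentMatrix: positional log2-fold enrichment vs the unselected library
#'
#' @slot log2fc Position x 20 matrix of log2-fold enrichments (finite
#'   everywhere by pseudocount).
#' @slot pvals Bonferroni-adjusted p-value matrix (same shape), or a 0 x 0
#'   matrix if significance was not computed.
#' @slot reference The unselected-library [FrequencyMatrix-class].
#' @slot round Selection round of the numerator frequencies.
#' @exportClass EnrichmentMatrix
setClass("EnrichmentMatrix", representation(
  log2fc = "matrix", pvals = "matrix", reference = "FrequencyMatrix",
  round = "integer"))

setValidity("EnrichmentMatrix", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@log2fc)))
    msg <- c(msg, "log2fc must be finite everywhere")
  if (length(object@pvals) &&
      (any(object@pvals <= 0) || any(object@pvals > 1)))
    msg <- c(msg, "adjusted p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' PSSM: 9-position position-specific scoring matrix
#'
#' Log2-fold-enrichment values transferred without positional weighting;
#' stored positions-in-rows (9 x 20, residues in [aminoAcids()] order).
#'
#' @slot scores 9 x 20 numeric matrix.
#' @slot sourceRound Selection round the enrichment derives from.
#' @exportClass PSSM
setClass("PSSM", representation(scores = "matrix", sourceRound = "integer"))

setValidity("PSSM", function(object) {
  msg <- character(0)
  if (!all(dim(object@scores) == c(9L, 20L)))
    msg <- c(msg, "PSSM requires 9 positions")
  if (!all(is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  if (length(msg)) msg else TRUE
})

#' GibbsSolution: register deconvolution by Gibbs-sampling clustering
#'
#' @slot assignments data.frame with columns `peptide`, `cluster`, `offset`
#'   (1-based core start), `score`; outlier peptides carry cluster `NA`.
#' @slot clusterPssms List of per-cluster log-odds matrices
#'   (motif length x 20).
#' @slot kldByK Mean Kullback-Leibler distance of the best solution at each
#'   candidate cluster count.
#' @slot chosenK Cluster count maximizing `kldByK`.
#' @slot outliers Peptides below the trash threshold.
#' @slot background Data-derived residue background used by the sampler.
#' @slot trashThreshold Log-odds trash threshold (`NA` when outlier removal
#'   was disabled).
#' @exportClass GibbsSolution
setClass("GibbsSolution", representation(
  assignments = "data.frame", clusterPssms = "list", kldByK = "numeric",
  chosenK = "integer", outliers = "character", background = "numeric",
  trashThreshold = "numeric"))

setValidity("GibbsSolution", function(object) {
  msg <- character(0)
  if (length(object@kldByK) &&
      object@chosenK != as.integer(names(which.max(object@kldByK))))
    msg <- c(msg, "chosenK must maximize kldByK")
  if (length(msg)) msg else TRUE
})

#' PredictorEnsemble: round-weighted neural-network binding predictor
#'
#' An NN-Align-style ensemble of single-hidden-layer networks. Each member
#' scans all 9mer core windows of a peptide and scores the best one; the
#' ensemble prediction is the mean member output in [0, 1].
#'
#' @slot members List of trained members (weights, encoding id, hidden width,
#'   cross-validation partition, seed).
#' @slot encoding Encoding scheme(s) used: subset of `sparse`, `blosum50`.
#' @slot usePFR Whether flank summary features are included (libraries whose
#'   peptides exceed the 9mer core).
#' @slot config Training configuration (see [trainingConfig()]).
#' @slot calibration Sorted score sample over random background peptides used
#'   for percent ranks (empty until [calibrateEnsemble()] is run).
#' @slot calibrationSeed Seed of the calibration peptide draw.
#' @exportClass PredictorEnsemble
setClass("PredictorEnsemble", representation(
  members = "list", encoding = "character", usePFR = "logical",
  config = "list", calibration = "numeric", calibrationSeed = "integer"))

setValidity("PredictorEnsemble", function(object) {
  msg <- character(0)
  if (!length(object@members)) msg <- c(msg, "empty ensemble")
  if (length(object@calibration) && is.unsorted(object@calibration))
    msg <- c(msg, "rank calibration must be sorted ascending")
  if (length(msg)) msg else TRUE
})

#' BenchmarkSet: positives plus matched decoys at a fixed ratio
#'
#' @slot positives,decoys Peptide vectors.
#' @slot ratio `"1:1"` or `"1:19"` (decoys per positive).
#' @slot provenance Free-text source labels.
#' @exportClass BenchmarkSet
setClass("BenchmarkSet", representation(
  positives = "character", decoys = "character", ratio = "character",
  provenance = "character"))

setValidity("BenchmarkSet", function(object) {
  msg <- character(0)
  mult <- as.integer(sub("^1:", "", object@ratio))
  if (!object@ratio %in% c("1:1", "1:19"))
    msg <- c(msg, "ratio must be 1:1 or 1:19")
  else if (length(object@decoys) != mult * length(object@positives))
    msg <- c(msg, "decoy/positive count must match the ratio exactly")
  if (length(msg)) msg else TRUE
})
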