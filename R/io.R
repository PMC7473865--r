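## File interfaces: FASTQ, TSV tables, JSON design/model descriptions.

#' Write a simulated read set as FASTQ plus truth map
#'
#' Writes standard 4-line Phred-33 FASTQ named
#' `{design}_round{r}.fastq` and a tab-separated truth map
#' (`dna, parent, peptide, core_start, binder`).
#'
#' @param reads A [SimulatedReadSet-class].
#' @param dir Output directory (created if needed).
#' @param design The [LibraryDesign-class] (names the files).
#' @return Invisibly, the FASTQ path.
#' @export
writeReadSet <- function(reads, dir, design) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- selectionRound(reads)
  fq <- file.path(dir, sprintf("%s_round%d.fastq", designName(design), r))
  dna <- readSequences(reads)
  ## benign warning: QualityScaledDNAStringSet drops (empty) mcols
  x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(dna),
    Biostrings::PhredQuality(readQualities(reads))))
  names(x) <- sprintf("read%06d_r%d", seq_along(dna), r)
  Biostrings::writeQualityScaledXStringSet(x, fq)
  truth <- readTruth(reads)
  names(truth)[names(truth) == "coreStart"] <- "core_start"
  utils::write.table(truth,
                     file.path(dir, sprintf("%s_round%d_truth.tsv",
                                            designName(design), r)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fq)
}

#' Read Phred-33 FASTQ into parallel sequence/quality vectors
#'
#' @param path FASTQ file.
#' @return List with character vectors `dna` and `qual`.
#' @export
readFastqReads <- function(path) {
  ## benign warning: empty mcols dropped during construction
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(dna = unname(as.character(x)),
       qual = unname(as.character(Biostrings::quality(x))))
}

#' Write / read a peptide table as TSV
#'
#' Columns: `peptide`, `reads_r0 ... reads_rR`, `final_round`.
#'
#' @param table A [PeptideTable-class].
#' @param path Output/input TSV path.
#' @return `writePeptideTable` invisibly returns `path`;
#'   `readPeptideTable` returns a [PeptideTable-class].
#' @export
writePeptideTable <- function(table, path) {
  m <- readCounts(table)
  df <- data.frame(peptide = peptides(table), m, check.names = FALSE)
  names(df)[-1L] <- paste0("reads_", colnames(m))
  df$final_round <- finalRound(table)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePeptideTable
#' @param design Design name recorded in the table.
#' @export
readPeptideTable <- function(path, design = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  rc <- as.matrix(df[grep("^reads_", names(df))])
  colnames(rc) <- sub("^reads_", "", colnames(rc))
  storage.mode(rc) <- "integer"
  new("PeptideTable", peptide = df$peptide, readCounts = rc,
      finalRound = as.integer(df$final_round), design = design)
}

#' Serialize a design or model to JSON
#'
#' @param x A [LibraryDesign-class] or [GroundTruthModel-class].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
writeDesignJson <- function(x, path) {
  obj <- if (is(x, "LibraryDesign")) {
    list(name = x@name, flank5_aa = x@flank5Aa, n_random = x@nRandom,
         flank3_aa = x@flank3Aa, core_start = x@coreStart,
         constant5_dna = x@constant5Dna, constant3_dna = x@constant3Dna,
         barcode_by_round = as.list(x@barcodes))
  } else if (is(x, "GroundTruthModel")) {
    list(pssm = x@pssm, stringency_by_round = x@stringency,
         score_threshold = x@threshold,
         register_mixture = as.list(x@registerMixture))
  } else stop("unsupported object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
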