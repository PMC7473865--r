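des9 <- builtinDesign("dr401_9mer")

## build a fully valid read for a design, then perturb it per test
validRead <- function(design, rand = strrep("GCG", design@nRandom),
                      round = "r0") {
  pep <- paste0(mhc2display:::flankDna(design@flank5Aa), rand,
                mhc2display:::flankDna(design@flank3Aa))
  paste0(design@barcodes[[round]], design@constant5Dna, pep,
         design@constant3Dna)
}

test_that("filter cascade enforces length, constants, quality and NNK", {
  r <- validRead(des9)
  hi <- strrep("I", nchar(r))
  keepCount <- function(dna, qual) {
    tabs <- filterReads(list(dna = dna, qual = qual), des9)
    sum(vapply(tabs, function(t) sum(t@counts), integer(1)))
  }
  expect_equal(keepCount(r, hi), 1L)

  ## one peptide-encoding base at Phred 19 ('4' = 33 + 19) -> discarded
  pepFrom <- nchar(des9@barcodes[[1]]) + nchar(des9@constant5Dna) + 1L
  q19 <- hi
  substr(q19, pepFrom + 5L, pepFrom + 5L) <- "4"
  expect_equal(keepCount(r, q19), 0L)
  ## Phred 20 ('5') is kept
  q20 <- hi
  substr(q20, pepFrom + 5L, pepFrom + 5L) <- "5"
  expect_equal(keepCount(r, q20), 1L)
  ## low quality outside the peptide region does not matter
  qout <- hi
  substr(qout, 1L, 1L) <- "!"
  expect_equal(keepCount(r, qout), 1L)

  ## NNK violation: randomized codon ending in A discarded, ATG kept
  rATA <- validRead(des9, paste0("ATA", strrep("GCG", 8)))
  rATG <- validRead(des9, paste0("ATG", strrep("GCG", 8)))
  expect_equal(keepCount(rATA, hi), 0L)
  expect_equal(keepCount(rATG, hi), 1L)

  ## one nucleotide short -> discarded
  short <- substr(r, 1L, nchar(r) - 1L)
  expect_equal(keepCount(short, substr(hi, 1L, nchar(r) - 1L)), 0L)

  ## constant-region mismatch -> discarded
  bad <- r
  substr(bad, pepFrom - 2L, pepFrom - 2L) <-
    setdiff(c("A", "C", "G", "T"),
            substr(bad, pepFrom - 2L, pepFrom - 2L))[1]
  expect_equal(keepCount(bad, hi), 0L)

  ## unknown barcode: counted in the attrition report, not kept
  unk <- r
  substr(unk, 1L, 6L) <- "NNNNNN"
  tabs <- filterReads(list(dna = unk, qual = hi), des9)
  expect_equal(attr(tabs, "attrition")$barcode, 1L)

  ## barcode routes reads to their round
  r3 <- validRead(des9, round = "r3")
  tabs <- filterReads(list(dna = c(r, r3, r3), qual = c(hi, hi, hi)), des9)
  expect_equal(sum(tabs$r0@counts), 1L)
  expect_equal(sum(tabs$r3@counts), 2L)

  expect_error(filterReads(list(dna = r, qual = "II"), des9),
               "malformed FASTQ record")
})

test_that("error collapse removes close children of prevalent parents", {
  tab <- function(counts) new("RawCountTable", round = 0L,
                              counts = as.integer(counts) |>
                                stats::setNames(names(counts)))
  base <- strrep("A", 12)
  h1 <- paste0("C", strrep("A", 11))
  ## a 3-read Hamming-1 child of a 10,000-read parent is discarded
  out <- collapseErrors(tab(c(`AAAAAAAAAAAA` = 10000, `CAAAAAAAAAAA` = 3)))
  expect_identical(names(out@counts), base)
  ## a single unique sequence is retained unchanged
  one <- collapseErrors(tab(c(`AAAAAAAAAAAA` = 5)))
  expect_equal(unname(one@counts), 5L)
  ## Hamming 3 at count ratio 50: below both the 100x and 10,000x gates
  h3 <- paste0("CCC", strrep("A", 9))
  out <- collapseErrors(tab(stats::setNames(c(5000, 100), c(base, h3))))
  expect_equal(length(out@counts), 2L)
  ## Hamming 2 at ratio >= 100 is discarded
  h2 <- paste0("CC", strrep("A", 10))
  out <- collapseErrors(tab(stats::setNames(c(10000, 100), c(base, h2))))
  expect_identical(names(out@counts), base)
  ## equal counts never discard each other
  out <- collapseErrors(tab(stats::setNames(c(7, 7), c(base, h1))))
  expect_equal(length(out@counts), 2L)
})

test_that("greedy collapse equals the brute-force oracle on random tables", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    L <- 12L
    ## low-cardinality alphabet draws force many near neighbors
    seqs <- unique(replicate(n, paste0(
      sample(c("A", "C", "G", "T"), L, replace = TRUE,
             prob = c(0.7, 0.1, 0.1, 0.1)), collapse = "")))
    counts <- stats::setNames(
      as.integer(round(10^stats::runif(length(seqs), 0, 4.5))), seqs)
    got <- collapseErrors(new("RawCountTable", round = 0L, counts = counts))
    expect_identical(got@counts, collapseOracle(counts))
  }
})

test_that("all-comparators collapse is stricter on discard chains", {
  ## b is absorbed by a; c is Hamming-1 from b only: retained-only keeps c,
  ## all-comparators drops it
  seqs <- c(a = "AAAAAAAAAAAA", b = "CAAAAAAAAAAA", c = "CCAAAAAAAAAA")
  counts <- stats::setNames(c(100L, 99L, 98L), unname(seqs))
  t0 <- new("RawCountTable", round = 0L, counts = counts)
  kept <- names(collapseErrors(t0, compare = "retained")@counts)
  expect_setequal(kept, unname(seqs[c("a", "c")]))
  keptAll <- names(collapseErrors(t0, compare = "all")@counts)
  expect_identical(keptAll, unname(seqs["a"]))
})

test_that("translation merges synonymous DNA and drops stop codons", {
  mk <- function(...) {
    x <- c(...)
    new("RawCountTable", round = 0L,
        counts = stats::setNames(as.integer(x), names(x)))
  }
  ## CTG and TTG both encode Leu: one row, counts summed
  tabs <- list(r0 = mk(c(CTG = 5, TTG = 7, ATG = 2)))
  pt <- translateAndTabulate(tabs, des9)
  expect_setequal(peptides(pt), c("L", "M"))
  expect_equal(unname(readCounts(pt)[match("L", peptides(pt)), 1]), 12L)
  ## a TAG-containing region is dropped
  pt <- translateAndTabulate(list(r0 = mk(c(TAGGCG = 4, GCGGCG = 1))), des9)
  expect_identical(peptides(pt), "AA")
  ## standard-genetic-code translation
  pt <- translateAndTabulate(list(r0 = mk(c(ATGGCT = 1))), des9)
  expect_identical(peptides(pt), "MA")
  expect_error(translateAndTabulate(list(r0 = mk(c(AT = 1))), des9),
               "frame error")
  ## final round reflects the last round of observation
  tabs <- list(r0 = mk(c(GCG = 3)),
               r1 = new("RawCountTable", round = 1L,
                        counts = c(GCG = 2L, TGG = 1L)))
  pt <- translateAndTabulate(tabs, des9)
  fr <- finalRound(pt)
  expect_equal(unname(fr[match(c("A", "W"), peptides(pt))]), c(1L, 1L))
})

test_that("pipeline conserves reads and never invents peptides", {
  sim <- smallSim()
  att <- attr(filterReads(sim$rounds, sim$design), "attrition")
  expect_lte(att$kept, att$input)
  stages <- c(att$length, att$constant, att$barcode, att$quality, att$nnk)
  expect_equal(att$kept + sum(stages), att$input)
  ## every reported peptide existed among the error-free truth peptides or
  ## arises from a surviving corrupted read; none is invented from nothing
  inputDna <- unlist(lapply(sim$rounds, function(r) readTruth(r)$dna))
  pepFrom <- nchar(sim$design@barcodes[[1]]) +
    nchar(sim$design@constant5Dna) + 1L
  inputPep <- unique(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(substr(inputDna, pepFrom, pepFrom + 44L)),
    no.init.codon = TRUE)))
  expect_true(all(peptides(sim$pt) %in% inputPep))
})

test_that("error-injected pipeline recovers parents and removes children", {
  ## evaluated on the final selected round: there parent prevalence makes
  ## the tiered collapse active (in the naive round all counts are 1 and
  ## the rule cannot fire by construction)
  sim <- smallSim()
  tr5 <- readTruth(sim$rounds$r5)
  parents <- unique(tr5$peptide[tr5$dna == tr5$parent &
                                  !grepl("*", tr5$peptide, fixed = TRUE)])
  r5pep <- peptides(sim$pt)[readCounts(sim$pt)[, "r5"] > 0]
  expect_gte(mean(parents %in% r5pep), 0.99)

  ## error children at the DNA level: corrupted reads that survive filters
  kept5 <- names(sim$tables$r5@counts)
  childDna <- unique(tr5$dna[tr5$dna != tr5$parent])
  pepFrom <- nchar(sim$design@barcodes[[1]]) +
    nchar(sim$design@constant5Dna) + 1L
  childPep <- unique(substr(childDna, pepFrom, pepFrom + 44L))
  childPep <- setdiff(childPep,
                      substr(tr5$dna[tr5$dna == tr5$parent], pepFrom,
                             pepFrom + 44L))
  expect_gte(mean(!childPep %in% kept5), 0.95)
})
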