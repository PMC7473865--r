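## Synthetic NNK selection simulator: a no-download test surface with known
## answers for every downstream stage.

#' Construct a ground-truth selection model
#'
#' @param pssm 9 x 20 score matrix (positions x residues, [aminoAcids()]
#'   order) on the log2-enrichment scale.
#' @param stringency Per-round logistic slopes (non-decreasing).
#' @param threshold Logistic midpoint; cores at the threshold are retained
#'   with probability 1/2.
#' @param registerMixture Named probabilities over permissible 1-based core
#'   starts; must sum to 1.
#' @return A [GroundTruthModel-class].
#' @export
groundTruthModel <- function(pssm, stringency, threshold, registerMixture) {
  colnames(pssm) <- AA20
  rownames(pssm) <- paste0("P", 1:9)
  new("GroundTruthModel", pssm = pssm, stringency = as.numeric(stringency),
      threshold = as.numeric(threshold),
      registerMixture = registerMixture / sum(registerMixture))
}

#' Default planted binding model for a design
#'
#' A DR401-flavoured planted motif on the log2-enrichment scale: favored
#' anchor residues carry positive scores (P1 large hydrophobics, P4 acidics,
#' P6 polars, P9 small residues plus Cys, a weak auxiliary P7 preference) and
#' disfavored anchor residues negative ones. The selection threshold is
#' placed at an upper quantile of the exact naive NNK core-score
#' distribution, computed by convolving the per-position score distributions,
#' so the planted binder fraction is a controlled property of the model
#' rather than of a particular sample.
#'
#' The anchor sets are chosen with comparable aggregate NNK codon mass
#' (roughly a quarter of draws each), so every anchor position contributes
#' comparably to selection and its planted preferences are recoverable from
#' realized enrichments; pocket-set sizes otherwise mirror the allele's
#' character.
#'
#' @param design A [LibraryDesign-class]; determines the permissible register
#'   mixture (a point mass for 9mer designs, centrally-peaked for 13mers).
#' @param binderQuantile Naive-score quantile at which the logistic midpoint
#'   sits (default 0.95: about 5\% of naive cores are binders).
#' @param stringency Per-round logistic slopes.
#' @param centralWeight Probability mass on the designed central register for
#'   13mer designs; the remainder is spread uniformly over shifted registers.
#' @return A [GroundTruthModel-class].
#' @export
defaultGroundTruth <- function(design, binderQuantile = 0.95,
                               stringency = c(1, 1.25, 1.5, 1.75, 2),
                               centralWeight = 0.6) {
  pssm <- matrix(0, 9L, 20L, dimnames = list(paste0("P", 1:9), AA20))
  anchor <- function(pos, fav, up, down) {
    pssm[pos, ] <<- down
    pssm[pos, fav] <<- up
  }
  anchor(1L, c("F", "I", "L", "M", "V", "W", "Y"), 1.5, -1.5)
  anchor(4L, c("D", "E", "Q", "N"), 2, -1.5)
  anchor(6L, c("N", "S", "T", "D"), 1.5, -1.5)
  anchor(9L, c("A", "G", "S", "C"), 1.5, -1.5)
  pssm[7L, c("N", "P")] <- 0.75
  thr <- naiveScoreQuantile(pssm, binderQuantile)
  starts <- permissibleCoreStarts(design)
  mix <- if (length(starts) == 1L) 1 else {
    w <- rep((1 - centralWeight) / (length(starts) - 1L), length(starts))
    w[starts == design@coreStart] <- centralWeight
    w
  }
  names(mix) <- starts
  groundTruthModel(pssm, stringency, thr, mix)
}

## exact quantile of the additive core score of a random NNK 9mer:
## convolve the nine per-position discrete score distributions
naiveScoreQuantile <- function(pssm, q) {
  bg <- nnkFrequencies()[AA20]
  dist <- c("0" = 1)
  for (p in 1:9) {
    vals <- round(pssm[p, ], 9)
    step <- tapply(bg, vals, sum)
    new <- outer(as.numeric(names(dist)), as.numeric(names(step)), `+`)
    pr <- outer(dist, step)
    dist <- tapply(as.vector(pr), round(as.vector(new), 6), sum)
  }
  s <- as.numeric(names(dist))
  cdf <- cumsum(dist[order(s)])
  sort(s)[which(cdf >= q)[1L]]
}

#' Sample an unselected NNK library
#'
#' Randomized codons are drawn by uniform sampling of N in \{A,C,G,T\} and K
#' in \{G,T\} per position, so codon usage carries the natural NNK redundancy
#' (e.g. Leu with 3 codons appears about three times as often as Met with 1;
#' the amber stop TAG occurs at 1/32 per codon and is removed downstream).
#' Fixed flank residues use a single canonical codon each. Reads carry the
#' round-0 barcode, the constant DNA context, and uniformly high qualities
#' (errors are added separately with [injectErrors()]).
#'
#' @param design A [LibraryDesign-class].
#' @param n Number of reads.
#' @param seed Integer seed; sampling is bit-reproducible.
#' @return A [SimulatedReadSet-class] with `round = 0`.
#' @export
sampleNaive <- function(design, n, seed = 1L) {
  stopifnot(n >= 1)
  withr_seed(seed)
  n <- as.integer(n)
  rand <- vapply(seq_len(design@nRandom), function(i)
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
           sample(c("A", "C", "G", "T"), n, replace = TRUE),
           sample(c("G", "T"), n, replace = TRUE)),
    character(n))
  if (!is.matrix(rand)) rand <- matrix(rand, nrow = n)
  pepDna <- paste0(flankDna(design@flank5Aa),
                   do.call(paste0, asplit(rand, 2L)),
                   flankDna(design@flank3Aa))
  dna <- paste0(design@barcodes[["r0"]], design@constant5Dna, pepDna,
                design@constant3Dna)
  qual <- strrep("I", nchar(dna[1L]))
  u <- !duplicated(dna)
  pep <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(pepDna[u]), no.init.codon = TRUE))
  truth <- data.frame(dna = dna[u], parent = dna[u], peptide = pep,
                      coreStart = design@coreStart, binder = NA,
                      stringsAsFactors = FALSE)
  new("SimulatedReadSet", round = 0L, dna = dna,
      qual = rep(qual, n), truth = truth)
}

## swap the inline barcode at the start of each read
swapBarcode <- function(dna, design, round) {
  bc <- design@barcodes[[paste0("r", round)]]
  paste0(bc, substr(dna, nchar(bc) + 1L, nchar(dna)))
}

## additive truth score of the core at a given 1-based start within the
## full peptide
truthCoreScore <- function(peptide, start, pssm) {
  m <- peptideMatrix(substr(peptide, start, start + 8L))
  idx <- matrix(match(m, AA20), nrow(m))
  sc <- numeric(nrow(m))
  for (p in 1:9) sc <- sc + pssm[p, ][idx[, p]]
  sc
}

#' Simulate iterative rounds of selection
#'
#' Each round, reads survive with retention probability
#' `plogis(stringency[r] * (coreScore - threshold))`, where the core score is
#' the additive planted-PSSM score at the peptide's true register (the
#' designed register for 9mer designs; a mixture-drawn register, fixed per
#' peptide, for 13mer designs). Survivors are resampled with replacement to
#' `carryover` reads, emulating regrowth after each sort. Stop-codon clones
#' (amber TAG at an NNK site) score as non-binders. Every peptide present in
#' round r+1 existed in round r.
#'
#' For multi-register (13mer) designs each peptide's candidate register is
#' drawn once from the model's register mixture; it becomes the peptide's
#' true register unless another permissible window outscores it by more than
#' `registerStickiness`, in which case that window does. The stickiness
#' margin stands in for register preferences outside the 9mer core that the
#' core PSSM cannot express; it keeps true register labels consistent with
#' the sequence signal while the mixture still shapes register diversity.
#'
#' @param naive A round-0 [SimulatedReadSet-class] from [sampleNaive()].
#' @param model A [GroundTruthModel-class].
#' @param design The [LibraryDesign-class] the naive set was sampled from.
#' @param nRounds Number of selection rounds (stringency is recycled or
#'   truncated to this length).
#' @param carryover Reads per round after regrowth.
#' @param registerStickiness Score margin by which a shifted window must
#'   beat the mixture-drawn register to claim the peptide.
#' @param seed Integer seed.
#' @return Named list of [SimulatedReadSet-class]: `r0` (the naive set with
#'   truth annotated under the model) followed by `r1 ... rN`.
#' @export
simulateSelection <- function(naive, model, design, nRounds = 5L,
                              carryover = 1e5, registerStickiness = 1.5,
                              seed = 1L) {
  if (!length(readSequences(naive))) stop("no peptides to select")
  stopifnot(nRounds >= 1)
  withr_seed(seed)
  nRounds <- as.integer(nRounds)
  stringency <- rep_len(model@stringency, nRounds)

  truth <- readTruth(naive)
  ## fixed true register per unique peptide: mixture-drawn, then overruled
  ## by any window that beats it by more than the stickiness margin
  upep <- unique(truth$peptide)
  starts <- as.integer(names(model@registerMixture))
  regOf <- structure(
    if (length(starts) == 1L) rep(starts, length(upep))
    else sample(starts, length(upep), replace = TRUE,
                prob = model@registerMixture),
    names = upep)
  truth$coreStart <- regOf[truth$peptide]
  hasStop <- grepl("*", truth$peptide, fixed = TRUE)
  score <- rep(-1e9, nrow(truth))  # finite sentinel: stop clones never bind
  if (length(starts) > 1L) {
    sc <- vapply(starts, function(s)
      truthCoreScore(truth$peptide[!hasStop], s, model@pssm),
      numeric(sum(!hasStop)))
    sc <- matrix(sc, ncol = length(starts))
    drawn <- match(truth$coreStart[!hasStop], starts)
    sticky <- sc
    sticky[cbind(seq_len(nrow(sc)), drawn)] <-
      sticky[cbind(seq_len(nrow(sc)), drawn)] + registerStickiness
    best <- max.col(sticky, ties.method = "first")
    truth$coreStart[!hasStop] <- starts[best]
    score[!hasStop] <- sc[cbind(seq_len(nrow(sc)), best)]
  } else {
    score[!hasStop] <- truthCoreScore(truth$peptide[!hasStop],
                                      truth$coreStart[!hasStop], model@pssm)
  }
  truth$binder <- score >= model@threshold & !hasStop
  naive@truth <- truth

  counts <- table(factor(readSequences(naive), levels = truth$dna))
  counts <- as.integer(counts)
  out <- list(r0 = naive)
  qual1 <- strrep("I", nchar(truth$dna[1L]))
  for (r in seq_len(nRounds)) {
    p <- stats::plogis(stringency[r] * (score - model@threshold))
    surv <- stats::rbinom(length(counts), counts, p)
    if (!sum(surv)) stop("no peptides to select")
    idx <- sample.int(length(surv), carryover, replace = TRUE,
                      prob = surv / sum(surv))
    counts <- tabulate(idx, nbins = length(surv))
    keep <- counts > 0L
    rtruth <- truth[keep, , drop = FALSE]
    rtruth$dna <- swapBarcode(rtruth$dna, design, r)
    rtruth$parent <- rtruth$dna
    dna <- rep(rtruth$dna, counts[keep])
    out[[paste0("r", r)]] <- new("SimulatedReadSet", round = r, dna = dna,
                                 qual = rep(qual1, length(dna)),
                                 truth = rtruth)
  }
  out
}

#' Inject substitution errors and low-quality bases
#'
#' Emulates PCR and sequencing artifacts: each base is substituted
#' independently with probability `subRate` (to one of the three other
#' nucleotides), and an independent `lowQFraction` of bases is assigned a
#' Phred score below 20 (the only quality distinction the downstream filter
#' uses). The truth map records the error-free parent of every corrupted
#' read.
#'
#' @param reads A [SimulatedReadSet-class].
#' @param subRate Per-base substitution probability.
#' @param lowQFraction Per-base probability of a Phred score below 20.
#' @param seed Integer seed.
#' @return A [SimulatedReadSet-class] with corrupted reads and an extended
#'   truth map.
#' @export
injectErrors <- function(reads, subRate, lowQFraction = 0, seed = 1L) {
  stopifnot(subRate >= 0, subRate <= 1, lowQFraction >= 0, lowQFraction <= 1)
  dna <- readSequences(reads)
  if (subRate == 0 && lowQFraction == 0) return(reads)
  withr_seed(seed)
  n <- length(dna)
  L <- nchar(dna[1L])
  m <- peptideMatrix(dna)
  nMut <- stats::rbinom(1L, n * L, subRate)
  if (nMut > 0L) {
    at <- sample.int(n * L, nMut)
    old <- m[at]
    alt <- c("A", "C", "G", "T")
    m[at] <- vapply(old, function(b) sample(setdiff(alt, b), 1L),
                    character(1))
  }
  newdna <- do.call(paste0, asplit(m, 2L))
  qual <- rep(strrep("I", L), n)
  nLow <- stats::rbinom(1L, n * L, lowQFraction)
  if (nLow > 0L) {
    qm <- matrix("I", n, L)
    qm[sample.int(n * L, nLow)] <- "+"  # Phred 10
    qual <- do.call(paste0, asplit(qm, 2L))
  }
  parent <- readTruth(reads)
  pidx <- match(dna, parent$dna)
  u <- !duplicated(newdna)
  truth <- data.frame(dna = newdna[u], parent = parent$dna[pidx[u]],
                      peptide = parent$peptide[pidx[u]],
                      coreStart = parent$coreStart[pidx[u]],
                      binder = parent$binder[pidx[u]],
                      stringsAsFactors = FALSE)
  new("SimulatedReadSet", round = selectionRound(reads), dna = newdna,
      qual = qual, truth = truth)
}
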