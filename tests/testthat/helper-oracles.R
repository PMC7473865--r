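## Independent brute-force oracles and shared fixtures (built in code).

AA <- aminoAcids()

hammingDist <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## O(n^2) all-pairs oracle for the tiered Hamming error collapse
## (retained-only comparators, descending count, lexicographic ties)
collapseOracle <- function(counts) {
  ord <- order(-counts, names(counts), method = "radix")
  seqs <- names(counts)[ord]
  cnt <- as.numeric(counts[ord])
  keep <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    drop <- FALSE
    for (j in seq_len(i - 1L)) {
      if (!keep[j] || cnt[j] <= cnt[i]) next
      d <- hammingDist(seqs[i], seqs[j])
      if (d <= 1 ||
          (d <= 2 && cnt[j] >= 100 * cnt[i]) ||
          (d <= 3 && cnt[j] >= 10000 * cnt[i])) {
        drop <- TRUE
        break
      }
    }
    keep[i] <- !drop
  }
  out <- counts[ord][keep]
  out[order(names(out), method = "radix")]
}

## exhaustive window-scoring oracle for register assignment
registerOracle <- function(peptide, pssm, expectedStart) {
  s <- pssmScores(pssm)
  nWin <- nchar(peptide) - 8L
  sc <- vapply(seq_len(nWin), function(o) {
    core <- strsplit(substr(peptide, o, o + 8L), "")[[1]]
    sum(vapply(1:9, function(p) s[p, core[p]], numeric(1)))
  }, numeric(1))
  mx <- max(sc)
  at <- which(sc == mx)
  best <- if (expectedStart %in% at) expectedStart else at[1L]
  list(best = best, score = mx)
}

## random peptides with a planted categorical motif at a fixed offset
plantedMotifPeptides <- function(n, len, anchors, offset = 0L, seed = 1L) {
  set.seed(seed)
  m <- matrix(sample(AA, n * len, replace = TRUE), n, len)
  for (p in names(anchors))
    m[, offset + as.integer(p)] <- sample(anchors[[p]], n, replace = TRUE)
  apply(m, 1L, paste0, collapse = "")
}

motifA <- list(`1` = c("F", "I", "L"), `4` = c("D", "E"),
               `6` = c("S", "T"), `9` = c("A", "G"))
motifB <- list(`1` = c("K", "R"), `4` = c("W", "Y"),
               `6` = c("P", "G"), `9` = c("E", "D"))

## ---- cached small end-to-end simulation (shared across test files) ----

.cache <- new.env(parent = emptyenv())

smallSim <- function() {
  if (!is.null(.cache$sim)) return(.cache$sim)
  des <- builtinDesign("dr401_9mer")
  model <- defaultGroundTruth(des)
  naive <- sampleNaive(des, 2e4, seed = 101)
  rounds <- simulateSelection(naive, model, des, nRounds = 5,
                              carryover = 2e4, seed = 102)
  rounds <- lapply(rounds, injectErrors, subRate = 1e-3,
                   lowQFraction = 1e-3, seed = 103)
  tabs <- lapply(filterReads(rounds, des), collapseErrors)
  pt <- translateAndTabulate(tabs, des)
  .cache$sim <- list(design = des, model = model, rounds = rounds,
                     tables = tabs, pt = pt)
  .cache$sim
}
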