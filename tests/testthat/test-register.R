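toyPssm <- function(scores) {
  m <- matrix(0, 9, 20, dimnames = list(paste0("P", 1:9), AA))
  for (cell in scores) m[cell[[1]], cell[[2]]] <- cell[[3]]
  new("PSSM", scores = m, sourceRound = 5L)
}

test_that("PSSM construction transfers enrichment without weighting", {
  sim <- smallSim()
  rnd <- randomizedRegion(peptides(sim$pt), sim$design)
  rc <- readCounts(sim$pt)
  en <- log2Enrichment(positionalFrequencies(rnd[rc[, "r5"] > 0]),
                       positionalFrequencies(rnd[rc[, "r0"] > 0]),
                       round = 5L)
  ps <- buildPssm(en)
  expect_identical(unname(pssmScores(ps)), unname(log2fc(en)))
  ## all-zero enrichment -> all-zero PSSM
  f <- positionalFrequencies(rnd[rc[, "r0"] > 0])
  expect_true(all(pssmScores(buildPssm(log2Enrichment(f, f))) == 0))
  ## 13-position input is rejected
  r13 <- randomPeptides(30, length = 13, seed = 1)
  f13 <- positionalFrequencies(r13)
  expect_error(buildPssm(log2Enrichment(f13, f13)), "PSSM requires 9")
})

test_that("core scores are additive positional lookups", {
  ps <- toyPssm(list(list(1, "A", 2), list(5, "C", -1), list(9, "W", 0.5)))
  expect_equal(scoreCores("AAAACAAAW", ps), 2 - 1 + 0.5)
  expect_equal(scoreCores("CAAAAAAAA", ps), 0)
  expect_error(scoreCores("AAAA", ps), "too short")
})

test_that("register assignment equals exhaustive window scoring", {
  sim <- smallSim()
  rnd <- randomizedRegion(peptides(sim$pt), sim$design)
  rc <- readCounts(sim$pt)
  ps <- buildPssm(log2Enrichment(positionalFrequencies(rnd[rc[, "r5"] > 0]),
                                 positionalFrequencies(rnd[rc[, "r0"] > 0]),
                                 round = 5L))
  set.seed(8)
  peps <- c(sample(peptides(sim$pt), 150),
            randomPeptides(50, length = 15, seed = 2),
            randomPeptides(20, length = 9, seed = 3),
            randomPeptides(20, length = 12, seed = 4))
  got <- assignRegister(peps, ps, expectedStart = 3L)
  for (i in seq_along(peps)) {
    oracle <- registerOracle(peps[i], ps, expectedStart = 3L)
    expect_equal(got$best_start[i], oracle$best)
    expect_equal(got$score[i], oracle$score)
  }
  ## a 15mer has exactly seven candidate windows
  p15 <- randomPeptides(200, length = 15, seed = 9)
  a15 <- assignRegister(p15, ps, expectedStart = 3L)
  expect_true(all(a15$best_start >= 1 & a15$best_start <= 7))
  allZero <- toyPssm(list())
  tie <- assignRegister(p15, allZero, expectedStart = 3L)
  expect_true(all(tie$best_start == 3L))  # ties prefer expected register
  ## 9mer input: single window, offset 1
  a9 <- assignRegister(randomPeptides(10, length = 9, seed = 1), allZero,
                       expectedStart = 1L)
  expect_true(all(a9$best_start == 1L))
  ## tie between two shifted windows, expected register not among them
  ps2 <- toyPssm(list(list(1, "W", 5)))
  p <- "WAAAWAAAAAAAAAA"  # windows 1 and 5 tie; expected 3 loses
  expect_equal(assignRegister(p, ps2, expectedStart = 3L)$best_start, 1L)
  expect_error(assignRegister("AAAA", ps, 1L), "too short")
  ## in_register flags exactly the expected-start assignments
  expect_identical(got$in_register, got$best_start == 3L)
})

test_that("Gibbs clustering finds the planted cluster structure", {
  one <- plantedMotifPeptides(300, 13, motifA, offset = 2, seed = 5)
  sol1 <- gibbsCluster(one, motifLen = 9, kRange = 1:4, nSeeds = 3,
                       iters = 60, seed = 7)
  expect_equal(chosenK(sol1), 1L)
  expect_equal(chosenK(sol1),
               as.integer(names(which.max(kldByK(sol1)))))
  ## modal recovered offset equals the planted offset
  off <- assignments(sol1)$offset
  expect_equal(as.integer(names(which.max(table(off)))), 3L)

  two <- c(plantedMotifPeptides(150, 13, motifA, offset = 2, seed = 6),
           plantedMotifPeptides(150, 13, motifB, offset = 2, seed = 8))
  sol2 <- gibbsCluster(two, motifLen = 9, kRange = 1:4, nSeeds = 3,
                       iters = 60, seed = 7)
  expect_equal(chosenK(sol2), 2L)
  ## partitions compared, not labels: purity over the confusion table
  tab <- table(rep(1:2, each = 150), assignments(sol2)$cluster)
  expect_gte(sum(apply(tab, 2, max)) / sum(tab), 0.9)

  expect_error(gibbsCluster(one[1:10]), "too few")
  expect_error(gibbsCluster(substr(one, 1, 8), motifLen = 9),
               "motif longer than peptides")
})

test_that("the sampler improves on its random initialization", {
  peps <- plantedMotifPeptides(120, 13, motifA, offset = 2, seed = 11)
  idx <- lapply(strsplit(peps, ""), match, AA)
  flat <- unlist(idx) - 1L
  lens <- nchar(peps)
  starts <- c(0L, cumsum(lens))[seq_along(peps)]
  bg <- rep(1 / 20, 20)
  set.seed(3)
  run <- mhc2display:::gibbs_run_cpp(flat, starts, lens, 2L, 9L, bg, 50,
                                     40L, 5L, 1.5, 0, FALSE)
  expect_gte(run$kld, run$init_kld)
})

test_that("outlier flagging isolates composition-breaking peptides", {
  mix <- c(plantedMotifPeptides(270, 13, motifA, offset = 2, seed = 4),
           vapply(1:30, function(i) paste0(
             sample(c("G", "P"), 13, replace = TRUE), collapse = ""),
             character(1)))
  sol <- gibbsCluster(unique(mix), motifLen = 9, kRange = 1, nSeeds = 2,
                      iters = 60, removeOutliers = TRUE,
                      trashThreshold = 0, seed = 3)
  fo <- flagOutliers(sol)
  expect_gt(fo$fraction, 0.05)
  polyGP <- !grepl("[^GP]", fo$outliers)
  expect_gt(mean(polyGP), 0.8)  # poly-Gly/Pro dominates the outlier set

  ## trash threshold at -Inf: no outliers
  sol0 <- gibbsCluster(unique(mix), motifLen = 9, kRange = 1, nSeeds = 2,
                       iters = 40, removeOutliers = TRUE,
                       trashThreshold = -Inf, seed = 3)
  expect_equal(flagOutliers(sol0)$fraction, 0)
  ## near-identical peptides all score above any low finite threshold
  same <- plantedMotifPeptides(40, 13, c(motifA,
    list(`2` = "A", `3` = "A", `5` = "A", `7` = "A", `8` = "A")),
    offset = 2, seed = 9)
  solS <- gibbsCluster(unique(same), motifLen = 9, kRange = 1, nSeeds = 2,
                       iters = 40, removeOutliers = TRUE,
                       trashThreshold = 0, seed = 5)
  expect_equal(flagOutliers(solS)$fraction, 0)
  ## outlier query requires a trash-enabled solution
  plain <- gibbsCluster(unique(mix)[1:50], motifLen = 9, kRange = 1,
                        nSeeds = 1, iters = 20, seed = 2)
  expect_error(flagOutliers(plain), "without trash")
})

test_that("13mer library registers are recovered on simulated selections", {
  des <- builtinDesign("dr401_13mer")
  model <- defaultGroundTruth(des)
  naive <- sampleNaive(des, 2e4, seed = 61)
  rounds <- simulateSelection(naive, model, des, nRounds = 5,
                              carryover = 2e4, seed = 62)
  tabs <- lapply(filterReads(rounds, des), collapseErrors)
  pt <- translateAndTabulate(tabs, des)
  rc <- readCounts(pt)
  full5 <- peptides(pt)[rc[, "r5"] > 0]
  r5 <- randomizedRegion(full5, des)
  sol <- gibbsCluster(r5, motifLen = 9, kRange = 1, nSeeds = 5,
                      iters = 100, seed = 63)
  a <- assignments(sol)
  tr <- readTruth(rounds$r5)
  tru <- tr[match(full5, tr$peptide), ]
  cen <- tru$binder %in% TRUE & tru$coreStart == coreStart(des)
  ## randomized region starts at peptide position 2: offset 3 = central
  expect_gte(mean(a$offset[cen] == coreStart(des) - 1L), 0.9)

  ## 13-long motif clustering (no within-peptide offsets): registers
  ## surface as clusters instead
  sol13 <- gibbsCluster(r5, motifLen = 13, kRange = 1:4, nSeeds = 3,
                        iters = 60, seed = 64)
  expect_true(all(assignments(sol13)$offset == 1L))

  ## solution export round-trips through TSV/JSON
  dir <- withr::local_tempdir()
  writeGibbsSolution(sol, dir)
  back <- read.table(file.path(dir, "assignments.tsv"), sep = "\t",
                     header = TRUE)
  expect_equal(back$offset, assignments(sol)$offset)
  kld <- jsonlite::read_json(file.path(dir, "kld_by_k.json"),
                             simplifyVector = TRUE)
  expect_equal(kld$chosen_k, chosenK(sol))
})
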