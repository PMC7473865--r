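test_that("minimal epitopes collapse nested sets and honor exclusions", {
  ## the innermost member of a nested set is kept
  got <- minimalEpitopes(c("ABCDEFGHIJK", "BCDEFGHIJ", "ABCDEFGHIJ"))
  expect_identical(got, "BCDEFGHIJ")
  ## non-overlapping peptides are both retained
  expect_setequal(minimalEpitopes(c("AAAAAAAAA", "CCCCCCCCC")),
                  c("AAAAAAAAA", "CCCCCCCCC"))
  ## exclusion-list substrings drop carriers
  expect_identical(minimalEpitopes(c("AAQQQAA", "CCCCC"), exclusion = "QQQ"),
                   "CCCCC")
  ## idempotence
  set.seed(4)
  peps <- randomPeptides(60, length = 12, seed = 4)
  nested <- c(peps, substr(peps[1:20], 2, 11))
  once <- minimalEpitopes(nested)
  expect_identical(minimalEpitopes(once), once)
})

test_that("decoy tiling follows the 8-residue-overlap geometry", {
  ## protein of 50 with constant tile length 15: starts 1,8,15,22,29,36
  ## (the final tile ends exactly at the protein end)
  set.seed(1)
  tiles <- mhc2display:::tileProtein(paste0(sample(AA, 50, TRUE),
                                            collapse = ""), 15L)
  expect_equal(nchar(tiles), rep(15L, 6))
  prot <- paste0(sample(AA, 50, TRUE), collapse = "")
  tiles <- mhc2display:::tileProtein(prot, 15L)
  starts <- vapply(tiles, function(t) as.integer(regexpr(t, prot, fixed = TRUE)),
                   integer(1))
  expect_equal(unname(starts[1:6]), c(1L, 8L, 15L, 22L, 29L, 36L))
})

test_that("decoy sets are length-matched and free of 9mer overlap", {
  set.seed(9)
  proteome <- vapply(1:30, function(i)
    paste0(sample(AA, 400, replace = TRUE), collapse = ""), character(1))
  names(proteome) <- paste0("prot", 1:30)
  positives <- randomPeptides(40, length = 15, seed = 10)
  bs <- generateDecoys(proteome, positives, ratio = "1:1", seed = 3)
  expect_equal(length(bs@decoys), length(positives))
  expect_equal(sort(nchar(bs@decoys)), sort(nchar(positives)))
  ## exhaustive 9mer disjointness between decoys and positives + decoys
  nine <- function(x) unlist(lapply(x, function(p)
    substring(p, 1:(nchar(p) - 8), 9:nchar(p))))
  expect_length(intersect(nine(bs@decoys), nine(positives)), 0L)
  expect_false(anyDuplicated(nine(bs@decoys)) > 0)
  ## 1:19 draws nineteen decoys per positive
  bs19 <- generateDecoys(proteome, positives[1:10], ratio = "1:19", seed = 4)
  expect_equal(length(bs19@decoys), 190L)
  ## mixed positive lengths are matched per length
  posMix <- c(randomPeptides(12, length = 12, seed = 11),
              randomPeptides(12, length = 17, seed = 12))
  bsMix <- generateDecoys(proteome, posMix, ratio = "1:1", seed = 5)
  expect_equal(as.vector(table(nchar(bsMix@decoys))),
               as.vector(table(nchar(posMix))))
  ## a tiny proteome cannot supply the decoys
  expect_error(generateDecoys(proteome[1], randomPeptides(200, 15, seed = 1),
                              ratio = "1:19", seed = 6),
               "decoy pool exhausted")
})

test_that("ROC-AUC matches rank statistics, worked example and pROC", {
  mkSet <- function(np, nd) new("BenchmarkSet",
                                positives = paste0("P", seq_len(np)),
                                decoys = paste0("D", seq_len(nd)),
                                ratio = "1:1", provenance = "toy")
  ## perfectly separating scores
  s <- stats::setNames(c(0.9, 0.8, 0.2, 0.1), c("P1", "P2", "D1", "D2"))
  r <- rocAuc(mkSet(2, 2), s)
  expect_equal(r$auc, 1.0)
  ## identical scores for all -> 0.5 (ties counted half)
  expect_equal(rocAuc(mkSet(2, 2), stats::setNames(rep(1, 4), names(s)))$auc,
               0.5)
  ## worked 3 vs 3 example: 8 of 9 concordant pairs
  s6 <- stats::setNames(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2),
                        c("P1", "P2", "P3", "D1", "D2", "D3"))
  expect_equal(rocAuc(mkSet(3, 3), s6)$auc, 8 / 9)
  ## complement symmetry on tie-free scores
  set.seed(2)
  s40 <- stats::setNames(stats::runif(40),
                         c(paste0("P", 1:20), paste0("D", 1:20)))
  expect_equal(rocAuc(mkSet(20, 20), s40)$auc +
                 rocAuc(mkSet(20, 20), -s40)$auc, 1)
  ## trapezoidal integral of the reported ROC points equals the AUC
  roc <- rocAuc(mkSet(20, 20), s40)
  trap <- sum(diff(roc$roc$fpr) *
                (utils::head(roc$roc$tpr, -1) + utils::tail(roc$roc$tpr, -1)) / 2)
  expect_equal(trap, roc$auc)
  expect_true(all(diff(roc$roc$fpr) >= 0) && all(diff(roc$roc$tpr) >= 0))
  ## independent implementation agrees
  skip_if_not_installed("pROC")
  ref <- suppressMessages(pROC::auc(rep(c(1, 0), each = 20), unname(s40)))
  expect_equal(roc$auc, as.numeric(ref))
  expect_error(rocAuc(mkSet(3, 3), s6[-1]), "unscored peptides")
})

test_that("top-5% PPV follows the documented selection and tie rules", {
  mk19 <- function(n = 10) new("BenchmarkSet",
                               positives = paste0("P", seq_len(n)),
                               decoys = paste0("D", seq_len(19 * n)),
                               ratio = "1:19", provenance = "toy")
  set <- mk19(10)
  ## perfect predictor: positives are exactly the top 5%
  s <- stats::setNames(c(seq(2, 3, length.out = 10),
                         seq(0, 1, length.out = 190)),
                       c(set@positives, set@decoys))
  expect_equal(ppvTop5(set, s), 1.0)
  ## all-equal scores: the stable tie rule keeps the internal layout
  ## (positives first), so every top slot is a positive
  sEq <- stats::setNames(rep(0.5, 200), c(set@positives, set@decoys))
  expect_equal(ppvTop5(set, sEq), 1.0)
  expect_error(ppvTop5(new("BenchmarkSet", positives = "P1", decoys = "D1",
                           ratio = "1:1", provenance = "t"), s),
               "PPV requires 1:19")
  ## ceil rule: N = 200 -> top 10 examined
  sHalf <- stats::setNames(c(rep(1, 5), rep(-1, 5), rep(0, 190)),
                           c(set@positives, set@decoys))
  expect_equal(ppvTop5(set, sHalf), 0.5)
})

test_that("random predictors benchmark at chance levels", {
  n <- 20
  set <- new("BenchmarkSet", positives = paste0("P", 1:n),
             decoys = paste0("D", 1:(19 * n)), ratio = "1:19",
             provenance = "toy")
  ppv <- vapply(1:50, function(s) {
    set.seed(s)
    ppvTop5(set, stats::setNames(stats::runif(20 * n),
                                 c(set@positives, set@decoys)))
  }, numeric(1))
  expect_equal(mean(ppv), 0.05, tolerance = 0.5)
})

test_that("predictor comparison flags only planted positional contrasts", {
  sim <- smallSim()
  rnd <- randomizedRegion(peptides(sim$pt), sim$design)
  rc <- readCounts(sim$pt)
  pssmA <- buildPssm(log2Enrichment(
    positionalFrequencies(rnd[rc[, "r5"] > 0]),
    positionalFrequencies(rnd[rc[, "r0"] > 0]), round = 5L))
  ## predictor B: same matrix with a strong P9 Cys preference removed
  mB <- pssmScores(pssmA)
  mB[9, "C"] <- min(mB[9, ])
  pssmB <- new("PSSM", scores = mB, sourceRound = 5L)
  peps <- randomPeptides(4000, length = 15, seed = 21)
  scoreWith <- function(pssm) {
    a <- assignRegister(peps, pssm, expectedStart = 3L)
    data.frame(peptide = peps, value = a$score,
               core = substr(peps, a$best_start, a$best_start + 8L))
  }
  sa <- scoreWith(pssmA)
  sb <- scoreWith(pssmB)
  ## identical predictors: no only-sets, nothing significant
  same <- comparePredictors(sa, sa)
  expect_equal(nrow(same$onlyA), 0L)
  expect_equal(same$nOnlyA, 0L)
  ## tiny noise: nothing survives Bonferroni
  sn <- sa
  set.seed(22)
  sn$value <- sn$value + stats::rnorm(nrow(sn), sd = 1e-3)
  noisy <- comparePredictors(sa, sn)
  expect_equal(sum(noisy$onlyA$p_adj < 0.05), 0L)
  ## the planted P9 Cys contrast is detected on A's side
  diffAB <- comparePredictors(sa, sb)
  cellA <- diffAB$onlyA[diffAB$onlyA$position == 9 &
                          diffAB$onlyA$residue == "C", ]
  expect_lt(cellA$p_adj, 0.05)
  expect_equal(cellA$direction, 1)
})
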