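## Register deconvolution: PSSM scanning and Gibbs-sampling clustering.

#' Build a PSSM from an enrichment matrix
#'
#' Direct transfer of the 9-position log2-fold-enrichment values, without
#' positional weighting.
#'
#' @param enrich An [EnrichmentMatrix-class] over 9 positions.
#' @return A [PSSM-class].
#' @export
buildPssm <- function(enrich) {
  m <- log2fc(enrich)
  if (nrow(m) != 9L) stop("PSSM requires 9 positions")
  rownames(m) <- paste0("P", 1:9)
  new("PSSM", scores = m, sourceRound = enrich@round)
}

#' Additive PSSM score of fixed 9mer cores
#'
#' @param cores Character vector of 9mers.
#' @param pssm A [PSSM-class].
#' @return Numeric scores (sum over the 9 positional lookups).
#' @export
scoreCores <- function(cores, pssm) {
  if (any(nchar(cores) != 9L)) stop("too short for core")
  m <- peptideMatrix(cores)
  idx <- matrix(match(m, AA20), nrow(m))
  s <- pssmScores(pssm)
  sc <- numeric(nrow(m))
  for (p in 1:9) sc <- sc + unname(s[p, ][idx[, p]])
  sc
}

#' Assign each peptide its best-scoring 9mer register
#'
#' Scores every possible 9mer window of each peptide under the PSSM (a
#' 15mer has exactly seven windows) and reports the argmax. Ties prefer the
#' design's expected register, then the lowest offset. A peptide scoring
#' highest in a shifted register, regardless of score, is deemed
#' out-of-register.
#'
#' @param peptides Character vector (length >= 9 each).
#' @param pssm A [PSSM-class].
#' @param expectedStart 1-based expected core start (the design register).
#' @return data.frame `peptide, best_start, score, in_register`.
#' @export
assignRegister <- function(peptides, pssm, expectedStart = 1L) {
  if (!length(peptides)) stop("no peptides")
  if (any(nchar(peptides) < 9L)) stop("too short for core")
  out <- do.call(rbind, lapply(split(peptides, nchar(peptides)),
    function(pp) {
      L <- nchar(pp[1L])
      nWin <- L - 8L
      sc <- vapply(seq_len(nWin), function(o)
        scoreCores(substr(pp, o, o + 8L), pssm), numeric(length(pp)))
      sc <- matrix(sc, nrow = length(pp))
      best <- apply(sc, 1L, function(row) {
        mx <- max(row)
        at <- which(row == mx)
        if (expectedStart %in% at) expectedStart else at[1L]
      })
      data.frame(peptide = pp, best_start = as.integer(best),
                 score = sc[cbind(seq_along(pp), best)],
                 in_register = best == expectedStart,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[match(peptides, out$peptide), , drop = FALSE]
}

#' Register deconvolution by Gibbs-sampling clustering
#'
#' Samples (cluster, core offset) assignments to maximize the size-weighted
#' Kullback-Leibler distance of pseudocount-smoothed cluster matrices
#' against a data-derived residue background, with annealed sweeps and
#' multiple seeded restarts per candidate cluster count. The chosen cluster
#' count maximizes the mean KLD over `kRange`. With `removeOutliers = TRUE`,
#' peptides whose best available log-odds score falls below
#' `trashThreshold` are parked as outliers and excluded from the matrices.
#'
#' @param peptides At least 20 peptides; `motifLen` must not exceed the
#'   shortest.
#' @param motifLen Motif length (9 for core clustering, or the full
#'   randomized length, e.g. 13).
#' @param kRange Candidate cluster counts.
#' @param nSeeds Seeded restarts per k (best final KLD kept).
#' @param iters Annealed sweeps through all peptides.
#' @param beta Effective pseudocount mass added to cluster frequencies.
#' @param t0 Initial sampling temperature (linear decay).
#' @param removeOutliers Enable the trash cluster.
#' @param trashThreshold Log-odds threshold below which a peptide is an
#'   outlier (used when `removeOutliers = TRUE`).
#' @param lambda Weight of the inter-cluster-similarity penalty applied to
#'   the KLD used for choosing k: redundant clusters that largely re-describe
#'   one another's motif are penalized, so splitting one true motif does not
#'   inflate the model-selection score.
#' @param seed Integer seed.
#' @return A [GibbsSolution-class].
#' @export
gibbsCluster <- function(peptides, motifLen = 9L, kRange = 1:6, nSeeds = 5L,
                         iters = 100L, beta = 50, t0 = 1.5,
                         removeOutliers = FALSE, trashThreshold = 0,
                         lambda = 0.8, seed = 1L) {
  peptides <- unique(peptides)
  if (length(peptides) < 20L) stop("too few peptides")
  lens <- nchar(peptides)
  if (motifLen > min(lens)) stop("motif longer than peptides")

  idx <- lapply(strsplit(peptides, "", fixed = TRUE), match, AA20)
  if (anyNA(unlist(idx))) stop("non-standard residue")
  flat <- unlist(idx) - 1L
  starts <- c(0L, cumsum(lens))[seq_along(peptides)]
  bg <- table(factor(unlist(strsplit(peptides, "", fixed = TRUE)),
                     levels = AA20))
  bg <- (as.numeric(bg) + 1) / (sum(bg) + 20)  # data-derived, floored

  ## size-weighted mean KLD with redundant-cluster penalty: each cluster's
  ## information is reduced by lambda times its best explanation under any
  ## other cluster's matrix
  penalizedKld <- function(run, k) {
    sizes <- tabulate(run$cluster + 1L, nbins = k)
    used <- which(sizes > 0L)
    if (!length(used)) return(0)
    lo <- lapply(seq_len(k), function(j)
      matrix(run$logodds[, j], nrow = motifLen, byrow = TRUE))
    fhat <- lapply(lo, function(m) sweep(2^m, 2L, bg, `*`))
    kldC <- vapply(used, function(j) sum(fhat[[j]] * lo[[j]]), numeric(1))
    pen <- vapply(used, function(j) {
      others <- setdiff(used, j)
      if (!length(others)) return(0)
      max(0, max(vapply(others, function(j2)
        sum(fhat[[j]] * lo[[j2]]), numeric(1))))
    }, numeric(1))
    sum(sizes[used] / sum(sizes) * (kldC - lambda * pen))
  }

  runs <- list()
  kldByK <- numeric(0)
  for (k in kRange) {
    best <- NULL
    for (s in seq_len(nSeeds)) {
      withr_seed(deriveSeed(seed, k * 1000L + s))
      r <- gibbs_run_cpp(flat, starts, lens, as.integer(k),
                         as.integer(motifLen), bg, beta,
                         as.integer(iters), 5L, t0,
                         trashThreshold, removeOutliers)
      if (is.null(best) || r$kld > best$kld) best <- r
    }
    runs[[as.character(k)]] <- best
    kldByK[as.character(k)] <- penalizedKld(best, k)
  }
  chosen <- as.integer(names(which.max(kldByK)))
  sol <- runs[[as.character(chosen)]]
  trash <- sol$cluster < 0L
  assign <- data.frame(
    peptide = peptides,
    cluster = ifelse(trash, NA_integer_, sol$cluster + 1L),
    offset = ifelse(trash, NA_integer_, sol$offset + 1L),
    score = sol$score, stringsAsFactors = FALSE)
  mats <- lapply(seq_len(chosen), function(k) {
    m <- matrix(sol$logodds[, k], nrow = motifLen, byrow = TRUE,
                dimnames = list(paste0("P", seq_len(motifLen)), AA20))
    m
  })
  new("GibbsSolution", assignments = assign, clusterPssms = mats,
      kldByK = kldByK, chosenK = chosen,
      outliers = peptides[trash], background = structure(bg, names = AA20),
      trashThreshold = if (removeOutliers) trashThreshold else NA_real_)
}

#' Export a Gibbs solution as TSV tables plus a KLD-vs-k report
#'
#' Writes `assignments.tsv` (`peptide, cluster, offset, score, outlier`),
#' one `cluster<k>_pssm.tsv` per cluster, and `kld_by_k.json`.
#'
#' @param solution A [GibbsSolution-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeGibbsSolution <- function(solution, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- assignments(solution)
  a$outlier <- a$peptide %in% outliers(solution)
  utils::write.table(a, file.path(dir, "assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (k in seq_along(solution@clusterPssms)) {
    m <- solution@clusterPssms[[k]]
    utils::write.table(data.frame(position = rownames(m), m,
                                  check.names = FALSE),
                       file.path(dir, sprintf("cluster%d_pssm.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(kld_by_k = as.list(kldByK(solution)),
                            chosen_k = chosenK(solution)),
                       file.path(dir, "kld_by_k.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Outlier subset of a Gibbs solution
#'
#' @param solution A [GibbsSolution-class] computed with
#'   `removeOutliers = TRUE`.
#' @return List with `fraction` (outliers / input peptides) and `outliers`.
#' @export
flagOutliers <- function(solution) {
  if (is.na(solution@trashThreshold))
    stop("solution computed without trash threshold")
  n <- nrow(assignments(solution))
  list(fraction = length(outliers(solution)) / n,
       outliers = outliers(solution))
}
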