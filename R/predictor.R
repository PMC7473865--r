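## Round-weighted binding predictors: NN-Align-style ensembles of small
## feed-forward networks with core register scanning.

#' Training examples from yeast-display selection rounds
#'
#' Peptides observed in any selected round become positives with a target
#' value linear in the final round of observation (`final_round / R`, so a
#' peptide last seen in the final round gets 1.0); peptides observed only in
#' the pre-selection library serve as the negative set (target 0). The
#' total is capped by seeded stratified subsampling that preserves
#' final-round proportions, and only the randomized residues are emitted.
#'
#' @param table A [PeptideTable-class] with rounds 0...R, R >= 1.
#' @param design The matching [LibraryDesign-class].
#' @param cap Maximum number of examples (default 80,000).
#' @param targetMap `"linear"` (default) or a function(finalRound, R) giving
#'   targets in `[0, 1]` increasing with the round.
#' @param seed Integer seed for the subsample.
#' @return data.frame `peptide` (randomized residues), `target`, `origin`.
#' @export
makeTrainingSet <- function(table, design, cap = 80000L,
                            targetMap = "linear", seed = 1L) {
  R <- ncol(readCounts(table)) - 1L
  stopifnot(R >= 1L)
  fr <- finalRound(table)
  if (!any(fr == 0L)) stop("no negative examples")
  fmap <- if (identical(targetMap, "linear"))
    function(f, R) f / R else targetMap
  df <- data.frame(peptide = randomizedRegion(peptides(table), design),
                   target = fmap(fr, R),
                   origin = ifelse(fr == 0L, "naive_only",
                                   paste0("yeast_round_", fr)),
                   stringsAsFactors = FALSE)
  if (nrow(df) > cap) {
    withr_seed(seed)
    strata <- split(seq_len(nrow(df)), fr)
    take <- floor(lengths(strata) / nrow(df) * cap)
    short <- cap - sum(take)
    if (short > 0) { # distribute the rounding remainder to largest strata
      ord <- order(-lengths(strata))
      take[ord[seq_len(short)]] <- take[ord[seq_len(short)]] + 1L
    }
    idx <- unlist(mapply(function(ix, k) sort(sample(ix, min(k, length(ix)))),
                         strata, take, SIMPLIFY = FALSE))
    df <- df[sort(idx), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Training examples from an MS-style positive set with scrambled negatives
#'
#' Each positive peptide (target 1) is paired with one uniform permutation
#' of its own residues (target 0), so the negative set carries exactly the
#' positive set's residue composition; scrambles identical to their parent
#' are re-drawn.
#'
#' @param positives Peptide set.
#' @param seed Integer seed.
#' @return data.frame `peptide`, `target`, `origin` with `2n` rows.
#' @export
makeTrainingSetMS <- function(positives, seed = 1L) {
  if (!length(positives)) stop("no peptides")
  if (any(nchar(positives) < 2L)) stop("cannot scramble")
  withr_seed(seed)
  scramble <- vapply(positives, function(p) {
    ch <- strsplit(p, "")[[1]]
    for (i in 1:100) {
      s <- paste0(sample(ch), collapse = "")
      if (s != p) return(s)
    }
    s  # homopolymer: permutation cannot differ
  }, character(1), USE.NAMES = FALSE)
  data.frame(peptide = c(positives, scramble),
             target = rep(c(1, 0), each = length(positives)),
             origin = rep(c("ms_positive", "ms_scrambled"),
                          each = length(positives)),
             stringsAsFactors = FALSE)
}

#' Training configuration for [trainEnsemble()]
#'
#' Defaults give the full 2 encodings x 2 hidden widths x 5 partitions x 2
#' seeds = 40-member grid; pass smaller grids for quick models.
#'
#' @param hidden Hidden-layer widths.
#' @param encodings Subset of `"sparse"` (one-hot) and `"blosum50"`
#'   (scaled BLOSUM50 rows).
#' @param nPartitions Cross-validation partitions (one member trained with
#'   each partition held out for early stopping).
#' @param nSeeds Weight-initialization seeds per grid point.
#' @param maxEpochs,patience Early stopping on held-out MSE.
#' @param lr Adam learning rate.
#' @param batch Mini-batch size.
#' @param l2 Weight-decay strength on the connection weights; regularizes
#'   toward shared positional features rather than example memorization.
#' @param rescanEvery Epoch interval at which each example's core window is
#'   re-chosen as its max-scoring window under the current network.
#' @return Named list.
#' @export
trainingConfig <- function(hidden = c(10L, 40L),
                           encodings = c("sparse", "blosum50"),
                           nPartitions = 5L, nSeeds = 2L,
                           maxEpochs = 500L, patience = 20L, lr = 0.01,
                           batch = 512L, l2 = 1e-4, rescanEvery = 5L) {
  list(hidden = as.integer(hidden), encodings = encodings,
       nPartitions = as.integer(nPartitions), nSeeds = as.integer(nSeeds),
       maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
       lr = lr, batch = as.integer(batch), l2 = l2,
       rescanEvery = as.integer(rescanEvery))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

blosumRows <- function() {
  B <- get("BLOSUM50", envir = asNamespace("Biostrings"))
  if (is.null(dim(B))) {
    e <- new.env()
    utils::data("BLOSUM50", package = "Biostrings", envir = e)
    B <- e$BLOSUM50
  }
  B[AA20, AA20] / 10
}

## encode 9mer cores (+ optional flank summaries) into a dense matrix
encodeWindows <- function(peptides, start, encoding, usePFR,
                          blosum = NULL) {
  n <- length(peptides)
  cores <- substr(peptides, start, start + 8L)
  m <- peptideMatrix(cores)
  idx <- matrix(match(m, AA20), n)
  enc1 <- function(aaIdx) { # n x 20 encoding of one residue column
    if (encoding == "sparse") {
      X <- matrix(0, length(aaIdx), 20L)
      X[cbind(seq_along(aaIdx), aaIdx)] <- 1
      X
    } else blosum[aaIdx, , drop = FALSE]
  }
  X <- matrix(0, n, 180L + if (usePFR) 42L else 0L)
  for (p in 1:9) X[, (p - 1L) * 20L + 1:20] <- enc1(idx[, p])
  if (usePFR) {
    lens <- nchar(peptides)
    mean2 <- function(chars1, chars2, k) {
      ## mean encoding of up to two flank residues adjacent to the core
      A <- matrix(0, n, 20L)
      has1 <- !is.na(chars1)
      if (any(has1)) A[has1, ] <- enc1(match(chars1[has1], AA20))
      has2 <- !is.na(chars2)
      if (any(has2)) A[has2, ] <- A[has2, , drop = FALSE] +
          enc1(match(chars2[has2], AA20))
      A / pmax(1, k)
    }
    f5a <- if (start >= 2L) substr(peptides, start - 1L, start - 1L)
           else rep(NA_character_, n)
    f5b <- if (start >= 3L) substr(peptides, start - 2L, start - 2L)
           else rep(NA_character_, n)
    n5 <- (!is.na(f5a)) + (!is.na(f5b))
    e3 <- start + 9L
    f3a <- substr(peptides, e3, e3)
    f3a[e3 > lens] <- NA_character_
    f3b <- substr(peptides, e3 + 1L, e3 + 1L)
    f3b[e3 + 1L > lens] <- NA_character_
    n3 <- (!is.na(f3a)) + (!is.na(f3b))
    X[, 181:200] <- mean2(f5a, f5b, n5)
    X[, 201:220] <- mean2(f3a, f3b, n3)
    X[, 221L] <- pmin(start - 1L, 4L) / 4
    X[, 222L] <- pmin(lens - (start + 8L), 4L) / 4
  }
  X
}

## forward pass of one member on an encoded matrix
memberForward <- function(member, X) {
  H <- tanh(sweep(X %*% member$W1, 2L, member$b1, `+`))
  as.vector(stats::plogis(H %*% member$W2 + member$b2))
}

## best-window score (and start) of one member over peptides
memberScan <- function(member, peptides, usePFR, blosum) {
  n <- length(peptides)
  best <- rep(-Inf, n)
  bestStart <- rep(1L, n)
  for (s in seq_len(max(nchar(peptides)) - 8L)) {
    sel <- nchar(peptides) >= s + 8L
    if (!any(sel)) next
    sc <- memberForward(member, encodeWindows(peptides[sel], s,
                                              member$encoding, usePFR,
                                              blosum))
    b <- best[sel]; bs <- bestStart[sel]
    better <- sc > b
    b[better] <- sc[better]; bs[better] <- s
    best[sel] <- b; bestStart[sel] <- bs
  }
  list(score = best, start = bestStart)
}

trainMember <- function(peptides, y, valIdx, encoding, hidden, usePFR,
                        config, seed, blosum) {
  d <- 180L + if (usePFR) 42L else 0L
  withr_seed(seed)
  W1 <- matrix(stats::runif(d * hidden, -0.1, 0.1), d, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::runif(hidden, -0.1, 0.1), hidden, 1L)
  b2 <- 0
  member <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, encoding = encoding,
                 hidden = hidden, seed = seed)
  multiWindow <- any(nchar(peptides) > 9L)
  ## core search starts at the central window (the expected register for
  ## library designs); register scanning refines it during training
  starts <- pmax(1L, (nchar(peptides) - 9L) %/% 2L + 1L)
  X <- reencode(peptides, starts, encoding, usePFR, blosum)
  tr <- setdiff(seq_along(y), valIdx)
  adam <- list(m = lapply(member[1:4], function(w) w * 0),
               v = lapply(member[1:4], function(w) w * 0), t = 0)
  bestVal <- Inf; bestMember <- member; wait <- 0L
  batch <- config$batch %||% 512L
  l2 <- config$l2 %||% 1e-4
  for (epoch in seq_len(config$maxEpochs)) {
    perm <- sample(tr)  # seeded stream: deterministic epoch shuffles
    for (bi in split(perm, ceiling(seq_along(perm) / batch))) {
      Xt <- X[bi, , drop = FALSE]
      H <- tanh(sweep(Xt %*% member$W1, 2L, member$b1, `+`))
      yh <- as.vector(stats::plogis(H %*% member$W2 + member$b2))
      delta <- (yh - y[bi]) * yh * (1 - yh) * (2 / length(bi))
      gW2 <- crossprod(H, delta)
      gb2 <- sum(delta)
      dH <- (delta %*% t(member$W2)) * (1 - H^2)
      gW1 <- crossprod(Xt, dH) + l2 * member$W1
      gb1 <- colSums(dH)
      g <- list(W1 = gW1, b1 = gb1, W2 = gW2 + l2 * member$W2, b2 = gb2)
      adam$t <- adam$t + 1
      for (w in names(g)) {
        adam$m[[w]] <- 0.9 * adam$m[[w]] + 0.1 * g[[w]]
        adam$v[[w]] <- 0.999 * adam$v[[w]] + 0.001 * g[[w]]^2
        mhat <- adam$m[[w]] / (1 - 0.9^adam$t)
        vhat <- adam$v[[w]] / (1 - 0.999^adam$t)
        member[[w]] <- member[[w]] - config$lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
    val <- memberForward(member, X[valIdx, , drop = FALSE])
    valMse <- mean((val - y[valIdx])^2)
    if (valMse < bestVal - 1e-7) {
      bestVal <- valMse; bestMember <- member; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
    if (multiWindow && epoch %% config$rescanEvery == 0L) {
      sc <- memberScan(member, peptides, usePFR, blosum)
      if (!identical(sc$start, starts)) {
        starts <- sc$start
        X <- reencode(peptides, starts, encoding, usePFR, blosum)
      }
    }
  }
  bestMember$valMse <- bestVal
  bestMember
}

## encode each peptide at its own chosen window start
reencode <- function(peptides, starts, encoding, usePFR, blosum) {
  d <- 180L + if (usePFR) 42L else 0L
  X <- matrix(0, length(peptides), d)
  for (s in unique(starts)) {
    sel <- starts == s
    X[sel, ] <- encodeWindows(peptides[sel], s, encoding, usePFR, blosum)
  }
  X
}

#' Train an NN-Align-style predictor ensemble
#'
#' Trains single-hidden-layer networks by backpropagation on (encoded 9mer
#' core, target) pairs over a grid of encodings x hidden widths x
#' cross-validation partitions x seeds. For peptides longer than nine
#' residues, each example's core window is re-chosen during training as the
#' max-scoring window under the current network (register scanning), and
#' flank residues contribute mean-encoded summary features (up to two per
#' side) plus flank-length features. Held-out partition MSE drives early
#' stopping. Training is bit-reproducible for a fixed configuration and
#' seed, and invariant to example order (examples are canonically sorted).
#'
#' @param examples data.frame with `peptide` and `target` columns (targets
#'   in `[0, 1]`, both zero and positive targets present).
#' @param config See [trainingConfig()].
#' @param seed Integer master seed.
#' @return A [PredictorEnsemble-class] (uncalibrated; see
#'   [calibrateEnsemble()]).
#' @export
trainEnsemble <- function(examples, config = trainingConfig(), seed = 1L) {
  if (!length(config$hidden) || !length(config$encodings) ||
      config$nPartitions < 2L || config$nSeeds < 1L)
    stop("empty ensemble")
  ord <- order(examples$peptide, examples$target)
  examples <- examples[ord, , drop = FALSE]
  y <- examples$target
  if (!any(y > 0) || !any(y == 0))
    stop("need both positive and zero targets")
  usePFR <- any(nchar(examples$peptide) > 9L)
  blosum <- if ("blosum50" %in% config$encodings) blosumRows() else NULL
  withr_seed(deriveSeed(seed, 0L))
  part <- sample(rep_len(seq_len(config$nPartitions), nrow(examples)))
  members <- list()
  k <- 0L
  for (enc in config$encodings)
    for (h in config$hidden)
      for (p in seq_len(config$nPartitions))
        for (s in seq_len(config$nSeeds)) {
          k <- k + 1L
          members[[k]] <- trainMember(
            examples$peptide, y, which(part == p), enc, h, usePFR,
            config, deriveSeed(seed, k), blosum)
          members[[k]]$partition <- p
        }
  new("PredictorEnsemble", members = members,
      encoding = config$encodings, usePFR = usePFR, config = config,
      calibration = numeric(0), calibrationSeed = NA_integer_)
}

#' Score peptides with a trained ensemble
#'
#' Each member scans all 9mer windows and contributes its best-window score;
#' the ensemble score is the member mean (in `[0, 1]`, higher = stronger
#' binding) and the reported core start is the modal best window across
#' members (ties: lowest start). Set `invert = TRUE` to report `1 - score`.
#'
#' @param ensemble A [PredictorEnsemble-class].
#' @param peptides Peptides of length >= 9.
#' @param invert Report inverted scores.
#' @return data.frame `peptide, score, core_start`.
#' @export
predictBinding <- function(ensemble, peptides, invert = FALSE) {
  if (!length(peptides)) stop("no peptides")
  if (any(nchar(peptides) < 9L)) stop("too short")
  blosum <- if ("blosum50" %in% ensemble@encoding) blosumRows() else NULL
  scores <- matrix(0, length(peptides), length(ensemble@members))
  starts <- matrix(1L, length(peptides), length(ensemble@members))
  for (j in seq_along(ensemble@members)) {
    sc <- memberScan(ensemble@members[[j]], peptides, ensemble@usePFR,
                     blosum)
    scores[, j] <- sc$score
    starts[, j] <- sc$start
  }
  modal <- apply(starts, 1L, function(s) {
    tab <- table(s)
    as.integer(names(tab)[which.max(tab)])  # which.max: first max = lowest
  })
  score <- rowMeans(scores)
  data.frame(peptide = peptides,
             score = if (invert) 1 - score else score,
             core_start = modal, stringsAsFactors = FALSE)
}

#' Calibrate percent ranks against random background peptides
#'
#' Scores `n` random background peptides (UniProt-average residue
#' frequencies) and stores the sorted score sample inside the ensemble; the
#' percent rank of a query score is then the percentage of calibration
#' scores at or above it (lower rank = stronger).
#'
#' @param ensemble A [PredictorEnsemble-class].
#' @param n Calibration sample size (default 50,000).
#' @param length Calibration peptide length (default 15).
#' @param seed Seed of the calibration draw (recorded in the model).
#' @param chunk Peptides scored per block.
#' @return The calibrated ensemble.
#' @export
calibrateEnsemble <- function(ensemble, n = 50000L, length = 15L, seed = 1L,
                              chunk = 10000L) {
  peps <- randomPeptides(n, length = length, seed = seed)
  sc <- unlist(lapply(split(peps, ceiling(seq_along(peps) / chunk)),
                      function(pp) predictBinding(ensemble, pp)$score),
               use.names = FALSE)
  ensemble@calibration <- sort(sc)
  ensemble@calibrationSeed <- as.integer(seed)
  ensemble
}

#' Percent rank of prediction scores
#'
#' @param ensemble A calibrated [PredictorEnsemble-class].
#' @param score Numeric vector of ensemble scores.
#' @return Percentages: `100 * fraction of calibration scores >= score`
#'   (monotone non-increasing in score).
#' @export
percentRank <- function(ensemble, score) {
  cal <- ensemble@calibration
  if (!length(cal)) stop("uncalibrated ensemble")
  n <- length(cal)
  100 * (n - findInterval(score, cal, left.open = TRUE)) / n
}

#' Save / load a predictor ensemble as JSON
#'
#' @param ensemble A [PredictorEnsemble-class].
#' @param path JSON path.
#' @return `writeEnsembleJson` invisibly returns `path`;
#'   `readEnsembleJson` returns the ensemble.
#' @export
writeEnsembleJson <- function(ensemble, path) {
  obj <- list(
    encoding = ensemble@encoding, usePFR = ensemble@usePFR,
    config = ensemble@config, calibration = ensemble@calibration,
    calibrationSeed = ensemble@calibrationSeed,
    members = lapply(ensemble@members, function(m)
      list(W1 = m$W1, b1 = m$b1, W2 = as.vector(m$W2), b2 = m$b2,
           encoding = m$encoding, hidden = m$hidden, seed = m$seed,
           partition = m$partition, valMse = m$valMse)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEnsembleJson
#' @export
readEnsembleJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  members <- lapply(seq_len(nrow(obj$members)), function(i) {
    m <- lapply(obj$members, function(col)
      if (is.list(col)) col[[i]] else col[i])
    m$W1 <- matrix(unlist(m$W1), ncol = m$hidden)
    m$W2 <- matrix(m$W2, ncol = 1L)
    m
  })
  cfg <- obj$config
  cfg$hidden <- as.integer(cfg$hidden)
  new("PredictorEnsemble", members = members, encoding = obj$encoding,
      usePFR = obj$usePFR, config = cfg,
      calibration = as.numeric(obj$calibration),
      calibrationSeed = as.integer(obj$calibrationSeed))
}
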