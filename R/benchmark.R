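## Benchmark construction (minimal epitopes, tiled decoys) and scoring
## (ROC-AUC at 1:1, top-5% PPV at 1:19, positional predictor comparison).

#' Minimal epitopes of nested peptide sets
#'
#' Collapses nested sets (peptides related by substring containment) to
#' their minimal member: a peptide is kept iff no other peptide of the set
#' is a proper substring of it. Peptides containing any exclusion-list
#' substring (e.g. immunoglobulin/HLA-derived sequences) are dropped first.
#' The operation is idempotent.
#'
#' @param peptides Peptide set.
#' @param exclusion Character vector of excluded substrings.
#' @return Character vector of minimal epitopes.
#' @export
minimalEpitopes <- function(peptides, exclusion = character(0)) {
  peptides <- unique(peptides)
  for (ex in exclusion)
    peptides <- peptides[!grepl(ex, peptides, fixed = TRUE)]
  if (length(peptides) < 2L) return(peptides)
  ord <- order(nchar(peptides))  # a proper substring is strictly shorter
  keep <- rep(TRUE, length(peptides))
  for (i in seq_along(ord)) {
    p <- peptides[ord[i]]
    for (j in seq_len(i - 1L)) {
      if (keep[ord[j]] && grepl(peptides[ord[j]], p, fixed = TRUE)) {
        keep[ord[i]] <- FALSE
        break
      }
    }
  }
  peptides[keep]
}

allNineMers <- function(peptides) {
  peptides <- peptides[nchar(peptides) >= 9L]
  unlist(lapply(peptides, function(p)
    substring(p, seq_len(nchar(p) - 8L), seq_len(nchar(p) - 8L) + 8L)),
    use.names = FALSE)
}

#' Tile a protein into candidate decoy peptides
#'
#' Lengths are drawn from the supplied length distribution; consecutive
#' tiles overlap by eight residues (step = length - 8), starting at the
#' first residue. If the final tile would overrun the protein, its start is
#' shifted to a random in-bounds position so all tiles lie within the
#' protein.
#'
#' @param protein One protein sequence.
#' @param lengths Peptide length pool to draw from.
#' @return Character vector of tiles (unnamed).
#' @keywords internal
tileProtein <- function(protein, lengths) {
  L <- nchar(protein)
  tiles <- character(0)
  start <- 1L
  repeat {
    len <- if (length(lengths) == 1L) lengths else sample(lengths, 1L)
    if (start + len - 1L > L) {
      ## the would-be final tile overruns: shift its start randomly to an
      ## unvisited in-bounds position (none exists when the previous tile
      ## already reached the protein end)
      lo <- start - (len - 8L) + 1L  # just past the previous start
      hi <- L - len + 1L
      if (length(tiles) == 0L) lo <- 1L
      if (hi >= lo && hi >= 1L) {
        s <- if (hi == lo) lo else sample(lo:hi, 1L)
        tiles <- c(tiles, substr(protein, s, s + len - 1L))
      }
      break
    }
    tiles <- c(tiles, substr(protein, start, start + len - 1L))
    start <- start + len - 8L
  }
  tiles
}

#' Generate a length-matched decoy benchmark set
#'
#' Tiles each source protein with peptide lengths drawn from the positives'
#' length distribution (eight-residue overlap between subsequent tiles),
#' then samples decoys from the tile pool to match the positives' length
#' distribution at the requested ratio, rejecting any tile that shares a
#' 9mer substring with a positive or an already-chosen decoy.
#'
#' @param proteome Named character vector of protein sequences, or an
#'   `AAStringSet`.
#' @param positives Positive peptides.
#' @param ratio `"1:1"` or `"1:19"` decoys per positive.
#' @param seed Integer seed.
#' @return A [BenchmarkSet-class].
#' @export
generateDecoys <- function(proteome, positives, ratio = "1:1", seed = 1L) {
  if (is(proteome, "AAStringSet")) proteome <- as.character(proteome)
  if (!length(proteome) || !length(positives)) stop("no peptides")
  mult <- as.integer(sub("^1:", "", ratio))
  withr_seed(seed)
  lens <- nchar(positives)
  pool <- unlist(lapply(proteome, tileProtein, lengths = lens),
                 use.names = FALSE)
  pool <- unique(pool[!pool %in% positives])
  pool <- pool[sample.int(length(pool))]

  banned <- new.env(hash = TRUE, parent = emptyenv())
  for (k in allNineMers(positives)) assign(k, TRUE, envir = banned)
  clean <- function(tile) {
    kmers <- allNineMers(tile)
    if (any(vapply(kmers, exists, logical(1), envir = banned,
                   inherits = FALSE))) return(FALSE)
    for (k in kmers) assign(k, TRUE, envir = banned)
    TRUE
  }
  decoys <- character(0)
  need <- table(lens) * mult
  poolByLen <- split(pool, nchar(pool))
  for (l in names(need)) {
    cand <- poolByLen[[l]]
    got <- 0L
    for (tile in cand) {
      if (got >= need[[l]]) break
      if (clean(tile)) {
        decoys <- c(decoys, tile)
        got <- got + 1L
      }
    }
    if (got < need[[l]])
      stop(sprintf("decoy pool exhausted: need %d more of length %s",
                   need[[l]] - got, l))
  }
  new("BenchmarkSet", positives = positives, decoys = decoys,
      ratio = ratio, provenance = "generateDecoys")
}

scoreVector <- function(set, scores) {
  all <- c(set@positives, set@decoys)
  s <- scores[all]
  if (anyNA(s)) stop("unscored peptides")
  s
}

#' ROC curve and AUC on a 1:1 benchmark set
#'
#' AUC by the rank (Mann-Whitney) statistic with ties counted half; ROC
#' points are computed at every distinct score threshold and the reported
#' AUC equals the trapezoidal integral of those points.
#'
#' @param set A [BenchmarkSet-class] at 1:1.
#' @param scores Named numeric vector covering every peptide of the set
#'   (higher = called stronger).
#' @return List with `auc`, `roc` (data.frame `fpr`, `tpr`) and `scores`.
#' @export
rocAuc <- function(set, scores) {
  s <- scoreVector(set, scores)
  lab <- rep(c(TRUE, FALSE), c(length(set@positives), length(set@decoys)))
  n1 <- sum(lab); n0 <- sum(!lab)
  r <- rank(s)  # ties: average rank = ties counted half
  auc <- (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(s[lab] >= t), numeric(1)) / n1)
  fpr <- c(0, vapply(thr, function(t) sum(s[!lab] >= t), numeric(1)) / n0)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr),
       scores = data.frame(peptide = c(set@positives, set@decoys),
                           score = unname(s), positive = lab))
}

#' Top-5% positive predictive value on a 1:19 benchmark set
#'
#' Sorts by score descending (stable for ties: the set's internal order,
#' positives before decoys) and returns the fraction of positives among the
#' top `ceiling(0.05 * N)` peptides. With positives at exactly 5% of the
#' set, a perfect predictor scores 1.
#'
#' @inheritParams rocAuc
#' @param set A [BenchmarkSet-class] at 1:19.
#' @return PPV in `[0, 1]`.
#' @export
ppvTop5 <- function(set, scores) {
  if (set@ratio != "1:19") stop("PPV requires 1:19 composition")
  s <- scoreVector(set, scores)
  lab <- rep(c(TRUE, FALSE), c(length(set@positives), length(set@decoys)))
  k <- ceiling(0.05 * length(s))
  top <- order(-s)[seq_len(k)]  # order() is stable: ties keep input order
  mean(lab[top])
}

#' Positional comparison of two predictors
#'
#' Applies both predictors to a common background peptide set; peptides in
#' the top `(100 - percentile)`\% for only one predictor are compared, core
#' position by residue, against peptides in the top set for both, by
#' two-sided binomial test with Bonferroni correction. Returns one signed
#' significance table per predictor.
#'
#' @param scoresA,scoresB data.frames with `peptide`, `value`, `core`
#'   columns over the same peptide set.
#' @param percentile Percentile cut (default 90: top 10\%).
#' @return List with elements `onlyA` and `onlyB`, each a data.frame
#'   `position, residue, freq_only, freq_both, p_adj, direction`, plus the
#'   set sizes.
#' @export
comparePredictors <- function(scoresA, scoresB, percentile = 90) {
  stopifnot(setequal(scoresA$peptide, scoresB$peptide))
  scoresB <- scoresB[match(scoresA$peptide, scoresB$peptide), ]
  qa <- stats::quantile(scoresA$value, percentile / 100, names = FALSE)
  qb <- stats::quantile(scoresB$value, percentile / 100, names = FALSE)
  inA <- scoresA$value >= qa
  inB <- scoresB$value >= qb
  both <- inA & inB
  if (!any(both)) stop("no shared top peptides")
  tableFor <- function(coresOnly, coresBoth) {
    if (!length(coresOnly))
      return(data.frame(position = integer(0), residue = character(0),
                        freq_only = numeric(0), freq_both = numeric(0),
                        p_adj = numeric(0), direction = integer(0)))
    mOnly <- peptideMatrix(coresOnly)
    fBoth <- frequencies(positionalFrequencies(coresBoth)) / 100
    res <- expand.grid(position = 1:9, residue = AA20,
                       stringsAsFactors = FALSE)
    res$freq_only <- NA_real_; res$p <- NA_real_
    n <- nrow(mOnly)
    for (pos in 1:9) {
      obs <- table(factor(mOnly[, pos], levels = AA20))
      for (a in seq_len(20L)) {
        i <- (a - 1L) * 9L + pos
        res$freq_only[i] <- obs[[a]] / n
        res$p[i] <- stats::binom.test(obs[[a]], n, fBoth[pos, a])$p.value
      }
    }
    res$freq_both <- fBoth[cbind(res$position, match(res$residue, AA20))]
    res$p_adj <- pmin(1, res$p * nrow(res))
    res$direction <- sign(res$freq_only - res$freq_both)
    res[order(res$position, res$residue),
        c("position", "residue", "freq_only", "freq_both", "p_adj",
          "direction")]
  }
  coresBoth <- scoresA$core[both]
  list(onlyA = tableFor(scoresA$core[inA & !inB], coresBoth),
       onlyB = tableFor(scoresB$core[inB & !inA], coresBoth),
       nOnlyA = sum(inA & !inB), nOnlyB = sum(inB & !inA),
       nBoth = sum(both))
}
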