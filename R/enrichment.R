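## Positional frequency, enrichment, significance and KL-logo matrices.

#' Unweighted positional residue frequencies
#'
#' Each unique peptide counts once (unweighted, matching unweighted
#' repertoire heat maps); frequencies are percentages per position over the
#' 20-residue alphabet.
#'
#' @param peptides Character vector of equal-length peptides (typically the
#'   randomized region, see [randomizedRegion()]). Duplicates are removed.
#' @return A [FrequencyMatrix-class] (positions x 20, rows sum to 100).
#' @export
positionalFrequencies <- function(peptides) {
  peptides <- unique(peptides)
  if (!length(peptides)) stop("no peptides")
  m <- peptideMatrix(peptides)
  freq <- t(apply(m, 2L, function(col)
    table(factor(col, levels = AA20)))) / length(peptides) * 100
  dimnames(freq) <- list(paste0("P", seq_len(nrow(freq))), AA20)
  new("FrequencyMatrix", freq = freq, nPeptides = length(peptides))
}

#' Log2-fold enrichment of a selected round over the unselected library
#'
#' `log2fc[p, a] = log2((selected + pseudo) / (naive + pseudo))`, computed
#' on percentage frequencies. The pseudocount (default 0.1 percentage
#' point, added to both numerator and denominator) keeps every entry finite
#' when a residue is absent from one library.
#'
#' @param selected,naive [FrequencyMatrix-class] objects of equal shape.
#' @param pseudo Pseudocount in percentage points.
#' @param round Selection round label stored in the result.
#' @return An [EnrichmentMatrix-class].
#' @export
log2Enrichment <- function(selected, naive, pseudo = 0.1, round = NA_integer_) {
  fs <- frequencies(selected)
  fn <- frequencies(naive)
  if (!all(dim(fs) == dim(fn))) stop("matrix shape error")
  lfc <- log2((fs + pseudo) / (fn + pseudo))
  new("EnrichmentMatrix", log2fc = lfc,
      pvals = matrix(numeric(0), 0L, 0L), reference = naive,
      round = as.integer(round))
}

#' Positional significance of enrichment by exact binomial test
#'
#' For each position/residue cell, a two-sided exact binomial test of the
#' observed residue count among up to `nSample` sampled selected peptides
#' against the unselected-library frequency as the null probability, with a
#' Bonferroni correction over all positions x 20 residues cells.
#'
#' @param peptides Selected unique peptides (equal length).
#' @param naive The unselected-library [FrequencyMatrix-class].
#' @param nSample Peptides sampled to establish the distribution (default
#'   10,000); if fewer are available all are used, with a warning.
#' @param seed Seed for the peptide subsample.
#' @return Matrix of Bonferroni-adjusted p-values (positions x 20).
#' @export
positionalSignificance <- function(peptides, naive, nSample = 10000L,
                                   seed = 1L) {
  peptides <- unique(peptides)
  if (!length(peptides)) stop("no peptides")
  withr_seed(seed)
  if (length(peptides) > nSample) {
    peptides <- sample(peptides, nSample)
  } else if (length(peptides) < nSample) {
    warning("fewer peptides than nSample; using all ", length(peptides))
  }
  m <- peptideMatrix(peptides)
  fn <- frequencies(naive) / 100
  nPos <- ncol(m)
  if (nPos != nrow(fn)) stop("matrix shape error")
  n <- length(peptides)
  p <- matrix(NA_real_, nPos, 20L, dimnames = list(rownames(fn), AA20))
  for (pos in seq_len(nPos)) {
    obs <- table(factor(m[, pos], levels = AA20))
    for (a in seq_len(20L)) {
      p[pos, a] <- stats::binom.test(obs[[a]], n, fn[pos, a],
                                     alternative = "two.sided")$p.value
    }
  }
  matrix(stats::p.adjust(p, method = "bonferroni", n = length(p)),
         nPos, 20L, dimnames = dimnames(p))
}

#' Kullback-Leibler relative-entropy logo
#'
#' Per-position information `I_p = sum_a f_a log2(f_a / bg_a)` (bits), with
#' signed letter heights `h_a = I_p * (f_a - bg_a) / sum_a |f_a - bg_a|`:
#' enriched residues point up, depleted residues down, and the absolute
#' heights at a position sum exactly to its information content. This is the
#' convention fixed for all logos in the package.
#'
#' @param freqs A [FrequencyMatrix-class].
#' @param background Strictly positive 20-vector of residue frequencies
#'   summing to 1 (the matched unselected library average for display
#'   libraries, [uniprotFrequencies()] for external peptide sets).
#' @return List with `info` (per-position bits), `heights` (positions x 20
#'   signed matrix) and `background`.
#' @export
klLogo <- function(freqs, background = uniprotFrequencies()) {
  bg <- background[AA20]
  if (any(is.na(bg)) || any(bg <= 0)) stop("degenerate background")
  bg <- bg / sum(bg)
  f <- frequencies(freqs) / 100
  info <- vapply(seq_len(nrow(f)), function(p) {
    nz <- f[p, ] > 0
    sum(f[p, nz] * log2(f[p, nz] / bg[nz]))
  }, numeric(1))
  d <- sweep(f, 2L, bg)
  z <- rowSums(abs(d))
  heights <- d * ifelse(z > 0, info / z, 0)
  dimnames(heights) <- dimnames(f)
  list(info = structure(info, names = rownames(f)), heights = heights,
       background = bg)
}

#' Positional average background of an unselected library
#'
#' @param naive The unselected-library [FrequencyMatrix-class].
#' @return 20-vector of residue frequencies (the positional average),
#'   summing to 1.
#' @export
libraryBackground <- function(naive) {
  colMeans(frequencies(naive)) / 100
}

#' KL logo of the binder cores called by a prediction algorithm
#'
#' Applies a published binder cutoff to externally computed predictions of a
#' random background peptide set and builds the KL logo of the predicted
#' 9mer cores of the passing peptides (random-background convention:
#' UniProt-average frequencies).
#'
#' @param scores data.frame with columns `peptide`, `value` (predicted
#'   value) and `core` (predicted 9mer core).
#' @param cutoff Numeric binder cutoff applied to `value` (e.g. IC50 < 500
#'   nM or rank < 10).
#' @param direction `"lt"` keeps `value < cutoff`, `"gt"` keeps
#'   `value > cutoff`.
#' @param background Background 20-vector; defaults to
#'   [uniprotFrequencies()].
#' @return As [klLogo()].
#' @export
algorithmMotif <- function(scores, cutoff, direction = c("lt", "gt"),
                           background = uniprotFrequencies()) {
  direction <- match.arg(direction)
  pass <- if (direction == "lt") scores$value < cutoff
          else scores$value > cutoff
  cores <- scores$core[pass]
  if (!length(cores)) stop("empty motif")
  klLogo(positionalFrequencies(cores), background)
}

#' Export a positional matrix as TSV
#'
#' Rows are positions (P1...P9 or P(-2)...P11), columns the 20 residues in
#' alphabetical order.
#'
#' @param x A [FrequencyMatrix-class], [EnrichmentMatrix-class] or
#'   [PSSM-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMatrixTsv <- function(x, path) {
  m <- if (is(x, "FrequencyMatrix")) frequencies(x)
       else if (is(x, "EnrichmentMatrix")) log2fc(x)
       else if (is(x, "PSSM")) pssmScores(x)
       else stop("unsupported object")
  utils::write.table(data.frame(position = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
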