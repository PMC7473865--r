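---
title: "Methods: repertoire-scale MHC-II peptide binding from yeast display"
author: "mhc2display"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire-scale MHC-II peptide binding from yeast display}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhc2display)
```

# The problem

Class II MHC (HLA-DR) molecules present peptides in an open groove: a
nine-residue core occupies the pockets (anchors at P1, P4, P6 and P9), while
flanking residues (PFRs) modulate affinity without occupying pockets. Yeast
surface display can screen ~10^8 randomized peptides for binding to a
displayed MHC-II allele: iterative rounds of protease-mediated peptide
release, competitor-driven peptide exchange and selection for peptide
retention enrich binders, and deep sequencing of each round yields a
repertoire-scale binding data set. This package implements the complete
computational workflow around such selections: library simulation, amplicon
read processing, positional enrichment statistics, register deconvolution,
binding-predictor training with percent-rank calibration, decoy-based
benchmarking, and competition-assay IC50 fitting.

# Library designs

Two library geometries are built in. The randomized 9mer design
`AA-X9-WEEG` constrains binding to a single register, so the nine NNK
positions are exactly the binding core (`coreStart(builtinDesign("dr401_9mer"))`
is 3). The randomized 13mer design `A-X13-G` diversifies positions P(-2)
through P11 around a central core and admits shifted registers. The constant
DNA context of each design carries the 3C-protease-site-encoding sequence
and an allele-identifying polymorphic segment; the read filter requires an
exact match to both, mirroring amplicons that span the peptide-encoding
region through the allele's polymorphic stretch.

# The synthetic selection simulator

The simulator is first-class, tested code: it gives every downstream stage a
no-download test surface with known answers.

**Naive libraries.** `sampleNaive()` draws each randomized codon as N-N-K
(N uniform over A/C/G/T, K over G/T), so codon-level redundancy is exact:
leucine (3 NNK codons) appears three times as often as methionine (1), TAA
and TGA never occur at randomized sites, and the amber stop TAG occurs at
1/32 per codon (removed downstream by the stop filter, as in the real
pipeline). Fixed flank residues use one canonical codon each, reflecting
template-encoded constant regions.

**Planted binding model.** A `GroundTruthModel` carries a 9 x 20 score
matrix on the log2-enrichment scale (the same scale the realized PSSM is
measured on, which is what makes planted-vs-recovered correlations
meaningful), a per-round logistic stringency, and a threshold. The default
motif is DR401-flavoured: P1 prefers large hydrophobics, P4 acidics (widened
to D/E/Q/N), P6 polars, P9 small residues including cysteine, plus a weak
P7 preference. The anchor sets are chosen with comparable aggregate NNK
codon mass so that every anchor position contributes comparably to
selection; without this balance, selection can satisfy its threshold while
ignoring an NNK-rare anchor entirely, and that anchor's planted preferences
never materialize in the realized enrichment. The threshold defaults to the
0.95 quantile of the exact naive core-score distribution, computed by
convolving the per-position score distributions under NNK frequencies, so
the binder fraction is a property of the model, not of a sample.

**Selection.** Each round retains a read with probability
`plogis(stringency * (coreScore - threshold))` and regrows survivors to a
fixed carryover depth by resampling with replacement. Stringency is
non-decreasing over rounds (default 1 to 2 in steps of 0.25). The defaults
keep selection in the logistic's quasi-linear regime through round 5; this
matters because in that regime the realized log2 enrichment is close to
proportional to the planted matrix, whereas a near-step selection saturates
depleted cells at the pseudocount floor and distorts the recovered motif.

**Registers on 13mer designs.** Each peptide draws a candidate register
from the model's register mixture (default 60% central); the drawn register
remains the truth unless another permissible window outscores it by more
than a stickiness margin (default 1.5 score units), in which case that
window becomes the truth. The margin stands in for register preferences
outside the 9mer core that a core-only PSSM cannot express. Without it,
labels drawn purely from the mixture are inconsistent with the sequence
signal: about 13% of binders score strictly higher in a shifted window, so
no inference procedure could recover more than ~87% of central labels. With
the margin, register labels are consistent with inferable structure, and
the realized register distribution among binders (roughly 20% per register,
central slightly favoured) matches the diversity reported for real 13mer
libraries.

**Errors.** `injectErrors()` substitutes bases independently at a given
rate and marks a fraction of bases with Phred < 20; the truth map records
each corrupted read's error-free parent. The quality model is two-valued
because the pipeline's only quality rule is the Phred-20 cut. There is no
indel or PCR-bias model: length-mismatched reads are discarded by the
filter anyway, and abundance bias would not change any per-position
statistic computed on unique peptides.

**What the simulator does not emulate.** Real amplicon data have
position-dependent error rates, quality-correlated errors, chimeras and
abundance-dependent PCR bias; the simulator's errors are uniform and
independent. Passing tests therefore demonstrate the correctness of the
statistical machinery under the stated model, not robustness to every
artifact of real sequencing runs.

# Read processing

`filterReads()` applies the filter cascade: exact expected length, exact
match to both constant regions (3C site and polymorphic segment), known
inline round barcode (unknown barcodes are counted in the attrition report,
never silently dropped), no peptide-encoding base below Phred-33 20, and
the NNK codon pattern (third base G or T) at every randomized codon.

`collapseErrors()` removes likely PCR/sequencing children of
high-prevalence peptides within a round: a sequence is discarded iff a
sufficiently more prevalent retained sequence lies within a tiered Hamming
radius — distance 1 from any more prevalent sequence, distance 2 at a
100-fold count ratio, distance 3 at a 10,000-fold ratio. Sequences are
processed in descending count order with lexicographic tie-breaks, making
the greedy pass deterministic; ties in count never discard one another. The
implementation finds radius-1 neighbours by exact single-substitution hash
probes and only scans the short descending list of 100-fold-more-prevalent
comparators for radii 2-3, but it is tested for exact identity against an
O(n^2) all-pairs oracle. A `compare = "all"` switch makes discarded
sequences also act as comparators, for users who prefer the stricter
reading.

`translateAndTabulate()` translates with the standard genetic code, drops
stop-containing sequences, merges synonymous DNA variants, and records each
peptide's final round of observation.

# Enrichment, significance and logos

Positional frequencies are unweighted — each unique peptide counts once —
matching unweighted repertoire heat maps. Log2-fold enrichment compares a
selected round to the unselected library with a 0.1-percentage-point
pseudocount in both numerator and denominator: matrices are finite
everywhere, identity gives exactly zero, and the transform is antisymmetric
under swapping the two libraries. Significance uses a two-sided exact
binomial test per position/residue on up to 10,000 sampled peptides against
the unselected frequency as the null, Bonferroni-corrected over all
positions x 20 cells (180 for a 9mer library).

Kullback-Leibler logos report per-position information
`I_p = sum_a f_a log2(f_a / bg_a)` in bits. Letter heights use the signed
convention `h_a = I_p (f_a - bg_a) / sum_a |f_a - bg_a|`: enriched residues
point up, depleted down, and absolute heights at a position sum exactly to
the information content. Display-library logos use the matched unselected
library's positional average as background; external peptide sets use the
packaged UniProt average frequencies. `algorithmMotif()` builds the logo of
predicted binder cores from an external predictor's scores on a random
background set, applying the predictor's published binder cutoff.

# Register deconvolution

For single-register (9mer) libraries, the 20 x 9 PSSM is the round-5 log2
enrichment transferred without positional weighting; `assignRegister()`
scores every 9mer window of each peptide (seven for a 15mer) and peptides
scoring highest in a shifted window, regardless of score, are out of
register. Ties prefer the designed register, then the lowest offset —
ties are vanishingly rare on real-valued matrices, and the designed
register is the natural reference for the in/out-of-register dichotomy.

For multi-register (13mer) libraries and external sets, `gibbsCluster()`
samples (cluster, offset) assignments to maximize the size-weighted KLD of
pseudocount-smoothed cluster matrices against a data-derived background
(beta = 50 effective pseudocounts; additive, no substitution-matrix
blurring — the constant is fixed and documented so tests are stable).
Annealed sweeps (linear temperature decay from 1.5, five greedy sweeps at
the end) are followed after every sweep by cluster-level phase-shift moves
(shift all members' offsets by up to +-3, keep if the objective improves),
which rescue the sampler from coherently shifted local optima. The cluster
count is chosen by maximum mean KLD over the candidate range, after
subtracting from each cluster a penalty of 0.8 times its best explanation
under any other cluster's matrix: redundant clusters that re-describe one
another's motif (as happens when one true motif is split) cancel their own
apparent information gain, while genuinely distinct motifs are unaffected.
With outlier removal enabled, peptides whose best available log-odds score
falls below the trash threshold (default 0) are parked outside the
clusters; this isolates composition-breaking peptides such as poly-Gly/Pro
stretches. Cluster labels are identifiable only up to permutation, so all
tests compare partitions, never labels. For 13mer data both views are
available and labelled distinctly: clustering with a 13-long motif (no
within-peptide offsets; registers surface as clusters) and 9mer-core
clustering (registers surface as offsets).

# Predictor training

Training examples from a selection table map each peptide's final round of
observation linearly to a target in [0, 1] (`final_round / R`; linear is the
minimal monotone choice and is overridable), with peptides seen only in the
unselected library as target-0 negatives; only randomized residues are
emitted, and the set is capped (default 80,000) by seeded stratified
subsampling that preserves round proportions. MS-style sets pair each
positive with one uniform permutation of its own residues, so the negative
class carries exactly the positive class's residue composition.

The model is an ensemble of single-hidden-layer networks over a grid of
encodings (one-hot, scaled BLOSUM50 rows) x hidden widths (10, 40) x
cross-validation partitions (5) x seeds (2) — 40 members by default; all
tests and the acceptance analyses use smaller documented grids sized to
their data. Each member trains by mini-batch Adam (batch 512, learning rate
0.01, weight decay 1e-4) on mean-squared error with a sigmoid output, early
stopping on its held-out partition (patience 20, max 500 epochs). The
weight decay is load-bearing: with 180 one-hot inputs a small network can
memorize thousands of examples instead of using shared positional features,
and an unregularized member generalizes poorly even on linearly separable
data.

For peptides longer than nine residues, the core window is re-chosen every
five epochs as the max-scoring window under the current network, and flank
residues enter as mean-encoded summaries of up to two residues per side
plus scaled flank-length features. The core search initializes at the
central window — the designed register for these libraries, and the
expected-placement convention of register-scanning trainers — because a
degenerate initialization (all cores at window 1) lets the network lock
into a shifted internal motif it cannot escape.

Prediction is the member mean of best-window scores (in [0, 1], higher =
stronger; an inverted output is available for comparison with tools that
report the complement), with the reported core the modal best window across
members. Percent ranks compare a score with the ensemble's scores on 50,000
random background peptides drawn from UniProt-average frequencies (seed
recorded in the model): the rank is the percentage of calibration scores at
or above the query, so ranks are monotone non-increasing in score.

# Benchmarking

`minimalEpitopes()` collapses nested peptide sets to the member contained
in all others and drops peptides matching a user-supplied exclusion list (a
stand-in for mapping against immunoglobulin/HLA sequences). Partial
overlaps without containment are deliberately not merged. `generateDecoys()`
tiles each source protein with lengths drawn from the positives' length
distribution at an eight-residue overlap between subsequent tiles (step =
length - 8), randomly shifting a final overrunning tile to an in-bounds
start, then samples decoys length-matched at 1:1 or 1:19 while rejecting
any tile sharing a 9mer substring with a positive or an already-chosen
decoy. Decoys are drawn only from proteins supplied by the caller (in
practice, proteins contributing at least one positive), approximating
expression matching.

AUC uses the rank (Mann-Whitney) statistic with ties counted half — tested
against an independent implementation — and equals the trapezoidal
integral of the reported ROC points. The top-5% PPV takes the top
`ceiling(0.05 N)` peptides of a 1:19 set under a stable descending sort
(ties keep the set's internal order; the ceiling choice is documented
because printed protocols rarely state it). `comparePredictors()` contrasts
the cores of peptides ranked in the top decile by only one of two
predictors against the cores ranked top by both, cell-by-cell binomial
tests with Bonferroni correction, returning signed significance tables.

# IC50 fitting

Relative binding is `(FP_sample - FP_free) / (FP_nocomp - FP_free)` per
replicate (never pre-averaged); the transform is affine-invariant in the
polarization readings. Curves fit `y = 1 / (1 + conc / IC50)` by nonlinear
least squares with IC50 parameterized on the log10 scale, because tested
concentrations span four orders of magnitude (five-fold dilutions from 20
uM to 1.28 nM) and the log parameterization makes the optimization
well-conditioned; confidence intervals come from the parameter covariance.
Fits outside `[min(conc)/100, 100 max(conc)]` or non-convergent fits are
censored and reported against the tested range ("> 20000 nM") rather than
extrapolated. Two-point assays invert each point
(`IC50_i = c_i y_i / (1 - y_i)`, replicates averaged per concentration)
and combine by geometric mean — the natural mean on the log scale, and
exactly equal to the full fit on noise-free two-point data.
Prediction-affinity correlations regress predictions on log10 IC50 by
default (both scales are available) and flag negative correlations.

# Problem sizes and numerical choices

The test suite and the acceptance analysis exercise the full pipeline at
10^5 reads per round over five rounds with substitution rate 10^-3 — the
scale at which round-5 repertoires hold several thousand unique peptides,
enough that positional enrichment estimates are limited by the motif, not
by counting noise. Module tests use smaller seeded instances (hundreds of
peptides for the Gibbs sampler, 2 x 10^4 reads per round for shared
fixtures). All randomness is seeded; seeded runs are bit-reproducible.
Degenerate inputs are rejected with specific errors (ragged peptide sets,
zero background cells, peptides shorter than a core, assays with an invalid
polarization window), and every matrix the package emits is finite by
construction.

# Known limitations

The simulator's selection model is logistic in an additive core score; real
selections include avidity, expression and display artifacts that are not
additive in sequence. The predictor is allele-specific (no pan-allele
sharing), trains on CPU-scale grids, and its absolute scores are not
affinities — only percent ranks and benchmark statistics are comparable
across models. The Gibbs sampler has no insertion/deletion moves (cores are
fixed-length), and its cluster-number choice depends on the documented
redundancy penalty; k is best read alongside the KLD-vs-k profile it
reports. Full-scale reproduction of published repertoires requires the
deposited sequencing data and is outside the test surface.
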