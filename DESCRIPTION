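Package: mhc2display
Title: Repertoire-Scale Analysis of Yeast-Displayed MHC Class II Peptide Libraries
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for determining class II MHC peptide-binding repertoires from
    yeast surface display selections of NNK-randomized peptide libraries. Covers
    the full computational workflow: simulation of degenerate-codon libraries
    under a planted binding model, amplicon read filtering with tiered
    Hamming-distance error collapse, positional enrichment and significance
    matrices, Kullback-Leibler sequence logos, register deconvolution by PSSM
    scanning or Gibbs-sampling clustering, round-weighted neural-network
    binding predictors with percent-rank calibration, decoy-based benchmarking
    (ROC-AUC, top-5 percent PPV), and fluorescence-polarization competition
    IC50 fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, MotifDiscovery, Classification, Epitope
RoxygenNote: 7.3.3
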