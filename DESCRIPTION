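Package: cine4dqa
Title: Automated Comparison of Motion Artifacts in Cine 4D CT Image Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and compares respiratory motion artifacts in two
    retrospectively sorted cine four-dimensional computed tomography (4D CT)
    image sets. Computes the normalized correlation coefficient (without mean
    centering) between spatially adjacent axial slices, a couch-transition
    discontinuity metric that contrasts the cross-transition edge-slice
    similarity with its intracouch neighbor baseline, and a residual-matrix
    sign score in [-1, +1] that identifies which of two sortings of the same
    acquisition shows fewer or smaller artifacts. Includes a deforming thorax
    phantom with cine acquisition, respiratory surrogate traces with
    editable inhalation peaks, phase-based sorting into respiratory bins for
    end-to-end validation without patient data, observer-score aggregation
    with agreement tables, and exact Wilcoxon signed-rank tests by full sign
    enumeration with mid-ranks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
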