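#' Edge-slice discontinuity metric at one couch transition
#'
#' At couch transition `n` the last slice of block `n` and the first slice
#' of block `n + 1` are spatially adjacent but were acquired in different
#' breathing cycles; their intracouch neighbors were acquired in the same
#' cycle and so carry only anatomical (non-respiratory) change. The
#' transition metric contrasts the two:
#' \deqn{D_{b,n} = \tfrac12\,(C_{n,n} + C_{n,n+1}) - C_n}
#' where \eqn{C_n} is the NCC between the edge slices `(n, S)` and
#' `(n+1, 1)`, \eqn{C_{n,n}} between `(n, S-1)` and `(n, S)`, and
#' \eqn{C_{n,n+1}} between `(n+1, 1)` and `(n+1, 2)`. A large `d_value`
#' means the cross-transition similarity falls well below its local
#' intracouch baseline — the signature of a sorting artifact.
#'
#' @param volume a [phase_volume()] with `S >= 2`.
#' @param n couch transition index in `[1, N - 1]`.
#' @return A list of class `transition_similarity` with fields `n`,
#'   `edge_ncc`, `left_ncc`, `right_ncc`, `d_value` (all dimensionless;
#'   `d_value` in `[-2, 2]`).
#' @export
transition_similarity <- function(volume, n) {
  stopifnot(inherits(volume, "phase_volume"))
  if (volume$S < 2L)
    c4_stop("insufficient slices for neighbor baseline (S >= 2 required)",
            "insufficient_slices")
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > volume$N - 1L)
    c4_stop(sprintf("couch transition n = %d outside [1, %d]", n, volume$N - 1L),
            "index_out_of_range")
  S <- volume$S
  edge  <- ncc(get_slice(volume, n, S),      get_slice(volume, n + 1L, 1L))
  left  <- ncc(get_slice(volume, n, S - 1L), get_slice(volume, n, S))
  right <- ncc(get_slice(volume, n + 1L, 1L), get_slice(volume, n + 1L, 2L))
  structure(list(n = n, edge_ncc = edge, left_ncc = left, right_ncc = right,
                 d_value = (left + right) / 2 - edge),
            class = "transition_similarity")
}

#' Artifact matrix of a sorted 4D CT image set
#'
#' Evaluates [transition_similarity()] at every couch transition of every
#' phase bin, giving a `B x (N - 1)` matrix whose rows are respiratory
#' phase bins (in phase-label order) and whose columns are couch
#' transitions `1 ... N - 1`.
#'
#' @param image_set a [fourdct()] image set with `S >= 2`, `N >= 2`.
#' @return A numeric matrix of class `artifact_matrix`, with the phase
#'   labels as row names and a `provenance` attribute carried over from
#'   the image set.
#' @export
artifact_matrix <- function(image_set) {
  stopifnot(inherits(image_set, "fourdct"))
  if (image_set$N < 2L)
    c4_stop("at least 2 couch positions required for a transition", "insufficient_slices")
  if (image_set$S < 2L)
    c4_stop("insufficient slices for neighbor baseline (S >= 2 required)",
            "insufficient_slices")
  B <- length(image_set$volumes)
  d <- matrix(0, nrow = B, ncol = image_set$N - 1L,
              dimnames = list(image_set$phase_labels, NULL))
  for (b in seq_len(B)) {
    vol <- image_set$volumes[[b]]
    # NCCs shared between consecutive transitions are reused via the full
    # adjacent profile: D_b,n = (profile[m-1] + profile[m+1])/2 - profile[m]
    # at m = S*n.
    prof <- adjacent_profile(vol)$value
    m <- image_set$S * seq_len(image_set$N - 1L)
    d[b, ] <- (prof[m - 1L] + prof[m + 1L]) / 2 - prof[m]
  }
  structure(d, class = c("artifact_matrix", class(d)),
            provenance = image_set$provenance)
}

#' Residual matrix between two artifact matrices
#'
#' Element-wise difference `original - recalculated` of the two
#' [artifact_matrix()] objects. A positive entry indicates higher
#' edge-slice similarity (fewer/smaller artifacts) at that transition and
#' phase in the *recalculated* set; discontinuities that are static in
#' both sets — e.g. an abrupt anatomical boundary — cancel exactly.
#'
#' @param original artifact matrix of the set playing "original".
#' @param recalculated artifact matrix of the set playing "recalculated".
#' @return A numeric matrix of class `residual_matrix`.
#' @export
residual_matrix <- function(original, recalculated) {
  stopifnot(inherits(original, "artifact_matrix"),
            inherits(recalculated, "artifact_matrix"))
  if (!all(dim(original) == dim(recalculated)) ||
      !identical(rownames(original), rownames(recalculated)))
    c4_stop("artifact matrices differ in dimensions or phase labels",
            "inconsistent_dimensions")
  delta <- unclass(original) - unclass(recalculated)
  structure(delta, class = c("residual_matrix", class(delta)))
}

#' Score a residual matrix
#'
#' Sums each phase-bin row of the residual matrix and assigns the phase
#' +1 if the sum is positive, -1 if negative, and 0 if zero; the overall
#' score is the mean of the `B` per-phase signs and always lies in
#' `[-1, +1]`. A row sum with magnitude at most `zero_tol * (N - 1)` is
#' treated as zero, which keeps self-comparison exactly 0 under
#' floating-point noise.
#'
#' @param residual a [residual_matrix()].
#' @param zero_tol per-transition tolerance for calling a row sum zero
#'   (default `1e-12`).
#' @return A list of class `comparison_report` with fields `residual`,
#'   `phase_sums`, `phase_signs`, `overall_score`, and `localization`
#'   (per-phase couch-transition index of the largest `|residual|` entry).
#' @export
score_residual <- function(residual, zero_tol = 1e-12) {
  stopifnot(inherits(residual, "residual_matrix"))
  sums <- rowSums(residual)
  tol <- zero_tol * ncol(residual)
  signs <- ifelse(abs(sums) <= tol, 0, sign(sums))
  structure(
    list(residual = residual,
         phase_sums = sums,
         phase_signs = signs,
         overall_score = mean(signs),
         localization = apply(abs(residual), 1, which.max)),
    class = "comparison_report")
}

#' Compare two sorted 4D CT image sets
#'
#' Runs the full automated comparison: artifact matrices of both sets,
#' their residual (`set_original` minus `set_recalculated`), and the sign
#' score. A positive `overall_score` means `set_recalculated` shows fewer
#' or smaller couch-transition artifacts than `set_original`; negative
#' means the opposite; 0 means no difference. The comparison is exactly
#' antisymmetric in its arguments.
#'
#' @param set_original,set_recalculated two [fourdct()] image sets with
#'   identical `B`, `N`, `S` and slice dimensions (typically the same cine
#'   acquisition sorted with two different breathing traces).
#' @param zero_tol passed to [score_residual()].
#' @return A `comparison_report`; see [score_residual()].
#' @export
compare_sets <- function(set_original, set_recalculated, zero_tol = 1e-12) {
  stopifnot(inherits(set_original, "fourdct"), inherits(set_recalculated, "fourdct"))
  if (!same_geometry(set_original, set_recalculated))
    c4_stop("image sets differ in B, N, S, phase labels or slice dimensions",
            "inconsistent_dimensions")
  score_residual(
    residual_matrix(artifact_matrix(set_original),
                    artifact_matrix(set_recalculated)),
    zero_tol = zero_tol)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("4D CT comparison: overall score %+.2f (B = %d phases, %d transitions)\n",
              x$overall_score, nrow(x$residual), ncol(x$residual)))
  cat("  per-phase signs:", paste(sprintf("%+d", as.integer(x$phase_signs)),
                                  collapse = " "), "\n")
  cat("  positive score favors the second (recalculated) set\n")
  invisible(x)
}
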