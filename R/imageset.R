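#' Sorted phase-bin volume of a cine 4D CT acquisition
#'
#' A `phase_volume` holds the axial slices of one respiratory phase bin,
#' already sorted and stacked in spatial order along the scan axis. The
#' `N * S` slices are grouped into `N` couch blocks of `S` slices each:
#' slice `(n, s)` is the `s`-th slice of couch block `n`, and slice
#' `(n, S)` is spatially adjacent to slice `(n + 1, 1)` across couch
#' transition `n`.
#'
#' @param data numeric 3-D array `[n_rows, n_cols, N * S]` of pixel values
#'   in Hounsfield Units, slices ordered by ascending scan-axis position.
#' @param S slices per couch position (a positive integer; the third array
#'   dimension must be divisible by `S`).
#' @param phase_label phase-bin label in percent (e.g. 0, 10, ..., 90).
#' @param acquisition_times optional numeric vector of per-slice
#'   acquisition times in seconds (length `N * S`).
#'
#' @return An object of class `phase_volume` with fields `data`, `N`, `S`,
#'   `phase_label` and (optionally) `acquisition_times`.
#' @export
phase_volume <- function(data, S, phase_label, acquisition_times = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    c4_stop("'data' must be a 3-D array [rows, cols, slices]", "invalid_argument")
  d <- dim(data)
  if (d[1] < 2L || d[2] < 2L)
    c4_stop("axial slices must be at least 2 x 2 pixels", "invalid_dimensions")
  if (!all(is.finite(data)))
    c4_stop("all pixel values must be finite", "nonfinite_pixels")
  S <- as.integer(S)
  if (is.na(S) || S < 1L)
    c4_stop("'S' must be a positive integer", "invalid_argument")
  if (d[3] %% S != 0L)
    c4_stop(sprintf("slice count not divisible by S (%d slices, S = %d)", d[3], S),
            "indivisible_slice_count")
  stopifnot_scalar_number(phase_label, "phase_label")
  if (!is.null(acquisition_times) && length(acquisition_times) != d[3])
    c4_stop("'acquisition_times' must have one entry per slice", "invalid_argument")
  structure(
    list(data = data, N = d[3] %/% S, S = S, phase_label = phase_label,
         acquisition_times = acquisition_times),
    class = "phase_volume"
  )
}

#' Extract one axial slice from a phase volume
#'
#' @param volume a [phase_volume()].
#' @param n 1-based couch position index in `[1, N]`.
#' @param s 1-based slice index within the couch block, in `[1, S]`.
#' @return The slice as a numeric matrix of Hounsfield Units.
#' @export
get_slice <- function(volume, n, s) {
  stopifnot(inherits(volume, "phase_volume"))
  if (n < 1L || n > volume$N || s < 1L || s > volume$S)
    c4_stop(sprintf("slice index (n = %d, s = %d) outside [1,%d] x [1,%d]",
                    n, s, volume$N, volume$S), "index_out_of_range")
  volume$data[, , (n - 1L) * volume$S + s]
}

#' Sorted 4D CT image set
#'
#' Bundles `B` sorted [phase_volume()]s (one per respiratory phase bin)
#' into a single image set. All volumes must share the same couch count
#' `N`, slices-per-couch `S`, and in-plane dimensions; phase labels must be
#' strictly increasing.
#'
#' @param volumes list of [phase_volume()] objects in phase order.
#' @param provenance free-text label recording how this sorting was
#'   produced (e.g. which breathing trace / peak set was used).
#' @return An object of class `fourdct` with fields `volumes`,
#'   `phase_labels`, `N`, `S`, `n_rows`, `n_cols`, `provenance`.
#' @export
fourdct <- function(volumes, provenance = "") {
  if (!is.list(volumes) || length(volumes) < 1L ||
      !all(vapply(volumes, inherits, logical(1), "phase_volume")))
    c4_stop("'volumes' must be a non-empty list of phase_volume objects",
            "invalid_argument")
  labels <- vapply(volumes, function(v) as.numeric(v$phase_label), numeric(1))
  if (any(diff(labels) <= 0))
    c4_stop("phase labels must be strictly increasing with no duplicates",
            "invalid_phase_labels")
  dims <- vapply(volumes, function(v) c(dim(v$data)[1:2], v$N, v$S), numeric(4))
  if (any(dims != dims[, 1]))
    c4_stop("all phase volumes must share identical (n_rows, n_cols, N, S)",
            "inconsistent_dimensions")
  structure(
    list(volumes = volumes, phase_labels = labels,
         N = volumes[[1]]$N, S = volumes[[1]]$S,
         n_rows = dim(volumes[[1]]$data)[1], n_cols = dim(volumes[[1]]$data)[2],
         provenance = provenance),
    class = "fourdct"
  )
}

#' @export
print.fourdct <- function(x, ...) {
  cat(sprintf(
    "4D CT image set: B = %d phase bins, N = %d couch positions, S = %d slices/couch\n",
    length(x$volumes), x$N, x$S))
  cat(sprintf("  slice size %d x %d px; %d couch transitions per phase\n",
              x$n_rows, x$n_cols, x$N - 1L))
  cat(sprintf("  phases: %s\n", paste0(x$phase_labels, "%", collapse = " ")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
print.phase_volume <- function(x, ...) {
  cat(sprintf("phase volume %g%%: N = %d couch x S = %d slices of %d x %d px\n",
              x$phase_label, x$N, x$S, dim(x$data)[1], dim(x$data)[2]))
  invisible(x)
}

# Shape compatibility between two image sets (phase labels included).
same_geometry <- function(a, b) {
  identical(a$phase_labels, b$phase_labels) &&
    a$N == b$N && a$S == b$S && a$n_rows == b$n_rows && a$n_cols == b$n_cols
}
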