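#' Read a sorted 4D CT image set from disk
#'
#' Two on-disk layouts are supported:
#'
#' * `"array-stack"` — a dependency-free text layout: a directory holding
#'   `meta.json` (fields `format = "cine4dqa-array-stack-v1"`, `B`, `N`,
#'   `S`, `n_rows`, `n_cols`, `phase_labels`) plus one CSV per phase bin,
#'   `phase_<label>.csv`, with `N * S` header-less rows; row `i` is slice
#'   `i` flattened row-major (`n_rows * n_cols` values in Hounsfield
#'   Units), slices in ascending scan-axis order.
#' * `"nifti-per-phase"` — a directory holding `meta.json` (`S`,
#'   `phase_labels`) and one NIfTI volume `phase_<label>.nii.gz` per phase
#'   bin, each a `n_rows x n_cols x N*S` array in scan-axis order.
#'
#' `"dicom-series"` is recognized but not implemented (no DICOM reader is
#' available to this package); requesting it raises an `unsupported_layout`
#' error.
#'
#' @param path directory produced by [write_imageset()] (or assembled by
#'   hand following the layout above).
#' @param layout one of `"array-stack"`, `"nifti-per-phase"`.
#' @param S slices per couch position; only needed when absent from
#'   `meta.json`.
#' @return A [fourdct()] image set.
#' @seealso [write_imageset()] for the inverse operation.
#' @export
read_imageset <- function(path, layout = c("array-stack", "nifti-per-phase",
                                           "dicom-series"), S = NULL) {
  layout <- match.arg(layout)
  if (layout == "dicom-series")
    c4_stop("unsupported layout 'dicom-series': no DICOM reader available",
            "unsupported_layout")
  if (!dir.exists(path))
    c4_stop(sprintf("input directory not found: %s", path), "missing_input")
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    c4_stop(sprintf("missing meta.json in %s", path), "missing_input")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  S <- as.integer(if (!is.null(meta$S)) meta$S else S)
  if (is.na(S) || length(S) != 1L)
    c4_stop("slices per couch (S) not in meta.json and not supplied", "missing_metadata")
  labels <- as.numeric(meta$phase_labels)

  volumes <- lapply(labels, function(lab) {
    if (layout == "array-stack") {
      f <- file.path(path, sprintf("phase_%03d.csv", as.integer(lab)))
      if (!file.exists(f)) c4_stop(sprintf("missing phase file: %s", f), "missing_input")
      m <- as.matrix(data.table::fread(f, header = FALSE))
      nr <- as.integer(meta$n_rows); nc <- as.integer(meta$n_cols)
      if (ncol(m) != nr * nc)
        c4_stop(sprintf("phase %g: %d values per slice, expected %d x %d",
                        lab, ncol(m), nr, nc), "inconsistent_dimensions")
      # rows are row-major flattened slices
      arr <- array(0, dim = c(nr, nc, nrow(m)))
      for (i in seq_len(nrow(m))) arr[, , i] <- matrix(m[i, ], nr, nc, byrow = TRUE)
    } else {
      f <- file.path(path, sprintf("phase_%03d.nii.gz", as.integer(lab)))
      if (!file.exists(f)) c4_stop(sprintf("missing phase file: %s", f), "missing_input")
      arr <- array(as.numeric(RNifti::readNifti(f)), dim = dim(RNifti::readNifti(f)))
    }
    phase_volume(arr, S = S, phase_label = lab)
  })
  fourdct(volumes, provenance = if (!is.null(meta$provenance)) meta$provenance else "")
}

#' Write a sorted 4D CT image set to disk
#'
#' @param image_set a [fourdct()] image set.
#' @param path output directory (created if needed).
#' @param layout `"array-stack"` (text CSV) or `"nifti-per-phase"`.
#' @return `path`, invisibly.
#' @export
write_imageset <- function(image_set, path,
                           layout = c("array-stack", "nifti-per-phase")) {
  layout <- match.arg(layout)
  stopifnot(inherits(image_set, "fourdct"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = if (layout == "array-stack") "cine4dqa-array-stack-v1"
             else "cine4dqa-nifti-per-phase-v1",
    B = length(image_set$volumes), N = image_set$N, S = image_set$S,
    n_rows = image_set$n_rows, n_cols = image_set$n_cols,
    phase_labels = image_set$phase_labels, provenance = image_set$provenance)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (v in image_set$volumes) {
    lab <- as.integer(v$phase_label)
    if (layout == "array-stack") {
      nsl <- dim(v$data)[3]
      lines <- vapply(seq_len(nsl), function(i)
        paste(sprintf("%.17g", as.vector(t(v$data[, , i]))), collapse = ","),
        character(1))
      writeLines(lines, file.path(path, sprintf("phase_%03d.csv", lab)))
    } else {
      RNifti::writeNifti(v$data, file.path(path, sprintf("phase_%03d.nii.gz", lab)))
    }
  }
  invisible(path)
}

#' Write a comparison report to disk
#'
#' Emits `report.json` (overall score, per-phase sums, signs and artifact
#' localization) and `residual.csv` (the full residual matrix, one row per
#' phase bin, one column per couch transition; 1-based indexing in the
#' headers).
#'
#' @param report a `comparison_report` from [compare_sets()] or
#'   [score_residual()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(overall_score = report$overall_score,
         phase_labels = as.numeric(rownames(report$residual)),
         phase_sums = unname(report$phase_sums),
         phase_signs = unname(report$phase_signs),
         localization = unname(report$localization)),
    file.path(path, "report.json"), auto_unbox = TRUE, digits = NA)
  delta <- unclass(report$residual)
  header <- paste(c("phase", paste0("transition_", seq_len(ncol(delta)))),
                  collapse = ",")
  lines <- vapply(seq_len(nrow(delta)), function(b)
    paste(c(rownames(delta)[b], sprintf("%.17g", delta[b, ])), collapse = ","),
    character(1))
  writeLines(c(header, lines), file.path(path, "residual.csv"))
  invisible(path)
}

#' Read back a comparison report written by [write_report()]
#'
#' @param path directory holding `report.json` and `residual.csv`.
#' @return A `comparison_report` object.
#' @export
read_report <- function(path) {
  js <- jsonlite::read_json(file.path(path, "report.json"), simplifyVector = TRUE)
  tab <- data.table::fread(file.path(path, "residual.csv"))
  delta <- as.matrix(tab[, -1])
  rownames(delta) <- as.character(tab[[1]])
  colnames(delta) <- NULL
  structure(
    list(residual = structure(delta, class = "residual_matrix"),
         phase_sums = js$phase_sums, phase_signs = js$phase_signs,
         overall_score = js$overall_score, localization = js$localization),
    class = "comparison_report")
}
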