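#' Normalized correlation coefficient between two axial slices
#'
#' Computes the NCC of two axial CT slices as the cosine similarity of
#' their raw pixel values,
#' \deqn{C_{A,B} = \frac{\sum_{u,v} I_A(u,v)\, I_B(u,v)}
#'   {\sqrt{\sum I_A^2}\,\sqrt{\sum I_B^2}},}
#' with no mean subtraction: the Hounsfield Units are used exactly as
#' stored. This is deliberate — it is *not* the Pearson correlation, and
#' centering would change the metric. Identical slices give +1; the value
#' always lies in \eqn{[-1, +1]} (clamped against floating-point
#' rounding). Accumulation is in double precision regardless of the input
#' storage type.
#'
#' @param a,b numeric matrices of identical dimensions (pixel values in
#'   Hounsfield Units).
#' @return The NCC as a single number in `[-1, 1]`.
#' @examples
#' a <- matrix(c(1, 2, 3, 4), 2, 2)
#' ncc(a, a)                       # +1
#' ncc(a, matrix(c(4, 3, 2, 1), 2, 2))
#' @export
ncc <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b))
    c4_stop("'a' and 'b' must be matrices", "invalid_argument")
  if (!all(dim(a) == dim(b)))
    c4_stop(sprintf("dimension mismatch: %dx%d vs %dx%d",
                    nrow(a), ncol(a), nrow(b), ncol(b)), "dimension_mismatch")
  a <- as.numeric(a); b <- as.numeric(b)
  qa <- sum(a * a); qb <- sum(b * b)
  if (qa == 0 || qb == 0)
    c4_stop("degenerate slice: all pixel values are zero", "degenerate_slice")
  min(1, max(-1, sum(a * b) / (sqrt(qa) * sqrt(qb))))
}

#' Adjacent-slice NCC profile of a sorted phase volume
#'
#' Concatenates the `N * S` slices of one phase bin in scan-axis order and
#' computes the NCC between every pair of adjacent slices `m` and `m + 1`,
#' `m` in `[1, N*S - 1]`. Entries at `m = S, 2S, ..., (N-1)S` cross a
#' couch transition: those two slices were acquired in different breathing
#' cycles, so a drop there (relative to its intracouch neighbors) signals
#' a respiratory sorting artifact.
#'
#' @param volume a [phase_volume()] with no all-zero slices.
#' @return A data frame with columns `m` (1-based adjacent-pair index),
#'   `value` (NCC), and `is_transition` (`TRUE` where `m` is a couch
#'   transition).
#' @export
adjacent_profile <- function(volume) {
  stopifnot(inherits(volume, "phase_volume"))
  total <- volume$N * volume$S
  vals <- numeric(total - 1L)
  for (m in seq_len(total - 1L)) {
    vals[m] <- tryCatch(
      ncc(volume$data[, , m], volume$data[, , m + 1L]),
      cine4dqa_error = function(e)
        c4_stop(sprintf("at adjacent pair m = %d: %s", m, conditionMessage(e)),
                "profile_failure"))
  }
  m <- seq_len(total - 1L)
  data.frame(m = m, value = vals, is_transition = m %% volume$S == 0L)
}
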