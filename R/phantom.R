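#' Configuration of the breathing thorax phantom
#'
#' Defines a minimal deforming-thorax phantom for cine 4D CT simulation:
#' a circular soft-tissue body containing two elliptical lungs, with a
#' hemispherical diaphragm dome rising into the right lung whose apex
#' moves along the scan axis with respiration. The geometry is deliberately
#' simple — the transition metric only needs a moving high-contrast
#' boundary that crosses couch transitions.
#'
#' The scan axis covers `N * S * slice_thickness` mm; couch block `n`
#' holds slices `(n-1)*S + 1 ... n*S`, with slice centers at
#' `(k - 0.5) * slice_thickness`.
#'
#' @param image_size pixels per side of the square axial slice (>= 16).
#' @param pixel_spacing in-plane pixel size, mm.
#' @param slice_thickness axial slice spacing, mm.
#' @param N couch positions; `S` slices per couch position.
#' @param body_radius radius of the soft-tissue body disk, mm.
#' @param body_hu,lung_hu,diaphragm_hu,background_hu tissue attenuation
#'   values, HU.
#' @param diaphragm_rest_position scan-axis position (mm) of the dome apex
#'   at full exhale; default 60% of the scan span.
#' @param dome_radius radius of the hemispherical dome, mm.
#' @param lung_z_min,lung_z_max axial extent of the lungs, mm; the default
#'   `lung_z_max` (87.5% of span) puts a static, abrupt anatomical boundary
#'   inside a couch block, which a residual comparison must cancel out.
#' @param motion_amplitude peak-to-trough diaphragm excursion, mm.
#' @param breathing_period respiratory period, seconds.
#' @param motion_exponent positive even integer; the trajectory is
#'   `z(t) = z0 - A * sin(pi t / tau)^motion_exponent`, so larger values
#'   give the longer end-exhale dwell typical of quiet breathing.
#' @param cine_duration_per_couch seconds spent imaging each couch
#'   position (must cover at least one breathing period).
#' @param frame_interval seconds between reconstructed cine frames.
#' @param noise_sd Gaussian image noise, HU.
#' @param trace_dt sampling interval of the surrogate trace, seconds.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 64, pixel_spacing = 6,
                           slice_thickness = 2.5, N = 8, S = 8,
                           body_radius = 150, body_hu = 40, lung_hu = -750,
                           diaphragm_hu = 60, background_hu = -1000,
                           diaphragm_rest_position = NULL, dome_radius = 60,
                           lung_z_min = 0, lung_z_max = NULL,
                           motion_amplitude = 15, breathing_period = 4,
                           motion_exponent = 4,
                           cine_duration_per_couch = 5, frame_interval = 0.25,
                           noise_sd = 20, trace_dt = 0.04) {
  span <- N * S * slice_thickness
  if (is.null(diaphragm_rest_position)) diaphragm_rest_position <- 0.6 * span
  if (is.null(lung_z_max)) lung_z_max <- 0.875 * span
  cfg <- list(image_size = as.integer(image_size), pixel_spacing = pixel_spacing,
              slice_thickness = slice_thickness, N = as.integer(N),
              S = as.integer(S), body_radius = body_radius, body_hu = body_hu,
              lung_hu = lung_hu, diaphragm_hu = diaphragm_hu,
              background_hu = background_hu,
              diaphragm_rest_position = diaphragm_rest_position,
              dome_radius = dome_radius, lung_z_min = lung_z_min,
              lung_z_max = lung_z_max, motion_amplitude = motion_amplitude,
              breathing_period = breathing_period,
              motion_exponent = as.integer(motion_exponent),
              cine_duration_per_couch = cine_duration_per_couch,
              frame_interval = frame_interval, noise_sd = noise_sd,
              trace_dt = trace_dt, scan_span = span)
  if (cfg$image_size < 16L)
    c4_stop("'image_size' must be >= 16", "invalid_argument")
  if (cfg$cine_duration_per_couch < cfg$breathing_period)
    c4_stop("'cine_duration_per_couch' must cover >= one breathing period",
            "invalid_argument")
  if (cfg$frame_interval <= 0)
    c4_stop("'frame_interval' must be positive", "invalid_argument")
  if (cfg$motion_amplitude < 0)
    c4_stop("'motion_amplitude' must be non-negative", "invalid_argument")
  if (cfg$motion_exponent < 2L || cfg$motion_exponent %% 2L != 0L)
    c4_stop("'motion_exponent' must be a positive even integer", "invalid_argument")
  structure(cfg, class = "phantom_config")
}

#' Diaphragm apex trajectory
#'
#' `z(t) = z0 - A * sin(pi t / breathing_period)^motion_exponent`: full
#' exhale (apex at its rest position `z0`) at `t = 0`, full inhale (apex
#' displaced by `A` toward the feet) at mid-cycle, period equal to
#' `breathing_period`.
#'
#' @param config a [phantom_config()].
#' @param t time(s), seconds.
#' @return Apex position(s) along the scan axis, mm.
#' @export
diaphragm_trajectory <- function(config, t) {
  stopifnot(inherits(config, "phantom_config"))
  config$diaphragm_rest_position -
    config$motion_amplitude *
      sin(pi * t / config$breathing_period)^config$motion_exponent
}

# Surrogate displacement recorded by the external monitor: proportional to
# diaphragm excursion, maximal at full inhale.
surrogate_amplitude <- function(config, t) {
  config$motion_amplitude * sin(pi * t / config$breathing_period)^config$motion_exponent
}

#' Render one axial slice of the phantom
#'
#' Pixels are classified by geometry: background outside the body disk,
#' soft tissue inside it, air inside the lung ellipses (within their axial
#' extent), and diaphragm where the right-lung cross-section falls inside
#' the dome at depth `z_apex(t) - z`. Gaussian noise (`noise_sd` HU) is
#' added from the current RNG stream when `noise = TRUE`.
#'
#' @param config a [phantom_config()].
#' @param z scan-axis position of the slice, mm.
#' @param t acquisition time, seconds (moves the diaphragm).
#' @param noise add Gaussian noise? Disable for geometry-only renders.
#' @return A numeric `image_size x image_size` matrix of HU values.
#' @export
render_slice <- function(config, z, t, noise = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  sz <- config$image_size
  coord <- (seq_len(sz) - (sz + 1) / 2) * config$pixel_spacing
  x <- matrix(coord, sz, sz)         # varies along rows
  y <- matrix(coord, sz, sz, byrow = TRUE)
  R <- config$body_radius
  img <- matrix(config$background_hu, sz, sz)
  body <- x^2 + y^2 <= R^2
  img[body] <- config$body_hu
  # two elliptical lungs, mirrored about x = 0
  cx <- 0.37 * R; ax <- 0.30 * R; ay <- 0.47 * R
  in_lung_z <- z >= config$lung_z_min && z <= config$lung_z_max
  if (in_lung_z) {
    left  <- ((x + cx) / ax)^2 + (y / ay)^2 <= 1
    right <- ((x - cx) / ax)^2 + (y / ay)^2 <= 1
    img[body & (left | right)] <- config$lung_hu
    # hemispherical diaphragm dome in the right lung
    z_apex <- diaphragm_trajectory(config, t)
    depth <- z_apex - z
    if (depth > 0) {
      rd <- config$dome_radius
      r_dome <- if (depth >= rd) Inf else sqrt(rd^2 - (rd - depth)^2)
      dome <- (x - cx)^2 + y^2 <= r_dome^2
      img[body & right & dome] <- config$diaphragm_hu
    }
  }
  if (noise && config$noise_sd > 0)
    img <- img + matrix(stats::rnorm(sz * sz, 0, config$noise_sd), sz, sz)
  img
}

#' Simulate a cine 4D CT acquisition of the breathing phantom
#'
#' Images couch positions sequentially: couch `n` is acquired over
#' `[(n-1) * cine_duration_per_couch, n * cine_duration_per_couch)`, with
#' one reconstructed frame (a stack of all `S` slices of that couch) every
#' `frame_interval` seconds. A surrogate breathing trace covering the
#' whole acquisition is recorded, with its true inhalation peaks at the
#' analytic maxima of the surrogate. Image noise is drawn from the seeded
#' RNG, so two runs with the same seed are identical.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed for the image noise stream.
#' @return A list of class `cine_series`: `config`, `frames` (per couch,
#'   a list with `times` and `stacks` — each stack an
#'   `image_size x image_size x S` array), `trace` (a
#'   [breathing_trace()]), and `true_peaks` (a [peak_set()]).
#' @export
simulate_cine <- function(config, seed) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(as.integer(seed))
  dur <- config$cine_duration_per_couch
  nf <- as.integer(floor(dur / config$frame_interval + 1e-9))
  frames <- vector("list", config$N)
  for (n in seq_len(config$N)) {
    t0 <- (n - 1) * dur
    times <- t0 + (seq_len(nf) - 1L) * config$frame_interval
    zs <- ((n - 1L) * config$S + seq_len(config$S) - 0.5) * config$slice_thickness
    stacks <- lapply(times, function(tt) {
      arr <- array(0, dim = c(config$image_size, config$image_size, config$S))
      for (s in seq_len(config$S)) arr[, , s] <- render_slice(config, zs[s], tt)
      arr
    })
    frames[[n]] <- list(times = times, stacks = stacks)
  }
  total <- config$N * dur
  tt <- seq(0, total, by = config$trace_dt)
  trace <- breathing_trace(tt, surrogate_amplitude(config, tt))
  # analytic surrogate maxima: mid-cycle instants tau/2 + j*tau
  tau <- config$breathing_period
  pk <- seq(tau / 2, total, by = tau)
  structure(list(config = config, frames = frames, trace = trace,
                 true_peaks = peak_set(pk)),
            class = "cine_series")
}

#' Sort a cine series into respiratory phase bins
#'
#' For every couch position and every bin label, selects the cine frame
#' whose retrospective phase (from `peaks`, see [compute_phase()]) is
#' closest to the label in circular distance on `[0, 100)`; ties are
#' broken by earlier acquisition time. Frames acquired outside the peak
#' span have undefined phase and are never selected.
#'
#' @param cine a `cine_series` from [simulate_cine()].
#' @param peaks a [peak_set()] defining the phase values (true or
#'   corrupted).
#' @param bin_labels phase-bin labels in percent (default 0, 10, ..., 90).
#' @return A [fourdct()] image set with attribute `"selection"`, a
#'   `B x N` integer matrix giving the chosen frame index per bin and
#'   couch position.
#' @export
phase_sort <- function(cine, peaks, bin_labels = seq(0, 90, by = 10)) {
  stopifnot(inherits(cine, "cine_series"), inherits(peaks, "peak_set"))
  cfg <- cine$config
  B <- length(bin_labels)
  selection <- matrix(NA_integer_, nrow = B, ncol = cfg$N)
  for (n in seq_len(cfg$N)) {
    fr <- cine$frames[[n]]
    ph <- compute_phase(peaks, fr$times, outside = "na")
    if (all(is.na(ph)))
      c4_stop(sprintf("couch position %d has no frames within the peak span", n),
              "empty_couch_position")
    for (b in seq_len(B)) {
      d <- abs(ph - bin_labels[b])
      d <- pmin(d, 100 - d)
      selection[b, n] <- which.min(d)   # NA distances lose; first min = earliest
    }
  }
  sz <- cfg$image_size
  volumes <- lapply(seq_len(B), function(b) {
    arr <- array(0, dim = c(sz, sz, cfg$N * cfg$S))
    times <- numeric(cfg$N * cfg$S)
    for (n in seq_len(cfg$N)) {
      idx <- (n - 1L) * cfg$S + seq_len(cfg$S)
      arr[, , idx] <- cine$frames[[n]]$stacks[[selection[b, n]]]
      times[idx] <- cine$frames[[n]]$times[selection[b, n]]
    }
    phase_volume(arr, S = cfg$S, phase_label = bin_labels[b],
                 acquisition_times = times)
  })
  out <- fourdct(volumes)
  attr(out, "selection") <- selection
  out
}

#' Generate an original-vs-recalculated validation pair
#'
#' Recreates, in silico, the situation where a respiratory monitor
#' miscalculates phases: one cine acquisition is simulated, its true
#' inhalation peaks are corrupted by deleting `n_missed_peaks` interior
#' peaks and inserting `n_spurious_peaks` spurious ones (seeded), and the
#' same cine is sorted twice — once with phases from the corrupted peak
#' set ("original") and once with phases from the true peaks
#' ("recalculated"). Because both sortings draw from the same frames, a
#' zero-corruption pair is frame-identical and scores exactly 0, and any
#' static anatomical discontinuity cancels in the residual.
#'
#' The first and last peaks are never deleted, so both peak sets span the
#' same time interval and the two sortings choose from the same frames.
#'
#' @param config a [phantom_config()].
#' @param n_missed_peaks interior inhalation peaks to delete (>= 0).
#' @param n_spurious_peaks spurious peaks to insert (>= 0).
#' @param seed integer seed driving noise and corruption choices.
#' @param bin_labels phase-bin labels, as in [phase_sort()].
#' @return A list of class `validation_pair`: `original` and
#'   `recalculated` [fourdct()] sets; `true_peaks` and `corrupted_peaks`;
#'   `changed` (`B x N` logical matrix of couch blocks whose selected
#'   frame differs); `affected_transitions` (per phase bin, the couch
#'   transitions adjacent to a changed block); `config`, `seed`.
#' @export
make_validation_pair <- function(config, n_missed_peaks, n_spurious_peaks,
                                 seed, bin_labels = seq(0, 90, by = 10)) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_missed_peaks < 0 || n_spurious_peaks < 0)
    c4_stop("corruption counts must be >= 0", "invalid_argument")
  cine <- simulate_cine(config, seed)   # seeds the RNG; corruption continues it
  pk <- cine$true_peaks$peak_times
  interior <- pk[-c(1L, length(pk))]
  if (n_missed_peaks > length(interior) ||
      length(pk) - n_missed_peaks < 2L)
    c4_stop("corruption would leave fewer than 2 peaks", "too_few_peaks")
  del <- if (n_missed_peaks > 0)
    sort(interior[sample.int(length(interior), n_missed_peaks)]) else numeric()
  ins <- numeric()
  if (n_spurious_peaks > 0) {
    gaps <- sample(length(pk) - 1L, n_spurious_peaks, replace = TRUE)
    ins <- pk[gaps] + stats::runif(n_spurious_peaks, 0.25, 0.75) *
      (pk[gaps + 1L] - pk[gaps])
  }
  corrupted <- edit_peaks(cine$true_peaks, insert = ins, delete = del,
                          match_tolerance = config$breathing_period / 8)
  original     <- phase_sort(cine, corrupted, bin_labels)
  recalculated <- phase_sort(cine, cine$true_peaks, bin_labels)
  original$provenance     <- "original-phase sorting (corrupted peak set)"
  recalculated$provenance <- "recalculated-phase sorting (true peak set)"
  changed <- attr(original, "selection") != attr(recalculated, "selection")
  affected <- lapply(seq_len(nrow(changed)), function(b) {
    n_tr <- config$N - 1L
    which(changed[b, seq_len(n_tr)] | changed[b, 1L + seq_len(n_tr)])
  })
  structure(list(original = original, recalculated = recalculated,
                 true_peaks = cine$true_peaks, corrupted_peaks = corrupted,
                 changed = changed, affected_transitions = affected,
                 config = config, seed = seed),
            class = "validation_pair")
}
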