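test_that("diaphragm trajectory hits exhale at t = 0, inhale at mid-cycle, and is periodic", {
  cfg <- phantom_config()
  z0 <- cfg$diaphragm_rest_position
  expect_equal(diaphragm_trajectory(cfg, 0), z0)
  expect_equal(diaphragm_trajectory(cfg, cfg$breathing_period / 2),
               z0 - cfg$motion_amplitude)
  set.seed(2)
  t <- runif(100, 0, 60)
  expect_equal(diaphragm_trajectory(cfg, t + cfg$breathing_period),
               diaphragm_trajectory(cfg, t))
})

test_that("slice rendering is deterministic and tracks the diaphragm", {
  cfg <- test_config()
  # far above the dome: independent of time (noise-free)
  hi <- cfg$lung_z_max - 1
  expect_identical(render_slice(cfg, hi, 0, noise = FALSE),
                   render_slice(cfg, hi, 1.7, noise = FALSE))
  # at the dome: diaphragm pixel count grows toward exhale (apex higher)
  zd <- cfg$diaphragm_rest_position - 5
  n_exhale <- sum(render_slice(cfg, zd, 0, noise = FALSE) == cfg$diaphragm_hu)
  n_inhale <- sum(render_slice(cfg, zd, cfg$breathing_period / 2,
                               noise = FALSE) == cfg$diaphragm_hu)
  expect_gt(n_exhale, n_inhale)
  # tissue classes present
  s <- render_slice(cfg, hi, 0, noise = FALSE)
  expect_setequal(unique(as.vector(s)),
                  c(cfg$background_hu, cfg$body_hu, cfg$lung_hu))
})

test_that("cine simulation produces the forced frame counts and is seed-deterministic", {
  cfg <- phantom_config(image_size = 16, pixel_spacing = 24, N = 4, S = 8,
                        cine_duration_per_couch = 5, frame_interval = 0.5,
                        noise_sd = 5)
  cine <- simulate_cine(cfg, seed = 7)
  expect_length(cine$frames, 4)
  expect_length(cine$frames[[1]]$times, 10)            # 5 s / 0.5 s
  expect_equal(dim(cine$frames[[1]]$stacks[[1]]), c(16, 16, 8))
  # trace peak count ~ number of breathing periods spanned
  expect_equal(length(cine$true_peaks$peak_times),
               floor(4 * 5 / cfg$breathing_period), tolerance = 1)
  # detected peaks on the recorded trace agree with the analytic truth
  det <- detect_peaks(cine$trace, min_prominence = cfg$motion_amplitude / 2,
                      min_separation = cfg$breathing_period / 2)
  expect_equal(det$peak_times, cine$true_peaks$peak_times, tolerance = 0.05)
  # seed determinism across the full series
  cine2 <- simulate_cine(cfg, seed = 7)
  expect_identical(cine$frames[[3]]$stacks[[4]], cine2$frames[[3]]$stacks[[4]])
  expect_identical(cine$trace$amplitudes, cine2$trace$amplitudes)
})

test_that("phase sorting picks the circularly closest frame per bin and couch", {
  cine <- simulate_cine(test_config(), seed = 3)
  set <- phase_sort(cine, cine$true_peaks)
  expect_s3_class(set, "fourdct")
  expect_length(set$volumes, 10)
  expect_equal(set$N, 4)
  sel <- attr(set, "selection")
  expect_equal(dim(sel), c(10, 4))
  # every selected frame's phase is circularly closest to its bin label
  for (n in 1:4) {
    ph <- compute_phase(cine$true_peaks, cine$frames[[n]]$times, outside = "na")
    for (b in 1:10) {
      lab <- set$phase_labels[b]
      d <- abs(ph - lab); d <- pmin(d, 100 - d)
      expect_equal(d[sel[b, n]], min(d, na.rm = TRUE))
    }
  }
})

test_that("validation pairs are seed-deterministic and trivial without corruption", {
  cfg <- test_config(noise_sd = 5)
  p1 <- make_validation_pair(cfg, 1, 1, seed = 11)
  p2 <- make_validation_pair(cfg, 1, 1, seed = 11)
  expect_identical(p1$corrupted_peaks$peak_times, p2$corrupted_peaks$peak_times)
  expect_identical(p1$original$volumes[[5]]$data, p2$original$volumes[[5]]$data)

  p0 <- make_validation_pair(cfg, 0, 0, seed = 11)
  expect_false(any(p0$changed))
  expect_identical(p0$original$volumes[[3]]$data, p0$recalculated$volumes[[3]]$data)
  expect_equal(compare_sets(p0$original, p0$recalculated)$overall_score, 0)
})

test_that("a missed peak changes frame selection in the affected cycles only", {
  cfg <- test_config()
  cine <- simulate_cine(cfg, seed = 4)
  pk <- cine$true_peaks$peak_times
  corrupted <- edit_peaks(cine$true_peaks, delete = pk[2])
  a <- phase_sort(cine, cine$true_peaks)
  b <- phase_sort(cine, corrupted)
  changed <- attr(a, "selection") != attr(b, "selection")
  expect_true(any(changed))
  # couch positions acquired entirely outside the merged cycle are untouched
  dur <- cfg$cine_duration_per_couch
  merged <- c(pk[1], pk[3])
  outside <- which(sapply(seq_len(cfg$N), function(n)
    (n * dur) <= merged[1] || ((n - 1) * dur) >= merged[2]))
  if (length(outside)) expect_false(any(changed[, outside]))
})

test_that("median comparison score increases with the number of missed peaks", {
  cfg <- phantom_config()
  med <- sapply(c(0, 1, 3), function(k) {
    median(sapply(1:8, function(s) {
      p <- make_validation_pair(cfg, k, 0, seed = 100 + s)
      compare_sets(p$original, p$recalculated)$overall_score
    }))
  })
  expect_true(all(diff(med) >= 0))
  expect_equal(med[1], 0)
})
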