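# Small in-code fixtures shared across test files.

# Phase volume of N*S random slices (seeded), offset keeps slices nonzero.
rand_volume <- function(N = 3, S = 4, nr = 6, nc = 6, phase = 0, seed = 1) {
  set.seed(seed)
  phase_volume(array(rnorm(nr * nc * N * S, mean = 5), c(nr, nc, N * S)),
               S = S, phase_label = phase)
}

# Image set of B seeded random phase volumes.
rand_set <- function(B = 2, N = 3, S = 4, nr = 6, nc = 6, seed = 1) {
  fourdct(lapply(seq_len(B), function(b)
    rand_volume(N, S, nr, nc, phase = (b - 1) * 10, seed = seed + b)))
}

# Phase volume where every slice is the same nonzero matrix.
const_volume <- function(N = 3, S = 4, nr = 4, nc = 4, phase = 0, value = 100) {
  phase_volume(array(value, c(nr, nc, N * S)), S = S, phase_label = phase)
}

# Artifact matrix wrapper for synthetic residual/score tests.
as_artifact <- function(m, labels = seq(0, by = 10, length.out = nrow(m))) {
  rownames(m) <- labels
  structure(m, class = c("artifact_matrix", class(m)), provenance = "")
}

# Literal double-loop evaluation of the slice NCC, kept independent of ncc().
ncc_oracle <- function(a, b) {
  num <- 0; qa <- 0; qb <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    num <- num + a[i, j] * b[i, j]
    qa <- qa + a[i, j]^2
    qb <- qb + b[i, j]^2
  }
  num / (sqrt(qa) * sqrt(qb))
}

# Brute-force exact two-sided signed-rank p over all 2^n sign assignments.
wilcoxon_bruteforce <- function(values, null = 0) {
  d <- values - null
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.numeric(signs %*% r)
  mean(abs(W - mu) >= abs(w - mu) - 1e-9)
}

# Fast small phantom configuration for pipeline tests.
test_config <- function(noise_sd = 0, ...) {
  phantom_config(image_size = 16, pixel_spacing = 24, N = 4, S = 4,
                 slice_thickness = 5,
                 cine_duration_per_couch = 4, frame_interval = 0.5,
                 noise_sd = noise_sd, ...)
}
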