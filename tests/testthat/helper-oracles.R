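# Independent oracles and small fixtures shared across tests.

# Brute-force categorical-judgement chain: explicit loops, no shared code
# with the package implementation beyond qnorm itself.
brute_thurstone <- function(counts) {
  S <- nrow(counts); C <- ncol(counts)
  cum <- matrix(0, S, C - 1)
  for (s in seq_len(S)) {
    n <- sum(counts[s, ])
    acc <- 0
    for (k in seq_len(C - 1)) {
      acc <- acc + counts[s, k]
      p <- acc / n
      lo <- 1 / (2 * n)
      if (p < lo) p <- lo
      if (p > 1 - lo) p <- 1 - lo
      cum[s, k] <- p
    }
  }
  z <- matrix(0, S, C - 1)
  for (s in seq_len(S)) for (k in seq_len(C - 1)) z[s, k] <- qnorm(cum[s, k])
  tau <- numeric(C - 1)
  for (k in seq_len(C - 1)) tau[k] <- sum(z[, k]) / S
  v <- numeric(S)
  for (s in seq_len(S)) v[s] <- sum(tau - z[s, ]) / (C - 1)
  v - sum(v) / S
}

random_counts <- function(S, C, n) {
  t(vapply(seq_len(S), function(s) {
    p <- as.numeric(rmultinom(1, n, prob = runif(C, 0.05, 1)))
    p
  }, numeric(C)))
}

# Tiny uniform face: every pixel the same (possibly non-integer) sRGB triple.
uniform_face <- function(h, w, rgb, subject_id = NULL) {
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  face_image(px, subject_id = subject_id)
}

# Minimal response data frame builder.
make_responses <- function(observer, stimulus, attribute, pole, score,
                           presentation = 1L) {
  data.frame(observer_id = observer, stimulus_id = stimulus,
             attribute = attribute, pole = pole, score = score,
             presentation_index = presentation)
}

all_bounds <- function() list(lower = c(0, 0, 0), upper = c(255, 255, 255))

# Standard synthetic face + segmentation inputs used by several files.
fixture_face <- function(seed = 1) {
  f <- make_synthetic_face(width = 100, height = 120, texture_sd = 2,
                           seed = seed, subject_id = "syn")
  f$bounds <- estimate_skin_thresholds(f$skin_samples, k = 2.5)
  f
}
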