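# Category encoding, the scaling chain, and observer-variation RMS.

test_that("pole + score fold bijectively into 10 ordered categories", {
  expect_equal(encode_category("second", 5), 1L)
  expect_equal(encode_category("second", 1), 5L)
  expect_equal(encode_category("first", 1), 6L)
  expect_equal(encode_category("first", 5), 10L)
  expect_equal(encode_category("masculine", 5, "feminine-masculine"), 1L)
  expect_equal(encode_category("feminine", 5, "feminine-masculine"), 10L)
  expect_equal(encode_category("likeable", 1, "likeable-dislikeable"), 6L)

  # bijective over the 10 cells, and decode inverts encode
  cats <- c(encode_category(rep("second", 5), 5:1),
            encode_category(rep("first", 5), 1:5))
  expect_equal(cats, 1:10)
  dec <- decode_category(1:10)
  expect_equal(encode_category(dec$pole, dec$score), 1:10)

  expect_error(encode_category("first", 6), "1..5")
  expect_error(encode_category("neutral", 3), "pole")
  expect_error(encode_category("masculine", 3, "likeable-dislikeable"), "belong")
})

test_that("frequency matrix counts responses per stimulus and category", {
  r <- make_responses("o1", rep("s1", 3), "feminine-masculine",
                      rep("feminine", 3), rep(2, 3))
  fm <- frequency_matrix(r, "feminine-masculine")
  expect_equal(as.numeric(fm["s1", ]), c(0, 0, 0, 0, 0, 0, 3, 0, 0, 0))

  expect_error(frequency_matrix(r, "likeable-dislikeable"), "no responses")

  # conservation: row sums equal responses per stimulus
  r2 <- simulate_responses(simulation_config(n_observers = 40, seed = 1))
  fm2 <- frequency_matrix(r2[r2$face_id == "OM", ], "feminine-masculine")
  expect_true(all(rowSums(fm2) == 40))
  expect_equal(nrow(fm2), 20)
})

test_that("cumulative probabilities are row-monotone proportions", {
  counts <- rbind(c(3, 0, 0, 0), c(1, 1, 1, 1))
  cp <- cumulative_probability(counts)
  expect_equal(cp[1, ], c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(cp[2, ], c(0.25, 0.5, 0.75), ignore_attr = TRUE)
  expect_equal(ncol(cp), ncol(counts) - 1) # final implicit 1 is dropped

  u <- matrix(1, 1, 10)
  expect_equal(as.numeric(cumulative_probability(u)), seq(0.1, 0.9, 0.1))

  expect_error(cumulative_probability(rbind(c(0, 0, 0))), "at least one")
})

test_that("z-score matrix is the clipped inverse-normal transform", {
  expect_equal(as.numeric(zscore_matrix(matrix(0.5), n = 40)), 0)
  expect_equal(as.numeric(zscore_matrix(matrix(0.8413), n = 1e6)),
               qnorm(0.8413))
  # an observed 1 clips to 1 - 1/(2n)
  expect_equal(as.numeric(zscore_matrix(matrix(1), n = 40)), qnorm(79 / 80))
  expect_equal(as.numeric(zscore_matrix(matrix(0), n = 40)), qnorm(1 / 80))
  expect_error(zscore_matrix(matrix(1.2), n = 10), "\\[0, 1\\]")
  expect_error(zscore_matrix(matrix(1), n = 10, clip = FALSE), "non-finite")
})

test_that("scale values separate extreme stimuli symmetrically", {
  counts <- rbind(A = c(40, rep(0, 9)), B = c(rep(0, 9), 40))
  z <- zscore_matrix(cumulative_probability(counts), n = 40)
  sv <- scale_values(z)
  expect_equal(unname(sv$values["B"]), qnorm(79 / 80), tolerance = 1e-9)
  expect_equal(unname(sv$values["A"]), -qnorm(79 / 80), tolerance = 1e-9)
  expect_gt(sv$values["B"], 0)
  expect_lt(sv$values["A"], 0)

  # indistinguishable stimuli scale to 0
  same <- rbind(c(5, 5, 5, 5), c(5, 5, 5, 5))
  z2 <- zscore_matrix(cumulative_probability(same), n = 20)
  expect_equal(as.numeric(scale_values(z2)$values), c(0, 0), tolerance = 1e-12)

  expect_warning(scale_values(z2[1, , drop = FALSE]), "single stimulus")
})

test_that("the full chain equals the brute-force oracle on small instances", {
  set.seed(42)
  for (rep in 1:60) {
    S <- sample(2:4, 1); C <- sample(2:4, 1); n <- sample(c(5, 12, 40), 1)
    counts <- random_counts(S, C, n)
    while (any(rowSums(counts) == 0)) counts <- random_counts(S, C, n)
    z <- zscore_matrix(cumulative_probability(counts), n = rowSums(counts))
    got <- as.numeric(scale_values(z)$values)
    expect_equal(got, brute_thurstone(counts), tolerance = 1e-9)
  }
})

test_that("stochastic dominance implies scale-value ordering", {
  set.seed(7)
  checked <- 0
  for (rep in 1:200) {
    counts <- random_counts(4, 10, 40)
    cp <- cumulative_probability(counts)
    z <- zscore_matrix(cp, n = 40)
    v <- scale_values(z)$values
    for (a in 1:3) for (b in (a + 1):4) {
      if (all(cp[a, ] <= cp[b, ])) {
        expect_gte(v[a], v[b]); checked <- checked + 1
      } else if (all(cp[b, ] <= cp[a, ])) {
        expect_gte(v[b], v[a]); checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 50) # the generator must actually exercise the property
})

test_that("latent translation leaves centred scale values unchanged", {
  # exact form: shifting latent process and category boundaries together
  # reproduces identical categories, hence identical values
  m0 <- latent_model(slope_w = 0.05, hue_amp = 0.4, sigma = 1)
  shift <- 0.7
  m1 <- latent_model(slope_w = 0.05, hue_amp = 0.4, sigma = 1,
                     intercept = shift,
                     boundaries = seq(-2, 2, length.out = 9) + shift)
  cfg <- function(m) simulation_config(
    n_observers = 15, observer_bias_sd = 0,
    models = list(OM = list("feminine-masculine" = m)), seed = 9)
  f0 <- thurstone_scale(simulate_responses(cfg(m0)), "feminine-masculine")
  f1 <- thurstone_scale(simulate_responses(cfg(m1)), "feminine-masculine")
  expect_equal(f0$values, f1$values, tolerance = 1e-12)

  # statistical form: a latent-only shift moves the boundary estimates, not
  # the centred values (up to discretisation noise)
  m2 <- latent_model(slope_w = 0.05, hue_amp = 0.4, sigma = 1, intercept = 0.5)
  f2 <- thurstone_scale(simulate_responses(cfg(m2)), "feminine-masculine")
  expect_equal(mean(f2$values), 0, tolerance = 1e-12)
  expect_gt(cor(f0$values, f2$values[names(f0$values)]), 0.8)
})

test_that("intra-observer RMS is the repeat-pair category RMS", {
  att <- "feminine-masculine"
  # perfectly consistent observer
  r <- rbind(
    make_responses("o1", "s1", att, "feminine", 3, 1L),
    make_responses("o1", "s1", att, "feminine", 3, 2L),
    make_responses("o1", "s2", att, "masculine", 2, 1L),
    make_responses("o1", "s2", att, "masculine", 2, 2L)
  )
  expect_equal(intra_observer_rms(r), 0)

  # one of m = 2 pairs differs by 2 categories -> sqrt(4 / 2)
  r$score[r$stimulus_id == "s1" & r$presentation_index == 2] <- 5
  expect_equal(intra_observer_rms(r), sqrt(4 / 2))

  expect_error(intra_observer_rms(r[r$presentation_index == 1, ]), "no repeat")
})

test_that("inter-observer RMS measures deviation from the panel mean", {
  att <- "likeable-dislikeable"
  # identical observers
  r <- rbind(
    make_responses("o1", c("s1", "s2"), att, "likeable", c(2, 4)),
    make_responses("o2", c("s1", "s2"), att, "likeable", c(2, 4))
  )
  expect_equal(inter_observer_rms(r), 0)

  # two observers always 2 categories apart: each sits 1 from the mean
  r2 <- rbind(
    make_responses("o1", c("s1", "s2"), att, "likeable", c(1, 2)),
    make_responses("o2", c("s1", "s2"), att, "likeable", c(3, 4))
  )
  expect_equal(inter_observer_rms(r2), 1)

  expect_error(inter_observer_rms(r[r$observer_id == "o1", ]), "two observers")
})

test_that("repeat noise raises intra RMS; observer bias raises inter RMS", {
  base <- function(sigma, bias) simulation_config(
    n_observers = 12, observer_bias_sd = bias,
    models = list(OM = list("feminine-masculine" =
      latent_model(slope_w = 0.03, sigma = sigma))),
    grid = stimulus_grid(repeat_count = 6, seed = 2), seed = 3)
  r_lo <- simulate_responses(base(0.3, 0))
  r_hi <- simulate_responses(base(1.5, 0))
  expect_lt(intra_observer_rms(r_lo), intra_observer_rms(r_hi))

  r_bias <- simulate_responses(base(0.8, 2))
  r_nobias <- simulate_responses(base(0.8, 0))
  expect_gt(inter_observer_rms(r_bias), inter_observer_rms(r_nobias))
  # with strong observer bias the panel disagrees more across observers
  # than each observer does with herself (the empirical panel ordering)
  expect_gt(inter_observer_rms(r_bias), intra_observer_rms(r_bias))
})

test_that("thurstone_scale returns a complete, printable fit object", {
  r <- simulate_responses(simulation_config(n_observers = 10, seed = 5))
  fit <- thurstone_scale(r[r$face_id == "OF", ], "likeable-dislikeable")
  expect_s3_class(fit, "thurstone")
  expect_equal(length(coef(fit)), 20)
  expect_equal(mean(coef(fit)), 0, tolerance = 1e-12)
  expect_equal(dim(fit$z), c(20, 9))
  expect_true(all(diff(t(fit$z)) >= -1e-12)) # rows nondecreasing
  expect_output(print(fit), "categorical-judgement")
  expect_output(print(summary(fit)), "boundaries")
})
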