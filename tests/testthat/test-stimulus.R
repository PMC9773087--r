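# Segmentation, texture extraction, recolouring and the stimulus grid.

test_that("threshold estimation is mean +/- k*SD, clipped to [0, 255]", {
  same <- rbind(c(200, 150, 130), c(200, 150, 130))
  b <- estimate_skin_thresholds(same, k = 2.5)
  expect_equal(b$lower, c(200, 150, 130), ignore_attr = TRUE)
  expect_equal(b$upper, c(200, 150, 130), ignore_attr = TRUE)

  two <- rbind(c(190, 140, 120), c(210, 160, 140))
  b <- estimate_skin_thresholds(two, k = 1)
  expect_equal(b$lower, c(200, 150, 130) - 10 * sqrt(2), ignore_attr = TRUE)
  expect_equal(b$upper, c(200, 150, 130) + 10 * sqrt(2), ignore_attr = TRUE)

  b0 <- estimate_skin_thresholds(two, k = 0)
  expect_equal(b0$lower, b0$upper)

  wide <- rbind(c(5, 250, 128), c(10, 240, 120))
  b <- estimate_skin_thresholds(wide, k = 100)
  expect_true(all(b$lower >= 0) && all(b$upper <= 255))

  expect_error(estimate_skin_thresholds(rbind(c(1, 2, 3))), "at least 2")
})

test_that("segmentation applies the threshold box and exclusion mask", {
  img <- uniform_face(10, 12, c(200, 150, 130))
  b <- list(lower = c(190, 140, 120), upper = c(210, 160, 140))
  m <- segment_skin(img, b)
  expect_true(all(m))
  expect_equal(attr(m, "provenance"), "auto")

  excl <- matrix(FALSE, 10, 12); excl[, 1:6] <- TRUE
  m2 <- segment_skin(img, b, exclusion_mask = excl)
  expect_equal(unclass(m2)[, 1:6], matrix(FALSE, 10, 6), ignore_attr = TRUE)
  expect_true(all(m2[, 7:12]))
  expect_equal(attr(m2, "provenance"), "manual-augmented")

  out_of_box <- uniform_face(4, 4, c(10, 10, 10))
  expect_error(segment_skin(out_of_box, b), "empty skin mask")
})

test_that("segmentation recovers the true mask of the synthetic face", {
  f <- fixture_face(seed = 1)
  m <- segment_skin(f$image, f$bounds)
  iou <- sum(m & f$mask) / sum(m | f$mask)
  expect_gte(iou, 0.99)
})

test_that("texture extraction is the zero-mean Lab deviation field", {
  # uniform skin: all deltas zero, mean equals the skin colour
  rgb <- lab_to_srgb(c(65, 14, 12))
  img <- uniform_face(8, 8, rgb)
  mask <- matrix(TRUE, 8, 8)
  tx <- extract_texture(img, mask)
  expect_equal(unname(tx$mean_color), c(65, 14, 12), tolerance = 1e-6)
  expect_lt(max(abs(tx$deltas)), 1e-6)

  # two pixels with L = 60 and 70: deltas forced to -5 / +5
  px <- array(0, c(1, 2, 3))
  px[1, 1, ] <- lab_to_srgb(c(60, 10, 10))
  px[1, 2, ] <- lab_to_srgb(c(70, 10, 10))
  tx2 <- extract_texture(face_image(px), matrix(TRUE, 1, 2))
  expect_equal(unname(tx2$mean_color["L"]), 65, tolerance = 1e-6)
  expect_equal(as.numeric(tx2$deltas[1, , 1]), c(-5, 5), tolerance = 1e-6)

  # zero-mean invariant on a noisy fixture
  f <- fixture_face(seed = 2)
  tx3 <- extract_texture(f$image, f$mask)
  for (ch in 1:3)
    expect_lt(abs(mean(tx3$deltas[, , ch][f$mask])), 1e-6)

  expect_error(extract_texture(img, matrix(FALSE, 8, 8)), "empty")
})

test_that("texture SD is recovered from simulated Gaussian skin noise", {
  f <- make_synthetic_face(width = 160, height = 170, texture_sd = 2, seed = 3)
  expect_gte(sum(f$mask), 1e4)
  tx <- extract_texture(f$image, f$mask)
  sdL <- sd(tx$deltas[, , 1][f$mask])
  expect_lt(abs(sdL - 2) / 2, 0.15)
})

test_that("recolouring preserves texture and is bit-exact off the mask", {
  f <- fixture_face(seed = 4)
  tx <- extract_texture(f$image, f$mask)

  # identity recolour reproduces the input on the mask
  same <- recolor_skin(f$image, f$mask, tx, tx$mean_color)
  expect_lt(max(abs(same$pixels - round(f$image$pixels))), 1.0001)

  target <- c(75, 10, 14)
  out <- recolor_skin(f$image, f$mask, tx, target)
  # conservation outside the mask, bit-exact
  for (ch in 1:3)
    expect_identical(out$pixels[, , ch][!f$mask], f$image$pixels[, , ch][!f$mask])
  # mean recoloured skin colour hits the target within Delta E*ab 0.5
  lab <- srgb_to_lab(cbind(out$pixels[, , 1][f$mask], out$pixels[, , 2][f$mask],
                           out$pixels[, , 3][f$mask]))
  de <- sqrt(sum((colMeans(lab) - target)^2))
  expect_lt(de, 0.5)
  # texture deltas survive the 8-bit round trip
  tx2 <- extract_texture(out, f$mask)
  for (ch in 1:3)
    expect_lt(max(abs(tx2$deltas[, , ch][f$mask] - tx$deltas[, , ch][f$mask])), 1.5)
})

test_that("uniform skin recolours to the uniform target colour", {
  rgb <- lab_to_srgb(c(60, 15, 13))
  img <- uniform_face(6, 6, rgb)
  mask <- matrix(TRUE, 6, 6)
  tx <- extract_texture(img, mask)
  out <- recolor_skin(img, mask, tx, c(72, 12, 10))
  expect_equal(max(out$pixels[, , 1]), min(out$pixels[, , 1]))
  lab <- srgb_to_lab(out$pixels[1, 1, ])
  expect_lt(sqrt(sum((lab - c(72, 12, 10))^2)), 0.5)
})

test_that("the stimulus grid yields the full design with seeded repeats", {
  profiles <- load_profiles()
  faces <- list()
  for (id in names(profiles)) {
    f <- fixture_face(seed = match(id, names(profiles)))
    faces[[id]] <- list(image = f$image,
                        mask = segment_skin(f$image, f$bounds),
                        profile = profiles[[id]])
    faces[[id]]$texture <- extract_texture(f$image, faces[[id]]$mask)
  }
  grid <- stimulus_grid(seed = 11)
  # the high-whiteness grid points exceed the sRGB gamut at the subjects'
  # natural chroma and are clipped with a warning
  w <- capture_warnings(out <- generate_stimulus_set(faces, grid))
  expect_match(w, "gamut", all = FALSE)
  man <- out$manifest
  expect_equal(nrow(man), 40)
  expect_equal(length(out$images), 40)
  expect_equal(nrow(unique(man[, c("whiteness", "hue_deg")])), 20)
  expect_equal(sum(man$is_repeat), 4)
  expect_true(all(man$gamut_clipped[man$whiteness == 80]))
  expect_false(any(man$gamut_clipped[man$whiteness == 50]))
  expect_true(all(man$clip_de[man$gamut_clipped] > 0))

  # determinism of the repeat draw
  man2 <- suppressWarnings(
    generate_stimulus_set(faces, stimulus_grid(seed = 11))$manifest)
  expect_identical(man$stimulus_id[man$is_repeat], man2$stimulus_id[man2$is_repeat])

  # 1 face, 1x1 grid
  g1 <- stimulus_grid(whiteness_levels = 60, hue_levels = 40,
                      repeat_count = 0, seed = 1)
  out1 <- generate_stimulus_set(faces["OM"], g1)
  expect_equal(nrow(out1$manifest), 1)

  # grid cardinality invariant for an asymmetric grid
  g2 <- stimulus_grid(whiteness_levels = c(55, 65, 75), hue_levels = c(35, 45),
                      repeat_count = 2, seed = 5)
  expect_equal(nrow(suppressWarnings(
    generate_stimulus_set(faces, g2))$manifest), 2 * 3 * 2)
})

test_that("PNG write/read round-trips a stimulus image", {
  f <- fixture_face(seed = 6)
  p <- withr::local_tempfile(fileext = ".png")
  write_face_png(f$image, p)
  back <- read_face_png(p)
  expect_equal(back$pixels, round(f$image$pixels))
})
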