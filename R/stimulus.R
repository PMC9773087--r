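# Stimulus preparation: threshold skin segmentation, texture extraction, and
# texture-preserving recolouring over the whiteness x hue-angle grid.

#' Face image container
#'
#' An 8-bit sRGB raster. Pixel values are stored as numbers in `[0, 255]`;
#' all CIELAB arithmetic is done in floating point and quantised to 8 bits
#' only when an image is written to disk.
#'
#' @param pixels H x W x 3 array of sRGB channel values in `[0, 255]`.
#' @param subject_id optional subject identifier.
#' @return an object of class `face_image`.
#' @export
face_image <- function(pixels, subject_id = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            dim(pixels)[1] > 0, dim(pixels)[2] > 0)
  if (any(pixels < 0) || any(pixels > 255)) stop("pixel values must lie in [0, 255]")
  structure(list(pixels = pixels, colorspace = "sRGB", subject_id = subject_id),
            class = "face_image")
}

#' @export
print.face_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("face_image%s: %d x %d, sRGB\n",
              if (is.null(x$subject_id)) "" else paste0(" [", x$subject_id, "]"),
              d[1], d[2]))
  invisible(x)
}

#' Read and write face images as PNG
#'
#' @param path PNG file path.
#' @param subject_id optional id attached to the image.
#' @return `read_face_png` returns a [face_image()]; `write_face_png`
#'   returns `path` invisibly after quantising to 8 bits.
#' @export
read_face_png <- function(path, subject_id = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  face_image(round(px[, , 1:3, drop = FALSE] * 255), subject_id = subject_id)
}

#' @rdname read_face_png
#' @param img a [face_image()].
#' @export
write_face_png <- function(img, path) {
  stopifnot(inherits(img, "face_image"))
  png::writePNG(round(img$pixels) / 255, path)
  invisible(path)
}

#' Per-channel segmentation thresholds from skin-colour samples
#'
#' Box thresholds in RGB: lower/upper bound per channel at the sample mean
#' minus/plus `k` standard deviations, clipped to `[0, 255]`. The samples
#' stand in for the database skin colours used to derive the segmentation
#' threshold.
#'
#' @param samples n x 3 matrix of 8-bit sRGB skin-colour samples (n >= 2).
#' @param k half-width of the box in standard deviations.
#' @return list with `lower` and `upper` length-3 bounds.
#' @export
estimate_skin_thresholds <- function(samples, k = 2.5) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) stop("at least 2 skin-colour samples are required")
  if (ncol(samples) != 3) stop("samples must be an n x 3 RGB matrix")
  m <- colMeans(samples)
  s <- apply(samples, 2, stats::sd)
  list(lower = pmax(m - k * s, 0), upper = pmin(m + k * s, 255))
}

#' Segment the skin area of a face image
#'
#' A pixel is skin iff all three channels fall within `bounds` and it is not
#' covered by the optional exclusion mask (the reproducible replacement for
#' manual marking of regions such as the sclera). After thresholding, the
#' largest connected component is kept and interior holes smaller than
#' `max_hole_area` pixels are filled, since box thresholds admit speckle
#' while real skin masks are contiguous.
#'
#' @param img a [face_image()].
#' @param bounds output of [estimate_skin_thresholds()].
#' @param exclusion_mask optional H x W logical matrix; `TRUE` = exclude.
#' @param clean apply the connected-component/hole cleanup.
#' @param max_hole_area fill interior holes up to this many pixels.
#' @return H x W logical matrix of class `skin_mask` with a `provenance`
#'   attribute (`"auto"` or `"manual-augmented"`).
#' @export
segment_skin <- function(img, bounds, exclusion_mask = NULL, clean = TRUE,
                         max_hole_area = 64) {
  stopifnot(inherits(img, "face_image"))
  d <- dim(img$pixels)
  inb <- img$pixels[, , 1] >= bounds$lower[1] & img$pixels[, , 1] <= bounds$upper[1] &
         img$pixels[, , 2] >= bounds$lower[2] & img$pixels[, , 2] <= bounds$upper[2] &
         img$pixels[, , 3] >= bounds$lower[3] & img$pixels[, , 3] <= bounds$upper[3]
  if (!is.null(exclusion_mask)) {
    if (!all(dim(exclusion_mask) == d[1:2]))
      stop("exclusion mask dimensions do not match the image")
    inb <- inb & !exclusion_mask
  }
  if (clean && any(inb)) {
    lab <- EBImage::bwlabel(inb * 1L)
    tab <- tabulate(lab[lab > 0])
    inb <- lab == which.max(tab)
    # fill only holes below the area cap; larger interior regions (e.g. eyes)
    # stay excluded
    filled <- EBImage::fillHull(inb * 1L) > 0
    holes <- filled & !inb
    if (any(holes)) {
      hlab <- EBImage::bwlabel(holes * 1L)
      hsz <- tabulate(hlab[hlab > 0])
      small <- which(hsz <= max_hole_area)
      inb <- inb | (hlab %in% small & holes)
    }
    if (!is.null(exclusion_mask)) inb <- inb & !exclusion_mask
    dim(inb) <- d[1:2]
  }
  if (!any(inb)) stop("segmentation produced an empty skin mask")
  structure(inb,
            provenance = if (is.null(exclusion_mask)) "auto" else "manual-augmented",
            class = c("skin_mask", class(inb)))
}

#' Extract the skin texture of a face
#'
#' Skin texture is the per-pixel deviation of (L*, a*, b*) from the mean
#' skin colour: masked pixels are converted to CIELAB, `mean_color` is the
#' channel-wise mean over the mask, and `deltas` are pixel minus mean (zero
#' mean by construction).
#'
#' @param img a [face_image()].
#' @param mask logical skin mask from [segment_skin()].
#' @return object of class `texture_map`: `deltas` (H x W x 3 array, `NA`
#'   off-mask), `mean_color` (Lab triple), `mask`.
#' @export
extract_texture <- function(img, mask) {
  stopifnot(inherits(img, "face_image"))
  d <- dim(img$pixels)
  if (!all(dim(mask) == d[1:2])) stop("mask dimensions do not match the image")
  if (!any(mask)) stop("cannot extract texture from an empty skin mask")
  idx <- which(mask)
  rgb <- cbind(img$pixels[, , 1][idx], img$pixels[, , 2][idx], img$pixels[, , 3][idx])
  lab <- srgb_to_lab(rgb)
  if (is.null(dim(lab))) lab <- matrix(lab, nrow = 1)
  mean_color <- colMeans(lab)
  names(mean_color) <- c("L", "a", "b")
  deltas <- array(NA_real_, d)
  for (ch in 1:3) {
    plane <- matrix(NA_real_, d[1], d[2])
    plane[idx] <- lab[, ch] - mean_color[ch]
    deltas[, , ch] <- plane
  }
  structure(list(deltas = deltas, mean_color = mean_color, mask = mask),
            class = "texture_map")
}

#' @export
print.texture_map <- function(x, ...) {
  cat(sprintf("texture_map: %d skin pixels, mean Lab (%.2f, %.2f, %.2f)\n",
              sum(x$mask), x$mean_color[1], x$mean_color[2], x$mean_color[3]))
  invisible(x)
}

#' Recolour the skin area, preserving texture
#'
#' Each masked pixel becomes `target + delta` in CIELAB, converted back to
#' sRGB (gamut-clipped channel-wise with a warning). Pixels outside the mask
#' are returned bit-identical to the input.
#'
#' @param img a [face_image()].
#' @param mask logical skin mask.
#' @param tex a [extract_texture()] result aligned with `mask`.
#' @param target Lab triple, the new mean skin colour.
#' @return a new [face_image()] (8-bit-quantised channels).
#' @export
recolor_skin <- function(img, mask, tex, target) {
  stopifnot(inherits(img, "face_image"), inherits(tex, "texture_map"))
  d <- dim(img$pixels)
  if (!all(dim(mask) == d[1:2])) stop("mask dimensions do not match the image")
  idx <- which(mask)
  if (any(is.na(tex$deltas[, , 1][idx])))
    stop("texture map is not defined on every mask pixel")
  lab_new <- cbind(
    target[1] + tex$deltas[, , 1][idx],
    target[2] + tex$deltas[, , 2][idx],
    target[3] + tex$deltas[, , 3][idx]
  )
  rgb <- lab_to_srgb(lab_new)
  if (is.null(dim(rgb))) rgb <- matrix(rgb, nrow = 1)
  out <- img$pixels
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[idx] <- round(rgb[, ch])
    out[, , ch] <- plane
  }
  face_image(out, subject_id = img$subject_id)
}

#' Stimulus design grid
#'
#' The study design: whiteness levels 50-80 in steps of 10 and hue angles
#' 30-70 degrees in steps of 10, i.e. 20 skin colours per face; applied to
#' two faces this yields 40 stimuli, of which `repeat_count` are randomly
#' flagged for the repeat (intra-observer) test.
#'
#' @param whiteness_levels strictly increasing whiteness levels.
#' @param hue_levels strictly increasing hue angles (degrees).
#' @param repeat_count number of repeat-flagged stimuli.
#' @param seed RNG seed driving the repeat selection.
#' @return an object of class `stimulus_grid`.
#' @export
stimulus_grid <- function(whiteness_levels = c(50, 60, 70, 80),
                          hue_levels = c(30, 40, 50, 60, 70),
                          repeat_count = 4, seed = 1) {
  stopifnot(all(diff(whiteness_levels) > 0), all(diff(hue_levels) > 0),
            repeat_count >= 0)
  structure(list(whiteness_levels = whiteness_levels, hue_levels = hue_levels,
                 repeat_count = repeat_count, seed = as.integer(seed)),
            class = "stimulus_grid")
}

# Shared stimulus bookkeeping: one row per face x whiteness x hue, with the
# repeat flags drawn uniformly without replacement under the grid seed.
grid_manifest <- function(face_ids, grid) {
  stopifnot(inherits(grid, "stimulus_grid"))
  rows <- expand.grid(hue_deg = grid$hue_levels,
                      whiteness = grid$whiteness_levels,
                      face_id = face_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[, c("face_id", "whiteness", "hue_deg")]
  rows$stimulus_id <- sprintf("%s_W%g_h%g", rows$face_id, rows$whiteness, rows$hue_deg)
  if (grid$repeat_count > nrow(rows))
    stop("repeat_count exceeds the number of stimuli")
  rows$is_repeat <- FALSE
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(grid$seed)
  rows$is_repeat[sample.int(nrow(rows), grid$repeat_count)] <- TRUE
  rownames(rows) <- NULL
  rows
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate the full stimulus set
#'
#' Recolours every face at every grid colour. Each face entry supplies its
#' image, skin mask, texture map and subject profile; grid whiteness/hue
#' pairs are resolved to CIELAB through [resolve_skin_color()].
#'
#' @param faces named list; each element a list with components `image`
#'   ([face_image()]), `mask`, `texture` ([extract_texture()]), and
#'   `profile` ([subject_profile()]).
#' @param grid a [stimulus_grid()].
#' @param out_dir optional directory; when given, stimuli are written as
#'   PNG files and the manifest gains their paths.
#' @return list with `manifest` (data frame: stimulus_id, face_id,
#'   whiteness, hue_deg, L, C, h, is_repeat, path) and `images` (named list
#'   of [face_image()]s).
#' @export
generate_stimulus_set <- function(faces, grid, out_dir = NULL) {
  stopifnot(is.list(faces), length(faces) > 0, !is.null(names(faces)))
  manifest <- grid_manifest(names(faces), grid)
  manifest$L <- NA_real_; manifest$C <- NA_real_; manifest$h <- NA_real_
  manifest$gamut_clipped <- FALSE; manifest$clip_de <- 0
  manifest$path <- NA_character_
  images <- vector("list", nrow(manifest))
  names(images) <- manifest$stimulus_id
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (i in seq_len(nrow(manifest))) {
    f <- faces[[manifest$face_id[i]]]
    spec <- tryCatch(
      resolve_skin_color(manifest$whiteness[i], manifest$hue_deg[i], f$profile),
      error = function(e) stop(sprintf("grid point (W=%g, h=%g, face=%s): %s",
                                       manifest$whiteness[i], manifest$hue_deg[i],
                                       manifest$face_id[i], conditionMessage(e)),
                               call. = FALSE)
    )
    target <- lch_to_lab(spec$resolved)
    # gamut check on the mean colour; per-pixel clipping is applied inside
    # recolor_skin and summarised here as one warning per grid point
    back <- srgb_to_lab(lab_to_srgb(target, warn_clip = FALSE))
    de <- sqrt(sum((back - target)^2))
    if (de > 0.05) {
      manifest$gamut_clipped[i] <- TRUE
      manifest$clip_de[i] <- de
      warning(sprintf(
        "grid point (W=%g, h=%g, face=%s) is outside the sRGB gamut; clipped (Delta E*ab = %.2f)",
        manifest$whiteness[i], manifest$hue_deg[i], manifest$face_id[i], de))
    }
    images[[i]] <- suppressWarnings(
      recolor_skin(f$image, f$mask, f$texture, target))
    manifest$L[i] <- spec$resolved["L"]
    manifest$C[i] <- spec$resolved["C"]
    manifest$h[i] <- spec$resolved["h"]
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, paste0(manifest$stimulus_id[i], ".png"))
      write_face_png(images[[i]], p)
      manifest$path[i] <- p
    }
  }
  list(manifest = manifest, images = images)
}
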