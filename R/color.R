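# Colorimetry: CIELAB/LCh conversions under D65 with the 10-degree observer,
# the whiteness model, and its inversion to concrete skin colours.

# D65, 10-degree observer white point (Y scaled to 100). The sRGB primaries are
# nominally defined for the 2-degree observer; the stated experimental
# colorimetry (D65, 10 degrees) is used throughout, including the sRGB bridge.
.WHITE_D65_10 <- c(X = 94.811, Y = 100.000, Z = 107.304)

# sRGB (linear, [0,1]) -> XYZ (Y in [0,100]) and back, IEC 61966-2-1 matrices
.M_RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE) * 100

.M_XYZ2RGB <- solve(.M_RGB2XYZ)

#' Convert CIELAB to CIELCh
#'
#' Rectangular (L*, a*, b*) to cylindrical (L*, C*ab, h_ab) coordinates.
#' Chroma is the radius `sqrt(a^2 + b^2)`; the hue angle is reported in
#' degrees in `[0, 360)`. An achromatic colour (C = 0) has hue 0 by
#' convention.
#'
#' @param lab numeric vector `c(L, a, b)` or an n x 3 matrix of CIELAB rows.
#' @return numeric vector `c(L, C, h)` or an n x 3 matrix of LCh rows.
#' @seealso [lch_to_lab()]
#' @export
lab_to_lch <- function(lab) {
  lab <- .as_color_matrix(lab, c("L", "a", "b"))
  C <- sqrt(lab[, 2]^2 + lab[, 3]^2)
  h <- atan2(lab[, 3], lab[, 2]) * 180 / pi
  h <- h %% 360
  h[C == 0] <- 0
  .color_result(cbind(L = lab[, 1], C = C, h = h))
}

#' Convert CIELCh to CIELAB
#'
#' @param lch numeric vector `c(L, C, h)` (h in degrees) or an n x 3 matrix.
#' @return numeric vector `c(L, a, b)` or an n x 3 matrix.
#' @export
lch_to_lab <- function(lch) {
  lch <- .as_color_matrix(lch, c("L", "C", "h"))
  if (any(lch[, 2] < 0)) stop("chroma must be non-negative")
  hr <- lch[, 3] * pi / 180
  .color_result(cbind(L = lch[, 1], a = lch[, 2] * cos(hr), b = lch[, 2] * sin(hr)))
}

#' Convert 8-bit sRGB to CIELAB (D65, 10 degrees)
#'
#' Standard sRGB decoding (gamma expansion, RGB-to-XYZ matrix) followed by
#' the XYZ-to-Lab transform under the D65/10-degree white point used for all
#' image processing in this package.
#'
#' @param rgb numeric vector `c(R, G, B)` in `[0, 255]` or an n x 3 matrix.
#' @return numeric vector `c(L, a, b)` or an n x 3 matrix.
#' @export
srgb_to_lab <- function(rgb) {
  rgb <- .as_color_matrix(rgb, c("R", "G", "B"))
  if (any(rgb < -1e-9) || any(rgb > 255 + 1e-9))
    stop("sRGB components must lie in [0, 255]")
  u <- rgb / 255
  lin <- ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.M_RGB2XYZ)
  .color_result(.xyz_to_lab(xyz))
}

#' Convert CIELAB to 8-bit sRGB (D65, 10 degrees)
#'
#' Colours outside the sRGB gamut are clipped channel-wise in linear RGB; a
#' warning reports the largest CIELAB distance (Delta E*ab) introduced by
#' clipping. Output channels are continuous in `[0, 255]`; quantise to
#' integers only when writing files.
#'
#' @param lab numeric vector `c(L, a, b)` or an n x 3 matrix.
#' @param warn_clip warn when out-of-gamut colours are clipped.
#' @return numeric vector/matrix of sRGB channels in `[0, 255]` (unrounded).
#' @export
lab_to_srgb <- function(lab, warn_clip = TRUE) {
  lab <- .as_color_matrix(lab, c("L", "a", "b"))
  xyz <- .lab_to_xyz(lab)
  lin <- xyz %*% t(.M_XYZ2RGB)
  clipped <- pmin(pmax(lin, 0), 1)
  hit <- rowSums(abs(clipped - lin)) > 1e-9
  if (warn_clip && any(hit)) {
    back <- .xyz_to_lab(clipped %*% t(.M_RGB2XYZ))
    de <- sqrt(rowSums((back - lab)^2))
    warning(sprintf("%d colour(s) clipped to the sRGB gamut (max Delta E*ab = %.3f)",
                    sum(hit), max(de[hit])))
  }
  u <- ifelse(clipped <= 0.0031308, 12.92 * clipped, 1.055 * clipped^(1 / 2.4) - 0.055)
  out <- 255 * pmin(pmax(u, 0), 1)
  colnames(out) <- c("R", "G", "B")
  .color_result(out)
}

.xyz_to_lab <- function(xyz) {
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[, 1] / .WHITE_D65_10[1])
  fy <- f(xyz[, 2] / .WHITE_D65_10[2])
  fz <- f(xyz[, 3] / .WHITE_D65_10[3])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

.lab_to_xyz <- function(lab) {
  finv <- function(t) ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  cbind(
    X = .WHITE_D65_10[1] * finv(fx),
    Y = .WHITE_D65_10[2] * finv(fy),
    Z = .WHITE_D65_10[3] * finv(fz)
  )
}

.as_color_matrix <- function(x, nm) {
  if (is.null(dim(x))) {
    if (length(x) != 3) stop("expected a length-3 colour triple")
    x <- matrix(as.numeric(x), nrow = 1)
    attr(x, "was_vector") <- TRUE
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3) stop("expected an n x 3 colour matrix")
    storage.mode(x) <- "double"
  }
  colnames(x) <- nm
  x
}

.color_result <- function(x) {
  if (nrow(x) == 1) {
    out <- drop(x)
    return(out)
  }
  x
}

#' Subject skin-colour profile
#'
#' Mean skin lightness `L_sub`, mean skin chroma `C_sub` and the whiteness
#' coefficient `beta` of a facial subject. The two study subjects (a Chinese
#' female, OF, and a Chinese male, OM) are shipped as a YAML fixture; see
#' [load_profiles()].
#'
#' @param L_sub mean skin lightness (CIELAB L*).
#' @param C_sub mean skin chroma (C*ab), must be positive.
#' @param beta whiteness coefficient (dimensionless), must be positive.
#' @param id optional subject identifier.
#' @return an object of class `subject_profile`.
#' @examples
#' subject_profile(63.74, 21.38, 76.0, id = "OM")
#' @export
subject_profile <- function(L_sub, C_sub, beta, id = NULL) {
  stopifnot(is.numeric(L_sub), is.numeric(C_sub), is.numeric(beta))
  if (C_sub <= 0) stop("C_sub must be positive")
  if (beta <= 0) stop("beta must be positive")
  structure(list(L_sub = L_sub, C_sub = C_sub, beta = beta, id = id),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("Subject profile%s: L* = %.2f, C*ab = %.2f, beta = %.1f\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$L_sub, x$C_sub, x$beta))
  invisible(x)
}

#' Load subject profiles from a YAML file
#'
#' The packaged default carries the mean skin colorimetry of the two study
#' faces (OM: L* 63.74, C*ab 21.38; OF: L* 66.83, C*ab 17.99; beta 76.0).
#'
#' @param path YAML file mapping subject ids to `L_sub`, `C_sub`, `beta`.
#' @return named list of [subject_profile()] objects.
#' @export
load_profiles <- function(path = system.file("extdata", "subject_profiles.yaml",
                                             package = "skinpercept")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(id) {
    p <- raw[[id]]
    miss <- setdiff(c("L_sub", "C_sub", "beta"), names(p))
    if (length(miss))
      stop(sprintf("profile '%s' is missing field(s): %s", id,
                   paste(miss, collapse = ", ")))
    subject_profile(p$L_sub, p$C_sub, p$beta, id = id)
  })
  names(out) <- names(raw)
  out
}

#' Skin whiteness index
#'
#' Scalar whiteness of a skin colour, `W = L - beta * C / (C + beta)`:
#' lighter and less chromatic skin scores whiter. Strictly increasing in L
#' and strictly decreasing in C for `beta > 0`. At `C = 0`, `W = L`.
#'
#' @param L lightness (CIELAB L*), vectorised.
#' @param C chroma (C*ab, non-negative), vectorised.
#' @param beta whiteness coefficient, must be positive.
#' @return whiteness on the same scale as L.
#' @examples
#' whiteness(63.74, 21.38, 76.0) # OM mean skin -> 47.05
#' @export
whiteness <- function(L, C, beta) {
  if (!is.numeric(beta) || any(beta <= 0)) stop("beta must be positive")
  if (any(C < 0)) stop("chroma must be non-negative")
  L - beta * C / (C + beta)
}

#' Resolve a (whiteness, hue) grid point to a concrete skin colour
#'
#' Inverts the whiteness index at the subject's natural chroma: chroma is
#' held at `C_sub` (minimal perturbation of the subject's own skin, and a
#' unique closed-form inverse) and lightness solves
#' `L = W + beta * C_sub / (C_sub + beta)`. The requested hue angle is
#' passed through unchanged.
#'
#' @param W target whiteness.
#' @param h target hue angle in degrees, in `[0, 360)`.
#' @param profile a [subject_profile()].
#' @param W_range plausible whiteness range; values outside it are rejected.
#' @return an object of class `skin_color_spec` with elements `whiteness`,
#'   `hue`, and `resolved` (an LCh triple).
#' @export
resolve_skin_color <- function(W, h, profile, W_range = c(30, 95)) {
  stopifnot(inherits(profile, "subject_profile"), length(W) == 1, length(h) == 1)
  if (W < W_range[1] || W > W_range[2])
    stop(sprintf("whiteness %.3f outside the plausible range [%g, %g]",
                 W, W_range[1], W_range[2]))
  if (h < 0 || h >= 360) stop("hue angle must lie in [0, 360)")
  L <- W + profile$beta * profile$C_sub / (profile$C_sub + profile$beta)
  if (L < 0 || L > 100)
    stop(sprintf("whiteness W = %.3f resolves to out-of-range lightness L = %.3f", W, L))
  structure(list(
    whiteness = W, hue = h,
    resolved = c(L = L, C = profile$C_sub, h = h),
    profile_id = profile$id
  ), class = "skin_color_spec")
}

#' @export
print.skin_color_spec <- function(x, ...) {
  cat(sprintf("Skin colour: W = %.2f, h = %.1f deg -> LCh (%.2f, %.2f, %.1f)\n",
              x$whiteness, x$hue, x$resolved["L"], x$resolved["C"], x$resolved["h"]))
  invisible(x)
}
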