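# Synthetic ground truth: face fixtures with known skin masks, and simulated
# observers responding from a known latent perceptual model, so every stage of
# the pipeline can be tested against truth.

#' Latent perceptual model for simulated observers
#'
#' Ground-truth perceived strength of an attribute as a function of the
#' stimulus colour: linear in whiteness (centred at W = 65, the middle of
#' the 50-80 design range) plus a Gaussian bump in hue angle,
#' `intercept + slope_w * (W - 65) + hue_amp * exp(-(h - hue_peak)^2 / (2 * hue_width^2))`.
#' This is the simplest family that reproduces the qualitative trends of
#' interest: monotone whiteness effects and a unimodal hue preference.
#'
#' @param slope_w latent units per whiteness unit.
#' @param hue_peak hue angle (degrees) of maximal response.
#' @param hue_width Gaussian width of the hue bump (degrees, > 0).
#' @param hue_amp amplitude of the hue bump (latent units).
#' @param intercept baseline latent value.
#' @param sigma discriminal dispersion (> 0): SD of the trial-to-trial
#'   perceptual noise.
#' @param boundaries 9 strictly increasing category cut points mapping the
#'   latent axis to the 10 encoded categories.
#' @return object of class `latent_model`.
#' @export
latent_model <- function(slope_w = 0.05, hue_peak = 40, hue_width = 10,
                         hue_amp = 0.5, intercept = 0, sigma = 1,
                         boundaries = seq(-2, 2, length.out = 9)) {
  stopifnot(sigma > 0, hue_width > 0, length(boundaries) == 9,
            all(diff(boundaries) > 0))
  structure(list(slope_w = slope_w, hue_peak = hue_peak, hue_width = hue_width,
                 hue_amp = hue_amp, intercept = intercept, sigma = sigma,
                 boundaries = boundaries),
            class = "latent_model")
}

#' Latent value of a stimulus colour
#'
#' @param W whiteness (vectorised).
#' @param h hue angle in degrees (vectorised).
#' @param model a [latent_model()].
#' @return latent perceptual value(s).
#' @export
latent_value <- function(W, h, model) {
  stopifnot(inherits(model, "latent_model"))
  model$intercept + model$slope_w * (W - 65) +
    model$hue_amp * exp(-(h - model$hue_peak)^2 / (2 * model$hue_width^2))
}

#' Simulation configuration
#'
#' Defaults mirror the study design: 40 observers judging the 4 x 5
#' whiteness-by-hue grid on two faces for two bipolar attributes, with 4
#' repeat stimuli. Per-observer additive bias (SD `observer_bias_sd`)
#' creates inter-observer variation over and above the trial noise, so the
#' inter-observer RMS exceeds the intra-observer RMS as in real panels.
#' Default latent models give OF and OM a shared positive whiteness slope
#' for femininity, a likeability peak near hue 40 for OF, and latent spans
#' of roughly one unit, matching the magnitude of typical categorical-
#' judgement z-scores.
#'
#' @param n_observers number of simulated observers (>= 1).
#' @param observer_bias_sd SD of the per-observer additive bias.
#' @param grid a [stimulus_grid()].
#' @param models nested list `models[[face]][[attribute]]` of
#'   [latent_model()]s; faces and attributes are taken from its names.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_observers = 40, observer_bias_sd = 1.5,
                              grid = stimulus_grid(), models = default_models(),
                              seed = 1) {
  stopifnot(n_observers >= 1, observer_bias_sd >= 0,
            inherits(grid, "stimulus_grid"), is.list(models),
            !is.null(names(models)))
  for (f in names(models)) {
    stopifnot(is.list(models[[f]]), !is.null(names(models[[f]])))
    for (a in names(models[[f]])) stopifnot(inherits(models[[f]][[a]], "latent_model"))
  }
  structure(list(n_observers = as.integer(n_observers),
                 observer_bias_sd = observer_bias_sd, grid = grid,
                 models = models, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default latent models for the two study faces
#'
#' Femininity rises with whiteness for both faces (stronger for the male
#' face); likeability rises with whiteness and peaks near hue angle 40 for
#' the female face, near 50 for the male face.
#'
#' @return nested list `models[[face]][[attribute]]`.
#' @export
default_models <- function() {
  list(
    OM = list(
      "feminine-masculine" = latent_model(slope_w = 0.035, hue_peak = 30,
                                          hue_width = 15, hue_amp = 0.2),
      "likeable-dislikeable" = latent_model(slope_w = 0.035, hue_peak = 50,
                                            hue_width = 15, hue_amp = 0.2)
    ),
    OF = list(
      "feminine-masculine" = latent_model(slope_w = 0.02, hue_peak = 40,
                                          hue_width = 10, hue_amp = 0.5),
      "likeable-dislikeable" = latent_model(slope_w = 0.025, hue_peak = 40,
                                            hue_width = 10, hue_amp = 0.6)
    )
  )
}

#' Simulate forced-choice observer responses
#'
#' For every observer x stimulus x attribute the latent stimulus value plus
#' the observer's bias plus Normal(0, sigma) noise is discretised through
#' the model's category boundaries into one of 10 categories, then decoded
#' to a (pole, 1-5 score) forced-choice record. Repeat-flagged stimuli get
#' a second, independently noisy presentation. Fully reproducible from the
#' configuration seed.
#'
#' @param config a [simulation_config()].
#' @return data frame of responses: `observer_id`, `stimulus_id`,
#'   `attribute`, `pole`, `score`, `presentation_index`, plus the design
#'   columns `face_id`, `whiteness`, `hue_deg`, `is_repeat_trial` and the
#'   ground-truth `latent` value.
#' @export
simulate_responses <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  man <- grid_manifest(names(config$models), config$grid)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  obs_ids <- sprintf("obs%02d", seq_len(config$n_observers))
  all_attrs <- unique(unlist(lapply(config$models, names)))
  bias <- matrix(stats::rnorm(config$n_observers * length(all_attrs),
                              sd = config$observer_bias_sd),
                 nrow = config$n_observers,
                 dimnames = list(obs_ids, all_attrs))
  blocks <- vector("list", 0)
  for (face in names(config$models)) {
    fman <- man[man$face_id == face, , drop = FALSE]
    for (a in names(config$models[[face]])) {
      model <- config$models[[face]][[a]]
      mu <- latent_value(fman$whiteness, fman$hue_deg, model)
      pres_per_stim <- ifelse(fman$is_repeat, 2L, 1L)
      stim_idx <- rep(seq_len(nrow(fman)), times = pres_per_stim)
      pres <- sequence(pres_per_stim)
      n_trial <- length(stim_idx)
      d <- data.frame(
        observer_id = rep(obs_ids, each = n_trial),
        stimulus_id = rep(fman$stimulus_id[stim_idx], config$n_observers),
        attribute = a,
        presentation_index = rep(pres, config$n_observers),
        face_id = face,
        whiteness = rep(fman$whiteness[stim_idx], config$n_observers),
        hue_deg = rep(fman$hue_deg[stim_idx], config$n_observers),
        is_repeat_trial = rep(fman$is_repeat[stim_idx], config$n_observers),
        latent = rep(mu[stim_idx], config$n_observers)
      )
      x <- d$latent + bias[d$observer_id, a] +
        stats::rnorm(nrow(d), sd = model$sigma)
      cat10 <- findInterval(x, model$boundaries) + 1L
      dec <- decode_category(cat10)
      terms <- attribute_terms(a)
      d$pole <- ifelse(dec$pole == "first", terms[1], terms[2])
      d$score <- dec$score
      blocks[[length(blocks) + 1L]] <- d
    }
  }
  out <- do.call(rbind, blocks)
  cols <- c("observer_id", "stimulus_id", "attribute", "pole", "score",
            "presentation_index", "face_id", "whiteness", "hue_deg",
            "is_repeat_trial", "latent")
  out <- out[, cols]
  rownames(out) <- NULL
  out
}

#' Make a synthetic face fixture with known ground truth
#'
#' A face-like test image: an elliptical skin region at a given CIELAB
#' colour with Gaussian CIELAB texture, non-skin eye and lip patches whose
#' colours fall far outside any plausible skin threshold box, and a
#' distinct background. The true skin mask is returned alongside the image,
#' so segmentation and recolouring can be scored against ground truth.
#'
#' @param width,height image size in pixels.
#' @param skin_color Lab triple of the mean skin colour.
#' @param texture_sd SD of the Gaussian texture added to each Lab channel.
#' @param seed RNG seed for the texture.
#' @param subject_id id stored on the image.
#' @return list with `image` ([face_image()]), `mask` (true logical skin
#'   mask), `skin_color`, and `skin_samples` (an n x 3 sRGB sample of true
#'   skin pixels for threshold estimation).
#' @export
make_synthetic_face <- function(width = 120, height = 150,
                                skin_color = c(66.83, 13.78, 11.57),
                                texture_sd = 2, seed = 1, subject_id = NULL) {
  stopifnot(width > 0, height > 0, texture_sd >= 0)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  H <- height; W <- width
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  # face ellipse
  mask <- ((rr - H / 2) / (H * 0.42))^2 + ((cc - W / 2) / (W * 0.38))^2 <= 1
  # eye and lip patches (non-skin), clearly inside the ellipse
  eyeL <- (abs(rr - H * 0.38) <= H * 0.04) & (abs(cc - W * 0.35) <= W * 0.08)
  eyeR <- (abs(rr - H * 0.38) <= H * 0.04) & (abs(cc - W * 0.65) <= W * 0.08)
  lips <- (abs(rr - H * 0.72) <= H * 0.035) & (abs(cc - W * 0.5) <= W * 0.12)
  features <- (eyeL | eyeR | lips) & mask
  skin <- mask & !features
  n_skin <- sum(skin)
  lab <- cbind(
    skin_color[1] + stats::rnorm(n_skin, sd = texture_sd),
    skin_color[2] + stats::rnorm(n_skin, sd = texture_sd),
    skin_color[3] + stats::rnorm(n_skin, sd = texture_sd)
  )
  rgb_skin <- lab_to_srgb(lab, warn_clip = FALSE)
  if (is.null(dim(rgb_skin))) rgb_skin <- matrix(rgb_skin, nrow = 1)
  px <- array(0, c(H, W, 3))
  # background: dark blue-grey, far from skin
  bg <- c(40, 60, 90)
  eye_col <- c(250, 250, 250)   # near-white sclera
  lip_col <- c(150, 30, 60)     # saturated red, outside the skin box
  for (ch in 1:3) {
    plane <- matrix(bg[ch], H, W)
    plane[features & (eyeL | eyeR)] <- eye_col[ch]
    plane[features & lips] <- lip_col[ch]
    plane[skin] <- round(rgb_skin[, ch])
    px[, , ch] <- plane
  }
  idx <- sample(n_skin, min(500, n_skin))
  list(
    image = face_image(px, subject_id = subject_id),
    mask = skin,
    skin_color = skin_color,
    skin_samples = round(rgb_skin[idx, , drop = FALSE])
  )
}
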