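# Thurstonian scaling of bipolar forced-choice ratings: category encoding,
# frequency -> cumulative probability -> inverse-normal z-score chain, scale
# values by the method of categorical judgement, and observer-variation RMS.

#' Bipolar attribute helpers
#'
#' An attribute such as `"feminine-masculine"` pairs a first (positive) term
#' with a second (negative) term. `attribute_terms()` splits the attribute
#' label into its two poles.
#'
#' @param attribute attribute label, two terms joined by `-`.
#' @return character vector `c(first, second)`.
#' @export
attribute_terms <- function(attribute) {
  parts <- strsplit(attribute, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("attribute must be two terms joined by '-'")
  parts
}

#' Encode a forced-choice judgement as one of 10 ordered categories
#'
#' The forced choice (which pole) and the 1-5 strength score fold into a
#' single 10-step bipolar scale with no neutral cell: second-pole scores map
#' 5 -> 1 ... 1 -> 5 and first-pole scores map 1 -> 6 ... 5 -> 10, so
#' category 1 is the strongest second-pole (e.g. masculine) judgement and
#' category 10 the strongest first-pole (e.g. feminine) judgement.
#'
#' @param pole `"first"` or `"second"` (vectorised), or a pole term when
#'   `attribute` is supplied.
#' @param score integer 1-5 (vectorised); 5 = strong association.
#' @param attribute optional attribute label used to translate pole terms.
#' @return integer category in 1-10.
#' @examples
#' encode_category("second", 5) # 1, extreme negative
#' encode_category("feminine", 5, attribute = "feminine-masculine") # 10
#' @export
encode_category <- function(pole, score, attribute = NULL) {
  if (!is.null(attribute)) {
    terms <- attribute_terms(attribute)
    unknown <- setdiff(unique(pole), terms)
    if (length(unknown))
      stop(sprintf("pole '%s' does not belong to attribute '%s'",
                   unknown[1], attribute))
    pole <- ifelse(pole == terms[1], "first", "second")
  }
  if (!all(pole %in% c("first", "second"))) stop("pole must be 'first' or 'second'")
  score <- as.integer(score)
  if (any(is.na(score)) || any(score < 1) || any(score > 5))
    stop("score must be an integer in 1..5")
  as.integer(ifelse(pole == "second", 6L - score, 5L + score))
}

#' Decode a category back to (pole, score)
#'
#' Inverse of [encode_category()]: categories 1-5 are second-pole judgements
#' with score `6 - category`; categories 6-10 are first-pole judgements with
#' score `category - 5`.
#'
#' @param category integer 1-10 (vectorised).
#' @return data frame with columns `pole` (`"first"`/`"second"`) and `score`.
#' @export
decode_category <- function(category) {
  category <- as.integer(category)
  if (any(is.na(category)) || any(category < 1) || any(category > 10))
    stop("category must be an integer in 1..10")
  data.frame(
    pole = ifelse(category <= 5L, "second", "first"),
    score = ifelse(category <= 5L, 6L - category, category - 5L)
  )
}

#' Frequency matrix of categorical responses
#'
#' Counts responses per stimulus per encoded category for one attribute.
#'
#' @param responses response data frame (see [validate_responses()] for the
#'   schema) with columns `observer_id`, `stimulus_id`, `attribute`, `pole`,
#'   `score`, `presentation_index`.
#' @param attribute attribute to tabulate; must match every record kept.
#' @param exclude_repeats drop second presentations (they are reserved for
#'   intra-observer variation, not scaling).
#' @param n_categories number of encoded categories (10 for the bipolar
#'   5-point design).
#' @return integer matrix, stimuli x categories; rows named by stimulus.
#' @export
frequency_matrix <- function(responses, attribute, exclude_repeats = TRUE,
                             n_categories = 10) {
  r <- responses[responses$attribute == attribute, , drop = FALSE]
  if (exclude_repeats && "presentation_index" %in% names(r))
    r <- r[r$presentation_index == 1, , drop = FALSE]
  if (nrow(r) == 0) stop(sprintf("no responses for attribute '%s'", attribute))
  cat <- encode_category(r$pole, r$score, attribute = attribute)
  if (any(cat > n_categories)) stop("encoded category exceeds n_categories")
  counts <- table(factor(r$stimulus_id), factor(cat, levels = seq_len(n_categories)))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(rownames(counts), seq_len(n_categories)))
  counts
}

#' Cumulative probability matrix
#'
#' Row-wise cumulative proportions over the first `C - 1` category
#' boundaries; the implicit final cumulative (always 1) is dropped.
#'
#' @param counts stimuli x categories count matrix (rows must be non-empty).
#' @return stimuli x (categories - 1) matrix of proportions in `[0, 1]`,
#'   nondecreasing along each row.
#' @export
cumulative_probability <- function(counts) {
  counts <- as.matrix(counts)
  n <- rowSums(counts)
  if (any(n == 0)) stop("every stimulus needs at least one response")
  cp <- t(apply(counts, 1, cumsum)) / n
  cp[, -ncol(cp), drop = FALSE]
}

#' Inverse-normal z-score matrix
#'
#' Applies the standard normal quantile function to cumulative category
#' proportions. Proportions are first clipped to
#' `[1/(2n), 1 - 1/(2n)]` per stimulus so the result stays finite at
#' observed 0s and 1s (the usual finite-sample correction).
#'
#' @param cumprob output of [cumulative_probability()].
#' @param n responses per stimulus (scalar or per-row vector) used for the
#'   clipping bound.
#' @param clip apply the clipping correction (disable only for data already
#'   strictly inside (0, 1)).
#' @return matrix of z-scores, same shape as `cumprob`.
#' @export
zscore_matrix <- function(cumprob, n, clip = TRUE) {
  cumprob <- as.matrix(cumprob)
  if (any(cumprob < 0) || any(cumprob > 1)) stop("probabilities must lie in [0, 1]")
  if (clip) {
    lo <- 1 / (2 * n)
    cumprob <- pmax(pmin(cumprob, 1 - lo), lo)
  }
  z <- stats::qnorm(cumprob)
  if (any(!is.finite(z))) stop("non-finite z-scores; enable clipping")
  z
}

#' Thurstonian scale values by the method of categorical judgement
#'
#' Fits the Case V categorical-judgement model to a z-score matrix: the
#' category-boundary locations are the column means of the z matrix over
#' stimuli, and each stimulus value is the mean signed distance from the
#' boundaries, `mean_k(tau_k - z[s, k])`. Values are centred to mean 0
#' across the stimulus set; a higher value means the response mass sits in
#' higher (first-pole) categories.
#'
#' @param z z-score matrix from [zscore_matrix()].
#' @return list with `values` (named per stimulus, mean 0) and `boundaries`
#'   (tau, one per internal category boundary).
#' @export
scale_values <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2) {
    warning("scale values are defined up to translation; a single stimulus scales to 0")
    return(list(values = stats::setNames(rep(0, nrow(z)), rownames(z)),
                boundaries = colMeans(z)))
  }
  tau <- colMeans(z)
  v <- rowMeans(matrix(tau, nrow(z), ncol(z), byrow = TRUE) - z)
  v <- v - mean(v)
  list(values = stats::setNames(v, rownames(z)), boundaries = tau)
}

#' Fit a Thurstonian categorical-judgement scaling
#'
#' The main fitting function: runs the frequency -> cumulative probability
#' -> inverse-normal -> scale-value chain on the forced-choice responses of
#' one attribute, pooled over observers. Second presentations of repeat
#' stimuli are excluded from scaling.
#'
#' @param responses response data frame (schema as in [validate_responses()]).
#' @param attribute attribute to scale, e.g. `"feminine-masculine"`.
#' @param clip apply the extreme-proportion clipping of [zscore_matrix()].
#' @return object of class `thurstone`: scale values (positive = first
#'   pole), boundary estimates, the intermediate matrices, and per-stimulus
#'   response counts.
#' @examples
#' r <- simulate_responses(simulation_config(n_observers = 8, seed = 1))
#' fit <- thurstone_scale(r, "feminine-masculine")
#' coef(fit)[1:3]
#' @export
thurstone_scale <- function(responses, attribute, clip = TRUE) {
  counts <- frequency_matrix(responses, attribute)
  n <- rowSums(counts)
  cp <- cumulative_probability(counts)
  z <- zscore_matrix(cp, n, clip = clip)
  sv <- scale_values(z)
  structure(list(
    values = sv$values, boundaries = sv$boundaries,
    z = z, cumprob = cp, counts = counts, n = n,
    attribute = attribute, terms = attribute_terms(attribute)
  ), class = "thurstone")
}

#' @export
print.thurstone <- function(x, ...) {
  cat(sprintf("Thurstonian categorical-judgement scaling: %s\n", x$attribute))
  nrng <- range(x$n)
  cat(sprintf("  %d stimuli, %s responses each; positive = %s, negative = %s\n",
              length(x$values),
              if (nrng[1] == nrng[2]) nrng[1] else paste(nrng, collapse = "-"),
              x$terms[1], x$terms[2]))
  rng <- range(x$values)
  cat(sprintf("  scale values in [%.3f, %.3f]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
summary.thurstone <- function(object, ...) {
  out <- list(
    attribute = object$attribute,
    values = sort(object$values, decreasing = TRUE),
    boundaries = object$boundaries,
    n = object$n
  )
  class(out) <- "summary.thurstone"
  out
}

#' @export
print.summary.thurstone <- function(x, ...) {
  cat(sprintf("Attribute: %s\n\nScale values (descending):\n", x$attribute))
  print(round(x$values, 4))
  cat("\nCategory boundaries (tau):\n")
  print(round(x$boundaries, 4))
  invisible(x)
}

#' @export
coef.thurstone <- function(object, ...) object$values

#' @export
plot.thurstone <- function(x, ...) {
  v <- sort(x$values)
  graphics::dotchart(v, labels = names(v),
                     xlab = sprintf("scale value (%s < 0 < %s)", x$terms[2], x$terms[1]),
                     main = x$attribute, ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Intra-observer repeatability (RMS)
#'
#' Root-mean-square difference, in encoded-category units, between the first
#' and second presentation of each repeated stimulus, over all (observer,
#' stimulus, attribute) repeat pairs.
#'
#' @param responses response data frame containing repeat presentations
#'   (`presentation_index` 1 and 2 for the repeated stimuli).
#' @param attribute optional; restrict to one attribute.
#' @return RMS in category units (scalar).
#' @export
intra_observer_rms <- function(responses, attribute = NULL) {
  r <- responses
  if (!is.null(attribute)) r <- r[r$attribute == attribute, , drop = FALSE]
  r$cat <- .encode_rows(r)
  second <- r[r$presentation_index == 2, , drop = FALSE]
  if (nrow(second) == 0) stop("no repeat presentations in the responses")
  key <- function(d) paste(d$observer_id, d$stimulus_id, d$attribute)
  first <- r[r$presentation_index == 1, , drop = FALSE]
  m <- match(key(second), key(first))
  if (any(is.na(m))) stop("repeat presentation without a matching first presentation")
  sqrt(mean((second$cat - first$cat[m])^2))
}

#' Inter-observer agreement (RMS)
#'
#' Root-mean-square deviation, in encoded-category units, of each observer's
#' response from the panel mean for that stimulus (first presentations
#' only), over all (observer, stimulus) cells.
#'
#' @inheritParams intra_observer_rms
#' @return RMS in category units (scalar).
#' @export
inter_observer_rms <- function(responses, attribute = NULL) {
  r <- responses
  if (!is.null(attribute)) r <- r[r$attribute == attribute, , drop = FALSE]
  r <- r[r$presentation_index == 1, , drop = FALSE]
  if (length(unique(r$observer_id)) < 2)
    stop("inter-observer RMS requires at least two observers")
  r$cat <- .encode_rows(r)
  cell <- paste(r$stimulus_id, r$attribute)
  panel <- ave(r$cat, cell)
  sqrt(mean((r$cat - panel)^2))
}

#' Observer variation summary
#'
#' Intra- and inter-observer RMS per attribute, reported in encoded-category
#' units and additionally as a percentage of the 9-step span of the
#' 10-category scale (the unit of the raw judgements).
#'
#' @param responses response data frame with repeat presentations.
#' @return data frame with one row per attribute and columns `intra_rms`,
#'   `inter_rms`, `intra_pct_span`, `inter_pct_span`.
#' @export
observer_variation <- function(responses) {
  atts <- sort(unique(responses$attribute))
  rows <- lapply(atts, function(a) {
    intra <- intra_observer_rms(responses, a)
    inter <- inter_observer_rms(responses, a)
    data.frame(attribute = a, intra_rms = intra, inter_rms = inter,
               intra_pct_span = 100 * intra / 9, inter_pct_span = 100 * inter / 9)
  })
  do.call(rbind, rows)
}

# Pole is stored as the attribute's own term (e.g. "feminine"); encode each
# row against its attribute's term pair.
.encode_rows <- function(r) {
  out <- integer(nrow(r))
  for (a in unique(r$attribute)) {
    i <- r$attribute == a
    out[i] <- encode_category(r$pole[i], r$score[i], attribute = a)
  }
  out
}
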