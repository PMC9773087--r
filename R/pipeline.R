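# End-to-end pipeline: response validation, per-factor inference, attribute
# correlation, and a reproducible report.

.RESPONSE_COLS <- c("observer_id", "stimulus_id", "attribute", "pole", "score",
                    "presentation_index")

#' Validate an observer-response file
#'
#' Strict schema check of a response CSV: required columns, integer scores
#' in 1-5, poles belonging to their attribute, presentation indices in
#' {1, 2}, and no duplicate (observer, stimulus, attribute, presentation)
#' rows. Every problem is reported with its line number (header = line 1);
#' any problem aborts with the aggregated list.
#'
#' @param path CSV file with columns `observer_id`, `stimulus_id`,
#'   `attribute`, `pole`, `score`, `presentation_index`.
#' @return the validated response data frame (invisibly usable downstream).
#' @export
validate_responses <- function(path) {
  if (!file.exists(path)) stop(sprintf("response file not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  errs <- character(0)
  missing <- setdiff(.RESPONSE_COLS, names(d))
  if (length(missing))
    stop(sprintf("response file is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  line <- seq_len(nrow(d)) + 1L # header is line 1
  sc <- suppressWarnings(as.numeric(d$score))
  bad <- which(is.na(sc) | sc != round(sc) | sc < 1 | sc > 5)
  for (i in bad)
    errs <- c(errs, sprintf("line %d: score '%s' is not an integer in 1..5",
                            line[i], d$score[i]))
  pr <- suppressWarnings(as.numeric(d$presentation_index))
  bad <- which(is.na(pr) | !(pr %in% c(1, 2)))
  for (i in bad)
    errs <- c(errs, sprintf("line %d: presentation_index '%s' must be 1 or 2",
                            line[i], d$presentation_index[i]))
  for (a in unique(d$attribute)) {
    terms <- tryCatch(attribute_terms(a), error = function(e) NULL)
    i_a <- which(d$attribute == a)
    if (is.null(terms)) {
      errs <- c(errs, sprintf("line %d: malformed attribute '%s'", line[i_a[1]], a))
      next
    }
    bad <- i_a[!(d$pole[i_a] %in% terms)]
    for (i in bad)
      errs <- c(errs, sprintf("line %d: pole '%s' does not belong to attribute '%s'",
                              line[i], d$pole[i], a))
  }
  key <- paste(d$observer_id, d$stimulus_id, d$attribute, d$presentation_index)
  dup <- which(duplicated(key))
  for (i in dup)
    errs <- c(errs, sprintf("line %d: duplicate (observer, stimulus, attribute, presentation) row",
                            line[i]))
  if (length(errs))
    stop(paste(c(sprintf("%d problem(s) in %s:", length(errs), path), errs),
               collapse = "\n"))
  d$score <- as.integer(d$score)
  d$presentation_index <- as.integer(d$presentation_index)
  d
}

#' Write responses to CSV
#'
#' @param responses response data frame (e.g. from [simulate_responses()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param grid a [stimulus_grid()].
#' @param sim a [simulation_config()] used when no response file is given.
#' @param responses_path optional CSV of real observer responses; when
#'   supplied it replaces the simulator (the design columns `face_id`,
#'   `whiteness`, `hue_deg` must then be recoverable from a manifest or be
#'   present in the file).
#' @param alpha significance level for the inferential tables.
#' @param out_dir optional output directory for the CSV/JSON report.
#' @param seed master seed (propagated to the simulator and grid).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid = stimulus_grid(seed = seed),
                            sim = simulation_config(grid = grid, seed = seed),
                            responses_path = NULL, alpha = 0.05,
                            out_dir = NULL, seed = 1) {
  stopifnot(alpha > 0, alpha < 1)
  if (!is.null(responses_path) && !file.exists(responses_path))
    stop(sprintf("responses_path does not exist: %s", responses_path))
  structure(list(grid = grid, sim = sim, responses_path = responses_path,
                 alpha = alpha, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Composes the stages of the study workflow: obtain responses (simulated
#' from the configuration, or a validated response file), fit the
#' Thurstonian scaling per face and attribute, compute observer variation,
#' run Welch's ANOVA and Games-Howell comparisons for each factor
#' (whiteness and hue angle, one-way each, the other factor pooled; groups
#' are per-observer encoded responses), and correlate the two attribute
#' scales per face. Deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return object of class `skin_report` with elements `scales` (data
#'   frame of scale values), `variation`, `anova` (per face/attribute/
#'   factor: `welch_anova` + `games_howell`), `correlations`, `responses`,
#'   and a `provenance` block (seed, counts, package version).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  responses <- if (is.null(config$responses_path)) {
    simulate_responses(config$sim)
  } else {
    validate_responses(config$responses_path)
  }
  need <- c("face_id", "whiteness", "hue_deg")
  if (!all(need %in% names(responses)))
    stop(sprintf("stage scaling: responses lack design column(s): %s",
                 paste(setdiff(need, names(responses)), collapse = ", ")))
  faces <- sort(unique(responses$face_id))
  attrs <- sort(unique(responses$attribute))

  fits <- list(); scales <- list()
  for (f in faces) for (a in attrs) {
    rf <- responses[responses$face_id == f & responses$attribute == a, , drop = FALSE]
    fit <- thurstone_scale(rf, a)
    fits[[paste(f, a, sep = ".")]] <- fit
    man <- unique(rf[rf$presentation_index == 1,
                     c("stimulus_id", "whiteness", "hue_deg")])
    m <- match(names(fit$values), man$stimulus_id)
    scales[[length(scales) + 1L]] <- data.frame(
      face_id = f, attribute = a, stimulus_id = names(fit$values),
      whiteness = man$whiteness[m], hue_deg = man$hue_deg[m],
      scale_value = unname(fit$values)
    )
  }
  scales <- do.call(rbind, scales)

  variation <- observer_variation(responses)

  anova_tables <- list()
  first <- responses[responses$presentation_index == 1, , drop = FALSE]
  first$cat <- .encode_rows(first)
  for (f in faces) for (a in attrs) for (factor_name in c("whiteness", "hue_deg")) {
    rf <- first[first$face_id == f & first$attribute == a, , drop = FALSE]
    groups <- split(as.numeric(rf$cat), rf[[factor_name]])
    key <- paste(f, a, factor_name, sep = ".")
    anova_tables[[key]] <- list(
      face_id = f, attribute = a, factor = factor_name,
      welch = welch_anova(groups),
      games_howell = games_howell(groups, alpha = config$alpha)
    )
  }

  correlations <- lapply(faces, function(f) {
    if (length(attrs) < 2) return(NULL)
    s1 <- scales[scales$face_id == f & scales$attribute == attrs[1], ]
    s2 <- scales[scales$face_id == f & scales$attribute == attrs[2], ]
    m <- match(s1$stimulus_id, s2$stimulus_id)
    pr <- pearson_r(s1$scale_value, s2$scale_value[m])
    c(list(face_id = f, attributes = attrs[1:2]), pr)
  })
  names(correlations) <- faces

  report <- structure(list(
    scales = scales, variation = variation, anova = anova_tables,
    correlations = correlations, fits = fits, responses = responses,
    provenance = list(
      seed = config$seed, alpha = config$alpha,
      n_observers = length(unique(responses$observer_id)),
      n_stimuli = length(unique(responses$stimulus_id)),
      n_repeat_stimuli = length(unique(
        responses$stimulus_id[responses$presentation_index == 2])),
      package_version = as.character(utils::packageVersion("skinpercept"))
    )
  ), class = "skin_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Tidy CSVs (scale values, observer variation, ANOVA and pairwise tables)
#' plus a JSON summary with the provenance block.
#'
#' @param report a `skin_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "skin_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$scales, file.path(dir, "scale_values.csv"),
                   row.names = FALSE)
  utils::write.csv(report$variation, file.path(dir, "observer_variation.csv"),
                   row.names = FALSE)
  welch <- do.call(rbind, lapply(report$anova, function(t) data.frame(
    face_id = t$face_id, attribute = t$attribute, factor = t$factor,
    F = t$welch$F, df1 = t$welch$df1, df2 = t$welch$df2, p = t$welch$p,
    eta_sq = t$welch$eta_sq)))
  utils::write.csv(welch, file.path(dir, "welch_anova.csv"), row.names = FALSE)
  gh <- do.call(rbind, lapply(report$anova, function(t) cbind(
    face_id = t$face_id, attribute = t$attribute, factor = t$factor,
    as.data.frame(t$games_howell))))
  utils::write.csv(gh, file.path(dir, "games_howell.csv"), row.names = FALSE)
  summary_json <- list(
    provenance = report$provenance,
    correlations = lapply(report$correlations, function(co)
      co[c("face_id", "r", "p", "n", "label")]),
    variation = report$variation
  )
  jsonlite::write_json(summary_json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.skin_report <- function(x, ...) {
  p <- x$provenance
  cat("Skin-colour perception analysis report\n")
  cat(sprintf("  %d observers, %d stimuli (%d repeated), alpha = %g, seed = %d\n",
              p$n_observers, p$n_stimuli, p$n_repeat_stimuli, p$alpha, p$seed))
  cat("\nObserver variation (encoded-category units):\n")
  print(cbind(x$variation[1], round(x$variation[-1], 3)), row.names = FALSE)
  cat("\nWelch ANOVA:\n")
  for (t in x$anova)
    cat(sprintf("  %s / %s / %s: F(%g, %.2f) = %.3f, p = %.4g, eta^2 = %.3f\n",
                t$face_id, t$attribute, t$factor, t$welch$df1, t$welch$df2,
                t$welch$F, t$welch$p, t$welch$eta_sq))
  cat("\nAttribute correlations:\n")
  for (co in x$correlations)
    if (!is.null(co))
      cat(sprintf("  %s: r = %.3f (%s), p = %.4g\n",
                  co$face_id, co$r, co$label, co$p))
  invisible(x)
}
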