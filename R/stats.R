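# Inferential layer: Welch's one-way ANOVA with classical eta-squared,
# Games-Howell pairwise comparisons, and Pearson correlation between the
# two bipolar attributes.

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("at least two groups are required")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  for (g in names(groups)) {
    v <- groups[[g]]
    if (!is.numeric(v) || length(v) < 2)
      stop(sprintf("group '%s' needs at least 2 numeric values", g))
  }
  vars <- vapply(groups, stats::var, numeric(1))
  if (all(vars == 0)) {
    if (length(unique(unlist(groups))) == 1) return("degenerate")
    stop(sprintf("zero-variance group '%s' makes Welch weights undefined",
                 names(groups)[which(vars == 0)[1]]))
  }
  if (any(vars == 0))
    stop(sprintf("zero-variance group '%s' makes Welch weights undefined",
                 names(groups)[which(vars == 0)[1]]))
  "ok"
}

#' Welch's one-way ANOVA with eta-squared
#'
#' Heteroscedasticity-robust one-way ANOVA (weights `n_i / s_i^2`,
#' Welch-Satterthwaite denominator degrees of freedom), as implemented by
#' `stats::oneway.test(var.equal = FALSE)`, plus the classical effect size
#' `eta^2 = SS_between / SS_total` computed on the same data.
#'
#' @param groups named list of numeric vectors (>= 2 values each), or a
#'   formula `values ~ group`.
#' @param data data frame for the formula interface.
#' @param ... unused.
#' @return object of class `welch_anova`: `F`, `df1`, `df2`, `p`, `eta_sq`,
#'   and the per-group summary table.
#' @examples
#' welch_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 9)))
#' @export
welch_anova <- function(groups, data = NULL, ...) {
  if (inherits(groups, "formula")) {
    mf <- stats::model.frame(groups, data)
    groups <- split(mf[[1]], mf[[2]])
  }
  state <- .check_groups(groups)
  k <- length(groups)
  nms <- names(groups)
  summ <- data.frame(
    group = nms,
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    var = vapply(groups, stats::var, numeric(1)),
    row.names = NULL
  )
  if (state == "degenerate") {
    warning("all values identical across groups; F = 0, p = 1")
    out <- list(F = 0, df1 = k - 1, df2 = Inf, p = 1, eta_sq = 0, groups = summ)
    class(out) <- "welch_anova"
    return(out)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(nms, times = summ$n), levels = nms)
  ow <- stats::oneway.test(y ~ g, var.equal = FALSE)
  ss_total <- sum((y - mean(y))^2)
  ss_between <- sum(summ$n * (summ$mean - mean(y))^2)
  out <- list(
    F = unname(ow$statistic),
    df1 = unname(ow$parameter["num df"]),
    df2 = unname(ow$parameter["denom df"]),
    p = unname(ow$p.value),
    eta_sq = ss_between / ss_total,
    groups = summ
  )
  class(out) <- "welch_anova"
  out
}

#' @export
print.welch_anova <- function(x, ...) {
  cat(sprintf("Welch's one-way ANOVA: F(%g, %.3f) = %.4f, p = %.4g, eta^2 = %.3f\n",
              x$df1, x$df2, x$F, x$p, x$eta_sq))
  invisible(x)
}

#' Games-Howell post hoc pairwise comparisons
#'
#' All pairwise group comparisons under unequal variances and sizes: for
#' each pair the standard error is `sqrt(s_i^2/n_i + s_j^2/n_j)` with
#' Welch-Satterthwaite degrees of freedom, and the statistic
#' `|mean_i - mean_j| / SE` is referred to the studentized-range
#' distribution with `k` groups (`q = t * sqrt(2)`), giving family-corrected
#' adjusted p-values.
#'
#' @inheritParams welch_anova
#' @param alpha significance level for the `significant` flag.
#' @return data frame of class `games_howell`: one row per pair with
#'   `diff`, `se`, `t`, `df`, `p_adj`, `significant`.
#' @export
games_howell <- function(groups, data = NULL, alpha = 0.05, ...) {
  if (inherits(groups, "formula")) {
    mf <- stats::model.frame(groups, data)
    groups <- split(mf[[1]], mf[[2]])
  }
  state <- .check_groups(groups)
  k <- length(groups)
  nms <- names(groups)
  n <- vapply(groups, length, numeric(1))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(idx) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    if (state == "degenerate")
      return(data.frame(group1 = nms[i], group2 = nms[j], diff = 0, se = 0,
                        t = 0, df = NA_real_, p_adj = 1, significant = FALSE))
    sei2 <- v[i] / n[i]; sej2 <- v[j] / n[j]
    se <- sqrt(sei2 + sej2)
    df <- (sei2 + sej2)^2 / (sei2^2 / (n[i] - 1) + sej2^2 / (n[j] - 1))
    tt <- abs(m[i] - m[j]) / se
    p <- stats::ptukey(tt * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group1 = nms[i], group2 = nms[j], diff = m[i] - m[j], se = se,
               t = tt, df = df, p_adj = p, significant = p <= alpha)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("games_howell", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.games_howell <- function(x, ...) {
  cat(sprintf("Games-Howell pairwise comparisons (alpha = %g)\n", attr(x, "alpha")))
  print.data.frame(cbind(x[1:2], round(x[3:7], 4), significant = x$significant),
                   row.names = FALSE)
  invisible(x)
}

#' Pearson correlation between two attribute scales
#'
#' Product-moment correlation with the two-sided t-transform p-value.
#'
#' @param x,y numeric vectors of equal length (>= 3), e.g. the scale values
#'   of two attributes over the same stimuli.
#' @return list with `r`, `p`, `n`, and `label` (see
#'   [classify_correlation()]).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, p = unname(ct$p.value), n = length(x),
       label = classify_correlation(r))
}

#' Classify a correlation as strong or weak
#'
#' Strength rule: `|r| > 0.6` is a strong linear correlation, otherwise
#' weak (strict inequality at the boundary). Sign is reported separately.
#'
#' @param r correlation coefficient in `[-1, 1]`.
#' @return character, e.g. `"strong positive"` or `"weak negative"`.
#' @examples
#' classify_correlation(0.95)  # "strong positive"
#' classify_correlation(0.503) # "weak positive"
#' @export
classify_correlation <- function(r) {
  if (abs(r) > 1) stop("r must lie in [-1, 1]")
  strength <- if (abs(r) > 0.6) "strong" else "weak"
  sign <- if (r > 0) "positive" else if (r < 0) "negative" else "zero"
  paste(strength, sign)
}
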