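#' Confidence interval overlap
#'
#' The average of the two intervals' shares of their intersection length:
#' \deqn{\frac{1}{2}\left[\frac{\min(hi)-\max(lo)}{hi_o-lo_o} +
#'   \frac{\min(hi)-\max(lo)}{hi_s-lo_s}\right]}
#' Equals 1 iff the intervals are identical, and is negative when they are
#' disjoint (the signed "gap" penalises separation).
#'
#' @param lo_o,hi_o Bounds of the observed-data interval.
#' @param lo_s,hi_s Bounds of the synthetic-data interval.
#' @return A number \eqn{\le 1}.
#' @export
ci_overlap <- function(lo_o, hi_o, lo_s, hi_s) {
  if (any(hi_o <= lo_o) || any(hi_s <= lo_s))
    stop("intervals must have positive length", call. = FALSE)
  inter <- pmin(hi_o, hi_s) - pmax(lo_o, lo_s)
  0.5 * (inter / (hi_o - lo_o) + inter / (hi_s - lo_s))
}

#' Standardized coefficient differences between two fits
#'
#' For each shared coefficient, \eqn{z_j = (\beta_{syn,j} - \beta_{obs,j}) /
#' se_{obs,j}}: the displacement of the synthetic-data estimate in units of
#' the original fit's standard error, with a two-sided normal p-value. The
#' denominator is deliberately the observed fit's standard error — the
#' question is whether synthesis moved the coefficient relative to the
#' original data's uncertainty.
#'
#' @param fit_obs,fit_syn `synth_fit` objects with identical coefficient
#'   name lists (observed-data fit first).
#' @return Data frame with columns `coef`, `z`, `p`.
#' @export
std_coef_diff <- function(fit_obs, fit_syn) {
  stopifnot(inherits(fit_obs, "synth_fit"), inherits(fit_syn, "synth_fit"))
  if (!identical(fit_obs$coef_names, fit_syn$coef_names))
    stop("fits have different coefficients: [",
         paste(fit_obs$coef_names, collapse = ", "), "] vs [",
         paste(fit_syn$coef_names, collapse = ", "), "]", call. = FALSE)
  if (any(fit_obs$se <= 0)) stop("observed fit has a zero standard error", call. = FALSE)
  z <- (fit_syn$beta - fit_obs$beta) / fit_obs$se
  data.frame(coef = fit_obs$coef_names, z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))), row.names = NULL)
}

#' Lack-of-fit test between two fits
#'
#' Joint chi-square test of the displacement of the synthetic-model
#' coefficient vector from the original-model one, in the metric of the
#' original fit's coefficient covariance (Mahalanobis form):
#' \eqn{\chi^2 = (\beta_s-\beta_o)^\top V_o^{-1} (\beta_s-\beta_o)} on
#' df = number of coefficients (intercept included). With a single
#' coefficient this reduces exactly to the squared standardized difference.
#'
#' @inheritParams std_coef_diff
#' @return List with `stat`, `df`, `p`.
#' @export
lack_of_fit <- function(fit_obs, fit_syn) {
  stopifnot(inherits(fit_obs, "synth_fit"), inherits(fit_syn, "synth_fit"))
  if (!identical(fit_obs$coef_names, fit_syn$coef_names))
    stop("fits have different coefficients", call. = FALSE)
  d <- fit_syn$beta - fit_obs$beta
  V <- fit_obs$vcov
  Vi <- tryCatch(solve(V), error = function(e)
    stop("observed-fit coefficient covariance is singular; simplify the model",
         call. = FALSE))
  stat <- drop(t(d) %*% Vi %*% d)
  df <- length(d)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Aligned counts for one variable: categorical -> declared levels; numeric ->
# equal-width bins over the pooled non-missing range. Missing cells are an
# explicit extra bar. Distances are total-variation over all bars, with
# proportions relative to the full row count, so distance 0 <=> identical
# relative tables and disjoint numeric supports give distance 1.
.marginal_counts <- function(obs, syn, n_bins) {
  if (is.factor(obs)) {
    lev <- levels(obs)
    co <- table(factor(obs, levels = lev), useNA = "no")
    cs <- table(factor(syn, levels = lev), useNA = "no")
    labels <- lev
  } else {
    pooled <- c(obs, syn)
    rng <- range(pooled, na.rm = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
    co <- table(cut(obs, breaks, include.lowest = TRUE), useNA = "no")
    cs <- table(cut(syn, breaks, include.lowest = TRUE), useNA = "no")
    labels <- names(co)
  }
  list(labels = labels,
       obs = c(as.vector(co), `<NA>` = sum(is.na(obs))),
       syn = c(as.vector(cs), `<NA>` = sum(is.na(syn))))
}

.tv_distance <- function(counts_a, counts_b) {
  pa <- counts_a / max(sum(counts_a), 1L)
  pb <- counts_b / max(sum(counts_b), 1L)
  0.5 * sum(abs(pa - pb))
}

#' Compare marginal distributions of observed and synthetic data
#'
#' For every variable, builds aligned frequency tables (categoricals over the
#' declared level set; numerics over shared equal-width bins spanning the
#' pooled range; missingness as an explicit extra bar) and reports the
#' total-variation distance between the two relative tables: 0 iff
#' identical, 1 for disjoint support.
#'
#' @param observed,synthetic Data frames with identical schemas.
#' @param n_bins Number of bins for numeric variables (default 20).
#' @return Object of class `marginal_comparison`: per-variable tables and a
#'   named `tv` vector of distances in \[0, 1\].
#' @export
compare_marginals <- function(observed, synthetic, n_bins = 20L) {
  observed <- .strip_label(observed); synthetic <- .strip_label(synthetic)
  if (!identical(unclass(schema_of(observed)), unclass(schema_of(synthetic))))
    stop("observed and synthetic tables have different schemas", call. = FALSE)
  per_var <- lapply(names(observed), function(v)
    .marginal_counts(observed[[v]], synthetic[[v]], n_bins))
  names(per_var) <- names(observed)
  tv <- vapply(per_var, function(m) .tv_distance(m$obs, m$syn), 0)
  structure(list(tables = per_var, tv = tv, n_bins = as.integer(n_bins),
                 n_obs = nrow(observed), n_syn = nrow(synthetic)),
            class = "marginal_comparison")
}

#' @export
print.marginal_comparison <- function(x, ...) {
  cat(sprintf("marginal comparison: %d observed vs %d synthetic rows\n",
              x$n_obs, x$n_syn))
  cat("total-variation distance per variable:\n")
  print(round(x$tv, 4L))
  invisible(x)
}

#' @export
#' @describeIn compare_marginals Side-by-side barplots, one panel per
#'   variable (observed next to synthetic counts).
#' @param x A `marginal_comparison`.
#' @param ... Passed to [graphics::barplot()].
plot.marginal_comparison <- function(x, ...) {
  vars <- names(x$tables)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(vars)),
                       mar = c(5, 3, 2, 1))
  on.exit(graphics::par(old))
  for (v in vars) {
    m <- x$tables[[v]]
    graphics::barplot(rbind(observed = m$obs, synthetic = m$syn),
                      beside = TRUE, main = sprintf("%s (TV %.3f)", v, x$tv[[v]]),
                      las = 2, cex.names = 0.7,
                      legend.text = v == vars[1L],
                      col = c("grey35", "steelblue"), ...)
  }
  invisible(x)
}

#' Compare a bivariate cross-tabulation
#'
#' Aligned two-way count tables of two variables (numerics are binned on
#' shared pooled-range breaks) for observed and synthetic data, with the
#' total-variation distance over cell proportions.
#'
#' @inheritParams compare_marginals
#' @param var1,var2 Column names to cross-tabulate.
#' @param n_bins Bins for numeric variables (default 10).
#' @return List with `observed`, `synthetic` (count matrices) and `tv`.
#' @export
compare_crosstab <- function(observed, synthetic, var1, var2, n_bins = 10L) {
  observed <- .strip_label(observed); synthetic <- .strip_label(synthetic)
  for (v in c(var1, var2))
    if (!v %in% names(observed) || !v %in% names(synthetic))
      stop("unknown column '", v, "'", call. = FALSE)
  cutv <- function(o, s) {
    if (is.factor(o)) {
      list(o = factor(o, levels = levels(o)), s = factor(s, levels = levels(o)))
    } else {
      rng <- range(c(o, s), na.rm = TRUE)
      if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
      br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
      list(o = cut(o, br, include.lowest = TRUE), s = cut(s, br, include.lowest = TRUE))
    }
  }
  a <- cutv(observed[[var1]], synthetic[[var1]])
  b <- cutv(observed[[var2]], synthetic[[var2]])
  to <- table(a$o, b$o, useNA = "ifany")
  ts <- table(a$s, b$s, useNA = "ifany")
  tv <- 0.5 * sum(abs(to / max(sum(to), 1L) - ts / max(sum(ts), 1L)))
  list(observed = to, synthetic = ts, tv = tv)
}

#' Specific utility of a synthetic dataset for one model
#'
#' Fits the same linear model to the observed and the synthetic data and
#' assembles the per-coefficient standardized differences ([std_coef_diff()]),
#' confidence interval overlaps ([ci_overlap()]) and the global lack-of-fit
#' chi-square ([lack_of_fit()]) into one report. A synthetic dataset that is
#' an exact copy of the observed one gives overlap 1, z = 0 and chi-square 0
#' for any model — the fixed point of the assessment.
#'
#' @inheritParams compare_marginals
#' @inheritParams fit_ols
#' @return Object of class `specific_utility`: `coefficients` data frame
#'   (estimates from both fits, z, p, ci_overlap), `lof` (stat, df, p) and
#'   the two fits.
#' @export
assess_specific <- function(observed, synthetic, response, predictors,
                            ci_level = 0.95) {
  fo <- fit_ols(observed, response, predictors, ci_level)
  fs <- fit_ols(synthetic, response, predictors, ci_level)
  sd_ <- std_coef_diff(fo, fs)
  ov <- mapply(ci_overlap, fo$ci_lower, fo$ci_upper, fs$ci_lower, fs$ci_upper)
  lof <- lack_of_fit(fo, fs)
  structure(list(
    coefficients = data.frame(coef = fo$coef_names,
                              beta_obs = unname(fo$beta),
                              beta_syn = unname(fs$beta),
                              z = sd_$z, p = sd_$p, ci_overlap = unname(ov),
                              row.names = NULL),
    lof = lof, fit_obs = fo, fit_syn = fs, ci_level = ci_level),
    class = "specific_utility")
}

#' @export
print.specific_utility <- function(x, digits = 4L, ...) {
  cat("specific utility report\n")
  print(cbind(x$coefficients[1L],
              round(x$coefficients[-1L], digits)), row.names = FALSE)
  cat(sprintf("lack-of-fit: X2(%d) = %.4g, p = %.4g\n",
              x$lof$df, x$lof$stat, x$lof$p))
  invisible(x)
}

#' Serialize a utility report to JSON
#'
#' Writes the marginal distances and/or specific-utility report in a flat
#' JSON structure consumed by the command-line interface.
#'
#' @param specific A `specific_utility` object, or `NULL`.
#' @param marginals A `marginal_comparison` object, or `NULL`.
#' @param path Output path (optional).
#' @return The JSON string, invisibly when written.
#' @export
write_utility_report <- function(specific = NULL, marginals = NULL, path = NULL) {
  obj <- list()
  if (!is.null(marginals))
    obj$marginal_tv <- as.list(marginals$tv)
  if (!is.null(specific))
    obj$specific <- list(coefficients = specific$coefficients,
                         lof = specific$lof)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
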