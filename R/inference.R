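.fit_result <- function(coef_names, beta, se, stat, df, p, ci_level, n_used,
                        vcov, kind) {
  q <- stats::qt(1 - (1 - ci_level) / 2, df)
  structure(list(coef_names = coef_names, beta = beta, se = se,
                 ci_lower = beta - q * se, ci_upper = beta + q * se,
                 stat = stat, df = df, p = p, ci_level = ci_level,
                 n_used = n_used, vcov = vcov, kind = kind),
            class = "synth_fit")
}

#' Fit an ordinary least squares model
#'
#' The workhorse model of the utility workflow: a linear model with
#' dummy-coded categorical predictors (reference level = first declared
#' factor level), classical standard errors, t-based confidence intervals
#' and two-sided p-values. Rows with any missing value among the model's
#' variables are dropped (listwise deletion). The two-group comparison and
#' the covariate-adjusted group comparison (ANCOVA) are special cases.
#'
#' @param data A data frame.
#' @param response Name of the numeric response column.
#' @param predictors Character vector of predictor column names.
#' @param ci_level Confidence level (default 0.95).
#' @return An object of class `synth_fit` with elements `coef_names`,
#'   `beta`, `se`, `ci_lower`, `ci_upper`, `stat` (t), `df` (residual),
#'   `p`, `n_used` and `vcov`.
#' @export
fit_ols <- function(data, response, predictors, ci_level = 0.95) {
  data <- .strip_label(data)
  stopifnot(response %in% names(data))
  miss <- setdiff(predictors, names(data))
  if (length(miss))
    stop("unknown predictor column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(data[[response]]))
    stop("response '", response, "' must be numeric", call. = FALSE)
  d <- data[c(response, predictors)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  f <- stats::as.formula(paste(response, "~",
                               if (length(predictors)) paste(predictors, collapse = " + ")
                               else "1"))
  fit <- stats::lm(f, data = d)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient model: collinear term(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         call. = FALSE)
  n_used <- nrow(d)
  if (n_used <= length(stats::coef(fit)))
    stop(sprintf("only %d complete rows for %d coefficients", n_used,
                 length(stats::coef(fit))), call. = FALSE)
  sm <- summary(fit)
  ct <- sm$coefficients
  .fit_result(coef_names = rownames(ct), beta = ct[, 1L], se = ct[, 2L],
              stat = ct[, 3L], df = fit$df.residual, p = ct[, 4L],
              ci_level = ci_level, n_used = n_used, vcov = stats::vcov(fit),
              kind = "ols")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance comparison of a numeric response between the two levels
#' of a binary grouping factor, reported in the common fit-result shape with
#' a single "difference" coefficient (first declared level minus second).
#'
#' @inheritParams fit_ols
#' @param group Name of a categorical column with exactly two observed levels.
#' @return A `synth_fit` with one coefficient, Welch--Satterthwaite df.
#' @export
welch_t <- function(data, response, group, ci_level = 0.95) {
  data <- .strip_label(data)
  stopifnot(response %in% names(data), group %in% names(data))
  g <- data[[group]]
  y <- data[[response]]
  keep <- !is.na(g) & !is.na(y)
  g <- droplevels(factor(g[keep])); y <- y[keep]
  if (nlevels(g) != 2L)
    stop("group '", group, "' must have exactly two observed levels, has ",
         nlevels(g), call. = FALSE)
  if (any(table(g) < 2L))
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  tt <- stats::t.test(y[g == levels(g)[1L]], y[g == levels(g)[2L]],
                      var.equal = FALSE, conf.level = ci_level)
  est <- unname(diff(rev(tt$estimate)))        # mean(level1) - mean(level2)
  se <- unname(tt$stderr)
  structure(list(coef_names = "difference", beta = est, se = se,
                 ci_lower = unname(tt$conf.int[1L]),
                 ci_upper = unname(tt$conf.int[2L]),
                 stat = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, ci_level = ci_level, n_used = length(y),
                 vcov = matrix(se^2, dimnames = list("difference", "difference")),
                 kind = "welch_t"),
            class = "synth_fit")
}

#' Pearson correlation with Fisher-transform confidence interval
#'
#' Product-moment correlation between two numeric columns (complete pairs
#' only), with the t-based p-value — by construction identical to the
#' p-value of the slope in the y-on-x least squares fit.
#'
#' @inheritParams fit_ols
#' @param x,y Names of the two numeric columns.
#' @return A `synth_fit` with one coefficient `r`; `ci_lower`/`ci_upper` are
#'   the Fisher-z interval bounds.
#' @export
pearson_r <- function(data, x, y, ci_level = 0.95) {
  data <- .strip_label(data)
  stopifnot(x %in% names(data), y %in% names(data))
  keep <- stats::complete.cases(data[c(x, y)])
  xv <- data[[x]][keep]; yv <- data[[y]][keep]
  n <- length(xv)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("zero variance in '", if (stats::sd(xv) == 0) x else y, "'", call. = FALSE)
  ct <- stats::cor.test(xv, yv, method = "pearson", conf.level = ci_level)
  r <- unname(ct$estimate)
  se <- sqrt((1 - r^2) / (n - 2L))
  structure(list(coef_names = "r", beta = r, se = se,
                 ci_lower = unname(ct$conf.int[1L]),
                 ci_upper = unname(ct$conf.int[2L]),
                 stat = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, ci_level = ci_level, n_used = n,
                 vcov = matrix(se^2, dimnames = list("r", "r")),
                 kind = "pearson"),
            class = "synth_fit")
}

#' @export
print.synth_fit <- function(x, digits = 4L, ...) {
  cat(sprintf("%s fit (n = %d, df = %.4g)\n", x$kind, x$n_used, x$df))
  tab <- data.frame(estimate = x$beta, se = x$se,
                    ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                    stat = x$stat, p = x$p, row.names = x$coef_names)
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.synth_fit <- function(object, ...) {
  stats::setNames(object$beta, object$coef_names)
}

#' @export
vcov.synth_fit <- function(object, ...) object$vcov

#' @export
confint.synth_fit <- function(object, ...) {
  m <- cbind(object$ci_lower, object$ci_upper)
  dimnames(m) <- list(object$coef_names,
                      paste0(100 * c((1 - object$ci_level) / 2,
                                     1 - (1 - object$ci_level) / 2), " %"))
  m
}

#' Serialize a fit result to JSON
#'
#' @param fit A `synth_fit`.
#' @param path Output path (optional; when `NULL` the JSON string is returned).
#' @return The JSON string, invisibly when written to a file.
#' @export
write_fit <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "synth_fit"))
  obj <- list(kind = fit$kind, ci_level = fit$ci_level, n_used = fit$n_used,
              df = fit$df,
              coefficients = data.frame(
                name = fit$coef_names, estimate = unname(fit$beta),
                se = unname(fit$se), ci_lower = unname(fit$ci_lower),
                ci_upper = unname(fit$ci_upper), stat = unname(fit$stat),
                p = unname(fit$p)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
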