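# Solve the log-normal shape parameter sigma whose skewness equals gamma:
# skew = (w + 2) * sqrt(w - 1), w = exp(sigma^2).
.lnorm_sigma_for_skew <- function(gamma) {
  f <- function(s) {
    w <- exp(s^2)
    (w + 2) * sqrt(w - 1) - gamma
  }
  stats::uniroot(f, c(1e-6, 2))$root
}

#' Parameters of the physiological simulator
#'
#' Defaults are physiologically plausible resting values for an adult
#' sample: heart rate ~ N(70, 10) bpm, weight ~ N(75, 15) kg, fitness
#' (e.g. VO2max-like score) ~ N(40, 8), HRV (RMSSD-like) ~ mean 42 sd 15 ms.
#' The only non-zero dependence is the medium-sized HRV--fitness correlation
#' (`target_r = 0.3`). Skew severities are the target sample skewness of the
#' HRV margin after its rank-preserving log-normal transform; the outlier
#' rule replaces `max(1, round(outlier_rate * n))` HRV values with draws 4-6
#' sd above the mean.
#'
#' @param target_r Correlation between HRV and fitness (default 0.3).
#' @param means,sds Named numeric vectors over `heart_rate`, `weight`,
#'   `fitness`, `hrv`.
#' @param skew_severity Target skewness for `"low"` and `"high"` (defaults
#'   1 and 3; `"none"` keeps the normal margin).
#' @param outlier_rate Fraction of rows replaced by outliers (default 0.01;
#'   at least one row is always replaced).
#' @param outlier_sd_range Outliers are drawn uniformly this many sd above
#'   the HRV mean (default c(4, 6)).
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(target_r = 0.3,
                       means = c(heart_rate = 70, weight = 75, fitness = 40, hrv = 42),
                       sds = c(heart_rate = 10, weight = 15, fitness = 8, hrv = 15),
                       skew_severity = c(low = 1, high = 3),
                       outlier_rate = 0.01,
                       outlier_sd_range = c(4, 6)) {
  vars <- c("heart_rate", "weight", "fitness", "hrv")
  stopifnot(all(vars %in% names(means)), all(vars %in% names(sds)),
            all(sds[vars] > 0), abs(target_r) < 1,
            all(c("low", "high") %in% names(skew_severity)),
            outlier_rate >= 0, length(outlier_sd_range) == 2L)
  structure(list(target_r = target_r, means = means[vars], sds = sds[vars],
                 skew_severity = skew_severity, outlier_rate = outlier_rate,
                 outlier_sd_range = outlier_sd_range),
            class = "sim_params")
}

#' One cell of the simulation grid
#'
#' @param n Sample size (the study design uses 40, 100, 10000).
#' @param skew HRV distribution shape: `"none"`, `"low"` or `"high"`.
#' @param miss_rate Missingness rate applied completely at random to all
#'   four variables (the design uses 0, 0.05, 0.20).
#' @param seed Integer seed for this cell.
#' @return Object of class `sim_cell`.
#' @export
sim_cell <- function(n, skew = c("none", "low", "high"), miss_rate = 0, seed) {
  skew <- match.arg(skew)
  stopifnot(n >= 2L, miss_rate >= 0, miss_rate < 1)
  structure(list(n = as.integer(n), skew = skew, miss_rate = miss_rate,
                 seed = as.integer(seed)),
            class = "sim_cell")
}

#' The full 3 x 3 x 3 simulation grid
#'
#' Crosses sample size (40, 100, 10000), HRV skew (none, low, high) and
#' missingness (0%, 5%, 20%) into 27 cells with per-cell seeds derived from
#' a root seed.
#'
#' @param seed Root seed.
#' @param n_values,skews,miss_rates Factor levels of the grid; defaults are
#'   the study design.
#' @return List of `sim_cell` objects.
#' @export
default_grid <- function(seed, n_values = c(40L, 100L, 10000L),
                         skews = c("none", "low", "high"),
                         miss_rates = c(0, 0.05, 0.20)) {
  cells <- list()
  i <- 0L
  for (n in n_values) for (sk in skews) for (mr in miss_rates) {
    i <- i + 1L
    cells[[i]] <- sim_cell(n, sk, mr, seed = (seed + 31L * i) %% 2147483647L)
  }
  cells
}

#' Simulate one physiological dataset
#'
#' Draws a latent jointly normal sample of (heart rate, weight, fitness,
#' HRV) with corr(HRV, fitness) = `target_r` and all other correlations 0,
#' then (i) maps the HRV margin rank-preservingly onto a moment-matched
#' log-normal at the cell's skew severity, (ii) injects outliers into HRV,
#' and (iii) masks each of the four columns completely at random at the
#' cell's missingness rate. The pre-transform latent draw is kept as the
#' `"latent"` attribute for diagnostics (e.g. checking the realised
#' correlation without outlier contamination).
#'
#' @param cell A [sim_cell()].
#' @param params A [sim_params()].
#' @return Data frame with numeric columns `heart_rate`, `weight`,
#'   `fitness`, `hrv`.
#' @export
simulate_hrv_dataset <- function(cell, params = sim_params()) {
  stopifnot(inherits(cell, "sim_cell"), inherits(params, "sim_params"))
  set.seed(cell$seed)
  vars <- names(params$means)
  R <- diag(4)
  dimnames(R) <- list(vars, vars)
  R["hrv", "fitness"] <- R["fitness", "hrv"] <- params$target_r
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("correlation matrix is not positive definite", call. = FALSE)
  S <- diag(params$sds) %*% R %*% diag(params$sds)
  lat <- MASS::mvrnorm(cell$n, mu = params$means, Sigma = S)
  colnames(lat) <- vars
  out <- as.data.frame(lat)

  if (cell$skew != "none") {
    gamma <- params$skew_severity[[cell$skew]]
    sig <- .lnorm_sigma_for_skew(gamma)
    z <- (out$hrv - params$means[["hrv"]]) / params$sds[["hrv"]]
    ln <- stats::qlnorm(stats::pnorm(z), meanlog = 0, sdlog = sig)
    m_ln <- exp(sig^2 / 2)
    s_ln <- sqrt((exp(sig^2) - 1) * exp(sig^2))
    out$hrv <- params$means[["hrv"]] +
      params$sds[["hrv"]] * (ln - m_ln) / s_ln
  }

  k <- max(1L, round(params$outlier_rate * cell$n))
  idx <- sample.int(cell$n, k)
  out$hrv[idx] <- params$means[["hrv"]] +
    stats::runif(k, params$outlier_sd_range[1L], params$outlier_sd_range[2L]) *
    params$sds[["hrv"]]

  if (cell$miss_rate > 0)
    for (v in vars)
      out[[v]][stats::runif(cell$n) < cell$miss_rate] <- NA_real_

  attr(out, "latent") <- lat
  out
}

#' Run the simulation grid end-to-end
#'
#' For every cell: simulate the dataset, synthesise it by sequential CART,
#' fit the fitness-on-HRV linear model to both versions and score specific
#' utility. The aggregate counts how many cells pass the lack-of-fit test
#' (p > 0.05), i.e. show no detectable displacement of the model
#' coefficients by synthesis.
#'
#' @param cells List of [sim_cell()] objects (e.g. [default_grid()]).
#' @param params A [sim_params()].
#' @param cart_control A [cart_params()] passed to [synthesize()].
#' @param response,predictors Model scored in each cell (default
#'   `fitness ~ hrv`).
#' @param proper Passed to [synthesize()].
#' @return Object of class `grid_report`: a `cells` data frame (one row per
#'   cell: design factors, HRV-coefficient z and CI overlap, lack-of-fit
#'   stat/df/p), the per-cell `reports`, and `n_lof_pass`.
#' @export
run_grid <- function(cells, params = sim_params(), cart_control = cart_params(),
                     response = "fitness", predictors = "hrv", proper = FALSE) {
  stopifnot(length(cells) >= 1L)
  reports <- vector("list", length(cells))
  rows <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    stopifnot(inherits(cell, "sim_cell"))
    dat <- simulate_hrv_dataset(cell, params)
    syn <- synthesize(dat, seed = cell$seed + 1L, cart_control = cart_control,
                      proper = proper)
    rep_i <- assess_specific(dat, syn$datasets[[1L]], response, predictors)
    reports[[i]] <- rep_i
    co <- rep_i$coefficients
    key <- if (predictors[1L] %in% co$coef) predictors[1L] else co$coef[nrow(co)]
    krow <- co[co$coef == key, ]
    rows[[i]] <- data.frame(n = cell$n, skew = cell$skew,
                            miss_rate = cell$miss_rate, seed = cell$seed,
                            z = krow$z, z_p = krow$p, ci_overlap = krow$ci_overlap,
                            lof_stat = rep_i$lof$stat, lof_df = rep_i$lof$df,
                            lof_p = rep_i$lof$p)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(cells = tab, reports = reports,
                 n_lof_pass = sum(tab$lof_p > 0.05)),
            class = "grid_report")
}

#' @export
print.grid_report <- function(x, digits = 4L, ...) {
  cat(sprintf("simulation grid: %d cell(s); lack-of-fit p > 0.05 in %d\n",
              nrow(x$cells), x$n_lof_pass))
  tab <- x$cells
  tab[c("z", "z_p", "ci_overlap", "lof_stat", "lof_p")] <-
    round(tab[c("z", "z_p", "ci_overlap", "lof_stat", "lof_p")], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
#' @describeIn run_grid Forest-style plot: per cell, the observed and
#'   synthetic estimates of the scored coefficient with their confidence
#'   intervals, side by side.
#' @param x A `grid_report`.
#' @param coef_name Coefficient to display (default: last non-intercept).
#' @param ... Unused.
plot.grid_report <- function(x, coef_name = NULL, ...) {
  k <- length(x$reports)
  est <- matrix(NA_real_, k, 6L)
  for (i in seq_len(k)) {
    fo <- x$reports[[i]]$fit_obs; fs <- x$reports[[i]]$fit_syn
    j <- if (is.null(coef_name)) length(fo$coef_names)
         else match(coef_name, fo$coef_names)
    est[i, ] <- c(fo$beta[j], fo$ci_lower[j], fo$ci_upper[j],
                  fs$beta[j], fs$ci_lower[j], fs$ci_upper[j])
  }
  ylim <- c(0.5, k + 0.5)
  xlim <- range(est, na.rm = TRUE)
  graphics::plot(NA, xlim = xlim, ylim = ylim, yaxt = "n",
                 xlab = "coefficient estimate", ylab = "",
                 main = "observed (grey) vs synthetic (blue) estimates")
  lab <- sprintf("n=%d %s %.0f%%", x$cells$n, x$cells$skew, 100 * x$cells$miss_rate)
  graphics::axis(2, at = seq_len(k), labels = lab, las = 1, cex.axis = 0.7)
  for (i in seq_len(k)) {
    graphics::segments(est[i, 2L], i + 0.15, est[i, 3L], i + 0.15, col = "grey35")
    graphics::points(est[i, 1L], i + 0.15, pch = 16, col = "grey35")
    graphics::segments(est[i, 5L], i - 0.15, est[i, 6L], i - 0.15, col = "steelblue")
    graphics::points(est[i, 4L], i - 0.15, pch = 17, col = "steelblue")
  }
  invisible(x)
}
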