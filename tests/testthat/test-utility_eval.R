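test_that("ci_overlap analytic identities", {
  expect_equal(ci_overlap(0, 1, 0, 1), 1)                 # identical -> 1
  expect_equal(ci_overlap(0, 2, 1, 3), 0.5)               # half-shifted -> 0.5
  expect_equal(ci_overlap(0, 1, 2, 3), -1)                # disjoint -> negative
  # symmetry in the two intervals; never exceeds 1
  set.seed(6)
  for (i in 1:50) {
    a <- sort(rnorm(2)); b <- sort(rnorm(2))
    o1 <- ci_overlap(a[1], a[2], b[1], b[2])
    o2 <- ci_overlap(b[1], b[2], a[1], a[2])
    expect_equal(o1, o2, tolerance = 1e-12)
    expect_lte(o1, 1)
    if (o1 == 1) expect_equal(a, b)
  }
  expect_error(ci_overlap(1, 1, 0, 2), "positive length")
})

test_that("std_coef_diff: scale, tails, and antisymmetry", {
  mkfit <- function(beta, se) {
    structure(list(coef_names = paste0("b", seq_along(beta)), beta = beta,
                   se = se, ci_lower = beta - 2 * se, ci_upper = beta + 2 * se,
                   stat = beta / se, df = 50, p = rep(0.5, length(beta)),
                   ci_level = 0.95, n_used = 52, vcov = diag(se^2, length(beta)),
                   kind = "ols"), class = "synth_fit")
  }
  f <- mkfit(1, 0.5)
  expect_equal(std_coef_diff(f, f)$z, 0)
  expect_equal(std_coef_diff(f, f)$p, 1)
  g <- mkfit(1.98, 0.5)
  sd_ <- std_coef_diff(f, g)
  expect_equal(sd_$z, 1.96)
  expect_equal(sd_$p, 2 * pnorm(-1.96), tolerance = 1e-12)
  expect_lt(abs(sd_$p - 0.05), 1e-3)
  # swapping fits negates z but only when the two ses agree (they do here)
  back <- std_coef_diff(g, f)
  expect_equal(back$z, -sd_$z)
  expect_equal(back$p, sd_$p)
  expect_error(std_coef_diff(f, mkfit(c(1, 2), c(1, 1))), "different coefficients")
})

test_that("lack_of_fit: identities and closed-form chi-square cases", {
  mkfit <- function(beta, V) {
    structure(list(coef_names = paste0("b", seq_along(beta)), beta = beta,
                   se = sqrt(diag(as.matrix(V))), ci_lower = beta - 1,
                   ci_upper = beta + 1, stat = beta, df = 50,
                   p = rep(0.5, length(beta)), ci_level = 0.95, n_used = 52,
                   vcov = as.matrix(V), kind = "ols"), class = "synth_fit")
  }
  f <- mkfit(c(1, 2), diag(2))
  expect_equal(lack_of_fit(f, f), list(stat = 0, df = 2L, p = 1))
  # one coefficient: chi2 = z^2, p = chi-square(1) upper tail of z^2
  fo <- mkfit(0.3, 0.04)        # se = 0.2
  fs <- mkfit(0.7, 0.09)
  z <- std_coef_diff(fo, fs)$z
  lof <- lack_of_fit(fo, fs)
  expect_equal(lof$stat, z^2, tolerance = 1e-12)
  expect_equal(lof$p, pchisq(z^2, 1, lower.tail = FALSE), tolerance = 1e-12)
  # two coefficients, identity covariance, differences (1, -1): chi2 = 2,
  # p = exp(-1)
  g <- mkfit(c(2, 1), diag(2))
  lof2 <- lack_of_fit(f, g)
  expect_equal(lof2$stat, 2)
  expect_equal(lof2$p, exp(-1), tolerance = 1e-12)
  # singular covariance is refused
  sing <- mkfit(c(1, 2), matrix(1, 2, 2))
  expect_error(lack_of_fit(sing, sing), "singular")
})

test_that("compare_marginals: identity, hand-computed TV, disjoint support", {
  d <- data.frame(g = factor(c("a", "a", "a", "b"), levels = c("a", "b")),
                  x = c(1, 2, 3, 4))
  expect_equal(unname(compare_marginals(d, d)$tv), c(0, 0))
  s <- data.frame(g = factor(c("a", "b", "b", "b"), levels = c("a", "b")),
                  x = c(1, 2, 3, 4))
  # (3/4, 1/4) vs (1/4, 3/4): TV = 0.5
  expect_equal(unname(compare_marginals(d, s)$tv[["g"]]), 0.5)
  # disjoint numeric supports -> distance 1
  o2 <- data.frame(x = c(1, 2, 3))
  s2 <- data.frame(x = c(100, 101, 102))
  expect_equal(unname(compare_marginals(o2, s2)$tv[["x"]]), 1)
  expect_error(compare_marginals(d, d[1L]), "different schemas")
})

test_that("compare_marginals counts missing cells as their own bar", {
  o <- data.frame(x = c(1, 2, NA, NA))
  s <- data.frame(x = c(1, 2, 3, 4))
  m <- compare_marginals(o, s)
  expect_equal(unname(m$tables$x$obs[["<NA>"]]), 2L)
  expect_equal(sum(m$tables$x$obs) , 4L)
  expect_gt(m$tv[["x"]], 0)
})

test_that("marginal TV distance behaves as a metric on random tables", {
  set.seed(23)
  lv <- c("a", "b", "c")
  mk <- function() data.frame(g = factor(sample(lv, 30, TRUE), levels = lv))
  for (i in 1:20) {
    t1 <- mk(); t2 <- mk(); t3 <- mk()
    d12 <- compare_marginals(t1, t2)$tv[["g"]]
    d21 <- compare_marginals(t2, t1)$tv[["g"]]
    d13 <- compare_marginals(t1, t3)$tv[["g"]]
    d23 <- compare_marginals(t2, t3)$tv[["g"]]
    expect_equal(d12, d21, tolerance = 1e-12)              # symmetry
    expect_equal(compare_marginals(t1, t1)$tv[["g"]], 0)   # identity
    expect_lte(d13, d12 + d23 + 1e-12)                     # triangle
  }
})

test_that("compare_crosstab: identity, engineered 2x2, independence at large n", {
  o <- data.frame(a = factor(rep(c("x", "y"), each = 10)),
                  b = factor(rep(c("u", "v"), times = 10)))
  expect_equal(compare_crosstab(o, o, "a", "b")$tv, 0)
  # observed uniform 2x2 (5,5,5,5) vs synthetic diagonal (10,0,0,10)
  obs <- data.frame(a = factor(rep(c("x", "x", "y", "y"), each = 5)),
                    b = factor(rep(c("u", "v", "u", "v"), each = 5)))
  syn <- data.frame(a = factor(rep(c("x", "y"), each = 10)),
                    b = factor(rep(c("u", "v"), each = 10)))
  expect_equal(compare_crosstab(obs, syn, "a", "b")$tv, 0.5)
  # both tables product-form -> distance small for large n
  set.seed(11)
  big <- function() data.frame(
    a = factor(sample(c("x", "y"), 4000, TRUE, prob = c(0.6, 0.4))),
    b = factor(sample(c("u", "v"), 4000, TRUE, prob = c(0.3, 0.7))))
  expect_lt(compare_crosstab(big(), big(), "a", "b")$tv, 0.05)
  expect_error(compare_crosstab(o, o, "a", "zz"), "unknown column")
})

test_that("assess_specific composes the individual metrics and has the copy fixed point", {
  set.seed(3)
  d <- data.frame(y = rnorm(40), x = rnorm(40),
                  g = factor(sample(c("a", "b"), 40, TRUE)))
  rep_ <- assess_specific(d, d, "y", c("x", "g"))
  expect_equal(rep_$coefficients$z, rep(0, 3))
  expect_equal(rep_$coefficients$ci_overlap, rep(1, 3))
  expect_equal(rep_$lof$stat, 0)
  expect_equal(rep_$lof$p, 1)
  # composition contract against the individual operations
  s <- d; s$y <- s$y + 0.1 * s$x
  r2 <- assess_specific(d, s, "y", c("x", "g"))
  fo <- fit_ols(d, "y", c("x", "g")); fs <- fit_ols(s, "y", c("x", "g"))
  expect_equal(r2$coefficients$z, std_coef_diff(fo, fs)$z)
  expect_equal(r2$lof, lack_of_fit(fo, fs))
  expect_equal(r2$coefficients$ci_overlap,
               unname(mapply(ci_overlap, fo$ci_lower, fo$ci_upper,
                             fs$ci_lower, fs$ci_upper)))
  expect_identical(r2$lof$df, nrow(r2$coefficients))
})

test_that("utility reports serialize to parseable JSON", {
  set.seed(3)
  d <- data.frame(y = rnorm(30), x = rnorm(30))
  rep_ <- assess_specific(d, d, "y", "x")
  mar <- compare_marginals(d, d)
  p <- tempfile(fileext = ".json")
  write_utility_report(rep_, mar, p)
  parsed <- jsonlite::fromJSON(p)
  expect_equal(parsed$marginal_tv$x, 0)
  expect_equal(parsed$specific$lof$stat, 0)
})
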