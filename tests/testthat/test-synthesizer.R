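test_that("the first visited variable is a marginal bootstrap", {
  d <- data.frame(v = factor(c("a", "a", "b", "c"), levels = c("a", "b", "c")))
  s <- synthesize(d, seed = 9)
  syn <- s$datasets[[1L]]
  expect_identical(names(syn), "v")
  expect_true(all(as.character(syn$v) %in% c("a", "b", "c")))
  expect_identical(s$log[[1L]]$method, "marginal bootstrap")
})

test_that("an exact functional dependence survives synthesis", {
  # binary X with 10 rows per level, Y = f(X): the single CART split is
  # forced, leaves are pure, donor sampling preserves the mapping row-wise
  d <- data.frame(x = factor(rep(c("a", "b"), each = 10)),
                  y = rep(c(1, 5), each = 10))
  s <- synthesize(d, seed = 4, cart_control = cart_params(min_leaf = 5L))
  syn <- s$datasets[[1L]]
  expect_true(all(syn$y[syn$x == "a"] == 1))
  expect_true(all(syn$y[syn$x == "b"] == 5))
})

test_that("synthesis is deterministic given (data, plan) and localised per variable", {
  set.seed(31)
  d <- data.frame(a = rnorm(50), g = factor(sample(c("x", "y"), 50, TRUE)),
                  b = rnorm(50))
  s1 <- synthesize(d, seed = 123)
  s2 <- synthesize(d, seed = 123)
  expect_identical(s1$datasets, s2$datasets)
  # substream protocol: truncating the visit sequence leaves earlier columns
  # bit-identical
  s3 <- synthesize(d, visit = c("a", "g"), seed = 123)
  expect_identical(s3$datasets[[1L]]$a, s1$datasets[[1L]]$a)
  expect_identical(s3$datasets[[1L]]$g, s1$datasets[[1L]]$g)
  # a different seed changes the draw
  expect_false(identical(synthesize(d, seed = 124)$datasets, s1$datasets))
})

test_that("donor property: every synthetic value occurs in the original column", {
  set.seed(8)
  d <- data.frame(num = rnorm(80),
                  cat = factor(sample(c("p", "q", "r"), 80, TRUE)),
                  num2 = runif(80))
  d$num2[sample(80, 16)] <- NA
  d$cat[sample(80, 8)] <- NA
  for (sd_ in 1:3) {
    syn <- synthesize(d, seed = sd_, n_out = 120)$datasets[[1L]]
    for (v in names(d)) {
      sv <- syn[[v]]; ov <- d[[v]]
      expect_true(all(sv[!is.na(sv)] %in% ov[!is.na(ov)]),
                  label = sprintf("column %s, seed %d", v, sd_))
      if (anyNA(ov)) expect_true(TRUE) else expect_false(anyNA(sv))
    }
  }
})

test_that("schema is preserved, including levels with zero observed count", {
  d <- data.frame(g = factor(c(rep("a", 6), rep("b", 6)), levels = c("a", "b", "ghost")),
                  y = rnorm(12))
  syn <- synthesize(d, seed = 2)$datasets[[1L]]
  expect_identical(levels(syn$g), c("a", "b", "ghost"))
  expect_identical(unclass(schema_of(syn)), unclass(schema_of(d)))
})

test_that("marginal frequencies are preserved within binomial error at n = 5000", {
  set.seed(99)
  probs <- c(a = 0.5, b = 0.3, c = 0.2)
  d <- data.frame(g = factor(sample(names(probs), 5000, TRUE, prob = probs),
                             levels = names(probs)),
                  y = rnorm(5000))
  syn <- synthesize(d, seed = 7)$datasets[[1L]]
  p_obs <- table(d$g) / 5000
  p_syn <- table(syn$g) / 5000
  for (lv in names(probs)) {
    se <- sqrt(p_obs[[lv]] * (1 - p_obs[[lv]]) / 5000)
    expect_lt(abs(p_syn[[lv]] - p_obs[[lv]]), 3 * se)
  }
})

test_that("two-part numeric missingness synthesis reproduces the missing rate", {
  set.seed(12)
  n <- 2000L
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$z[runif(n) < 0.2] <- NA
  syn <- synthesize(d, seed = 5)$datasets[[1L]]
  # binomial bound: +/- 3 pp at n = 2000
  expect_lt(abs(mean(is.na(syn$z)) - mean(is.na(d$z))), 0.03)
  expect_true(all(syn$z[!is.na(syn$z)] %in% d$z[!is.na(d$z)]))
})

test_that("all-missing columns pass through with a warning", {
  d <- data.frame(x = rnorm(30), z = rep(NA_real_, 30))
  expect_warning(s <- synthesize(d, seed = 1), "entirely missing")
  expect_true(all(is.na(s$datasets[[1L]]$z)))
})

test_that("proper synthesis and m > 1 produce valid, distinct datasets", {
  set.seed(55)
  d <- data.frame(a = rnorm(60), b = rnorm(60))
  s <- synthesize(d, seed = 42, proper = TRUE, m = 3L)
  expect_length(s$datasets, 3L)
  expect_false(identical(s$datasets[[1L]], s$datasets[[2L]]))
  for (k in 1:3)
    expect_true(all(s$datasets[[k]]$b %in% d$b))
})

test_that("invalid plans are refused", {
  d <- data.frame(x = 1:10)
  expect_error(synthesize(d, seed = 1, n_out = 0), "n_out")
  expect_error(synthesize(d, visit = c("x", "x"), seed = 1), "repeats")
  expect_error(synthesize(d, visit = "nope", seed = 1), "unknown column")
  expect_error(synthesize(d[0L, , drop = FALSE], seed = 1), "zero rows")
  expect_error(synthesize(d), "seed")
})

test_that("relationship preservation: synthetic slope falls in the original CI", {
  # linear dependence with r ~ 0.3; across seeded replicates the
  # synthetic-data slope should usually stay inside the original fit's 95% CI
  hits <- 0L
  n_rep <- 50L
  for (i in seq_len(n_rep)) {
    dat <- simulate_hrv_dataset(sim_cell(500L, "none", 0, seed = 3000L + i))
    fo <- fit_ols(dat, "fitness", "hrv")
    syn <- synthesize(dat, seed = 4000L + i)$datasets[[1L]]
    fs <- fit_ols(syn, "fitness", "hrv")
    b <- fs$beta[["hrv"]]
    if (b >= fo$ci_lower[["hrv"]] && b <= fo$ci_upper[["hrv"]]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})
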