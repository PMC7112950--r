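# Independent oracles and fixture generators. These deliberately use naive
# direct computation (subset-and-sum, explicit enumeration, hand-built design
# matrices) rather than any code path from the package.

NA_SENTINEL <- ".__NA__"

# -- impurities (direct definitions) -----------------------------------------

sse_of <- function(y) if (length(y) == 0L) 0 else sum((y - mean(y))^2)

gini_count_of <- function(cls) {
  n <- length(cls)
  if (n == 0L) return(0)
  n - sum(table(cls)^2) / n
}

node_impurity_of <- function(y) {
  if (is.numeric(y)) sse_of(y) else gini_count_of(as.character(y))
}

# -- exhaustive first-split search --------------------------------------------
# Enumerates every admissible split of every predictor: all midpoint
# thresholds with both missing-branch assignments for numeric predictors, all
# proper level subsets (missing as its own category) for categorical ones.
# Returns the minimal total child impurity, or NULL when no admissible split.

oracle_best_split <- function(data, target, predictors, min_leaf) {
  y <- data[[target]]
  imp <- function(rows) node_impurity_of(y[rows])
  best <- Inf
  for (p in predictors) {
    x <- data[[p]]
    if (is.numeric(x)) {
      xs <- sort(unique(x[!is.na(x)]))
      if (length(xs) < 2L) next
      thr <- (xs[-length(xs)] + xs[-1L]) / 2
      for (t in thr) for (na_left in c(TRUE, FALSE)) {
        left <- which(ifelse(is.na(x), na_left, x <= t))
        right <- setdiff(seq_along(x), left)
        if (length(left) < min_leaf || length(right) < min_leaf) next
        best <- min(best, imp(left) + imp(right))
      }
    } else {
      v <- as.character(x)
      v[is.na(v)] <- NA_SENTINEL
      lev <- unique(v)
      L <- length(lev)
      if (L < 2L) next
      for (mask in 1:(2L^L - 2L)) {
        members <- lev[bitwAnd(mask, bitwShiftL(1L, seq_len(L) - 1L)) > 0L]
        left <- which(v %in% members)
        right <- setdiff(seq_along(v), left)
        if (length(left) < min_leaf || length(right) < min_leaf) next
        best <- min(best, imp(left) + imp(right))
      }
    }
  }
  if (is.finite(best)) best else NULL
}

# Total child impurity actually achieved by the root split of a fitted tree,
# recomputed directly from the recorded rule.
achieved_split_impurity <- function(tree, data, target) {
  nd <- tree$nodes[[1L]]
  if (nd$type != "split") return(NULL)
  x <- data[[nd$var]]
  go_left <- if (nd$kind == "numeric_threshold") {
    ifelse(is.na(x), nd$na_left, x <= nd$threshold)
  } else {
    v <- as.character(x)
    v[is.na(v)] <- NA_SENTINEL
    v %in% nd$left_levels
  }
  y <- data[[target]]
  node_impurity_of(y[go_left]) + node_impurity_of(y[!go_left])
}

# -- random mixed-type fixtures ----------------------------------------------

random_fixture <- function(n_rows, n_pred, p_missing = 0.15) {
  cols <- list()
  for (j in seq_len(n_pred)) {
    if (runif(1) < 0.5) {
      v <- round(runif(n_rows, 0, 10), 1)
    } else {
      lev <- letters[seq_len(sample(2:4, 1L))]
      v <- factor(sample(lev, n_rows, replace = TRUE), levels = lev)
    }
    if (runif(1) < 0.5) v[runif(n_rows) < p_missing] <- NA
    cols[[paste0("p", j)]] <- v
  }
  if (runif(1) < 0.5) {
    cols$y <- round(rnorm(n_rows), 2)
  } else {
    cols$y <- factor(sample(c("u", "v"), n_rows, replace = TRUE), levels = c("u", "v"))
  }
  as.data.frame(cols)
}

# -- normal-equations least squares oracle ------------------------------------
# Hand-built dummy-coded design matrix (reference = first declared level),
# beta and classical covariance from the explicit normal equations.

ols_oracle <- function(data, response, predictors) {
  d <- data[c(response, predictors)]
  d <- d[complete.cases(d), , drop = FALSE]
  y <- d[[response]]
  X <- matrix(1, nrow(d), 1L)
  for (p in predictors) {
    v <- d[[p]]
    if (is.numeric(v)) X <- cbind(X, v)
    else for (lv in levels(v)[-1L]) X <- cbind(X, as.numeric(v == lv))
  }
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(beta = drop(beta), vcov = s2 * solve(XtX),
       se = sqrt(diag(s2 * solve(XtX))), df = nrow(X) - ncol(X))
}

sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

# small helper table used across core-table tests
mixed_table <- function() {
  data.frame(age = c(31.5, NA, 44, 20.25),
             score = c(-1.2, 0.4, 3.75, NA),
             group = factor(c("a", "b", NA, "a"), levels = c("a", "b", "c")))
}
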