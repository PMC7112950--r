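# Missing categorical predictor values are their own category during fitting
# and routing; this sentinel is appended to the level set internally.
.NA_LEVEL <- ".__NA__"

#' Tree growth controls
#'
#' @param min_leaf Minimum rows in any leaf (default 5).
#' @param min_split Minimum rows in a node for it to be considered for
#'   splitting (default 10).
#' @param max_depth Maximum tree depth, root at depth 0 (default 30).
#' @param min_impurity_decrease Minimum impurity reduction for a split to be
#'   kept, as a fraction of the root node's impurity (default 1e-8).
#' @return An object of class `cart_params`.
#' @export
cart_params <- function(min_leaf = 5L, min_split = 10L, max_depth = 30L,
                        min_impurity_decrease = 1e-8) {
  stopifnot(min_leaf >= 1L, min_split >= min_leaf, max_depth >= 0L,
            min_impurity_decrease >= 0)
  structure(list(min_leaf = as.integer(min_leaf),
                 min_split = as.integer(min_split),
                 max_depth = as.integer(max_depth),
                 min_impurity_decrease = min_impurity_decrease),
            class = "cart_params")
}

# --- split search -----------------------------------------------------------
# All searches return list(imp_children, ...) or NULL when no admissible
# split exists. Ties are broken deterministically: predictors in the order
# given, numeric thresholds ascending, level subsets in enumeration order,
# missing-value branch assignment preferring left.

.split_num <- function(x, y, cls_mat, min_leaf) {
  miss <- is.na(x)
  xo <- x[!miss]
  nc <- length(xo)
  if (nc < 2L) return(NULL)
  o <- order(xo, method = "radix")
  xs <- xo[o]
  cand <- which(xs[-nc] < xs[-1L])
  if (!length(cand)) return(NULL)
  nm <- sum(miss)
  nl <- cand; nr <- nc - cand

  if (is.null(cls_mat)) {                       # regression: within-node SSE
    yo <- y[!miss][o]
    cs <- cumsum(yo); css <- cumsum(yo * yo)
    sm <- sum(y[miss]); ssm <- sum(y[miss]^2)
    sl <- cs[cand]; ssl <- css[cand]
    sr <- cs[nc] - sl; ssr <- css[nc] - ssl
    tot_l <- (ssl + ssm) - (sl + sm)^2 / (nl + nm) + (ssr - sr^2 / nr)
    tot_r <- (ssl - sl^2 / nl) + (ssr + ssm) - (sr + sm)^2 / (nr + nm)
  } else {                                      # classification: count-scaled Gini
    M <- cls_mat[!miss, , drop = FALSE][o, , drop = FALSE]
    M <- apply(M, 2L, cumsum)
    if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
    cm <- colSums(cls_mat[miss, , drop = FALSE])
    Ml <- M[cand, , drop = FALSE]
    Mr <- rep(M[nc, ], each = length(cand)) - Ml
    Mlm <- Ml + rep(cm, each = length(cand))
    Mrm <- Mr + rep(cm, each = length(cand))
    gini <- function(cnt, n) n - rowSums(cnt * cnt) / n
    tot_l <- gini(Mlm, nl + nm) + gini(Mr, nr)
    tot_r <- gini(Ml, nl) + gini(Mrm, nr + nm)
  }
  ok_l <- (nl + nm) >= min_leaf & nr >= min_leaf
  ok_r <- nl >= min_leaf & (nr + nm) >= min_leaf
  tot_l[!ok_l] <- Inf; tot_r[!ok_r] <- Inf
  na_left <- tot_l <= tot_r                     # tie -> left
  tot <- pmin(tot_l, tot_r)
  if (all(!is.finite(tot))) return(NULL)
  b <- which.min(tot)                           # first minimum: smallest threshold
  i <- cand[b]
  list(imp_children = tot[b],
       threshold = (xs[i] + xs[i + 1L]) / 2,
       na_left = na_left[b],
       n_left = nl[b] + if (na_left[b]) nm else 0L,
       n_right = nr[b] + if (na_left[b]) 0L else nm)
}

.split_cat <- function(x, y, cls_mat, min_leaf, level_order) {
  lev <- level_order[level_order %in% x]
  L <- length(lev)
  if (L < 2L) return(NULL)
  idx <- match(x, lev)
  n_l <- tabulate(idx, L)
  if (is.null(cls_mat)) {
    s_l <- vapply(seq_len(L), function(k) sum(y[idx == k]), 0)
    ss_l <- vapply(seq_len(L), function(k) sum(y[idx == k]^2), 0)
    imp_of <- function(members) {
      n1 <- sum(n_l[members]); n2 <- sum(n_l) - n1
      s1 <- sum(s_l[members]); ss1 <- sum(ss_l[members])
      (ss1 - s1^2 / n1) + ((sum(ss_l) - ss1) - (sum(s_l) - s1)^2 / n2)
    }
    score <- s_l / n_l                          # level ordering for many levels
  } else {
    cnt <- rowsum(cls_mat, group = idx)         # L x C class counts
    imp_of <- function(members) {
      c1 <- colSums(cnt[members, , drop = FALSE])
      c2 <- colSums(cnt) - c1
      n1 <- sum(c1); n2 <- sum(c2)
      (n1 - sum(c1 * c1) / n1) + (n2 - sum(c2 * c2) / n2)
    }
    score <- cnt[, 1L] / n_l
  }
  cand <- if (L <= 10L) {
    # exhaustive: every proper subset containing the first level, counted once
    lapply(0L:(2L^(L - 1L) - 2L), function(mask)
      c(1L, which(bitwAnd(mask, bitwShiftL(1L, seq_len(L - 1L) - 1L)) > 0L) + 1L))
  } else {
    # classic reduction: order levels by mean response / first-class share,
    # search contiguous cuts
    o <- order(score, method = "radix")
    lapply(seq_len(L - 1L), function(k) o[seq_len(k)])
  }
  best <- NULL
  for (members in cand) {
    n1 <- sum(n_l[members])
    n2 <- sum(n_l) - n1
    if (n1 < min_leaf || n2 < min_leaf) next
    imp <- imp_of(members)
    if (is.null(best) || imp < best$imp_children) {
      best <- list(imp_children = imp, left_levels = lev[sort(members)],
                   n_left = n1, n_right = n2)
    }
  }
  best
}

.node_impurity <- function(y, cls_mat) {
  n <- if (is.null(cls_mat)) length(y) else nrow(cls_mat)
  if (n == 0L) return(0)
  if (is.null(cls_mat)) sum((y - mean(y))^2)
  else n - sum(colSums(cls_mat)^2) / n
}

#' Fit a classification or regression tree with donor pools
#'
#' Greedy top-down binary recursive partitioning. Regression targets split to
#' maximise the reduction in within-node sum of squared deviations;
#' categorical targets to maximise the reduction in count-weighted Gini
#' impurity. Each leaf records the training rows it contains (its donor
#' pool), from which synthetic values are drawn during synthesis.
#'
#' Missing values: a missing categorical predictor value is its own category;
#' a missing numeric predictor value follows a branch chosen at fit time
#' (whichever side gives lower impurity, ties to the left) and stored with
#' the split. A missing categorical *target* value is treated as an
#' additional class, so donor sampling reproduces target missingness.
#' Missing numeric targets are refused: synthesise those with the two-part
#' indicator scheme (see [synthesize()]).
#'
#' @param data Data frame holding target and predictors.
#' @param target Name of the target column.
#' @param predictors Character vector of predictor column names (order is the
#'   tie-break order); defaults to all other columns.
#' @param params A [cart_params()] object.
#' @return An object of class `cart_tree`.
#' @examples
#' d <- data.frame(x = 1:8, y = c(1, 1, 1, 1, 5, 5, 5, 5))
#' tr <- cart(d, "y", "x", cart_params(min_leaf = 2, min_split = 4))
#' print(tr)
#' @export
cart <- function(data, target, predictors = setdiff(names(data), target),
                 params = cart_params()) {
  stopifnot(is.data.frame(data), target %in% names(data))
  if (nrow(data) == 0L) stop("cannot fit a tree on zero rows", call. = FALSE)
  missing_p <- setdiff(predictors, names(data))
  if (length(missing_p))
    stop("unknown predictor column(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)

  y_raw <- data[[target]]
  if (is.numeric(y_raw)) {
    target_kind <- "numeric"
    if (anyNA(y_raw))
      stop(sprintf("numeric target '%s' has missing values; synthesize via the missingness-indicator scheme", target),
           call. = FALSE)
    y <- as.double(y_raw)
    cls_mat <- NULL
    classes <- NULL
  } else {
    target_kind <- "categorical"
    yv <- as.character(y_raw)
    yv[is.na(yv)] <- .NA_LEVEL
    classes <- unique(c(if (is.factor(y_raw)) levels(y_raw), yv))
    classes <- classes[classes %in% yv]
    if (length(classes) == 0L) stop("target column is all-missing with no levels", call. = FALSE)
    cls_mat <- outer(yv, classes, "==") * 1
    y <- yv
  }

  # prepared predictors: numeric as double; categorical as character with the
  # NA sentinel, plus the declared level order for deterministic subsets
  X <- list(); lev_order <- list()
  for (p in predictors) {
    v <- data[[p]]
    if (is.numeric(v)) {
      X[[p]] <- as.double(v)
      lev_order[[p]] <- NULL
    } else {
      lv <- if (is.factor(v)) levels(v) else unique(as.character(v[!is.na(v)]))
      vv <- as.character(v)
      vv[is.na(vv)] <- .NA_LEVEL
      X[[p]] <- vv
      lev_order[[p]] <- c(lv, .NA_LEVEL)
    }
  }

  root_imp <- .node_impurity(y, cls_mat)
  tol <- root_imp * 1e-12
  env <- new.env(parent = emptyenv())
  env$nodes <- list()

  grow <- function(rows, depth) {
    id <- length(env$nodes) + 1L
    env$nodes[[id]] <- list()                   # reserve slot
    n <- length(rows)
    node_imp <- .node_impurity(
      if (is.null(cls_mat)) y[rows] else y[rows],
      if (is.null(cls_mat)) NULL else cls_mat[rows, , drop = FALSE])
    make_leaf <- function() {
      env$nodes[[id]] <<- list(type = "leaf", n = n, donors = rows)
      id
    }
    if (n < params$min_split || depth >= params$max_depth || node_imp <= tol)
      return(make_leaf())

    best <- NULL
    for (p in predictors) {
      xv <- X[[p]][rows]
      cm <- if (is.null(cls_mat)) NULL else cls_mat[rows, , drop = FALSE]
      sp <- if (is.numeric(xv))
        .split_num(xv, y[rows], cm, params$min_leaf)
      else
        .split_cat(xv, y[rows], cm, params$min_leaf, lev_order[[p]])
      if (!is.null(sp)) {
        gain <- node_imp - sp$imp_children
        if (is.null(best) || gain > best$gain + tol) {
          sp$gain <- gain; sp$var <- p
          best <- sp
        }
      }
    }
    if (is.null(best) ||
        best$gain <= max(params$min_impurity_decrease * root_imp, tol))
      return(make_leaf())

    xv <- X[[best$var]][rows]
    go_left <- if (!is.null(best$left_levels)) xv %in% best$left_levels
               else ifelse(is.na(xv), best$na_left, xv <= best$threshold)
    left_id <- grow(rows[go_left], depth + 1L)
    right_id <- grow(rows[!go_left], depth + 1L)
    env$nodes[[id]] <- list(
      type = "split", n = n, var = best$var,
      kind = if (is.null(best$left_levels)) "numeric_threshold" else "level_subset",
      threshold = best$threshold, na_left = best$na_left,
      left_levels = best$left_levels,
      seen_levels = if (is.null(best$left_levels)) NULL else unique(xv),
      bigger_left = best$n_left >= best$n_right,
      left = left_id, right = right_id)
    id
  }
  grow(seq_len(nrow(data)), 0L)

  structure(list(nodes = env$nodes, target = target, target_kind = target_kind,
                 classes = classes, predictors = predictors,
                 params = params, root_impurity = root_imp,
                 n_train = nrow(data)),
            class = "cart_tree")
}

# Vectorized routing: leaf node id for every row of newdata. Unseen
# categorical levels follow the branch that held the majority of training
# rows at that node; a value exactly at a numeric threshold goes left.
.route <- function(tree, newdata) {
  n <- nrow(newdata)
  X <- lapply(tree$predictors, function(p) {
    v <- newdata[[p]]
    if (is.numeric(v)) as.double(v) else {
      vv <- as.character(v); vv[is.na(vv)] <- .NA_LEVEL; vv
    }
  })
  names(X) <- tree$predictors
  at <- rep(1L, n)
  repeat {
    types <- vapply(tree$nodes[at], `[[`, character(1L), "type")
    live <- which(types == "split")
    if (!length(live)) break
    for (id in unique(at[live])) {
      nd <- tree$nodes[[id]]
      rows <- live[at[live] == id]
      xv <- X[[nd$var]][rows]
      go_left <- if (nd$kind == "numeric_threshold") {
        ifelse(is.na(xv), nd$na_left, xv <= nd$threshold)
      } else {
        gl <- xv %in% nd$left_levels
        unseen <- !(xv %in% nd$seen_levels)
        gl[unseen] <- nd$bigger_left
        gl
      }
      at[rows] <- ifelse(go_left, nd$left, nd$right)
    }
  }
  at
}

#' Route one row to its leaf donor pool
#'
#' Deterministic descent of the fitted tree: same tree and same row always
#' reach the same leaf. Returns the training-row indices in that leaf.
#'
#' @param tree A `cart_tree`.
#' @param row A single-row data frame containing the tree's predictors.
#' @return Integer vector of donor row indices.
#' @export
route_row <- function(tree, row) {
  stopifnot(inherits(tree, "cart_tree"), is.data.frame(row), nrow(row) == 1L)
  miss <- setdiff(tree$predictors, names(row))
  if (length(miss))
    stop("row lacks predictor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tree$nodes[[.route(tree, row)]]$donors
}

#' @export
#' @describeIn cart Predict leaf membership (`type = "node"`) or sample one
#'   donor value per row (`type = "donor"`, requires the training target).
#' @param object A `cart_tree`.
#' @param newdata Data frame of rows to route.
#' @param type `"node"` for leaf ids, `"donor"` for donor row indices sampled
#'   uniformly from each leaf pool.
#' @param ... Unused.
predict.cart_tree <- function(object, newdata, type = c("node", "donor"), ...) {
  type <- match.arg(type)
  at <- .route(object, newdata)
  if (type == "node") return(at)
  vapply(at, function(id) {
    pool <- object$nodes[[id]]$donors
    pool[sample.int(length(pool), 1L)]
  }, integer(1L))
}

.tree_lines <- function(tree, id = 1L, indent = "") {
  nd <- tree$nodes[[id]]
  if (nd$type == "leaf")
    return(sprintf("%sleaf: n=%d", indent, nd$n))
  rule <- if (nd$kind == "numeric_threshold")
    sprintf("%s <= %.6g%s", nd$var, nd$threshold,
            if (isTRUE(nd$na_left)) " (NA left)" else " (NA right)")
  else
    sprintf("%s in {%s}", nd$var,
            paste(sub(.NA_LEVEL, "<NA>", nd$left_levels, fixed = TRUE), collapse = ", "))
  c(sprintf("%ssplit: %s (n=%d)", indent, rule, nd$n),
    .tree_lines(tree, nd$left, paste0(indent, "  ")),
    .tree_lines(tree, nd$right, paste0(indent, "  ")))
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("CART (%s target '%s', %d training rows, %d leaves)\n",
              x$target_kind, x$target, x$n_train,
              sum(vapply(x$nodes, function(n) n$type == "leaf", logical(1L)))))
  cat(.tree_lines(x), sep = "\n")
  invisible(x)
}

#' Serialize a fitted tree to an indented key-value text file
#'
#' A debugging/fixture format: one line per node, indentation encodes depth.
#'
#' @param tree A `cart_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cart <- function(tree, path) {
  writeLines(.tree_lines(tree), path)
  invisible(path)
}
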