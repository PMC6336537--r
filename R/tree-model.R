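# Descriptor-to-phenotype modelling: correlation-based feature elimination,
# stratified train/test splitting, binary classification trees (Gini
# impurity, exhaustive midpoint search, cost-complexity pruning chosen by
# cross-validated misclassification with a conservative SE rule), ROC/AUC
# and planted-structure recovery evaluation.

TREE_TIE_TOL <- 1e-10

#' Eliminate highly correlated features
#'
#' Iterates feature pairs in canonical (column) order and, whenever the
#' pairwise squared Pearson correlation exceeds `r2_max`, drops the later
#' column; zero-variance features are dropped up front. Deterministic and
#' idempotent.
#'
#' @param table A feature data.frame.
#' @param r2_max Squared-correlation threshold (default 0.75).
#' @param feature_cols Feature column names (default: all numeric columns
#'   except `label`).
#' @return A list with `table` (features filtered) and `dropped`
#'   (data.frame `feature`, `reason`, `partner`, `r2`).
#' @export
filter_correlated <- function(table, r2_max = 0.75, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- names(table)[vapply(table, is.numeric, logical(1))]
    feature_cols <- setdiff(feature_cols, "label")
  }
  if (length(feature_cols) < 2L) stopf("need at least 2 features")
  if (nrow(table) < 3L) stopf("need at least 3 rows")
  dropped <- list()
  keep <- feature_cols
  zv <- keep[vapply(keep, function(f) stats::sd(table[[f]]) == 0, logical(1))]
  for (f in zv) {
    dropped[[f]] <- quick_df(list(feature = f, reason = "zero_variance",
                                  partner = NA_character_, r2 = NA_real_))
  }
  keep <- setdiff(keep, zv)
  i <- 1L
  while (i < length(keep)) {
    j <- i + 1L
    while (j <= length(keep)) {
      r2 <- stats::cor(table[[keep[i]]], table[[keep[j]]])^2
      if (!is.na(r2) && r2 > r2_max) {
        dropped[[keep[j]]] <- quick_df(list(feature = keep[j],
                                            reason = "correlated",
                                            partner = keep[i], r2 = r2))
        keep <- keep[-j]
      } else j <- j + 1L
    }
    i <- i + 1L
  }
  out_cols <- names(table)[!(names(table) %in% setdiff(feature_cols, keep))]
  drop_log <- if (length(dropped)) do.call(rbind, unname(dropped)) else
    quick_df(list(feature = character(0), reason = character(0),
                  partner = character(0), r2 = numeric(0)))
  row.names(drop_log) <- NULL
  list(table = table[out_cols], dropped = drop_log, kept = keep)
}

#' Stratified train/test split
#'
#' Samples `round(frac * n)` rows per class into the training set;
#' deterministic per seed.
#'
#' @param table A labelled data.frame.
#' @param frac Training fraction (default 0.75).
#' @param seed Integer seed.
#' @param label_col Label column name.
#' @return A list with `train` and `test` data.frames and the row indices.
#' @export
split_train_test <- function(table, frac = 0.75, seed = 1,
                             label_col = "label") {
  y <- table[[label_col]]
  if (is.null(y)) stopf("no '%s' column", label_col)
  tab <- table(y)
  if (length(tab) < 2L) stopf("both classes must be present")
  if (any(tab < 4L)) stopf("each class needs at least 4 rows to stratify")
  with_seed(seed, {
    train_idx <- sort(unlist(lapply(names(tab), function(cl) {
      i <- which(y == cl)
      sample(i, round(frac * length(i)))
    }), use.names = FALSE))
    test_idx <- setdiff(seq_len(nrow(table)), train_idx)
    list(train = table[train_idx, , drop = FALSE],
         test = table[test_idx, , drop = FALSE],
         train_idx = train_idx, test_idx = test_idx)
  })
}

# exhaustive best split of one node; returns NULL when no admissible split
# improves the Gini impurity. Ties (within TREE_TIE_TOL) resolve to the
# earliest feature in canonical order, then the smallest threshold.
best_split <- function(X, y, min_leaf) {
  n <- length(y)
  h <- sum(y)
  parent <- 2 * h * (n - h) / n
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    o <- order(v)
    vs <- v[o]; ys <- y[o]
    ch <- cumsum(ys)
    i <- seq_len(n - 1L)
    valid <- (vs[i] < vs[i + 1L]) & (i >= min_leaf) & ((n - i) >= min_leaf)
    if (!any(valid)) next
    i <- i[valid]
    nl <- i; nr <- n - i
    hl <- ch[i]; hr <- h - hl
    w <- 2 * (hl * (nl - hl) / nl + hr * (nr - hr) / nr)
    dec <- parent - w
    k <- which.max(dec)
    if (dec[k] <= TREE_TIE_TOL) next
    if (is.null(best) || dec[k] > best$dec + TREE_TIE_TOL) {
      ii <- i[k]
      best <- list(feature = j, threshold = (vs[ii] + vs[ii + 1L]) / 2,
                   dec = dec[k])
    }
  }
  best
}

#' Fit a binary classification tree
#'
#' Recursive binary partitioning of the `high`/`low` labels over numeric
#' descriptors, minimising Gini impurity with an exhaustive search over
#' (feature, midpoint threshold) pairs. The tree is grown to `max_depth`
#' with at least `min_leaf` rows per leaf, then cost-complexity pruned at
#' the complexity value selected by `cv_folds`-fold cross-validated
#' misclassification under a conservative SE rule: the simplest tree whose
#' cross-validated error lies within `se_factor` standard errors of the
#' minimum is kept. The default `se_factor = 2.5` is deliberately stricter
#' than the classic one-SE rule (`se_factor = 1`) so that label noise
#' prunes back to the trivial tree; chance patterns in a finite noise
#' sample survive validation within that same sample more often than the
#' one-SE slack allows. Impurity ties resolve to the earliest feature in
#' column order, then the smallest threshold.
#'
#' @param train Training data.frame.
#' @param label_col Label column (`"high"`/`"low"`).
#' @param feature_cols Feature columns (default all numeric but the label).
#' @param min_leaf Minimum rows per leaf.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param cv_folds Number of cross-validation folds (0 disables pruning
#'   by cross-validation; the full tree is returned).
#' @param seed Seed for the fold assignment.
#' @param se_factor SE multiplier of the pruning rule (1 = classic one-SE).
#' @return An object of class `topo_tree`.
#' @export
fit_tree <- function(train, label_col = "label", feature_cols = NULL,
                     min_leaf = 8, max_depth = 5, cv_folds = 10, seed = 1,
                     se_factor = 2.5) {
  y_raw <- train[[label_col]]
  if (is.null(y_raw)) stopf("no '%s' column", label_col)
  if (is.null(feature_cols)) {
    feature_cols <- names(train)[vapply(train, is.numeric, logical(1))]
    feature_cols <- setdiff(feature_cols, label_col)
  }
  if (!length(feature_cols)) stopf("no feature columns")
  X <- as.matrix(train[feature_cols])
  if (anyNA(X)) stopf("features contain missing values; impute or drop first")
  y <- y_raw == "high"
  if (length(unique(y)) < 2L) {
    warnf("fit_tree: single-class training set; returning a single leaf")
  }
  full <- grow_tree(X, y, min_leaf, max_depth)
  cv_table <- NULL
  alpha <- 0
  if (cv_folds > 1L && nrow(full) > 1L) {
    cv <- cv_complexity(X, y, full, min_leaf, max_depth, cv_folds, seed,
                        se_factor)
    alpha <- cv$alpha
    cv_table <- cv$table
    nodes <- prune_at(full, alpha)
  } else {
    nodes <- full
  }
  structure(list(nodes = nodes, features = feature_cols,
                 label_col = label_col, min_leaf = min_leaf,
                 max_depth = max_depth, alpha = alpha, cv_table = cv_table,
                 n_train = length(y)),
            class = "topo_tree")
}

# grow the maximal tree; nodes as a data.frame
grow_tree <- function(X, y, min_leaf, max_depth) {
  rows <- new.env(parent = emptyenv())
  rows$list <- list()
  add <- function(rec) { rows$list[[rec$id]] <- rec; rec$id }
  next_id <- function() length(rows$list) + 1L
  build <- function(idx, depth) {
    id <- next_id()
    n <- length(idx); h <- sum(y[idx])
    rec <- list(id = id, depth = depth, n = n, n_high = h,
                feature = NA_character_, threshold = NA_real_,
                left = NA_integer_, right = NA_integer_)
    add(rec)
    if (depth < max_depth && n >= 2 * min_leaf && h > 0L && h < n) {
      sp <- best_split(X[idx, , drop = FALSE], y[idx], min_leaf)
      if (!is.null(sp)) {
        f <- colnames(X)[sp$feature]
        lidx <- idx[X[idx, sp$feature] < sp$threshold]
        ridx <- idx[X[idx, sp$feature] >= sp$threshold]
        lid <- build(lidx, depth + 1L)
        rid <- build(ridx, depth + 1L)
        rec$feature <- f; rec$threshold <- sp$threshold
        rec$left <- lid; rec$right <- rid
        rows$list[[id]] <- rec
      }
    }
    id
  }
  build(seq_along(y), 0L)
  do.call(rbind, lapply(rows$list, function(r) quick_df(r[-1]))) -> df
  df <- cbind(quick_df(list(id = seq_len(nrow(df)))), df)
  df
}

node_is_leaf <- function(nodes) is.na(nodes$feature)

# per-node misclassification count of the subtree rooted at each node
subtree_stats <- function(nodes) {
  k <- nrow(nodes)
  r_sub <- numeric(k); leaves <- integer(k)
  # children always have larger ids than the parent: process in reverse
  for (i in rev(seq_len(k))) {
    if (is.na(nodes$feature[i])) {
      r_sub[i] <- min(nodes$n_high[i], nodes$n[i] - nodes$n_high[i])
      leaves[i] <- 1L
    } else {
      r_sub[i] <- r_sub[nodes$left[i]] + r_sub[nodes$right[i]]
      leaves[i] <- leaves[nodes$left[i]] + leaves[nodes$right[i]]
    }
  }
  list(r_sub = r_sub, leaves = leaves)
}

# weakest-link critical value g(t) per internal node, on the error scale
# normalised by the training size
node_g <- function(nodes, n_total) {
  st <- subtree_stats(nodes)
  r_node <- pmin(nodes$n_high, nodes$n - nodes$n_high)
  g <- rep(Inf, nrow(nodes))
  internal <- !node_is_leaf(nodes)
  g[internal] <- (r_node[internal] - st$r_sub[internal]) /
    pmax(st$leaves[internal] - 1L, 1L) / n_total
  g
}

collapse_node <- function(nodes, i) {
  # drop the whole subtree below i and renumber
  drop <- integer(0)
  stack <- c(nodes$left[i], nodes$right[i])
  while (length(stack)) {
    j <- stack[[1]]; stack <- stack[-1]
    drop <- c(drop, j)
    if (!is.na(nodes$feature[j])) stack <- c(stack, nodes$left[j], nodes$right[j])
  }
  nodes$feature[i] <- NA_character_; nodes$threshold[i] <- NA_real_
  nodes$left[i] <- NA_integer_; nodes$right[i] <- NA_integer_
  keep <- setdiff(seq_len(nrow(nodes)), drop)
  remap <- integer(nrow(nodes)); remap[keep] <- seq_along(keep)
  nodes <- nodes[keep, , drop = FALSE]
  nodes$id <- seq_len(nrow(nodes))
  ok <- !is.na(nodes$left)
  nodes$left[ok] <- remap[nodes$left[ok]]
  nodes$right[ok] <- remap[nodes$right[ok]]
  row.names(nodes) <- NULL
  nodes
}

# prune all weakest links with g <= alpha (plus float slack)
prune_at <- function(nodes, alpha) {
  n_total <- nodes$n[1]
  repeat {
    if (nrow(nodes) == 1L) return(nodes)
    g <- node_g(nodes, n_total)
    gmin <- min(g)
    if (gmin > alpha + TREE_TIE_TOL) return(nodes)
    i <- which(g <= gmin + TREE_TIE_TOL)[1]
    nodes <- collapse_node(nodes, i)
  }
}

# the nested alpha sequence of weakest-link pruning
alpha_sequence <- function(nodes) {
  n_total <- nodes$n[1]
  alphas <- 0
  while (nrow(nodes) > 1L) {
    g <- node_g(nodes, n_total)
    gmin <- min(g)
    alphas <- c(alphas, gmin)
    while (min(node_g(nodes, n_total)) <= gmin + TREE_TIE_TOL &&
           nrow(nodes) > 1L) {
      g <- node_g(nodes, n_total)
      i <- which(g <= gmin + TREE_TIE_TOL)[1]
      nodes <- collapse_node(nodes, i)
    }
  }
  unique(alphas)
}

# route rows of a feature matrix to leaf indices
route_rows <- function(nodes, X) {
  leaf <- integer(nrow(X))
  idx <- seq_len(nrow(X))
  assign_node <- rep(1L, nrow(X))
  repeat {
    open <- which(!is.na(nodes$feature[assign_node]) & leaf == 0L)
    if (!length(open)) break
    nd <- assign_node[open]
    f <- nodes$feature[nd]; th <- nodes$threshold[nd]
    v <- X[cbind(open, match(f, colnames(X)))]
    goes_left <- v < th
    assign_node[open] <- ifelse(goes_left, nodes$left[nd], nodes$right[nd])
  }
  # any node reached that is a leaf
  is_leaf_now <- is.na(nodes$feature[assign_node])
  leaf[is_leaf_now] <- assign_node[is_leaf_now]
  leaf
}

#' Predict from a classification tree
#'
#' @param object A `topo_tree`.
#' @param newdata Data.frame containing the model's features.
#' @param type `"prob"` for the leaf proportion of `high` (default) or
#'   `"class"` for the majority label (ties resolve to `low`).
#' @param ... Unused.
#' @return Numeric scores or character labels, one per row.
#' @export
predict.topo_tree <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  missing_f <- setdiff(object$features, names(newdata))
  if (length(missing_f)) {
    stopf("newdata lacks feature(s): %s", paste(missing_f, collapse = ", "))
  }
  X <- as.matrix(newdata[object$features])
  if (anyNA(X)) {
    bad <- object$features[colSums(is.na(X)) > 0]
    stopf("missing values in feature(s): %s", paste(bad, collapse = ", "))
  }
  leaf <- route_rows(object$nodes, X)
  p <- object$nodes$n_high[leaf] / object$nodes$n[leaf]
  if (type == "prob") p else ifelse(p > 0.5, "high", "low")
}

# cross-validated choice of the complexity parameter (one-SE rule)
cv_complexity <- function(X, y, full, min_leaf, max_depth, cv_folds, seed,
                          se_factor) {
  alphas <- alpha_sequence(full)
  k <- length(alphas)
  betas <- if (k == 1L) 0 else
    c(sqrt(alphas[-k] * alphas[-1]), alphas[k] * 2 + 1e-12)
  n <- length(y)
  folds <- with_seed(seed, {
    f <- integer(n)
    for (cl in unique(y)) {
      i <- which(y == cl)
      f[i] <- sample(rep_len(seq_len(cv_folds), length(i)))
    }
    f
  })
  err <- matrix(0, length(betas), 1L)
  for (fold in seq_len(cv_folds)) {
    tr <- folds != fold
    if (length(unique(y[tr])) < 2L) next
    ft <- grow_tree(X[tr, , drop = FALSE], y[tr], min_leaf, max_depth)
    for (b in seq_along(betas)) {
      pt <- prune_at(ft, betas[b])
      leaf <- route_rows(pt, X[!tr, , drop = FALSE])
      pred <- pt$n_high[leaf] / pt$n[leaf] > 0.5
      err[b, 1] <- err[b, 1] + sum(pred != y[!tr])
    }
  }
  e <- err[, 1] / n
  se <- sqrt(e * (1 - e) / n)
  best <- which.min(e)
  limit <- e[best] + se_factor * se[best]
  chosen <- max(which(e <= limit + 1e-12))
  list(alpha = betas[chosen],
       table = quick_df(list(alpha = betas, cv_error = e, se = se)))
}

#' @export
print.topo_tree <- function(x, ...) {
  nodes <- x$nodes
  cat(sprintf("topo_tree: %d nodes (%d leaves), %d training rows, alpha = %.3g\n",
              nrow(nodes), sum(node_is_leaf(nodes)), x$n_train, x$alpha))
  show <- function(i, indent) {
    nd <- nodes[i, ]
    lab <- if (is.na(nd$feature)) {
      sprintf("leaf: n=%d P(high)=%.3f", nd$n, nd$n_high / nd$n)
    } else {
      sprintf("%s < %.4g  (n=%d)", nd$feature, nd$threshold, nd$n)
    }
    cat(strrep("  ", indent), lab, "\n", sep = "")
    if (!is.na(nd$feature)) {
      show(nd$left, indent + 1L)
      show(nd$right, indent + 1L)
    }
  }
  show(1L, 0L)
  invisible(x)
}

#' @export
summary.topo_tree <- function(object, ...) {
  print(object)
  if (!is.null(object$cv_table)) {
    cat("\ncross-validated complexity table:\n")
    print(object$cv_table, digits = 4)
  }
  invisible(object)
}

#' Features used in the top two levels of a tree
#' @param tree A `topo_tree`.
#' @return Character vector (empty for a single leaf).
#' @export
top_level_features <- function(tree) {
  nodes <- tree$nodes
  top <- nodes[nodes$depth <= 1L & !is.na(nodes$feature), , drop = FALSE]
  unique(top$feature)
}

#' Empirical ROC curve and AUC
#'
#' The AUC is the normalised Mann-Whitney rank statistic (ties counted with
#' mid-ranks), which equals the trapezoidal area under the empirical ROC.
#'
#' @param scores Numeric scores (higher = more `positive`).
#' @param labels Class labels.
#' @param positive The positive class (default `"high"`).
#' @return A list of class `roc_result`: `auc`, `roc` (data.frame
#'   `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`. One-class input yields
#'   `auc = NA` with a warning.
#' @export
roc_auc <- function(scores, labels, positive = "high") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    warnf("roc_auc: only one class present; AUC undefined")
    return(structure(list(auc = NA_real_, roc = NULL, n_pos = n1,
                          n_neg = n0), class = "roc_result"))
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- which(grp != c(grp[-1], -1))
  roc <- quick_df(list(threshold = c(Inf, s[last]),
                       fpr = c(0, fp[last] / n0),
                       tpr = c(0, tp[last] / n1)))
  structure(list(auc = auc, roc = roc, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Evaluate recovery of a planted decision structure
#'
#' A fitted tree "recovers" the planted structure when the features used in
#' its top two levels intersect the features named by the planted model's
#' rules; a single-leaf tree never recovers.
#'
#' @param tree A `topo_tree`.
#' @param planted A `planted_model`.
#' @param auc Optional held-out AUC to carry in the report.
#' @return A list of class `recovery_report`: `recovered`, `top_features`,
#'   `planted_features`, `auc`.
#' @export
evaluate_recovery <- function(tree, planted, auc = NA_real_) {
  top <- top_level_features(tree)
  pf <- planted_features(planted)
  structure(list(recovered = length(intersect(top, pf)) > 0,
                 top_features = top, planted_features = pf, auc = auc),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: recovered = %s, held-out AUC = %s\n",
              x$recovered, ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  cat("  top-level features:", paste(x$top_features, collapse = ", "), "\n")
  cat("  planted features:  ", paste(x$planted_features, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a tree to JSON
#'
#' @param tree A `topo_tree`.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  jsonlite::write_json(
    list(nodes = tree$nodes, features = tree$features, alpha = tree$alpha,
         n_train = tree$n_train),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
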