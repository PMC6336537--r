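rand_table <- function(n, p = 3, informative = FALSE, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- if (informative) {
    ifelse(X[, 1] + rnorm(n, 0, 0.2) > 0.5, "high", "low")
  } else {
    sample(c("high", "low"), n, replace = TRUE)
  }
  cbind(as.data.frame(X), label = y)
}

test_that("correlation filtering drops duplicates, later column first", {
  set.seed(2)
  d <- data.frame(a = rnorm(100))
  d$b <- d$a
  d$c <- rnorm(100)
  out <- filter_correlated(d, feature_cols = c("a", "b", "c"))
  expect_equal(out$kept, c("a", "c"))
  expect_equal(out$dropped$feature, "b")
  expect_equal(out$dropped$partner, "a")
})

test_that("independent features survive the r-squared filter", {
  set.seed(3)
  d <- as.data.frame(matrix(rnorm(200 * 5), 200, 5))
  out <- filter_correlated(d, feature_cols = names(d))
  expect_equal(out$kept, names(d))
  expect_equal(nrow(out$dropped), 0L)
})

test_that("correlation filtering is idempotent and flags zero variance", {
  set.seed(4)
  d <- data.frame(a = rnorm(50), z = rep(1, 50))
  d$b <- d$a * 2 + rnorm(50, 0, 0.01)
  d$c <- rnorm(50)
  out1 <- filter_correlated(d, feature_cols = c("a", "z", "b", "c"))
  expect_true("z" %in% out1$dropped$feature[out1$dropped$reason == "zero_variance"])
  expect_true("b" %in% out1$dropped$feature)
  out2 <- filter_correlated(out1$table, feature_cols = out1$kept)
  expect_equal(out2$kept, out1$kept)
  expect_equal(nrow(out2$dropped), 0L)
})

test_that("fcpn01 is eliminated as a near-copy of fcp on real descriptors", {
  fx <- fx_small()
  keep <- setdiff(names(fx$dv), "design_id")
  dv <- fx$dv
  for (f in keep) dv[[f]][is.na(dv[[f]])] <- 0
  out <- filter_correlated(dv, feature_cols = keep)
  expect_true("fcpn01" %in% out$dropped$feature)
  expect_equal(out$dropped$partner[out$dropped$feature == "fcpn01"], "fcp")
})

test_that("the stratified split respects fractions, determinism and disjointness", {
  d <- rand_table(100, seed = 5)
  d$label <- c(rep("high", 40), rep("low", 60))
  sp <- split_train_test(d, seed = 9)
  expect_equal(sum(sp$train$label == "high"), 30L)
  expect_equal(sum(sp$train$label == "low"), 45L)
  sp2 <- split_train_test(d, seed = 9)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), 1:100)
  d$label <- c(rep("high", 3), rep("low", 97))
  expect_error(split_train_test(d), "at least 4")
})

test_that("a perfectly separating feature yields a depth-1 tree", {
  d <- data.frame(x = c(1:10, 21:30), noise = runif(20),
                  label = rep(c("low", "high"), each = 10))
  tr <- fit_tree(d, min_leaf = 2, cv_folds = 5, seed = 1)
  expect_equal(nrow(tr$nodes), 3L)
  expect_equal(tr$nodes$feature[1], "x")
  expect_gt(tr$nodes$threshold[1], 10)
  expect_lt(tr$nodes$threshold[1], 21)
  expect_equal(unname(predict(tr, data.frame(x = 25, noise = 0.5))), 1)
  expect_equal(unname(predict(tr, data.frame(x = 3, noise = 0.5))), 0)
})

test_that("the root split matches the exhaustive-search oracle", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(30:200, 1)
    p <- sample(2:4, 1)
    d <- rand_table(n, p, informative = i %% 2 == 0, seed = 1000 + i)
    X <- as.matrix(d[seq_len(p)])
    y <- d$label == "high"
    min_leaf <- sample(c(2, 5, 8), 1)
    o <- oracle_root_split(X, y, min_leaf)
    tr <- fit_tree(d, min_leaf = min_leaf, max_depth = 1, cv_folds = 0)
    if (is.null(o)) {
      expect_equal(nrow(tr$nodes), 1L)
    } else {
      expect_equal(tr$nodes$feature[1], o$feature)
      expect_equal(tr$nodes$threshold[1], o$threshold, tolerance = 1e-12)
    }
  }
})

test_that("pure-noise labels prune back to a single leaf", {
  single <- 0L
  for (s in 1:20) {
    d <- rand_table(200, 4, informative = FALSE, seed = 3000 + s)
    tr <- fit_tree(d, seed = s)
    if (nrow(tr$nodes) == 1L) single <- single + 1L
  }
  expect_gte(single, 18L)
})

test_that("planted two-level structure is recovered by the grown tree", {
  set.seed(77)
  n <- 400
  fcp <- runif(n, 0, 0.6)
  circ_diam <- runif(n, 2, 20)
  noise <- runif(n)
  label <- ifelse(fcp >= 0.256 & circ_diam >= 8.293, "high", "low")
  d <- data.frame(fcp = fcp, circ_diam = circ_diam, noise = noise,
                  label = label)
  tr <- fit_tree(d, seed = 2)
  expect_equal(tr$nodes$feature[1], "fcp")
  expect_setequal(top_level_features(tr), c("fcp", "circ_diam"))
  expect_lt(abs(tr$nodes$threshold[1] - 0.256), 0.05)
})

test_that("single-class training yields a single warned leaf", {
  d <- rand_table(30, seed = 6)
  d$label <- "high"
  expect_warning(tr <- fit_tree(d), "single-class")
  expect_equal(nrow(tr$nodes), 1L)
  expect_equal(unname(predict(tr, d[1:5, ])), rep(1, 5))
})

test_that("predictions are order-invariant and demand the model features", {
  d <- rand_table(120, informative = TRUE, seed = 8)
  tr <- fit_tree(d, seed = 1)
  p <- predict(tr, d)
  perm <- sample(nrow(d))
  expect_equal(predict(tr, d[perm, ]), p[perm])
  expect_error(predict(tr, d[, -1]), "f1")
  d_na <- d
  d_na$f2[3] <- NA
  expect_error(predict(tr, d_na), "f2")
  # single-leaf tree scores at the training prevalence
  d0 <- rand_table(100, informative = FALSE, seed = 100)
  tr0 <- fit_tree(d0, seed = 4)
  if (nrow(tr0$nodes) == 1L) {
    expect_equal(unique(predict(tr0, d0)), mean(d0$label == "high"))
  }
})

test_that("tree invariants hold on fitted models", {
  d <- rand_table(300, 4, informative = TRUE, seed = 13)
  tr <- fit_tree(d, seed = 3)
  nodes <- tr$nodes
  leaves <- nodes[is.na(nodes$feature), ]
  expect_true(all(leaves$n >= tr$min_leaf))
  expect_true(all(nodes$depth <= tr$max_depth))
  # thresholds lie strictly between observed values
  for (i in which(!is.na(nodes$feature))) {
    v <- d[[nodes$feature[i]]]
    expect_true(any(v < nodes$threshold[i]) && any(v > nodes$threshold[i]))
  }
})

test_that("increasing the complexity penalty never grows the tree", {
  d <- rand_table(300, 4, informative = TRUE, seed = 21)
  tr <- fit_tree(d, cv_folds = 0, seed = 1)
  sizes <- vapply(c(0, 0.001, 0.005, 0.01, 0.05, 0.2, 1),
                  function(a) nrow(toposcreen:::prune_at(tr$nodes, a)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("AUC equals the Mann-Whitney statistic and its trapezoidal area", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c("low", "low", "low", "high", "high", "high"))$auc, 1)
  expect_equal(roc_auc(rep(5, 10), rep(c("high", "low"), 5))$auc, 0.5)
  set.seed(31)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # heavy ties
    labels <- sample(c("high", "low"), n, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    w <- wilcox.test(scores[labels == "high"], scores[labels == "low"],
                     exact = FALSE)
    u <- unname(w$statistic) / (sum(labels == "high") * sum(labels == "low"))
    expect_equal(r$auc, u, tolerance = 1e-12)
    trap <- sum(diff(r$roc$fpr) * (head(r$roc$tpr, -1) + tail(r$roc$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
  }
  expect_warning(r <- roc_auc(1:5, rep("high", 5)), "one class")
  expect_true(is.na(r$auc))
})

test_that("random scores give a null AUC near one half", {
  set.seed(41)
  r <- roc_auc(runif(2000), sample(c("high", "low"), 2000, replace = TRUE))
  expect_gt(r$auc, 0.47)
  expect_lt(r$auc, 0.53)
})

test_that("recovery reports intersect top-level and planted features", {
  pm <- default_planted_model()
  d <- data.frame(fcp = runif(100), other = runif(100),
                  label = rep(c("high", "low"), 50))
  d$label <- ifelse(d$fcp > 0.5, "high", "low")
  tr <- fit_tree(d, min_leaf = 5, seed = 1)
  rec <- evaluate_recovery(tr, pm, auc = 0.9)
  expect_true(rec$recovered)
  expect_equal(rec$auc, 0.9)
})

test_that("a single-leaf model reports no recovery", {
  pm <- default_planted_model()
  set.seed(51)
  d <- data.frame(x = runif(60), y = runif(60),
                  label = sample(c("high", "low"), 60, replace = TRUE))
  tr <- fit_tree(d, seed = 7)
  if (nrow(tr$nodes) > 1L) tr$nodes <- tr$nodes[1, , drop = FALSE]
  tr$nodes$feature <- NA_character_
  rec <- evaluate_recovery(tr, pm)
  expect_false(rec$recovered)
})

test_that("our tree agrees with rpart on a clean two-split problem", {
  skip_if_not_installed("rpart")
  set.seed(61)
  n <- 500
  a <- runif(n); b <- runif(n)
  label <- ifelse(a > 0.5 & b > 0.4, "high", "low")
  d <- data.frame(a = a, b = b, label = label)
  tr <- fit_tree(d, seed = 1)
  rp <- rpart::rpart(factor(label) ~ a + b, d,
                     control = rpart::rpart.control(minbucket = 8, cp = 0.01))
  expect_equal(tr$nodes$feature[1],
               as.character(rp$frame$var[1]))
  expect_equal(tr$nodes$threshold[1], rp$splits[1, "index"],
               tolerance = 0.02)
})
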