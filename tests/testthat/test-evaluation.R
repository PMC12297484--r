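test_that("metric report matches hand arithmetic on small confusions", {
  # confusion [[2,0],[1,1]]: class F1s 0.8 and 2/3, macro 0.73333
  y_true <- c(0L, 0L, 1L, 1L)
  y_pred <- c(0L, 0L, 0L, 1L)
  r <- metrics_report(y_true, y_pred)
  expect_equal(r$per_class$f1, c(0.8, 2 / 3), tolerance = 1e-9)
  expect_equal(r$macro_f1, mean(c(0.8, 2 / 3)), tolerance = 1e-9)
  expect_equal(r$macro_f1, 0.73333, tolerance = 1e-4)
  expect_equal(r$accuracy, 0.75)
  expect_identical(unname(rowSums(r$confusion)), c(2, 2))
  # perfect predictions
  rp <- metrics_report(0:3, 0:3)
  expect_equal(rp$macro_f1, 1)
  expect_equal(rp$macro_precision, 1)
  expect_equal(rp$accuracy, 1)
  # everything predicted as one class on balanced labels
  ra <- metrics_report(c(0L, 0L, 1L, 1L), c(0L, 0L, 0L, 0L))
  expect_equal(ra$macro_f1, (2 / 3 + 0) / 2, tolerance = 1e-9)
  expect_equal(ra$macro_f1, 0.33333, tolerance = 1e-4)
  expect_error(metrics_report(c(0L, 1L), c(0L, 5L), n_classes = 2L), "label")
})

test_that("macro-F1 is invariant to class relabeling", {
  set.seed(1)
  y <- sample(0:2, 60, replace = TRUE)
  p <- ifelse(runif(60) < 0.7, y, sample(0:2, 60, replace = TRUE))
  base <- metrics_report(y, p)$macro_f1
  perm <- c(2L, 0L, 1L)
  expect_equal(metrics_report(perm[y + 1L], perm[p + 1L])$macro_f1, base,
               tolerance = 1e-12)
})

test_that("rank-based AUROC agrees with pROC on a two-class problem", {
  set.seed(4)
  y <- rep(0:1, each = 30)
  s <- rnorm(60, mean = y)
  scores <- cbind(-s, s)
  r <- metrics_report(y, as.integer(s > 0.5), scores)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c(0, 1),
                                        direction = "<", quiet = TRUE)))
  expect_equal(r$auroc, ref, tolerance = 1e-9)
})

test_that("KNN probe votes, breaks ties as documented, and respects k", {
  # ten co-located labeled points: their shared label wins
  train <- rbind(matrix(0, 10, 2) + rnorm(20, sd = 1e-3),
                 matrix(5, 5, 2))
  labs <- c(rep(1L, 10), rep(0L, 5))
  r <- knn_probe(train, labs, matrix(0, 1, 2), 1L, k = 10)
  expect_identical(unname(which(r$confusion > 0, arr.ind = TRUE)[, 2]), 2L)
  expect_error(knn_probe(train, labs, matrix(0, 1, 2), 1L, k = 50), "k exceeds")
  # three distinct points, k = 1, eval = train: exact recovery
  tr3 <- rbind(c(0, 0), c(5, 0), c(0, 5))
  r3 <- knn_probe(tr3, 0:2, tr3, 0:2, k = 1)
  expect_equal(r3$accuracy, 1)
  # vote tie between two classes: the class with smaller mean distance wins
  # (class 0 voters at 0.9 and 1.1, class 1 voters both at ~1.02)
  tr4 <- rbind(c(0.9, 0), c(1.1, 0), c(-1, 0.2), c(-1, -0.2))
  r4 <- knn_probe(tr4, c(0L, 0L, 1L, 1L), matrix(c(0, 0), 1), 1L, k = 4)
  expect_identical(unname(which(r4$confusion > 0, arr.ind = TRUE)[, 2]), 1L)
})

test_that("KNN probe separates well-separated Gaussian blobs across seeds", {
  f1 <- vapply(1:5, function(seed) {
    set.seed(seed)
    centers <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5), 4, 2, byrow = TRUE) * 1
    tr <- do.call(rbind, lapply(1:4, function(k) {
      sweep(matrix(rnorm(60, sd = 1), 30, 2), 2, centers[k, ], "+")
    }))
    te <- do.call(rbind, lapply(1:4, function(k) {
      sweep(matrix(rnorm(30, sd = 1), 15, 2), 2, centers[k, ], "+")
    }))
    knn_probe(tr, rep(0:3, each = 30), te, rep(0:3, each = 15),
              k = 10)$macro_f1
  }, numeric(1))
  expect_gte(mean(f1), 0.95)
})

test_that("linear probe fits separable data and stays at chance on noise", {
  set.seed(7)
  tr <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
              matrix(rnorm(100, 5, 0.3), 50, 2))
  labs <- rep(0:1, each = 50)
  r <- linear_probe(tr, labs, tr, labs)
  expect_equal(r$accuracy, 1)
  # permuted labels, 4 balanced classes: macro-F1 near chance
  f1 <- vapply(1:5, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(200 * 4), 200, 4)
    y <- rep(0:3, each = 50)
    yp <- sample(y)
    linear_probe(X[1:120, ], yp[1:120], X[121:200, ], yp[121:200])$macro_f1
  }, numeric(1))
  expect_lt(abs(mean(f1) - 0.25), 0.1)
  expect_error(linear_probe(tr, rep(0L, 100), tr, labs), "two classes")
})

test_that("balanced softmax reduces to cross-entropy and matches the toy case", {
  set.seed(2)
  logits <- matrix(rnorm(12), 4, 3)
  labels <- c(0L, 2L, 1L, 0L)
  eq <- balanced_softmax_ce(logits, labels, class_counts = c(7, 7, 7))
  ce <- mean(vapply(1:4, function(i) {
    -(logits[i, labels[i] + 1] - wearssl:::logsumexp(logits[i, ]))
  }, numeric(1)))
  expect_equal(eq, ce, tolerance = 1e-12)
  # counts (9, 1), zero logits, true label = minority: -ln(1/10)
  toy <- balanced_softmax_ce(matrix(0, 1, 2), 1L, class_counts = c(9, 1))
  expect_equal(toy, -log(0.1), tolerance = 1e-9)
  expect_equal(toy, 2.30259, tolerance = 1e-5)
  # overwhelming logit for the true class drives the loss to zero
  big <- balanced_softmax_ce(matrix(c(50, 0), 1), 0L, class_counts = c(9, 1))
  expect_lt(big, 1e-6)
  expect_error(balanced_softmax_ce(matrix(0, 1, 2), 1L, c(5, 0)), "count")
  # gradient check
  g <- balanced_softmax_ce(logits, labels, c(3, 2, 5), with_grad = TRUE)
  eps <- 1e-6
  for (j in seq_along(logits)) {
    lp <- logits; lp[j] <- lp[j] + eps
    lm <- logits; lm[j] <- lm[j] - eps
    num <- (balanced_softmax_ce(lp, labels, c(3, 2, 5)) -
              balanced_softmax_ce(lm, labels, c(3, 2, 5))) / (2 * eps)
    expect_lt(abs(num - g$dlogits[j]), 1e-6)
  }
})

test_that("stratified subsampling is exact, seeded, and errors on empty classes", {
  labels <- rep(0:3, each = 100)
  idx <- stratified_subset(labels, 0.1, seed = 3)
  expect_identical(as.integer(table(labels[idx])), rep(10L, 4L))
  expect_identical(idx, stratified_subset(labels, 0.1, seed = 3))
  expect_false(identical(idx, stratified_subset(labels, 0.1, seed = 4)))
  expect_identical(stratified_subset(labels, 1.0, seed = 1), seq_along(labels))
  expect_error(stratified_subset(c(rep(0L, 100), 1L), 0.1, seed = 1),
               "class 1")
})

test_that("probes leave the backbone untouched, fine-tuning moves it", {
  ds <- generate_dataset(synth_config(n_subjects = 6, segments_per_subject = 6,
                                      window_s = 5, seed = 4))
  ds <- make_splits(ds, c(0.6, 0.2, 0.2), seed = 4)
  f <- znormalize_features(extract_domain_features(ds, "cardiac"))
  tr <- split_subset(ds, "train")
  fit <- sscl_pretrain(tr, domain_feature_matrix(
    f$values[ds$split == "train", , drop = FALSE], f$feature_names),
    train_config(batch_size = 8L, epochs = 2L, encoder = tiny_encoder(),
                 K = 4L, seed = 1L))
  before <- fit$model$params
  te <- split_subset(ds, "test")
  invisible(knn_probe(predict(fit, tr), tr$y, predict(fit, te), te$y, k = 3))
  invisible(linear_probe(predict(fit, tr), tr$y, predict(fit, te), te$y))
  expect_identical(fit$model$params, before)
  ft <- fine_tune(fit, ds, label_fraction = 1.0, epochs = 2L, seed = 1L)
  expect_false(identical(ft$model$params, before))
  expect_s3_class(ft$report, "probe_report")
  # fraction 1.0 uses every train label exactly once
  expect_identical(ft$label_indices, seq_len(n_segments(tr)))
})
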