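# Evaluation protocols: KNN probing, linear probing, fine-tuning with
# balanced softmax cross-entropy, and class-average metric reports.

#' Class-average metric report
#'
#' Per-class one-vs-rest precision, recall and F1 (empty denominators score
#' 0), their macro averages, accuracy, the confusion matrix, and — when
#' scores are supplied — macro one-vs-rest AUROC computed from the
#' Mann-Whitney rank statistic.
#'
#' @param y_true integer labels in `0:(K-1)`.
#' @param y_pred predicted labels from the same set.
#' @param scores optional matrix `[n x K]` of class scores (columns ordered
#'   by class index); AUROC is omitted when absent.
#' @param n_classes number of classes; inferred from labels when omitted.
#' @param protocol tag recorded in the report.
#' @return list of class `probe_report`.
#' @export
metrics_report <- function(y_true, y_pred, scores = NULL, n_classes = NULL,
                           protocol = "custom") {
  if (length(y_true) != length(y_pred)) stop("label error: length mismatch")
  if (is.null(n_classes)) n_classes <- max(y_true, y_pred) + 1L
  if (any(y_pred < 0L | y_pred >= n_classes)) {
    stop("label error: prediction outside known classes")
  }
  classes <- 0:(n_classes - 1L)
  cm <- table(factor(y_true, levels = classes), factor(y_pred, levels = classes))
  cm <- unclass(cm)
  prec <- rec <- f1 <- numeric(n_classes)
  for (k in seq_len(n_classes)) {
    tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  auroc <- NA_real_
  if (!is.null(scores)) {
    aucs <- vapply(seq_len(n_classes), function(k) {
      pos <- y_true == classes[k]
      if (!any(pos) || all(pos)) return(NA_real_)
      rank_auc(scores[, k], pos)
    }, numeric(1))
    auroc <- mean(aucs, na.rm = TRUE)
  }
  structure(list(protocol = protocol,
                 per_class = data.frame(class = classes, precision = prec,
                                        recall = rec, f1 = f1,
                                        support = rowSums(cm)),
                 macro_f1 = mean(f1), macro_precision = mean(prec),
                 macro_recall = mean(rec),
                 accuracy = sum(diag(cm)) / length(y_true),
                 auroc = auroc, confusion = cm),
            class = "probe_report")
}

# AUC via the Mann-Whitney statistic with midrank tie handling.
rank_auc <- function(score, positive) {
  r <- rank(score)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.probe_report <- function(x, ...) {
  cat(sprintf("probe_report [%s]: macro-F1 %.4f  accuracy %.4f%s\n",
              x$protocol, x$macro_f1, x$accuracy,
              if (is.finite(x$auroc)) sprintf("  AUROC %.4f", x$auroc) else ""))
  invisible(x)
}

#' KNN probe on frozen representations
#'
#' Majority vote among the `k` Euclidean nearest training points. Vote ties
#' are broken by the smallest mean distance to the tied class's voters, then
#' by the lowest class index. Scores for AUROC are the per-class vote
#' fractions.
#'
#' @param train_repr,train_labels frozen-backbone representations and labels
#'   of the probe training split.
#' @param eval_repr,eval_labels held-out representations and labels.
#' @param k neighbourhood size (default 10).
#' @param n_classes class count; inferred when omitted.
#' @return A `probe_report`.
#' @export
knn_probe <- function(train_repr, train_labels, eval_repr, eval_labels,
                      k = 10L, n_classes = NULL) {
  train_repr <- as.matrix(train_repr); eval_repr <- as.matrix(eval_repr)
  if (k > nrow(train_repr)) stop("probe error: k exceeds training size")
  if (is.null(n_classes)) n_classes <- max(train_labels, eval_labels) + 1L
  n_eval <- nrow(eval_repr)
  preds <- integer(n_eval)
  scores <- matrix(0, n_eval, n_classes)
  tr_sq <- rowSums(train_repr^2)
  for (i in seq_len(n_eval)) {
    d2 <- tr_sq - 2 * drop(train_repr %*% eval_repr[i, ]) + sum(eval_repr[i, ]^2)
    nn <- order(d2)[seq_len(k)]
    votes <- tabulate(train_labels[nn] + 1L, nbins = n_classes)
    scores[i, ] <- votes / k
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      mean_d <- vapply(top, function(cl) {
        mean(sqrt(pmax(d2[nn[train_labels[nn] + 1L == cl]], 0)))
      }, numeric(1))
      top <- top[order(mean_d, top)]
    }
    preds[i] <- top[1L] - 1L
  }
  metrics_report(eval_labels, preds, scores, n_classes = n_classes,
                 protocol = sprintf("knn(k=%d)", k))
}

#' Linear probe on frozen representations
#'
#' Multinomial logistic regression (`nnet::multinom`, convex objective,
#' fixed iteration cap and tolerance) trained on frozen representations; the
#' backbone is untouched by construction since only the representation
#' matrix is visible to the solver.
#'
#' @param train_repr,train_labels probe training data.
#' @param eval_repr,eval_labels held-out data.
#' @param maxit solver iteration cap.
#' @param n_classes class count; inferred when omitted.
#' @return A `probe_report`.
#' @export
linear_probe <- function(train_repr, train_labels, eval_repr, eval_labels,
                         maxit = 200L, n_classes = NULL) {
  if (length(unique(train_labels)) < 2L) {
    stop("probe error: need at least two classes in probe training labels")
  }
  if (is.null(n_classes)) n_classes <- max(train_labels, eval_labels) + 1L
  present <- sort(unique(train_labels))
  df_tr <- data.frame(.y = factor(train_labels, levels = present),
                      as.data.frame(as.matrix(train_repr)))
  fit <- nnet::multinom(.y ~ ., data = df_tr, maxit = maxit, trace = FALSE,
                        MaxNWts = 100000L, reltol = 1e-10)
  df_ev <- data.frame(as.data.frame(as.matrix(eval_repr)))
  names(df_ev) <- names(df_tr)[-1L]
  pr <- stats::predict(fit, newdata = df_ev, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # two-class case
  # classes absent from probe training get probability 0
  probs <- matrix(0, nrow(df_ev), n_classes)
  probs[, present + 1L] <- pr
  preds <- max.col(probs, ties.method = "first") - 1L
  metrics_report(eval_labels, preds, probs, n_classes = n_classes,
                 protocol = "linear_probe")
}

#' Balanced softmax cross-entropy
#'
#' Cross-entropy with each logit shifted by the log of its class's training
#' count: `-log( n_y e^{f_y} / sum_k n_k e^{f_k} )`, averaged over the batch.
#' With equal counts this is exactly standard softmax cross-entropy.
#'
#' @param logits matrix `[n x K]`.
#' @param labels integer labels in `0:(K-1)`.
#' @param class_counts positive training-set counts per class.
#' @param with_grad also return the gradient w.r.t. the logits.
#' @return scalar loss, or `list(loss, dlogits)`.
#' @export
balanced_softmax_ce <- function(logits, labels, class_counts,
                                with_grad = FALSE) {
  logits <- as.matrix(logits)
  n <- nrow(logits); K <- ncol(logits)
  if (any(class_counts[labels + 1L] <= 0)) {
    stop("count error: zero class count for a present label")
  }
  shifted <- sweep(logits, 2L, log(class_counts), "+")
  loss <- 0
  dlog <- if (with_grad) logits * 0
  for (i in seq_len(n)) {
    lse <- logsumexp(shifted[i, ])
    loss <- loss + (lse - shifted[i, labels[i] + 1L])
    if (with_grad) {
      q <- exp(shifted[i, ] - lse)
      q[labels[i] + 1L] <- q[labels[i] + 1L] - 1
      dlog[i, ] <- q / n
    }
  }
  loss <- loss / n
  if (!with_grad) return(loss)
  list(loss = loss, dlogits = dlog)
}

#' Stratified label subsampling
#'
#' Seeded, stratified-by-class selection of a fraction of the labeled
#' training indices; every class keeps `round(fraction * n_class)` examples
#' (at least 1 — a class whose share would round to zero raises an error
#' naming it).
#'
#' @param labels integer labels.
#' @param fraction fraction in `(0, 1]`.
#' @param seed integer seed.
#' @return integer indices into `labels`.
#' @export
stratified_subset <- function(labels, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(seq_along(labels))
  with_rng(derive_seed(seed, "finetune"), {
    out <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      take <- round(fraction * length(idx))
      if (take < 1L) {
        stop("stratification error: class ", cl,
             " has no examples at fraction ", fraction)
      }
      out <- c(out, sort(sample(idx, take)))
    }
    sort(out)
  })
}

#' Fine-tune the encoder with a linear head
#'
#' Attaches a linear classification head to the backbone representation and
#' optimizes the whole network (encoder + head) with balanced softmax
#' cross-entropy and Adam on a stratified, seeded subset of the train labels.
#' Reports class-average metrics on the test split. Initialization is either
#' a pretrained `sscl` fit or a random encoder.
#'
#' @param init an `sscl` fit, or an `encoder_spec` for random initialization.
#' @param dataset a split-tagged, labeled [segment_dataset()].
#' @param label_fraction fraction of train labels used, in `(0, 1]`.
#' @param epochs fine-tuning epochs; with a small labeled subset one epoch
#'   is a single gradient step, so size this to the step budget.
#' @param batch_size mini-batch size.
#' @param lr Adam step size (default 5e-4, half the pretraining rate).
#' @param seed integer seed (label subset, shuffling, head/encoder init).
#' @param eval_split split to report on.
#' @return list with the `probe_report` (`$report`), the trained weights and
#'   the selected label indices.
#' @export
fine_tune <- function(init, dataset, label_fraction = 1.0, epochs = 15L,
                      batch_size = 32L, lr = 5e-4, seed = 1L,
                      eval_split = "test") {
  train <- split_subset(dataset, "train")
  test <- split_subset(dataset, eval_split)
  if (anyNA(train$y)) stop("fine-tuning needs labeled training segments")
  n_classes <- max(dataset$y, na.rm = TRUE) + 1L
  keep <- stratified_subset(train$y, label_fraction, seed = seed)
  Xtr <- train$X[keep, , , drop = FALSE]
  ytr <- train$y[keep]
  counts <- tabulate(ytr + 1L, nbins = n_classes)
  counts[counts == 0L] <- 1L  # absent classes never appear as labels

  if (inherits(init, "sscl")) {
    model <- init$model
  } else if (inherits(init, "encoder_spec")) {
    model <- init_encoder(init, seed = derive_seed(seed, "optimizer"))
  } else stop("init must be an sscl fit or an encoder_spec")
  rd <- model$spec$repr_dim
  head <- with_rng(derive_seed(seed, "finetune") + 1L, {
    list(W = he_init(rd, n_classes, rd), b = numeric(n_classes))
  })
  opt <- adam_init(c(model$params, list(head_W = head$W, head_b = head$b)))
  params <- model$params

  n <- length(ytr)
  bsz <- min(batch_size, n)
  n_batches <- max(1L, n %/% bsz)
  for (epoch in seq_len(epochs)) {
    perm <- with_rng((derive_seed(seed, "shuffle") + 7000L + epoch) %% 2147483587,
                     sample.int(n))
    for (bi in seq_len(n_batches)) {
      idx <- perm[((bi - 1L) * bsz + 1L):min(bi * bsz, n)]
      model$params <- params
      fw <- encoder_forward(model, Xtr[idx, , , drop = FALSE], with_cache = TRUE)
      logits <- sweep(fw$h %*% head$W, 2L, head$b, "+")
      ce <- balanced_softmax_ce(logits, ytr[idx], counts, with_grad = TRUE)
      dh <- ce$dlogits %*% t(head$W)
      g_head_W <- crossprod(fw$h, ce$dlogits)
      g_head_b <- colSums(ce$dlogits)
      grads <- encoder_backward(model, fw$cache, dz = NULL, dh = dh)
      all_params <- c(params, list(head_W = head$W, head_b = head$b))
      all_grads <- c(grads, list(head_W = g_head_W, head_b = g_head_b))
      upd <- adam_step(all_params, all_grads, opt, lr = lr)
      opt <- upd$state
      head$W <- upd$params$head_W; head$b <- upd$params$head_b
      params <- upd$params[names(params)]
    }
  }
  model$params <- params
  fw <- encoder_forward(model, test$X, with_cache = FALSE)
  logits <- sweep(fw$h %*% head$W, 2L, head$b, "+")
  probs <- t(apply(logits, 1L, function(r) exp(r - logsumexp(r))))
  preds <- max.col(probs, ties.method = "first") - 1L
  report <- metrics_report(test$y, preds, probs, n_classes = n_classes,
                           protocol = sprintf("fine_tune(frac=%g)", label_fraction))
  list(report = report, model = model, head = head, label_indices = keep)
}
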