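# End-to-end self-supervised pretraining: view sampling, domain-guided
# instance loss, EMA prototypes with dynamic temperatures, and the ramped
# combined objective, optimized with Adam under linear learning-rate warm-up.

#' Ramp weight for the prototype loss
#'
#' `min(max((T - T0) / Tmax, 0), 1)`: zero until epoch `T0`, then a linear
#' ramp. With the default denominator (`Tmax`, the total epoch count) the
#' weight reaches 1 only at `T = T0 + Tmax`; set
#' `denominator = "span"` to use `Tmax - T0` instead so the ramp completes
#' within the run (off by default).
#'
#' @param T current epoch.
#' @param T0 ramp start epoch.
#' @param Tmax total epoch count (> 0).
#' @param denominator `"total"` (the default convention) or `"span"`.
#' @return scalar in `[0, 1]`.
#' @export
ramp_weight <- function(T, T0, Tmax, denominator = c("total", "span")) {
  if (Tmax <= 0) stop("schedule error: Tmax must be positive")
  denominator <- match.arg(denominator)
  den <- if (denominator == "total") Tmax else max(Tmax - T0, 1)
  min(max((T - T0) / den, 0), 1)
}

#' Combined training loss
#'
#' `instance + ramp_weight * proto`.
#'
#' @param instance instance-level loss (finite scalar).
#' @param proto prototype-level loss (finite scalar).
#' @param T,T0,Tmax schedule, as in [ramp_weight()].
#' @param denominator ramp denominator convention.
#' @return scalar total loss.
#' @export
total_loss <- function(instance, proto, T, T0, Tmax, denominator = "total") {
  if (!is.finite(instance) || !is.finite(proto)) {
    stop("training error: non-finite loss (instance = ", instance,
         ", proto = ", proto, ")")
  }
  instance + ramp_weight(T, T0, Tmax, denominator) * proto
}

#' Pretraining configuration
#'
#' @param batch_size segments per batch (>= 2); the incomplete final batch is
#'   dropped so neighbour pools and cluster counts are comparable.
#' @param epochs total epochs (>= 1).
#' @param lr Adam step size.
#' @param warmup_epochs linear learning-rate warm-up span.
#' @param lr_schedule `"constant"` or `"cosine"` (half-cosine decay to zero
#'   after warm-up).
#' @param base_tau global temperature for both loss levels.
#' @param K prototype count.
#' @param alpha EMA momentum.
#' @param m temperature smoothing count.
#' @param n_neighbors domain neighbours per anchor (2 = the two most similar
#'   views); ignored when `guidance = "none"`.
#' @param guidance `"domain"` for the full framework, `"none"` for plain
#'   instance discrimination (ablation baseline).
#' @param use_prototypes include the prototype-level loss.
#' @param T0 ramp start epoch; default 10% of `epochs` (at least 1).
#' @param ramp_denominator `"total"` (default) or `"span"`.
#' @param augmentation an [augmentation_spec()].
#' @param encoder an [encoder_spec()] or `NULL` to size from data.
#' @param normalize_prototypes unit-normalize prototypes after EMA.
#' @param dynamic_tau per-cluster dynamic temperatures updated each epoch;
#'   when `FALSE` every cluster keeps `base_tau` (ablation switch).
#' @param seed master seed; every random stream (augmentation, shuffling,
#'   k-means, weight init) derives from it.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32L, epochs = 20L, lr = 1e-3,
                         warmup_epochs = 2L, lr_schedule = c("constant", "cosine"),
                         base_tau = 0.1, K = 8L,
                         alpha = 0.5, m = 10, n_neighbors = 2L,
                         guidance = c("domain", "none"), use_prototypes = TRUE,
                         T0 = NULL, ramp_denominator = "total",
                         augmentation = augmentation_spec(),
                         encoder = NULL, normalize_prototypes = TRUE,
                         dynamic_tau = TRUE, seed = 1L) {
  guidance <- match.arg(guidance)
  lr_schedule <- match.arg(lr_schedule)
  if (batch_size < 2L) stop("config error: batch_size must be >= 2")
  if (epochs < 1L) stop("config error: epochs must be >= 1")
  if (is.null(T0)) T0 <- max(1L, round(0.1 * epochs))
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 warmup_epochs = as.integer(warmup_epochs),
                 lr_schedule = lr_schedule,
                 base_tau = base_tau, K = as.integer(K), alpha = alpha, m = m,
                 n_neighbors = as.integer(n_neighbors), guidance = guidance,
                 use_prototypes = isTRUE(use_prototypes), T0 = as.integer(T0),
                 ramp_denominator = ramp_denominator,
                 augmentation = augmentation, encoder = encoder,
                 normalize_prototypes = isTRUE(normalize_prototypes),
                 dynamic_tau = isTRUE(dynamic_tau),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Named configuration presets
#'
#' `"desk"` is the documented small-scale default every test runs at
#' (batch 32, 20 epochs, 8 prototypes, compact encoder, cosine decay, ramp
#' start at 80% of the schedule so immature prototypes cannot dominate a
#' short run). `"large"` is the GPU-scale
#' configuration this method is normally trained at (batch 1024, 1000
#' epochs, 128 prototypes, Adam lr 1e-3 with 5 warm-up epochs), for users
#' with the hardware to match.
#'
#' @param name `"desk"` or `"large"`.
#' @param ... overrides forwarded to [train_config()].
#' @return A `train_config`.
#' @export
train_preset <- function(name = c("desk", "large"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    desk = list(batch_size = 32L, epochs = 20L, lr = 1e-3, warmup_epochs = 2L,
                lr_schedule = "cosine", T0 = 16L, K = 8L),
    large = list(batch_size = 1024L, epochs = 1000L, lr = 1e-3,
                 warmup_epochs = 5L, K = 128L))
  do.call(train_config, utils::modifyList(defaults, list(...)))
}

# Stack augmented view pairs for a batch of segment indices.
# Returns views array [2B x C x T] and the view_to_source map (within-batch).
make_view_batch <- function(dataset, idx, aug, seed_epoch_batch) {
  Bn <- length(idx)
  C <- dim(dataset$X)[2L]; Tt <- dim(dataset$X)[3L]
  V <- array(0, c(2L * Bn, C, Tt))
  with_rng(seed_epoch_batch, {
    for (b in seq_len(Bn)) {
      x <- dataset$X[idx[b], , , drop = TRUE]
      if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
      pair <- sample_view_pair(x, aug)
      V[2L * b - 1L, , ] <- pair[[1L]]
      V[2L * b, , ] <- pair[[2L]]
    }
  })
  list(views = V, view_to_source = rep(seq_len(Bn), each = 2L))
}

#' Self-supervised pretraining (the package's fitting function)
#'
#' Runs the full pipeline on a training dataset and its aligned, z-normalized
#' domain feature matrix: one offline k-means on the domain features; then,
#' per batch, augmented view pairs are embedded, the multi-positive
#' domain-guided instance loss is computed, prototypes are EMA-updated, the
#' prototype loss is added under the ramp schedule, and Adam updates the
#' encoder. Per-cluster temperatures are refreshed after every epoch.
#' Fully reproducible: the same inputs, configuration and seed give
#' bit-identical loss curves.
#'
#' @param dataset a [segment_dataset()] (typically the train split).
#' @param features a z-normalized [domain_feature_matrix()] with one row per
#'   segment of `dataset`, in the same order.
#' @param config a [train_config()].
#' @param resume_from optional checkpoint (from [load_checkpoint()]) to
#'   continue; training proceeds from the recorded epoch to `config$epochs`
#'   (pass the same configuration — the ramp schedule depends on the total
#'   epoch count).
#' @param stop_after optional epoch at which to interrupt the run (for
#'   checkpointing mid-schedule); the returned object can be saved and
#'   resumed.
#' @param snapshot_every optional epoch stride at which encoder weights are
#'   snapshotted into the returned object (`$snapshots`), enabling
#'   validation-based model selection ([select_best_epoch()]).
#' @return An object of class `sscl`: the trained encoder, prototype bank,
#'   per-step training log, and configuration.
#' @export
sscl_pretrain <- function(dataset, features, config = train_config(),
                          resume_from = NULL, stop_after = NULL,
                          snapshot_every = NULL) {
  n <- n_segments(dataset)
  if (nrow(features$values) != n) {
    stop("config error: features not aligned to dataset (",
         nrow(features$values), " rows vs ", n, " segments)")
  }
  if (config$batch_size > n) stop("config error: batch size exceeds training set")
  C <- dim(dataset$X)[2L]
  espec <- config$encoder %||% encoder_spec(in_channels = C)
  if (espec$in_channels != C) stop("config error: encoder channel mismatch")

  if (is.null(resume_from)) {
    km <- kmeans_assign(features, config$K, seed = config$seed)
    K_eff <- max(km$assignments)
    bank <- prototype_bank(km$assignments, K = max(config$K, K_eff),
                           proj_dim = espec$proj_dim,
                           base_tau = config$base_tau, alpha = config$alpha,
                           m = config$m,
                           normalize_prototypes = config$normalize_prototypes)
    model <- init_encoder(espec, seed = derive_seed(config$seed, "optimizer"))
    opt <- adam_init(model$params)
    log <- list()
    start_epoch <- 1L
    init_sum <- matrix(0, bank$K, espec$proj_dim)
    init_n <- integer(bank$K)
  } else {
    ck <- resume_from
    bank <- ck$bank; model <- ck$model; opt <- ck$opt
    log <- ck$log; start_epoch <- ck$epoch + 1L
    init_sum <- ck$init_sum; init_n <- ck$init_n
    if (!identical(ck$seed, config$seed)) {
      stop("config error: checkpoint seed differs from config seed")
    }
    if (start_epoch > config$epochs) stop("config error: checkpoint already covers all epochs")
  }

  snapshots <- list()
  n_batches <- n %/% config$batch_size  # incomplete final batch dropped
  if (n_batches < 1L) stop("config error: batch size exceeds training set")
  steps_per_epoch <- n_batches

  last_epoch <- min(config$epochs, stop_after %||% config$epochs)
  for (epoch in seq.int(start_epoch, last_epoch)) {
    perm <- with_rng((derive_seed(config$seed, "shuffle") + epoch) %% 2147483587,
                     sample.int(n))
    lr_t <- config$lr * min(1, epoch / max(1L, config$warmup_epochs))
    if (config$lr_schedule == "cosine" && epoch > config$warmup_epochs) {
      prog <- (epoch - config$warmup_epochs) / max(1L, config$epochs - config$warmup_epochs)
      lr_t <- config$lr * 0.5 * (1 + cos(pi * prog))
    }
    w <- ramp_weight(epoch, config$T0, config$epochs, config$ramp_denominator)
    for (bi in seq_len(n_batches)) {
      idx <- perm[((bi - 1L) * config$batch_size + 1L):(bi * config$batch_size)]
      aug_seed <- (derive_seed(config$seed, "augment") +
                     epoch * 131071 + bi) %% 2147483587
      vb <- make_view_batch(dataset, idx, config$augmentation, aug_seed)
      fw <- encoder_forward(model, vb$views, with_cache = TRUE)
      dview <- features$values[idx[vb$view_to_source], , drop = FALSE]
      batch <- structure(list(z = fw$z, h = fw$h,
                              view_to_source = vb$view_to_source, d = dview),
                         class = "embedding_batch")
      nn <- if (config$guidance == "domain") config$n_neighbors else 0L
      pairs <- assign_pairs(batch, n_neighbors = nn)
      ins <- instance_loss(batch, pairs, tau = config$base_tau, with_grad = TRUE)
      dz <- ins$dz
      proto_val <- 0
      if (config$use_prototypes) {
        ks <- bank$assignments[idx[vb$view_to_source]]
        if (epoch == 1L) {
          # warm-up collection: prototype initialization data only
          for (k in unique(ks)) {
            rows <- which(ks == k)
            init_sum[k, ] <- init_sum[k, ] + colSums(fw$z[rows, , drop = FALSE])
            init_n[k] <- init_n[k] + length(rows)
          }
        } else {
          bank <- ema_update(bank, batch, source_index = idx)
          if (w > 0 && any(bank$initialized)) {
            pl <- prototype_loss(batch, bank, source_index = idx,
                                 with_grad = TRUE)
            proto_val <- pl$loss
            dz <- dz + w * pl$dz
          } else {
            proto_val <- 0
          }
        }
      }
      grads <- encoder_backward(model, fw$cache, dz = dz)
      upd <- adam_step(model$params, grads, opt, lr = lr_t)
      model$params <- upd$params
      opt <- upd$state
      tot <- total_loss(ins$loss, proto_val, epoch, config$T0, config$epochs,
                        config$ramp_denominator)
      if (!is.finite(tot)) stop("training error: loss diverged at epoch ", epoch)
      log[[length(log) + 1L]] <- data.frame(epoch = epoch, step = bi,
                                            lr = lr_t, ramp = w,
                                            loss_instance = ins$loss,
                                            loss_proto = proto_val,
                                            loss_total = tot)
    }
    if (!is.null(snapshot_every) &&
        (epoch %% snapshot_every == 0L || epoch == config$epochs)) {
      snapshots[[as.character(epoch)]] <- model$params
    }
    if (config$use_prototypes) {
      if (epoch == 1L) {
        nz <- init_n > 0L
        if (any(nz)) {
          cm <- init_sum[nz, , drop = FALSE] / init_n[nz]
          if (bank$normalize_prototypes) cm <- l2_normalize_rows(cm)
          bank$c[nz, ] <- cm
          bank$initialized[nz] <- TRUE
        }
      } else if (config$dynamic_tau %||% TRUE) {
        if (any(bank$acc_n > 0L)) bank <- update_temperatures(bank)
      } else {
        bank$acc_dist <- numeric(bank$K)
        bank$acc_n <- integer(bank$K)
      }
    }
  }

  structure(list(model = model, bank = if (config$use_prototypes) bank,
                 config = config, log = do.call(rbind, log),
                 opt = opt, init_sum = init_sum, init_n = init_n,
                 snapshots = if (length(snapshots)) snapshots,
                 n_train = n, digest = config_digest(unclass(config))),
            class = "sscl")
}

#' @export
print.sscl <- function(x, ...) {
  sp <- x$model$spec
  cat("Domain-guided self-supervised contrastive model (sscl)\n")
  cat(sprintf("  encoder: 1-D residual conv, widths [%s], repr dim %d, proj dim %d\n",
              paste(sp$widths, collapse = ", "), sp$repr_dim, sp$proj_dim))
  cat(sprintf("  guidance: %s%s\n", x$config$guidance,
              if (x$config$use_prototypes)
                sprintf(" + %d prototypes (alpha = %g)", x$config$K, x$config$alpha)
              else ""))
  lt <- x$log$loss_total
  cat(sprintf("  trained %d epochs on %d segments; final total loss %.4f\n",
              max(x$log$epoch), x$n_train, lt[length(lt)]))
  invisible(x)
}

#' @export
summary.sscl <- function(object, ...) {
  by_epoch <- stats::aggregate(
    object$log[c("loss_instance", "loss_proto", "loss_total")],
    by = list(epoch = object$log$epoch), FUN = mean)
  structure(list(fit = object, by_epoch = by_epoch), class = "summary.sscl")
}

#' @export
print.summary.sscl <- function(x, ...) {
  print(x$fit)
  cat("\nper-epoch mean losses (first/last 3):\n")
  be <- x$by_epoch
  show <- unique(c(utils::head(seq_len(nrow(be)), 3), utils::tail(seq_len(nrow(be)), 3)))
  print(be[show, ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.sscl <- function(x, ...) {
  be <- stats::aggregate(x$log["loss_total"], by = list(epoch = x$log$epoch),
                         FUN = mean)
  graphics::plot(be$epoch, be$loss_total, type = "b", pch = 16,
                 xlab = "epoch", ylab = "mean total loss",
                 main = "pretraining loss", ...)
  invisible(x)
}

#' Frozen-backbone representations
#'
#' `predict` on an `sscl` object runs the frozen encoder in inference mode
#' and returns the pre-projector representations used by all probes. The
#' object is not modified.
#'
#' @param object an `sscl` fit.
#' @param newdata a [segment_dataset()] or array `[n x channels x timesteps]`.
#' @param type `"representation"` (backbone) or `"projection"` (unit-norm
#'   contrastive embedding).
#' @param ... unused.
#' @return numeric matrix `[n x dim]`.
#' @export
predict.sscl <- function(object, newdata,
                         type = c("representation", "projection"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "segment_dataset")) newdata$X else newdata
  fw <- encoder_forward(object$model, X, with_cache = FALSE)
  if (type == "representation") fw$h else fw$z
}

#' Checkpointing
#'
#' Saves the complete training state — encoder weights, Adam moments,
#' prototype bank, log, configuration and epoch counter — so a run can be
#' resumed and reproduce the uninterrupted run's losses. The file embeds the
#' config digest and seed.
#'
#' @param fit an `sscl` object (or mid-run state).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  ck <- list(model = fit$model, bank = fit$bank, opt = fit$opt,
             log = split(fit$log, seq_len(nrow(fit$log))),
             epoch = max(fit$log$epoch), config_resumed = fit$config,
             init_sum = fit$init_sum, init_n = fit$init_n,
             digest = fit$digest, seed = fit$config$seed,
             format_version = 1L)
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format_version, 1L)) {
    stop("versioned format error: unknown checkpoint version")
  }
  ck
}


#' Validation-based epoch selection
#'
#' Probes every snapshotted epoch with a linear classifier on frozen
#' representations (train split fit, validation split scored) and returns the
#' fit with the best validation macro-F1 installed as its final weights —
#' the standard protocol of monitoring self-supervised training with a
#' periodic probe and keeping the best checkpoint.
#'
#' @param fit an `sscl` object trained with `snapshot_every`.
#' @param train,val labeled [segment_dataset()] splits.
#' @return the fit with the selected weights (and `$selected_epoch`).
#' @export
select_best_epoch <- function(fit, train, val) {
  if (is.null(fit$snapshots)) return(fit)
  best <- -Inf
  best_ep <- NULL
  for (ep in names(fit$snapshots)) {
    m <- fit$model
    m$params <- fit$snapshots[[ep]]
    probe <- structure(list(model = m), class = "sscl")
    f1 <- linear_probe(predict.sscl(probe, train), train$y,
                       predict.sscl(probe, val), val$y)$macro_f1
    if (f1 > best) {
      best <- f1
      best_ep <- ep
    }
  }
  fit$model$params <- fit$snapshots[[best_ep]]
  fit$selected_epoch <- as.integer(best_ep)
  fit$selected_val_f1 <- best
  fit
}
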