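# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data.

# small, clean rhythm fixture: class 0 beats at 60/min with tight jitter and
# no secondary bump, moderate noise
clean_rhythm_config <- function(seed = 11L) {
  synth_config(n_classes = 2L, n_subjects = 6L, segments_per_subject = 4L,
               rate_range = c(60, 90), jitter_range = c(0.01, 0.03),
               width_range = c(0.04, 0.06), second_amp_range = c(0, 0.3),
               rate_factor_range = c(1, 1), noise_range = c(0.05, 0.15),
               seed = seed)
}

tiny_encoder <- function(channels = 1L) {
  encoder_spec(in_channels = channels, widths = c(4L, 6L), kernel = 5L,
               stem_kernel = 7L, proj_hidden = 5L, proj_dim = 3L)
}

# unit-normalize rows
norm_rows <- function(m) m / sqrt(rowSums(m^2))

# random embedding batch of B source segments (2B views), unit-norm z,
# sibling views share the domain feature row
random_batch <- function(B, proj_dim = 4L, d_dim = 3L) {
  z <- norm_rows(matrix(stats::rnorm(2 * B * proj_dim), 2 * B, proj_dim))
  d <- matrix(stats::rnorm(2 * B * d_dim), 2 * B, d_dim)
  for (b in seq_len(B)) d[2 * b, ] <- d[2 * b - 1, ]
  structure(list(z = z, h = z, view_to_source = rep(seq_len(B), each = 2L),
                 d = d),
            class = "embedding_batch")
}

# naive double-loop oracle for the multi-positive instance objective
oracle_instance_loss <- function(Z, pairs, tau) {
  nv <- nrow(Z)
  tot <- 0
  for (i in seq_len(nv)) {
    P <- pairs[[i]]$P
    Ns <- pairs[[i]]$Nstar
    acc <- 0
    for (p in P) {
      num <- exp(sum(Z[i, ] * Z[p, ]) / tau)
      den <- num
      for (nn in Ns) den <- den + exp(sum(Z[i, ] * Z[nn, ]) / tau)
      acc <- acc - log(num / den)
    }
    tot <- tot + acc / length(P)
  }
  tot / nv
}

# naive double-loop oracle for the prototype objective
oracle_prototype_loss <- function(Z, C, tau_k, ks) {
  tot <- 0
  for (i in seq_len(nrow(Z))) {
    num <- exp(sum(Z[i, ] * C[ks[i], ]) / tau_k[ks[i]])
    den <- 0
    for (j in seq_len(nrow(C))) den <- den + exp(sum(Z[i, ] * C[j, ]) / tau_k[j])
    tot <- tot - log(num / den)
  }
  tot / nrow(Z)
}

# prototype bank with externally fixed state (for algebra tests)
fixed_bank <- function(assignments, C, tau_k, base_tau = 0.1, alpha = 0.5,
                       m = 10, normalize = TRUE) {
  bank <- prototype_bank(assignments, K = nrow(C), proj_dim = ncol(C),
                         base_tau = base_tau, alpha = alpha, m = m,
                         normalize_prototypes = normalize)
  bank$c <- C
  bank$initialized <- rep(TRUE, nrow(C))
  bank$tau_k <- tau_k
  bank
}

# the documented comparison-experiment settings (subject-structured synthetic
# cohort, nuisance-matched augmentations, compact residual encoder, batch a
# third of the train split so in-batch neighbours are meaningful, ramp start
# at 80% of the schedule, validation-selected snapshot)
experiment_synth_config <- function(seed) {
  synth_config(n_subjects = 30L, segments_per_subject = 12L, seed = seed)
}

experiment_encoder <- function(channels = 1L) {
  encoder_spec(in_channels = channels, widths = c(16L, 32L),
               proj_hidden = 32L, proj_dim = 16L)
}

experiment_train_config <- function(seed, guidance = "domain", ...) {
  train_preset("desk", seed = seed, guidance = guidance, batch_size = 72L,
               epochs = 50L, T0 = 40L, n_neighbors = 4L,
               lr_schedule = "cosine", encoder = experiment_encoder(),
               use_prototypes = identical(guidance, "domain"), ...)
}

# full pipeline for one seed: dataset, splits, normalized train features
experiment_inputs <- function(seed) {
  ds <- generate_dataset(experiment_synth_config(seed))
  ds <- make_splits(ds, c(0.6, 0.2, 0.2), seed = seed)
  f_all <- extract_domain_features(ds, "cardiac")
  tr_rows <- which(ds$split == "train")
  f_tr <- znormalize_features(domain_feature_matrix(
    f_all$values[tr_rows, , drop = FALSE], f_all$feature_names, "cardiac"))
  list(dataset = ds, train = split_subset(ds, "train"),
       val = split_subset(ds, "val"), test = split_subset(ds, "test"),
       features = f_tr)
}

# one pretraining arm with validation-based snapshot selection
run_experiment_arm <- function(inputs, seed, guidance) {
  fit <- sscl_pretrain(inputs$train, inputs$features,
                       experiment_train_config(seed, guidance),
                       snapshot_every = 5L)
  select_best_epoch(fit, inputs$train, inputs$val)
}

linear_probe_f1 <- function(fit, inputs) {
  linear_probe(predict(fit, inputs$train), inputs$train$y,
               predict(fit, inputs$test), inputs$test$y)$macro_f1
}
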