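# Prototype machinery: offline k-means on domain features, online EMA
# prototype updates in embedding space, per-cluster dynamic temperatures,
# and the prototype-level contrastive loss.

#' Offline k-means assignment on domain features
#'
#' Greedy spreading (farthest-point) initialization — a seeded random first
#' centre, then repeatedly the point farthest from the chosen set — followed
#' by Lloyd iterations (`stats::kmeans`, `algorithm = "Lloyd"`). Assignments
#' are computed once before training and never revisited.
#'
#' @param features a (normalized) [domain_feature_matrix()] or numeric matrix.
#' @param K number of clusters; reduced with a warning when there are fewer
#'   rows than `K`.
#' @param seed integer seed (first-centre choice).
#' @param iter_max Lloyd iteration cap.
#' @return list with `assignments` (1-based, length = rows) and `centroids`
#'   (`[K x features]`).
#' @export
kmeans_assign <- function(features, K, seed = 1L, iter_max = 100L) {
  X <- if (inherits(features, "domain_feature_matrix")) features$values else as.matrix(features)
  if (anyNA(X)) stop("feature error: NaN in features; normalize/impute first")
  n <- nrow(X)
  if (K < 1L) stop("K must be >= 1")
  if (n < K) {
    warning("fewer rows than K; reducing K to ", n)
    K <- n
  }
  centers <- with_rng(derive_seed(seed, "kmeans"), {
    first <- sample.int(n, 1L)
    chosen <- first
    d2 <- rowSums((X - matrix(X[first, ], n, ncol(X), byrow = TRUE))^2)
    while (length(chosen) < K) {
      nxt <- which.max(d2)
      chosen <- c(chosen, nxt)
      d2 <- pmin(d2, rowSums((X - matrix(X[nxt, ], n, ncol(X), byrow = TRUE))^2))
    }
    X[chosen, , drop = FALSE]
  })
  if (K == 1L) {
    return(list(assignments = rep(1L, n), centroids = matrix(colMeans(X), 1L)))
  }
  km <- suppressWarnings(stats::kmeans(X, centers = centers, iter.max = iter_max,
                                       algorithm = "Lloyd"))
  list(assignments = as.integer(km$cluster), centroids = km$centers)
}

#' Prototype bank
#'
#' Holds the `K` prototype vectors in projection space, the fixed offline
#' cluster assignment of every source segment, per-cluster temperatures, the
#' EMA momentum, and the epoch-scoped accumulators used by the dynamic
#' temperature update.
#'
#' @param assignments 1-based cluster index per source segment.
#' @param K cluster count.
#' @param proj_dim projection dimensionality.
#' @param base_tau global temperature; temperatures are initialized to it and
#'   re-normalized to have this mean after every update.
#' @param alpha EMA momentum in `[0, 1]` (1 freezes the prototypes).
#' @param m smoothing count in the temperature formula.
#' @param normalize_prototypes re-normalize prototypes to unit norm after
#'   each EMA step so prototype similarities stay cosine-commensurate with
#'   the instance-level terms (default on; switchable).
#' @return A `prototype_bank`.
#' @export
prototype_bank <- function(assignments, K, proj_dim, base_tau = 0.1,
                           alpha = 0.5, m = 10, normalize_prototypes = TRUE) {
  if (alpha < 0 || alpha > 1) stop("config error: alpha must be in [0, 1]")
  if (any(assignments < 1L | assignments > K)) {
    stop("config error: assignments outside [1, K]")
  }
  structure(list(c = matrix(0, K, proj_dim), initialized = rep(FALSE, K),
                 assignments = as.integer(assignments), K = as.integer(K),
                 tau_k = rep(base_tau, K), base_tau = base_tau, alpha = alpha,
                 m = m, normalize_prototypes = isTRUE(normalize_prototypes),
                 acc_dist = numeric(K), acc_n = integer(K)),
            class = "prototype_bank")
}

# cluster index for each view in a batch
view_clusters <- function(bank, batch, source_index) {
  bank$assignments[source_index[batch$view_to_source]]
}

#' EMA prototype update from one batch
#'
#' For every cluster with members among the batch views,
#' `c_k' = alpha * c_k + (1 - alpha) * mean(z_members)`; clusters without
#' members are unchanged. Updated prototypes are re-normalized to unit norm
#' when the bank says so. Member distances `||z - c_k||` are accumulated for
#' the end-of-epoch temperature update (streaming, using the prototype
#' current at each batch). Both views of a segment contribute.
#'
#' @param bank a [prototype_bank()].
#' @param batch an `embedding_batch`.
#' @param source_index maps `batch$view_to_source` values to dataset source
#'   positions (defaults to identity).
#' @return the updated bank.
#' @export
ema_update <- function(bank, batch, source_index = NULL) {
  src <- if (is.null(source_index)) batch$view_to_source else source_index[batch$view_to_source]
  ks <- bank$assignments[src]
  for (k in unique(ks)) {
    rows <- which(ks == k)
    zbar <- colMeans(batch$z[rows, , drop = FALSE])
    if (!bank$initialized[k]) {
      cx <- zbar
      bank$initialized[k] <- TRUE
    } else {
      cx <- bank$alpha * bank$c[k, ] + (1 - bank$alpha) * zbar
    }
    if (bank$normalize_prototypes) {
      nrm <- sqrt(sum(cx^2))
      if (nrm > 1e-12) cx <- cx / nrm
    }
    bank$c[k, ] <- cx
    dd <- sqrt(rowSums((batch$z[rows, , drop = FALSE] -
                          matrix(cx, length(rows), ncol(batch$z), byrow = TRUE))^2))
    bank$acc_dist[k] <- bank$acc_dist[k] + sum(dd)
    bank$acc_n[k] <- bank$acc_n[k] + length(rows)
  }
  bank
}

#' End-of-epoch dynamic temperature update
#'
#' Raw per-cluster temperature
#' `tau_k = sum_i ||z_i - c_k|| / (n_k * ln(n_k + m))` from the epoch's
#' accumulated member distances (natural log); clusters with no members this
#' epoch keep their previous temperature. All temperatures are then rescaled
#' by one multiplicative constant so their mean equals `base_tau`
#' (idempotent), and the accumulators are reset.
#'
#' @param bank a [prototype_bank()].
#' @return the updated bank.
#' @export
update_temperatures <- function(bank) {
  if (all(bank$acc_n == 0L)) {
    warning("all clusters empty this epoch; temperatures unchanged")
    return(bank)
  }
  raw <- bank$tau_k
  nz <- bank$acc_n > 0L
  raw[nz] <- bank$acc_dist[nz] / (bank$acc_n[nz] * log(bank$acc_n[nz] + bank$m))
  raw <- pmax(raw, 1e-8)
  bank$tau_k <- raw * (bank$base_tau / mean(raw))
  bank$acc_dist <- numeric(bank$K)
  bank$acc_n <- integer(bank$K)
  bank
}

#' Prototype-level contrastive loss (and its embedding gradient)
#'
#' Mean over views of
#' `-log( exp(zi.c_{k_i} / tau_{k_i}) / sum_j exp(zi.c_j / tau_j) )`,
#' where each denominator term uses its own cluster's temperature. Stable
#' log-sum-exp; prototypes are constants for the gradient (they evolve via
#' EMA, not backpropagation). `K = 1` gives a loss of exactly 0.
#'
#' @param batch an `embedding_batch`.
#' @param bank a [prototype_bank()] with initialized prototypes.
#' @param source_index maps view sources to dataset positions (identity by
#'   default).
#' @param with_grad also return `dz`.
#' @return scalar loss, or `list(loss, dz)`.
#' @export
prototype_loss <- function(batch, bank, source_index = NULL, with_grad = FALSE) {
  if (bank$K < 1L) stop("bank error: no prototypes")
  src <- if (is.null(source_index)) batch$view_to_source else source_index[batch$view_to_source]
  ks <- bank$assignments[src]
  Z <- batch$z
  nv <- nrow(Z)
  Sc <- sweep(Z %*% t(bank$c), 2L, bank$tau_k, "/")  # [nv x K], s_ij / tau_j
  total <- 0
  dz <- if (with_grad) Z * 0
  for (i in seq_len(nv)) {
    lse <- logsumexp(Sc[i, ])
    total <- total + (lse - Sc[i, ks[i]])
    if (with_grad) {
      q <- exp(Sc[i, ] - lse)
      coef <- q / bank$tau_k
      coef[ks[i]] <- coef[ks[i]] - 1 / bank$tau_k[ks[i]]
      dz[i, ] <- (coef %*% bank$c) / nv
    }
  }
  loss <- total / nv
  if (!with_grad) return(loss)
  list(loss = loss, dz = dz)
}
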