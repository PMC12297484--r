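# Compact 1-D residual convolutional encoder with an MLP projector, written
# in base R with explicit im2col convolutions and hand-derived backprop.
# There is no batch normalization or dropout, so inference equals training
# mode and fixed weights give bit-reproducible embeddings. Gradients are
# verified against finite differences in the test suite.
#
# Internal tensor layout: [batch, time, channels] (column-major friendly).

#' Encoder architecture specification
#'
#' A residual 1-D convolutional backbone: a strided stem convolution,
#' one stride-2 residual block per entry of `widths` (two convolutions plus
#' a projected shortcut), global average pooling over time to the
#' representation, and a two-layer projector whose output is l2-normalized.
#' The representation dimension equals the last width; probes consume the
#' representation, the contrastive losses consume the projection.
#'
#' @param in_channels input channel count.
#' @param widths channel widths of the residual stages (each halves time).
#' @param kernel block convolution kernel length (odd).
#' @param stem_kernel stem convolution kernel length (odd, stride 2).
#' @param proj_hidden projector hidden width.
#' @param proj_dim projection (contrastive) dimension.
#' @return An `encoder_spec` list.
#' @export
encoder_spec <- function(in_channels = 1L, widths = c(8L, 16L), kernel = 5L,
                         stem_kernel = 7L, proj_hidden = 16L, proj_dim = 8L) {
  stopifnot(kernel %% 2L == 1L, stem_kernel %% 2L == 1L, length(widths) >= 1L)
  structure(list(in_channels = as.integer(in_channels),
                 widths = as.integer(widths), kernel = as.integer(kernel),
                 stem_kernel = as.integer(stem_kernel),
                 proj_hidden = as.integer(proj_hidden),
                 proj_dim = as.integer(proj_dim),
                 repr_dim = as.integer(widths[length(widths)])),
            class = "encoder_spec")
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Initialize encoder weights
#' @param spec an [encoder_spec()].
#' @param seed integer seed for the (He-normal) initialization.
#' @return a model list with `$spec` and `$params`.
#' @export
init_encoder <- function(spec, seed = 1L) {
  with_rng(seed, {
    p <- list()
    k <- spec$kernel
    cin <- spec$in_channels
    w1 <- spec$widths[1L]
    p$stem_W <- he_init(cin * spec$stem_kernel, w1, cin * spec$stem_kernel)
    p$stem_b <- numeric(w1)
    prev <- w1
    for (i in seq_along(spec$widths)) {
      wi <- spec$widths[i]
      p[[sprintf("blk%d_c1_W", i)]] <- he_init(prev * k, wi, prev * k)
      p[[sprintf("blk%d_c1_b", i)]] <- numeric(wi)
      p[[sprintf("blk%d_c2_W", i)]] <- he_init(wi * k, wi, wi * k)
      p[[sprintf("blk%d_c2_b", i)]] <- numeric(wi)
      p[[sprintf("blk%d_sc_W", i)]] <- he_init(prev, wi, prev)
      p[[sprintf("blk%d_sc_b", i)]] <- numeric(wi)
      prev <- wi
    }
    p$proj_W1 <- he_init(prev, spec$proj_hidden, prev)
    p$proj_b1 <- numeric(spec$proj_hidden)
    p$proj_W2 <- he_init(spec$proj_hidden, spec$proj_dim, spec$proj_hidden)
    p$proj_b2 <- numeric(spec$proj_dim)
    list(spec = spec, params = p)
  })
}

# -- convolution primitives ---------------------------------------------------

# im2col with a single gather: the padded input is viewed as a [B x Tp*C]
# matrix and all (offset, channel, position) columns are pulled in one
# subset call, then reinterpreted as the [B*To x C*k] patch matrix.
conv1d_fwd <- function(X, Wmat, b, k, stride) {
  d <- dim(X)  # [B, T, C]
  B <- d[1L]; Tt <- d[2L]; C <- d[3L]
  P <- (k - 1L) %/% 2L
  Tp <- Tt + 2L * P
  Xp <- array(0, c(B, Tp, C))
  Xp[, (P + 1L):(P + Tt), ] <- X
  To <- (Tp - k) %/% stride + 1L
  base <- (0:(To - 1L)) * stride
  dim(Xp) <- c(B, Tp * C)
  # column order: feature f = (c-1)*k + j outer, window position t0 inner
  feat_off <- as.vector(vapply(seq_len(C), function(c)
    (c - 1L) * Tp + seq_len(k), integer(k)))
  cols <- as.vector(outer(base, feat_off, "+"))
  Xcol <- Xp[, cols]
  dim(Xcol) <- c(B * To, C * k)
  Ymat <- Xcol %*% Wmat
  Ymat <- sweep(Ymat, 2L, b, "+")
  list(Y = array(Ymat, c(B, To, ncol(Wmat))),
       cache = list(Xcol = Xcol, B = B, Tt = Tt, C = C, k = k,
                    stride = stride, P = P, Tp = Tp, To = To))
}

conv1d_bwd <- function(dY, Wmat, cache) {
  B <- cache$B; To <- cache$To; k <- cache$k; C <- cache$C
  dYmat <- matrix(dY, B * To, dim(dY)[3L])
  dW <- crossprod(cache$Xcol, dYmat)
  db <- colSums(dYmat)
  dXcol <- dYmat %*% t(Wmat)
  # scatter-add back; windows overlap only across kernel offsets, so one
  # accumulation pass per offset suffices (columns within a pass are unique)
  dXp <- matrix(0, B, cache$Tp * C)
  base <- (0:(To - 1L)) * cache$stride
  ch_off <- (seq_len(C) - 1L) * cache$Tp
  for (j in seq_len(k)) {
    idx <- as.vector(outer(base + j, ch_off, "+"))
    contrib <- dXcol[, seq.int(j, C * k, by = k), drop = FALSE]
    dim(contrib) <- c(B, To * C)
    dXp[, idx] <- dXp[, idx] + contrib
  }
  dim(dXp) <- c(B, cache$Tp, C)
  dX <- dXp[, (cache$P + 1L):(cache$P + cache$Tt), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# -- forward ------------------------------------------------------------------

#' Encode a batch of views
#'
#' Runs the backbone and projector. `X` uses the dataset layout
#' `[batch x channels x timesteps]`. The projection rows are l2-normalized
#' (unit Euclidean norm); the representation is the pre-projector global
#' average pooling output used by all probes.
#'
#' @param model a model from [init_encoder()].
#' @param X numeric array `[n x channels x timesteps]`.
#' @param with_cache keep intermediates for [encoder_backward()].
#' @return list with `z` (`[n x proj_dim]`, unit rows), `h`
#'   (`[n x repr_dim]`) and (optionally) `cache`.
#' @export
encoder_forward <- function(model, X, with_cache = FALSE) {
  p <- model$params; sp <- model$spec
  if (length(dim(X)) != 3L) stop("model error: views must be [n x channels x timesteps]")
  if (dim(X)[2L] != sp$in_channels) {
    stop("model error: expected ", sp$in_channels, " channel(s), got ", dim(X)[2L])
  }
  A <- aperm(X, c(1L, 3L, 2L))  # [B, T, C]
  cache <- list()
  st <- conv1d_fwd(A, p$stem_W, p$stem_b, sp$stem_kernel, 2L)
  mask <- st$Y > 0
  A <- st$Y * mask
  cache$stem <- list(conv = st$cache, mask = mask)
  for (i in seq_along(sp$widths)) {
    c1 <- conv1d_fwd(A, p[[sprintf("blk%d_c1_W", i)]],
                     p[[sprintf("blk%d_c1_b", i)]], sp$kernel, 2L)
    m1 <- c1$Y > 0
    H <- c1$Y * m1
    c2 <- conv1d_fwd(H, p[[sprintf("blk%d_c2_W", i)]],
                     p[[sprintf("blk%d_c2_b", i)]], sp$kernel, 1L)
    sc <- conv1d_fwd(A, p[[sprintf("blk%d_sc_W", i)]],
                     p[[sprintf("blk%d_sc_b", i)]], 1L, 2L)
    S <- c2$Y + sc$Y
    m2 <- S > 0
    A <- S * m2
    cache[[sprintf("blk%d", i)]] <- list(c1 = c1$cache, m1 = m1,
                                         c2 = c2$cache, sc = sc$cache, m2 = m2)
  }
  d <- dim(A)  # [B, To, Cl]
  To <- d[2L]
  h <- matrix(colMeans(matrix(aperm(A, c(2L, 1L, 3L)), To, d[1L] * d[3L])),
              d[1L], d[3L])
  cache$gap <- list(B = d[1L], To = To, Cl = d[3L])
  a1 <- sweep(h %*% p$proj_W1, 2L, p$proj_b1, "+")
  mp <- a1 > 0
  r1 <- a1 * mp
  v <- sweep(r1 %*% p$proj_W2, 2L, p$proj_b2, "+")
  nrm <- sqrt(rowSums(v^2))
  nrm_safe <- pmax(nrm, 1e-12)
  z <- v / nrm_safe
  cache$proj <- list(h = h, mp = mp, r1 = r1, v = v, nrm = nrm_safe, z = z)
  out <- list(z = z, h = h)
  if (with_cache) out$cache <- cache
  out
}

# -- backward -----------------------------------------------------------------

#' Backpropagate through the encoder
#'
#' Given the forward cache and gradients of a scalar loss with respect to the
#' projection `z` (and optionally the representation `h`, e.g. from a
#' classification head), returns gradients for every parameter.
#'
#' @param model a model from [init_encoder()].
#' @param cache the `cache` from `encoder_forward(..., with_cache = TRUE)`.
#' @param dz gradient w.r.t. `z` (`[n x proj_dim]`), or `NULL`.
#' @param dh gradient w.r.t. `h` (`[n x repr_dim]`), or `NULL`.
#' @return named list of parameter gradients (same shapes as `model$params`).
#' @export
encoder_backward <- function(model, cache, dz = NULL, dh = NULL) {
  p <- model$params; sp <- model$spec
  pr <- cache$proj
  g <- list()
  if (!is.null(dz)) {
    # through l2 normalization: dv = (dz - z * <dz, z>) / ||v||
    dv <- (dz - pr$z * rowSums(dz * pr$z)) / pr$nrm
    g$proj_W2 <- crossprod(pr$r1, dv)
    g$proj_b2 <- colSums(dv)
    dr1 <- (dv %*% t(p$proj_W2)) * pr$mp
    g$proj_W1 <- crossprod(pr$h, dr1)
    g$proj_b1 <- colSums(dr1)
    dhh <- dr1 %*% t(p$proj_W1)
  } else {
    g$proj_W2 <- p$proj_W2 * 0; g$proj_b2 <- p$proj_b2 * 0
    g$proj_W1 <- p$proj_W1 * 0; g$proj_b1 <- p$proj_b1 * 0
    dhh <- pr$h * 0
  }
  if (!is.null(dh)) dhh <- dhh + dh
  gp <- cache$gap
  # GAP backward: every timestep receives dh / To
  dA <- array(0, c(gp$B, gp$To, gp$Cl))
  for (t in seq_len(gp$To)) dA[, t, ] <- dhh / gp$To
  for (i in rev(seq_along(sp$widths))) {
    bc <- cache[[sprintf("blk%d", i)]]
    dS <- dA * bc$m2
    b2 <- conv1d_bwd(dS, p[[sprintf("blk%d_c2_W", i)]], bc$c2)
    g[[sprintf("blk%d_c2_W", i)]] <- b2$dW
    g[[sprintf("blk%d_c2_b", i)]] <- b2$db
    dH <- b2$dX * bc$m1
    b1 <- conv1d_bwd(dH, p[[sprintf("blk%d_c1_W", i)]], bc$c1)
    g[[sprintf("blk%d_c1_W", i)]] <- b1$dW
    g[[sprintf("blk%d_c1_b", i)]] <- b1$db
    bs <- conv1d_bwd(dS, p[[sprintf("blk%d_sc_W", i)]], bc$sc)
    g[[sprintf("blk%d_sc_W", i)]] <- bs$dW
    g[[sprintf("blk%d_sc_b", i)]] <- bs$db
    dA <- b1$dX + bs$dX
  }
  dA <- dA * cache$stem$mask
  bst <- conv1d_bwd(dA, p$stem_W, cache$stem$conv)
  g$stem_W <- bst$dW
  g$stem_b <- bst$db
  g[names(p)]
}

# -- Adam ---------------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Embed views into the contrastive space
#'
#' Convenience wrapper producing an embedding batch: unit-norm projections
#' `z`, backbone representations `h`, and the view-to-source index map.
#' Deterministic for fixed weights (the encoder has no stochastic layers).
#'
#' @param views array `[n x channels x timesteps]`.
#' @param model encoder model.
#' @param view_to_source integer vector mapping each view row to its source
#'   segment (defaults to identity).
#' @param d optional matrix of domain feature rows aligned to views.
#' @return list of class `embedding_batch` with `z`, `h`, `view_to_source`,
#'   `d`.
#' @export
encode_project <- function(views, model, view_to_source = seq_len(dim(views)[1L]),
                           d = NULL) {
  fw <- encoder_forward(model, views, with_cache = FALSE)
  structure(list(z = fw$z, h = fw$h,
                 view_to_source = as.integer(view_to_source), d = d),
            class = "embedding_batch")
}
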