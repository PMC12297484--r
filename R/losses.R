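# Instance-level contrastive losses: the InfoNCE form, domain-feature
# nearest-neighbour positive selection, and the multi-positive instance loss
# whose denominator pairs each positive with the pruned negative set only.
# Analytic gradients with respect to the embeddings are returned alongside
# the loss values so the trainer can backpropagate without autodiff.

#' InfoNCE loss for a single anchor
#'
#' `-log( exp(zi.zp / tau) / (exp(zi.zp / tau) + sum_n exp(zi.zn / tau)) )`,
#' computed with a max-shifted log-sum-exp. With an empty negative set the
#' denominator equals the numerator and the loss is 0.
#'
#' @param zi,zp unit-norm anchor and positive vectors.
#' @param negatives matrix of unit-norm negative rows (possibly 0-row).
#' @param tau temperature, > 0.
#' @return non-negative scalar.
#' @export
info_nce <- function(zi, zp, negatives = NULL, tau = 0.1) {
  if (tau <= 0) stop("tau must be positive")
  pos <- sum(zi * zp) / tau
  if (is.null(negatives) || NROW(negatives) == 0L) return(0)
  negs <- as.matrix(negatives) %*% zi / tau
  -(pos - logsumexp(c(pos, negs)))
}

#' Domain-feature nearest neighbours of an anchor view
#'
#' Among all views in the batch except the anchor and its sibling view
#' (the augmentation partner, which is already the original positive),
#' returns the `count` views with the smallest Euclidean distance in domain
#' feature space. Ties are broken by ascending view index. Because the two
#' views of a segment share one domain feature vector, the top-2 are
#' normally the two views of the nearest other source segment.
#'
#' @param anchor view index.
#' @param batch an `embedding_batch` carrying aligned `d` rows.
#' @param count number of neighbours (default 2, the two most similar views).
#' @return integer vector of view indices, length `count`.
#' @export
select_domain_neighbors <- function(anchor, batch, count = 2L) {
  if (is.null(batch$d)) stop("neighbour error: batch carries no domain features")
  src <- batch$view_to_source
  if (length(unique(src)) < 2L) stop("neighbour error: need at least 2 source segments")
  sib <- which(src == src[anchor])
  cand <- setdiff(seq_along(src), sib)
  di <- batch$d[anchor, ]
  dist <- sqrt(rowSums((batch$d[cand, , drop = FALSE] -
                          matrix(di, length(cand), length(di), byrow = TRUE))^2))
  cand[order(dist, cand)][seq_len(min(count, length(cand)))]
}

#' Per-anchor positive / neighbour / negative assignment
#'
#' For each anchor view `i`: the sibling view `p`, the domain neighbours
#' `S(i)`, the positive set `P(i) = {p} union S(i)`, and the negative set
#' `N*(i)` = all other views excluding the anchor, its sibling, and `S(i)`.
#'
#' @param batch an `embedding_batch` with `d` rows.
#' @param n_neighbors neighbours per anchor; 0 disables domain guidance
#'   (plain instance discrimination, `P(i) = {p}`).
#' @return list of class `pair_assignment`: per anchor, `p`, `S`, `P`, `Nstar`.
#' @export
assign_pairs <- function(batch, n_neighbors = 2L) {
  src <- batch$view_to_source
  nv <- length(src)
  lapply(seq_len(nv), function(i) {
    sibs <- setdiff(which(src == src[i]), i)
    if (length(sibs) != 1L) stop("assignment error: each source needs exactly two views")
    S <- if (n_neighbors > 0L) select_domain_neighbors(i, batch, n_neighbors) else integer(0)
    P <- c(sibs, S)
    Nstar <- setdiff(seq_len(nv), c(i, P))
    list(p = sibs, S = S, P = P, Nstar = Nstar)
  })
}

#' Multi-positive instance-level loss (and its embedding gradient)
#'
#' For each anchor `i`, averages over positives `p* in P(i)` the term
#' `-log( exp(zi.zp*/tau) / (exp(zi.zp*/tau) + sum_{n in N*(i)} exp(zi.zn/tau)) )`
#' — each positive's denominator contains only that positive and the pruned
#' negatives — then takes the mean over anchors. With `P(i) = {p}` for every
#' anchor this reduces exactly to the batch InfoNCE loss.
#'
#' @param batch an `embedding_batch` (unit-norm `z` rows).
#' @param pairs a `pair_assignment` from [assign_pairs()].
#' @param tau temperature, > 0.
#' @param with_grad also return `dz`, the gradient of the loss w.r.t. `z`.
#' @return scalar loss, or `list(loss, dz)` when `with_grad = TRUE`.
#' @export
instance_loss <- function(batch, pairs, tau = 0.1, with_grad = FALSE) {
  if (tau <= 0) stop("tau must be positive")
  Z <- batch$z
  nv <- nrow(Z)
  if (length(pairs) != nv) stop("assignment error: pairs inconsistent with batch")
  S <- Z %*% t(Z) / tau
  total <- 0
  G <- if (with_grad) matrix(0, nv, nv)
  for (i in seq_len(nv)) {
    P <- pairs[[i]]$P
    if (!length(P)) stop("assignment error: empty positive set for anchor ", i)
    Nstar <- pairs[[i]]$Nstar
    negs <- S[i, Nstar]
    for (p in P) {
      lse <- logsumexp(c(S[i, p], negs))
      total <- total + (lse - S[i, p]) / length(P)
      if (with_grad) {
        w <- 1 / (nv * length(P))
        q <- exp(c(S[i, p], negs) - lse)
        G[i, p] <- G[i, p] + w * (q[1] - 1) / tau
        if (length(Nstar)) {
          G[i, Nstar] <- G[i, Nstar] + w * q[-1] / tau
        }
      }
    }
  }
  loss <- total / nv
  if (!with_grad) return(loss)
  dz <- G %*% Z + t(G) %*% Z
  list(loss = loss, dz = dz)
}
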