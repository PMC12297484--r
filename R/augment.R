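#' Augmentation specification
#'
#' The modality-agnostic view-generation pipeline for contrastive training:
#' temporal jittering (circular shift), per-channel amplitude scaling,
#' magnitude warping by a smooth random curve, additive Gaussian noise, and
#' cutout. Transforms are applied in that fixed order, each with an
#' independent application probability, so a single seeded random stream
#' yields reproducible view pairs.
#'
#' The defaults are sized to the nuisance ranges of the synthetic generator
#' (subject gain roughly 0.5-2x, additive noise s.d. up to 0.4): scaling and
#' noise magnitudes of that order make the contrastive task demand invariance
#' to exactly the nuisance the data carries.
#'
#' @param jitter_max maximum circular shift, in samples.
#' @param scaling_sd s.d. of the per-channel multiplicative factor
#'   (factor ~ N(1, sd^2)).
#' @param warp_knots number of interior knots of the magnitude-warp curve
#'   (>= 2).
#' @param warp_sd s.d. of knot values around 1.
#' @param noise_sd s.d. of additive white Gaussian noise.
#' @param cutout_frac fraction of the window zeroed by cutout, in `[0, 1)`.
#' @param apply_prob named or scalar application probability per transform.
#' @return An `augmentation_spec` list.
#' @export
augmentation_spec <- function(jitter_max = 100L, scaling_sd = 0.35,
                              warp_knots = 4L, warp_sd = 0.2,
                              noise_sd = 0.2, cutout_frac = 0.15,
                              apply_prob = 0.5) {
  stopifnot(scaling_sd >= 0, warp_sd >= 0, noise_sd >= 0,
            cutout_frac >= 0, cutout_frac < 1, warp_knots >= 2L)
  kinds <- c("jitter", "scaling", "magnitude_warp", "gaussian_noise", "cutout")
  if (length(apply_prob) == 1L) {
    apply_prob <- stats::setNames(rep(apply_prob, 5L), kinds)
  }
  if (!all(kinds %in% names(apply_prob))) stop("apply_prob must cover all transforms")
  structure(list(jitter_max = as.integer(jitter_max), scaling_sd = scaling_sd,
                 warp_knots = as.integer(warp_knots), warp_sd = warp_sd,
                 noise_sd = noise_sd, cutout_frac = cutout_frac,
                 apply_prob = apply_prob[kinds]),
            class = "augmentation_spec")
}

#' Apply one stochastic transform
#'
#' All transforms preserve the input shape. Randomness is drawn from the
#' current RNG stream; callers wrap invocations in a seeded context.
#'
#' @param x matrix `[channels x timesteps]`.
#' @param kind one of `"jitter"`, `"scaling"`, `"magnitude_warp"`,
#'   `"gaussian_noise"`, `"cutout"`.
#' @param spec an [augmentation_spec()] providing the parameters.
#' @return transformed matrix of identical shape.
#' @export
apply_transform <- function(x, kind, spec) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  switch(kind,
    jitter = {
      s <- sample.int(2L * spec$jitter_max + 1L, 1L) - spec$jitter_max - 1L
      if (s == 0L) x else x[, ((seq_len(n) - 1L - s) %% n) + 1L, drop = FALSE]
    },
    scaling = {
      fac <- stats::rnorm(nrow(x), 1, spec$scaling_sd)
      x * fac
    },
    magnitude_warp = {
      knots_t <- seq(0, 1, length.out = spec$warp_knots + 2L)
      out <- x
      for (ch in seq_len(nrow(x))) {
        knots_v <- c(1, stats::rnorm(spec$warp_knots, 1, spec$warp_sd), 1)
        curve <- stats::spline(knots_t, knots_v,
                               xout = (seq_len(n) - 1) / (n - 1))$y
        out[ch, ] <- x[ch, ] * curve
      }
      out
    },
    gaussian_noise = x + matrix(stats::rnorm(length(x), 0, spec$noise_sd),
                                nrow(x), n),
    cutout = {
      w <- round(spec$cutout_frac * n)
      if (w == 0L) x else {
        start <- sample.int(n - w + 1L, 1L)
        x[, start:(start + w - 1L)] <- 0
        x
      }
    },
    stop("spec error: unknown transform kind '", kind, "'"))
}

#' Sample a pair of augmented views
#'
#' Draws two independent transform chains (fixed order jitter, scaling,
#' magnitude warp, Gaussian noise, cutout; each applied with its configured
#' probability) from the current RNG stream and applies them to the same
#' segment. Both views inherit the source segment's identity — and therefore
#' its domain feature vector — which is the pairing contract the
#' domain-guided losses rely on.
#'
#' @param x matrix `[channels x timesteps]`.
#' @param spec an [augmentation_spec()].
#' @return list of two matrices shaped like `x`.
#' @export
sample_view_pair <- function(x, spec) {
  one_view <- function() {
    v <- x
    for (kind in names(spec$apply_prob)) {
      if (stats::runif(1) < spec$apply_prob[[kind]]) {
        v <- apply_transform(v, kind, spec)
      }
    }
    v
  }
  list(one_view(), one_view())
}
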