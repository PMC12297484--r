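# Energy-based beat detector for quasi-periodic signals: detrend, square,
# moving-window integrate, adaptive threshold, refractory period — the
# classic QRS-detector recipe reduced to its modality-agnostic core.

moving_mean <- function(v, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  n <- length(v)
  vp <- c(rev(v[seq_len(min(half, n))]), v, rev(v[seq.int(max(1L, n - half + 1L), n)]))
  cs <- cumsum(c(0, vp))
  (cs[(w + 1L):(w + n)] - cs[1L:n]) / w
}

#' Detect dominant periodic peaks in one segment
#'
#' Band-limits the reference channel by moving-average detrending, squares,
#' integrates over a short moving window, thresholds adaptively at a fraction
#' of the maximum integrated energy, and enforces a refractory period.
#' Detected peak positions are refined to the local energy maximum of the
#' squared signal.
#'
#' @param segment matrix `[channels x timesteps]` with an `fs` attribute, or a
#'   numeric vector.
#' @param fs sampling rate in Hz; defaults to the `fs` attribute.
#' @param ref_channel channel used for detection (default 1).
#' @param refractory_s minimum spacing between detections, seconds
#'   (default 0.2).
#' @param integrate_s energy integration window, seconds (default 0.15).
#' @param threshold_frac adaptive threshold as a fraction of the maximum
#'   integrated energy (default 0.3).
#' @return strictly increasing integer vector of peak sample indices; empty
#'   when nothing crosses the threshold (e.g. a flat signal) or when the
#'   segment is shorter than one refractory period.
#' @export
detect_beats <- function(segment, fs = attr(segment, "fs"), ref_channel = 1L,
                         refractory_s = 0.2, integrate_s = 0.15,
                         threshold_frac = 0.3) {
  if (is.null(fs)) stop("sampling rate unknown; supply fs")
  v <- if (is.matrix(segment)) segment[ref_channel, ] else as.numeric(segment)
  n <- length(v)
  refr <- round(refractory_s * fs)
  if (n < refr) return(integer(0))
  v <- v - moving_mean(v, round(0.6 * fs))
  # short moving-average low-pass: beat energy sits well below ~10 Hz while
  # broadband noise is attenuated by the window length
  v <- moving_mean(v, round(0.08 * fs))
  energy <- moving_mean(v^2, round(integrate_s * fs))
  emax <- max(energy)
  if (emax <= 1e-20) return(integer(0))  # flat signal (up to rounding)
  # rate-adaptive refractory: the dominant period of the energy envelope
  # (first autocorrelation peak past the base refractory) guards against
  # counting delayed intra-beat components as extra beats
  ec <- energy - mean(energy)
  max_lag <- min(n - 1L, round(2.5 * fs))
  ac <- stats::acf(ec, lag.max = max_lag, plot = FALSE)$acf[-1L]
  lo <- max(refr, round(0.25 * fs))
  if (max_lag > lo + 2L) {
    seg <- ac[lo:max_lag]
    pk <- which(seg >= c(seg[1] + 1, seg[-length(seg)]) &
                  seg >= c(seg[-1], seg[length(seg)] + 1) & seg > 0.15)
    if (length(pk)) {
      period <- lo + pk[1L] - 1L
      refr <- max(refr, round(0.5 * period))
    }
  }
  thr <- threshold_frac * emax
  # local maxima above threshold
  cand <- which(energy > thr &
                  energy >= c(-Inf, energy[-n]) &
                  energy >= c(energy[-1], -Inf))
  if (!length(cand)) return(integer(0))
  # greedy refractory suppression, strongest first (ties: earliest)
  cand <- cand[order(-energy[cand], cand)]
  kept <- integer(0)
  for (p in cand) {
    if (!length(kept) || all(abs(kept - p) >= refr)) kept <- c(kept, p)
  }
  # refine to the local squared-signal energy peak
  fine <- moving_mean(v^2, round(0.05 * fs))
  half <- round(0.08 * fs)
  refined <- vapply(kept, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    as.integer(lo + which.max(fine[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # refractory can be re-violated after refinement; suppress again
  if (length(refined) > 1L) {
    out <- refined[1L]
    for (p in refined[-1L]) {
      if (p - out[length(out)] >= refr) out <- c(out, p)
      else if (fine[p] > fine[out[length(out)]]) out[length(out)] <- p
    }
    refined <- out
  }
  as.integer(refined)
}
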