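#' Synthetic quasi-periodic waveform configuration
#'
#' Describes a labeled, subject-structured synthetic dataset of pulse-like
#' signals. Each class is defined by a rhythm rate (beats/min), a
#' beat-to-beat interval jitter, and a beat morphology (width of the main
#' bump and amplitude of a delayed secondary bump). Each subject carries
#' nuisance parameters — a multiplicative amplitude gain, an additive
#' baseline offset, and an additive Gaussian noise level — applied after the
#' class component. Domain features (rate, interval variability, spectral
#' content) therefore carry class signal, while raw amplitude statistics
#' carry subject signal: the failure mode where instance-discrimination
#' pretraining latches onto subject identity is reproducible on purpose.
#'
#' Per-class parameters are spread linearly between the extremes of each
#' range; `class_sep` scales every class parameter's deviation from the
#' across-class midpoint, so `class_sep = 0` makes all classes identical and
#' larger values spread them further apart.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_subjects number of subjects (>= 3).
#' @param segments_per_subject segments generated per subject; classes are
#'   cycled so each subject sees every class when
#'   `segments_per_subject >= n_classes`.
#' @param channels number of identical-process channels (independent noise).
#' @param fs sampling rate, Hz (>= 20).
#' @param window_s segment duration, seconds.
#' @param class_sep non-negative scalar scaling between-class parameter
#'   spread (default 1 = the documented separable preset).
#' @param rate_range beats/min range spanned by the classes (class mean
#'   rates; each subject additionally carries a resting-rate factor).
#' @param jitter_range per-beat interval jitter s.d. range, seconds.
#' @param width_range main bump width range, seconds.
#' @param second_amp_range relative amplitude range of the delayed secondary
#'   bump.
#' @param rate_factor_range per-subject multiplicative resting-rate factor
#'   range (uniform): each individual's rhythm runs at their own pace, so the
#'   mean rate is partially subject-confounded while interval irregularity
#'   and morphology stay class-determined.
#' @param gain_range per-subject multiplicative gain range (uniform).
#' @param baseline_sd per-subject baseline offset s.d.
#' @param noise_range per-subject additive noise s.d. range (uniform).
#' @param seed integer seed; identical configs (including seed) generate
#'   bit-identical datasets.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_classes = 4L, n_subjects = 12L,
                         segments_per_subject = 10L, channels = 1L,
                         fs = 100, window_s = 10, class_sep = 1,
                         rate_range = c(60, 90), jitter_range = c(0.01, 0.12),
                         width_range = c(0.04, 0.085),
                         second_amp_range = c(0, 0.9),
                         rate_factor_range = c(0.85, 1.15),
                         gain_range = c(0.5, 2.0), baseline_sd = 0.5,
                         noise_range = c(0.05, 0.40), seed = 7L) {
  cfg <- list(n_classes = as.integer(n_classes),
              n_subjects = as.integer(n_subjects),
              segments_per_subject = as.integer(segments_per_subject),
              channels = as.integer(channels), fs = fs, window_s = window_s,
              class_sep = class_sep, rate_range = rate_range,
              jitter_range = jitter_range, width_range = width_range,
              second_amp_range = second_amp_range,
              rate_factor_range = rate_factor_range, gain_range = gain_range,
              baseline_sd = baseline_sd, noise_range = noise_range,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_classes < 2L) stop("configuration error: n_classes must be >= 2")
  if (cfg$n_subjects < 3L) stop("configuration error: n_subjects must be >= 3")
  if (cfg$segments_per_subject < 1L) stop("configuration error: segments_per_subject must be positive")
  if (cfg$channels < 1L) stop("configuration error: channels must be positive")
  if (cfg$fs < 20) stop("configuration error: fs must be >= 20 Hz")
  if (cfg$window_s <= 0) stop("configuration error: window_s must be positive")
  if (cfg$class_sep < 0) stop("configuration error: class_sep must be non-negative")
  # window must hold at least one beat period at the slowest class rate
  slow_rate <- min(class_parameter(cfg$rate_range, cfg$n_classes, cfg$class_sep)) *
    min(cfg$rate_factor_range)
  if (cfg$window_s < 60 / slow_rate) {
    stop("configuration error: window shorter than one beat period at the slowest class rate")
  }
  invisible(cfg)
}

# Linear spread of one parameter across classes, scaled about the midpoint.
class_parameter <- function(range, n_classes, class_sep) {
  mid <- mean(range)
  base <- seq(range[1], range[2], length.out = n_classes)
  mid + class_sep * (base - mid)
}

# Beat kernel: main positive Gaussian bump plus a delayed, wider secondary
# bump — a smooth abstraction of a pulse waveform, not a clinical template.
beat_kernel <- function(width, second_amp, fs) {
  half <- 0.4
  t <- seq(-half, half, by = 1 / fs)
  k <- exp(-t^2 / (2 * width^2)) +
    second_amp * exp(-(t - 0.15)^2 / (2 * (1.8 * width)^2))
  k
}

#' Generate a synthetic subject-structured dataset
#'
#' Each segment is the sum of (a) a class component — an impulse train at the
#' class rhythm rate (with class-dependent interval jitter) convolved with the
#' class morphology kernel — and (b) subject nuisance: multiplicative gain,
#' additive baseline, and white Gaussian noise. Ground-truth beat sample
#' indices (the impulse locations) and all generating parameters are retained
#' in the returned dataset.
#'
#' @param config a [synth_config()].
#' @return A [segment_dataset()] with labels, per-segment `beats` metadata and
#'   a `truth` data.frame of generating parameters.
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  cfg <- config
  n <- cfg$n_subjects * cfg$segments_per_subject
  len <- round(cfg$fs * cfg$window_s)
  rate_c <- class_parameter(cfg$rate_range, cfg$n_classes, cfg$class_sep)
  jit_c <- pmax(class_parameter(cfg$jitter_range, cfg$n_classes, cfg$class_sep), 0)
  wid_c <- pmax(class_parameter(cfg$width_range, cfg$n_classes, cfg$class_sep), 0.01)
  amp_c <- pmax(class_parameter(cfg$second_amp_range, cfg$n_classes, cfg$class_sep), 0)

  with_rng(derive_seed(cfg$seed, "generator"), {
    ratef_s <- stats::runif(cfg$n_subjects, cfg$rate_factor_range[1],
                            cfg$rate_factor_range[2])
    gain_s <- stats::runif(cfg$n_subjects, cfg$gain_range[1], cfg$gain_range[2])
    base_s <- stats::rnorm(cfg$n_subjects, 0, cfg$baseline_sd)
    noise_s <- stats::runif(cfg$n_subjects, cfg$noise_range[1], cfg$noise_range[2])

    X <- array(0, dim = c(n, cfg$channels, len))
    y <- integer(n)
    subject <- character(n)
    beats <- vector("list", n)
    truth <- vector("list", n)
    idx <- 0L
    for (s in seq_len(cfg$n_subjects)) {
      labels <- rep(seq_len(cfg$n_classes) - 1L,
                    length.out = cfg$segments_per_subject)
      for (g in seq_len(cfg$segments_per_subject)) {
        idx <- idx + 1L
        cls <- labels[g] + 1L
        ibi <- 60 / (rate_c[cls] * ratef_s[s])
        # beat times: jittered renewal process covering the window
        t0 <- stats::runif(1, 0, ibi)
        times <- t0
        while (TRUE) {
          gap <- ibi + stats::rnorm(1, 0, jit_c[cls])
          gap <- max(gap, 0.25 * ibi)
          nt <- times[length(times)] + gap
          if (nt >= cfg$window_s) break
          times <- c(times, nt)
        }
        beat_idx <- pmin(pmax(round(times * cfg$fs) + 1L, 1L), len)
        impulse <- numeric(len)
        impulse[beat_idx] <- 1
        kern <- beat_kernel(wid_c[cls], amp_c[cls], cfg$fs)
        clean <- stats::convolve(impulse, rev(kern), type = "open")
        off <- (length(kern) - 1L) %/% 2L
        clean <- clean[(off + 1L):(off + len)]
        for (ch in seq_len(cfg$channels)) {
          X[idx, ch, ] <- gain_s[s] * clean + base_s[s] +
            stats::rnorm(len, 0, noise_s[s])
        }
        y[idx] <- labels[g]
        subject[idx] <- sprintf("subj%03d", s)
        beats[[idx]] <- as.integer(beat_idx)
        truth[[idx]] <- data.frame(rate_bpm = rate_c[cls] * ratef_s[s],
                                   class_rate_bpm = rate_c[cls],
                                   subject_rate_factor = ratef_s[s],
                                   rr_jitter_sd = jit_c[cls],
                                   morph_width = wid_c[cls],
                                   second_amp = amp_c[cls],
                                   gain = gain_s[s], baseline = base_s[s],
                                   noise_sd = noise_s[s])
      }
    }
    segment_dataset(X = X, fs = cfg$fs, subject = subject, y = y,
                    beats = beats, truth = do.call(rbind, truth),
                    attrs = list(generator = "wearssl-synth",
                                 config_digest = config_digest(unclass(cfg)),
                                 seed = cfg$seed))
  })
}
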