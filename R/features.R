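# Domain feature banks: rhythm/morphology ("old-school" HRV-style
# statistics), spectral band powers, and motion statistics. These are the
# handcrafted descriptors d_i that guide positive-pair selection and
# prototype clustering.

# Welch-style averaged modified periodogram: Hann window, 50% overlap.
# Returns one-sided density so that sum(psd) * df ~= signal variance.
welch_psd <- function(v, fs, nperseg = min(length(v), 512L)) {
  n <- length(v)
  nperseg <- min(as.integer(nperseg), n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- v[s:(s + nperseg - 1L)] * w
    sp <- abs(stats::fft(seg))^2 / (fs * u)
    acc <- acc + sp[seq_len(nfreq)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1L) * fs / nperseg, psd = psd * dbl,
       df = fs / nperseg)
}

#' Spectral band-power features
#'
#' Absolute and relative power per channel and band from a Welch-averaged
#' modified periodogram (Hann window, 50% overlap). Relative power divides by
#' the total power between the lowest and highest band edge, so when the
#' bands tile that range the relative powers sum to 1. A zero signal yields
#' zero absolute and (by guard) zero relative power.
#'
#' @param segment matrix `[channels x timesteps]` or numeric vector.
#' @param bands list of `c(low, high)` pairs in Hz, all below Nyquist.
#' @param fs sampling rate; defaults to the `fs` attribute.
#' @return named numeric vector, per-channel blocks of
#'   `chN_bp_<low>_<high>_{abs,rel}`.
#' @export
bandpower_features <- function(segment, bands, fs = attr(segment, "fs")) {
  if (is.null(fs)) stop("sampling rate unknown; supply fs")
  if (!length(bands)) stop("spec error: empty band list")
  x <- if (is.matrix(segment)) segment else matrix(segment, nrow = 1L)
  for (b in bands) {
    if (length(b) != 2L || b[1] < 0 || b[2] <= b[1] || b[2] > fs / 2 + 1e-9) {
      stop("spec error: bands must satisfy 0 <= low < high <= Nyquist")
    }
  }
  lo_all <- min(vapply(bands, `[`, 0, 1L))
  hi_all <- max(vapply(bands, `[`, 0, 2L))
  out <- c()
  for (ch in seq_len(nrow(x))) {
    w <- welch_psd(x[ch, ], fs)
    total <- sum(w$psd[w$freq >= lo_all & w$freq < hi_all]) * w$df
    for (b in bands) {
      absp <- sum(w$psd[w$freq >= b[1] & w$freq < b[2]]) * w$df
      relp <- if (total > 1e-300) absp / total else 0
      nm <- sprintf("ch%d_bp_%g_%g", ch, b[1], b[2])
      out <- c(out, stats::setNames(c(absp, relp), paste0(nm, c("_abs", "_rel"))))
    }
  }
  out
}

rhythm_feature_names <- c("n_beats", "rate_bpm", "ibi_mean", "ibi_median",
                          "ibi_min", "ibi_max", "ibi_sdnn", "ibi_rmssd",
                          "ibi_cv", "ibi_cvsd", "ibi_pnn50", "peak_amp_mean",
                          "peak_amp_sd", "template_corr", "beat_coverage")

#' Rhythm and morphology features over detected beats
#'
#' The heart-rate-variability-style bank: inter-beat interval statistics
#' (mean/median/min/max, SDNN, RMSSD, a pNN50-style proportion of successive
#' differences exceeding 50 ms, rate in beats/min, and the rate-normalized
#' coefficients of variation CVNN = SDNN/mean and CVSD = RMSSD/mean), peak
#' amplitude
#' statistics, a beat-template correlation quality index (mean pairwise
#' Pearson correlation of beat-centred windows), and the fraction of the
#' window spanned by detections. SDNN and the amplitude s.d. use population
#' normalization. Features undefined for the given beat count (e.g. interval
#' statistics with fewer than two beats) are returned as `NA` sentinels and
#' mean-imputed at the feature-matrix level.
#'
#' @param segment matrix `[channels x timesteps]` or vector.
#' @param beats integer peak indices from [detect_beats()].
#' @param fs sampling rate; defaults to the `fs` attribute.
#' @param ref_channel channel the beats refer to.
#' @return named numeric vector of fixed length and order
#'   (`rhythm_feature_names`).
#' @export
rhythm_morphology_features <- function(segment, beats,
                                       fs = attr(segment, "fs"),
                                       ref_channel = 1L) {
  if (is.null(fs)) stop("sampling rate unknown; supply fs")
  v <- if (is.matrix(segment)) segment[ref_channel, ] else as.numeric(segment)
  n <- length(v)
  f <- stats::setNames(rep(NA_real_, length(rhythm_feature_names)),
                       rhythm_feature_names)
  f["n_beats"] <- length(beats)
  if (length(beats) >= 1L) {
    amps <- v[beats]
    f["peak_amp_mean"] <- mean(amps)
    f["peak_amp_sd"] <- pop_sd(amps)
    f["beat_coverage"] <- (beats[length(beats)] - beats[1L]) / n
  }
  if (length(beats) >= 2L) {
    ibi <- diff(beats) / fs
    f["ibi_mean"] <- mean(ibi)
    f["ibi_median"] <- stats::median(ibi)
    f["ibi_min"] <- min(ibi)
    f["ibi_max"] <- max(ibi)
    f["ibi_sdnn"] <- pop_sd(ibi)
    f["ibi_cv"] <- pop_sd(ibi) / mean(ibi)
    f["rate_bpm"] <- 60 / mean(ibi)
    if (length(ibi) >= 2L) {
      dd <- diff(ibi)
      f["ibi_rmssd"] <- sqrt(mean(dd^2))
      f["ibi_cvsd"] <- sqrt(mean(dd^2)) / mean(ibi)
      f["ibi_pnn50"] <- mean(abs(dd) > 0.05)
    }
    f["template_corr"] <- beat_template_correlation(v, beats, fs)
  }
  f
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

beat_template_correlation <- function(v, beats, fs, half_s = 0.2) {
  half <- round(half_s * fs)
  wins <- lapply(beats, function(b) {
    if (b - half >= 1L && b + half <= length(v)) v[(b - half):(b + half)] else NULL
  })
  wins <- wins[!vapply(wins, is.null, TRUE)]
  if (length(wins) < 2L) return(NA_real_)
  m <- do.call(cbind, wins)
  cc <- suppressWarnings(stats::cor(m))
  vals <- cc[upper.tri(cc)]
  # constant windows give NA correlations; identical constants count as 1
  if (anyNA(vals)) {
    const <- apply(m, 2, function(w) pop_sd(w) < 1e-12)
    if (all(const)) return(1)
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_real_)
  }
  mean(vals)
}

motion_feature_names <- c("ax_mean", "ax_sd", "ax_range", "ay_mean", "ay_sd",
                          "ay_range", "az_mean", "az_sd", "az_range",
                          "vm_mean", "vm_sd", "dom_freq_hz", "dom_freq_power",
                          "spectral_entropy", "roll_deg", "pitch_deg")

#' Motion features for 3-axis accelerometry
#'
#' Temporal, spectral and angular statistics for a 3-channel segment
#' interpreted as x/y/z acceleration: per-axis mean, population s.d. and
#' range; vector-magnitude mean and s.d.; dominant frequency and its power
#' from the axis-averaged Welch periodogram of the demeaned signals; spectral
#' entropy (normalized to `[0, 1]`); and mean roll/pitch from the gravity
#' direction. Angle convention: `roll = atan2(ay, az)`,
#' `pitch = atan2(ax, sqrt(ay^2 + az^2))`, both in degrees, so a gravity
#' vector of `(0, 0, 1)` gives roll = pitch = 0 and `(1, 0, 0)` gives
#' pitch = 90.
#'
#' @param segment matrix `[3 x timesteps]`.
#' @param fs sampling rate; defaults to the `fs` attribute.
#' @return named numeric vector of fixed length and order
#'   (`motion_feature_names`).
#' @export
motion_features <- function(segment, fs = attr(segment, "fs")) {
  if (is.null(fs)) stop("sampling rate unknown; supply fs")
  if (!is.matrix(segment) || nrow(segment) != 3L) {
    stop("modality error: motion features require a 3-channel segment")
  }
  mns <- rowMeans(segment)
  sds <- apply(segment, 1, pop_sd)
  rngs <- apply(segment, 1, function(r) max(r) - min(r))
  vm <- sqrt(colSums(segment^2))
  psd <- NULL
  for (ch in 1:3) {
    w <- welch_psd(segment[ch, ] - mns[ch], fs)
    psd <- if (is.null(psd)) w$psd else psd + w$psd
  }
  psd <- psd / 3
  freq <- welch_psd(segment[1, ] - mns[1], fs)$freq
  imax <- which.max(psd)
  p <- psd / max(sum(psd), 1e-300)
  p <- p[p > 0]
  sent <- if (length(p) > 1L) -sum(p * log(p)) / log(length(psd)) else 0
  stats::setNames(
    c(mns[1], sds[1], rngs[1], mns[2], sds[2], rngs[2], mns[3], sds[3],
      rngs[3], mean(vm), pop_sd(vm), freq[imax],
      if (sum(psd) > 1e-300) psd[imax] * (freq[2] - freq[1]) else 0,
      sent, atan2(mns[2], mns[3]) * 180 / pi,
      atan2(mns[1], sqrt(mns[2]^2 + mns[3]^2)) * 180 / pi),
    motion_feature_names)
}

#' Domain feature matrix
#'
#' Container for per-segment domain feature vectors with the normalization
#' statistics needed to apply a fitted z-transform to held-out data.
#'
#' @param values numeric matrix `[segments x features]`.
#' @param feature_names ordered column labels.
#' @param modality tag (`"cardiac"`, `"spectral"`, `"motion"`, ...).
#' @param segment_id optional row identifiers.
#' @param norm statistics list (`mean`, `sd`, `impute_mean`) or `NULL` before
#'   normalization.
#' @return A `domain_feature_matrix`.
#' @export
domain_feature_matrix <- function(values, feature_names = colnames(values),
                                  modality = "generic", segment_id = NULL,
                                  norm = NULL) {
  values <- as.matrix(values)
  if (is.null(feature_names)) stop("feature_names required")
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 modality = modality, segment_id = segment_id, norm = norm),
            class = "domain_feature_matrix")
}

#' @export
print.domain_feature_matrix <- function(x, ...) {
  cat(sprintf("domain_feature_matrix: %d segments x %d features (%s)%s\n",
              nrow(x$values), ncol(x$values), x$modality,
              if (is.null(x$norm)) "" else ", z-normalized"))
  invisible(x)
}

default_bands <- function(modality, fs) {
  bands <- switch(modality,
                  cardiac = list(c(0.5, 2), c(2, 5), c(5, 10), c(10, 20)),
                  spectral = list(c(0.5, 4), c(4, 8), c(8, 13), c(13, 30)),
                  stop("no default bands for modality ", modality))
  Filter(function(b) b[2] <= fs / 2, bands)
}

#' Extract the domain feature bank for a dataset
#'
#' Applies the modality's feature bank to every segment: `"cardiac"` runs the
#' beat detector and the rhythm/morphology bank plus low-frequency band
#' powers; `"spectral"` computes band powers over classic EEG-style bands;
#' `"motion"` computes the 3-axis motion bank. Extraction is deterministic.
#'
#' @param dataset a [segment_dataset()].
#' @param modality `"cardiac"`, `"spectral"` or `"motion"`.
#' @param bands optional band list overriding the modality default.
#' @return An un-normalized [domain_feature_matrix()]; pass it to
#'   [znormalize_features()].
#' @export
extract_domain_features <- function(dataset,
                                    modality = c("cardiac", "spectral", "motion"),
                                    bands = NULL) {
  modality <- match.arg(modality)
  n <- n_segments(dataset)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    seg <- get_segment(dataset, i)
    rows[[i]] <- switch(modality,
      cardiac = {
        beats <- detect_beats(seg)
        c(rhythm_morphology_features(seg, beats),
          bandpower_features(seg, bands %||% default_bands("cardiac", dataset$fs)))
      },
      spectral = bandpower_features(seg, bands %||% default_bands("spectral", dataset$fs)),
      motion = motion_features(seg))
  }
  values <- do.call(rbind, rows)
  domain_feature_matrix(values, colnames(values), modality = modality,
                        segment_id = dataset$segment_id)
}

#' Z-normalize a domain feature matrix
#'
#' Mean-imputes missing entries, then maps each feature to zero mean and unit
#' population standard deviation. When `stats` (from a fitting split) is
#' supplied, its imputation means and z-statistics are applied unchanged, so
#' held-out columns need not end up centred — the leak-free convention for
#' train/test protocols. Constant features (s.d. `< 1e-12`) map to zero.
#'
#' @param matrix a [domain_feature_matrix()].
#' @param stats optional statistics list from a previously normalized matrix
#'   (its `$norm` field).
#' @return the matrix with normalized `values` and `norm` statistics
#'   attached.
#' @export
znormalize_features <- function(matrix, stats = NULL) {
  v <- matrix$values
  all_na <- colSums(!is.na(v)) == 0L
  if (any(all_na) && is.null(stats)) {
    stop("feature error: all-NA feature column(s): ",
         paste(matrix$feature_names[all_na], collapse = ", "))
  }
  if (is.null(stats)) {
    imp <- colMeans(v, na.rm = TRUE)
    for (j in seq_len(ncol(v))) v[is.na(v[, j]), j] <- imp[j]
    mu <- colMeans(v)
    sd <- apply(v, 2, pop_sd)
    stats <- list(impute_mean = imp, mean = mu, sd = sd)
  } else {
    if (length(stats$mean) != ncol(v)) stop("feature error: stats dimension mismatch")
    for (j in seq_len(ncol(v))) v[is.na(v[, j]), j] <- stats$impute_mean[j]
  }
  sd_safe <- ifelse(stats$sd < 1e-12, 1, stats$sd)
  v <- sweep(sweep(v, 2, stats$mean), 2, sd_safe, "/")
  v[, stats$sd < 1e-12] <- 0
  out <- matrix
  out$values <- v
  out$norm <- stats
  out
}

#' Write / read feature tables as CSV
#'
#' The feature table round-trips as a CSV with a `segment_id` column followed
#' by one column per feature; normalization statistics go to a JSON sidecar.
#'
#' @param matrix a [domain_feature_matrix()].
#' @param path CSV path.
#' @param stats_path optional JSON path for normalization statistics.
#' @return `path`, invisibly.
#' @export
write_features <- function(matrix, path, stats_path = NULL) {
  dt <- data.table::as.data.table(matrix$values)
  dt <- cbind(data.table::data.table(
    segment_id = matrix$segment_id %||% sprintf("seg%05d", seq_len(nrow(matrix$values)))), dt)
  data.table::fwrite(dt, path)
  if (!is.null(stats_path) && !is.null(matrix$norm)) {
    jsonlite::write_json(c(matrix$norm, list(modality = matrix$modality,
                                             feature_names = matrix$feature_names)),
                         stats_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_features
#' @param modality tag recorded on the read matrix.
#' @export
read_features <- function(path, modality = "generic") {
  dt <- data.table::fread(path)
  ids <- dt$segment_id
  dt[, "segment_id" := NULL]
  domain_feature_matrix(as.matrix(dt), names(dt), modality = modality,
                        segment_id = ids)
}
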