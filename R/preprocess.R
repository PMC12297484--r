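#' Preprocessing specification
#'
#' Resampling, optional zero-phase band-pass filtering and per-channel
#' z-normalization — the standard conditioning applied to every wearable
#' modality before feature extraction or encoding.
#'
#' @param target_fs output sampling rate, Hz.
#' @param band optional `c(low, high)` pass band in Hz; must satisfy
#'   `0 < low < high < target_fs / 2`.
#' @param window_s output window length, seconds; the output always has
#'   `round(target_fs * window_s)` samples.
#' @param znorm_signal z-normalize each channel after filtering.
#' @param filter_order Butterworth order for the band-pass (applied
#'   forward-backward, so the effective order is doubled).
#' @return A `preprocess_spec` list.
#' @export
preprocess_spec <- function(target_fs, band = NULL, window_s,
                            znorm_signal = TRUE, filter_order = 4L) {
  if (!is.null(band)) {
    if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
        band[2] >= target_fs / 2) {
      stop("spec error: band must satisfy 0 < low < high < target_fs/2")
    }
  }
  structure(list(target_fs = target_fs, band = band, window_s = window_s,
                 znorm_signal = isTRUE(znorm_signal),
                 filter_order = as.integer(filter_order)),
            class = "preprocess_spec")
}

#' Preprocess one segment
#'
#' Resamples each channel to `spec$target_fs` (linear interpolation on the
#' segment's time base), applies a zero-phase Butterworth band-pass when a
#' band is given (`signal::filtfilt`), and per-channel z-normalizes when
#' flagged. Output length is exactly `round(target_fs * window_s)`.
#'
#' @param segment matrix `[channels x timesteps]` with an `fs` attribute (as
#'   returned by [get_segment()]), or a plain matrix with `fs` supplied.
#' @param spec a [preprocess_spec()].
#' @param fs input sampling rate; defaults to the segment's `fs` attribute.
#' @return matrix `[channels x round(target_fs * window_s)]` with updated
#'   `fs` attribute.
#' @export
preprocess <- function(segment, spec, fs = attr(segment, "fs")) {
  if (is.null(fs)) stop("input sampling rate unknown; supply fs")
  x <- if (is.matrix(segment)) segment else matrix(segment, nrow = 1L)
  n_in <- ncol(x)
  n_out <- round(spec$target_fs * spec$window_s)
  t_in <- (seq_len(n_in) - 1) / fs
  t_out <- (seq_len(n_out) - 1) / spec$target_fs
  if (max(t_out) > max(t_in) + 1e-9) {
    stop("spec error: requested window longer than the input segment")
  }
  out <- matrix(0, nrow(x), n_out)
  for (ch in seq_len(nrow(x))) {
    v <- stats::approx(t_in, x[ch, ], xout = t_out, rule = 2)$y
    if (!is.null(spec$band)) {
      # removing the mean first keeps the high-pass transient short
      v <- v - mean(v)
      bf <- signal::butter(spec$filter_order,
                           spec$band / (spec$target_fs / 2), type = "pass")
      v <- signal::filtfilt(bf, v)
    }
    if (spec$znorm_signal) {
      s <- stats::sd(v)
      v <- if (s < 1e-12) v - mean(v) else (v - mean(v)) / s
    }
    out[ch, ] <- v
  }
  structure(out, fs = spec$target_fs,
            subject = attr(segment, "subject"),
            label = attr(segment, "label"),
            segment_id = attr(segment, "segment_id"))
}

#' Preprocess every segment of a dataset
#'
#' Applies [preprocess()] segment-wise and reassembles the dataset (beat
#' metadata indices are rescaled to the new sampling rate).
#'
#' @param dataset a [segment_dataset()].
#' @param spec a [preprocess_spec()].
#' @return the preprocessed [segment_dataset()].
#' @export
preprocess_dataset <- function(dataset, spec) {
  n <- n_segments(dataset)
  n_out <- round(spec$target_fs * spec$window_s)
  X <- array(0, c(n, dim(dataset$X)[2L], n_out))
  for (i in seq_len(n)) {
    X[i, , ] <- preprocess(get_segment(dataset, i), spec, fs = dataset$fs)
  }
  beats <- dataset$beats
  if (!is.null(beats) && abs(spec$target_fs - dataset$fs) > 1e-9) {
    scale <- spec$target_fs / dataset$fs
    beats <- lapply(beats, function(b) {
      pmin(pmax(as.integer(round((b - 1L) * scale) + 1L), 1L), n_out)
    })
  }
  segment_dataset(X = X, fs = spec$target_fs, subject = dataset$subject,
                  y = dataset$y, segment_id = dataset$segment_id,
                  split = dataset$split, beats = beats, truth = dataset$truth,
                  attrs = c(dataset$attrs,
                            list(preprocess_digest = config_digest(unclass(spec)))))
}
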