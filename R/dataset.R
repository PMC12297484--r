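#' Segmented waveform dataset
#'
#' The package's central container: a stack of fixed-length multichannel
#' waveform segments with per-segment subject identifiers and optional class
#' labels, plus free-form attributes. Segments are stored as a dense numeric
#' array `X` of shape `[segments x channels x timesteps]`.
#'
#' @param X numeric array `[N x C x T]`, finite everywhere.
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param subject character or integer vector of length `N`; which individual
#'   each segment was recorded from.
#' @param y integer class labels in `0:(K-1)`, or `NA` for unlabeled segments.
#'   Defaults to all-`NA`.
#' @param segment_id unique identifiers; generated when omitted.
#' @param split optional per-segment tag in `c("train","val","test")`. When
#'   present, no subject may appear in more than one split.
#' @param beats optional list of integer vectors: ground-truth beat sample
#'   indices per segment (retained by the synthetic generator).
#' @param truth optional data.frame of generating parameters per segment.
#' @param attrs free-form metadata list (modality, preprocessing digest, ...).
#'
#' @return An object of class `segment_dataset`.
#' @export
segment_dataset <- function(X, fs, subject, y = NULL, segment_id = NULL,
                            split = NULL, beats = NULL, truth = NULL,
                            attrs = list()) {
  if (length(dim(X)) != 3L) stop("X must be a 3-d array [segments x channels x timesteps]")
  n <- dim(X)[1L]
  if (dim(X)[2L] < 1L) stop("at least one channel required")
  if (dim(X)[3L] < 2L) stop("segments must have at least 2 timesteps")
  if (any(!is.finite(X))) stop("X contains NaN or Inf")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar (Hz)")
  if (length(subject) != n) stop("subject must have one entry per segment")
  if (is.null(y)) y <- rep(NA_integer_, n)
  if (length(y) != n) stop("y must have one entry per segment")
  y <- as.integer(y)
  if (any(!is.na(y) & y < 0L)) stop("labels must be non-negative class indices (NA = unlabeled)")
  if (is.null(segment_id)) segment_id <- sprintf("seg%05d", seq_len(n))
  if (anyDuplicated(segment_id)) stop("segment_id values must be unique")
  if (!is.null(split)) {
    if (length(split) != n) stop("split must have one tag per segment")
    bad <- setdiff(unique(split), c("train", "val", "test"))
    if (length(bad)) stop("unknown split tags: ", paste(bad, collapse = ", "))
    check_subject_disjoint(subject, split)
  }
  if (!is.null(beats) && length(beats) != n) stop("beats must have one entry per segment")
  structure(list(X = X, fs = fs, subject = as.character(subject), y = y,
                 segment_id = as.character(segment_id), split = split,
                 beats = beats, truth = truth, attrs = attrs),
            class = "segment_dataset")
}

check_subject_disjoint <- function(subject, split) {
  tab <- table(subject, split)
  spans <- rowSums(tab > 0) > 1
  if (any(spans)) {
    stop("subjects appear in more than one split: ",
         paste(rownames(tab)[spans], collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.segment_dataset <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("segment_dataset: %d segments x %d channel(s) x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  subjects: %d  labeled: %d/%d", length(unique(x$subject)),
              sum(!is.na(x$y)), d[1]))
  if (!is.null(x$split)) {
    cat("  split: ", paste(sprintf("%s=%d", names(table(x$split)), table(x$split)),
                           collapse = " "))
  }
  cat("\n")
  invisible(x)
}

#' @export
`[.segment_dataset` <- function(x, i, ...) {
  i <- seq_len(dim(x$X)[1L])[i]
  segment_dataset(X = x$X[i, , , drop = FALSE], fs = x$fs,
                  subject = x$subject[i], y = x$y[i],
                  segment_id = x$segment_id[i],
                  split = if (!is.null(x$split)) x$split[i],
                  beats = if (!is.null(x$beats)) x$beats[i],
                  truth = if (!is.null(x$truth)) x$truth[i, , drop = FALSE],
                  attrs = x$attrs)
}

#' Number of segments in a dataset
#' @param dataset a `segment_dataset`.
#' @return integer count.
#' @export
n_segments <- function(dataset) dim(dataset$X)[1L]

#' Extract one segment as a channels-by-time matrix
#' @param dataset a `segment_dataset`.
#' @param i segment index.
#' @return numeric matrix `[channels x timesteps]` with attributes `fs`,
#'   `subject`, `label`, `segment_id`.
#' @export
get_segment <- function(dataset, i) {
  x <- dataset$X[i, , , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  structure(x, fs = dataset$fs, subject = dataset$subject[i],
            label = dataset$y[i], segment_id = dataset$segment_id[i])
}

#' Subject-disjoint train/validation/test splits
#'
#' Partitions subjects (not segments) at the given ratios so that no
#' individual contributes segments to more than one split, the protocol used
#' for all evaluation in this package. Subject counts per split are the
#' largest-remainder rounding of `ratios * n_subjects`, with every non-empty
#' ratio guaranteed at least one subject.
#'
#' @param dataset a `segment_dataset`.
#' @param ratios numeric length-3 vector `(train, val, test)` summing to 1.
#' @param seed integer seed controlling the subject permutation.
#' @return The dataset with a `split` tag per segment.
#' @export
make_splits <- function(dataset, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be three fractions summing to 1")
  }
  subjects <- unique(dataset$subject)
  ns <- length(subjects)
  n_nonempty <- sum(ratios > 0)
  if (ns < max(3L, n_nonempty)) stop("need at least as many subjects as non-empty splits (and >= 3)")
  counts <- largest_remainder(ratios, ns)
  # guarantee one subject per non-empty split
  for (k in which(ratios > 0 & counts == 0)) {
    donor <- which.max(counts)
    counts[donor] <- counts[donor] - 1L
    counts[k] <- 1L
  }
  perm <- with_rng(derive_seed(seed, "splits"), sample(subjects))
  tags <- rep(c("train", "val", "test"), times = counts)
  subj_tag <- stats::setNames(tags, perm)
  dataset$split <- unname(subj_tag[dataset$subject])
  check_subject_disjoint(dataset$subject, dataset$split)
  dataset
}

largest_remainder <- function(ratios, total) {
  raw <- ratios * total
  base <- floor(raw)
  rem <- raw - base
  short <- total - sum(base)
  if (short > 0) {
    order_rem <- order(rem, decreasing = TRUE)
    base[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Restrict a dataset to one split
#' @param dataset a `segment_dataset` carrying split tags.
#' @param which one of `"train"`, `"val"`, `"test"`.
#' @return the subset as a `segment_dataset`.
#' @export
split_subset <- function(dataset, which = c("train", "val", "test")) {
  which <- match.arg(which)
  if (is.null(dataset$split)) stop("dataset has no split tags; call make_splits() first")
  dataset[dataset$split == which]
}
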