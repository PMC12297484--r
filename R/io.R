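# Dataset container I/O. The on-disk layout is a directory of plain-text
# files — signals.csv (one row per segment-channel, one column per sample),
# meta.csv (segment_id, subject, label, split), attrs.json (fs, shape,
# schema version, config digest) and optional truth.json with generator
# ground truth — so datasets stay portable, diffable and round-trip exactly.

CONTAINER_VERSION <- 1L

#' Write a dataset container
#'
#' @param dataset a [segment_dataset()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_container <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(dataset$X)
  n <- d[1L]; C <- d[2L]; Tt <- d[3L]
  # rows ordered segment-major, channel-minor
  sig <- do.call(rbind, lapply(seq_len(n), function(i) {
    m <- dataset$X[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    m
  }))
  # %.17g guarantees binary64 round-trip through text
  txt <- matrix(sprintf("%.17g", sig), nrow(sig), ncol(sig))
  data.table::fwrite(data.table::as.data.table(txt),
                     file.path(path, "signals.csv"), col.names = FALSE,
                     quote = FALSE)
  meta <- data.table::data.table(segment_id = dataset$segment_id,
                                 subject = dataset$subject,
                                 y = ifelse(is.na(dataset$y), -1L, dataset$y),
                                 split = dataset$split %||% rep(NA_character_, n))
  data.table::fwrite(meta, file.path(path, "meta.csv"))
  jsonlite::write_json(list(schema_version = CONTAINER_VERSION, fs = dataset$fs,
                            n_segments = n, channels = C, timesteps = Tt,
                            attrs = dataset$attrs),
                       file.path(path, "attrs.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(dataset$beats)) {
    jsonlite::write_json(list(beats = dataset$beats,
                              truth = dataset$truth),
                         file.path(path, "truth.json"), digits = NA)
  }
  invisible(path)
}

#' Read a dataset container
#'
#' Validates the schema version and every container invariant (consistent
#' array sizes, positive sampling rate, label range, subject-disjoint
#' splits) before returning; `y = -1` rows load as unlabeled.
#'
#' @param path container directory written by [write_container()].
#' @return A [segment_dataset()].
#' @export
read_container <- function(path) {
  af <- file.path(path, "attrs.json")
  if (!file.exists(af)) stop("validation error: attrs.json missing in ", path)
  attrs <- jsonlite::read_json(af, simplifyVector = TRUE)
  if (!identical(as.integer(attrs$schema_version), CONTAINER_VERSION)) {
    stop("versioned format error: unsupported container schema ",
         attrs$schema_version)
  }
  if (is.null(attrs$fs) || attrs$fs <= 0) stop("validation error: field fs must be positive")
  n <- as.integer(attrs$n_segments); C <- as.integer(attrs$channels)
  Tt <- as.integer(attrs$timesteps)
  sig <- as.matrix(data.table::fread(file.path(path, "signals.csv"),
                                     header = FALSE))
  if (nrow(sig) != n * C || ncol(sig) != Tt) {
    stop("validation error: field X has shape ", nrow(sig), "x", ncol(sig),
         ", expected ", n * C, "x", Tt)
  }
  meta <- data.table::fread(file.path(path, "meta.csv"))
  if (nrow(meta) != n) stop("validation error: field meta row count mismatch")
  X <- array(0, c(n, C, Tt))
  for (i in seq_len(n)) {
    X[i, , ] <- sig[((i - 1L) * C + 1L):(i * C), , drop = FALSE]
  }
  y <- as.integer(meta$y)
  y[y < 0L] <- NA_integer_
  split <- if (all(is.na(meta$split))) NULL else as.character(meta$split)
  beats <- truth <- NULL
  tf <- file.path(path, "truth.json")
  if (file.exists(tf)) {
    tj <- jsonlite::read_json(tf, simplifyVector = TRUE)
    beats <- lapply(tj$beats, as.integer)
    truth <- as.data.frame(tj$truth)
  }
  segment_dataset(X = X, fs = attrs$fs, subject = meta$subject, y = y,
                  segment_id = meta$segment_id, split = split, beats = beats,
                  truth = truth, attrs = as.list(attrs$attrs))
}

#' Serialize a probe report to JSON (confusion matrix to CSV)
#'
#' @param report a `probe_report`.
#' @param path JSON path; the confusion matrix goes beside it as
#'   `<path>.confusion.csv`.
#' @param extra named list merged into the JSON (seed, config digest, ...).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, extra = list()) {
  out <- c(list(protocol = report$protocol, macro_f1 = report$macro_f1,
                macro_precision = report$macro_precision,
                macro_recall = report$macro_recall,
                accuracy = report$accuracy, auroc = report$auroc,
                per_class = report$per_class), extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  cm <- report$confusion
  utils::write.csv(matrix(cm, nrow(cm), ncol(cm), dimnames = dimnames(cm)),
                   paste0(path, ".confusion.csv"))
  invisible(path)
}
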