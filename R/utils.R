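# Internal numerics and reproducibility helpers.

#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

# Evaluate expr under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All package randomness goes through this so
# no function mutates the global stream.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: one user-facing seed fans out to
# independent streams (generator, augmentation, k-means, optimizer, splits).
# Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(generator = 101L, splits = 211L, augment = 307L,
               kmeans = 401L, optimizer = 503L, shuffle = 601L,
               probe = 701L, finetune = 809L)
  if (is.character(stream)) {
    if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
    off <- offsets[[stream]]
  } else {
    off <- as.integer(stream)
  }
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483587)
}

# Max-shifted log-sum-exp over a numeric vector.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise l2 normalization of a matrix; zero rows are left at zero.
l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm < 1e-30] <- 1
  m / nrm
}

# FNV-1a hash of a canonical JSON rendering; used as a config digest so every
# artifact records exactly which configuration produced it.
config_digest <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b))
    # keep arithmetic in double to avoid integer overflow, then fold
    h <- (as.numeric(h + 2^30) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
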