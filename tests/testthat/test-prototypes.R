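test_that("k-means separates well-separated blobs with full purity", {
  set.seed(2)
  blob1 <- matrix(rnorm(100, mean = 0, sd = 0.1), 50, 2)
  blob2 <- matrix(rnorm(100, mean = 10, sd = 0.1), 50, 2)
  X <- rbind(blob1, blob2)
  km <- kmeans_assign(X, K = 2, seed = 1)
  purity <- max(table(km$assignments[1:50])) + max(table(km$assignments[51:100]))
  expect_identical(as.integer(purity), 100L)
  expect_identical(length(unique(km$assignments[1:50])), 1L)
  km2 <- kmeans_assign(X, K = 2, seed = 1)
  expect_identical(km$assignments, km2$assignments)
  k1 <- kmeans_assign(X, K = 1, seed = 1)
  expect_true(all(k1$assignments == 1L))
  expect_equal(as.numeric(k1$centroids), colMeans(X), tolerance = 1e-12)
  expect_warning(kmeans_assign(X[1:3, ], K = 5, seed = 1), "reducing K")
  expect_error(kmeans_assign(rbind(c(1, NA)), K = 1, seed = 1), "NaN")
})

test_that("EMA update follows the momentum algebra", {
  # alpha = 1: prototypes unchanged
  C <- norm_rows(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  bank <- fixed_bank(c(1L, 2L), C, tau_k = c(0.1, 0.1), alpha = 1)
  batch <- structure(list(z = norm_rows(matrix(rnorm(8), 4, 2)),
                          view_to_source = rep(1:2, each = 2)),
                     class = "embedding_batch")
  b1 <- ema_update(bank, batch)
  expect_equal(b1$c, C, tolerance = 1e-12)
  # alpha = 0: prototype jumps to the (normalized) member mean
  bank0 <- fixed_bank(c(1L, 1L), C, tau_k = c(0.1, 0.1), alpha = 0)
  zb <- norm_rows(matrix(rnorm(8), 4, 2))
  b0 <- ema_update(bank0, structure(list(z = zb, view_to_source = rep(1:2, each = 2)),
                                    class = "embedding_batch"))
  mm <- colMeans(zb)
  expect_equal(b0$c[1, ], mm / sqrt(sum(mm^2)), tolerance = 1e-12)
  expect_equal(b0$c[2, ], C[2, ], tolerance = 1e-12)  # no members -> unchanged
  # alpha = 0.5 with c = (1,0) and member mean (0,1): renormalized midpoint
  bankh <- fixed_bank(c(1L, 2L), rbind(c(1, 0), c(0, 1)), c(0.1, 0.1), alpha = 0.5)
  zb2 <- rbind(c(0, 1), c(0, 1), c(1, 0), c(1, 0))
  bh <- ema_update(bankh, structure(list(z = zb2, view_to_source = rep(1:2, each = 2)),
                                    class = "embedding_batch"))
  expect_equal(bh$c[1, ], c(0.70710678, 0.70710678), tolerance = 1e-6)
  expect_error(prototype_bank(c(1L), K = 1, proj_dim = 2, alpha = 1.2), "alpha")
})

test_that("EMA fixed point: prototypes stationary when batch means equal them", {
  C <- norm_rows(matrix(rnorm(6), 3, 2))
  for (alpha in c(0, 0.5, 1)) {
    bank <- fixed_bank(c(1L, 2L, 3L), C, tau_k = rep(0.1, 3), alpha = alpha)
    z <- C[rep(1:3, each = 2), ]
    b <- ema_update(bank, structure(list(z = z, view_to_source = rep(1:3, each = 2)),
                                    class = "embedding_batch"))
    expect_equal(b$c, C, tolerance = 1e-12)
  }
})

test_that("dynamic temperatures follow the dispersion formula and normalization", {
  # one member, distance 0.5, m = 10: raw temperature 0.5 / ln(11)
  bank <- fixed_bank(c(1L), matrix(c(1, 0), 1), tau_k = 0.3, base_tau = 0.2,
                     m = 10)
  bank$acc_dist <- 0.5
  bank$acc_n <- 1L
  up <- update_temperatures(bank)
  raw <- 0.5 / log(11)
  expect_equal(raw, 0.5 / log(11), tolerance = 1e-12)
  expect_equal(raw, 0.20852, tolerance = 1e-4)
  # single cluster: normalization rescales it to exactly base_tau
  expect_equal(up$tau_k, 0.2, tolerance = 1e-9)
  # two clusters with identical raw temperatures both land on base_tau
  b2 <- fixed_bank(c(1L, 2L), norm_rows(matrix(rnorm(4), 2, 2)),
                   tau_k = c(1, 1), base_tau = 0.15, m = 10)
  b2$acc_dist <- c(0.8, 0.8); b2$acc_n <- c(2L, 2L)
  u2 <- update_temperatures(b2)
  expect_equal(u2$tau_k, c(0.15, 0.15), tolerance = 1e-9)
  # raw {0.2, 0.6} with base 0.2 -> {0.1, 0.3}
  b3 <- fixed_bank(c(1L, 2L), norm_rows(matrix(rnorm(4), 2, 2)),
                   tau_k = c(1, 1), base_tau = 0.2, m = 10)
  b3$acc_dist <- c(0.2 * log(11), 0.6 * log(11)); b3$acc_n <- c(1L, 1L)
  u3 <- update_temperatures(b3)
  expect_equal(u3$tau_k, c(0.1, 0.3), tolerance = 1e-9)
  expect_equal(mean(u3$tau_k), 0.2, tolerance = 1e-9)
  # empty clusters keep their previous temperature (then rescale)
  expect_warning({
    be <- fixed_bank(c(1L), matrix(c(1, 0), 1), tau_k = 0.4, base_tau = 0.2)
    update_temperatures(be)
  }, "empty")
})

test_that("temperature normalization is idempotent", {
  bank <- fixed_bank(c(1L, 2L, 3L), norm_rows(matrix(rnorm(6), 3, 2)),
                     tau_k = c(0.05, 0.2, 0.35), base_tau = 0.2)
  bank$acc_dist <- c(0.3, 0.9, 1.5); bank$acc_n <- c(2L, 3L, 4L)
  u1 <- update_temperatures(bank)
  # feed statistics whose raw temperatures equal the current ones: the
  # normalization must leave everything in place
  u1$acc_n <- c(1L, 1L, 1L)
  u1$acc_dist <- u1$tau_k * log(1 + u1$m)
  u2 <- update_temperatures(u1)
  expect_equal(u2$tau_k, u1$tau_k, tolerance = 1e-9)
  expect_equal(mean(u2$tau_k), u2$base_tau, tolerance = 1e-9)
})

test_that("prototype loss closed forms and oracle equivalence", {
  # K = 1: sole denominator term, loss identically 0
  b1 <- fixed_bank(c(1L, 1L), matrix(c(1, 0), 1), tau_k = 0.2)
  batch <- structure(list(z = norm_rows(matrix(rnorm(8), 4, 2)),
                          view_to_source = rep(1:2, each = 2)),
                     class = "embedding_batch")
  expect_equal(prototype_loss(batch, b1), 0, tolerance = 1e-12)
  # z on its own prototype, one orthogonal alternative, unit temperatures
  b2 <- fixed_bank(c(1L), rbind(c(1, 0), c(0, 1)), tau_k = c(1, 1))
  bz <- structure(list(z = rbind(c(1, 0)), view_to_source = 1L),
                  class = "embedding_batch")
  expect_equal(prototype_loss(bz, b2), -log(exp(1) / (exp(1) + 1)),
               tolerance = 1e-9)
  expect_equal(prototype_loss(bz, b2), 0.31326, tolerance = 1e-5)
  # all prototypes identical, uniform temperature: ln K
  K <- 6L
  bk <- fixed_bank(sample(1:K, 3, replace = TRUE),
                   matrix(rep(c(1, 0), each = K), K, 2), tau_k = rep(0.3, K))
  bz3 <- structure(list(z = norm_rows(matrix(rnorm(6), 3, 2)),
                        view_to_source = 1:3), class = "embedding_batch")
  expect_equal(prototype_loss(bz3, bk), log(K), tolerance = 1e-9)
  # randomized oracle equivalence with per-cluster temperatures
  set.seed(5)
  for (case in 1:25) {
    B <- sample(2:6, 1); K <- sample(2:8, 1); pd <- sample(2:5, 1)
    bank <- fixed_bank(sample(1:K, B, replace = TRUE),
                       norm_rows(matrix(rnorm(K * pd), K, pd)),
                       tau_k = runif(K, 0.05, 0.5))
    bb <- random_batch(B, proj_dim = pd)
    got <- prototype_loss(bb, bank, with_grad = TRUE)
    ks <- bank$assignments[bb$view_to_source]
    expect_lt(abs(got$loss - oracle_prototype_loss(bb$z, bank$c, bank$tau_k, ks)),
              1e-6)
  }
})

test_that("prototype loss gradient matches central differences", {
  set.seed(8)
  K <- 4L; pd <- 3L
  bank <- fixed_bank(c(1L, 3L, 4L), norm_rows(matrix(rnorm(K * pd), K, pd)),
                     tau_k = runif(K, 0.05, 0.4))
  batch <- random_batch(3, proj_dim = pd)
  v <- prototype_loss(batch, bank, with_grad = TRUE)
  eps <- 1e-6
  num <- batch$z * 0
  for (j in seq_along(batch$z)) {
    bp <- batch; bp$z[j] <- bp$z[j] + eps
    bm <- batch; bm$z[j] <- bm$z[j] - eps
    num[j] <- (prototype_loss(bp, bank) - prototype_loss(bm, bank)) / (2 * eps)
  }
  expect_lt(max(abs(num - v$dz)), 1e-6)
})
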