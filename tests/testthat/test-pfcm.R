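test_that("membership update matches the closed-form rule and sums to one", {
  set.seed(1)
  x <- fuzzify(matrix(runif(40), 10))
  v <- fuzzify(matrix(runif(12), 3))
  u <- update_memberships(x, v, m = 2)
  expect_equal(colSums(u), rep(1, 10), tolerance = 1e-12)
  # brute-force formula on the actual distances
  d <- sapply(seq_len(10), function(j)
    sapply(seq_len(3), function(i) pfn_vector_distance(x[j, ], v[i, ])))
  uref <- apply(d, 2, function(dj) { r <- dj^-2; r / sum(r) })
  expect_equal(u, uref, tolerance = 1e-9)
  # zero-distance rule: a point sitting on one centroid gets full membership
  x2 <- fuzzify(rbind(matrix(runif(8), 2), c(0.1, 0.9, 0.4, 0.3)))
  v2 <- fuzzify(rbind(c(0.1, 0.9, 0.4, 0.3), c(0.8, 0.2, 0.6, 0.5)))
  u2 <- update_memberships(x2, v2)
  expect_equal(u2[, 3], c(1, 0))
  # equidistant point: equal split
  v3 <- fuzzify(rbind(c(0.2, 0.5), c(0.8, 0.5)))
  u3 <- update_memberships(fuzzify(matrix(c(0.5, 0.5), 1)), v3)
  expect_equal(u3[, 1], c(0.5, 0.5))
})

test_that("centroid update is the weighted squared-degree mean", {
  x <- fuzzify(matrix(c(0.2, 0.6,
                        0.8, 0.4), 2, byrow = TRUE))
  u <- matrix(c(1, 1), 1)                     # one cluster holding both points
  v <- update_centroids(x, u, m = 2)
  # hand computation: mean of mu^2 then sqrt
  expect_equal(as.numeric(v$mu_hi), sqrt(c((0.04 + 0.64) / 2, (0.36 + 0.16) / 2)))
  expect_equal(as.numeric(v$nu_hi), sqrt(c((0.64 + 0.04) / 2, (0.16 + 0.36) / 2)))
  expect_valid_pfn(v)
  # a single point is its own centroid
  x1 <- fuzzify(matrix(c(0.3, 0.7), 1))
  v1 <- update_centroids(x1, matrix(1, 1, 1), m = 2)
  expect_equal(as.numeric(v1$mu_hi), c(0.3, 0.7), tolerance = 1e-12)
  # dead cluster is re-seeded with a message
  expect_message(update_centroids(x, rbind(c(1, 1), c(0, 0)), m = 2), "re-seeding")
})

test_that("objective matches the brute-force double summation", {
  set.seed(2)
  x <- fuzzify(matrix(runif(16), 4))
  v <- fuzzify(matrix(runif(8), 2))
  u <- update_memberships(x, v)
  j <- pfcm_objective(x, u, v, m = 2)
  ref <- 0
  for (i in 1:2) for (jj in 1:4)
    ref <- ref + u[i, jj]^2 * pfn_vector_distance(x[jj, ], v[i, ])^2
  expect_equal(j, ref / 8, tolerance = 1e-10)
  expect_gte(j, 0)
  # perfect clustering scores zero
  xp <- fuzzify(matrix(c(0.2, 0.2, 0.9, 0.9), 2, byrow = TRUE))
  vp <- fuzzify(matrix(c(0.2, 0.2, 0.9, 0.9), 2, byrow = TRUE))
  expect_equal(pfcm_objective(xp, diag(2), vp), 0)
})

test_that("alternating optimization converges with a non-increasing trace", {
  set.seed(3)
  x <- rbind(matrix(runif(60, 0.05, 0.3), 15),
             matrix(runif(60, 0.7, 0.95), 15))
  fit <- pfcm(x, centers = 2, seed = 4)
  expect_true(all(diff(fit$trace) <= 1e-9))
  expect_equal(colSums(fit$u), rep(1, 30), tolerance = 1e-9)
  truth <- rep(1:2, each = 15)
  expect_equal(mclust::adjustedRandIndex(fit$cluster, truth), 1)
})

test_that("grouping agrees with standard FCM in transformed coordinates", {
  # the Pythagorean metric is Euclidean in (mu^2, nu^2, pi^2)/sqrt(2) space, so
  # on fuzzified data the partition must match e1071's classical FCM there
  skip_if_not_installed("e1071")
  set.seed(5)
  for (inst in 1:20) {
    centers_true <- matrix(runif(6, c(0.1, 0.6), c(0.35, 0.95)), 2, 3, byrow = FALSE)
    x <- rbind(matrix(runif(30, 0.05, 0.35), 10),
               matrix(runif(30, 0.65, 0.95), 10))
    p <- fuzzify(x)
    ch <- list(mu2 = pfn_centroid(p)$c_mu^2, nu2 = pfn_centroid(p)$c_nu^2)
    z <- cbind(ch$mu2, ch$nu2, 1 - ch$mu2 - ch$nu2) / sqrt(2)
    ref <- e1071::cmeans(z, centers = 2, m = 2)
    fit <- pfcm(x, centers = 2, seed = inst)
    expect_equal(mclust::adjustedRandIndex(fit$cluster, ref$cluster), 1)
  }
})

test_that("seeded initial-centroid search is reproducible and valid", {
  set.seed(6)
  x <- rbind(matrix(runif(40, 0, 0.4), 10), matrix(runif(40, 0.6, 1), 10))
  v1 <- wwo_init_centroids(x, 2, budget = 120, seed = 7)
  v2 <- wwo_init_centroids(x, 2, budget = 120, seed = 7)
  expect_equal(v1, v2)
  expect_valid_pfn(v1)
  expect_equal(dim(v1$mu_hi), c(2, 4))
})

test_that("membership floor filters the group training set", {
  u <- matrix(0.2, 5, 10)                      # uniform memberships, c = 5
  ts <- group_training_set(u, 3, u_floor = 0.1)
  expect_equal(ts$idx, 1:10)                   # everyone passes at 0.1
  expect_equal(ts$weights, rep(0.2, 10))
  u2 <- rbind(c(0.9, 0.05), c(0.1, 0.95))
  expect_equal(group_training_set(u2, 1, 0.1)$idx, 1)
  expect_error(group_training_set(u2, 1, u_floor = 1), "lower u_floor")
  expect_equal(group_training_set(u2, 2, u_floor = 0)$idx, 1:2)
})
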