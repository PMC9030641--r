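test_that("masking corruption has the right limits and rate", {
  x <- matrix(runif(200), 20)
  expect_identical(corrupt(x, 0), x)
  expect_true(all(corrupt(x, 1) == 0))
  set.seed(1)
  big <- matrix(1, 100, 100)
  frac <- mean(corrupt(big, 0.2) == 0)
  expect_equal(frac, 0.2, tolerance = 0.02)       # binomial oracle, n = 10000
})

test_that("genomes decode to valid layers of the advertised size", {
  expect_equal(genome_length(12, 4), 4 * (48 + 12 + 4))
  set.seed(2)
  for (scaling in c(TRUE, FALSE)) {
    layer <- decode_genome(runif(genome_length(5, 3)), 5, 3, scaling)
    expect_s3_class(layer, "fuzzy_layer")
    expect_valid_pfn(layer$W)
    expect_valid_pfn(layer$b)
    expect_valid_pfn(layer$b_dec)
    expect_equal(dim(layer$W$mu_hi), c(3, 5))
  }
  # without fan-in scaling the map is the plain (g1 g2, g2, g3 sqrt(1-g2^2), ...)
  g <- c(0.5, 0.8, 0.6, 0.9)          # one parameter: layer 1 -> 0 is not valid,
  layer <- decode_genome(rep(g, each = 3), 1, 1, fan_in_scaling = FALSE)
  expect_equal(layer$W$mu_hi, matrix(0.8), tolerance = 1e-12)
  expect_equal(layer$W$nu_hi, matrix(0.6 * sqrt(1 - 0.64)), tolerance = 1e-12)
  expect_equal(layer$W$mu_lo, matrix(0.4), tolerance = 1e-12)
})

test_that("encoder matches the scalar operational-law oracle", {
  set.seed(3)
  layer <- decode_genome(runif(genome_length(6, 4)), 6, 4)
  x <- runif(6)
  batch <- encode(layer, x)
  ref <- naive_encode(layer, x)
  expect_equal(as.numeric(rbind(batch$mu_lo, batch$mu_hi, batch$nu_lo, batch$nu_hi)),
               as.numeric(ref), tolerance = 1e-9)
  h <- runif(4)
  dec <- decode(layer, matrix(h, 1))
  refd <- naive_decode(layer, h)
  expect_equal(as.numeric(rbind(dec$mu_lo, dec$mu_hi, dec$nu_lo, dec$nu_hi)),
               as.numeric(refd), tolerance = 1e-9)
})

test_that("identity-element weights make the encoder constant in x", {
  # genes (.., g2 = 0, g3 = 1, g4 = 1) give W = b = P(0, 1), the additive identity
  p <- genome_length(4, 2) / 4
  genes <- as.numeric(rbind(runif(p), 0, 1, 1))
  genes <- c(matrix(genes, ncol = 4, byrow = TRUE))   # block layout g1|g2|g3|g4
  layer <- decode_genome(genes, 4, 2)
  y1 <- encode(layer, runif(4))
  y2 <- encode(layer, runif(4))
  expect_equal(y1, y2)
  # zero input: output is the activated bias
  set.seed(4)
  layer2 <- decode_genome(runif(genome_length(3, 2)), 3, 2)
  y0 <- encode(layer2, rep(0, 3))
  yb <- pfn_activate(layer2$b)
  expect_equal(as.numeric(y0$mu_hi), as.numeric(yb$mu_hi), tolerance = 1e-9)
  expect_equal(as.numeric(y0$nu_hi), as.numeric(yb$nu_hi), tolerance = 1e-9)
})

test_that("forward pass stays inside the PFN invariants for arbitrary inputs", {
  set.seed(5)
  layer <- decode_genome(runif(genome_length(8, 3)), 8, 3)
  X <- matrix(runif(400), 50)
  y <- encode(layer, X)
  expect_valid_pfn(y)
  expect_equal(dim(y$mu_hi), c(50, 3))
  rec <- decode(layer, y)
  expect_valid_pfn(rec)
  expect_equal(dim(rec$mu_hi), c(50, 8))
})

test_that("layer loss is non-negative, weight-linear, and matches a hand oracle", {
  set.seed(6)
  layer <- decode_genome(runif(genome_length(4, 2)), 4, 2)
  X <- matrix(runif(20), 5)
  masks <- matrix(1, 5, 4)
  l0 <- layer_loss(layer, X, masks = masks)
  expect_gte(l0, 0)
  # hand oracle: mean of row squared distances computed via the public pieces
  rows <- sapply(seq_len(5), function(j) {
    rec <- decode(layer, encode(layer, X[j, ]))
    crisp_fuzzy_vector_distance(X[j, ], rec)^2
  })
  expect_equal(l0, mean(rows), tolerance = 1e-10)
  # membership weighting is linear: doubling one weight adds its contribution
  w <- rep(1, 5)
  w2 <- w; w2[3] <- 2
  expect_equal(layer_loss(layer, X, masks = masks, weights = w2) -
                 layer_loss(layer, X, masks = masks, weights = w),
               rows[3] / 5, tolerance = 1e-10)
  expect_error(layer_loss(layer, X[0, , drop = FALSE]), "empty")
})

test_that("pretraining beats random parameters on low-rank data", {
  set.seed(7)
  latent <- matrix(runif(40 * 3), 40)
  mix <- matrix(runif(36, 0, 1), 3)
  X <- pmin(pmax(0.15 + 0.7 * (latent %*% mix) / 3, 0), 1)   # rank-3 in [0,1]^12
  stack <- pretrain_stack(pfddae(c(12, 4)), X, budget = 800, seed = 8)
  expect_true(stack$trained)
  expect_true(all(diff(stack$traces[[1]]) <= 0))
  rand <- init_random(pfddae(c(12, 4)), seed = 9)
  err_t <- stack_reconstruction_error(stack, X)
  err_r <- stack_reconstruction_error(rand, X)
  expect_lt(err_t, err_r)
  H <- encode_topmost(stack, X)
  expect_equal(dim(H), c(40, 4))
  expect_true(all(H >= 0 & H <= 1))
  expect_identical(H, encode_topmost(stack, X))    # deterministic
})

test_that("stack shape contracts and budget validation hold", {
  s <- pfddae(c(10, 6, 3))
  expect_error(pretrain_stack(s, matrix(runif(50), 5), budget = 10),
               "budget too small")
  expect_error(pretrain_stack(s, matrix(runif(45), 5), budget = 400),
               "width")
  s2 <- init_random(s, seed = 1)
  X <- matrix(runif(50), 5)
  expect_equal(dim(encode_topmost(s2, X)), c(5, 3))
  rec <- reconstruct(s2, X)
  expect_equal(dim(rec$mu_hi), c(5, 10))
})

test_that("stacks serialize to JSON and back", {
  stack <- init_random(pfddae(c(6, 3)), seed = 10)
  path <- tempfile(fileext = ".json")
  write_stack(stack, path)
  back <- read_stack(path)
  X <- matrix(runif(18), 3)
  expect_equal(encode_topmost(back, X), encode_topmost(stack, X), tolerance = 1e-12)
  unlink(path)
})
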