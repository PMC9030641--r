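test_that("constructor enforces the interval and Pythagorean invariants", {
  p <- pfn(0.6, 0.6, 0.8, 0.8)                      # mu^2 + nu^2 = 1 boundary
  expect_s3_class(p, "pfn")
  expect_equal(pfn_hesitancy(p), 0)
  expect_error(pfn(0.9, 0.95, 0.4, 0.5), "Pythagorean")
  expect_error(pfn(0.5, 0.3, 0.1, 0.2), "ordering")
  expect_error(pfn(-0.2, 0.3, 0.1, 0.2), "\\[0, 1\\]")
  expect_error(pfn(0.1, 0.3, 0.4, 0.2), "ordering")
})

test_that("centroid is the interval midpoint, matching the quadrature oracle", {
  expect_equal(pfn_centroid(pfn(0.6, 0.6, 0.3, 0.3)), list(c_mu = 0.6, c_nu = 0.3))
  for (p in list(pfn(0.2, 0.8, 0.1, 0.5), pfn(0, 1, 0, 0), rand_pfn(1))) {
    ct <- pfn_centroid(p)
    expect_equal(c(ct$c_mu, ct$c_nu), quadrature_centroid(p), tolerance = 1e-4)
  }
  ct <- pfn_centroid(pfn(0.2, 0.8, 0.1, 0.5))
  expect_equal(c(ct$c_mu, ct$c_nu), c(0.5, 0.3))
})

test_that("crisp-PFN distance follows the decided reading", {
  expect_equal(crisp_distance(0.5, pfn(0.5, 0.5, 0, 0)), 0)
  expect_equal(crisp_distance(0, pfn(1, 1, 0, 0)), sqrt(0.5))
  expect_equal(crisp_distance(0.2, pfn(0.2, 0.2, 0.3, 0.3)), 0.3)
  # alternative reading halves the nu term too
  expect_equal(crisp_distance(0.2, pfn(0.2, 0.2, 0.3, 0.3), variant = "half_both"),
               0.3 / sqrt(2))
  # first term vanishes at the centroid for every PFN
  set.seed(1)
  p <- rand_pfn(200)
  ct <- pfn_centroid(p)
  expect_equal(crisp_distance(ct$c_mu, p), ct$c_nu)
})

test_that("crisp-fuzzy vector distance is the RMS of coordinate distances", {
  p <- pfn(c(0.5, 0.1), c(0.5, 0.1), c(0, 0), c(0, 0))
  expect_equal(crisp_fuzzy_vector_distance(c(0.5, 0.1), p), 0)
  # coordinates engineered to give per-coordinate distances 0.3 and 0.4
  q <- pfn(c(0.2, 0.2), c(0.2, 0.2), c(0.3, 0.4), c(0.3, 0.4))
  expect_equal(crisp_fuzzy_vector_distance(c(0.2, 0.2), q),
               sqrt((0.09 + 0.16) / 2))
  # D = 1 reduces to the scalar distance
  r <- rand_pfn(1)
  expect_equal(crisp_fuzzy_vector_distance(0.4, r), crisp_distance(0.4, r))
  expect_error(crisp_fuzzy_vector_distance(c(0.1, 0.2), r), "length mismatch")
})

test_that("PFN distance reproduces hand values and the brute-force oracle", {
  expect_equal(pfn_distance(pfn(0.3, 0.3, 0.4, 0.4), pfn(0.3, 0.3, 0.4, 0.4)), 0)
  expect_equal(pfn_distance(pfn(1, 1, 0, 0), pfn(0, 0, 1, 1)), 1)
  expect_equal(pfn_distance(pfn(0.6, 0.6, 0.8, 0.8), pfn(0.8, 0.8, 0.6, 0.6)), 0.28)
  set.seed(2)
  for (k in 1:50) {
    a <- rand_pfn(1); b <- rand_pfn(1)
    expect_equal(pfn_distance(a, b), brute_pfn_distance(a, b))
  }
})

test_that("PFN distance is a metric with range [0, 1] on random triples", {
  set.seed(3)
  n <- 2000
  a <- rand_pfn(n); b <- rand_pfn(n); c3 <- rand_pfn(n)
  dab <- pfn_distance(a, b); dba <- pfn_distance(b, a)
  dac <- pfn_distance(a, c3); dcb <- pfn_distance(c3, b)
  expect_true(all(dab >= 0 & dab <= 1))
  expect_equal(dab, dba)
  expect_true(all(dab <= dac + dcb + 1e-12))           # triangle inequality
  expect_equal(pfn_distance(a, a), rep(0, n))
})

test_that("PFN vector distance aggregates as an RMS and reduces at D = 1", {
  a <- rand_pfn(4)
  expect_equal(pfn_vector_distance(a, a), 0)
  # per-coordinate distances (1, 0)
  x <- pfn(c(1, 0.3), c(1, 0.3), c(0, 0.2), c(0, 0.2))
  v <- pfn(c(0, 0.3), c(0, 0.3), c(1, 0.2), c(1, 0.2))
  expect_equal(pfn_vector_distance(x, v), sqrt(0.5))
  a1 <- rand_pfn(1); b1 <- rand_pfn(1)
  expect_equal(pfn_vector_distance(a1, b1), pfn_distance(a1, b1))
  expect_error(pfn_vector_distance(rand_pfn(2), rand_pfn(3)), "length mismatch")
})

test_that("operational laws have the right identities and closure", {
  b <- pfn(0.3, 0.5, 0.2, 0.6)
  ident <- pfn(0, 0, 1, 1)
  expect_equal(pfn_add(b, ident), b)
  s0 <- pfn_scale(0, b)
  expect_equal(c(s0$mu_hi, s0$nu_lo), c(0, 1))
  s <- pfn_scale(0.5, pfn(0.8, 0.8, 0.6, 0.6))
  expect_equal(s$mu_hi, sqrt(0.4), tolerance = 1e-12)
  expect_equal(s$nu_hi, sqrt(0.6), tolerance = 1e-12)
  set.seed(4)
  p1 <- rand_pfn(1000); p2 <- rand_pfn(1000)
  expect_valid_pfn(pfn_add(p1, p2))
  expect_valid_pfn(pfn_scale(runif(1000, 0, 3), p1))
  expect_valid_pfn(pfn_activate(p1))
})

test_that("activation fixes mu = 1, is monotone, and preserves validity", {
  a <- pfn_activate(pfn(1, 1, 0, 0))
  expect_equal(a$mu_hi, 1)
  set.seed(5)
  lo <- rand_pfn(500)
  bump <- function(m) sqrt(m^2 + 0.1 * (1 - m^2))    # monotone, keeps validity
  hi <- pfn(bump(lo$mu_lo), bump(lo$mu_hi), lo$nu_lo * 0.5, lo$nu_hi * 0.5)
  expect_true(all(pfn_activate(hi)$mu_hi >= pfn_activate(lo)$mu_hi - 1e-12))
  expect_true(all(pfn_activate(hi)$mu_lo >= pfn_activate(lo)$mu_lo - 1e-12))
})

test_that("projection restores validity and is idempotent", {
  p <- pfn(0.2, 0.6, 0.1, 0.7)
  q <- project_valid(p$mu_lo, p$mu_hi, p$nu_lo, p$nu_hi)
  expect_equal(q, p)
  r <- project_valid(1, 1, 1, 1)
  expect_equal(c(r$mu_hi, r$nu_hi), c(sqrt(0.5), sqrt(0.5)))
  set.seed(6)
  for (k in 1:200) {
    x <- runif(4, -0.5, 1.5)
    p1 <- project_valid(x[1], x[2], x[3], x[4])
    expect_valid_pfn(p1)
    p2 <- project_valid(p1$mu_lo, p1$mu_hi, p1$nu_lo, p1$nu_hi)
    expect_equal(p1, p2)
  }
})

test_that("fuzzify round-trips through the centroid", {
  f1 <- fuzzify(1)
  expect_equal(c(f1$mu_hi, f1$nu_hi), c(1, 0))
  f5 <- fuzzify(0.5)
  expect_equal(c(f5$mu_hi, f5$nu_hi), c(0.5, 0.5))
  expect_equal(pfn_hesitancy(f5), sqrt(0.5))
  x <- runif(100)
  expect_equal(pfn_centroid(fuzzify(x))$c_mu, x)
  expect_error(fuzzify(1.2), "\\[0, 1\\]")
})
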