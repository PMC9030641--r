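# Independent oracles and fixture builders used across the suite.

# random valid interval-valued PFNs (valid by construction)
rand_pfn <- function(n = 1) {
  mu_hi <- runif(n)
  nu_hi <- runif(n) * sqrt(1 - mu_hi^2)
  pfn(runif(n) * mu_hi, mu_hi, runif(n) * nu_hi, nu_hi)
}

# ratio-of-integrals centroid by numerical quadrature with uniform density
quadrature_centroid <- function(p, n = 200000) {
  mid <- function(lo, hi) {
    if (hi - lo < 1e-14) return(lo)
    x <- seq(lo, hi, length.out = n)
    sum(x) / n
  }
  c(mid(p$mu_lo, p$mu_hi), mid(p$nu_lo, p$nu_hi))
}

# brute-force PFN distance: Euclidean in (mu^2, nu^2, pi^2) scaled by 1/sqrt(2)
brute_pfn_distance <- function(p1, p2) {
  chan <- function(p) {
    cm <- (p$mu_lo + p$mu_hi) / 2
    cn <- (p$nu_lo + p$nu_hi) / 2
    c(cm^2, cn^2, max(0, 1 - cm^2 - cn^2))
  }
  sqrt(sum((chan(p1) - chan(p2))^2) / 2)
}

# scalar reference of the fuzzy affine encoder/decoder: plain loops over the
# operational laws, one fuzzy number at a time (independent of the batched
# log-space path in the package)
scalar_pfn <- function(p, i, j = NULL) {
  pick <- function(ch) if (is.null(j)) ch[i] else ch[i, j]
  pfn(pick(p$mu_lo), pick(p$mu_hi), pick(p$nu_lo), pick(p$nu_hi))
}

naive_encode <- function(layer, x) {
  sapply(seq_len(layer$d_out), function(i) {
    acc <- pfn(0, 0, 1, 1)
    for (d in seq_len(layer$d_in))
      acc <- pfn_add(acc, pfn_scale(x[d], scalar_pfn(layer$W, i, d)))
    acc <- pfn_add(acc, scalar_pfn(layer$b, i))
    out <- pfn_activate(acc)
    c(out$mu_lo, out$mu_hi, out$nu_lo, out$nu_hi)
  })
}

naive_decode <- function(layer, h) {
  sapply(seq_len(layer$d_in), function(d) {
    acc <- pfn(0, 0, 1, 1)
    for (i in seq_len(layer$d_out))
      acc <- pfn_add(acc, pfn_scale(h[i], scalar_pfn(layer$W, i, d)))
    acc <- pfn_add(acc, scalar_pfn(layer$b_dec, d))
    out <- pfn_activate(acc)
    c(out$mu_lo, out$mu_hi, out$nu_lo, out$nu_hi)
  })
}

expect_valid_pfn <- function(p, tol = 1e-9) {
  expect_true(all(p$mu_lo >= -tol & p$mu_hi <= 1 + tol))
  expect_true(all(p$nu_lo >= -tol & p$nu_hi <= 1 + tol))
  expect_true(all(p$mu_lo <= p$mu_hi + tol))
  expect_true(all(p$nu_lo <= p$nu_hi + tol))
  expect_true(all(p$mu_hi^2 + p$nu_hi^2 <= 1 + 1e-8))
}

# small record fixture shared by behavior/control/io tests (built once per run)
tiny_cohort <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_cohort(n_moths = 6, n_groups = 2, seed = 42)
    val
  }
})

tiny_records <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_records(tiny_cohort(), records_per_moth = 30, seed = 7)
    val
  }
})
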