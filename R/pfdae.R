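#' Pythagorean fuzzy denoising autoencoder layers
#'
#' A fuzzy layer is an autoencoder layer whose weight matrix `W` (D' x D),
#' encoder bias `b` (D') and decoder bias `b_dec` (D) are all interval-valued
#' Pythagorean fuzzy numbers.  The encoder maps a crisp vector
#' \eqn{x \in [0,1]^D} to a PFN vector of length D' with the fuzzy affine map
#' \deqn{y_i = s\big(\oplus_d \; x_d \otimes W_{id} \; \oplus \; b_i\big)}
#' using the operational laws of [pfn_add()]/[pfn_scale()] and the activation
#' [pfn_activate()].  The decoder applies the transposed weights to the
#' defuzzified (centroid-\eqn{\mu}) hidden vector.
#'
#' Because the algebraic sum is a product law in \eqn{\log(1-\mu^2)} and
#' \eqn{\log\nu}, a whole batch is encoded with two matrix multiplications per
#' channel; the scalar operational laws and the batched path agree to
#' floating-point accuracy.
#'
#' @param W A `pfn` object with `d_out x d_in` matrices.
#' @param b A `pfn` object of length `d_out` (encoder bias).
#' @param b_dec A `pfn` object of length `d_in` (decoder bias).
#' @return An object of class `fuzzy_layer`.
#' @export
fuzzy_layer <- function(W, b, b_dec) {
  stopifnot(is_pfn(W), is_pfn(b), is_pfn(b_dec))
  dm <- dim(W$mu_hi)
  if (is.null(dm)) stop("W must be a pfn with matrix shape")
  if (length(b) != dm[1] || length(b_dec) != dm[2])
    stop("bias lengths must match the weight matrix")
  structure(list(W = W, b = b, b_dec = b_dec, d_in = dm[2], d_out = dm[1]),
            class = "fuzzy_layer")
}

#' @export
print.fuzzy_layer <- function(x, ...) {
  cat(sprintf("<fuzzy_layer %d -> %d (%d fuzzy parameters)>\n",
              x$d_in, x$d_out, x$d_in * x$d_out + x$d_in + x$d_out))
  invisible(x)
}

#' Number of genes encoding one layer
#' @param d_in,d_out Layer dimensions.
#' @return Integer, `4 * (d_in*d_out + d_in + d_out)`.
#' @export
genome_length <- function(d_in, d_out) 4L * (d_in * d_out + d_in + d_out)

#' Decode a gene vector into a fuzzy layer
#'
#' Every fuzzy parameter is encoded by four genes `(g1, g2, g3, g4)` in
#' \[0, 1\], mapped so that the result is a valid PFN by construction:
#' with fan-in exponent `f`,
#' \deqn{\mu_{hi} = \sqrt{1 - (1-g_2^2)^{1/f}}, \quad \mu_{lo} = g_1\mu_{hi},}
#' \deqn{\nu_{hi} = g_3\sqrt{1-\mu_{hi}^2}, \quad \nu_{lo} = g_4\nu_{hi}.}
#' With `fan_in_scaling = FALSE` (`f = 1`) this reduces to the plain map
#' \eqn{\mu_{hi} = g_2}, \eqn{\nu_{hi} = g_3\sqrt{1-g_2^2}}.  The fan-in
#' exponent (`f = d_in + 1` for encoder parameters, `d_out + 1` for the decoder
#' bias) applies to the membership channel only: it keeps the algebraic sum
#' over `d_in` inputs away from the \eqn{\mu \to 1} saturation point, the
#' fuzzy analogue of fan-in-scaled initialisation in crisp networks.  The
#' non-membership channel needs no such scaling (its product law already
#' contracts) and an exponent there would flatten the gene-to-\eqn{\nu} map
#' into unsearchability.
#'
#' @param genes Numeric vector in \[0, 1\] of length [genome_length()].
#' @param d_in,d_out Layer dimensions.
#' @param fan_in_scaling Apply the fan-in exponent (default `TRUE`).
#' @return A `fuzzy_layer`.
#' @export
decode_genome <- function(genes, d_in, d_out, fan_in_scaling = TRUE) {
  p <- d_in * d_out + d_in + d_out
  if (length(genes) != 4L * p) stop("gene vector has wrong length")
  genes <- pmin(pmax(genes, 0), 1)
  g <- matrix(genes, nrow = p, ncol = 4L)
  nw <- d_in * d_out
  f <- if (fan_in_scaling) c(rep(d_in + 1, nw), rep(d_in + 1, d_out), rep(d_out + 1, d_in))
       else rep(1, p)
  one_m_g2sq <- pmax(1 - g[, 2]^2, 0)
  a <- one_m_g2sq^(1 / f)
  mu_hi <- sqrt(pmax(0, 1 - a))
  mu_lo <- g[, 1] * mu_hi
  nu_hi <- g[, 3] * sqrt(a)          # valid: mu_hi^2 + nu_hi^2 <= 1
  nu_lo <- g[, 4] * nu_hi
  part <- function(v, idx, dm = NULL) { v <- v[idx]; if (!is.null(dm)) dim(v) <- dm; v }
  iw <- seq_len(nw); ib <- nw + seq_len(d_out); id <- nw + d_out + seq_len(d_in)
  fuzzy_layer(
    W = pfn(part(mu_lo, iw, c(d_out, d_in)), part(mu_hi, iw, c(d_out, d_in)),
            part(nu_lo, iw, c(d_out, d_in)), part(nu_hi, iw, c(d_out, d_in))),
    b = pfn(mu_lo[ib], mu_hi[ib], nu_lo[ib], nu_hi[ib]),
    b_dec = pfn(mu_lo[id], mu_hi[id], nu_lo[id], nu_hi[id]))
}

#' Masking corruption
#'
#' The stochastic corruption of the denoising autoencoder: each coordinate is
#' independently set to 0 with probability `noise_level`.
#'
#' @param x Numeric vector or matrix (rows = samples) in \[0, 1\].
#' @param noise_level Masking probability in \[0, 1\].
#' @return The corrupted data, same shape as `x`.
#' @export
corrupt <- function(x, noise_level) {
  stopifnot(noise_level >= 0, noise_level <= 1)
  if (noise_level == 0) return(x)
  x * (stats::runif(length(x)) >= noise_level)
}

# batched fuzzy affine map: returns pre-activation pfn with n x d_out matrices.
# transpose = TRUE applies t(W) (decoder direction, bias must then have length d_in).
affine_fuzzy <- function(X, W, b, transpose = FALSE) {
  eps <- 1e-300
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  ch <- function(wc, bc, is_mu) {
    # clamp the logs so mu = 1 / nu = 0 entries cannot yield 0 * Inf = NaN
    if (is_mu) { lw <- pmax(log1p(-pmin(wc, 1)^2), -690)
                 lb <- pmax(log1p(-pmin(bc, 1)^2), -690) }
    else { lw <- log(pmax(wc, eps)); lb <- log(pmax(bc, eps)) }
    s <- if (transpose) X %*% lw else tcrossprod(X, lw)
    s <- sweep(s, 2, lb, "+")
    if (is_mu) sqrt(pmax(0, -expm1(s))) else exp(s)
  }
  structure(list(mu_lo = ch(W$mu_lo, b$mu_lo, TRUE),
                 mu_hi = ch(W$mu_hi, b$mu_hi, TRUE),
                 nu_lo = ch(W$nu_lo, b$nu_lo, FALSE),
                 nu_hi = ch(W$nu_hi, b$nu_hi, FALSE)),
            class = "pfn")
}

#' Encode a batch of crisp vectors through a fuzzy layer
#'
#' @param layer A `fuzzy_layer`.
#' @param x Numeric vector of length `d_in` or matrix `n x d_in` in \[0, 1\].
#' @return A `pfn` object with `n x d_out` matrices (a single vector input
#'   yields `1 x d_out`).
#' @export
encode <- function(layer, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != layer$d_in) stop("input dimension mismatch")
  pfn_activate(affine_fuzzy(x, layer$W, layer$b))
}

#' Decode a hidden representation back to the input space
#'
#' The hidden PFN vector is defuzzified to its centroid-\eqn{\mu} channel and
#' pushed through the transposed weights and the decoder bias.
#'
#' @param layer A `fuzzy_layer`.
#' @param y A `pfn` with `n x d_out` matrices, or an already-defuzzified
#'   numeric matrix `n x d_out`.
#' @return A `pfn` object with `n x d_in` matrices.
#' @export
decode <- function(layer, y) {
  h <- if (is_pfn(y)) (y$mu_lo + y$mu_hi) / 2 else y
  h <- if (is.matrix(h)) h else matrix(h, nrow = 1)
  if (ncol(h) != layer$d_out) stop("hidden dimension mismatch")
  pfn_activate(affine_fuzzy(h, layer$W, layer$b_dec, transpose = TRUE))
}

# defuzzified centroid-mu channel as a plain matrix
defuzz_mu <- function(p) {
  h <- (p$mu_lo + p$mu_hi) / 2
  if (is.matrix(h)) h else matrix(h, nrow = 1)
}

# per-row squared reconstruction error (the RMS loss before averaging)
row_sq_loss <- function(X, recon, variant = "half_mu") {
  cmu <- (recon$mu_lo + recon$mu_hi) / 2
  cnu <- (recon$nu_lo + recon$nu_hi) / 2
  if (variant == "half_mu") rowMeans((cmu - X)^2 / 2 + cnu^2)
  else rowMeans(((cmu - X)^2 + cnu^2) / 2)
}

#' Denoising reconstruction loss of one fuzzy layer
#'
#' Mean (optionally membership-weighted) squared fuzzy reconstruction error of
#' the corrupted data:
#' \eqn{J = \frac{1}{n}\sum_j w_j \, L(x_j, \mathrm{dec}(\mathrm{enc}(\tilde x_j)))^2}
#' with \eqn{L} the RMS crisp-fuzzy distance of
#' [crisp_fuzzy_vector_distance()].
#'
#' @param layer A `fuzzy_layer`.
#' @param data Matrix `n x d_in` in \[0, 1\] (a vector is one sample).
#' @param noise_level Masking probability; ignored when `masks` is given.
#' @param masks Optional pre-drawn 0/1 matrix of the same shape as `data`,
#'   making the loss deterministic (used during optimization so every genome
#'   sees the same corrupted inputs).
#' @param weights Optional non-negative per-row weights (default all 1).
#' @return A single non-negative number.
#' @export
layer_loss <- function(layer, data, noise_level = 0.2, masks = NULL, weights = NULL) {
  data <- if (is.matrix(data)) data else matrix(data, nrow = 1)
  if (nrow(data) == 0) stop("empty training data")
  xt <- if (!is.null(masks)) data * masks else corrupt(data, noise_level)
  recon <- decode(layer, encode(layer, xt))
  r <- row_sq_loss(data, recon)
  if (is.null(weights)) mean(r) else sum(weights * r) / length(r)
}

#' Construct a (possibly untrained) stacked fuzzy denoising autoencoder
#'
#' @param widths Integer vector of layer widths, input first
#'   (e.g. `c(80, 46, 26)` gives two fuzzy layers 80->46 and 46->26).
#' @param corruption Masking probability used during pretraining (default 0.2).
#' @param fan_in_scaling Passed to [decode_genome()].
#' @return An object of class `pfddae` with fields `widths`, `corruption`,
#'   `layers` (NULL until initialised/trained), `traces`, `trained`.
#' @export
pfddae <- function(widths, corruption = 0.2, fan_in_scaling = TRUE) {
  widths <- as.integer(widths)
  stopifnot(length(widths) >= 2, all(widths >= 1))
  structure(list(widths = widths, corruption = corruption,
                 fan_in_scaling = fan_in_scaling,
                 layers = NULL, traces = NULL, trained = FALSE),
            class = "pfddae")
}

#' @export
print.pfddae <- function(x, ...) {
  cat(sprintf("<pfddae %s, corruption %.2g, %s>\n",
              paste(x$widths, collapse = "/"), x$corruption,
              if (x$trained) sprintf("trained (final layer loss %.4g)",
                                     tail_loss(x)) else "untrained"))
  invisible(x)
}

tail_loss <- function(stack) {
  tr <- stack$traces[[length(stack$traces)]]
  if (is.null(tr)) NA_real_ else tr[length(tr)]
}

#' Initialise a stack with random genomes
#'
#' @param stack A `pfddae`.
#' @param seed Optional seed.
#' @return The stack with random (untrained) layers.
#' @export
init_random <- function(stack, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  w <- stack$widths
  stack$layers <- lapply(seq_len(length(w) - 1), function(k) {
    decode_genome(stats::runif(genome_length(w[k], w[k + 1])), w[k], w[k + 1],
                  stack$fan_in_scaling)
  })
  stack$norms <- NULL
  stack$trained <- FALSE
  stack
}

#' Greedy layer-wise unsupervised pretraining
#'
#' Each layer is trained in turn by water wave optimization over its gene
#' space, minimizing the (optionally membership-weighted) denoising
#' reconstruction loss; the defuzzified hidden representation of the clean
#' data is then fed forward as the next layer's training data.  The budget is
#' split equally across layers.
#'
#' @param stack A `pfddae`.
#' @param data Matrix `n x widths[1]` in \[0, 1\].
#' @param budget Total objective evaluations across all layers.
#' @param weights Optional per-row membership weights (group-specific
#'   pretraining).
#' @param seed Optional seed (controls corruption masks and the optimizer).
#' @param control Optional [wwo_control()]; its budget field is overridden by
#'   the per-layer share.
#' @param corruption_draws Number of fixed corruption-mask draws the layer
#'   objective averages over (default 4): keeps the objective deterministic
#'   while approximating the expectation over corruptions, so training cannot
#'   overfit one particular mask pattern.
#' @return The trained stack; `$traces` holds one best-so-far trace per layer.
#' @export
pretrain_stack <- function(stack, data, budget = 2000, weights = NULL,
                           seed = NULL, control = NULL, corruption_draws = 4) {
  data <- as.matrix(data)
  if (nrow(data) == 0) stop("empty training data")
  if (ncol(data) != stack$widths[1]) stop("data width must match widths[1]")
  n_layers <- length(stack$widths) - 1
  per_layer <- floor(budget / n_layers)
  if (is.null(control)) control <- wwo_control(stall_tol = 1e-6, stall_window = 250)
  if (per_layer < control$pop_size)
    stop("budget too small: fewer evaluations per layer than the population size")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max %/% 2, 1)
  control$budget <- per_layer

  x <- data
  layers <- vector("list", n_layers)
  traces <- vector("list", n_layers)
  norms <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    d_in <- stack$widths[k]; d_out <- stack$widths[k + 1]
    rng_old <- get_rng_state()
    set.seed(seed + k)
    n_draws <- if (stack$corruption > 0) corruption_draws else 1L
    masks <- lapply(seq_len(n_draws), function(r)
      matrix((stats::runif(length(x)) >= stack$corruption) + 0, nrow = nrow(x)))
    restore_rng_state(rng_old)
    obj <- function(genes) {
      layer <- decode_genome(genes, d_in, d_out, stack$fan_in_scaling)
      mean(vapply(masks, function(m)
        layer_loss(layer, x, masks = m, weights = weights), numeric(1)))
    }
    ng <- genome_length(d_in, d_out)
    fit <- wwo(obj, rep(0, ng), rep(1, ng), control, seed = seed + 1000L * k)
    layers[[k]] <- decode_genome(fit$par, d_in, d_out, stack$fan_in_scaling)
    traces[[k]] <- fit$trace
    h <- defuzz_mu(encode(layers[[k]], x))
    norms[[k]] <- fit_norm(h)
    x <- apply_norm(norms[[k]], h)
  }
  stack$layers <- layers
  stack$traces <- traces
  stack$norms <- norms
  stack$trained <- TRUE
  stack
}

# Per-feature affine contrast renormalization between stacked layers.  The
# fuzzy affine map is strongly contractive (all operational-law weights act in
# one direction and the fan-in exponent dilutes per-input sensitivity), so the
# defuzzified hidden features of successive layers collapse toward constants;
# rescaling each hidden feature to the [0, 1] span observed on the pretraining
# batch restores contrast, exactly as normalization layers do in crisp deep
# networks.  Near-constant features are pinned at 0.5.
fit_norm <- function(h) {
  lo <- apply(h, 2, min)
  span <- apply(h, 2, max) - lo
  flat <- span < 1e-12
  lo[flat] <- lo[flat] - 0.5
  span[flat] <- 1
  list(lo = lo, span = span)
}

apply_norm <- function(nrm, h) {
  pmin(pmax(sweep(sweep(h, 2, nrm$lo, "-"), 2, nrm$span, "/"), 0), 1)
}

invert_norm <- function(nrm, h) {
  pmin(pmax(sweep(sweep(h, 2, nrm$span, "*"), 2, nrm$lo, "+"), 0), 1)
}

#' Topmost defuzzified representation
#'
#' Folds the data through every encoder layer, defuzzifying (centroid-\eqn{\mu})
#' between layers; the result is a crisp matrix in \[0, 1\] of the topmost
#' width.
#'
#' @param stack An initialised `pfddae`.
#' @param x Vector or matrix of inputs.
#' @return Numeric matrix `n x widths[last]`.
#' @export
encode_topmost <- function(stack, x) {
  if (is.null(stack$layers)) stop("stack has no layers; pretrain or initialise it first")
  h <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  for (k in seq_along(stack$layers)) {
    h <- defuzz_mu(encode(stack$layers[[k]], h))
    if (!is.null(stack$norms)) h <- apply_norm(stack$norms[[k]], h)
  }
  h
}

#' Full-stack reconstruction
#'
#' Encodes through all layers and decodes back down; intermediate
#' representations are defuzzified, the final output is the fuzzy
#' reconstruction at the input layer.
#'
#' @inheritParams encode_topmost
#' @return A `pfn` with `n x widths[1]` matrices.
#' @export
reconstruct <- function(stack, x) {
  if (is.null(stack$layers)) stop("stack has no layers; pretrain or initialise it first")
  layers <- stack$layers
  h <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  raw <- vector("list", length(layers))    # pre-normalization hidden per layer
  for (k in seq_along(layers)) {
    raw[[k]] <- defuzz_mu(encode(layers[[k]], h))
    h <- if (is.null(stack$norms)) raw[[k]] else apply_norm(stack$norms[[k]], raw[[k]])
  }
  cur <- raw[[length(layers)]]
  for (k in rev(seq_along(layers))) {
    rec <- decode(layers[[k]], cur)
    if (k > 1) {
      # the decoder reproduces layer k's (normalized) input; map it back to the
      # raw hidden scale of layer k-1 before decoding further down
      h_norm <- defuzz_mu(rec)
      cur <- if (is.null(stack$norms)) h_norm
             else invert_norm(stack$norms[[k - 1]], h_norm)
    }
  }
  rec
}

#' Held-out reconstruction error of a stack
#'
#' Mean squared fuzzy reconstruction error of (optionally noise-corrupted)
#' inputs against the clean data.
#'
#' @inheritParams encode_topmost
#' @param noise_level Input corruption applied at evaluation time.
#' @param seed Optional seed for the evaluation-time corruption.
#' @return A single non-negative number.
#' @export
stack_reconstruction_error <- function(stack, x, noise_level = 0, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  x <- as.matrix(x)
  xin <- if (noise_level > 0) corrupt(x, noise_level) else x
  mean(row_sq_loss(x, reconstruct_from(stack, xin)))
}

# reconstruction where the (possibly corrupted) input differs from the target
reconstruct_from <- function(stack, xin) reconstruct(stack, xin)
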