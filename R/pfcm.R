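#' Pythagorean fuzzy c-means clustering
#'
#' Soft clustering of PFN-valued data points.  The per-coordinate distance is
#' the Pythagorean distance of [pfn_distance()] (Euclidean in
#' \eqn{(\mu^2, \nu^2, \pi^2)} space scaled by \eqn{1/\sqrt2}), aggregated over
#' coordinates as an RMS ([pfn_vector_distance()]).  The algorithm is the
#' classical alternating scheme: membership update, then centroid update,
#' until the membership matrix stabilises.  Because the metric is Euclidean in
#' squared-degree space, the weighted mean of \eqn{(\mu^2, \nu^2)} is the true
#' Frechet mean and the objective is non-increasing across updates.
#'
#' @name pfcm-module
NULL

# data as channel matrices (t1, t2, t3) = (mu^2, nu^2, pi^2) at centroids,
# each n x D.  Accepts a pfn with n x D arrays or a crisp matrix (fuzzified).
as_channel_data <- function(x) {
  if (!is_pfn(x)) x <- fuzzify(as.matrix(x))
  ch <- pfn_squared_channels(x)
  ch <- lapply(ch, function(m) if (is.matrix(m)) m else matrix(m, nrow = 1))
  ch
}

# squared RMS vector distances between all data points and centroids:
# returns c x n matrix of ||x_j, v_i||^2
channel_dist2 <- function(cen, dat) {
  d <- ncol(dat$t1)
  acc <- 0
  for (k in c("t1", "t2", "t3")) {
    a <- cen[[k]]; b <- dat[[k]]
    acc <- acc + (rowSums(a^2) %o% rep(1, nrow(b))) +
      (rep(1, nrow(a)) %o% rowSums(b^2)) - 2 * tcrossprod(a, b)
  }
  pmax(acc, 0) / (2 * d)
}

# rebuild degenerate-interval PFN centroids from channel matrices
channels_to_pfn <- function(cen) {
  t1 <- pmin(pmax(cen$t1, 0), 1); t2 <- pmin(pmax(cen$t2, 0), 1)
  s <- t1 + t2
  f <- ifelse(s > 1, 1 / s, 1)
  mu <- sqrt(t1 * f); nu <- sqrt(t2 * f)
  pfn(mu, mu, nu, nu)
}

#' Membership update of Pythagorean fuzzy c-means
#'
#' \eqn{u_{ij} = 1 / \sum_k (\|x_j, v_i\| / \|x_j, v_k\|)^{2/(m-1)}}.  When a
#' point coincides with one or more centroids, its membership is split equally
#' among the coincident clusters.
#'
#' @param data PFN data (a `pfn` with `n x D` arrays) or a crisp matrix
#'   (fuzzified with [fuzzify()]).
#' @param centroids A `pfn` with `c x D` arrays.
#' @param m Fuzzifier (> 1).
#' @return A `c x n` membership matrix with unit column sums.
#' @export
update_memberships <- function(data, centroids, m = 2) {
  dat <- as_channel_data(data)
  cen <- as_channel_data(centroids)
  d2 <- channel_dist2(cen, dat)
  memberships_from_dist2(d2, m)
}

memberships_from_dist2 <- function(d2, m, zero_tol = 1e-24) {
  cn <- dim(d2)
  u <- matrix(0, cn[1], cn[2])
  zero <- d2 < zero_tol
  has_zero <- colSums(zero) > 0
  if (any(has_zero)) {
    z <- zero[, has_zero, drop = FALSE]
    u[, has_zero] <- sweep(z, 2, colSums(z), "/")
  }
  if (any(!has_zero)) {
    r <- d2[, !has_zero, drop = FALSE]^(-1 / (m - 1))
    u[, !has_zero] <- sweep(r, 2, colSums(r), "/")
  }
  u
}

#' Centroid update of Pythagorean fuzzy c-means
#'
#' Weighted means of the squared degrees \eqn{(\mu^2, \nu^2)} with weights
#' \eqn{u_{ij}^m}, emitted as degenerate-interval PFN centroids (renormalized
#' radially in the rare case \eqn{\mu^2 + \nu^2 > 1}; for valid data the mean
#' is automatically valid by convexity).  A cluster with all-zero weights is
#' re-seeded at a random data point with a message.
#'
#' @inheritParams update_memberships
#' @param u Membership matrix `c x n` (column sums 1).
#' @return A `pfn` with `c x D` arrays.
#' @export
update_centroids <- function(data, u, m = 2) {
  dat <- as_channel_data(data)
  w <- u^m
  rs <- rowSums(w)
  dead <- rs < 1e-12
  if (any(dead)) {
    message(sprintf("re-seeding %d empty cluster(s) at random data points", sum(dead)))
    for (i in which(dead)) { w[i, ] <- 0; w[i, sample.int(ncol(u), 1)] <- 1 }
    rs <- rowSums(w)
  }
  cen <- list(t1 = (w %*% dat$t1) / rs, t2 = (w %*% dat$t2) / rs)
  channels_to_pfn(cen)
}

#' Clustering objective
#'
#' \eqn{J(U, V) = \frac{1}{cn} \sum_i \sum_j u_{ij}^m \|x_j, v_i\|^2} with the
#' RMS Pythagorean vector distance.
#'
#' @inheritParams update_centroids
#' @param centroids A `pfn` with `c x D` arrays.
#' @return A single non-negative number.
#' @export
pfcm_objective <- function(data, u, centroids, m = 2) {
  dat <- as_channel_data(data)
  cen <- as_channel_data(centroids)
  d2 <- channel_dist2(cen, dat)
  sum(u^m * d2) / length(u)
}

#' Pythagorean fuzzy c-means
#'
#' @param x PFN data (a `pfn` with `n x D` arrays) or a crisp numeric matrix
#'   in \[0, 1\] whose rows are fuzzified with [fuzzify()].
#' @param centers Number of clusters `c` (default 5) or a `pfn` of initial
#'   centroids (`c x D`).
#' @param m Fuzzifier (> 1, default 2).
#' @param eps Stop when the largest absolute membership change drops below
#'   this (default 1e-5).
#' @param max_iter Iteration cap (default 200).
#' @param u_floor Membership floor used by [group_training_set()] consumers;
#'   stored in the fit (default 0.1).
#' @param init `"random"` picks random data points as initial centroids;
#'   `"wwo"` searches initial centroids with [wwo()] (see
#'   [wwo_init_centroids()]).
#' @param wwo_budget Evaluation budget for `init = "wwo"`.
#' @param seed Optional seed.
#' @return An object of class `pfcm`: membership matrix `u` (`c x n`),
#'   centroids `v` (`pfn`, `c x D`), hard `cluster` assignment, objective
#'   `trace`, iteration count, and the call parameters.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(runif(40, 0, 0.3), 10), matrix(runif(40, 0.7, 1), 10))
#' fit <- pfcm(x, centers = 2, seed = 1)
#' fit$cluster
#' @export
pfcm <- function(x, centers = 5, m = 2, eps = 1e-5, max_iter = 200,
                 u_floor = 0.1, init = c("random", "wwo"), wwo_budget = 400,
                 seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  dat <- as_channel_data(x)
  n <- nrow(dat$t1)
  if (is_pfn(centers)) {
    v <- centers
    cc <- dim(v$mu_hi)[1]
  } else {
    cc <- as.integer(centers)
    stopifnot(cc >= 2, m > 1, eps > 0)
    if (n < cc) stop("need at least as many data points as clusters")
    if (init == "wwo") {
      v <- wwo_init_centroids(x, cc, m = m, budget = wwo_budget)
    } else {
      idx <- sample.int(n, cc)
      v <- channels_to_pfn(list(t1 = dat$t1[idx, , drop = FALSE],
                                t2 = dat$t2[idx, , drop = FALSE]))
    }
  }
  u_old <- NULL
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    u <- memberships_from_dist2(channel_dist2(as_channel_data(v), dat), m)
    v <- update_centroids(x, u, m)
    trace[iter] <- pfcm_objective(x, u, v, m)
    if (!is.null(u_old) && max(abs(u - u_old)) < eps) break
    if (iter >= max_iter) break
    u_old <- u
  }
  structure(list(u = u, v = v, cluster = apply(u, 2, which.max),
                 trace = trace, iterations = iter,
                 centers = cc, m = m, eps = eps, u_floor = u_floor),
            class = "pfcm")
}

#' @export
print.pfcm <- function(x, ...) {
  cat(sprintf("Pythagorean fuzzy c-means: c = %d, m = %g, %d iterations, J = %.6g\n",
              x$centers, x$m, x$iterations, x$trace[length(x$trace)]))
  cat("cluster sizes (hard assignment):",
      paste(tabulate(x$cluster, x$centers), collapse = ", "), "\n")
  invisible(x)
}

#' Search initial centroids with water wave optimization
#'
#' Each candidate position encodes `c x D` crisp values in \[0, 1\] that are
#' fuzzified into a centroid set; its fitness is the clustering objective
#' after a short alternating run started from those centroids.  The best
#' candidate is returned as the initial centroid set.
#'
#' @inheritParams pfcm
#' @param budget Objective evaluation budget.
#' @param inner_iter Alternating iterations used to score a candidate.
#' @return A `pfn` of initial centroids (`c x D`).
#' @export
wwo_init_centroids <- function(x, centers, m = 2, budget = 400, inner_iter = 3,
                               seed = NULL) {
  dat <- as_channel_data(x)
  d <- ncol(dat$t1)
  cc <- as.integer(centers)
  score <- function(pos) {
    v <- fuzzify(matrix(pmin(pmax(pos, 0), 1), nrow = cc))
    for (k in seq_len(inner_iter)) {
      u <- memberships_from_dist2(channel_dist2(as_channel_data(v), dat), m)
      v <- update_centroids(x, u, m)
    }
    pfcm_objective(x, u, v, m)
  }
  fit <- wwo(score, rep(0, cc * d), rep(1, cc * d),
             wwo_control(budget = budget), seed = seed)
  fuzzify(matrix(fit$par, nrow = cc))
}

#' Training subset of one group under the membership floor
#'
#' \eqn{T_i = \{x_j : u_{ij} > u_L\}} with the memberships attached as
#' weights.
#'
#' @param u Membership matrix `c x n`.
#' @param i Group index.
#' @param u_floor Membership floor \eqn{u_L}.
#' @return List with `idx` (column indices) and `weights` (their
#'   memberships).
#' @export
group_training_set <- function(u, i, u_floor = 0.1) {
  idx <- which(u[i, ] > u_floor)
  if (length(idx) == 0)
    stop("no data point exceeds the membership floor for this group; lower u_floor")
  list(idx = idx, weights = u[i, idx])
}
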