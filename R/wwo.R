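#' Control parameters for water wave optimization
#'
#' Operator constants follow the original water wave optimization method;
#' the training protocol here only fixes the evaluation budget, so every
#' constant is exposed.
#'
#' @param pop_size Number of waves (default 8).
#' @param h_max Maximum wave height: propagation failures tolerated before a
#'   wave refracts toward the best solution (default 6).
#' @param alpha Wavelength reduction base (> 1, default 1.0026).
#' @param beta_range Breaking coefficient, annealed geometrically from the
#'   first to the second value over the budget (default 0.25 to 0.001), so the
#'   local search around new bests refines at the same relative rate as the
#'   wavelengths.
#' @param k_max Maximum number of solitary waves per breaking event; `NULL`
#'   means `min(12, max(1, floor(D/2)))`.
#' @param lambda_init Initial wavelength as a fraction of the box (default 0.5).
#' @param eps Guard against division by zero in the wavelength update.
#' @param budget Total number of objective evaluations allowed.
#' @param stall_tol,stall_window Early stop: quit when the best-so-far value
#'   improves by less than `stall_tol` over `stall_window` consecutive
#'   evaluations (`stall_window = Inf` disables).
#' @return A list of class `wwo_control`.
#' @export
wwo_control <- function(pop_size = 8, h_max = 6, alpha = 1.0026,
                        beta_range = c(0.25, 0.001), k_max = NULL,
                        lambda_init = 0.5, eps = 1e-31, budget = 5000,
                        stall_tol = 1e-6, stall_window = Inf) {
  stopifnot(pop_size >= 2, h_max >= 1, alpha > 1, lambda_init > 0,
            budget >= pop_size, eps > 0)
  structure(list(pop_size = pop_size, h_max = h_max, alpha = alpha,
                 beta_range = beta_range, k_max = k_max,
                 lambda_init = lambda_init, eps = eps, budget = budget,
                 stall_tol = stall_tol, stall_window = stall_window),
            class = "wwo_control")
}

#' Propagation operator
#'
#' Shifts coordinates by `U(-1, 1) * lambda * len_d`; coordinates that leave
#' the box are re-drawn uniformly inside it.  In high dimension, perturbing
#' every coordinate at once makes improving moves vanishingly rare, so above
#' `active_dims` dimensions each coordinate is perturbed independently with
#' probability `active_dims / D` (at least one always moves); low-dimensional
#' problems keep the classical full-vector move.
#'
#' @param position Numeric vector, current wave position.
#' @param lambda Current wavelength.
#' @param lower,upper Box bounds (vectors of the same length).
#' @param active_dims Expected number of perturbed coordinates (default 24).
#' @return A candidate position inside the box.
#' @export
wwo_propagate <- function(position, lambda, lower, upper, active_dims = 24) {
  d <- length(position)
  len <- upper - lower
  step <- stats::runif(d, -1, 1) * lambda * len
  if (d > active_dims) {
    keep <- stats::runif(d) < active_dims / d
    if (!any(keep)) keep[sample.int(d, 1)] <- TRUE
    step[!keep] <- 0
  }
  x <- position + step
  out <- x < lower | x > upper
  if (any(out)) x[out] <- lower[out] + stats::runif(sum(out)) * len[out]
  x
}

#' Wavelength update
#'
#' After all fitnesses are known, each wavelength is multiplied by
#' `alpha^(-(f_max - f + eps) / (f_max - f_min + eps))` (minimization), so the
#' best wave takes the shortest steps and the worst keeps exploring.  With a
#' degenerate population (`f_max == f_min`) every exponent is about -1.
#'
#' @param lambda Vector of wavelengths.
#' @param fitness Vector of objective values (minimized).
#' @param alpha Reduction base.
#' @param eps Division guard.
#' @return Updated wavelength vector.
#' @export
wwo_update_wavelengths <- function(lambda, fitness, alpha = 1.0026, eps = 1e-31) {
  fmin <- min(fitness); fmax <- max(fitness)
  lambda * alpha^(-(fmax - fitness + eps) / (fmax - fmin + eps))
}

#' Refraction operator
#'
#' A stalled wave (height exhausted) is re-drawn between its position and the
#' best one: per dimension `N((x*_d + x_d)/2, |x*_d - x_d|/2)`.  When the wave
#' sits on the best position the Gaussian is degenerate and the wave moves
#' exactly onto it.
#'
#' @param position Stalled wave position.
#' @param best Best-so-far position.
#' @param lower,upper Box bounds.
#' @return New position inside the box.
#' @export
wwo_refract <- function(position, best, lower, upper) {
  x <- stats::rnorm(length(position), (best + position) / 2, abs(best - position) / 2)
  pmin(pmax(x, lower), upper)
}

#' Breaking operator
#'
#' Around a new best solution, launches `k` solitary waves, each perturbing one
#' randomly chosen dimension by `N(0, 1) * beta * len_d`.
#'
#' @param best Position to break around.
#' @param beta Breaking coefficient (fraction of the box).
#' @param lower,upper Box bounds.
#' @param k Number of solitary waves.
#' @return A `k x D` matrix of candidate positions.
#' @export
wwo_break <- function(best, beta, lower, upper, k) {
  d <- length(best)
  len <- upper - lower
  cand <- matrix(rep(best, each = k), nrow = k)
  dims <- sample.int(d, k, replace = TRUE)
  for (i in seq_len(k)) {
    j <- dims[i]
    cand[i, j] <- min(max(best[j] + stats::rnorm(1) * beta * len[j], lower[j]), upper[j])
  }
  cand
}

#' Water wave optimization
#'
#' Derivative-free minimizer used throughout the package to train fuzzy
#' autoencoder layers, fine-tune regression heads, and seed fuzzy c-means
#' centroids.  A population of waves evolves by propagation (wavelength-scaled
#' moves), refraction (stagnation reset toward the best), and breaking (local
#' search around new bests).  The best-so-far trace is monotone non-increasing
#' and the evaluation count never exceeds the budget.
#'
#' @param objective Function mapping a numeric vector to a scalar (minimized).
#'   Non-finite values are treated as `+Inf` with a warning.
#' @param lower,upper Numeric vectors delimiting the search box.
#' @param control A [wwo_control()] list.
#' @param init Optional matrix of initial positions (one per row) used to seed
#'   part of the initial population.
#' @param seed Optional integer seed; when given, the run is reproducible and
#'   the caller's RNG state is restored on exit.
#' @return An object of class `wwo_fit`: list with `par`, `value`, `trace`
#'   (best-so-far value after each evaluation), `evals`, and `control`.
#' @examples
#' fit <- wwo(function(x) sum(x^2), rep(-5, 4), rep(5, 4),
#'            wwo_control(budget = 2000), seed = 1)
#' fit$value
#' @export
wwo <- function(objective, lower, upper, control = wwo_control(), init = NULL,
                seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  d <- length(lower)
  stopifnot(length(upper) == d, all(lower < upper))
  np <- control$pop_size
  budget <- control$budget
  k_max <- if (is.null(control$k_max)) min(12L, max(1L, floor(d / 2))) else control$k_max
  len <- upper - lower

  warned <- FALSE
  evals <- 0L
  trace <- numeric(budget)
  best_par <- NULL
  best_val <- Inf
  stall_anchor <- c(0L, Inf)  # (eval index, best value) at window start

  stopped <- FALSE
  evaluate <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) {
      if (!warned) { warning("objective returned a non-finite value; treated as +Inf"); warned <<- TRUE }
      v <- Inf
    }
    evals <<- evals + 1L
    if (v < best_val) { best_val <<- v; best_par <<- x }
    trace[evals] <<- best_val
    # stall-based early stop bookkeeping
    if (evals - stall_anchor[1] >= control$stall_window) {
      if (stall_anchor[2] - best_val < control$stall_tol) stopped <<- TRUE
      stall_anchor <<- c(evals, best_val)
    }
    v
  }

  pos <- matrix(stats::runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                nrow = np)
  if (!is.null(init)) {
    init <- as.matrix(init)
    m <- min(nrow(init), np)
    pos[seq_len(m), ] <- pmin(pmax(init[seq_len(m), , drop = FALSE],
                                   rep(lower, each = m)), rep(upper, each = m))
  }
  fit <- apply(pos, 1, evaluate)
  lam <- rep(control$lambda_init, np)
  h <- rep(control$h_max, np)

  while (evals < budget && !stopped) {
    # geometric anneal of the breaking coefficient across the budget
    beta <- control$beta_range[1] *
      (control$beta_range[2] / control$beta_range[1])^(evals / budget)
    for (i in seq_len(np)) {
      if (evals >= budget || stopped) break
      cand <- wwo_propagate(pos[i, ], lam[i], lower, upper)
      v <- evaluate(cand)
      if (v < fit[i]) {
        pos[i, ] <- cand; fit[i] <- v; h[i] <- control$h_max
        if (v <= best_val) {
          # breaking around the new best (elitist: stored best never worsens)
          k <- min(k_max, budget - evals)
          if (k > 0) {
            bc <- wwo_break(cand, beta, lower, upper, k)
            for (b in seq_len(nrow(bc))) {
              bv <- evaluate(bc[b, ])
              if (bv < fit[i]) { pos[i, ] <- bc[b, ]; fit[i] <- bv }
              if (stopped) break
            }
          }
        }
      } else {
        h[i] <- h[i] - 1L
        if (h[i] <= 0L && evals < budget && !is.null(best_par)) {
          newp <- wwo_refract(pos[i, ], best_par, lower, upper)
          nv <- evaluate(newp)
          # wavelength rescaled by the fitness ratio (shrinks on improvement)
          ratio <- max(nv, control$eps) / max(fit[i], control$eps)
          if (is.finite(ratio)) lam[i] <- lam[i] * ratio
          pos[i, ] <- newp; fit[i] <- nv; h[i] <- control$h_max
        }
      }
    }
    flam <- fit
    if (any(!is.finite(flam)))   # cap +Inf so the update exponent stays finite
      flam[!is.finite(flam)] <- if (any(is.finite(flam)))
        max(flam[is.finite(flam)]) + 1 else 1
    lam <- wwo_update_wavelengths(lam, flam, control$alpha, control$eps)
    lam <- pmin(pmax(lam, 1e-12), 2)
  }

  structure(list(par = best_par, value = best_val, trace = trace[seq_len(evals)],
                 evals = evals, control = control),
            class = "wwo_fit")
}

#' @export
print.wwo_fit <- function(x, ...) {
  cat(sprintf("Water wave optimization fit: %d evaluations, best value %.6g\n",
              x$evals, x$value))
  invisible(x)
}

#' @export
plot.wwo_fit <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l", log = "y",
                 xlab = "objective evaluation", ylab = "best-so-far value", ...)
  invisible(x)
}

#' Random-search control optimizer
#'
#' Uniform sampling in the box at the same evaluation budget; used as the
#' paired control when assessing what structured search adds.
#'
#' @inheritParams wwo
#' @param budget Number of evaluations.
#' @return An object of class `wwo_fit` (same fields).
#' @export
random_search <- function(objective, lower, upper, budget, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  d <- length(lower)
  best_val <- Inf; best_par <- NULL
  trace <- numeric(budget)
  for (i in seq_len(budget)) {
    x <- lower + stats::runif(d) * (upper - lower)
    v <- objective(x)
    if (!is.finite(v)) v <- Inf
    if (v < best_val) { best_val <- v; best_par <- x }
    trace[i] <- best_val
  }
  structure(list(par = best_par, value = best_val, trace = trace,
                 evals = budget, control = NULL),
            class = "wwo_fit")
}

# -- RNG state helpers (keep seeded runs from clobbering the caller's stream) --
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
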