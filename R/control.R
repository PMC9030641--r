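#' Inverse control learner
#'
#' The control learner maps a required flight behavior (plus ambient
#' conditions, flight history, and the moth's fuzzy grouping) to the 32-lamp
#' stimulus vector expected to elicit it.  A fuzzy denoising autoencoder
#' stack learns a high-order representation of the control input, and a
#' linear regression head on the topmost representation emits the stimulus.
#' The head is initialised by inverse regression on rollout pairs (random
#' stimuli and the behaviors they produce) and then fine-tuned by water wave
#' optimization against the mixed physical/model-feedback loss, in which
#' model feedback is discounted by a weight reflecting how well the behavior
#' learner itself fits.
#'
#' @name control-module
NULL

#' Model-feedback weight
#'
#' \eqn{w_m = 1 - \sum_j J_R(j) / |T_m|}, the weight given to behavior-model
#' feedback relative to physical verification: the larger the behavior
#' learner's per-moth regression errors, the smaller the trust in its
#' feedback.  Clipped into \[0, 1\] with a warning if negative.
#'
#' @param individual_errors Per-moth weighted regression errors \eqn{J_R(j)}
#'   (outputs normalized to \[0, 1\]).
#' @param n_m Size of the model-feedback subset \eqn{|T_m|}.
#' @return A single number in \[0, 1\].
#' @export
compute_wm <- function(individual_errors, n_m) {
  if (n_m <= 0) stop("model-feedback subset is empty")
  w <- 1 - sum(individual_errors) / n_m
  if (w < 0) {
    warning("behavior learner errors exceed the feedback budget; w_m clipped to 0")
    w <- 0
  }
  min(w, 1)
}

# control input vector: [required(7) | ambient(34, wind normalized) |
#                        prev(7) | accum(7) | membership(c)]
control_input <- function(required, ambient, prev, accum, membership) {
  c(required, as.numeric(normalize_ambient(ambient)), prev, accum, membership)
}

#' Generate control instructions
#'
#' Samples achievable instructions: for each one, a context (ambient,
#' history) and a stimulus are drawn as in [generate_records()], the required
#' behavior is the cohort's noise-free response to that stimulus, and a
#' relevant-parameter mask marks which flight parameters the instruction
#' actually sets (a horizontal turn sets the first two, a vertical maneuver
#' the next two, an acceleration command the last three, and a full
#' instruction all seven).
#'
#' @param cohort A `moth_cohort`.
#' @param n Number of instructions.
#' @param seed Integer seed.
#' @param moth_ids Moths to draw from (default all in the cohort).
#' @return A list of class `instruction_set` with matrices `required`
#'   (`n x 7`), `relevant` (logical `n x 7`), `ambient` (`n x 34`, wind in
#'   m/s), `prev`, `accum` (`n x 7`), vector `moth_id`, and the generating
#'   `stimulus` (`n x 32`, the reference solution, not shown to the
#'   controller).
#' @export
generate_instructions <- function(cohort, n, seed = 1,
                                  moth_ids = cohort$moths$id) {
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  dyn <- cohort$dynamics
  masks <- rbind(c(1, 1, 0, 0, 0, 0, 0), c(0, 0, 1, 1, 0, 0, 0),
                 c(0, 0, 0, 0, 1, 1, 1), rep(1, 7)) > 0
  out <- list(required = matrix(NA_real_, n, 7), relevant = matrix(TRUE, n, 7),
              ambient = matrix(NA_real_, n, 34), prev = matrix(NA_real_, n, 7),
              accum = matrix(NA_real_, n, 7), moth_id = integer(n),
              stimulus = matrix(NA_real_, n, 32))
  for (k in seq_len(n)) {
    id <- sample(moth_ids, 1)
    s <- pmin(pmax(0.5 * stats::runif(32) +
                     0.5 * as.numeric(dyn$Q_s %*% stats::runif(8)), 0), 1)
    a <- pmin(pmax(0.5 * stats::runif(34) +
                     0.5 * as.numeric(dyn$Q_a %*% stats::runif(4)), 0), 1)
    a[WIND_COLS] <- a[WIND_COLS] * WIND_MAX
    prev <- stats::runif(7, 0.25, 0.75)
    accum <- prev
    y <- simulate_flight(cohort, id, s, a, prev, accum, noise = FALSE)
    out$required[k, ] <- y
    out$relevant[k, ] <- masks[sample.int(4, 1), ]
    out$ambient[k, ] <- a
    out$prev[k, ] <- prev
    out$accum[k, ] <- accum
    out$moth_id[k] <- id
    out$stimulus[k, ] <- s
  }
  structure(out, class = "instruction_set")
}

#' @export
print.instruction_set <- function(x, ...) {
  cat(sprintf("<instruction_set: %d instructions for %d moths>\n",
              nrow(x$required), length(unique(x$moth_id))))
  invisible(x)
}

# membership column of each instruction's moth (c x n -> n x c)
instruction_memberships <- function(instructions, behavior) {
  j <- match(instructions$moth_id, behavior$moth_ids)
  if (any(is.na(j))) stop("instruction references a moth unknown to the behavior learner")
  t(behavior$u[, j, drop = FALSE])
}

# batch matrix of control inputs for an instruction set
control_inputs <- function(instructions, behavior) {
  memb <- instruction_memberships(instructions, behavior)
  cbind(instructions$required, normalize_ambient(instructions$ambient),
        instructions$prev, instructions$accum, memb)
}

# behavior-model responses to a stimulus matrix under instruction contexts
behavior_respond <- function(behavior, instructions, S) {
  X <- cbind(S, normalize_ambient(instructions$ambient),
             instructions$prev, instructions$accum)
  predict(behavior, list(X = X, id = instructions$moth_id))
}

#' Ground-truth ("physical") responder
#'
#' Applies the cohort dynamics to a stimulus matrix under the instruction
#' contexts; the stand-in for stimulating physical moths.
#'
#' @param cohort A `moth_cohort`.
#' @param instructions An `instruction_set`.
#' @param S Stimulus matrix (`n x 32`).
#' @param noise Add observation noise (default `FALSE`).
#' @return Matrix `n x 7` of produced flight parameters.
#' @export
physical_respond <- function(cohort, instructions, S, noise = FALSE) {
  n <- nrow(S)
  out <- matrix(NA_real_, n, 7)
  for (k in seq_len(n))
    out[k, ] <- simulate_flight(cohort, instructions$moth_id[k], S[k, ],
                                instructions$ambient[k, ], instructions$prev[k, ],
                                instructions$accum[k, ], noise = noise)
  out
}

#' Mixed control loss
#'
#' \deqn{J_c = \big(\sum_{x \in T_p} \|x, o_p \circ o_c(x)\| +
#'   w_m \sum_{x \in T_m} \|x, o_m \circ o_c(x)\|\big) / |T_c|}
#' where \eqn{o_c} is the controller's stimulus, \eqn{o_p} the physical
#' responder, \eqn{o_m} the behavior learner, and \eqn{\|\cdot\|} the RMS
#' deviation across the 7 normalized flight parameters.
#'
#' @param required Matrix `n x 7` of required flight parameters.
#' @param produced_p Responses of the physical subset (`|T_p| x 7`, may have
#'   zero rows).
#' @param produced_m Responses of the model subset (`|T_m| x 7`).
#' @param p_idx,m_idx Row indices of the two subsets (a partition of
#'   `1..n`).
#' @param w_m Model-feedback weight.
#' @return A single non-negative number.
#' @export
control_loss <- function(required, produced_p, produced_m, p_idx, m_idx, w_m) {
  n <- nrow(required)
  if (n == 0) stop("empty instruction batch")
  if (length(intersect(p_idx, m_idx)) > 0 ||
      length(union(p_idx, m_idx)) != n)
    stop("p_idx and m_idx must partition the batch")
  dev <- function(idx, prod) {
    if (length(idx) == 0) return(0)
    sum(sqrt(rowMeans((required[idx, , drop = FALSE] - prod)^2)))
  }
  (dev(p_idx, produced_p) + w_m * dev(m_idx, produced_m)) / n
}

#' Train the control learner
#'
#' @param behavior A fitted [behavior_learner()].
#' @param cohort The `moth_cohort` (physical responder and rollout
#'   generation).
#' @param instructions Training `instruction_set`.
#' @param widths Stack widths; the default 75/49/35/32 is used with the first
#'   width replaced by the actual control-input width (55 + number of
#'   groups) when they differ.
#' @param corruption Pretraining masking noise (default 0.2).
#' @param t_p_frac Fraction of the training batch verified on the physical
#'   responder (default 0.1; the rest uses behavior-model feedback).
#' @param n_rollout Rollout pairs for the inverse-regression head
#'   initialisation.
#' @param budget_pretrain,budget_finetune Evaluation budgets for stack
#'   pretraining and head fine-tuning.
#' @param seed Integer seed.
#' @return An object of class `control_learner` with the stack, head
#'   coefficients, `w_m`, the fine-tuning trace, and the training loss.
#' @export
control_learner <- function(behavior, cohort, instructions,
                            widths = c(75, 49, 35, 32), corruption = 0.2,
                            t_p_frac = 0.1, n_rollout = 400,
                            budget_pretrain = 600, budget_finetune = 1200,
                            seed = 1) {
  if (is.null(behavior$individuals)) stop("behavior learner must be trained first")
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  c_groups <- nrow(behavior$u)
  d_in <- 55 + c_groups
  if (widths[1] != d_in) widths[1] <- d_in

  # rollout pairs for inverse regression: random stimuli under instruction-like
  # contexts, behavior produced by the responders the loss itself uses
  roll <- generate_instructions(cohort, n_rollout, seed = seed + 1,
                                moth_ids = behavior$moth_ids)
  n_p <- max(1L, round(t_p_frac * n_rollout))
  p_idx <- seq_len(n_p)
  m_idx <- setdiff(seq_len(n_rollout), p_idx)
  produced <- matrix(NA_real_, n_rollout, 7)
  produced[p_idx, ] <- physical_respond(cohort, roll[p_idx], roll$stimulus[p_idx, , drop = FALSE])
  produced[m_idx, ] <- behavior_respond(behavior, roll[m_idx], roll$stimulus[m_idx, , drop = FALSE])
  roll$required <- produced           # the behavior these stimuli produce

  U_in <- control_inputs(roll, behavior)
  stack <- pretrain_stack(pfddae(widths, corruption), U_in,
                          budget = budget_pretrain, seed = seed + 2)
  Z <- encode_topmost(stack, U_in)
  coef <- fit_mlr(Z, roll$stimulus)

  # fine-tune the head by WWO on the mixed loss over the instruction batch
  n_i <- nrow(instructions$required)
  ip <- seq_len(max(1L, round(t_p_frac * n_i)))
  im <- setdiff(seq_len(n_i), ip)
  w_m <- compute_wm(behavior$individual_errors, length(im))
  Zi <- encode_topmost(stack, control_inputs(instructions, behavior))
  span <- pmax(2 * abs(coef), 0.5)
  lower <- as.numeric(coef - span); upper <- as.numeric(coef + span)
  obj <- function(theta) {
    A <- matrix(theta, nrow = nrow(coef))
    S <- pmin(pmax(cbind(1, Zi) %*% A, 0), 1)
    pp <- physical_respond(cohort, instructions[ip], S[ip, , drop = FALSE])
    pm <- behavior_respond(behavior, instructions[im], S[im, , drop = FALSE])
    control_loss(instructions$required, pp, pm, ip, im, w_m)
  }
  fit <- wwo(obj, lower, upper, wwo_control(budget = budget_finetune),
             init = matrix(as.numeric(coef), nrow = 1), seed = seed + 3)
  coef <- matrix(fit$par, nrow = nrow(coef))

  structure(list(stack = stack, coef = coef, w_m = w_m, trace = fit$trace,
                 training_loss = fit$value, widths = widths,
                 t_p_frac = t_p_frac, n_groups = c_groups, seed = seed),
            class = "control_learner")
}

#' @export
print.control_learner <- function(x, ...) {
  cat(sprintf("Control learner: widths %s, w_m = %.4g, training loss %.4g\n",
              paste(x$widths, collapse = "/"), x$w_m, x$training_loss))
  invisible(x)
}

# subsetting an instruction set by row
#' @export
`[.instruction_set` <- function(x, i, ...) {
  structure(list(required = x$required[i, , drop = FALSE],
                 relevant = x$relevant[i, , drop = FALSE],
                 ambient = x$ambient[i, , drop = FALSE],
                 prev = x$prev[i, , drop = FALSE],
                 accum = x$accum[i, , drop = FALSE],
                 moth_id = x$moth_id[i],
                 stimulus = x$stimulus[i, , drop = FALSE]),
            class = "instruction_set")
}

#' Recommend stimuli for an instruction set
#'
#' @param object A fitted `control_learner`.
#' @param instructions An `instruction_set`.
#' @param behavior The behavior learner supplying the moth memberships.
#' @param ... Unused.
#' @return Matrix `n x 32` of stimulus vectors in \[0, 1\].
#' @export
predict.control_learner <- function(object, instructions, behavior, ...) {
  Z <- encode_topmost(object$stack, control_inputs(instructions, behavior))
  pmin(pmax(cbind(1, Z) %*% object$coef, 0), 1)
}

#' @rdname predict.control_learner
#' @export
recommend_stimulus <- function(object, instructions, behavior, ...) {
  predict(object, instructions, behavior, ...)
}

#' Success rate of closed-loop control
#'
#' An instruction succeeds when, for every relevant flight parameter, the
#' deviation of the produced value from the required value is below the
#' tolerance — by default 15% of the parameter's normalized full range
#' (`relative = "expected"` divides by the required value instead).
#'
#' @param produced,required Matrices `n x 7`.
#' @param relevant Logical `n x 7` mask of the parameters each instruction
#'   sets (default: all).
#' @param tol Deviation tolerance (default 0.15).
#' @param relative Deviation denominator: `"range"` (normalized full scale,
#'   i.e. 1) or `"expected"` (the required value).
#' @return A list with the success fraction `sr` and the per-instruction
#'   worst relevant deviation `deviation`.
#' @export
evaluate_success_rate <- function(produced, required, relevant = NULL,
                                  tol = 0.15,
                                  relative = c("range", "expected")) {
  relative <- match.arg(relative)
  if (nrow(required) == 0) stop("empty instruction set")
  if (is.null(relevant)) relevant <- matrix(TRUE, nrow(required), 7)
  dev <- abs(produced - required)
  if (relative == "expected") dev <- dev / pmax(abs(required), 1e-6)
  dev[!relevant] <- 0
  worst <- apply(dev, 1, max)
  list(sr = mean(worst < tol), deviation = worst)
}
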