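#' Three-hierarchy behavior learner
#'
#' The behavior learner predicts the seven flight parameters (horizontal and
#' vertical deflection angles and angular velocities, x/y/z accelerations)
#' from 80 input variables: 32 lamp-stimulus variables, 34 ambient variables,
#' and 14 flight-history variables (previous step plus an accumulation over
#' the previous three steps).  It is organised in three hierarchies:
#' \enumerate{
#'   \item a species-common fuzzy denoising autoencoder stack (80/46/26),
#'   \item per-group stacks (26/15/9) trained with membership-weighted losses
#'     on the moths of each fuzzy cluster,
#'   \item per-moth stacks (9/6/7) fed the membership-mixed group outputs,
#'     topped by a multivariable linear regression head.
#' }
#'
#' @name behavior-module
NULL

#' Default output-parameter weights
#'
#' Importance weights of the seven flight parameters in the regression loss:
#' horizontal deflection angle 0.24, horizontal angular velocity 0.2,
#' vertical deflection angle 0.2, vertical angular velocity 0.15, and 0.07
#' for each axis acceleration.  They sum to 1.
#'
#' @return Numeric vector of length 7.
#' @export
default_output_weights <- function() c(0.24, 0.2, 0.2, 0.15, 0.07, 0.07, 0.07)

#' Accumulate flight history
#'
#' Exponentially weighted accumulation of up to the previous three flight
#' parameter vectors, decay `gamma`, normalized over the steps available
#' (weights `(4, 2, 1)/7` for three steps at the default `gamma = 0.5`).
#' An empty history yields the zero vector.
#'
#' @param history Numeric matrix with up to 3 rows (most recent first), 7
#'   columns; rows beyond the third are ignored.
#' @param gamma Decay per step back in time (default 0.5).
#' @return Numeric vector of length 7.
#' @export
accumulate_history <- function(history, gamma = 0.5) {
  history <- if (is.matrix(history)) history else matrix(history, ncol = 7)
  k <- min(nrow(history), 3L)
  if (k == 0) return(rep(0, 7))
  w <- gamma^(seq_len(k) - 1)
  w <- w / sum(w)
  as.numeric(w %*% history[seq_len(k), , drop = FALSE])
}

#' Assemble the 80-variable model input
#'
#' Concatenates \[stimulus (32) | ambient (34) | previous parameters (7) |
#' accumulated history (7)\], normalising the ambient wind speeds by the
#' 1.5 m/s cap; a record whose wind exceeds the cap is rejected.
#'
#' @param stimulus Numeric vector of 32 lamp variables in \[0, 1\].
#' @param ambient Numeric vector of 34 ambient variables (wind in m/s).
#' @param prev Previous flight parameters (7).
#' @param accum Accumulated history (7).
#' @return Numeric vector of length 80 in \[0, 1\].
#' @export
build_input_vector <- function(stimulus, ambient, prev, accum) {
  if (length(stimulus) != 32 || length(ambient) != 34 ||
      length(prev) != 7 || length(accum) != 7)
    stop("input blocks must have lengths 32, 34, 7, 7")
  x <- c(stimulus, as.numeric(normalize_ambient(ambient)), prev, accum)
  if (any(x < -1e-9) || any(x > 1 + 1e-9))
    stop("input features must normalise into [0, 1]")
  pmin(pmax(x, 0), 1)
}

# batch conversion of a record table to (X, Y, id)
records_to_xy <- function(records) {
  check_record_schema(records)
  a <- as.matrix(records[, sprintf("a%02d", 1:34)])
  X <- cbind(as.matrix(records[, sprintf("s%02d", 1:32)]),
             normalize_ambient(a),
             as.matrix(records[, paste0("p", 1:7)]),
             as.matrix(records[, paste0("q", 1:7)]))
  colnames(X) <- NULL
  list(X = X, Y = as.matrix(records[, paste0("y", 1:7)]), id = records$id)
}

#' Weighted regression error of flight-parameter predictions
#'
#' \eqn{J_R = \frac{1}{n}\sum_j \sum_{d=1}^{7} w_d (y_{jd} - \hat y_{jd})^2}.
#'
#' @param pred,actual Numeric vectors of length 7 or `n x 7` matrices.
#' @param w Output weights (default [default_output_weights()]).
#' @return A single non-negative number.
#' @export
weighted_regression_error <- function(pred, actual, w = default_output_weights()) {
  pred <- if (is.matrix(pred)) pred else matrix(pred, ncol = 7)
  actual <- if (is.matrix(actual)) actual else matrix(actual, ncol = 7)
  if (!all(dim(pred) == dim(actual))) stop("prediction/actual length mismatch")
  mean(as.numeric((pred - actual)^2 %*% w))
}

#' Mix group-learner outputs into an individual-learner input
#'
#' \eqn{x_d = \sum_i u_i \, y'_d(i)} over the groups whose membership exceeds
#' the floor; by default the memberships are used unrenormalized after the
#' cut.
#'
#' @param u Membership vector of one moth (length c).
#' @param outputs List of c group outputs (vectors or matrices of equal
#'   width).
#' @param u_floor Membership floor.
#' @param renormalize Renormalize the surviving memberships to sum to 1.
#' @return The mixed output (same shape as each list entry).
#' @export
mix_group_outputs <- function(u, outputs, u_floor = 0.1, renormalize = FALSE) {
  keep <- which(u > u_floor)
  if (length(keep) == 0) stop("no group membership exceeds the floor")
  w <- u[keep]
  if (renormalize) w <- w / sum(w)
  out <- 0
  for (k in seq_along(keep)) out <- out + w[k] * outputs[[keep[k]]]
  out
}

# least squares with intercept, ridge fallback for rank deficiency
fit_mlr <- function(X, Y, ridge = 1e-6) {
  A <- cbind(1, X)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    message("rank-deficient regression design; ridge fallback applied")
    coef <- solve(crossprod(A) + diag(ridge, ncol(A)), crossprod(A, Y))
  } else {
    coef <- qr.coef(qrA, Y)
  }
  coef
}

#' Stimulus-response profiles for moth grouping
#'
#' For each moth, concatenates its shape features (wing span, body length,
#' mass) with the topmost common-layer representation of its response to each
#' of the 36 probes (3 ambient x 12 stimulus settings): the probe input uses
#' the probe stimulus and ambient with the moth's own (noise-free) probe
#' response as flight history, so the profile reflects how the individual,
#' not the probe, shapes the representation.
#'
#' @param common A pretrained `pfddae` (the species-common stack).
#' @param cohort A `moth_cohort` (supplies shapes and, absent measured
#'   responses, the responder used for probing).
#' @param probes Probe grid from [probe_settings()].
#' @param probe_responses Optional pre-measured responses, an
#'   `n_moths x 36 x 7` array overriding the simulated probe protocol.
#' @return Numeric matrix `n_moths x (3 + 36 * topmost width)` in \[0, 1\].
#' @export
compute_group_profiles <- function(common, cohort, probes = probe_settings(),
                                   probe_responses = NULL) {
  n_probe <- nrow(probes$ambient) * nrow(probes$stimulus)
  ids <- cohort$moths$id
  top <- common$widths[length(common$widths)]
  prof <- matrix(NA_real_, length(ids), 3 + n_probe * top)
  for (mi in seq_along(ids)) {
    Xp <- matrix(NA_real_, n_probe, 80)
    k <- 0
    for (ai in seq_len(nrow(probes$ambient))) {
      for (si in seq_len(nrow(probes$stimulus))) {
        k <- k + 1
        y <- if (is.null(probe_responses))
          simulate_flight(cohort, ids[mi], probes$stimulus[si, ],
                          probes$ambient[ai, ], noise = FALSE)
        else probe_responses[mi, k, ]
        Xp[k, ] <- build_input_vector(probes$stimulus[si, ],
                                      probes$ambient[ai, ], y, y)
      }
    }
    H <- encode_topmost(common, Xp)
    prof[mi, ] <- c(cohort$moths$wing_span[mi], cohort$moths$body_length[mi],
                    cohort$moths$mass[mi], as.numeric(t(H)))
  }
  rownames(prof) <- ids
  pmin(pmax(prof, 0), 1)
}

#' Fit the three-hierarchy behavior learner
#'
#' Pipeline: (1) pretrain the species-common stack on all records;
#' (2) compute stimulus-response profiles and group the moths with
#' Pythagorean fuzzy c-means; (3) pretrain one group stack per cluster on the
#' membership-filtered, membership-weighted topmost-common representations;
#' (4) per moth, mix the group outputs by membership, pretrain the individual
#' stack, and fit the linear regression head by least squares.
#'
#' @param records Record table in the canonical 89-column schema.
#' @param cohort The `moth_cohort` the records belong to (shapes and probe
#'   responder for grouping).
#' @param groups Number of fuzzy groups (default 5).
#' @param widths_common,widths_group,widths_individual Layer widths of the
#'   three hierarchies (defaults 80/46/26, 26/15/9, 9/6/7).
#' @param corruption Masking noise level for pretraining (default 0.2).
#' @param m Clustering fuzzifier (default 2).
#' @param u_floor Membership floor \eqn{u_L} (default 0.1).
#' @param budget Total pretraining budget in objective evaluations, split
#'   across the common stack (40%), the group stacks (30%) and the
#'   individual stacks (30%).
#' @param pretrain_sample Maximum number of records used in any one
#'   pretraining objective (a seeded subsample keeps each evaluation cheap).
#' @param pretrain_draws Corruption-mask draws averaged in each pretraining
#'   objective (see [pretrain_stack()]; default 2).
#' @param cluster_init Centroid initialisation for the grouping step
#'   (`"random"` or `"wwo"`).
#' @param renormalize_mixing Renormalize memberships after the floor cut in
#'   the group-output mixing (default `FALSE`).
#' @param output_weights Regression loss weights
#'   (default [default_output_weights()]).
#' @param seed Integer seed controlling every random element.
#' @return An object of class `behavior_learner` with the common stack,
#'   group stacks, membership matrix `u` (groups x moths), per-moth
#'   individual models, per-moth training errors `individual_errors`, and
#'   the overall weighted `training_error`.
#' @export
behavior_learner <- function(records, cohort, groups = 5,
                             widths_common = c(80, 46, 26),
                             widths_group = c(26, 15, 9),
                             widths_individual = c(9, 6, 7),
                             corruption = 0.2, m = 2, u_floor = 0.1,
                             budget = 3000, pretrain_sample = 400,
                             pretrain_draws = 2,
                             cluster_init = c("random", "wwo"),
                             renormalize_mixing = FALSE,
                             output_weights = default_output_weights(),
                             seed = 1) {
  cluster_init <- match.arg(cluster_init)
  xy <- records_to_xy(records)
  ids <- sort(unique(xy$id))
  if (widths_group[1] != widths_common[length(widths_common)])
    stop("group input width must equal the common topmost width")
  if (widths_individual[1] != widths_group[length(widths_group)])
    stop("individual input width must equal the group topmost width")

  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  sub <- function(X) {
    if (nrow(X) <= pretrain_sample) X
    else X[sample.int(nrow(X), pretrain_sample), , drop = FALSE]
  }

  # (1) species-common hierarchy
  common <- pretrain_stack(pfddae(widths_common, corruption), sub(xy$X),
                           budget = ceiling(0.4 * budget), seed = seed + 1,
                           corruption_draws = pretrain_draws)

  # (2) grouping on stimulus-response profiles
  profiles <- compute_group_profiles(common, cohort)
  profiles <- profiles[match(ids, cohort$moths$id), , drop = FALSE]
  grouping <- pfcm(profiles, centers = groups, m = m, u_floor = u_floor,
                   init = cluster_init, seed = seed + 2)
  u <- grouping$u                       # groups x moths

  # (3) group-specific hierarchy on topmost-common representations
  H <- encode_topmost(common, xy$X)
  rec_moth <- match(xy$id, ids)
  group_budget <- ceiling(0.3 * budget / groups)
  group_stacks <- vector("list", groups)
  for (i in seq_len(groups)) {
    ts <- group_training_set(u, i, u_floor)
    rows <- which(rec_moth %in% ts$idx)
    w_rec <- u[i, rec_moth[rows]]
    Hi <- H[rows, , drop = FALSE]
    keep <- if (nrow(Hi) > pretrain_sample) sample.int(nrow(Hi), pretrain_sample)
            else seq_len(nrow(Hi))
    group_stacks[[i]] <- pretrain_stack(pfddae(widths_group, corruption),
                                        Hi[keep, , drop = FALSE],
                                        budget = group_budget,
                                        weights = w_rec[keep],
                                        seed = seed + 10 + i,
                                        corruption_draws = pretrain_draws)
  }

  # (4) individual hierarchy + regression heads
  ind_budget <- max(ceiling(0.3 * budget / length(ids)), 8 * (length(widths_individual) - 1))
  individuals <- vector("list", length(ids))
  individual_errors <- numeric(length(ids))
  names(individuals) <- names(individual_errors) <- ids
  for (j in seq_along(ids)) {
    rows <- which(rec_moth == j)
    if (length(rows) < 10) stop("need at least 10 records per moth")
    Hj <- H[rows, , drop = FALSE]
    outputs <- lapply(group_stacks, function(gs) encode_topmost(gs, Hj))
    Mj <- mix_group_outputs(u[, j], outputs, u_floor, renormalize_mixing)
    stack_j <- pretrain_stack(pfddae(widths_individual, corruption), Mj,
                              budget = ind_budget, seed = seed + 100 + j,
                              corruption_draws = pretrain_draws)
    Tj <- encode_topmost(stack_j, Mj)
    coef <- fit_mlr(Tj, xy$Y[rows, , drop = FALSE])
    pred <- pmin(pmax(cbind(1, Tj) %*% coef, 0), 1)
    individuals[[j]] <- list(stack = stack_j, coef = coef)
    individual_errors[j] <- weighted_regression_error(pred, xy$Y[rows, , drop = FALSE],
                                                      output_weights)
  }

  fit <- structure(list(common = common, group_stacks = group_stacks,
                        grouping = grouping, u = u, moth_ids = ids,
                        individuals = individuals,
                        individual_errors = individual_errors,
                        u_floor = u_floor,
                        renormalize_mixing = renormalize_mixing,
                        output_weights = output_weights,
                        widths = list(common = widths_common,
                                      group = widths_group,
                                      individual = widths_individual),
                        seed = seed),
                   class = "behavior_learner")
  fit$training_error <- weighted_regression_error(
    predict(fit, records), xy$Y, output_weights)
  fit
}

#' @export
print.behavior_learner <- function(x, ...) {
  cat(sprintf("Three-hierarchy behavior learner: %d moths, %d groups\n",
              length(x$moth_ids), nrow(x$u)))
  cat(sprintf("  widths %s | %s | %s\n",
              paste(x$widths$common, collapse = "/"),
              paste(x$widths$group, collapse = "/"),
              paste(x$widths$individual, collapse = "/")))
  cat(sprintf("  weighted training error %.4g\n", x$training_error))
  invisible(x)
}

#' Predict flight parameters
#'
#' Runs records through the full hierarchy: common stack, membership-mixed
#' group stacks, the moth's individual stack, and its regression head;
#' outputs are clipped to \[0, 1\].
#'
#' @param object A fitted `behavior_learner`.
#' @param newdata Record table (the `y*` columns may be absent or ignored),
#'   or a list with fields `X` (`n x 80`) and `id`.
#' @param ... Unused.
#' @return Numeric matrix `n x 7` of predicted flight parameters.
#' @export
predict.behavior_learner <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    xy <- records_to_xy(newdata)
    X <- xy$X; id <- xy$id
  } else {
    X <- newdata$X; id <- newdata$id
  }
  j <- match(id, object$moth_ids)
  if (any(is.na(j))) stop("prediction requested for a moth unknown to the model")
  H <- encode_topmost(object$common, X)
  out <- matrix(NA_real_, nrow(H), 7)
  for (jj in unique(j)) {
    rows <- which(j == jj)
    Hj <- H[rows, , drop = FALSE]
    outputs <- lapply(object$group_stacks, function(gs) encode_topmost(gs, Hj))
    Mj <- mix_group_outputs(object$u[, jj], outputs, object$u_floor,
                            object$renormalize_mixing)
    ind <- object$individuals[[jj]]
    Tj <- encode_topmost(ind$stack, Mj)
    out[rows, ] <- pmin(pmax(cbind(1, Tj) %*% ind$coef, 0), 1)
  }
  out
}

#' Per-moth weighted regression errors on a record set
#'
#' @param object A fitted `behavior_learner`.
#' @param records Record table.
#' @param w Output weights.
#' @return Named numeric vector of per-moth errors.
#' @export
behavior_individual_errors <- function(object, records,
                                       w = object$output_weights) {
  xy <- records_to_xy(records)
  pred <- predict(object, records)
  ids <- sort(unique(xy$id))
  vapply(ids, function(id) {
    rows <- xy$id == id
    weighted_regression_error(pred[rows, , drop = FALSE],
                              xy$Y[rows, , drop = FALSE], w)
  }, numeric(1))
}

#' Monolithic comparator of equal parameter budget
#'
#' A single integrated fuzzy denoising autoencoder (default widths
#' 80/46/26/9/7, roughly the hierarchy's parameter count in one stack) with
#' one regression head shared across all moths; the architecture-ablation
#' baseline for the hierarchy.
#'
#' @inheritParams behavior_learner
#' @param widths Stack widths (input 80 first).
#' @return An object of class `monolithic_learner`.
#' @export
monolithic_learner <- function(records, widths = c(80, 46, 26, 9, 7),
                               corruption = 0.2, budget = 3000,
                               pretrain_sample = 400, pretrain_draws = 2,
                               output_weights = default_output_weights(),
                               seed = 1) {
  xy <- records_to_xy(records)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  Xs <- if (nrow(xy$X) > pretrain_sample)
    xy$X[sample.int(nrow(xy$X), pretrain_sample), , drop = FALSE] else xy$X
  stack <- pretrain_stack(pfddae(widths, corruption), Xs, budget = budget,
                          seed = seed + 1, corruption_draws = pretrain_draws)
  Tt <- encode_topmost(stack, xy$X)
  coef <- fit_mlr(Tt, xy$Y)
  pred <- pmin(pmax(cbind(1, Tt) %*% coef, 0), 1)
  structure(list(stack = stack, coef = coef,
                 training_error = weighted_regression_error(pred, xy$Y,
                                                            output_weights),
                 output_weights = output_weights),
            class = "monolithic_learner")
}

#' @export
predict.monolithic_learner <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) records_to_xy(newdata)$X else newdata$X
  Tt <- encode_topmost(object$stack, X)
  pmin(pmax(cbind(1, Tt) %*% object$coef, 0), 1)
}
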