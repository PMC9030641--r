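test_that("history accumulation has the declared EWMA weights", {
  v <- runif(7)
  expect_equal(accumulate_history(rbind(v, v, v)), v)     # constant history
  expect_equal(accumulate_history(matrix(numeric(0), ncol = 7)), rep(0, 7))
  # steps (1, 0, 0) most-recent-first with gamma = 0.5: weights (4, 2, 1)/7
  h <- rbind(rep(1, 7), rep(0, 7), rep(0, 7))
  expect_equal(accumulate_history(h), rep(4 / 7, 7))
  # only the three most recent steps count
  h4 <- rbind(h, rep(100, 7))
  expect_equal(accumulate_history(h4), accumulate_history(h))
})

test_that("input vectors concatenate and normalise the four blocks", {
  x <- build_input_vector(rep(0, 32), rep(0, 34), rep(0, 7), rep(0, 7))
  expect_equal(x, rep(0, 80))                              # all-minimum features
  amb <- rep(0.5, 34); amb[6] <- 1.5; amb[7] <- 0.75
  x2 <- build_input_vector(runif(32), amb, runif(7), runif(7))
  expect_length(x2, 80)
  expect_equal(x2[33 + 5], 1)                              # wind normalized by cap
  expect_equal(x2[33 + 6], 0.5)
  expect_error(build_input_vector(rep(0, 31), amb, rep(0, 7), rep(0, 7)),
               "lengths")
})

test_that("the regression loss applies the printed parameter weights", {
  w <- default_output_weights()
  expect_equal(sum(w), 1)
  p <- rep(0.5, 7)
  expect_equal(weighted_regression_error(p, p), 0)
  e1 <- rep(0.5, 7); e1[1] <- 1.5                          # unit error, dim 1
  expect_equal(weighted_regression_error(e1, p), 0.24)
  e4 <- rep(0.5, 7); e4[4] <- 1.5                          # unit error, dim 4
  expect_equal(weighted_regression_error(e4, p), 0.15)
  # two-record hand computation
  pred <- rbind(c(0.4, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
                c(0.5, 0.5, 0.8, 0.5, 0.5, 0.5, 0.2))
  act <- matrix(0.5, 2, 7)
  expect_equal(weighted_regression_error(pred, act),
               (0.24 * 0.01 + (0.2 * 0.09 + 0.07 * 0.09)) / 2)
})

test_that("group-output mixing follows the membership-weighted sum", {
  outs <- list(matrix(0.2, 2, 3), matrix(0.4, 2, 3), matrix(0.9, 2, 3))
  expect_equal(mix_group_outputs(c(0, 1, 0), outs, u_floor = 0.1), outs[[2]])
  mixed <- mix_group_outputs(c(0.5, 0.5, 0), outs, u_floor = 0.1)
  expect_equal(mixed, matrix(0.3, 2, 3))
  expect_error(mix_group_outputs(c(0.05, 0.05, 0.05), outs, u_floor = 0.1),
               "floor")
  renorm <- mix_group_outputs(c(0.4, 0.4, 0.05), outs, 0.1, renormalize = TRUE)
  expect_equal(renorm, matrix(0.3, 2, 3))
})

test_that("least-squares head recovers exact linear structure, ridge on deficiency", {
  set.seed(1)
  X <- matrix(runif(120), 20)
  B <- matrix(rnorm(49), 7)
  Y <- cbind(1, X[, 1:6]) %*% B
  coef <- cyborgmoth:::fit_mlr(X[, 1:6], Y)
  expect_equal(cbind(1, X[, 1:6]) %*% coef, Y, tolerance = 1e-8)
  # collinear design falls back to ridge with a message
  Xd <- cbind(X[, 1:3], X[, 3])
  expect_message(cyborgmoth:::fit_mlr(Xd, Y), "ridge")
})

test_that("profiles have the contracted layout and identical moths coincide", {
  co <- generate_cohort(n_moths = 4, n_groups = 2, seed = 2)
  # make moths 1 and 3 true clones (same group, offsets, shape)
  co$offsets[3, ] <- co$offsets[1, ]
  co$moths[3, c("wing_span", "body_length", "mass")] <-
    co$moths[1, c("wing_span", "body_length", "mass")]
  stack <- init_random(pfddae(c(80, 46, 26)), seed = 3)
  prof <- compute_group_profiles(stack, co)
  expect_equal(dim(prof), c(4, 3 + 36 * 26))
  expect_equal(prof[3, ], prof[1, ], ignore_attr = TRUE)
  expect_true(all(prof >= 0 & prof <= 1))
})

test_that("the fitted hierarchy honors the end-to-end shape contract", {
  fit <- tiny_behavior()
  expect_equal(fit$widths$common, c(80, 46, 26))
  expect_equal(fit$widths$group, c(26, 15, 9))
  expect_equal(fit$widths$individual, c(9, 6, 7))
  rec <- tiny_records()
  xy <- cyborgmoth:::records_to_xy(rec)
  H <- encode_topmost(fit$common, xy$X[1:5, ])
  expect_equal(ncol(H), 26)
  G1 <- encode_topmost(fit$group_stacks[[1]], H)
  expect_equal(ncol(G1), 9)
  Tj <- encode_topmost(fit$individuals[[1]]$stack, G1)
  expect_equal(ncol(Tj), 7)
  pred <- predict(fit, rec[1:10, ])
  expect_equal(dim(pred), c(10, 7))
  expect_true(all(pred >= 0 & pred <= 1))
  expect_identical(pred, predict(fit, rec[1:10, ]))       # deterministic
  expect_equal(colSums(fit$u), rep(1, length(fit$moth_ids)), tolerance = 1e-9)
  # width mismatches between hierarchies are rejected up front
  expect_error(behavior_learner(rec, tiny_cohort(), groups = 2,
                                widths_group = c(20, 15, 9), budget = 600),
               "common topmost width")
})

test_that("prediction refuses moths the model has never seen", {
  fit <- tiny_behavior()
  rec <- tiny_records()[1:4, ]
  rec$id <- 999
  expect_error(predict(fit, rec), "unknown")
})

test_that("per-moth errors aggregate to the training error", {
  fit <- tiny_behavior()
  errs <- behavior_individual_errors(fit, tiny_records())
  expect_length(errs, length(fit$moth_ids))
  expect_true(all(errs >= 0))
  # the record-weighted mean of per-moth errors equals the pooled error
  rec <- tiny_records()
  n_per <- as.numeric(table(rec$id))
  pooled <- weighted_regression_error(
    predict(fit, rec), as.matrix(rec[, paste0("y", 1:7)]), fit$output_weights)
  expect_equal(sum(errs * n_per) / sum(n_per), pooled, tolerance = 1e-10)
})

test_that("the monolithic comparator trains and predicts in shape", {
  mono <- monolithic_learner(tiny_records(), budget = 800, seed = 12)
  pred <- predict(mono, tiny_records()[1:6, ])
  expect_equal(dim(pred), c(6, 7))
  expect_true(all(pred >= 0 & pred <= 1))
})
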