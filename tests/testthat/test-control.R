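test_that("the model-feedback weight responds inversely to behavior error", {
  expect_equal(compute_wm(rep(0, 10), 100), 1)             # perfect learner
  expect_equal(compute_wm(rep(0.03, 10), 1), 0.7)          # direct substitution
  expect_warning(w0 <- compute_wm(c(0.9, 0.6), 1), "clipped")
  expect_equal(w0, 0)
  expect_error(compute_wm(0.1, 0), "empty")
  # strictly decreasing in the error total
  expect_lt(compute_wm(rep(0.05, 4), 10), compute_wm(rep(0.01, 4), 10))
})

test_that("the mixed control loss matches hand summation and its invariances", {
  req <- rbind(rep(0.5, 7), rep(0.2, 7))
  # identity loop: produced equals required
  expect_equal(control_loss(req, req[1, , drop = FALSE], req[2, , drop = FALSE],
                            1, 2, w_m = 0.8), 0)
  # two-instruction hand oracle
  pp <- matrix(0.6, 1, 7)                                  # physical, off by 0.1
  pm <- matrix(0.5, 1, 7)                                  # model, off by 0.3
  got <- control_loss(req, pp, pm, 1, 2, w_m = 0.5)
  expect_equal(got, (0.1 + 0.5 * 0.3) / 2)
  # empty physical subset with w_m = 1 is the pure model-feedback loss
  expect_equal(control_loss(req, req[0, , drop = FALSE], rbind(pp, pm),
                            integer(0), 1:2, w_m = 1),
               (sqrt(mean((req[1, ] - 0.6)^2)) + sqrt(mean((req[2, ] - 0.5)^2))) / 2)
  # instruction order inside a subset does not matter
  req3 <- matrix(runif(21), 3)
  pm3 <- matrix(runif(21), 3)
  a <- control_loss(req3, req3[0, , drop = FALSE], pm3, integer(0), 1:3, 0.7)
  b <- control_loss(req3[3:1, ], req3[0, , drop = FALSE], pm3[3:1, ],
                    integer(0), 1:3, 0.7)
  expect_equal(a, b)
  expect_error(control_loss(req, pp, pm, 1, 1, 0.5), "partition")
  expect_error(control_loss(req[0, , drop = FALSE], pp, pm, 1, 2, 0.5), "empty")
})

test_that("the success rule counts instructions by their relevant parameters", {
  req <- matrix(0.5, 4, 7)
  prod <- req
  prod[, 1] <- 0.5 + c(0.10, 0.14, 0.16, 0.50)      # known deviations on dim 1
  rel <- matrix(FALSE, 4, 7); rel[, 1] <- TRUE
  res <- evaluate_success_rate(prod, req, rel, tol = 0.15)
  expect_equal(res$sr, 0.5)
  expect_equal(res$deviation, c(0.10, 0.14, 0.16, 0.50))
  expect_equal(evaluate_success_rate(req, req)$sr, 1)       # perfect responder
  off <- req; off[, 3] <- 0.7                               # 20% off everywhere
  expect_equal(evaluate_success_rate(off, req)$sr, 0)
  # irrelevant parameters are ignored even when badly off
  rel2 <- matrix(TRUE, 4, 7); rel2[, 3] <- FALSE
  expect_equal(evaluate_success_rate(off, req, rel2)$sr, 1)
  # expected-relative variant rescales by the required value
  r1 <- matrix(0.5, 1, 7); p1 <- matrix(0.56, 1, 7)
  expect_equal(evaluate_success_rate(p1, r1, tol = 0.15, relative = "expected")$sr, 1)
  expect_equal(evaluate_success_rate(p1, r1, tol = 0.10, relative = "expected")$sr, 0)
  expect_error(evaluate_success_rate(req[0, , drop = FALSE], req[0, , drop = FALSE]),
               "empty")
})

test_that("generated instructions are achievable and well-formed", {
  co <- tiny_cohort()
  ins <- generate_instructions(co, 30, seed = 21)
  expect_equal(dim(ins$required), c(30, 7))
  expect_true(all(ins$required >= 0 & ins$required <= 1))
  expect_true(all(rowSums(ins$relevant) %in% c(2, 3, 7)))
  # the stored reference stimulus reproduces the required behavior exactly
  prod <- physical_respond(co, ins, ins$stimulus)
  expect_equal(prod, ins$required, tolerance = 1e-12)
  sub <- ins[4:6]
  expect_equal(sub$required, ins$required[4:6, ])
  expect_equal(sub$moth_id, ins$moth_id[4:6])
})

test_that("a trained controller recommends in-range, reproducible stimuli", {
  fit <- tiny_behavior()
  co <- tiny_cohort()
  ins <- generate_instructions(co, 40, seed = 22)
  ctl <- control_learner(fit, co, ins, n_rollout = 120, budget_pretrain = 300,
                         budget_finetune = 300, seed = 23)
  expect_true(ctl$w_m >= 0 && ctl$w_m <= 1)
  expect_true(all(diff(ctl$trace) <= 0))                   # monotone fine-tuning
  expect_equal(ctl$widths[1], 55 + 2)                      # input-width override
  S <- recommend_stimulus(ctl, ins, fit)
  expect_equal(dim(S), c(40, 32))
  expect_true(all(S >= 0 & S <= 1))
  expect_identical(S, recommend_stimulus(ctl, ins, fit))
  # JSON round-trip preserves the controller
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_control(ctl, p1)
  back <- read_control(p1)
  expect_equal(recommend_stimulus(back, ins, fit), S, tolerance = 1e-12)
  write_instructions(ins, p2)
  ins2 <- read_instructions(p2)
  expect_equal(ins2$required, ins$required, tolerance = 1e-12)
  expect_equal(ins2$relevant, ins$relevant)
  unlink(c(p1, p2))
})

test_that("degrading the behavior learner strictly decreases w_m", {
  fit <- tiny_behavior()
  rec <- tiny_records()
  degraded <- fit
  set.seed(24)
  for (j in seq_along(degraded$individuals))
    degraded$individuals[[j]]$coef <-
      degraded$individuals[[j]]$coef + matrix(rnorm(8 * 7, 0, 0.3), 8)
  e_good <- behavior_individual_errors(fit, rec)
  e_bad <- behavior_individual_errors(degraded, rec)
  expect_gt(sum(e_bad), sum(e_good))
  n_m <- 50
  expect_lt(compute_wm(e_bad, n_m), compute_wm(e_good, n_m))
})
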