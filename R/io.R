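#' Record tables, configuration, and the evaluation harness
#'
#' Flight records travel as tab-delimited text in a fixed 89-column schema:
#' `id, t, s01..s32 (stimulus), a01..a34 (ambient, wind in m/s), p1..p7
#' (previous parameters), q1..q7 (accumulated history), y1..y7 (targets)`.
#'
#' @name io-module
NULL

check_record_schema <- function(records) {
  want <- record_columns()
  if (!identical(names(records), want)) {
    missing <- setdiff(want, names(records))
    extra <- setdiff(names(records), want)
    stop(sprintf("record table schema mismatch%s%s",
                 if (length(missing)) paste0("; missing: ",
                                             paste(missing, collapse = ", ")) else "",
                 if (length(extra)) paste0("; unexpected: ",
                                           paste(extra, collapse = ", ")) else ""))
  }
  bad <- !vapply(records, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric record columns: ", paste(want[bad], collapse = ", "))
  if (anyDuplicated(records[, c("id", "t")]))
    stop("duplicate (id, t) rows in record table")
  invisible(records)
}

#' Read / write flight record tables
#'
#' Tab-delimited with a mandatory header; the schema (column names, numeric
#' types, unique `(id, t)`) is validated strictly, and `save_records` /
#' `load_records` round-trip exactly.
#'
#' @param path File path.
#' @param records Record data frame in the canonical schema.
#' @return `load_records` returns the validated data frame;
#'   `save_records` returns `path` invisibly.
#' @export
load_records <- function(path) {
  records <- utils::read.delim(path, check.names = FALSE)
  check_record_schema(records)
}

#' @rdname load_records
#' @export
save_records <- function(records, path) {
  check_record_schema(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Every tunable of the stack with its default: layer widths, clustering
#' parameters (c = 5, m = 2, membership floor 0.1), corruption level 0.2,
#' the 200 ms time step, the 1.5 m/s wind cap, the 15% success tolerance,
#' the flight-parameter weights, cross-validation folds (5) and repeats
#' (20), and the optimizer budget (100,000 evaluations for a full run;
#' `quick_budget` is the scaled-down default the bundled examples use).
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    widths = list(common = c(80, 46, 26), group = c(26, 15, 9),
                  individual = c(9, 6, 7), control = c(75, 49, 35, 32)),
    clustering = list(groups = 5, m = 2, u_floor = 0.1, eps = 1e-5,
                      max_iter = 200, init = "wwo"),
    pretrain = list(corruption = 0.2, budget = 100000, quick_budget = 5000),
    records = list(step_ms = 200, wind_max = 1.5),
    output_weights = default_output_weights(),
    control = list(tol = 0.15, t_p_frac = 0.1),
    evaluation = list(folds = 5, repeats = 20),
    seed = 1
  )
}

#' Load and validate a YAML configuration
#'
#' Values missing from the file keep their defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return The merged configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user, "config")
}

merge_config <- function(base, user, where) {
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s) under %s: %s", where,
                 paste(unknown, collapse = ", ")))
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && !is.null(names(base[[k]])))
      merge_config(base[[k]], user[[k]], paste(where, k, sep = "."))
    else user[[k]]
  }
  base
}

#' Five-fold cross-validation of the behavior learner
#'
#' Partitions the records into disjoint folds (deterministically under the
#' seed), trains the behavior learner on the complement of each fold,
#' and scores the held-out weighted regression error; repeated with
#' different training seeds.
#'
#' @param records Record table.
#' @param cohort The matching `moth_cohort`.
#' @param folds Number of folds (default 5).
#' @param repeats Training repetitions per fold (default 2).
#' @param seed Integer seed (fold assignment and training).
#' @param ... Passed to [behavior_learner()] (groups, budgets, widths...).
#' @return An object of class `cv_report`: fold assignment, a
#'   `repeats x folds` error matrix, and the summary mean and standard
#'   deviation.
#' @export
run_cv <- function(records, cohort, folds = 5, repeats = 2, seed = 1, ...) {
  check_record_schema(records)
  n <- nrow(records)
  if (n < 5 * folds) stop("too few records for cross-validation")
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  errors <- matrix(NA_real_, repeats, folds)
  for (r in seq_len(repeats)) {
    for (f in seq_len(folds)) {
      train <- records[fold != f, , drop = FALSE]
      test <- records[fold == f, , drop = FALSE]
      fit <- behavior_learner(train, cohort, seed = seed + 100 * r + f, ...)
      pred <- predict(fit, test)
      errors[r, f] <- weighted_regression_error(
        pred, as.matrix(test[, paste0("y", 1:7)]), fit$output_weights)
    }
  }
  structure(list(fold = fold, errors = errors,
                 mean = mean(errors), sd = stats::sd(as.numeric(errors)),
                 folds = folds, repeats = repeats, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d repeat(s): error %.4g +/- %.4g\n",
              x$folds, x$repeats, x$mean, x$sd))
  invisible(x)
}

# ---- JSON serialization of models -----------------------------------------

pfn_to_list <- function(p) {
  lapply(unclass(p), function(ch) { dm <- dim(ch); list(dim = dm, values = as.numeric(ch)) })
}

pfn_from_list <- function(l) {
  ch <- lapply(l, function(e) {
    v <- as.numeric(e$values)
    if (!is.null(e$dim) && length(e$dim)) dim(v) <- as.integer(e$dim)
    v
  })
  structure(ch, class = "pfn")
}

stack_to_list <- function(stack) {
  list(widths = stack$widths, corruption = stack$corruption,
       fan_in_scaling = stack$fan_in_scaling, trained = stack$trained,
       layers = lapply(stack$layers, function(l)
         list(W = pfn_to_list(l$W), b = pfn_to_list(l$b),
              b_dec = pfn_to_list(l$b_dec))),
       norms = lapply(stack$norms, function(n)
         list(lo = as.numeric(n$lo), span = as.numeric(n$span))))
}

stack_from_list <- function(l) {
  s <- pfddae(unlist(l$widths), l$corruption, isTRUE(l$fan_in_scaling))
  s$layers <- lapply(l$layers, function(e)
    fuzzy_layer(pfn_from_list(e$W), pfn_from_list(e$b), pfn_from_list(e$b_dec)))
  if (length(l$norms))
    s$norms <- lapply(l$norms, function(n)
      list(lo = as.numeric(unlist(n$lo)), span = as.numeric(unlist(n$span))))
  s$trained <- isTRUE(l$trained)
  s
}

#' Serialize a fuzzy stack to JSON
#'
#' Layer dimensions and the PFN 4-tuples, written as plain JSON so models
#' survive as text.
#'
#' @param stack A `pfddae`.
#' @param path Output file.
#' @return `path` invisibly; `read_stack` returns the `pfddae`.
#' @export
write_stack <- function(stack, path) {
  jsonlite::write_json(stack_to_list(stack), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) stack_from_list(jsonlite::read_json(path))
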