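# JSON serialization of the larger model objects (text-only artifacts for the
# command-line interface).  Matrices travel as {dim, values} pairs.

mat_to_list <- function(m) list(dim = dim(m), values = as.numeric(m))
mat_from_list <- function(l) {
  v <- as.numeric(unlist(l$values))
  if (!is.null(l$dim) && length(l$dim)) dim(v) <- as.integer(unlist(l$dim))
  v
}

#' Serialize a synthetic cohort to JSON
#'
#' @param cohort A `moth_cohort`.
#' @param path Output file.
#' @return `path` invisibly; `read_cohort` returns the `moth_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  dyn <- cohort$dynamics
  obj <- list(moths = cohort$moths, offsets = mat_to_list(cohort$offsets),
              dynamics = list(G = lapply(dyn$G, mat_to_list),
                              A_amb = mat_to_list(dyn$A_amb),
                              A_prev = mat_to_list(dyn$A_prev),
                              Q_s = mat_to_list(dyn$Q_s),
                              Q_a = mat_to_list(dyn$Q_a),
                              gain = dyn$gain, sigma_obs = dyn$sigma_obs),
              n_groups = cohort$n_groups, separation = cohort$separation,
              sigma_ind = cohort$sigma_ind, seed = cohort$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(
    moths = as.data.frame(lapply(o$moths, unlist)),
    offsets = mat_from_list(o$offsets),
    dynamics = list(G = lapply(o$dynamics$G, mat_from_list),
                    A_amb = mat_from_list(o$dynamics$A_amb),
                    A_prev = mat_from_list(o$dynamics$A_prev),
                    Q_s = mat_from_list(o$dynamics$Q_s),
                    Q_a = mat_from_list(o$dynamics$Q_a),
                    gain = o$dynamics$gain, sigma_obs = o$dynamics$sigma_obs),
    n_groups = o$n_groups, separation = o$separation,
    sigma_ind = o$sigma_ind, seed = o$seed), class = "moth_cohort")
}

#' Serialize a fitted behavior learner to JSON
#'
#' @param model A `behavior_learner`.
#' @param path Output file.
#' @return `path` invisibly; `read_behavior` returns the model (without the
#'   clustering diagnostics object, which is not needed for prediction).
#' @export
write_behavior <- function(model, path) {
  obj <- list(common = stack_to_list(model$common),
              group_stacks = lapply(model$group_stacks, stack_to_list),
              u = mat_to_list(model$u), moth_ids = model$moth_ids,
              individuals = lapply(model$individuals, function(ind)
                list(stack = stack_to_list(ind$stack),
                     coef = mat_to_list(ind$coef))),
              individual_errors = as.numeric(model$individual_errors),
              u_floor = model$u_floor,
              renormalize_mixing = model$renormalize_mixing,
              output_weights = model$output_weights,
              widths = model$widths, training_error = model$training_error,
              seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  o <- jsonlite::read_json(path)
  ids <- as.numeric(unlist(o$moth_ids))
  structure(list(
    common = stack_from_list(o$common),
    group_stacks = lapply(o$group_stacks, stack_from_list),
    grouping = NULL, u = mat_from_list(o$u), moth_ids = ids,
    individuals = stats::setNames(lapply(o$individuals, function(ind)
      list(stack = stack_from_list(ind$stack), coef = mat_from_list(ind$coef))),
      ids),
    individual_errors = stats::setNames(as.numeric(unlist(o$individual_errors)), ids),
    u_floor = o$u_floor, renormalize_mixing = isTRUE(o$renormalize_mixing),
    output_weights = as.numeric(unlist(o$output_weights)),
    widths = lapply(o$widths, function(w) as.integer(unlist(w))),
    training_error = o$training_error, seed = o$seed),
    class = "behavior_learner")
}

#' Serialize a fitted control learner to JSON
#'
#' @param model A `control_learner`.
#' @param path Output file.
#' @return `path` invisibly; `read_control` returns the model.
#' @export
write_control <- function(model, path) {
  obj <- list(stack = stack_to_list(model$stack), coef = mat_to_list(model$coef),
              w_m = model$w_m, widths = model$widths,
              t_p_frac = model$t_p_frac, n_groups = model$n_groups,
              training_loss = model$training_loss, seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_control
#' @export
read_control <- function(path) {
  o <- jsonlite::read_json(path)
  structure(list(stack = stack_from_list(o$stack), coef = mat_from_list(o$coef),
                 w_m = o$w_m, trace = NULL, training_loss = o$training_loss,
                 widths = as.integer(unlist(o$widths)),
                 t_p_frac = o$t_p_frac, n_groups = o$n_groups, seed = o$seed),
            class = "control_learner")
}

#' Serialize an instruction set to JSON
#'
#' @param instructions An `instruction_set`.
#' @param path Output file.
#' @return `path` invisibly; `read_instructions` returns the set.
#' @export
write_instructions <- function(instructions, path) {
  obj <- lapply(unclass(instructions), function(e)
    if (is.matrix(e)) mat_to_list(e * 1) else e)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_instructions
#' @export
read_instructions <- function(path) {
  o <- jsonlite::read_json(path)
  out <- list(required = mat_from_list(o$required),
              relevant = mat_from_list(o$relevant) > 0,
              ambient = mat_from_list(o$ambient),
              prev = mat_from_list(o$prev), accum = mat_from_list(o$accum),
              moth_id = as.numeric(unlist(o$moth_id)),
              stimulus = mat_from_list(o$stimulus))
  structure(out, class = "instruction_set")
}
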