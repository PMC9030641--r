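#' Synthetic moth cohorts and flight records
#'
#' The generator emulates the statistical structure the learners assume:
#' a cohort of moths with latent group structure in the stimulus-to-response
#' mapping, individual-specific response offsets, morphological (shape)
#' features correlated with the group, bounded observation noise, and flight
#' records on a 200 ms grid whose features all normalise into \[0, 1\]
#' (ambient wind speed capped at 1.5 m/s).
#'
#' The ground-truth dynamics are deliberately low-dimensional: the 32 lamp
#' variables act through 7 interpretable stimulus summaries (left-right
#' intensity and duration contrasts, overall intensity/duration/velocity/
#' distance levels, UVA-UVB contrast), so the stimulus-to-behavior map is
#' injective on those summaries and invertible control is well posed.  The
#' horizontal deflection angle responds only to left-right contrasts, so a
#' left/right-symmetric stimulus gives a normalized deflection of exactly 0.5
#' (no turn) in expectation.
#'
#' @name synthetic-module
NULL

# canonical 89-column record schema
record_columns <- function() {
  c("id", "t", sprintf("s%02d", 1:32), sprintf("a%02d", 1:34),
    paste0("p", 1:7), paste0("q", 1:7), paste0("y", 1:7))
}

# stimulus layout: 4 lamps x 8 vars (intensity, duration, vel x/y/z, dist x/y/z);
# lamps 1-2 are left (UVA, UVB), lamps 3-4 are right (UVA, UVB).
stim_index <- function(lamp, var) (lamp - 1) * 8 + var

#' Interpretable stimulus summaries
#'
#' Maps the 32 lamp variables to the 7 summary features the ground-truth
#' dynamics act on.
#'
#' @param s Numeric vector of length 32 or matrix `n x 32` in \[0, 1\].
#' @return Matrix `n x 7` of summaries (contrasts in \[-1, 1\], levels
#'   centered at 0).
#' @export
stimulus_summaries <- function(s) {
  s <- if (is.matrix(s)) s else matrix(s, nrow = 1)
  ii <- stim_index(1:4, 1)           # intensities per lamp
  dd <- stim_index(1:4, 2)           # durations per lamp
  vv <- as.vector(outer(1:4, 3:5, stim_index))
  xx <- as.vector(outer(1:4, 6:8, stim_index))
  left <- 1:2; right <- 3:4; uva <- c(1, 3); uvb <- c(2, 4)
  cbind(
    rowMeans(s[, ii[left], drop = FALSE]) - rowMeans(s[, ii[right], drop = FALSE]),
    rowMeans(s[, dd[left], drop = FALSE]) - rowMeans(s[, dd[right], drop = FALSE]),
    rowMeans(s[, ii, drop = FALSE]) - 0.5,
    rowMeans(s[, dd, drop = FALSE]) - 0.5,
    rowMeans(s[, vv, drop = FALSE]) - 0.5,
    rowMeans(s[, xx, drop = FALSE]) - 0.5,
    rowMeans(s[, ii[uva], drop = FALSE]) - rowMeans(s[, ii[uvb], drop = FALSE]))
}

# ambient layout: 1 temperature, 2 humidity, 3 pressure, 4 O2, 5 CO2,
# 6 horizontal wind (m/s), 7 vertical wind (m/s), 8-34 nine wavelengths x
# (duration, intensity, illuminance).  All except the two wind speeds are
# already on a [0, 1] normalized scale; wind is stored in m/s, capped 1.5.
WIND_COLS <- c(6, 7)
WIND_MAX <- 1.5

normalize_ambient <- function(a) {
  a <- if (is.matrix(a)) a else matrix(a, nrow = 1)
  if (ncol(a) != 34) stop("ambient vector must have 34 variables")
  if (any(a[, WIND_COLS] > WIND_MAX + 1e-12))
    stop(sprintf("ambient wind speed exceeds the %.1f m/s cap", WIND_MAX))
  if (any(a < 0) || any(a[, -WIND_COLS] > 1))
    stop("ambient variables out of range")
  a[, WIND_COLS] <- a[, WIND_COLS] / WIND_MAX
  a
}

#' Generate a synthetic moth cohort
#'
#' Moths are assigned to behavior groups in a balanced round-robin; each group
#' carries its own stimulus-response matrix, each moth its own response offset
#' and shape features whose group means separate in proportion to
#' `separation`.
#'
#' @param n_moths Number of moths (default 36).
#' @param n_groups Number of latent behavior groups (default 3).
#' @param seed Integer seed; the cohort is fully reproducible.
#' @param separation Group-separation knob in \[0, 1+\]: 0 makes all groups
#'   (and shape means) identical, 1 is the default well-separated regime.
#' @param sigma_ind Std. dev. of the per-moth response offsets (default 0.05).
#' @param sigma_obs Std. dev. of the per-record observation noise
#'   (default 0.05).
#' @param gain Logistic slope of the response nonlinearity (default 2.2).
#' @return An object of class `moth_cohort` with fields `moths` (data frame:
#'   id, group, wing_span, body_length, mass), `offsets` (`n x 7`), and
#'   `dynamics` (group response matrices and mixing structure).
#' @export
generate_cohort <- function(n_moths = 36, n_groups = 3, seed = 1,
                            separation = 1, sigma_ind = 0.05,
                            sigma_obs = 0.05, gain = 2.2) {
  if (n_moths < n_groups) stop("need at least one moth per group")
  if (n_groups < 1) stop("need at least one group")
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  group <- rep(seq_len(n_groups), length.out = n_moths)
  # shared base response on the 7 stimulus summaries
  B <- diag(0.7, 7) + matrix(stats::rnorm(49, 0, 0.08), 7)
  G <- lapply(seq_len(n_groups), function(g) {
    P <- matrix(stats::rnorm(49, 0, 0.35), 7)
    M <- B + separation * P
    # horizontal deflection row: only left-right contrasts may act
    M[1, ] <- c(0.9 + separation * stats::rnorm(1, 0, 0.25),
                0.25 * stats::rnorm(1), 0, 0, 0, 0, 0)
    M
  })
  A_amb <- matrix(stats::rnorm(7 * 34, 0, 0.3 / sqrt(34)), 7)
  A_prev <- matrix(stats::rnorm(7 * 14, 0, 0.2 / sqrt(14)), 7)
  A_amb[1, ] <- 0
  A_prev[1, ] <- 0
  # low-rank mixing for record generation (correlated stimuli/ambient)
  Q_s <- matrix(stats::runif(32 * 8), 32)
  Q_s <- Q_s / rowSums(Q_s)
  Q_a <- matrix(stats::runif(34 * 4), 34)
  Q_a <- Q_a / rowSums(Q_a)

  shape_dev <- matrix(stats::rnorm(n_groups * 3, 0, 0.1), n_groups)
  shape <- 0.5 + separation * shape_dev[group, , drop = FALSE] +
    matrix(stats::rnorm(n_moths * 3, 0, 0.02), n_moths)
  shape <- pmin(pmax(shape, 0), 1)
  offsets <- matrix(stats::rnorm(n_moths * 7, 0, sigma_ind), n_moths)

  moths <- data.frame(id = seq_len(n_moths), group = group,
                      wing_span = shape[, 1], body_length = shape[, 2],
                      mass = shape[, 3])
  structure(list(moths = moths, offsets = offsets,
                 dynamics = list(G = G, A_amb = A_amb, A_prev = A_prev,
                                 Q_s = Q_s, Q_a = Q_a, gain = gain,
                                 sigma_obs = sigma_obs),
                 n_groups = n_groups, separation = separation,
                 sigma_ind = sigma_ind, seed = seed),
            class = "moth_cohort")
}

#' @export
print.moth_cohort <- function(x, ...) {
  cat(sprintf("<moth_cohort: %d moths in %d groups, separation %.2g, sigma_ind %.2g, sigma_obs %.2g>\n",
              nrow(x$moths), x$n_groups, x$separation, x$sigma_ind,
              x$dynamics$sigma_obs))
  invisible(x)
}

#' Simulate one flight response
#'
#' Ground-truth dynamics: the seven flight parameters are a squashed linear
#' response \eqn{y = \mathrm{logistic}(\mathrm{gain}\cdot\eta)} to the
#' stimulus summaries, centered ambient conditions, and centered flight
#' history, plus the moth's individual offset and optional Gaussian
#' observation noise, clipped to \[0, 1\].
#'
#' @param cohort A `moth_cohort`.
#' @param moth_id Moth identifier (row of `cohort$moths`).
#' @param stimulus Numeric vector of 32 lamp variables in \[0, 1\].
#' @param ambient Numeric vector of 34 ambient variables (wind in m/s).
#' @param prev Previous flight parameters (7, default neutral 0.5).
#' @param accum Accumulated history (7, default `prev`).
#' @param noise Add observation noise (default `TRUE`).
#' @return Numeric vector of 7 flight parameters in \[0, 1\].
#' @export
simulate_flight <- function(cohort, moth_id, stimulus, ambient,
                            prev = rep(0.5, 7), accum = prev, noise = TRUE) {
  stopifnot(length(stimulus) == 32, length(prev) == 7, length(accum) == 7)
  g <- cohort$moths$group[match(moth_id, cohort$moths$id)]
  if (is.na(g)) stop("unknown moth id")
  dyn <- cohort$dynamics
  z <- as.numeric(stimulus_summaries(stimulus))
  amb <- as.numeric(normalize_ambient(ambient))
  eta <- dyn$G[[g]] %*% z + dyn$A_amb %*% (amb - 0.5) +
    dyn$A_prev %*% (c(prev, accum) - 0.5)
  y <- stats::plogis(dyn$gain * as.numeric(eta)) +
    cohort$offsets[match(moth_id, cohort$moths$id), ]
  if (noise) y <- y + stats::rnorm(7, 0, dyn$sigma_obs)
  pmin(pmax(y, 0), 1)
}

#' Generate a table of flight records
#'
#' Time-ordered records per moth on the 200 ms grid: stimuli and ambient
#' conditions are drawn from a correlated (low-rank plus noise) process, the
#' previous-parameters field is the last emitted response, and the
#' accumulated-history field applies [accumulate_history()] to the previous
#' three responses.  Defaults echo the scale of a laboratory campaign
#' (36 moths x 304 records, about 10,900 rows).
#'
#' @param cohort A `moth_cohort`.
#' @param records_per_moth Records per moth (default 304).
#' @param seed Integer seed.
#' @return A data frame in the canonical 89-column record schema
#'   (id, t, s01..s32, a01..a34, p1..p7, q1..q7, y1..y7).
#' @export
generate_records <- function(cohort, records_per_moth = 304, seed = 1) {
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  dyn <- cohort$dynamics
  ids <- cohort$moths$id
  rows <- vector("list", length(ids))
  for (mi in seq_along(ids)) {
    id <- ids[mi]
    hist <- matrix(numeric(0), ncol = 7)     # most recent first
    prev <- rep(0.5, 7)
    rec <- matrix(NA_real_, records_per_moth, length(record_columns()))
    for (t in seq_len(records_per_moth)) {
      s <- pmin(pmax(0.5 * stats::runif(32) +
                       0.5 * as.numeric(dyn$Q_s %*% stats::runif(8)), 0), 1)
      a <- pmin(pmax(0.5 * stats::runif(34) +
                       0.5 * as.numeric(dyn$Q_a %*% stats::runif(4)), 0), 1)
      a[WIND_COLS] <- a[WIND_COLS] * WIND_MAX      # store wind in m/s
      q <- accumulate_history(hist)
      y <- simulate_flight(cohort, id, s, a, prev, q, noise = TRUE)
      rec[t, ] <- c(id, t, s, a, prev, q, y)
      hist <- rbind(y, hist)[seq_len(min(nrow(hist) + 1, 3)), , drop = FALSE]
      prev <- y
    }
    rows[[mi]] <- rec
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- record_columns()
  out
}

#' Probe settings for grouping
#'
#' The fixed grouping probe protocol: 3 typical ambient settings combined
#' with 12 typical lamp stimulation settings (36 probes).  The stimulus
#' presets cover the intensity, duration, laterality, and band (UVA/UVB)
#' extremes, including a left-only and a right-only intensity preset.
#'
#' @return A list with `ambient` (3 x 34 matrix, wind in m/s) and `stimulus`
#'   (12 x 32 matrix).
#' @export
probe_settings <- function() {
  amb <- matrix(0.5, 3, 34)
  amb[1, WIND_COLS] <- 0.3                     # neutral
  amb[2, ] <- 0.75; amb[2, WIND_COLS] <- 0.6   # warm, bright, breezy
  amb[3, ] <- 0.25; amb[3, WIND_COLS] <- 0.1   # cool, dim, calm
  ii <- stim_index(1:4, 1); dd <- stim_index(1:4, 2)
  vv <- as.vector(outer(1:4, 3:5, stim_index))
  xx <- as.vector(outer(1:4, 6:8, stim_index))
  base <- rep(0.5, 32)
  set_vals <- function(idx, val, start = base) { start[idx] <- val; start }
  st <- rbind(
    set_vals(ii[3:4], 0, set_vals(ii[1:2], 1)),   # left-only intensity
    set_vals(ii[1:2], 0, set_vals(ii[3:4], 1)),   # right-only intensity
    set_vals(ii, 1),                              # all lamps bright
    set_vals(ii, 0.05),                           # all lamps dim
    set_vals(ii[c(2, 4)], 0, set_vals(ii[c(1, 3)], 1)),  # UVA only
    set_vals(ii[c(1, 3)], 0, set_vals(ii[c(2, 4)], 1)),  # UVB only
    set_vals(dd, 1),                              # long exposure
    set_vals(dd, 0.05),                           # short exposure
    set_vals(vv, 1),                              # fast moving pattern
    set_vals(xx, 1),                              # far moving pattern
    set_vals(dd[3:4], 0.1, set_vals(dd[1:2], 1)), # left-long duration
    set_vals(c(ii[1], dd[4], vv[1:3]), 1, set_vals(ii[-1], 0.1)))  # mixed extreme
  list(ambient = amb, stimulus = st)
}
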