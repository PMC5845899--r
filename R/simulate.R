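# Generative twin of the analysis: simulated listeners with ANOVA-structured
# true sensitivity and criterion, binomial trial outcomes through the probit
# link, and sigmoid-governed timbre ratings.

#' Ground-truth parameters for simulated cohorts
#'
#' Defines the generative ANOVA structure for per-subject, per-cell true
#' d-prime and criterion: grand mean, attention / timbre / interaction
#' effects (each constrained to sum to zero for identifiability of the
#' simulation truth), a between-subject standard deviation, and
#' attention-specific residual standard deviations. Defaults place the
#' cohort in the regime the analysis is designed for: near-ceiling
#' sensitivity (grand mean 4.7 with three timbre distances, 3.45 for the
#' attention-only experiment), no attention effects, a -0.7 effect of the
#' minimum timbre distance (balanced by +0.35 at the other two levels), and
#' criterion centred on zero.
#'
#' @param experiment `"exp2"` (attention x timbre) or `"exp1"`
#'   (attention only).
#' @param grand_mean_dprime grand mean sensitivity.
#' @param attention_effects length-3 numeric (bassoon, cello, aggregate),
#'   sum zero.
#' @param timbre_effects length-3 numeric (maximum, intermediate, minimum),
#'   sum zero; ignored for `"exp1"`.
#' @param interaction_effects 3x3 matrix (attention x timbre), rows and
#'   columns summing to zero; ignored for `"exp1"`.
#' @param subject_sd between-subject standard deviation of sensitivity.
#' @param residual_sd_per_attention length-3 positive numeric in (0, 4],
#'   residual cell-level standard deviation per attention condition.
#' @param bias_grand_mean,bias_attention_effects,bias_timbre_effects,bias_interaction_effects,bias_subject_sd,bias_residual_sd_per_attention
#'   criterion counterparts of the above.
#' @param n_subjects cohort size (default 19 for `"exp2"`, 29 for `"exp1"`).
#' @param seed integer seed used by [simulate_subject_params()].
#' @return an object of class `"truth_params"`.
#' @export
truth_params <- function(experiment = c("exp2", "exp1"),
                         grand_mean_dprime = NULL,
                         attention_effects = c(0, 0, 0),
                         timbre_effects = c(0.35, 0.35, -0.7),
                         interaction_effects = matrix(0, 3, 3),
                         subject_sd = 1,
                         residual_sd_per_attention = c(0.5, 0.5, 0.5),
                         bias_grand_mean = 0,
                         bias_attention_effects = c(0, 0, 0),
                         bias_timbre_effects = c(0, 0, 0),
                         bias_interaction_effects = matrix(0, 3, 3),
                         bias_subject_sd = 0.2,
                         bias_residual_sd_per_attention = c(0.2, 0.2, 0.2),
                         n_subjects = NULL, seed = 1L) {
  experiment <- match.arg(experiment)
  if (is.null(grand_mean_dprime)) {
    grand_mean_dprime <- if (experiment == "exp2") 4.7 else 3.45
  }
  if (is.null(n_subjects)) n_subjects <- if (experiment == "exp2") 19L else 29L
  if (experiment == "exp1") {
    timbre_effects <- c(0, 0, 0)
    interaction_effects <- matrix(0, 3, 3)
    bias_timbre_effects <- c(0, 0, 0)
    bias_interaction_effects <- matrix(0, 3, 3)
  }
  tp <- list(experiment = experiment,
             grand_mean_dprime = grand_mean_dprime,
             attention_effects = setNames(attention_effects, ATTENTION_LEVELS),
             timbre_effects = setNames(timbre_effects, TIMBRE_LEVELS),
             interaction_effects = structure(as.matrix(interaction_effects),
                                             dimnames = list(ATTENTION_LEVELS,
                                                             TIMBRE_LEVELS)),
             subject_sd = subject_sd,
             residual_sd_per_attention = setNames(residual_sd_per_attention,
                                                  ATTENTION_LEVELS),
             bias_grand_mean = bias_grand_mean,
             bias_attention_effects = setNames(bias_attention_effects,
                                               ATTENTION_LEVELS),
             bias_timbre_effects = setNames(bias_timbre_effects, TIMBRE_LEVELS),
             bias_interaction_effects = structure(as.matrix(bias_interaction_effects),
                                                  dimnames = list(ATTENTION_LEVELS,
                                                                  TIMBRE_LEVELS)),
             bias_subject_sd = bias_subject_sd,
             bias_residual_sd_per_attention = setNames(bias_residual_sd_per_attention,
                                                       ATTENTION_LEVELS),
             n_subjects = as.integer(n_subjects), seed = as.integer(seed))
  validate_truth_params(tp)
  class(tp) <- "truth_params"
  tp
}

validate_truth_params <- function(tp) {
  nums <- c(tp$grand_mean_dprime, tp$attention_effects, tp$timbre_effects,
            tp$interaction_effects, tp$subject_sd,
            tp$residual_sd_per_attention, tp$bias_grand_mean,
            tp$bias_attention_effects, tp$bias_timbre_effects,
            tp$bias_interaction_effects, tp$bias_subject_sd,
            tp$bias_residual_sd_per_attention)
  if (any(!is.finite(nums))) stop("truth parameters must be finite", call. = FALSE)
  if (tp$subject_sd < 0 || tp$bias_subject_sd < 0) {
    stop("subject standard deviations must be >= 0", call. = FALSE)
  }
  if (any(tp$residual_sd_per_attention <= 0) ||
      any(tp$residual_sd_per_attention > 4)) {
    stop("residual standard deviations must lie in (0, 4]", call. = FALSE)
  }
  zero_sum <- function(x) abs(sum(x)) < 1e-8
  if (!zero_sum(tp$attention_effects) || !zero_sum(tp$timbre_effects) ||
      !zero_sum(tp$bias_attention_effects) || !zero_sum(tp$bias_timbre_effects) ||
      !all(abs(rowSums(tp$interaction_effects)) < 1e-8) ||
      !all(abs(colSums(tp$interaction_effects)) < 1e-8)) {
    stop("effect vectors must sum to zero (interaction: per row and column)",
         call. = FALSE)
  }
  if (tp$n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  invisible(TRUE)
}

#' Draw per-subject, per-cell true sensitivity and criterion
#'
#' Subject offsets are drawn from a zero-mean normal with the truth's
#' between-subject standard deviation; each cell's true d-prime is drawn
#' around its ANOVA mean (grand mean + attention + timbre + interaction +
#' subject offset) with the attention-specific residual standard deviation.
#' The criterion follows the mirrored structure.
#'
#' @param truth a [truth_params()] object.
#' @return data frame of class `"true_cells"`: `subject_id`, `attention`,
#'   `timbre_level`, `true_dprime`, `true_bias`, plus the subject offsets as
#'   attributes.
#' @export
simulate_subject_params <- function(truth) {
  stopifnot(inherits(truth, "truth_params"))
  ns <- truth$n_subjects
  timbre <- if (truth$experiment == "exp2") TIMBRE_LEVELS else NA_character_
  grid <- expand.grid(subject = seq_len(ns), attention = ATTENTION_LEVELS,
                      timbre_level = timbre, stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject), ]
  with_seed(truth$seed, {
    off_d <- rnorm(ns, 0, truth$subject_sd)
    off_b <- rnorm(ns, 0, truth$bias_subject_sd)
    ti <- if (truth$experiment == "exp2") {
      cbind(truth$timbre_effects[grid$timbre_level],
            truth$interaction_effects[cbind(grid$attention, grid$timbre_level)])
    } else cbind(0, 0)
    mu_d <- truth$grand_mean_dprime + truth$attention_effects[grid$attention] +
      ti[, 1L] + ti[, 2L] + off_d[grid$subject]
    bi <- if (truth$experiment == "exp2") {
      cbind(truth$bias_timbre_effects[grid$timbre_level],
            truth$bias_interaction_effects[cbind(grid$attention,
                                                 grid$timbre_level)])
    } else cbind(0, 0)
    mu_b <- truth$bias_grand_mean +
      truth$bias_attention_effects[grid$attention] + bi[, 1L] + bi[, 2L] +
      off_b[grid$subject]
    sd_d <- truth$residual_sd_per_attention[grid$attention]
    sd_b <- truth$bias_residual_sd_per_attention[grid$attention]
    out <- data.frame(subject_id = sprintf("S%02d", grid$subject),
                      attention = grid$attention,
                      timbre_level = grid$timbre_level,
                      true_dprime = rnorm(nrow(grid), mu_d, sd_d),
                      true_bias = rnorm(nrow(grid), mu_b, sd_b),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "subject_offsets_dprime") <- off_d
    attr(out, "subject_offsets_bias") <- off_b
    class(out) <- c("true_cells", "data.frame")
    out
  })
}

#' Simulate one subject's responses over a schedule
#'
#' For every trial the probability of a "present" response is
#' \eqn{\Phi(0.5 d' - bias)} when the trial is a target and
#' \eqn{\Phi(-0.5 d' - bias)} otherwise, using the subject's true cell
#' parameters; outcomes are then classified with [classify_trial()].
#'
#' @param true_cells a `"true_cells"` data frame (one subject, or filtered
#'   to one subject via `subject_id`).
#' @param schedule a `"schedule"` object or a data frame of trial stubs with
#'   columns `attention`, `triplet_version` and (when the truth has timbre
#'   structure) `timbre_level`.
#' @param seed integer seed for the response draws.
#' @param subject_id subject to simulate when `true_cells` holds several.
#' @return data frame of classified trial records.
#' @export
simulate_trials <- function(true_cells, schedule, seed = 1L,
                            subject_id = NULL) {
  if (!is.null(subject_id)) {
    true_cells <- true_cells[true_cells$subject_id == subject_id, , drop = FALSE]
    if (nrow(true_cells) == 0L) stop("unknown subject_id: ", subject_id,
                                     call. = FALSE)
  }
  if (length(unique(true_cells$subject_id)) != 1L) {
    stop("`true_cells` must describe exactly one subject ",
         "(use `subject_id` to select one)", call. = FALSE)
  }
  stubs <- schedule_trials(schedule)
  group <- if (inherits(schedule, "schedule")) schedule$group else NA_character_
  has_timbre <- any(!is.na(true_cells$timbre_level))
  key_cells <- paste(true_cells$attention,
                     if (has_timbre) true_cells$timbre_level else "NA")
  key_trials <- paste(stubs$attention,
                      if (has_timbre && "timbre_level" %in% names(stubs))
                        stubs$timbre_level else "NA")
  idx <- match(key_trials, key_cells)
  if (anyNA(idx)) {
    stop("no true parameters for cell(s): ",
         paste(unique(key_trials[is.na(idx)]), collapse = "; "), call. = FALSE)
  }
  d <- true_cells$true_dprime[idx]
  b <- true_cells$true_bias[idx]
  target <- is_target_trial(stubs$attention, stubs$triplet_version)
  p_present <- pnorm(ifelse(target, 0.5 * d - b, -0.5 * d - b))
  out <- with_seed(seed, {
    response <- ifelse(runif(nrow(stubs)) < p_present, "present", "absent")
    cbind(data.frame(subject_id = true_cells$subject_id[1L],
                     experiment = if (has_timbre) "exp2" else "exp1",
                     group = group, stringsAsFactors = FALSE),
          stubs,
          data.frame(response = response,
                     outcome = classify_trial(stubs$attention,
                                              stubs$triplet_version, response),
                     stringsAsFactors = FALSE))
  })
  rownames(out) <- NULL
  out
}

#' Simulate a full cohort performing an experiment
#'
#' Generates one schedule per subject (participant index = subject number,
#' rotating the condition-order balancing) and simulates every subject's
#' responses under the truth's generative structure.
#'
#' @param truth a [truth_params()] object.
#' @param group for `"exp2"` truths: `"LAB"` or `"SCAN"`.
#' @param n_compositions for `"exp1"` truths: 10 or 16.
#' @param seed integer master seed for schedules and responses (defaults to
#'   the truth's seed); per-subject sub-seeds are derived from it.
#' @param schedules optional pre-generated list of schedules, one per
#'   subject, to reuse across replicate simulations.
#' @return list with elements `trials` (all subjects' classified trial
#'   records), `true_cells`, and `schedules`.
#' @export
simulate_cohort <- function(truth, group = c("LAB", "SCAN"),
                            n_compositions = 16L, seed = truth$seed,
                            schedules = NULL) {
  stopifnot(inherits(truth, "truth_params"))
  group <- match.arg(group)
  ns <- truth$n_subjects
  true_cells <- simulate_subject_params(truth)
  sub_seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                                 2L * ns), nrow = 2L))
  if (is.null(schedules)) {
    schedules <- lapply(seq_len(ns), function(s) {
      if (truth$experiment == "exp2") {
        exp2_schedule(s, group = group, seed = sub_seeds[1L, s])
      } else {
        exp1_schedule(s, n_compositions = n_compositions,
                      seed = sub_seeds[1L, s])
      }
    })
  }
  trials <- lapply(seq_len(ns), function(s) {
    simulate_trials(true_cells, schedules[[s]], seed = sub_seeds[2L, s],
                    subject_id = sprintf("S%02d", s))
  })
  list(trials = do.call(rbind, trials), true_cells = true_cells,
       schedules = schedules)
}

#' Ground truth for the timbre-rating session
#'
#' @param x50 named length-2 numeric in (0, 1): true perceptual centre per
#'   voice (`upper`, `lower`) on the morph-fraction axis.
#' @param m named length-2 positive numeric: true sigmoid slopes.
#' @param rating_noise_sd standard deviation of the Gaussian rating noise
#'   added before clamping and rounding to the integer 1-5 scale.
#' @param seed integer seed.
#' @return an object of class `"rating_truth"`.
#' @export
rating_truth <- function(x50 = c(upper = 0.5, lower = 0.5),
                         m = c(upper = 8, lower = 8),
                         rating_noise_sd = 0.5, seed = 1L) {
  if (any(x50 <= 0) || any(x50 >= 1)) stop("x50 must lie in (0, 1)", call. = FALSE)
  if (any(m <= 0)) stop("slopes must be positive", call. = FALSE)
  if (rating_noise_sd < 0) stop("rating_noise_sd must be >= 0", call. = FALSE)
  structure(list(x50 = x50, m = m, rating_noise_sd = rating_noise_sd,
                 seed = as.integer(seed)),
            class = "rating_truth")
}

#' Simulate timbre-morph ratings over a rating schedule
#'
#' Each trial's rating is the sigmoid value at the trial's morph fraction
#' for its voice, plus Gaussian noise, clamped to \[1, 5\] and rounded
#' (half up) to the integer rating scale. Ratings are reported on the
#' absolute instrument scale (1 = bassoon percept, 5 = cello percept): the
#' upper voice starts at 1 and rises toward 5 along its morph axis, the
#' lower voice starts at 5 and falls toward 1 (its sigmoid is reflected,
#' `6 - S`). [fit_voice_sigmoids()] undoes the reflection before fitting.
#'
#' @param truth a [rating_truth()] object.
#' @param schedule a rating `"schedule"` (see [rating_schedule()]).
#' @param subject_id label attached to the records.
#' @return data frame of rating records: `subject_id`, `block`, `trial`,
#'   `voice`, `morph_fraction`, `composition_id`, `rating`.
#' @export
simulate_ratings <- function(truth, schedule, subject_id = "S01") {
  stopifnot(inherits(truth, "rating_truth"))
  stubs <- schedule_trials(schedule)
  mu <- sigmoid_value(stubs$morph_fraction, truth$x50[stubs$voice],
                      truth$m[stubs$voice])
  mu <- ifelse(stubs$voice == "lower", 6 - mu, mu)
  with_seed(truth$seed, {
    raw <- mu + rnorm(nrow(stubs), 0, truth$rating_noise_sd)
    rating <- as.integer(pmin(5, pmax(1, floor(pmin(5, pmax(1, raw)) + 0.5))))
    data.frame(subject_id = subject_id, block = stubs$block_index,
               trial = stubs$trial_index, voice = stubs$voice,
               morph_fraction = stubs$morph_fraction,
               composition_id = stubs$composition_id, rating = rating,
               stringsAsFactors = FALSE)
  })
}
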