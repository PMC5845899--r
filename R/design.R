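# Constrained session-schedule generation for the two attention experiments
# and the timbre-rating session. All generators are pure with respect to
# their seed and every generated schedule passes validate_schedule() with
# zero violations (the generator stops otherwise).

# The five compositions for which timbre morphs exist; they carry the full
# timbre-distance design and the rating session.
MORPHED_COMPOSITIONS <- c("comp01", "comp04", "comp05", "comp08", "comp10")

MAX_PROPOSALS <- 10000L

# All 6 permutations of the three attention conditions, fixed order.
attention_permutations <- function() {
  p <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
  p <- p[p$a != p$b & p$a != p$c & p$b != p$c, ]
  p <- p[order(p$a, p$b, p$c), ]
  lapply(seq_len(nrow(p)), function(i) ATTENTION_LEVELS[unlist(p[i, ])])
}

# Legal block-order pairs for the six-block attention session: both halves
# are permutations of the three conditions, the halves differ, and the same
# condition never occupies adjacent blocks (junction included). Participants
# rotate deterministically through the 18 legal pairs, balancing conditions
# over serial positions.
exp1_condition_order <- function(participant_index) {
  perms <- attention_permutations()
  pairs <- list()
  for (i in seq_along(perms)) {
    for (j in seq_along(perms)) {
      if (i != j && perms[[j]][1L] != perms[[i]][3L]) {
        pairs[[length(pairs) + 1L]] <- c(perms[[i]], perms[[j]])
      }
    }
  }
  pairs[[(as.integer(participant_index) - 1L) %% length(pairs) + 1L]]
}

# Per-block triplet-version multiset: targets fill half the block; under
# single-voice attention the other half splits equally between opposite-voice
# patterns and pattern-absent trials.
exp1_block_versions <- function(attention, n_trials = 16L) {
  half <- n_trials %/% 2L
  quarter <- n_trials %/% 4L
  switch(attention,
         aggregate = c(rep("crossing", half), rep("none", half)),
         bassoon = c(rep("upper", half), rep("lower", quarter), rep("none", quarter)),
         cello = c(rep("lower", half), rep("upper", quarter), rep("none", quarter)),
         stop("unknown attention level: ", attention, call. = FALSE))
}

# Draw a length-n sequence of composition ids with each id used at most
# `max_rep` times and no id adjacent to itself; randomized retry with a
# proposal cap.
draw_composition_sequence <- function(ids, n, max_rep = 2L, forbid_first = NULL) {
  stopifnot(length(ids) * max_rep >= n)
  n_double <- n - length(ids)
  for (attempt in seq_len(MAX_PROPOSALS)) {
    pool <- ids
    if (n_double > 0L) pool <- c(pool, sample(ids, n_double, replace = FALSE))
    if (length(pool) > n) pool <- sample(pool, n, replace = FALSE)
    seqn <- sample(pool, length(pool), replace = FALSE)
    if (!is.null(forbid_first) && seqn[1L] == forbid_first) next
    if (!any(seqn[-1L] == seqn[-length(seqn)])) return(seqn)
  }
  stop("generation failure: could not order compositions without adjacent ",
       "repeats within the proposal cap", call. = FALSE)
}

new_schedule <- function(experiment, group, participant_index, seed, trials,
                         extra = list()) {
  sch <- c(list(experiment = experiment, group = group,
                participant_index = participant_index, seed = seed,
                trials = trials), extra)
  class(sch) <- "schedule"
  sch$constraint_report <- validate_schedule(sch)
  if (nrow(sch$constraint_report)) {
    stop("generation failure: generated schedule violates constraint(s): ",
         paste(unique(sch$constraint_report$constraint), collapse = "; "),
         call. = FALSE)
  }
  sch
}

#' @export
print.schedule <- function(x, ...) {
  cat("<schedule>", x$experiment,
      if (!is.na(x$group)) paste0("(", x$group, ")") else "",
      "participant", x$participant_index, "seed", x$seed, "\n")
  cat("  trials:", nrow(x$trials), " blocks:",
      length(unique(paste(x$trials$run_index, x$trials$block_index))), "\n")
  cat("  constraint violations:", nrow(x$constraint_report), "\n")
  invisible(x)
}

schedule_trials <- function(schedule) {
  if (inherits(schedule, "schedule")) schedule$trials else schedule
}

#' Generate a six-block attention session schedule
#'
#' Builds one participant's session for the attention-only experiment: 6
#' attentive blocks of 16 trials (96 trials), each attention condition in
#' exactly 2 blocks. Per block the trial mix is: aggregate — 8 crossing +
#' 8 pattern-absent; bassoon — 8 upper + 4 lower + 4 absent; cello — 8
#' lower + 4 upper + 4 absent, giving 48 target and 48 non-target trials
#' overall. Within a block the same composition is never adjacent to itself
#' and occurs at most twice. Condition order follows the participant's
#' rotation through the legal half-order pairs (no condition repeats across
#' adjacent blocks; the two half-orders differ) so ordering is balanced
#' across participants.
#'
#' @param participant_index positive integer identifying the participant's
#'   slot in the condition-order rotation.
#' @param n_compositions number of unique compositions available (10 or 16).
#' @param seed integer seed; identical inputs give identical schedules.
#' @return an object of class `"schedule"` whose `trials` element is a data
#'   frame of trial stubs (no responses), plus the seed and a constraint
#'   report.
#' @export
exp1_schedule <- function(participant_index, n_compositions = 16L, seed = 1L) {
  if (!n_compositions %in% c(10L, 16L)) {
    stop("`n_compositions` must be 10 or 16", call. = FALSE)
  }
  order6 <- exp1_condition_order(participant_index)
  ids <- sprintf("comp%02d", seq_len(n_compositions))
  trials <- with_seed(seed, {
    blocks <- lapply(1:6, function(b) {
      att <- order6[b]
      versions <- sample(exp1_block_versions(att))
      comps <- draw_composition_sequence(ids, 16L, max_rep = 2L)
      data.frame(run_index = 1L, block_index = b,
                 trial_index = 1:16, attention = att,
                 triplet_version = versions, composition_id = comps,
                 timbre_level = NA_character_,
                 crossing_start = ifelse(versions == "crossing",
                                         sample(c("bassoon", "cello"), 16L,
                                                replace = TRUE),
                                         NA_character_),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, blocks)
  })
  new_schedule("exp1", NA_character_, participant_index, seed, trials,
               extra = list(n_compositions = n_compositions))
}

# --- timbre experiment internals ------------------------------------------

# Sample per-composition position offsets k(c, t) in {0,1,2} (a permutation
# over the three timbre distances for each composition) such that every
# block's timbre counts fall in {1, 2}. Offset k places stimulus
# (composition, timbre) at block position ((r - 1 + k) mod 3) + 1 of run r,
# which is cyclic in the run index, so over three runs each stimulus visits
# every block position and hence (through the Latin condition rows) every
# attention condition.
draw_timbre_offsets <- function() {
  n_comp <- length(MORPHED_COMPOSITIONS)
  for (attempt in seq_len(MAX_PROPOSALS)) {
    k <- t(vapply(seq_len(n_comp), function(i) sample(0:2), integer(3)))
    counts <- vapply(0:2, function(v) colSums(k == v), numeric(3))
    if (all(counts >= 1 & counts <= 2)) {
      dimnames(k) <- list(MORPHED_COMPOSITIONS, TIMBRE_LEVELS)
      return(k)
    }
  }
  stop("generation failure: per-block timbre balance unsatisfiable",
       call. = FALSE)
}

# Order one block's five (composition, timbre) stimuli: no identical timbre
# distances adjacent, first composition differs from the previous block's
# last.
order_block_stimuli <- function(block_df, prev_last_comp) {
  for (attempt in seq_len(MAX_PROPOSALS)) {
    idx <- sample(nrow(block_df))
    tl <- block_df$timbre_level[idx]
    if (any(tl[-1L] == tl[-length(tl)])) next
    if (!is.null(prev_last_comp) &&
        block_df$composition_id[idx[1L]] == prev_last_comp) next
    return(block_df[idx, , drop = FALSE])
  }
  stop("generation failure: block ordering constraints unsatisfiable",
       call. = FALSE)
}

#' Generate a timbre-distance attention session schedule
#'
#' Builds one participant's session for the attention-by-timbre experiment:
#' runs of three 5-trial attention blocks (one block per condition), six
#' runs in the laboratory version (90 trials) or nine in the scanner
#' version (135 trials). Each run presents each of the 15 stimuli (5
#' morphed compositions x 3 timbre distances) exactly once; each run holds
#' 8 target and 7 control trials. Within a block every composition occurs
#' once, identical timbre distances are never adjacent and each timbre
#' distance occurs once or twice; the first composition of a block differs
#' from the last of the previous block. Over every three-run repetition the
#' condition order forms a cyclic Latin square (every condition at every
#' within-run position) and every timbre version of every composition is
#' covered by every condition. Control trials in the single-voice
#' conditions alternate 3 pattern-absent + 4 opposite-voice and 4 + 3
#' across repetitions.
#'
#' @inheritParams exp1_schedule
#' @param group `"LAB"` (6 runs, 90 trials) or `"SCAN"` (9 runs, 135
#'   trials).
#' @return an object of class `"schedule"`.
#' @export
exp2_schedule <- function(participant_index, group = c("LAB", "SCAN"),
                          seed = 1L) {
  group <- match.arg(group)
  n_rep <- if (group == "LAB") 2L else 3L
  perms <- attention_permutations()
  base_order <- perms[[(as.integer(participant_index) - 1L) %% 6L + 1L]]
  rotate <- function(x, k) x[((seq_along(x) - 1L + k) %% length(x)) + 1L]

  trials <- with_seed(seed, {
    all_rows <- list()
    prev_last_comp <- NULL
    for (rep_i in seq_len(n_rep)) {
      offsets <- draw_timbre_offsets()
      # Cyclic rotations of (3,3,2) target counts, one per condition, so
      # every run sums to 8 targets; which condition takes which rotation is
      # randomized per repetition.
      target_base <- c(3L, 3L, 2L)
      rot_assign <- sample(0:2)
      names(rot_assign) <- ATTENTION_LEVELS
      # Control subtype split for single-voice conditions alternates across
      # repetitions: odd repetitions 3 absent + 4 opposite, even 4 + 3.
      n_none <- if (rep_i %% 2L == 1L) 3L else 4L

      # The 15 stimuli of a run (5 compositions x 3 timbre distances) are
      # partitioned into the 3 blocks by the per-composition position
      # offsets; which condition owns which block follows the Latin rows.
      stim <- expand.grid(composition_id = MORPHED_COMPOSITIONS,
                          timbre_level = TIMBRE_LEVELS,
                          stringsAsFactors = FALSE)
      stim$offset <- offsets[cbind(stim$composition_id, stim$timbre_level)]

      for (r_local in 1:3) {
        run_index <- (rep_i - 1L) * 3L + r_local
        row_order <- rotate(base_order, (r_local - 1L + rep_i - 1L) %% 3L)
        for (p in 1:3) {
          att <- row_order[p]
          in_block <- ((r_local - 1L + stim$offset) %% 3L) + 1L == p
          block_df <- stim[in_block, c("composition_id", "timbre_level"),
                           drop = FALSE]
          stopifnot(nrow(block_df) == 5L)
          block_df <- order_block_stimuli(block_df, prev_last_comp)
          block_df$triplet_version <- NA_character_
          block_df$run_index <- run_index
          block_df$block_index <- p
          block_df$trial_index <- 1:5
          block_df$attention <- att
          prev_last_comp <- block_df$composition_id[5L]
          all_rows[[length(all_rows) + 1L]] <- block_df
        }
      }

      # Assign targets and control versions per condition over the whole
      # repetition: per-run target counts follow the condition's (3,3,2)
      # rotation, and every timbre distance of the condition receives at
      # least one target and one control trial, so every subject x
      # attention x timbre measurement cell is estimable. The
      # absent/opposite control split is exact per repetition.
      rep_rows <- (length(all_rows) - 8L):length(all_rows)
      rep_df <- do.call(rbind, all_rows[rep_rows])
      for (att in ATTENTION_LEVELS) {
        tc <- rotate(target_base, rot_assign[[att]])
        rows_att <- which(rep_df$attention == att)
        r_local_att <- ((rep_df$run_index[rows_att] - 1L) %% 3L) + 1L
        tgt <- logical(length(rows_att))
        for (attempt in seq_len(MAX_PROPOSALS)) {
          tgt[] <- FALSE
          for (r in 1:3) {
            in_run <- which(r_local_att == r)
            tgt[in_run[sample(length(in_run), tc[r])]] <- TRUE
          }
          per_timbre <- table(factor(rep_df$timbre_level[rows_att][tgt],
                                     levels = TIMBRE_LEVELS))
          if (all(per_timbre >= 1L) && all(per_timbre <= 4L)) break
          if (attempt == MAX_PROPOSALS) {
            stop("generation failure: could not balance targets over ",
                 "timbre distances", call. = FALSE)
          }
        }
        target_version <- switch(att, bassoon = "upper", cello = "lower",
                                 aggregate = "crossing")
        rep_df$triplet_version[rows_att[tgt]] <- target_version
        ctrl <- rows_att[!tgt]
        stopifnot(length(ctrl) == 7L)
        if (att == "aggregate") {
          rep_df$triplet_version[ctrl] <- "none"
        } else {
          opposite <- if (att == "bassoon") "lower" else "upper"
          vers <- sample(c(rep("none", n_none), rep(opposite, 7L - n_none)))
          rep_df$triplet_version[ctrl] <- vers
        }
      }
      # push filled rows back, split by block
      key <- paste(rep_df$run_index, rep_df$block_index)
      filled <- split(rep_df, factor(key, levels = unique(key)))
      all_rows[rep_rows] <- filled
    }
    out <- do.call(rbind, all_rows)
    out$crossing_start <- ifelse(out$triplet_version == "crossing",
                                 sample(c("bassoon", "cello"), nrow(out),
                                        replace = TRUE),
                                 NA_character_)
    rownames(out) <- NULL
    out[, c("run_index", "block_index", "trial_index", "attention",
            "triplet_version", "composition_id", "timbre_level",
            "crossing_start")]
  })
  new_schedule("exp2", group, participant_index, seed, trials)
}

#' Generate a timbre-rating session schedule
#'
#' Builds the pseudo-random presentation order for the morph-rating
#' session: 176 trials over 8 equal-length blocks, each block presenting
#' every combination of the two voices and the 11 morph steps (0, 0.1, ...,
#' 1 of the way toward the other instrument) exactly once. The two voices
#' strictly alternate and the same composition never follows itself;
#' compositions are drawn round-robin from the five morphed compositions.
#'
#' @param seed integer seed.
#' @return an object of class `"schedule"` with `experiment = "rating"`;
#'   trials carry `voice`, `morph_fraction` and `composition_id`.
#' @export
rating_schedule <- function(seed = 1L) {
  steps <- seq(0, 1, by = 0.1)
  trials <- with_seed(seed, {
    start_voice <- sample(c("upper", "lower"), 1L)
    comp_offset <- sample(5L, 1L) - 1L
    blocks <- lapply(1:8, function(b) {
      su <- sample(steps)
      sl <- sample(steps)
      voice <- rep(if (start_voice == "upper") c("upper", "lower")
                   else c("lower", "upper"), 11L)
      frac <- numeric(22L)
      frac[voice == "upper"] <- su
      frac[voice == "lower"] <- sl
      data.frame(run_index = 1L, block_index = b, trial_index = 1:22,
                 voice = voice, morph_fraction = frac,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, blocks)
    idx <- seq_len(nrow(out)) - 1L
    out$composition_id <- MORPHED_COMPOSITIONS[((idx + comp_offset) %% 5L) + 1L]
    out
  })
  new_schedule("rating", NA_character_, NA_integer_, seed, trials)
}

# --- validation ------------------------------------------------------------

#' Validate a session schedule against its design constraints
#'
#' Checks every ordering, balance and composition constraint for the
#' schedule's experiment type and returns the violations found. The
#' validator is total: it never errors, it reports.
#'
#' @param schedule a `"schedule"` object, or a list with elements
#'   `experiment`, `group` and `trials`.
#' @return a data frame with columns `constraint`, `location` and `detail`;
#'   zero rows when the schedule satisfies every constraint.
#' @export
validate_schedule <- function(schedule) {
  experiment <- schedule$experiment
  trials <- schedule$trials
  v <- list()
  add <- function(constraint, location, detail) {
    v[[length(v) + 1L]] <<- data.frame(constraint = constraint,
                                       location = location, detail = detail,
                                       stringsAsFactors = FALSE)
  }
  if (experiment == "exp1") {
    validate_exp1(trials, add)
  } else if (experiment == "exp2") {
    validate_exp2(trials, add, group = schedule$group)
  } else if (experiment == "rating") {
    validate_rating(trials, add)
  } else {
    add("unknown experiment", "schedule", as.character(experiment))
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(constraint = character(), location = character(),
               detail = character(), stringsAsFactors = FALSE)
}

validate_exp1 <- function(trials, add) {
  if (nrow(trials) != 96L) {
    add("total trial count", "schedule", paste0("expected 96, got ", nrow(trials)))
  }
  blocks <- split(trials, trials$block_index)
  if (length(blocks) != 6L || any(vapply(blocks, nrow, 0L) != 16L)) {
    add("block structure", "schedule", "expected 6 blocks of 16 trials")
    return(invisible())
  }
  block_att <- vapply(blocks, function(b) {
    if (length(unique(b$attention)) != 1L) NA_character_ else b$attention[1L]
  }, "")
  if (anyNA(block_att)) {
    add("single condition per block",
        paste0("block ", names(block_att)[is.na(block_att)]), "mixed attention")
    return(invisible())
  }
  tab <- table(factor(block_att, levels = ATTENTION_LEVELS))
  if (any(tab != 2L)) {
    add("condition balance", "schedule",
        paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  rep_adj <- which(block_att[-1L] == block_att[-6L])
  for (i in rep_adj) {
    add("no condition self-follow", paste0("blocks ", i, "-", i + 1L),
        block_att[i])
  }
  if (identical(unname(block_att[1:3]), unname(block_att[4:6]))) {
    add("order within halves not unique", "blocks 1-6",
        paste(block_att[1:3], collapse = "-"))
  }
  if (length(unique(block_att[1:3])) != 3L || length(unique(block_att[4:6])) != 3L) {
    add("half is a permutation of conditions", "blocks 1-6",
        paste(block_att, collapse = "-"))
  }
  for (b in names(blocks)) {
    bl <- blocks[[b]]
    want <- sort(exp1_block_versions(bl$attention[1L]))
    if (!identical(sort(bl$triplet_version), want)) {
      add("block version mix", paste0("block ", b),
          paste(sort(bl$triplet_version), collapse = ","))
    }
    ct <- table(bl$composition_id)
    if (any(ct > 2L)) {
      add("composition repeated more than once", paste0("block ", b),
          paste(names(ct)[ct > 2L], collapse = ","))
    }
    adj <- which(bl$composition_id[-1L] == bl$composition_id[-nrow(bl)])
    for (i in adj) {
      add("composition adjacent to itself",
          paste0("block ", b, " trials ", i, "-", i + 1L),
          bl$composition_id[i])
    }
  }
  n_target <- sum(is_target_trial(trials$attention, trials$triplet_version))
  if (n_target != nrow(trials) / 2) {
    add("target/non-target balance", "schedule",
        paste0(n_target, " targets of ", nrow(trials)))
  }
  invisible()
}

validate_exp2 <- function(trials, add, group = NA_character_) {
  n_expected <- if (identical(group, "SCAN")) 135L else 90L
  if (!is.na(group) && nrow(trials) != n_expected) {
    add("total trial count", "schedule",
        paste0("expected ", n_expected, ", got ", nrow(trials)))
  }
  runs <- split(trials, trials$run_index)
  n_runs <- length(runs)
  if (n_runs %% 3L != 0L) {
    add("runs per repetition", "schedule", paste0(n_runs, " runs"))
  }
  prev_last <- NULL
  for (r in names(runs)) {
    run <- runs[[r]]
    run <- run[order(run$block_index, run$trial_index), ]
    stim <- paste(run$composition_id, run$timbre_level)
    if (anyDuplicated(stim)) {
      add("stimulus unique within run", paste0("run ", r),
          paste(stim[duplicated(stim)], collapse = ","))
    }
    n_target <- sum(is_target_trial(run$attention, run$triplet_version))
    if (n_target != 8L) {
      add("eight targets per run", paste0("run ", r), as.character(n_target))
    }
    if (nrow(run) - n_target != 7L) {
      add("seven controls per run", paste0("run ", r),
          as.character(nrow(run) - n_target))
    }
    blocks <- split(run, run$block_index)
    for (b in names(blocks)) {
      bl <- blocks[[b]]
      loc <- paste0("run ", r, " block ", b)
      if (nrow(bl) != 5L) add("block size", loc, as.character(nrow(bl)))
      if (length(unique(bl$attention)) != 1L) add("single condition per block", loc, "")
      if (anyDuplicated(bl$composition_id)) {
        add("composition once per block", loc,
            paste(bl$composition_id[duplicated(bl$composition_id)], collapse = ","))
      }
      tl <- bl$timbre_level
      adj <- which(tl[-1L] == tl[-length(tl)])
      for (i in adj) {
        add("identical timbre distances adjacent",
            paste0(loc, " trials ", i, "-", i + 1L), tl[i])
      }
      ct <- table(factor(tl, levels = TIMBRE_LEVELS))
      if (any(ct < 1L) || any(ct > 2L)) {
        add("timbre distance occurs once or twice per block", loc,
            paste(names(ct), ct, sep = "=", collapse = ", "))
      }
      att <- bl$attention[1L]
      allowed <- switch(att,
                        aggregate = c("crossing", "none"),
                        bassoon = c("upper", "lower", "none"),
                        cello = c("lower", "upper", "none"))
      badv <- setdiff(unique(bl$triplet_version), allowed)
      if (length(badv)) add("triplet version allowed for condition", loc,
                            paste(badv, collapse = ","))
      if (!is.null(prev_last) && bl$composition_id[1L] == prev_last) {
        add("first composition equals last of previous block", loc,
            bl$composition_id[1L])
      }
      prev_last <- bl$composition_id[nrow(bl)]
    }
    # per composition, each timbre distance once per run
    per_comp <- table(run$composition_id, run$timbre_level)
    if (any(per_comp != 1L)) {
      add("equal timbre occurrences per composition within run",
          paste0("run ", r), "")
    }
  }
  # repetition-level structure
  run_ids <- sort(as.integer(names(runs)))
  for (rep_start in seq(1L, length(run_ids) - 2L, by = 3L)) {
    rep_runs <- run_ids[rep_start:(rep_start + 2L)]
    rep_df <- trials[trials$run_index %in% rep_runs, ]
    loc <- paste0("runs ", paste(rep_runs, collapse = ","))
    # Latin structure: condition x within-run position
    pos <- table(rep_df$attention[!duplicated(paste(rep_df$run_index,
                                                    rep_df$block_index))],
                 rep_df$block_index[!duplicated(paste(rep_df$run_index,
                                                      rep_df$block_index))])
    if (any(pos != 1L)) {
      add("condition occupies every within-run position once", loc, "")
    }
    for (att in ATTENTION_LEVELS) {
      sub <- rep_df[rep_df$attention == att, ]
      stim <- paste(sub$composition_id, sub$timbre_level)
      if (length(unique(stim)) != 15L) {
        add("all timbre versions covered by condition", paste0(loc, " ", att),
            paste0(length(unique(stim)), " of 15 stimuli"))
      }
      if (att != "aggregate") {
        opposite <- if (att == "bassoon") "lower" else "upper"
        ctrl <- sub$triplet_version[!is_target_trial(sub$attention,
                                                     sub$triplet_version)]
        split_ok <- (sum(ctrl == "none") %in% 3:4) &&
          (sum(ctrl == opposite) == 7L - sum(ctrl == "none"))
        if (!split_ok) {
          add("control split three/four", paste0(loc, " ", att),
              paste0("none=", sum(ctrl == "none"), " opposite=",
                     sum(ctrl == opposite)))
        }
      }
    }
  }
  # alternation of the control split across repetitions
  n_rep <- length(run_ids) %/% 3L
  if (n_rep >= 2L) {
    for (att in c("bassoon", "cello")) {
      splits <- vapply(seq_len(n_rep), function(k) {
        rep_runs <- run_ids[((k - 1L) * 3L + 1L):(k * 3L)]
        sub <- trials[trials$run_index %in% rep_runs & trials$attention == att, ]
        ctrl <- sub$triplet_version[!is_target_trial(sub$attention,
                                                     sub$triplet_version)]
        sum(ctrl == "none")
      }, 0)
      if (any(diff(splits) == 0)) {
        add("control split alternates across repetitions", att,
            paste(splits, collapse = ","))
      }
    }
  }
  invisible()
}

validate_rating <- function(trials, add) {
  if (nrow(trials) != 176L) {
    add("total trial count", "schedule",
        paste0("expected 176, got ", nrow(trials)))
  }
  blocks <- split(trials, trials$block_index)
  sizes <- vapply(blocks, nrow, 0L)
  if (length(unique(sizes)) != 1L) {
    add("equal block lengths", "schedule", paste(sizes, collapse = ","))
  }
  if (length(blocks) != 8L) {
    add("eight blocks", "schedule", as.character(length(blocks)))
  }
  for (b in names(blocks)) {
    bl <- blocks[[b]]
    key <- paste(bl$voice, bl$morph_fraction)
    if (anyDuplicated(key) || nrow(bl) != 22L) {
      add("each voice x morph step once per block", paste0("block ", b), "")
    }
  }
  trials <- trials[order(trials$block_index, trials$trial_index), ]
  same_voice <- which(trials$voice[-1L] == trials$voice[-nrow(trials)])
  for (i in same_voice) {
    add("voices alternate", paste0("trials ", i, "-", i + 1L), trials$voice[i])
  }
  same_comp <- which(trials$composition_id[-1L] ==
                       trials$composition_id[-nrow(trials)])
  for (i in same_comp) {
    add("composition adjacent to itself", paste0("trials ", i, "-", i + 1L),
        trials$composition_id[i])
  }
  invisible()
}
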