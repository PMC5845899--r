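#' Classify trial outcomes under an attention instruction
#'
#' A trial is a *target* when the triplet pattern sits in the attended
#' stream: the upper (bassoon) voice under attend-bassoon, the lower (cello)
#' voice under attend-cello, or crossing both voices under attend-aggregate.
#' A "present" response to a target is a hit, "absent" a miss; for
#' non-targets (no pattern, or a pattern in an unattended voice) "present"
#' is a false alarm and "absent" a correct rejection. Trials with a missing
#' response are classified `"invalid"` and are excluded from downstream
#' counts.
#'
#' @param attention character vector of attention instructions
#'   (`"bassoon"`, `"cello"`, `"aggregate"`).
#' @param triplet_version character vector of pattern versions (`"none"`,
#'   `"upper"`, `"lower"`, `"crossing"`).
#' @param response character vector of responses (`"present"`, `"absent"`,
#'   `"missing"`).
#' @return character vector of outcomes: `"hit"`, `"miss"`, `"fa"`, `"cr"`
#'   or `"invalid"`.
#' @examples
#' classify_trial("bassoon", "upper", "present")  # hit
#' classify_trial("bassoon", "lower", "present")  # false alarm
#' @export
classify_trial <- function(attention, triplet_version, response) {
  n <- max(length(attention), length(triplet_version), length(response))
  attention <- rep_len(as.character(attention), n)
  triplet_version <- rep_len(as.character(triplet_version), n)
  response <- rep_len(as.character(response), n)

  bad_att <- !attention %in% ATTENTION_LEVELS
  bad_ver <- !triplet_version %in% TRIPLET_VERSIONS
  bad_rsp <- !response %in% RESPONSE_LEVELS
  if (any(bad_att | bad_ver | bad_rsp)) {
    stop("invalid level value(s) at position(s): ",
         paste(which(bad_att | bad_ver | bad_rsp), collapse = ", "),
         call. = FALSE)
  }
  # Aggregate-attention trials only exist with crossing or absent patterns.
  bad_design <- attention == "aggregate" & triplet_version %in% c("upper", "lower")
  if (any(bad_design)) {
    stop("invalid design: aggregate attention with single-voice triplet ",
         "version at position(s): ", paste(which(bad_design), collapse = ", "),
         call. = FALSE)
  }

  target <- is_target_trial(attention, triplet_version)
  out <- ifelse(target,
                ifelse(response == "present", "hit", "miss"),
                ifelse(response == "present", "fa", "cr"))
  out[response == "missing"] <- "invalid"
  out
}

# Target rule shared by classification, design validation and simulation.
is_target_trial <- function(attention, triplet_version) {
  (attention == "bassoon" & triplet_version == "upper") |
    (attention == "cello" & triplet_version == "lower") |
    (attention == "aggregate" & triplet_version == "crossing")
}

#' Edge-corrected d-prime
#'
#' Sensitivity with the edge correction that keeps perfect scores finite:
#' \deqn{d'_{ec} = \Phi^{-1}\!\left(\frac{H + 0.5}{H + M + 1}\right) -
#'               \Phi^{-1}\!\left(\frac{FA + 0.5}{FA + CR + 1}\right)}
#' where \eqn{\Phi^{-1}} is the standard normal quantile function.
#'
#' @param n_hit,n_miss,n_fa,n_cr non-negative counts of hits, misses, false
#'   alarms and correct rejections (vectors are recycled).
#' @return numeric vector of edge-corrected d-prime values, finite for all
#'   legal counts including perfect scores.
#' @examples
#' edge_corrected_dprime(16, 0, 0, 16)  # ceiling performance, ~3.78
#' @export
edge_corrected_dprime <- function(n_hit, n_miss, n_fa, n_cr) {
  check_counts(n_hit, n_miss, n_fa, n_cr)
  qnorm((n_hit + 0.5) / (n_hit + n_miss + 1)) -
    qnorm((n_fa + 0.5) / (n_fa + n_cr + 1))
}

#' Edge-corrected response criterion
#'
#' Symmetric criterion summary paralleling [edge_corrected_dprime()]:
#' \eqn{-\frac12[\Phi^{-1}(\tilde H) + \Phi^{-1}(\tilde{FA})]} on the
#' edge-corrected rates. Zero for symmetric responding; positive values
#' indicate a conservative (absent-leaning) criterion. Used for descriptive
#' output and to initialize the hierarchical model's latent bias terms.
#'
#' @inheritParams edge_corrected_dprime
#' @return numeric vector of criterion values.
#' @export
edge_corrected_bias <- function(n_hit, n_miss, n_fa, n_cr) {
  check_counts(n_hit, n_miss, n_fa, n_cr)
  -0.5 * (qnorm((n_hit + 0.5) / (n_hit + n_miss + 1)) +
            qnorm((n_fa + 0.5) / (n_fa + n_cr + 1)))
}

check_counts <- function(n_hit, n_miss, n_fa, n_cr) {
  counts <- cbind(n_hit, n_miss, n_fa, n_cr)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (any(n_hit + n_miss < 1)) {
    stop("undefined cell: zero target trials", call. = FALSE)
  }
  if (any(n_fa + n_cr < 1)) {
    stop("undefined cell: zero non-target trials", call. = FALSE)
  }
  invisible(TRUE)
}

#' Aggregate classified trials into measurement cells
#'
#' Tallies hits, misses, false alarms and correct rejections for every
#' subject-by-attention cell (by attention-by-timbre for designs with a
#' timbre manipulation) and attaches edge-corrected d-prime and criterion
#' values. One measurement cell per observed combination: a full
#' three-timbre design yields 9 cells per subject, a single-session
#' attention-only design yields 3.
#'
#' @param trials data frame of classified trials with at least columns
#'   `subject_id`, `attention`, `outcome` and, when present, `timbre_level`,
#'   plus `run_index`, `block_index`, `trial_index` used for the duplicate
#'   key check. Trials with outcome `"invalid"` are excluded (a message
#'   reports how many per subject).
#' @return data frame of class `"measurement_cells"` with columns
#'   `subject_id`, `attention`, `timbre_level`, `n_hit`, `n_miss`, `n_fa`,
#'   `n_cr`, `n_tri`, `n_ntri`, `dprime_ec`, `bias_ec`.
#' @export
aggregate_counts <- function(trials) {
  if (!is.data.frame(trials)) stop("`trials` must be a data frame", call. = FALSE)
  if (nrow(trials) == 0L) {
    out <- data.frame(subject_id = character(), attention = character(),
                      timbre_level = character(), n_hit = integer(),
                      n_miss = integer(), n_fa = integer(), n_cr = integer(),
                      n_tri = integer(), n_ntri = integer(),
                      dprime_ec = numeric(), bias_ec = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("measurement_cells", "data.frame")
    return(out)
  }
  need <- c("subject_id", "attention", "outcome")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key_cols <- intersect(c("subject_id", "run_index", "block_index", "trial_index"),
                        names(trials))
  if (length(key_cols) == 4L) {
    key <- do.call(paste, c(trials[key_cols], sep = "\r"))
    if (anyDuplicated(key)) {
      stop("integrity error: duplicate (subject, run, block, trial) keys",
           call. = FALSE)
    }
  }

  invalid <- trials$outcome == "invalid"
  if (any(invalid)) {
    per <- table(trials$subject_id[invalid])
    message("excluding ", sum(invalid), " invalid trial(s): ",
            paste(names(per), per, sep = "=", collapse = ", "))
    trials <- trials[!invalid, , drop = FALSE]
  }

  has_timbre <- "timbre_level" %in% names(trials) &&
    any(!is.na(trials$timbre_level))
  timbre <- if (has_timbre) as.character(trials$timbre_level) else
    rep(NA_character_, nrow(trials))

  key <- paste(trials$subject_id, trials$attention, timbre, sep = "\r")
  groups <- split(seq_len(nrow(trials)), key)
  rows <- lapply(groups, function(idx) {
    oc <- trials$outcome[idx]
    data.frame(subject_id = trials$subject_id[idx[1L]],
               attention = trials$attention[idx[1L]],
               timbre_level = timbre[idx[1L]],
               n_hit = sum(oc == "hit"), n_miss = sum(oc == "miss"),
               n_fa = sum(oc == "fa"), n_cr = sum(oc == "cr"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$n_tri <- out$n_hit + out$n_miss
  out$n_ntri <- out$n_fa + out$n_cr
  ok <- out$n_tri >= 1L & out$n_ntri >= 1L
  out$dprime_ec <- NA_real_
  out$bias_ec <- NA_real_
  out$dprime_ec[ok] <- edge_corrected_dprime(out$n_hit[ok], out$n_miss[ok],
                                             out$n_fa[ok], out$n_cr[ok])
  out$bias_ec[ok] <- edge_corrected_bias(out$n_hit[ok], out$n_miss[ok],
                                         out$n_fa[ok], out$n_cr[ok])
  if (any(!ok)) {
    warning(sum(!ok), " cell(s) without both target and non-target trials; ",
            "edge-corrected values set to NA", call. = FALSE)
  }
  out <- out[order(out$subject_id,
                   match(out$attention, ATTENTION_LEVELS),
                   match(out$timbre_level, TIMBRE_LEVELS)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("measurement_cells", "data.frame")
  out
}
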