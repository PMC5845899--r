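# Descriptive and reliability statistics: split-half reliability of
# edge-corrected d-prime, Spearman rank correlation with an exact
# small-sample permutation p-value, the per-subject morph effect, and
# median/IQR group summaries.

#' Per-subject correct-rate scores
#'
#' Correct rate = (hits + correct rejections) / counted trials, over all
#' trials or restricted to one timbre distance. Correct rates (rather than
#' d-prime) are the comparable quantity across scopes with different trial
#' counts.
#'
#' @param trials data frame of classified trials.
#' @param scope `"all_trials"`, `"max_timbre_only"` or `"min_timbre_only"`.
#' @return data frame with `subject_id`, `scope`, `correct_rate`,
#'   `dprime_ec`.
#' @export
subject_scores <- function(trials, scope = c("all_trials", "max_timbre_only",
                                             "min_timbre_only")) {
  scope <- match.arg(scope)
  trials <- trials[trials$outcome != "invalid", , drop = FALSE]
  if (scope != "all_trials") {
    lvl <- if (scope == "max_timbre_only") "maximum" else "minimum"
    if (!"timbre_level" %in% names(trials)) {
      stop("timbre scope requested but trials carry no timbre_level",
           call. = FALSE)
    }
    trials <- trials[!is.na(trials$timbre_level) &
                       trials$timbre_level == lvl, , drop = FALSE]
  }
  if (nrow(trials) == 0L) stop("no trials in scope `", scope, "`", call. = FALSE)
  groups <- split(trials, trials$subject_id)
  out <- lapply(groups, function(tr) {
    oc <- tr$outcome
    data.frame(subject_id = tr$subject_id[1L], scope = scope,
               correct_rate = mean(oc %in% c("hit", "cr")),
               dprime_ec = edge_corrected_dprime(sum(oc == "hit"),
                                                 sum(oc == "miss"),
                                                 sum(oc == "fa"),
                                                 sum(oc == "cr")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Split-half reliability of edge-corrected d-prime
#'
#' Trials are split by odd/even serial position within each condition cell
#' (attention, and timbre distance when present) so both halves sample every
#' condition evenly; per subject, edge-corrected d-prime is computed over
#' each half's pooled counts, and the Pearson correlation across subjects is
#' returned with a permutation p-value.
#'
#' @param trials data frame of classified trials for >= 3 subjects.
#' @param seed integer seed for the permutation test.
#' @param n_perm number of permutations (default 2000).
#' @return list with `r`, `p`, `n_subjects`, and `halves` (per-subject
#'   half d-primes).
#' @export
split_half_reliability <- function(trials, seed = 1L, n_perm = 2000L) {
  trials <- trials[trials$outcome != "invalid", , drop = FALSE]
  has_timbre <- "timbre_level" %in% names(trials) &&
    any(!is.na(trials$timbre_level))
  cond <- paste(trials$attention,
                if (has_timbre) trials$timbre_level else "")
  ord <- order(trials$subject_id, cond,
               if ("run_index" %in% names(trials)) trials$run_index else 0,
               if ("block_index" %in% names(trials)) trials$block_index else 0,
               if ("trial_index" %in% names(trials)) trials$trial_index else
                 seq_len(nrow(trials)))
  trials <- trials[ord, , drop = FALSE]
  cond <- cond[ord]
  serial <- stats::ave(seq_len(nrow(trials)),
                       paste(trials$subject_id, cond), FUN = seq_along)
  half <- ifelse(serial %% 2L == 1L, 1L, 2L)

  subjects <- unique(trials$subject_id)
  d1 <- d2 <- numeric(length(subjects))
  for (i in seq_along(subjects)) {
    idx <- trials$subject_id == subjects[i]
    for (h in 1:2) {
      oc <- trials$outcome[idx & half == h]
      if (sum(oc %in% c("hit", "miss")) < 1L ||
          sum(oc %in% c("fa", "cr")) < 1L) {
        stop("empty half for subject ", subjects[i],
             ": need target and non-target trials in both halves",
             call. = FALSE)
      }
      val <- edge_corrected_dprime(sum(oc == "hit"), sum(oc == "miss"),
                                   sum(oc == "fa"), sum(oc == "cr"))
      if (h == 1L) d1[i] <- val else d2[i] <- val
    }
  }
  if (length(subjects) < 3L) stop("need >= 3 subjects", call. = FALSE)
  r <- cor(d1, d2)
  p <- with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) cor(d1, sample(d2)), 0)
    (1 + sum(abs(perm) >= abs(r) - 1e-12)) / (n_perm + 1)
  })
  list(r = r, p = p, n_subjects = length(subjects),
       halves = data.frame(subject_id = subjects, dprime_half1 = d1,
                           dprime_half2 = d2, stringsAsFactors = FALSE))
}

# All permutations of 1..n as an n! x n integer matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(p), n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(p) + seq_len(nrow(p))
    shifted <- p + (p >= k)
    out[rows, ] <- cbind(rep.int(k, nrow(p)), shifted)
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The two-sided p-value is
#' exact (full permutation enumeration) for n <= 9 and uses the
#' t-approximation on `rho * sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y numeric vectors of equal length >= 4, neither constant.
#' @return list with `rho`, `p` and `method`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 4L) stop("need n >= 4", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("constant vector", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9L) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- (matrix(rxc[perms], nrow(perms), n) %*% ryc) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, method = method)
}

#' Per-subject morph effect
#'
#' Accuracy over all maximum-timbre-distance trials minus accuracy over all
#' minimum-distance trials: the behavioural footprint of the bottom-up
#' timbre manipulation, per subject.
#'
#' @param trials data frame of classified timbre-experiment trials.
#' @return data frame with `subject_id`, `morph_effect`.
#' @export
morph_effect <- function(trials) {
  trials <- trials[trials$outcome != "invalid", , drop = FALSE]
  if (!"timbre_level" %in% names(trials) || all(is.na(trials$timbre_level))) {
    stop("trials carry no timbre_level", call. = FALSE)
  }
  groups <- split(trials, trials$subject_id)
  out <- lapply(groups, function(tr) {
    mx <- tr$outcome[tr$timbre_level == "maximum"]
    mn <- tr$outcome[tr$timbre_level == "minimum"]
    if (length(mx) == 0L || length(mn) == 0L) {
      stop("subject ", tr$subject_id[1L],
           " is missing a timbre level", call. = FALSE)
    }
    data.frame(subject_id = tr$subject_id[1L],
               morph_effect = mean(mx %in% c("hit", "cr")) -
                 mean(mn %in% c("hit", "cr")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Median and interquartile range of a score vector
#'
#' @param scores numeric vector (>= 1 value).
#' @return list with `median`, `q25`, `q75` (linear interpolation between
#'   order statistics).
#' @export
group_summary <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  q <- unname(quantile(scores, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2L], q25 = q[1L], q75 = q[3L])
}
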