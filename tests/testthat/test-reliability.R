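test_that("identical halves give perfect split-half reliability", {
  # every trial cloned into consecutive serial positions: odd/even halves
  # hold identical trial sets per subject
  set.seed(7)
  rows <- list()
  for (s in 1:5) {
    d <- 0.5 + s * 0.6
    versions <- rep(c("upper", "none"), each = 8)
    resp <- ifelse(runif(16) < pnorm(ifelse(versions == "upper", 1, -1) *
                                       0.5 * d),
                   "present", "absent")
    one <- data.frame(subject_id = sprintf("S%02d", s), run_index = 1L,
                      block_index = 1L, attention = "bassoon",
                      triplet_version = versions, response = resp,
                      stringsAsFactors = FALSE)
    two <- rbind(one, one)
    two <- two[rep(seq_len(16), each = 2) + c(0, 16), ]
    two$trial_index <- 1:32
    rows[[s]] <- two
  }
  trials <- do.call(rbind, rows)
  trials$outcome <- classify_trial(trials$attention, trials$triplet_version,
                                   trials$response)
  rel <- split_half_reliability(trials, seed = 1)
  expect_equal(rel$r, 1)
  expect_equal(rel$halves$dprime_half1, rel$halves$dprime_half2)
})

test_that("split-half reliability tracks between-subject spread", {
  schedules <- lapply(1:12, function(s) exp1_schedule(s, 16, seed = 600 + s))
  r_spread <- r_null <- numeric(25)
  for (i in 1:25) {
    tp <- truth_params("exp1", n_subjects = 12, subject_sd = 1.5,
                       seed = 700 + i)
    sim <- simulate_cohort(tp, seed = 700 + i, schedules = schedules)
    r_spread[i] <- split_half_reliability(sim$trials, seed = i)$r
    tp0 <- truth_params("exp1", n_subjects = 12, subject_sd = 0,
                        residual_sd_per_attention = rep(1e-6, 3),
                        seed = 800 + i)
    sim0 <- simulate_cohort(tp0, seed = 800 + i, schedules = schedules)
    r_null[i] <- split_half_reliability(sim0$trials, seed = i)$r
  }
  expect_gt(median(r_spread), 0.7)
  # with all between-subject variance removed the correlation centres on 0
  expect_lt(abs(mean(r_null)), 0.2)
  expect_true(all(abs(c(r_spread, r_null)) <= 1))
})

test_that("spearman matches an exhaustive permutation oracle with ties", {
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2, 1, 3, 3, 5, 6)
  got <- spearman(x, y)
  # oracle: enumerate all 6! permutations recursively (independent code)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  all_r <- vapply(perms(ry), function(p) cor(rx, p), 0)
  expect_equal(got$rho, obs)
  expect_equal(got$p, mean(abs(all_r) >= abs(obs) - 1e-12))
})

test_that("spearman handles monotone data and input validation", {
  expect_equal(spearman(1:6, c(2, 4, 9, 11, 30, 31))$rho, 1)
  expect_equal(spearman(1:6, rev(1:6))$rho, -1)
  big <- spearman(1:20, (1:20)^2 + c(0.1, -0.2))
  expect_equal(big$method, "t approximation")
  expect_true(big$p >= 0 && big$p <= 1)
  expect_error(spearman(1:5, 1:4), "length mismatch")
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:3, 1:3), "n >= 4")
})

test_that("morph effect is the max-minus-min accuracy difference", {
  mk <- function(subject, level, outcomes) {
    data.frame(subject_id = subject, timbre_level = level,
               outcome = outcomes, stringsAsFactors = FALSE)
  }
  trials <- rbind(mk("S01", "maximum", rep("hit", 10)),
                  mk("S01", "minimum", c(rep("hit", 8), "miss", "fa")),
                  mk("S02", "maximum", rep(c("hit", "cr"), 5)),
                  mk("S02", "minimum", rep(c("hit", "cr"), 5)))
  me <- morph_effect(trials)
  expect_equal(me$morph_effect[me$subject_id == "S01"], 0.2)
  expect_equal(me$morph_effect[me$subject_id == "S02"], 0)
  expect_error(morph_effect(mk("S03", "maximum", "hit")), "missing a timbre")
})

test_that("difficulty-linked timbre deficits show in the rank correlation", {
  # minimum-distance deficit confined to low-sensitivity subjects produces a
  # positive correlation between overall error rate and morph effect
  set.seed(15)
  n <- 10
  base_d <- seq(1.2, 4.8, length.out = n)
  rows <- list()
  schedules <- lapply(1:n, function(s) exp2_schedule(s, "LAB", seed = 900 + s))
  for (s in 1:n) {
    deficit <- if (base_d[s] < 3) 1.4 else 0
    grid <- expand.grid(attention = c("bassoon", "cello", "aggregate"),
                        timbre_level = c("maximum", "intermediate", "minimum"),
                        stringsAsFactors = FALSE)
    grid$true_dprime <- base_d[s] -
      ifelse(grid$timbre_level == "minimum", deficit, 0)
    grid$true_bias <- 0
    grid$subject_id <- sprintf("S%02d", s)
    rows[[s]] <- simulate_trials(grid, schedules[[s]], seed = 900 + s)
  }
  trials <- do.call(rbind, rows)
  me <- morph_effect(trials)
  sc <- subject_scores(trials)
  stopifnot(identical(me$subject_id, sc$subject_id))
  rho <- spearman(1 - sc$correct_rate, me$morph_effect)$rho
  expect_gt(rho, 0)
})

test_that("group summaries report median and interpolated quartiles", {
  gs <- group_summary(c(0.8, 0.9, 1.0))
  expect_equal(gs$median, 0.9)
  gc <- group_summary(rep(0.7, 8))
  expect_equal(gc$q75 - gc$q25, 0)
  set.seed(2)
  gu <- group_summary(runif(100))
  expect_lt(abs(gu$q25 - 0.25), 0.05)
  expect_lt(abs(gu$q75 - 0.75), 0.05)
  expect_error(group_summary(numeric()), "empty")
})
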