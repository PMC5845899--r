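test_that("exp1 schedules have the published structure", {
  sch <- exp1_schedule(1, 16, seed = 11)
  tr <- sch$trials
  expect_equal(nrow(tr), 96L)
  expect_equal(length(unique(tr$block_index)), 6L)
  tgt <- streamsdt:::is_target_trial(tr$attention, tr$triplet_version)
  expect_equal(sum(tgt), 48L)
  expect_equal(sum(!tgt), 48L)
  # each condition in exactly two blocks
  block_att <- tapply(tr$attention, tr$block_index, function(x) x[1])
  expect_true(all(table(block_att) == 2))
  # per-block mixes
  for (b in unique(tr$block_index)) {
    bl <- tr[tr$block_index == b, ]
    vt <- table(bl$triplet_version)
    if (bl$attention[1] == "aggregate") {
      expect_equal(as.vector(vt[c("crossing", "none")]), c(8L, 8L))
    } else {
      expect_equal(as.vector(sum(vt[c("upper", "lower")])), 12L)
      expect_equal(as.vector(vt["none"]), 4L)
    }
  }
  # the 10-composition variant keeps the same structure
  sch10 <- exp1_schedule(2, 10, seed = 11)
  expect_equal(nrow(sch10$trials), 96L)
  expect_lte(max(table(sch10$trials$composition_id,
                       sch10$trials$block_index)), 2)
})

test_that("exp2 schedules have the published structure", {
  lab <- exp2_schedule(1, "LAB", seed = 21)
  expect_equal(nrow(lab$trials), 90L)
  scan <- exp2_schedule(1, "SCAN", seed = 21)
  expect_equal(nrow(scan$trials), 135L)
  # 8 targets, 7 controls per run
  for (r in unique(lab$trials$run_index)) {
    run <- lab$trials[lab$trials$run_index == r, ]
    expect_equal(sum(streamsdt:::is_target_trial(run$attention,
                                                 run$triplet_version)), 8L)
  }
  # every attention x timbre cell has targets and controls (estimability)
  tgt <- streamsdt:::is_target_trial(lab$trials$attention,
                                     lab$trials$triplet_version)
  expect_true(all(table(lab$trials$attention, lab$trials$timbre_level, tgt) >= 1))
})

test_that("rating schedules alternate voices over eight equal blocks", {
  sch <- rating_schedule(seed = 31)
  tr <- sch$trials
  expect_equal(nrow(tr), 176L)
  expect_true(all(table(tr$block_index) == 22))
  tr <- tr[order(tr$block_index, tr$trial_index), ]
  expect_true(all(tr$voice[-1] != tr$voice[-nrow(tr)]))
  for (b in unique(tr$block_index)) {
    bl <- tr[tr$block_index == b, ]
    expect_equal(nrow(unique(bl[c("voice", "morph_fraction")])), 22L)
  }
})

test_that("generation is pure with respect to the seed", {
  expect_identical(exp1_schedule(3, 16, seed = 7)$trials,
                   exp1_schedule(3, 16, seed = 7)$trials)
  expect_identical(exp2_schedule(2, "SCAN", seed = 7)$trials,
                   exp2_schedule(2, "SCAN", seed = 7)$trials)
  expect_identical(rating_schedule(seed = 7)$trials,
                   rating_schedule(seed = 7)$trials)
  expect_false(identical(exp2_schedule(2, "LAB", seed = 7)$trials,
                         exp2_schedule(2, "LAB", seed = 8)$trials))
})

test_that("every generated schedule validates with zero violations", {
  for (s in 1:40) {
    expect_equal(nrow(exp2_schedule((s %% 12) + 1,
                                    if (s %% 2) "LAB" else "SCAN",
                                    seed = 1000 + s)$constraint_report), 0L)
    expect_equal(nrow(exp1_schedule((s %% 18) + 1,
                                    if (s %% 2) 16L else 10L,
                                    seed = 2000 + s)$constraint_report), 0L)
  }
  for (s in 1:20) {
    expect_equal(nrow(rating_schedule(seed = 3000 + s)$constraint_report), 0L)
  }
})

test_that("condition order balances across a rotation of participants", {
  # over the 18 legal half-order pairs, each condition occupies each serial
  # position equally often
  pos <- matrix(0L, 3, 6, dimnames = list(c("bassoon", "cello", "aggregate"),
                                          NULL))
  for (p in 1:18) {
    ord <- streamsdt:::exp1_condition_order(p)
    for (b in 1:6) pos[ord[b], b] <- pos[ord[b], b] + 1L
  }
  expect_true(all(pos == 6L))
})

test_that("the validator flags targeted corruptions and nothing else", {
  # adjacent identical timbre distances within an exp2 block
  sch <- exp2_schedule(1, "LAB", seed = 5)
  tr <- sch$trials
  b1 <- which(tr$run_index == 1 & tr$block_index == 1)
  tl <- tr$timbre_level[b1]
  # find two trials whose swap creates an adjacent duplicate
  swapped <- FALSE
  for (i in 1:4) {
    for (j in (i + 1):5) {
      tl2 <- tl; tmp <- tl2[i]; tl2[i] <- tl2[j]; tl2[j] <- tmp
      if (any(tl2[-1] == tl2[-5]) ) {
        tr$timbre_level[b1[c(i, j)]] <- tl[c(j, i)]
        swapped <- TRUE
        break
      }
    }
    if (swapped) break
  }
  expect_true(swapped)
  rep <- validate_schedule(list(experiment = "exp2", group = "LAB",
                                trials = tr))
  expect_true("identical timbre distances adjacent" %in% rep$constraint)

  # an exp1 block with one composition three times
  sch1 <- exp1_schedule(1, 16, seed = 5)
  tr1 <- sch1$trials
  idx <- which(tr1$block_index == 2)
  tr1$composition_id[idx[c(1, 8, 16)]] <- "comp03"
  rep1 <- validate_schedule(list(experiment = "exp1", trials = tr1))
  expect_true("composition repeated more than once" %in% rep1$constraint)

  # identical half-orders (built with per-condition version mixes intact)
  blocks <- lapply(1:6, function(b) {
    att <- c("aggregate", "cello", "bassoon")[(b - 1) %% 3 + 1]
    data.frame(run_index = 1L, block_index = b, trial_index = 1:16,
               attention = att,
               triplet_version = streamsdt:::exp1_block_versions(att),
               composition_id = sprintf("comp%02d", 1:16),
               timbre_level = NA_character_, stringsAsFactors = FALSE)
  })
  rep2 <- validate_schedule(list(experiment = "exp1",
                                 trials = do.call(rbind, blocks)))
  expect_true("order within halves not unique" %in% rep2$constraint)
})
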