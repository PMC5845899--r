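test_that("classify_trial matches an exhaustive truth-table oracle", {
  # independent statement of the rule: a trial is a target exactly when the
  # pattern sits in the attended stream
  oracle_target <- list(bassoon = "upper", cello = "lower",
                        aggregate = "crossing")
  for (att in c("bassoon", "cello", "aggregate")) {
    versions <- if (att == "aggregate") c("none", "crossing") else
      c("none", "upper", "lower", "crossing")
    for (ver in versions) {
      for (rsp in c("present", "absent")) {
        target <- identical(ver, oracle_target[[att]])
        want <- if (target && rsp == "present") "hit"
          else if (target) "miss"
          else if (rsp == "present") "fa"
          else "cr"
        expect_identical(classify_trial(att, ver, rsp), want,
                         info = paste(att, ver, rsp))
      }
    }
  }
})

test_that("classification handles invalid designs and missing responses", {
  expect_identical(classify_trial("bassoon", "upper", "present"), "hit")
  expect_identical(classify_trial("bassoon", "lower", "present"), "fa")
  expect_identical(classify_trial("aggregate", "none", "absent"), "cr")
  expect_identical(classify_trial("cello", "lower", "missing"), "invalid")
  expect_error(classify_trial("aggregate", "upper", "present"),
               "invalid design")
  expect_error(classify_trial("flute", "upper", "present"), "invalid level")
})

test_that("edge-corrected d-prime and criterion reproduce oracle values", {
  expect_equal(edge_corrected_dprime(8, 8, 8, 8), 0)
  # frozen from an independent normal-quantile oracle (scipy.stats.norm.ppf)
  expect_equal(edge_corrected_dprime(16, 0, 0, 16), 3.77901992066686,
               tolerance = 1e-12)
  expect_equal(edge_corrected_dprime(12, 4, 2, 14), 1.6780356155961607,
               tolerance = 1e-12)
  expect_equal(edge_corrected_bias(8, 8, 8, 8), 0)
  expect_equal(edge_corrected_bias(16, 0, 0, 16), 0)
  expect_equal(edge_corrected_bias(4, 12, 0, 16), 1.25920708898281,
               tolerance = 1e-12)
  expect_gt(edge_corrected_bias(4, 12, 0, 16), 0)  # conservative criterion
  expect_error(edge_corrected_dprime(0, 0, 3, 5), "zero target")
  expect_error(edge_corrected_dprime(3, 5, 0, 0), "zero non-target")
})

test_that("edge-corrected d-prime satisfies its analytic properties", {
  set.seed(41)
  for (i in 1:200) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    H <- sample(0:n1, 1); FA <- sample(0:n2, 1)
    d <- edge_corrected_dprime(H, n1 - H, FA, n2 - FA)
    # antisymmetry (exact up to floating-point rounding of the two rates)
    expect_equal(d, -edge_corrected_dprime(n1 - H, H, n2 - FA, FA),
                 tolerance = 1e-12)
    # monotonicity
    if (H < n1) {
      expect_gte(edge_corrected_dprime(H + 1, n1 - H - 1, FA, n2 - FA), d)
    }
    if (FA < n2) {
      expect_lte(edge_corrected_dprime(H, n1 - H, FA + 1, n2 - FA - 1), d)
    }
    # boundedness
    bound <- qnorm((n1 + 0.5) / (n1 + 1)) + qnorm((n2 + 0.5) / (n2 + 1))
    expect_lte(abs(d), bound + 1e-12)
  }
})

test_that("aggregate_counts forms one cell per condition with exact tallies", {
  trials <- data.frame(subject_id = "S01", run_index = 1L, block_index = 1L,
                       trial_index = 1:4, attention = "bassoon",
                       triplet_version = c("upper", "upper", "none", "lower"),
                       response = c("present", "absent", "absent", "present"),
                       stringsAsFactors = FALSE)
  trials$outcome <- classify_trial(trials$attention, trials$triplet_version,
                                   trials$response)
  cells <- aggregate_counts(trials)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$n_tri + cells$n_ntri, 4L)
  expect_equal(cells$n_hit, 1L)
  expect_equal(cells$n_miss, 1L)
  expect_equal(cells$n_fa, 1L)
  expect_equal(cells$n_cr, 1L)
  expect_equal(cells$dprime_ec, edge_corrected_dprime(1, 1, 1, 1))

  # duplicate trial keys are an integrity error
  dup <- rbind(trials, trials[1, ])
  expect_error(aggregate_counts(dup), "duplicate")

  # empty input gives an empty frame
  expect_equal(nrow(aggregate_counts(trials[0, ])), 0L)

  # invalid outcomes are excluded with a message
  trials$outcome[2] <- "invalid"
  expect_message(cells2 <- aggregate_counts(trials), "invalid")
  expect_equal(cells2$n_tri + cells2$n_ntri, 3L)
})

test_that("cohort aggregation yields the full cell grid per subject", {
  tp <- truth_params("exp2", n_subjects = 3, seed = 5)
  sim <- simulate_cohort(tp, group = "LAB", seed = 5)
  cells <- aggregate_counts(sim$trials)
  expect_equal(nrow(cells), 3 * 9)
  expect_true(all(table(cells$subject_id) == 9))
  expect_true(all(cells$n_tri >= 1 & cells$n_ntri >= 1))
  expect_true(all(is.finite(cells$dprime_ec)))

  tp1 <- truth_params("exp1", n_subjects = 4, seed = 5)
  sim1 <- simulate_cohort(tp1, seed = 5)
  cells1 <- aggregate_counts(sim1$trials)
  expect_equal(nrow(cells1), 4 * 3)
  expect_true(all(is.na(cells1$timbre_level)))
})
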