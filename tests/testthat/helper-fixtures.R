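# Shared fixtures: small hand-built trial/cell frames and an independently
# coded oracle for the model's log joint density.

# Trial stubs with the minimal columns the simulator and aggregator need.
make_stubs <- function(attention, triplet_version, timbre_level = NA,
                       subject = "S01") {
  n <- max(length(attention), length(triplet_version), length(timbre_level))
  data.frame(run_index = 1L, block_index = 1L, trial_index = seq_len(n),
             attention = rep_len(attention, n),
             triplet_version = rep_len(triplet_version, n),
             composition_id = "comp01",
             timbre_level = rep_len(timbre_level, n),
             stringsAsFactors = FALSE)
}

# A small hand-built measurement-cells frame (exp1 shape: attention only).
tiny_cells <- function(n_subj = 2, counts = c(8, 2, 1, 9)) {
  grid <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subj)),
                      attention = c("bassoon", "cello", "aggregate"),
                      stringsAsFactors = FALSE)
  out <- data.frame(grid, timbre_level = NA_character_,
                    n_hit = counts[1], n_miss = counts[2],
                    n_fa = counts[3], n_cr = counts[4],
                    stringsAsFactors = FALSE)
  out$n_tri <- out$n_hit + out$n_miss
  out$n_ntri <- out$n_fa + out$n_cr
  out
}

# Brute-force log joint, written term by term and independently of the
# package implementation (explicit loops, dbinom/dnorm on the probability
# scale). Exp1 structure (attention + subject), matching log_joint's
# contract for experiment = "exp1".
oracle_log_joint_exp1 <- function(state, cells, config) {
  subjects <- sort(unique(cells$subject_id))
  atts <- c("bassoon", "cello", "aggregate")
  total <- 0
  for (i in seq_len(nrow(cells))) {
    d <- state$dprime[i]
    b <- state$bias[i]
    p_hit <- pnorm(0.5 * d - b)
    p_fa <- pnorm(-0.5 * d - b)
    total <- total + dbinom(cells$n_hit[i], cells$n_tri[i], p_hit, log = TRUE)
    total <- total + dbinom(cells$n_fa[i], cells$n_ntri[i], p_fa, log = TRUE)
  }
  for (side in c("d", "b")) {
    g <- function(nm) state[[paste0(if (side == "b") "bias_" else "", nm)]]
    latent <- if (side == "d") state$dprime else state$bias
    s_res <- g("sigma_res")
    s_beta <- g("sigma_beta")
    if (any(s_res <= 0 | s_res >= config$sigma_upper) || any(s_beta <= 0)) {
      return(-Inf)
    }
    for (i in seq_len(nrow(cells))) {
      a <- match(cells$attention[i], atts)
      s <- match(cells$subject_id[i], subjects)
      mu <- g("beta0") + g("beta_att")[a] + g("beta_subj")[s]
      total <- total + dnorm(latent[i], mu, s_res[a], log = TRUE)
    }
    total <- total + dnorm(g("beta0"), 0,
                           sqrt(config$prior_intercept_variance), log = TRUE)
    for (k in 1:3) {
      total <- total + dnorm(g("beta_att")[k], 0, s_beta[1], log = TRUE)
    }
    for (s in seq_along(subjects)) {
      total <- total + dnorm(g("beta_subj")[s], 0, s_beta[2], log = TRUE)
    }
    for (k in 1:3) total <- total - log(config$sigma_upper)
    for (j in 1:2) {
      total <- total + dgamma(s_beta[j], shape = config$gamma_shape,
                              rate = config$gamma_rate, log = TRUE)
    }
  }
  total
}

# A valid random state for the exp1 log-joint comparison.
random_exp1_state <- function(cells, seed) {
  set.seed(seed)
  n_subj <- length(unique(cells$subject_id))
  M <- nrow(cells)
  list(dprime = rnorm(M, 1.5, 0.5), bias = rnorm(M, 0, 0.3),
       beta0 = rnorm(1), beta_att = rnorm(3, 0, 0.5),
       beta_subj = rnorm(n_subj, 0, 0.5),
       sigma_res = runif(3, 0.3, 2), sigma_beta = rgamma(2, 2, 1),
       bias_beta0 = rnorm(1), bias_beta_att = rnorm(3, 0, 0.3),
       bias_beta_subj = rnorm(n_subj, 0, 0.3),
       bias_sigma_res = runif(3, 0.3, 2), bias_sigma_beta = rgamma(2, 2, 1))
}
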