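# ANOVA-like hierarchical Bayesian probit-binomial signal detection model:
# configuration, log joint density, MCMC driver (compiled sampler), HDI
# inference, and the recentered effect re-expression.

#' Configuration for the hierarchical signal detection model
#'
#' @param experiment `"exp2"` (attention x timbre structure) or `"exp1"`
#'   (attention only).
#' @param n_samples retained MCMC draws per chain (default 10000).
#' @param burn_in discarded warm-up iterations per chain (default 2000);
#'   proposal adaptation is confined to this phase.
#' @param n_chains number of independent chains (default 4).
#' @param seed integer seed; per-chain seeds are derived from it.
#' @param prior_intercept_variance variance of the zero-centred normal prior
#'   on the intercept (default 1000, i.e. essentially flat on the d-prime
#'   scale).
#' @param sigma_upper upper bound of the uniform prior on the residual
#'   standard deviations (default 4).
#' @param gamma_shape,gamma_rate shape and rate of the gamma prior on the
#'   coefficient-group standard deviations; the defaults (1.64, 0.32) give
#'   mode 2 and standard deviation 4.
#' @return an object of class `"model_config"`.
#' @export
model_config <- function(experiment = c("exp2", "exp1"), n_samples = 10000L,
                         burn_in = 2000L, n_chains = 4L, seed = 1L,
                         prior_intercept_variance = 1000,
                         sigma_upper = 4, gamma_shape = 1.64,
                         gamma_rate = 0.32) {
  experiment <- match.arg(experiment)
  vals <- c(n_samples = n_samples, burn_in = burn_in, n_chains = n_chains,
            prior_intercept_variance = prior_intercept_variance,
            sigma_upper = sigma_upper, gamma_shape = gamma_shape,
            gamma_rate = gamma_rate)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all model configuration values must be positive and finite",
         call. = FALSE)
  }
  structure(list(experiment = experiment, n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), n_chains = as.integer(n_chains),
                 seed = as.integer(seed),
                 prior_intercept_variance = prior_intercept_variance,
                 sigma_upper = sigma_upper, gamma_shape = gamma_shape,
                 gamma_rate = gamma_rate),
            class = "model_config")
}

# Integer-coded design data extracted from a measurement_cells frame.
build_model_data <- function(cells, config) {
  stopifnot(is.data.frame(cells))
  need <- c("subject_id", "attention", "n_hit", "n_fa", "n_tri", "n_ntri")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cells missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(cells$n_tri < 1L) || any(cells$n_ntri < 1L)) {
    stop("every cell needs at least one target and one non-target trial",
         call. = FALSE)
  }
  subjects <- sort(unique(cells$subject_id))
  if (length(subjects) < 2L) stop("need >= 2 subjects", call. = FALSE)
  has_timb <- config$experiment == "exp2"
  if (has_timb && (!"timbre_level" %in% names(cells) ||
                   anyNA(cells$timbre_level))) {
    stop("exp2 model requires a complete timbre_level column", call. = FALSE)
  }
  att <- match(cells$attention, ATTENTION_LEVELS)
  if (anyNA(att)) stop("unknown attention level in cells", call. = FALSE)
  timb <- if (has_timb) match(cells$timbre_level, TIMBRE_LEVELS) else
    rep(0L, nrow(cells))
  if (has_timb && anyNA(timb)) stop("unknown timbre level in cells",
                                    call. = FALSE)
  list(H = as.integer(cells$n_hit), ntri = as.integer(cells$n_tri),
       FA = as.integer(cells$n_fa), nntri = as.integer(cells$n_ntri),
       att = as.integer(att), timb = as.integer(timb),
       subj = match(cells$subject_id, subjects),
       subjects = subjects, n_subj = length(subjects), has_timb = has_timb,
       dprime_init = edge_corrected_dprime(cells$n_hit, cells$n_tri - cells$n_hit,
                                           cells$n_fa, cells$n_ntri - cells$n_fa),
       bias_init = edge_corrected_bias(cells$n_hit, cells$n_tri - cells$n_hit,
                                       cells$n_fa, cells$n_ntri - cells$n_fa))
}

# Parameter names in the exact column order the compiled sampler writes.
model_param_names <- function(dat) {
  M <- length(dat$H)
  side <- function(prefix) {
    nm <- c(paste0(prefix, "beta0"),
            paste0(prefix, "beta_att[", ATTENTION_LEVELS, "]"))
    if (dat$has_timb) {
      nm <- c(nm, paste0(prefix, "beta_timb[", TIMBRE_LEVELS, "]"),
              paste0(prefix, "beta_ati[",
                     rep(ATTENTION_LEVELS, each = 3), ".",
                     rep(TIMBRE_LEVELS, 3), "]"))
    }
    nm <- c(nm, paste0(prefix, "beta_subj[", dat$subjects, "]"),
            paste0(prefix, "sigma_res[", ATTENTION_LEVELS, "]"))
    groups <- if (dat$has_timb) c("att", "timb", "ati", "subj") else
      c("att", "subj")
    c(nm, paste0(prefix, "sigma_beta[", groups, "]"))
  }
  c(paste0("dprime[", seq_len(M), "]"), paste0("bias[", seq_len(M), "]"),
    side(""), side("bias_"))
}

# Flat named initial state used by log_joint checks and tests.
initial_state <- function(dat) {
  groups <- if (dat$has_timb) 4L else 2L
  st <- list(dprime = dat$dprime_init, bias = dat$bias_init,
             beta0 = 0, beta_att = rep(0, 3), beta_subj = rep(0, dat$n_subj),
             sigma_res = rep(1, 3), sigma_beta = rep(1, groups),
             bias_beta0 = 0, bias_beta_att = rep(0, 3),
             bias_beta_subj = rep(0, dat$n_subj), bias_sigma_res = rep(1, 3),
             bias_sigma_beta = rep(1, groups))
  if (dat$has_timb) {
    st$beta_timb <- rep(0, 3); st$beta_ati <- rep(0, 9)
    st$bias_beta_timb <- rep(0, 3); st$bias_beta_ati <- rep(0, 9)
  }
  st
}

#' Log joint density of the hierarchical signal detection model
#'
#' Sum of every log-likelihood term (binomial hits with success probability
#' \eqn{\Phi(0.5 d'_m - bias_m)}, binomial false alarms with
#' \eqn{\Phi(-0.5 d'_m - bias_m)}) and every log-prior term (latent cells
#' normal around their ANOVA mean with attention-specific residual sd;
#' Gaussian coefficients; flat-variance normal intercept; uniform residual
#' sds; gamma coefficient-group sds). Returns `-Inf` outside any prior
#' support.
#'
#' @param state named list of parameter values: `dprime`, `bias` (length-M
#'   vectors), `beta0`, `beta_att` (3), `beta_timb` (3, exp2), `beta_ati`
#'   (9, exp2), `beta_subj` (one per subject), `sigma_res` (3),
#'   `sigma_beta` (4 for exp2, 2 for exp1), and the `bias_`-prefixed
#'   counterparts.
#' @param cells a `"measurement_cells"` data frame.
#' @param config a [model_config()] object.
#' @return single numeric, the unnormalised log posterior.
#' @export
log_joint <- function(state, cells, config) {
  dat <- build_model_data(cells, config)
  M <- length(dat$H)
  need_len <- function(x, n, nm) {
    if (is.null(x) || length(x) != n) {
      stop("state dimension mismatch for `", nm, "` (need ", n, ")",
           call. = FALSE)
    }
    x
  }
  d <- need_len(state$dprime, M, "dprime")
  bi <- need_len(state$bias, M, "bias")
  n_groups <- if (dat$has_timb) 4L else 2L

  side_lp <- function(latent, prefix) {
    g <- function(nm) state[[paste0(prefix, nm)]]
    beta0 <- need_len(g("beta0"), 1L, paste0(prefix, "beta0"))
    b_att <- need_len(g("beta_att"), 3L, paste0(prefix, "beta_att"))
    b_subj <- need_len(g("beta_subj"), dat$n_subj, paste0(prefix, "beta_subj"))
    s_res <- need_len(g("sigma_res"), 3L, paste0(prefix, "sigma_res"))
    s_beta <- need_len(g("sigma_beta"), n_groups, paste0(prefix, "sigma_beta"))
    if (any(s_res <= 0) || any(s_res >= config$sigma_upper) ||
        any(s_beta <= 0)) {
      return(-Inf)
    }
    mu <- beta0 + b_att[dat$att] + b_subj[dat$subj]
    coef_lp <- sum(dnorm(b_att, 0, s_beta[1L], log = TRUE)) +
      sum(dnorm(b_subj, 0, s_beta[n_groups], log = TRUE))
    if (dat$has_timb) {
      b_timb <- need_len(g("beta_timb"), 3L, paste0(prefix, "beta_timb"))
      b_ati <- need_len(g("beta_ati"), 9L, paste0(prefix, "beta_ati"))
      mu <- mu + b_timb[dat$timb] + b_ati[(dat$att - 1L) * 3L + dat$timb]
      coef_lp <- coef_lp + sum(dnorm(b_timb, 0, s_beta[2L], log = TRUE)) +
        sum(dnorm(b_ati, 0, s_beta[3L], log = TRUE))
    }
    sum(dnorm(latent, mu, s_res[dat$att], log = TRUE)) + coef_lp +
      dnorm(beta0, 0, sqrt(config$prior_intercept_variance), log = TRUE) +
      sum(dunif(s_res, 0, config$sigma_upper, log = TRUE)) +
      sum(dgamma(s_beta, shape = config$gamma_shape, rate = config$gamma_rate,
                 log = TRUE))
  }

  lp_d <- side_lp(d, "")
  lp_b <- side_lp(bi, "bias_")
  if (!is.finite(lp_d) || !is.finite(lp_b)) return(-Inf)

  qh <- 0.5 * d - bi
  qf <- -0.5 * d - bi
  ll <- sum(lchoose(dat$ntri, dat$H) +
              dat$H * pnorm(qh, log.p = TRUE) +
              (dat$ntri - dat$H) * pnorm(qh, lower.tail = FALSE, log.p = TRUE)) +
    sum(lchoose(dat$nntri, dat$FA) +
          dat$FA * pnorm(qf, log.p = TRUE) +
          (dat$nntri - dat$FA) * pnorm(qf, lower.tail = FALSE, log.p = TRUE))
  ll + lp_d + lp_b
}

#' Fit the hierarchical signal detection model by MCMC
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler (compiled): random-walk
#' updates for the latent per-cell sensitivity and criterion, conjugate
#' Gibbs draws for every Gaussian coefficient, and log-scale random-walk
#' updates for the standard deviations, with proposal adaptation confined
#' to burn-in. Latent cells are initialized at their edge-corrected
#' d-prime / criterion values, coefficients at 0 and standard deviations at
#' 1. Split-R-hat is computed for every parameter and effective sample
#' sizes for the structural (non-latent) parameters; an R-hat above 1.1 on
#' any structural parameter attaches a convergence warning.
#'
#' @param cells a `"measurement_cells"` data frame (>= 2 subjects; every
#'   cell needs at least one target and one non-target trial).
#' @param config a [model_config()] object.
#' @return an object of class `"sdt_fit"`: list with `draws` (one
#'   `n_samples` x parameter matrix per chain), `param_names`, `data`
#'   (integer-coded design), `cells`, `config`, `diagnostics` (data frame
#'   with `rhat` and `ess`), and `convergence_warnings`.
#' @export
fit_model <- function(cells, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  dat <- build_model_data(cells, config)
  st <- initial_state(dat)
  lj <- log_joint(st, cells, config)
  if (!is.finite(lj)) stop("initialization error: non-finite initial log joint",
                           call. = FALSE)
  pn <- model_param_names(dat)
  draws <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    chain_seed <- (config$seed %% 100000L) * 1000L + 7L * ch
    draws[[ch]] <- with_seed(chain_seed, {
      mcmc_sdt_chain(dat$H, dat$ntri, dat$FA, dat$nntri, dat$att, dat$timb,
                     dat$subj, dat$n_subj, dat$has_timb, config$n_samples,
                     config$burn_in, config$prior_intercept_variance,
                     config$sigma_upper, config$gamma_shape, config$gamma_rate,
                     dat$dprime_init, dat$bias_init)
    })
    colnames(draws[[ch]]) <- pn
  }
  rhat <- split_rhat(draws)
  structural <- !grepl("^(dprime|bias)\\[", pn)
  ess <- rep(NA_real_, length(pn))
  ess[structural] <- vapply(which(structural), function(j) {
    sum(vapply(draws, function(d) unname(coda::effectiveSize(d[, j])), 0))
  }, 0)
  diagnostics <- data.frame(param = pn, rhat = rhat, ess = ess,
                            structural = structural, stringsAsFactors = FALSE)
  warn <- character()
  bad <- structural & is.finite(rhat) & rhat > 1.1
  if (any(bad)) {
    warn <- paste0("convergence warning: split-R-hat > 1.1 for ",
                   paste(pn[bad], collapse = ", "))
    warning(warn, call. = FALSE)
  }
  structure(list(draws = draws, param_names = pn, data = dat, cells = cells,
                 config = config, diagnostics = diagnostics,
                 convergence_warnings = warn),
            class = "sdt_fit")
}

#' @export
print.sdt_fit <- function(x, ...) {
  cat("<sdt_fit>", x$config$experiment, "model:",
      length(x$data$H), "cells,", x$data$n_subj, "subjects\n")
  cat("  chains:", length(x$draws), " retained draws/chain:",
      nrow(x$draws[[1]]), "\n")
  st <- x$diagnostics[x$diagnostics$structural, ]
  cat(sprintf("  max split-R-hat (structural): %.3f  min ESS: %.0f\n",
              max(st$rhat, na.rm = TRUE), min(st$ess, na.rm = TRUE)))
  if (length(x$convergence_warnings)) cat(" ", x$convergence_warnings, "\n")
  invisible(x)
}

#' Combine chains of a fitted model into one draw matrix
#'
#' @param x an `"sdt_fit"` object.
#' @param ... unused.
#' @return matrix with one column per parameter, chains stacked row-wise.
#' @export
as.matrix.sdt_fit <- function(x, ...) {
  do.call(rbind, x$draws)
}

# Split-R-hat (each chain halved) for a list of draw matrices; vectorized
# over parameters. Returns NA for parameters with zero variance.
split_rhat <- function(draws) {
  halves <- list()
  for (d in draws) {
    n <- nrow(d)
    h <- n %/% 2L
    halves[[length(halves) + 1L]] <- d[seq_len(h), , drop = FALSE]
    halves[[length(halves) + 1L]] <- d[(h + 1L):(2L * h), , drop = FALSE]
  }
  m <- length(halves)
  n <- nrow(halves[[1L]])
  means <- vapply(halves, colMeans, numeric(ncol(halves[[1L]])))
  vars <- vapply(halves, function(h) apply(h, 2L, stats::var),
                 numeric(ncol(halves[[1L]])))
  B <- n * apply(means, 1L, stats::var)
  W <- rowMeans(vars)
  rhat <- sqrt(((n - 1) / n * W + B / n) / W)
  rhat[W == 0] <- NA_real_
  unname(rhat)
}

#' Highest density interval of a sample
#'
#' The shortest interval containing the stated probability mass of the
#' draws: the interval spanning `ceiling(mass * n)` consecutive order
#' statistics with the smallest width (the left-most such interval when
#' several tie).
#'
#' @param draws numeric vector of at least 100 draws.
#' @param mass probability mass in (0, 1), default 0.95.
#' @return an object of class `"hdi"`: list with `low`, `high`, `mass`.
#' @examples
#' hdi(rnorm(1e5))  # approximately [-1.96, 1.96]
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100L) stop("need at least 100 draws", call. = FALSE)
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1) {
    stop("`mass` must lie in (0, 1)", call. = FALSE)
  }
  x <- sort(draws)
  keep <- ceiling(mass * n)
  n_start <- n - keep + 1L
  widths <- x[keep:n] - x[seq_len(n_start)]
  i <- which.min(widths)  # which.min returns the first (left-most) minimum
  structure(list(low = x[i], high = x[i + keep - 1L], mass = mass),
            class = "hdi")
}

#' @export
print.hdi <- function(x, ...) {
  cat(sprintf("%.0f%% HDI [%.4g, %.4g]\n", 100 * x$mass, x$low, x$high))
  invisible(x)
}

#' Recentered cell means and effects from a fitted model
#'
#' The raw ANOVA parameterization is over-parameterized (no sum-to-zero
#' constraints; hierarchical shrinkage keeps the posterior proper), so
#' effects are reported through a draw-wise re-expression: reconstruct
#' every condition cell mean (averaging over the subject terms), define the
#' grand mean as the average cell mean, main effects as marginal cell-mean
#' deviations from it, and interactions as the residuals. Main effects sum
#' to zero at every draw by construction.
#'
#' @param fit an `"sdt_fit"` object.
#' @param component `"dprime"` (default) or `"bias"` side of the model.
#' @return list of draw matrices (chains stacked): `grand` (vector),
#'   `attention` (n x 3), and for exp2 fits `timbre` (n x 3),
#'   `interaction` (n x 9) and `cell_means` (n x 9, columns
#'   `attention.timbre`).
#' @export
cell_effects <- function(fit, component = c("dprime", "bias")) {
  stopifnot(inherits(fit, "sdt_fit"))
  component <- match.arg(component)
  pre <- if (component == "dprime") "" else "bias_"
  X <- as.matrix(fit)
  col <- function(nm) X[, paste0(pre, nm), drop = FALSE]
  beta0 <- col("beta0")[, 1L]
  b_att <- X[, paste0(pre, "beta_att[", ATTENTION_LEVELS, "]"), drop = FALSE]
  b_subj <- X[, paste0(pre, "beta_subj[", fit$data$subjects, "]"),
              drop = FALSE]
  subj_mean <- rowMeans(b_subj)
  if (fit$data$has_timb) {
    b_timb <- X[, paste0(pre, "beta_timb[", TIMBRE_LEVELS, "]"), drop = FALSE]
    ati_names <- paste0(pre, "beta_ati[", rep(ATTENTION_LEVELS, each = 3),
                        ".", rep(TIMBRE_LEVELS, 3), "]")
    b_ati <- X[, ati_names, drop = FALSE]
    cells <- matrix(0, nrow(X), 9L)
    colnames(cells) <- paste0(rep(ATTENTION_LEVELS, each = 3), ".",
                              rep(TIMBRE_LEVELS, 3))
    for (a in 1:3) {
      for (t in 1:3) {
        j <- (a - 1L) * 3L + t
        cells[, j] <- beta0 + b_att[, a] + b_timb[, t] + b_ati[, j] + subj_mean
      }
    }
    grand <- rowMeans(cells)
    att_eff <- sapply(1:3, function(a)
      rowMeans(cells[, (a - 1L) * 3L + 1:3, drop = FALSE]) - grand)
    timb_eff <- sapply(1:3, function(t)
      rowMeans(cells[, t + c(0L, 3L, 6L), drop = FALSE]) - grand)
    colnames(att_eff) <- ATTENTION_LEVELS
    colnames(timb_eff) <- TIMBRE_LEVELS
    inter <- cells
    for (a in 1:3) {
      for (t in 1:3) {
        j <- (a - 1L) * 3L + t
        inter[, j] <- cells[, j] - grand - att_eff[, a] - timb_eff[, t]
      }
    }
    list(grand = grand, attention = att_eff, timbre = timb_eff,
         interaction = inter, cell_means = cells)
  } else {
    cells <- sweep(b_att, 1L, beta0 + subj_mean, `+`)
    colnames(cells) <- ATTENTION_LEVELS
    grand <- rowMeans(cells)
    att_eff <- cells - grand
    list(grand = grand, attention = att_eff, cell_means = cells)
  }
}

#' Posterior contrast between two effect levels or cells
#'
#' Draw-wise difference between two levels of a factor's recentered effects
#' (or between two reconstructed cell means), its highest density interval
#' and an excludes-zero flag.
#'
#' @param fit an `"sdt_fit"` object.
#' @param type `"attention"`, `"timbre"` (exp2 only) or `"cell"`.
#' @param levels character vector of the two level names to subtract
#'   (first minus second); for `type = "cell"`, names of the form
#'   `"attention.timbre"` (or plain attention names for exp1).
#' @param mass HDI mass (default 0.95).
#' @param component `"dprime"` or `"bias"`.
#' @return list with `draws` (difference vector), `hdi`, `excludes_zero`,
#'   `mean`.
#' @export
contrast <- function(fit, type = c("attention", "timbre", "cell"),
                     levels, mass = 0.95, component = c("dprime", "bias")) {
  type <- match.arg(type)
  component <- match.arg(component)
  eff <- cell_effects(fit, component)
  mat <- switch(type, attention = eff$attention, timbre = eff$timbre,
                cell = eff$cell_means)
  if (is.null(mat)) stop("effect type `", type, "` not present in this model",
                         call. = FALSE)
  if (length(levels) != 2L) stop("`levels` must name exactly two levels",
                                 call. = FALSE)
  bad <- setdiff(levels, colnames(mat))
  if (length(bad)) stop("unknown level(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  d <- mat[, levels[1L]] - mat[, levels[2L]]
  h <- hdi(d, mass)
  list(draws = d, hdi = h, excludes_zero = (h$low > 0 || h$high < 0),
       mean = mean(d))
}

#' Mode and standard deviation of a gamma prior
#'
#' For shape \eqn{a} and rate \eqn{b}: mode \eqn{(a-1)/b} (defined for
#' \eqn{a > 1}) and standard deviation \eqn{\sqrt{a}/b}. The package default
#' prior Gamma(1.64, 0.32) has mode 2 and standard deviation (almost
#' exactly) 4.
#'
#' @param shape,rate gamma shape and rate, both positive.
#' @return list with `mode` and `sd`.
#' @examples
#' gamma_prior_stats(1.64, 0.32)
#' @export
gamma_prior_stats <- function(shape, rate) {
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (shape <= 1) stop("mode undefined for shape <= 1", call. = FALSE)
  list(mode = (shape - 1) / rate, sd = sqrt(shape) / rate)
}
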