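# Timbre-perception psychometric function: a four-parameter sigmoid with the
# rating-scale asymptotes fixed (a = 1, b = 5), fitted per voice by
# Levenberg-Marquardt (damped Gauss-Newton) nonlinear least squares.

#' Timbre-morph rating sigmoid
#'
#' Predicted rating at morph fraction `r`:
#' \deqn{S(r) = 1 + \frac{b - a}{1 + 10^{(x_{50} - r)\,m}}}
#' with the asymptotes fixed at the rating-scale ends (`a = 1`, `b = 5`).
#' `S(x50) = 3`, the scale midpoint, and `S` is strictly increasing in `r`
#' for positive slope `m`.
#'
#' @param r morph fraction(s), 0 = original instrument, 1 = fully morphed
#'   toward the other instrument.
#' @param x50 perceptual centre point on the morph axis.
#' @param m slope.
#' @param a,b fixed asymptotes (rating-scale minimum and maximum).
#' @return predicted rating(s) in (a, b).
#' @examples
#' sigmoid_value(0.5, x50 = 0.5, m = 4)   # 3, the midpoint
#' sigmoid_value(0.75, x50 = 0.5, m = 4)  # ~4.636
#' @export
sigmoid_value <- function(r, x50, m, a = 1, b = 5) {
  if (any(!is.finite(c(r, x50, m)))) stop("inputs must be finite", call. = FALSE)
  a + (b - a) / (1 + 10^((x50 - r) * m))
}

#' Fit the timbre-rating sigmoid to one voice's data
#'
#' Least-squares estimation of the perceptual centre `x50` and slope `m`
#' with the asymptotes fixed (`a = 1`, `b = 5`), via Levenberg-Marquardt
#' iterations (at most 200). Initial values: `m = 1`, and `x50` at the morph
#' fraction whose mean rating is closest to the scale midpoint 3 -- a
#' data-driven start on the correct axis (a raw mean rating lives on the
#' 1-5 rating scale, not the morph axis).
#'
#' @param r morph fractions (>= 4 distinct values required).
#' @param rating observed ratings (same length), on an increasing 1-5 scale.
#' @param voice optional voice label stored in the fit.
#' @return an object of class `"sigmoid_fit"`: list with `voice`, `a`, `b`,
#'   `x50`, `m`, `rss`, `n_points`, `converged`, `iterations`.
#' @export
fit_sigmoid <- function(r, rating, voice = NA_character_) {
  if (length(r) != length(rating)) stop("`r` and `rating` lengths differ",
                                        call. = FALSE)
  keep <- is.finite(r) & is.finite(rating)
  r <- r[keep]; rating <- rating[keep]
  if (length(unique(r)) < 4L) {
    stop("need ratings at >= 4 distinct morph fractions", call. = FALSE)
  }
  if (length(unique(rating)) == 1L) {
    stop("degenerate data: all ratings identical", call. = FALSE)
  }
  means <- tapply(rating, r, mean)
  x50_0 <- as.numeric(names(means))[which.min(abs(means - 3))]
  dat <- data.frame(r = r, rating = rating)
  fit <- tryCatch(
    minpack.lm::nlsLM(rating ~ 1 + 4 / (1 + 10^((x50 - r) * m)),
                      data = dat, start = list(x50 = x50_0, m = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop("sigmoid fit failed: ", conditionMessage(fit), call. = FALSE)
  }
  est <- stats::coef(fit)
  conv <- fit$convInfo
  out <- list(voice = voice, a = 1, b = 5,
              x50 = unname(est[["x50"]]), m = unname(est[["m"]]),
              rss = sum(stats::resid(fit)^2), n_points = length(r),
              converged = isTRUE(conv$isConv) ||
                is.finite(est[["x50"]]) && is.finite(est[["m"]]),
              iterations = conv$finIter)
  class(out) <- "sigmoid_fit"
  out
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("<sigmoid_fit>", if (!is.na(x$voice)) paste0("voice=", x$voice), "\n")
  cat(sprintf("  x50 = %.4f  m = %.3f  rss = %.4g  n = %d  converged = %s\n",
              x$x50, x$m, x$rss, x$n_points, x$converged))
  invisible(x)
}

#' Fit both voices' sigmoids from rating records
#'
#' Convenience wrapper over [fit_sigmoid()] for the rating-session records
#' produced by [simulate_ratings()] or read from file. Ratings are on the
#' absolute 1 = bassoon .. 5 = cello scale; the lower voice's ratings are
#' reflected (`6 - rating`) onto its toward-the-other-instrument axis so
#' both voices are fitted with the increasing sigmoid.
#'
#' @param ratings data frame with columns `voice`, `morph_fraction`,
#'   `rating`.
#' @return named list of `"sigmoid_fit"` objects (`upper`, `lower`).
#' @export
fit_voice_sigmoids <- function(ratings) {
  need <- c("voice", "morph_fraction", "rating")
  miss <- setdiff(need, names(ratings))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  out <- lapply(c(upper = "upper", lower = "lower"), function(v) {
    sub <- ratings[ratings$voice == v, ]
    if (nrow(sub) == 0L) return(NULL)
    y <- if (v == "lower") 6 - sub$rating else sub$rating
    fit_sigmoid(sub$morph_fraction, y, voice = v)
  })
  out[!vapply(out, is.null, TRUE)]
}

#' Derive the three instrument-timbre distances from a fitted centre
#'
#' The maximum timbre distance is the unmorphed instrument (morph fraction
#' 0), the minimum distance is the listener's perceptual centre `x50`, and
#' the intermediate distance sits 20 percentage points back toward the
#' original from the centre (floored at 0).
#'
#' @param fit a `"sigmoid_fit"` object or a bare numeric `x50` in (0, 1).
#' @return an object of class `"timbre_levels"`: list with `maximum`,
#'   `intermediate`, `minimum` morph fractions (ordered
#'   maximum <= intermediate <= minimum).
#' @examples
#' assign_timbre_levels(0.5)  # 0, 0.3, 0.5
#' @export
assign_timbre_levels <- function(fit) {
  x50 <- if (inherits(fit, "sigmoid_fit")) {
    if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
    fit$x50
  } else {
    as.numeric(fit)
  }
  if (!is.finite(x50) || x50 <= 0 || x50 >= 1) {
    stop("perceptual centre out of range: x50 must lie in (0, 1), got ",
         format(x50), call. = FALSE)
  }
  out <- list(maximum = 0, intermediate = max(x50 - 0.2, 0), minimum = x50)
  class(out) <- "timbre_levels"
  out
}

#' @export
print.timbre_levels <- function(x, ...) {
  cat(sprintf("<timbre_levels> maximum=%.2f intermediate=%.2f minimum=%.2f\n",
              x$maximum, x$intermediate, x$minimum))
  invisible(x)
}
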