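# Per-meal behavioural outcomes: duration, total bites, per-10%-segment
# bite counts and the quadratic meal-progress fit.

#' Summarise one meal from its annotation log
#'
#' For manual logs the meal starts at the first spoonful (falling back to
#' an explicit meal_start event, then to the first bite) and stops at the
#' last bite.  Detected logs carry bites only, so the meal is anchored at
#' the first and last detected bite.  Segment counts partition the meal
#' into \code{n_segments} equal spans of its duration.
#'
#' @param log an \code{\link{annotation_log}} with at least one bite.
#' @param n_segments number of equal meal-progress segments.
#' @return list of class \code{meal_summary}: \code{duration_min},
#'   \code{total_bites}, \code{segment_counts}, \code{start_s},
#'   \code{stop_s}, \code{source}.
#' @export
meal_summary <- function(log, n_segments = 10L) {
  stopifnot(inherits(log, "annotation_log"))
  bt <- bite_times(log)
  if (!length(bt))
    stop("no bites in log: meal duration undefined", call. = FALSE)
  if (log_source(log) == "manual") {
    sp <- log$time_s[log$event == "spoonful"]
    ms <- log$time_s[log$event == "meal_start"]
    start_s <- if (length(sp)) min(sp) else if (length(ms)) ms else min(bt)
  } else {
    start_s <- min(bt)
  }
  stop_s <- max(bt)
  counts <- segment_bite_rates(bt, start_s, stop_s, n_segments)
  structure(list(duration_min = (stop_s - start_s) / 60,
                 total_bites = length(bt), segment_counts = counts,
                 start_s = start_s, stop_s = stop_s,
                 source = log_source(log)),
            class = "meal_summary")
}

#' @export
print.meal_summary <- function(x, ...) {
  cat(sprintf(
    "<meal_summary> (%s) %.2f min, %d bites\n  per-segment: %s\n",
    x$source, x$duration_min, x$total_bites,
    paste(x$segment_counts, collapse = " ")))
  invisible(x)
}

#' Bite counts per equal meal-progress segment
#'
#' Segment \code{i} (1-based) covers
#' \code{[start + (i-1) D/n, start + i D/n)} with the final segment closed
#' on the right, so a bite exactly at \code{stop_s} counts in the last
#' segment and the counts always sum to the number of bites.
#'
#' @param bite_times_s increasing bite times (seconds).
#' @param start_s,stop_s meal anchors; every bite must lie within.
#' @param n_segments number of segments (10 for the usual 10\% grid).
#' @return integer vector of \code{n_segments} counts.
#' @export
segment_bite_rates <- function(bite_times_s, start_s, stop_s,
                               n_segments = 10L) {
  if (stop_s <= start_s)
    stop("stop_s must exceed start_s", call. = FALSE)
  if (length(bite_times_s) &&
      (min(bite_times_s) < start_s || max(bite_times_s) > stop_s))
    stop("bite outside the meal bounds", call. = FALSE)
  D <- stop_s - start_s
  idx <- floor((bite_times_s - start_s) / D * n_segments) + 1L
  idx[idx > n_segments] <- n_segments   # bite exactly at stop_s
  tabulate(idx, n_segments)
}

#' Average several per-segment bite profiles element-wise
#' @param profiles list of equal-length numeric vectors (or a matrix with
#'   one profile per row).
#' @return numeric vector of per-segment means.
#' @export
average_segment_profile <- function(profiles) {
  if (is.matrix(profiles)) profiles <- asplit(profiles, 1L)
  stopifnot(length(profiles) >= 1L)
  len <- unique(vapply(profiles, length, integer(1L)))
  if (length(len) != 1L)
    stop("profiles must all have the same length", call. = FALSE)
  Reduce(`+`, lapply(profiles, as.numeric)) / length(profiles)
}

#' Quadratic fit of a meal-progress bite profile
#'
#' Ordinary least squares of \code{y = y0 + a x + b x^2} on the segment
#' index \code{x = 1..n}; the segment index (not the midpoint fraction) is
#' the fixed convention, since any affine re-parameterisation changes the
#' coefficients.  Exact on noiseless quadratic input.
#'
#' @param profile per-segment values (counts or averaged counts).
#' @param x predictor values (defaults to the 1-based segment index).
#' @return list of class \code{quadratic_fit}: \code{y0}, \code{a},
#'   \code{b}, \code{rss}, \code{fitted}.
#' @export
fit_quadratic <- function(profile, x = seq_along(profile)) {
  y <- as.numeric(profile)
  if (length(unique(x)) < 3L)
    stop("need at least 3 distinct x values for a quadratic fit",
         call. = FALSE)
  fit <- lm(y ~ x + I(x^2))
  cf <- unname(coef(fit))
  structure(list(y0 = cf[1L], a = cf[2L], b = cf[3L],
                 rss = sum(fit$residuals^2), fitted = unname(fit$fitted),
                 x = x),
            class = "quadratic_fit")
}

#' Evaluate a quadratic rate profile at segment indices
#' @param coefs numeric \code{c(y0, a, b)} or a \code{quadratic_fit}.
#' @param x segment indices.
#' @return expected values \code{y0 + a x + b x^2}.
#' @export
quadratic_profile <- function(coefs, x = 1:10) {
  if (inherits(coefs, "quadratic_fit"))
    coefs <- c(coefs$y0, coefs$a, coefs$b)
  coefs[1L] + coefs[2L] * x + coefs[3L] * x^2
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("<quadratic_fit> y0 = %.4f, a = %.4f, b = %.4f (rss %.4g)\n",
              x$y0, x$a, x$b, x$rss))
  invisible(x)
}

#' Plot a per-segment bite profile and its quadratic fit
#' @param x a \code{quadratic_fit}.
#' @param profile optional observed per-segment values to overlay.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.quadratic_fit <- function(x, profile = NULL, ...) {
  xs <- seq(min(x$x), max(x$x), length.out = 100L)
  graphics::plot(xs, quadratic_profile(x, xs), type = "l",
                 xlab = "meal segment (10% steps)",
                 ylab = "bites per segment", ...)
  if (!is.null(profile)) graphics::points(x$x, profile, pch = 19)
  invisible(x)
}
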