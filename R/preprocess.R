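# Keypoint cleaning, spline smoothing and normalisation into the two
# feature streams consumed by the bite classifier.

#' Cleaning and smoothing configuration
#'
#' @param confidence_floor points detected with confidence below this are
#'   treated as missing (default 0.1).
#' @param jump_fraction a single-frame displacement larger than this
#'   fraction of the frame diagonal marks the point as an outlier spike
#'   (default 0.15).
#' @param spline_smoothing smoothing parameter of the cubic smoothing
#'   spline (\code{lambda} of \code{\link[stats]{smooth.spline}}):
#'   \code{NULL} selects it per trajectory by generalised cross-validation;
#'   \code{0} means an interpolating spline, which evaluated at the frames
#'   reproduces the input exactly.
#' @param spline_degree spline degree; cubic (3) is the supported degree.
#' @return list of class \code{cleaning_config}.
#' @export
cleaning_config <- function(confidence_floor = 0.1, jump_fraction = 0.15,
                            spline_smoothing = NULL, spline_degree = 3L) {
  stopifnot(confidence_floor >= 0, confidence_floor <= 1,
            jump_fraction > 0)
  if (!is.null(spline_smoothing) && spline_smoothing < 0)
    stop("spline_smoothing must be non-negative or NULL", call. = FALSE)
  if (spline_degree != 3L)
    stop("only cubic smoothing splines (spline_degree = 3) are supported",
         call. = FALSE)
  structure(list(confidence_floor = confidence_floor,
                 jump_fraction = jump_fraction,
                 spline_smoothing = spline_smoothing,
                 spline_degree = 3L),
            class = "cleaning_config")
}

#' Clean a keypoint sequence
#'
#' Marks as missing every point detected with confidence below
#' \code{confidence_floor} and every point whose displacement from the last
#' valid position exceeds \code{jump_fraction} of the frame diagonal (a
#' one-frame pose-estimator spike), then imputes every missing value with
#' the previous frame's value for that point; leading missing values are
#' back-filled from the first valid frame.  Imputed frames inherit the
#' confidence of their source frame, so the output has no missing values
#' provided each point is detected at least once.  The operation is
#' idempotent.
#'
#' @param seq a \code{\link{keypoint_sequence}}.
#' @param cfg a \code{\link{cleaning_config}}.
#' @return A cleaned \code{keypoint_sequence} with zero missing values.
#' @export
clean_sequence <- function(seq, cfg = cleaning_config()) {
  stopifnot(inherits(seq, "keypoint_sequence"),
            inherits(cfg, "cleaning_config"))
  n <- n_frames(seq)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  thr <- cfg$jump_fraction * sqrt(sum(seq$frame_size^2))
  clean_arr <- function(a, names) {
    for (j in seq_len(dim(a)[2L])) {
      x <- a[, j, 1L]; y <- a[, j, 2L]; cf <- a[, j, 3L]
      miss <- is.na(x) | cf < cfg$confidence_floor
      # sequential spike scan against the last accepted position
      last <- NA_integer_
      for (t in seq_len(n)) {
        if (miss[t]) next
        if (!is.na(last) &&
            sqrt((x[t] - x[last])^2 + (y[t] - y[last])^2) > thr) {
          miss[t] <- TRUE
        } else last <- t
      }
      if (all(miss))
        stop("point '", names[j], "' is never detected; cannot clean",
             call. = FALSE)
      src <- fill_forward_index(!miss)
      a[, j, 1L] <- x[src]; a[, j, 2L] <- y[src]; a[, j, 3L] <- cf[src]
    }
    a
  }
  seq$body <- clean_arr(seq$body, body_joint_names())
  seq$mouth <- clean_arr(seq$mouth, mouth_point_names())
  seq
}

# for each position, the index of the most recent TRUE (first TRUE for
# leading FALSE runs)
fill_forward_index <- function(valid) {
  idx <- ifelse(valid, seq_along(valid), NA_integer_)
  idx <- cummax_na(idx)
  first <- which(valid)[1L]
  idx[is.na(idx)] <- first
  idx
}

cummax_na <- function(x) {
  out <- x
  last <- NA_integer_
  for (i in seq_along(x)) {
    if (!is.na(x[i])) last <- x[i]
    out[i] <- last
  }
  out
}

#' Smooth a cleaned keypoint sequence with cubic smoothing splines
#'
#' Each coordinate trajectory is replaced by a cubic smoothing spline fit
#' over frame index, evaluated at every frame.  With
#' \code{spline_smoothing = NULL} the penalty is chosen per trajectory by
#' generalised cross-validation; \code{0} requests the interpolation limit
#' and returns the input unchanged.  Confidences are not smoothed.
#'
#' @inheritParams clean_sequence
#' @return A smoothed \code{keypoint_sequence}.
#' @export
smooth_sequence <- function(seq, cfg = cleaning_config()) {
  stopifnot(inherits(seq, "keypoint_sequence"),
            inherits(cfg, "cleaning_config"))
  if (any(missing_points(seq)))
    stop("sequence has missing values; run clean_sequence() first",
         call. = FALSE)
  n <- n_frames(seq)
  if (n < cfg$spline_degree + 1L)
    stop("too few frames (", n, ") for a degree-", cfg$spline_degree,
         " spline", call. = FALSE)
  lam <- cfg$spline_smoothing
  if (!is.null(lam) && lam == 0) return(seq)
  tgrid <- seq_len(n) - 1
  smooth_arr <- function(a) {
    for (j in seq_len(dim(a)[2L])) for (k in 1:2) {
      yv <- a[, j, k]
      if (stats::var(yv) < .Machine$double.eps) next  # constant: leave as is
      fit <- if (is.null(lam))
        smooth.spline(tgrid, yv, cv = FALSE, all.knots = TRUE,
                      keep.data = FALSE)
      else
        smooth.spline(tgrid, yv, lambda = lam, all.knots = TRUE,
                      keep.data = FALSE)
      a[, j, k] <- predict(fit, tgrid)$y
    }
    a
  }
  seq$body <- smooth_arr(seq$body)
  seq$mouth <- smooth_arr(seq$mouth)
  seq
}

#' Select the visible mouth-corner side
#'
#' With the camera viewing the eater from one side, only one mouth corner
#' (A = left, C = right) is reliably detected.  The corner with the higher
#' mean detection confidence over the meal is selected; ties go to the
#' left.
#'
#' @param seq a \code{\link{keypoint_sequence}} (raw or cleaned).
#' @return \code{"left"} or \code{"right"}.
#' @export
select_mouth_side <- function(seq) {
  stopifnot(inherits(seq, "keypoint_sequence"))
  cA <- seq$mouth[, "A", 3L]
  cC <- seq$mouth[, "C", 3L]
  if (all(cA == 0) && all(cC == 0))
    stop("neither mouth corner is ever detected", call. = FALSE)
  if (mean(cA) >= mean(cC)) "left" else "right"
}

# fixed feature layouts --------------------------------------------------

body_feature_names <- function() {
  jn <- body_joint_names()
  coords <- as.vector(t(outer(jn, c("x", "y"), paste, sep = "_")))
  pairs <- utils::combn(jn, 2L)
  c(coords, paste0("d_", pairs[1L, ], "_", pairs[2L, ]))
}

mouth_feature_names <- function(side) {
  corner <- if (side == "left") "A" else "C"
  pn <- c("B", "D", corner)
  coords <- as.vector(t(outer(pn, c("x", "y"), paste, sep = "_")))
  pairs <- utils::combn(pn, 2L)
  c(coords, paste0("d_", pairs[1L, ], "_", pairs[2L, ]))
}

#' Assemble the two classifier feature streams
#'
#' The body stream holds the 2-D coordinates of the 8 joints re-origined on
#' the neck (16 values; the neck itself becomes (0,0)) plus all 28 pairwise
#' inter-joint Euclidean distances.  The mouth stream holds the coordinates
#' of the upper-lip mid (B), lower-lip mid (D) and the selected visible
#' corner, re-origined on the nose (6 values), plus their 3 pairwise
#' distances.  Re-origining makes both streams exactly invariant to global
#' translation of the subject in the frame; scale is deliberately left in
#' pixels.
#'
#' @param seq a cleaned (and normally smoothed) \code{keypoint_sequence}.
#' @param side visible mouth corner side, from
#'   \code{\link{select_mouth_side}}.
#' @return list of class \code{two_stream_features}: \code{body}
#'   (n_frames x 44), \code{mouth} (n_frames x 9), \code{fps},
#'   \code{n_frames}, \code{side}.
#' @export
assemble_features <- function(seq, side = select_mouth_side(seq)) {
  stopifnot(inherits(seq, "keypoint_sequence"),
            side %in% c("left", "right"))
  if (any(missing_points(seq)))
    stop("sequence has missing values; run clean_sequence() first",
         call. = FALSE)
  n <- n_frames(seq)

  bx <- seq$body[, , 1L, drop = TRUE]; by <- seq$body[, , 2L, drop = TRUE]
  bx <- matrix(bx, n, 8L); by <- matrix(by, n, 8L)
  rx <- bx - bx[, 2L]; ry <- by - by[, 2L]          # neck origin
  body_coords <- matrix(0, n, 16L)
  body_coords[, seq(1L, 15L, 2L)] <- rx
  body_coords[, seq(2L, 16L, 2L)] <- ry
  pairs <- utils::combn(8L, 2L)
  body_d <- sqrt((bx[, pairs[1L, ]] - bx[, pairs[2L, ]])^2 +
                 (by[, pairs[1L, ]] - by[, pairs[2L, ]])^2)
  body_d <- matrix(body_d, n, ncol(pairs))
  body_stream <- cbind(body_coords, body_d)
  colnames(body_stream) <- body_feature_names()

  corner <- if (side == "left") "A" else "C"
  sel <- c("B", "D", corner)
  mx <- matrix(seq$mouth[, sel, 1L], n, 3L)
  my <- matrix(seq$mouth[, sel, 2L], n, 3L)
  nx <- bx[, 1L]; ny <- by[, 1L]                     # nose origin
  mouth_coords <- matrix(0, n, 6L)
  mouth_coords[, c(1L, 3L, 5L)] <- mx - nx
  mouth_coords[, c(2L, 4L, 6L)] <- my - ny
  mp <- utils::combn(3L, 2L)
  mouth_d <- sqrt((mx[, mp[1L, ]] - mx[, mp[2L, ]])^2 +
                  (my[, mp[1L, ]] - my[, mp[2L, ]])^2)
  mouth_d <- matrix(mouth_d, n, 3L)
  mouth_stream <- cbind(mouth_coords, mouth_d)
  colnames(mouth_stream) <- mouth_feature_names(side)

  structure(list(body = body_stream, mouth = mouth_stream, fps = seq$fps,
                 n_frames = n, side = side),
            class = "two_stream_features")
}

#' Run the full preprocessing chain on a raw sequence
#'
#' Convenience wrapper: clean, smooth, select the visible mouth side and
#' assemble the two feature streams.
#'
#' @inheritParams clean_sequence
#' @return A \code{two_stream_features} object.
#' @export
preprocess_sequence <- function(seq, cfg = cleaning_config()) {
  side <- select_mouth_side(seq)
  assemble_features(smooth_sequence(clean_sequence(seq, cfg), cfg), side)
}

#' @export
print.two_stream_features <- function(x, ...) {
  cat(sprintf(
    "<two_stream_features> %d frames @ %g fps; body %d, mouth %d features; side %s\n",
    x$n_frames, x$fps, ncol(x$body), ncol(x$mouth), x$side))
  invisible(x)
}
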