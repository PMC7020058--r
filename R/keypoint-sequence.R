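#' @importFrom stats rnorm rpois runif sd median smooth.spline predict runmed
#'   lm coef cor quantile
#' @importFrom utils read.csv head tail
NULL

# Canonical point schema.  Body joints follow the usual upper-body pose
# numbering (0-7): nose, neck, right/left shoulder-elbow-wrist.  Mouth points
# are A (left corner), B (upper-lip mid), C (right corner), D (lower-lip mid);
# on 70-point face layouts these are indices 48, 51, 54 and 57.
body_joint_names <- function() {
  c("nose", "neck", "r_shoulder", "r_elbow", "r_wrist",
    "l_shoulder", "l_elbow", "l_wrist")
}

mouth_point_names <- function() c("A", "B", "C", "D")

#' Per-meal keypoint sequence
#'
#' Container for one meal's per-frame 2-D keypoints: 8 upper-body joints
#' (nose, neck, shoulders, elbows, wrists) and 4 mouth points (corners A/C,
#' upper-lip mid B, lower-lip mid D), each with a detection confidence in
#' \code{[0, 1]}.  Coordinates are pixels, origin at the top-left corner of
#' the frame, y increasing downward.  Frames are 0-based; frame \code{i}
#' occurs at time \code{i / fps} seconds.  A missing (non-detected) point is
#' encoded explicitly as \code{NA} coordinates with confidence 0.
#'
#' @param body numeric array \code{n_frames x 8 x 3} with slices
#'   \code{x, y, conf}.
#' @param mouth numeric array \code{n_frames x 4 x 3} (points A, B, C, D).
#' @param fps frames per second (must be positive).
#' @param frame_size integer vector \code{c(width, height)} in pixels.
#' @param meta free-text source identifier.
#' @return An object of class \code{keypoint_sequence}.
#' @export
keypoint_sequence <- function(body, mouth, fps, frame_size = c(720L, 576L),
                              meta = "") {
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  body <- as_point_array(body, body_joint_names(), "body")
  mouth <- as_point_array(mouth, mouth_point_names(), "mouth")
  if (dim(body)[1L] != dim(mouth)[1L])
    stop("body and mouth arrays disagree on the number of frames",
         call. = FALSE)
  if (length(frame_size) != 2L || any(frame_size <= 0))
    stop("`frame_size` must be c(width, height), both positive",
         call. = FALSE)
  structure(
    list(body = body, mouth = mouth, fps = fps,
         frame_size = as.numeric(frame_size), meta = as.character(meta)[1L]),
    class = "keypoint_sequence"
  )
}

as_point_array <- function(a, point_names, what) {
  a <- unname(a)
  if (!is.array(a) || length(dim(a)) != 3L ||
      dim(a)[2L] != length(point_names) || dim(a)[3L] != 3L)
    stop(sprintf("`%s` must be an n_frames x %d x 3 array", what,
                 length(point_names)), call. = FALSE)
  storage.mode(a) <- "double"
  # enforce the missingness encoding: NA coordinate <=> confidence 0
  miss <- is.na(a[, , 1L, drop = FALSE]) | is.na(a[, , 2L, drop = FALSE])
  if (any(miss)) {
    idx <- which(miss)
    a[, , 1L][idx] <- NA_real_
    a[, , 2L][idx] <- NA_real_
    a[, , 3L][idx] <- 0
  }
  a[, , 3L][is.na(a[, , 3L])] <- 0
  dimnames(a) <- list(NULL, point_names, c("x", "y", "conf"))
  a
}

#' Number of frames in a keypoint sequence
#' @param seq a \code{keypoint_sequence}.
#' @return integer frame count.
#' @export
n_frames <- function(seq) {
  stopifnot(inherits(seq, "keypoint_sequence"))
  dim(seq$body)[1L]
}

#' Frame timestamps of a keypoint sequence
#'
#' Frame \code{i} (0-based) occurs at \code{i / fps} seconds; the mapping is
#' exact rational arithmetic evaluated in double precision, so there is no
#' cumulative drift over long meals.
#'
#' @param seq a \code{keypoint_sequence}.
#' @return numeric vector of times in seconds, one per frame.
#' @export
frame_times <- function(seq) {
  (seq_len(n_frames(seq)) - 1) / seq$fps
}

# logical n_frames x 12 matrix of missing points (body then mouth)
missing_points <- function(seq) {
  cbind(is.na(seq$body[, , 1L]), is.na(seq$mouth[, , 1L]))
}

#' @export
print.keypoint_sequence <- function(x, ...) {
  miss <- mean(missing_points(x))
  cat(sprintf(
    "<keypoint_sequence> %d frames @ %g fps (%.1f s), frame %gx%g px\n",
    n_frames(x), x$fps, n_frames(x) / x$fps,
    x$frame_size[1L], x$frame_size[2L]))
  cat(sprintf("  missing points: %.2f%%   meta: %s\n", 100 * miss,
              if (nzchar(x$meta)) x$meta else "<none>"))
  invisible(x)
}

#' @method all.equal keypoint_sequence
#' @export
all.equal.keypoint_sequence <- function(target, current, ...) {
  all.equal(unclass(target), unclass(current), ...)
}
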