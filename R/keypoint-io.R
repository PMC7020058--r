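# Keypoint stream I/O in two fixed dialects.
#
# json_frames: one top-level object {fps, frame_size, meta, frames:[...]},
#   each frame {body: 8 x [x,y,c], mouth: 4 x [x,y,c]} -- a constrained
#   subset of OpenPose-style per-frame output.  Missing points are nulls.
# csv_flat: comment header (# fps/frame_size/meta) then rows
#   frame,point,x,y,confidence with 0-based frame indices and the canonical
#   point names (nose..l_wrist, A..D).  Missing points have empty x/y and
#   confidence 0.
#
# Numbers are rendered with 17 significant digits so that write -> read ->
# write reproduces identical bytes and read() recovers the exact doubles.

#' Write a keypoint sequence
#'
#' @param seq a \code{\link{keypoint_sequence}}.
#' @param path output file path.
#' @param dialect \code{"json_frames"} or \code{"csv_flat"} (see Details in
#'   \code{\link{read_keypoints}}).
#' @return \code{path}, invisibly.
#' @export
write_keypoints <- function(seq, path, dialect = c("json_frames", "csv_flat")) {
  stopifnot(inherits(seq, "keypoint_sequence"))
  dialect <- match.arg(dialect)
  if (dialect == "json_frames") write_keypoints_json(seq, path)
  else write_keypoints_csv(seq, path)
  invisible(path)
}

write_keypoints_json <- function(seq, path) {
  n <- n_frames(seq)
  frames <- vector("list", n)
  rows <- function(m) lapply(seq_len(nrow(m)), function(j) unname(m[j, ]))
  for (i in seq_len(n)) {
    frames[[i]] <- list(
      body = rows(matrix(seq$body[i, , ], 8L, 3L)),
      mouth = rows(matrix(seq$mouth[i, , ], 4L, 3L))
    )
  }
  obj <- list(fps = seq$fps, frame_size = seq$frame_size, meta = seq$meta,
              frames = frames)
  txt <- jsonlite::toJSON(obj, digits = NA, na = "null", auto_unbox = TRUE)
  writeLines(txt, path)
}

write_keypoints_csv <- function(seq, path) {
  n <- n_frames(seq)
  pts <- c(body_joint_names(), mouth_point_names())
  flat <- function(a) matrix(a, nrow = dim(a)[1L] * dim(a)[2L], ncol = 3L)
  m <- rbind(flat(seq$body), flat(seq$mouth))  # (n*12) rows: frame fastest
  frame <- rep(0:(n - 1L), times = 12L)
  point <- rep(pts, each = n)
  ord <- order(frame, match(point, pts))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  lines <- c(
    sprintf("# fps: %s", format_num(seq$fps)),
    sprintf("# frame_size: %s %s", format_num(seq$frame_size[1L]),
            format_num(seq$frame_size[2L])),
    sprintf("# meta: %s", seq$meta),
    "frame,point,x,y,confidence",
    sprintf("%d,%s,%s,%s,%s", frame[ord], point[ord], fmt(m[ord, 1L]),
            fmt(m[ord, 2L]), fmt(m[ord, 3L]))
  )
  writeLines(lines, path)
}

#' Read a keypoint sequence
#'
#' Reads the two supported dialects.  \code{json_frames} is a constrained
#' subset of OpenPose-style per-frame JSON: a single object with top-level
#' \code{fps}, \code{frame_size}, \code{meta} and a \code{frames} array in
#' frame order, each frame holding \code{body} (8 points) and \code{mouth}
#' (4 points: A, B, C, D) as \code{[x, y, confidence]} triplets with
#' \code{null} for missing coordinates.  \code{csv_flat} is a long table
#' \code{frame,point,x,y,confidence} preceded by \code{# fps}, \code{#
#' frame_size} and \code{# meta} comment lines.  Absent fps metadata is an
#' error (never guessed); frames out of order or with an inconsistent point
#' schema are errors; points outside the frame bounds are kept and reported
#' via the \code{out_of_bounds} attribute.
#'
#' @inheritParams write_keypoints
#' @return A \code{\link{keypoint_sequence}}.
#' @export
read_keypoints <- function(path, dialect = c("json_frames", "csv_flat")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dialect <- match.arg(dialect)
  seq <- if (dialect == "json_frames") read_keypoints_json(path)
         else read_keypoints_csv(path)
  flag_out_of_bounds(seq)
}

read_keypoints_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$fps)) stop("keypoint JSON lacks fps metadata",
                             call. = FALSE)
  n <- length(obj$frames)
  body <- array(NA_real_, c(n, 8L, 3L))
  mouth <- array(NA_real_, c(n, 4L, 3L))
  unpack <- function(pt, what, i) {
    if (length(pt) != 3L)
      stop(sprintf("frame %d: malformed %s point (need [x,y,conf])", i - 1L,
                   what), call. = FALSE)
    vapply(pt, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
           numeric(1L))
  }
  for (i in seq_len(n)) {
    fr <- obj$frames[[i]]
    if (length(fr$body) != 8L || length(fr$mouth) != 4L)
      stop(sprintf("frame %d: inconsistent point counts (schema error)",
                   i - 1L), call. = FALSE)
    for (j in 1:8) body[i, j, ] <- unpack(fr$body[[j]], "body", i)
    for (j in 1:4) mouth[i, j, ] <- unpack(fr$mouth[[j]], "mouth", i)
  }
  keypoint_sequence(body, mouth, fps = as.numeric(obj$fps),
                    frame_size = as.numeric(unlist(obj$frame_size)),
                    meta = if (is.null(obj$meta)) "" else obj$meta)
}

read_keypoints_csv <- function(path) {
  hdr <- read_comment_header(path)
  if (is.null(hdr$fps)) stop("keypoint CSV lacks '# fps:' metadata",
                             call. = FALSE)
  fsz <- if (!is.null(hdr$frame_size))
    as.numeric(strsplit(hdr$frame_size, "\\s+")[[1L]]) else c(720, 576)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 colClasses = c("integer", "character", "numeric", "numeric",
                                "numeric"))
  if (is.unsorted(df$frame))
    stop("frame indices out of order in keypoint CSV", call. = FALSE)
  pts <- c(body_joint_names(), mouth_point_names())
  frames <- unique(df$frame)
  n <- length(frames)
  if (!identical(frames, 0:(n - 1L)))
    stop("frame indices must be 0-based and contiguous", call. = FALSE)
  if (nrow(df) != n * 12L || !all(df$point %in% pts))
    stop("inconsistent point schema in keypoint CSV", call. = FALSE)
  per_frame <- tabulate(df$frame + 1L, n)
  if (any(per_frame != 12L))
    stop("inconsistent point counts per frame (schema error)",
         call. = FALSE)
  body <- array(NA_real_, c(n, 8L, 3L))
  mouth <- array(NA_real_, c(n, 4L, 3L))
  j <- match(df$point, pts)
  isb <- j <= 8L
  ridx <- cbind(df$frame + 1L, ifelse(isb, j, j - 8L))
  for (k in 1:3) {
    v <- df[[k + 2L]]
    body[cbind(ridx[isb, , drop = FALSE], k)] <- v[isb]
    mouth[cbind(ridx[!isb, , drop = FALSE], k)] <- v[!isb]
  }
  keypoint_sequence(body, mouth, fps = as.numeric(hdr$fps),
                    frame_size = fsz,
                    meta = if (is.null(hdr$meta)) "" else hdr$meta)
}

flag_out_of_bounds <- function(seq) {
  w <- seq$frame_size[1L]; h <- seq$frame_size[2L]
  oob <- function(a) which(
    !is.na(a[, , 1L]) &
      (a[, , 1L] < 0 | a[, , 1L] > w | a[, , 2L] < 0 | a[, , 2L] > h),
    arr.ind = TRUE)
  ob <- oob(seq$body); om <- oob(seq$mouth)
  flagged <- rbind(
    if (nrow(ob)) data.frame(frame = ob[, 1L] - 1L,
                             point = body_joint_names()[ob[, 2L]]),
    if (nrow(om)) data.frame(frame = om[, 1L] - 1L,
                             point = mouth_point_names()[om[, 2L]])
  )
  attr(seq, "out_of_bounds") <- flagged
  seq
}

#' Write a behavioural meal log with its summary sidecar
#'
#' Emits the event CSV at \code{path} and a JSON sidecar
#' (\code{<path-sans-ext>_summary.json}) holding duration, total bites,
#' per-segment counts and, when available, the quadratic meal-progress fit
#' coefficients.  Re-reading with \code{\link{read_behavior_log}} reproduces
#' the inputs; write-read-write is byte identical.
#'
#' @param summary a \code{\link{meal_summary}}, or \code{NULL} for an empty
#'   event list (a zero-bite summary with flagged undefined duration is
#'   written).
#' @param events an \code{\link{annotation_log}} consistent with
#'   \code{summary}.
#' @param path output CSV path.
#' @param fit optional \code{\link{fit_quadratic}} result to record.
#' @return \code{path}, invisibly.
#' @export
write_behavior_log <- function(summary, events, path, fit = NULL) {
  stopifnot(inherits(events, "annotation_log"))
  if (is.null(summary)) {
    if (any(events$event == "bite"))
      stop("summary is NULL but events contain bites", call. = FALSE)
    side <- list(total_bites = 0L, duration_min = NULL,
                 duration_undefined = TRUE)
  } else {
    stopifnot(inherits(summary, "meal_summary"))
    if (summary$total_bites != sum(events$event == "bite"))
      stop("summary inconsistent with events (bite counts differ)",
           call. = FALSE)
    side <- list(total_bites = summary$total_bites,
                 duration_min = summary$duration_min,
                 start_s = summary$start_s, stop_s = summary$stop_s,
                 segment_counts = summary$segment_counts,
                 source = summary$source)
  }
  if (!is.null(fit))
    side$fit <- list(y0 = fit$y0, a = fit$a, b = fit$b, rss = fit$rss)
  write_annotations(events, path)
  jsonlite::write_json(side, summary_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

summary_sidecar_path <- function(path) {
  paste0(sub("\\.[A-Za-z0-9]+$", "", path), "_summary.json")
}

#' Read a behavioural meal log written by \code{write_behavior_log}
#' @param path the event CSV path.
#' @return list with \code{events} (an \code{annotation_log}) and
#'   \code{summary} (a named list as written).
#' @export
read_behavior_log <- function(path) {
  list(events = read_annotations(path),
       summary = jsonlite::fromJSON(summary_sidecar_path(path)))
}
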