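# Behavioural annotation logs: timestamped meal events.

EVENT_KINDS <- c("meal_start", "meal_stop", "spoonful", "food_addition",
                 "bite")

#' Timestamped behavioural annotation log
#'
#' Ordered record of in-meal events.  Five event kinds are recognised:
#' \code{meal_start} (time of the initial spoonful), \code{meal_stop} (time
#' of the last bite), \code{spoonful} (food leaves the personal plate),
#' \code{food_addition} (food transferred from the serving tray to the
#' plate) and \code{bite} (food enters the mouth).  A log is either
#' \code{manual} (human annotation / simulation ground truth) or
#' \code{detected} (algorithm output, bites only).
#'
#' @param time_s event times in seconds (non-negative).
#' @param event character vector of event kinds (see above).
#' @param source \code{"manual"} or \code{"detected"}.
#' @param fps optional frames-per-second of the parent recording, carried
#'   along so downstream comparisons can refuse mismatched logs.
#' @return A data frame of class \code{annotation_log} with columns
#'   \code{time_s} and \code{event}, sorted by time.
#' @export
annotation_log <- function(time_s, event, source = c("manual", "detected"),
                           fps = NULL) {
  source <- match.arg(source)
  time_s <- as.numeric(time_s)
  event <- as.character(event)
  if (length(time_s) != length(event))
    stop("`time_s` and `event` must have the same length", call. = FALSE)
  bad <- setdiff(unique(event), EVENT_KINDS)
  if (length(bad))
    stop("unknown event kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(is.na(time_s)) || any(time_s < 0))
    stop("event times must be non-negative numbers", call. = FALSE)
  if (sum(event == "meal_start") > 1L || sum(event == "meal_stop") > 1L)
    stop("at most one meal_start and one meal_stop allowed", call. = FALSE)
  # stable sort; ties broken so that meal_start precedes and meal_stop
  # follows the events they bracket
  prio <- match(event, c("meal_start", "spoonful", "food_addition", "bite",
                         "meal_stop"))
  ord <- order(time_s, prio)
  out <- data.frame(time_s = time_s[ord], event = event[ord],
                    stringsAsFactors = FALSE)
  bt <- out$time_s[out$event == "bite"]
  ms <- out$time_s[out$event == "meal_start"]
  me <- out$time_s[out$event == "meal_stop"]
  if (length(bt)) {
    if (length(ms) && ms > min(bt))
      stop("meal_start must not come after the first bite", call. = FALSE)
    if (length(me) && me < max(bt))
      stop("meal_stop must not come before the last bite", call. = FALSE)
  }
  structure(out, source = source, fps = fps,
            class = c("annotation_log", "data.frame"))
}

#' Bite times of an annotation log
#' @param log an \code{annotation_log}.
#' @return numeric vector of bite times in seconds, increasing.
#' @export
bite_times <- function(log) {
  stopifnot(inherits(log, "annotation_log"))
  log$time_s[log$event == "bite"]
}

log_source <- function(log) attr(log, "source", exact = TRUE)

#' @export
print.annotation_log <- function(x, ...) {
  cat(sprintf("<annotation_log> %d events (%s), %d bites\n", nrow(x),
              log_source(x), sum(x$event == "bite")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read an annotation log from CSV
#'
#' Expects columns \code{time_s,event}, optionally preceded by comment lines
#' (\code{# source: manual} and \code{# fps: 25}).  Rows out of time order
#' are sorted with a warning; unknown event kinds and negative times are
#' errors.
#'
#' @param path CSV file path.
#' @param source source label used when the file carries none.
#' @return An \code{annotation_log}.
#' @export
read_annotations <- function(path, source = "manual") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- read_comment_header(path)
  if (!is.null(hdr$source)) source <- hdr$source
  fps <- if (!is.null(hdr$fps)) as.numeric(hdr$fps) else NULL
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("time_s", "event") %in% names(df)))
    stop("annotation CSV needs columns time_s,event", call. = FALSE)
  if (is.unsorted(df$time_s))
    warning("annotation rows out of time order; sorting", call. = FALSE)
  annotation_log(df$time_s, df$event, source = source, fps = fps)
}

#' Write an annotation log to CSV
#'
#' Times are rendered with six decimals, which makes
#' write-read-write round trips byte identical.
#'
#' @param log an \code{annotation_log}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_annotations <- function(log, path) {
  stopifnot(inherits(log, "annotation_log"))
  lines <- c(sprintf("# source: %s", log_source(log)),
             if (!is.null(attr(log, "fps")))
               sprintf("# fps: %s", format_num(attr(log, "fps"))),
             "time_s,event",
             sprintf("%.6f,%s", log$time_s, log$event))
  writeLines(lines, path)
  invisible(path)
}

read_comment_header <- function(path) {
  out <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    m <- regmatches(ln, regexec("^#\\s*([a-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) out[[m[2L]]] <- trimws(m[3L])
  }
  out
}

# shortest decimal rendering that round-trips the double exactly
format_num <- function(x) sprintf("%.17g", x)
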