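# Agreement statistics between two annotation sources: clip-level
# confusion metrics, event-level matching, per-meal correlations.

#' Clip-level confusion matrix (bite = positive class)
#'
#' Rows are the manual annotation, columns the automatic one: \code{tp}
#' clips labelled bite by both, \code{fn} bite clips missed, \code{fp}
#' non-bite clips called bite, \code{tn} agreed non-bite.
#'
#' @param tp,fn,fp,tn non-negative counts.
#' @return list of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  if (tp + fn + fp + tn <= 0)
    stop("confusion matrix must contain at least one clip", call. = FALSE)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_matrix")
}

#' Confusion matrix from two parallel label vectors
#' @param manual,detected logical or factor vectors (\code{TRUE}/"bite" =
#'   positive), same length.
#' @return A \code{confusion_matrix}.
#' @export
confusion_from_labels <- function(manual, detected) {
  as_pos <- function(v) if (is.logical(v)) v else v == "bite"
  m <- as_pos(manual); d <- as_pos(detected)
  stopifnot(length(m) == length(d))
  confusion_matrix(tp = sum(m & d), fn = sum(m & !d),
                   fp = sum(!m & d), tn = sum(!m & !d))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows manual, cols automatic)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, byrow = TRUE,
              dimnames = list(c("manual bite", "manual not_bite"),
                              c("auto bite", "auto not_bite")))
  print(m)
  invisible(x)
}

#' Agreement metrics from a confusion matrix
#'
#' Computes Cohen's kappa
#' \deqn{\kappa = (p_o - p_e) / (1 - p_e)}
#' with observed agreement \eqn{p_o = (tp+tn)/N} and chance agreement
#' \eqn{p_e = [(tp+fn)(tp+fp) + (fp+tn)(fn+tn)]/N^2}, plus recall
#' (\code{tp/(tp+fn)}), specificity (\code{tn/(tn+fp)}), precision, and
#' two F1 variants: \code{f1_bite}, the standard harmonic mean of
#' precision and recall for the bite class, and \code{f1_rs}, the harmonic
#' mean of recall and specificity.  Both variants are reported and
#' labelled because published summaries sometimes quote the latter.
#' Kappa interpretation bands: values above 0.80 indicate very high (near
#' perfect) agreement, 0.60-0.80 satisfactory agreement.
#'
#' @param m a \code{\link{confusion_matrix}}.
#' @return list of class \code{agreement_metrics} with fields
#'   \code{kappa}, \code{po}, \code{pe}, \code{recall},
#'   \code{specificity}, \code{precision}, \code{f1_bite}, \code{f1_rs},
#'   \code{n}.
#' @export
confusion_metrics <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  N <- m$tp + m$fn + m$fp + m$tn
  po <- (m$tp + m$tn) / N
  pe <- ((m$tp + m$fn) * (m$tp + m$fp) + (m$fp + m$tn) * (m$fn + m$tn)) /
    N^2
  if (abs(1 - pe) < .Machine$double.eps * 4)
    stop("degenerate marginals: pe = 1, kappa undefined", call. = FALSE)
  kappa <- (po - pe) / (1 - pe)
  recall <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else NA_real_
  specificity <- if (m$tn + m$fp > 0) m$tn / (m$tn + m$fp) else NA_real_
  precision <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else NA_real_
  hm <- function(a, b) if (is.na(a) || is.na(b) || a + b == 0) NA_real_
                       else 2 * a * b / (a + b)
  structure(list(kappa = kappa, po = po, pe = pe, recall = recall,
                 specificity = specificity, precision = precision,
                 f1_bite = hm(precision, recall),
                 f1_rs = hm(recall, specificity), n = N),
            class = "agreement_metrics")
}

kappa_band <- function(kappa) {
  if (kappa > 0.80) "very high (near perfect) agreement"
  else if (kappa >= 0.60) "satisfactory agreement"
  else if (kappa > 0) "weak agreement"
  else "no agreement"
}

#' @export
print.agreement_metrics <- function(x, ...) {
  cat(sprintf("<agreement_metrics> n = %d\n", x$n))
  cat(sprintf("  kappa       %.3f  (%s)\n", x$kappa, kappa_band(x$kappa)))
  cat(sprintf("  recall      %.3f\n  specificity %.3f\n  precision   %.3f\n",
              x$recall, x$specificity, x$precision))
  cat(sprintf("  F1 (bite)   %.3f\n  F1 (rec/spec harmonic mean) %.3f\n",
              x$f1_bite, x$f1_rs))
  invisible(x)
}

#' Match detected bite events to reference bite events
#'
#' Maximum-cardinality one-to-one matching of detected to reference bites
#' under a time tolerance, solved greedily in time order (optimal for
#' points on a line).  With zero detections and zero references precision
#' and recall are 1; with zero detections and some references recall is 0
#' and precision undefined (\code{NA}, flagged).
#'
#' @param detected,reference \code{\link{annotation_log}}s containing only
#'   bite events.
#' @param tolerance_s maximum |time difference| for a match, seconds.
#' @return list of class \code{event_match}: \code{tp}, \code{fp},
#'   \code{fn}, \code{precision}, \code{recall}, \code{f1}.
#' @export
match_events <- function(detected, reference, tolerance_s = 1.0) {
  for (lg in list(detected, reference)) {
    stopifnot(inherits(lg, "annotation_log"))
    if (any(lg$event != "bite"))
      stop("match_events expects bite-only logs", call. = FALSE)
  }
  fd <- attr(detected, "fps"); fr <- attr(reference, "fps")
  if (!is.null(fd) && !is.null(fr) && fd != fr)
    stop("refusing to match logs recorded at different fps", call. = FALSE)
  d <- sort(detected$time_s)
  r <- sort(reference$time_s)
  tp <- 0L
  i <- 1L; j <- 1L
  while (i <= length(d) && j <= length(r)) {
    if (abs(d[i] - r[j]) <= tolerance_s) {
      tp <- tp + 1L; i <- i + 1L; j <- j + 1L
    } else if (d[i] < r[j] - tolerance_s) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  fp <- length(d) - tp
  fn <- length(r) - tp
  precision <- if (length(d)) tp / length(d)
               else if (!length(r)) 1 else NA_real_
  recall <- if (length(r)) tp / length(r)
            else if (!length(d)) 1 else NA_real_
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1,
                 precision_undefined = is.na(precision)),
            class = "event_match")
}

#' @export
print.event_match <- function(x, ...) {
  cat(sprintf(
    "<event_match> tp %d, fp %d, fn %d; precision %.3f, recall %.3f, F1 %.3f\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Pearson correlation between paired per-meal measures
#'
#' Standard product-moment correlation with qualitative bands at
#' R^2 >= 0.50 ("medium"), 0.75 ("high") and 0.90 ("very high").
#'
#' @param manual,detected paired numeric vectors (e.g., total bites per
#'   meal under each annotation source); alternatively \code{manual} may
#'   be a two-column matrix/data frame of pairs.
#' @return list of class \code{measure_correlation}: \code{r},
#'   \code{r_squared}, \code{band}, \code{n}.
#' @export
correlate_measures <- function(manual, detected = NULL) {
  if (is.null(detected)) {
    manual <- as.matrix(manual)
    stopifnot(ncol(manual) == 2L)
    detected <- manual[, 2L]
    manual <- manual[, 1L]
  }
  stopifnot(length(manual) == length(detected))
  if (length(manual) < 3L)
    stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(manual) == 0 || stats::var(detected) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  r <- cor(manual, detected)
  r2 <- r^2
  band <- if (r2 >= 0.90) "very high"
          else if (r2 >= 0.75) "high"
          else if (r2 >= 0.50) "medium"
          else "low"
  structure(list(r = r, r_squared = r2, band = band, n = length(manual)),
            class = "measure_correlation")
}

#' @export
print.measure_correlation <- function(x, ...) {
  cat(sprintf("<measure_correlation> r = %.3f (R^2 = %.3f, %s), n = %d\n",
              x$r, x$r_squared, x$band, x$n))
  invisible(x)
}
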