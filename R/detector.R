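# Two-stream conv+LSTM bite detector: training-clip construction,
# training, sliding-window inference and probability-signal peak
# extraction.

#' Model configuration for the two-stream bite classifier
#'
#' The architecture is fixed in shape -- per stream, two blocks of two
#' 1-D convolutional layers with max pooling after each block, a stack of
#' LSTM layers whose final hidden state summarises the window, then
#' concatenation of the two streams and a fully connected fusion layer
#' feeding a single sigmoid output -- with configurable widths.
#'
#' @param conv_filters filters of the two convolutional blocks (two conv
#'   layers per block share a width), length 2.
#' @param conv_kernel odd kernel size of every convolution.
#' @param pool_size pooling size over time (2 is the supported size).
#' @param lstm_units units of the stacked LSTM layers (>= 1 layer).
#' @param fusion_units width of the fully connected fusion layer.
#' @param dropout dropout rate on the fusion layer during training.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param class_weighting if \code{TRUE}, positives are up-weighted by the
#'   negative:positive ratio of the training set (the study-scale corpus is
#'   roughly 2:1 non-bite:bite).
#' @param seed integer seed for initialisation and shuffling.
#' @return list of class \code{model_config}.
#' @export
model_config <- function(conv_filters = c(16L, 32L), conv_kernel = 3L,
                         pool_size = 2L, lstm_units = c(32L, 16L),
                         fusion_units = 32L, dropout = 0.1,
                         learning_rate = 1e-3, batch_size = 64L,
                         epochs = 15L, class_weighting = TRUE, seed = 1L) {
  stopifnot(length(conv_filters) == 2L, all(conv_filters >= 1L),
            conv_kernel %% 2L == 1L, conv_kernel >= 1L,
            length(lstm_units) >= 1L, all(lstm_units >= 1L),
            fusion_units >= 1L, dropout >= 0, dropout < 1,
            learning_rate > 0, batch_size >= 1L, epochs >= 1L)
  if (pool_size != 2L)
    stop("only pool_size = 2 is supported", call. = FALSE)
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel), pool_size = 2L,
                 lstm_units = as.integer(lstm_units),
                 fusion_units = as.integer(fusion_units), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 class_weighting = isTRUE(class_weighting),
                 seed = as.integer(seed)),
            class = "model_config")
}

# gather windows centred on `centers` (0-based frames) from a feature
# matrix -> array [n_windows, window, n_features]
gather_windows <- function(mat, centers, w) {
  half <- w %/% 2L
  offs <- (-half):(half - 1L)
  idx <- outer(centers, offs, `+`) + 1L
  array(mat[as.vector(idx), , drop = FALSE],
        c(length(centers), w, ncol(mat)))
}

#' Extract labelled training clips from one meal
#'
#' Cuts fixed-length windows (2 s by default) from the two feature
#' streams: one positive clip centred on each annotated bite, and negative
#' clips tiled every \code{negative_stride_s} over the regions whose centre
#' lies at least \code{window_s} seconds from every bite.  Windows that
#' would cross the meal boundary are dropped (positives with a warning).
#'
#' @param features a \code{\link{two_stream_features}} object.
#' @param log an \code{\link{annotation_log}} with at least one bite.
#' @param window_s clip duration in seconds.
#' @param negative_stride_s spacing of the negative-clip tiling, seconds.
#' @return list of class \code{clip_set}: \code{body}
#'   \code{[n, window, 44]}, \code{mouth} \code{[n, window, 9]},
#'   \code{labels} factor (\code{bite}/\code{not_bite}), \code{provenance}
#'   data frame (meal, center_frame), \code{window}, \code{fps}.
#' @export
extract_labeled_clips <- function(features, log, window_s = 2.0,
                                  negative_stride_s = 1.0) {
  stopifnot(inherits(features, "two_stream_features"),
            inherits(log, "annotation_log"))
  bt <- bite_times(log)
  if (!length(bt)) stop("annotation log contains no bites", call. = FALSE)
  fps <- features$fps
  n <- features$n_frames
  w <- round(window_s * fps)
  if (w > n) stop("clip window longer than the meal", call. = FALSE)
  half <- w %/% 2L
  cmin <- half; cmax <- n - 1L - (w - half - 1L)   # valid centre range

  pos <- round(bt * fps)
  keep <- pos >= cmin & pos <= cmax
  if (any(!keep))
    warning(sum(!keep), " bite clip(s) dropped at the meal boundary",
            call. = FALSE)
  pos <- pos[keep]

  stride <- max(1L, round(negative_stride_s * fps))
  cand <- seq.int(cmin, cmax, by = stride)
  if (length(bt)) {
    mind <- vapply(cand / fps, function(tc) min(abs(tc - bt)), numeric(1L))
    cand <- cand[mind >= window_s]
  }
  centers <- c(pos, cand)
  labels <- factor(rep(c("bite", "not_bite"), c(length(pos), length(cand))),
                   levels = c("bite", "not_bite"))
  structure(list(body = gather_windows(features$body, centers, w),
                 mouth = gather_windows(features$mouth, centers, w),
                 labels = labels,
                 provenance = data.frame(meal = "meal",
                                         center_frame = centers),
                 window = w, fps = fps),
            class = "clip_set")
}

#' Combine clip sets from several meals
#' @param ... \code{clip_set} objects (or one list of them).
#' @param meal_ids optional ids recorded in the provenance.
#' @return A single \code{clip_set}.
#' @export
combine_clips <- function(..., meal_ids = NULL) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "clip_set"))
    sets <- sets[[1L]]
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1L), "clip_set")))
  w <- sets[[1L]]$window
  fps <- sets[[1L]]$fps
  if (!all(vapply(sets, function(s) s$window == w && s$fps == fps,
                  logical(1L))))
    stop("clip sets disagree on window length or fps", call. = FALSE)
  if (is.null(meal_ids)) meal_ids <- seq_along(sets)
  bind3 <- function(field) {
    mats <- lapply(sets, function(s) {
      a <- s[[field]]
      matrix(aperm(a, c(2L, 3L, 1L)), ncol = dim(a)[1L])
    })
    flat <- do.call(cbind, mats)
    ntot <- ncol(flat)
    aperm(array(flat, c(w, dim(sets[[1L]][[field]])[3L], ntot)),
          c(3L, 1L, 2L))
  }
  prov <- do.call(rbind, Map(function(s, id) {
    p <- s$provenance; p$meal <- id; p
  }, sets, meal_ids))
  structure(list(body = bind3("body"), mouth = bind3("mouth"),
                 labels = factor(unlist(lapply(sets,
                                               function(s) as.character(s$labels))),
                                 levels = c("bite", "not_bite")),
                 provenance = prov, window = w, fps = fps),
            class = "clip_set")
}

n_clips <- function(cs) length(cs$labels)

subset_clips <- function(cs, idx) {
  structure(list(body = cs$body[idx, , , drop = FALSE],
                 mouth = cs$mouth[idx, , , drop = FALSE],
                 labels = cs$labels[idx],
                 provenance = cs$provenance[idx, , drop = FALSE],
                 window = cs$window, fps = cs$fps),
            class = "clip_set")
}

#' @export
print.clip_set <- function(x, ...) {
  cat(sprintf("<clip_set> %d clips of %d frames (%d bite / %d not_bite)\n",
              n_clips(x), x$window, sum(x$labels == "bite"),
              sum(x$labels == "not_bite")))
  invisible(x)
}

#' Stratified train/evaluation split of a clip set
#'
#' The evaluation set size is \code{floor((1 - train_fraction) * N)}
#' overall, allocated across the two labels proportionally (largest
#' remainder), so a 90/10 split of 12,121 clips yields 1212 evaluation
#' clips.  Deterministic given \code{seed}.
#'
#' @param clips a \code{clip_set} (or a factor of labels, for which index
#'   vectors are returned).
#' @param train_fraction fraction of clips used for training.
#' @param seed integer seed.
#' @return list with \code{train} and \code{eval} \code{clip_set}s (or
#'   index vectors when \code{clips} is a factor).
#' @export
split_clips <- function(clips, train_fraction = 0.9, seed = 1L) {
  labels <- if (inherits(clips, "clip_set")) clips$labels
            else as.factor(clips)
  N <- length(labels)
  if (N < 2L) stop("need at least 2 clips to split", call. = FALSE)
  # guard against binary-fraction fuzz, e.g. (1 - 0.9) * 10 < 1
  n_eval <- floor((1 - train_fraction) * N + 1e-9)
  tab <- table(labels)
  exact <- (1 - train_fraction) * as.numeric(tab)
  base <- pmin(floor(exact + 1e-9), as.numeric(tab))
  rem <- n_eval - sum(base)
  if (rem > 0) {
    ord <- order(exact - floor(exact), decreasing = TRUE)
    add <- ord[seq_len(rem)]
    base[add] <- pmin(base[add] + 1, as.numeric(tab)[add])
  }
  set.seed(seed)
  eval_idx <- integer(0)
  for (k in seq_along(tab)) {
    pool <- which(labels == names(tab)[k])
    eval_idx <- c(eval_idx, sample(pool, base[k]))
  }
  eval_idx <- sort(eval_idx)
  train_idx <- setdiff(seq_len(N), eval_idx)
  if (inherits(clips, "clip_set"))
    list(train = subset_clips(clips, train_idx),
         eval = subset_clips(clips, eval_idx))
  else
    list(train = train_idx, eval = eval_idx)
}

#' Train the two-stream conv+LSTM bite classifier
#'
#' Each stream (body, mouth) passes through two blocks of two 1-D
#' convolutions with max pooling after each block, then a stacked LSTM
#' whose final hidden state summarises the 2-s window; the two summaries
#' are concatenated and fused by a fully connected layer into a single
#' bite probability.  Training minimises binary cross-entropy (positives
#' optionally up-weighted by the class imbalance) with Adam.  Given a
#' seed, training is deterministic on a fixed BLAS.
#'
#' @param train a \code{clip_set} containing both labels.
#' @param cfg a \code{\link{model_config}}.
#' @param verbose print per-epoch loss/accuracy.
#' @return list of class \code{bite_model}: \code{params}, \code{config},
#'   \code{history} (per-epoch loss and training accuracy), input dims.
#' @export
train_model <- function(train, cfg = model_config(), verbose = FALSE) {
  stopifnot(inherits(train, "clip_set"), inherits(cfg, "model_config"))
  y <- as.numeric(train$labels == "bite")
  if (length(unique(y)) < 2L)
    stop("training set must contain both labels", call. = FALSE)
  N <- length(y)
  pos_w <- if (cfg$class_weighting) sum(y == 0) / sum(y == 1) else 1
  wts <- ifelse(y == 1, pos_w, 1)

  set.seed(cfg$seed)
  par <- model_init(cfg, dim(train$body)[3L], dim(train$mouth)[3L])
  st <- adam_state(par)
  step <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(N)
    tot_loss <- 0
    correct <- 0L
    for (b0 in seq.int(1L, N, by = cfg$batch_size)) {
      bi <- perm[b0:min(b0 + cfg$batch_size - 1L, N)]
      Xb <- train$body[bi, , , drop = FALSE]
      Xm <- train$mouth[bi, , , drop = FALSE]
      fw <- model_forward(par, Xb, Xm, dropout = cfg$dropout, train = TRUE)
      ls <- bce_loss(fw$p, fw$logit, y[bi], wts[bi])
      gr <- model_backward(ls$dlogit, fw$cache, par)
      step <- step + 1L
      upd <- adam_step(par, gr, st, cfg$learning_rate, step)
      par <- upd$p
      st <- upd$s
      tot_loss <- tot_loss + ls$loss * length(bi)
      correct <- correct + sum((fw$p > 0.5) == (y[bi] == 1))
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = tot_loss / N,
                                   accuracy = correct / N))
    if (verbose)
      message(sprintf("epoch %d  loss %.4f  acc %.4f", ep, tot_loss / N,
                      correct / N))
  }
  structure(list(params = par, config = cfg, history = hist,
                 window = train$window, fps = train$fps,
                 c_body = dim(train$body)[3L],
                 c_mouth = dim(train$mouth)[3L]),
            class = "bite_model")
}

#' @export
print.bite_model <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<bite_model> window %d frames; conv %s, lstm %s, fusion %d\n",
    x$window, paste(x$config$conv_filters, collapse = "/"),
    paste(x$config$lstm_units, collapse = "/"), x$config$fusion_units))
  cat(sprintf("  trained %d epochs; final loss %.4f, accuracy %.4f\n",
              nrow(x$history), h$loss, h$accuracy))
  invisible(x)
}

#' Predict bite probabilities for a clip set (or raw window arrays)
#'
#' @param model a trained \code{bite_model}.
#' @param clips a \code{clip_set}, or a list with \code{body}/\code{mouth}
#'   window arrays.
#' @param batch_size evaluation batch size.
#' @return numeric vector of bite probabilities in \code{[0, 1]}.
#' @export
predict_bite_prob <- function(model, clips, batch_size = 256L) {
  stopifnot(inherits(model, "bite_model"))
  Xb <- clips$body
  Xm <- clips$mouth
  N <- dim(Xb)[1L]
  out <- numeric(N)
  for (b0 in seq.int(1L, N, by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1L, N)
    fw <- model_forward(model$params, Xb[bi, , , drop = FALSE],
                        Xm[bi, , , drop = FALSE])
    out[bi] <- fw$p
  }
  out
}

#' Per-frame bite probability signal by sliding-window inference
#'
#' Slides the model's window over the meal with a step of one frame and
#' assigns each window's probability to its centre frame; frames near the
#' edges, whose window would cross the meal boundary, replicate the
#' nearest computed value.  The output length equals the number of frames.
#'
#' @param model a trained \code{bite_model}.
#' @param features a \code{\link{two_stream_features}} for one meal.
#' @param batch_size windows evaluated per BLAS batch.
#' @return list of class \code{probability_signal}: \code{values} (one
#'   probability per frame), \code{fps}, \code{meal}.
#' @export
probability_signal <- function(model, features, batch_size = 256L) {
  stopifnot(inherits(model, "bite_model"),
            inherits(features, "two_stream_features"))
  n <- features$n_frames
  w <- model$window
  if (n < w) stop("meal shorter than the model window", call. = FALSE)
  half <- w %/% 2L
  cmin <- half; cmax <- n - 1L - (w - half - 1L)
  centers <- cmin:cmax
  vals <- numeric(length(centers))
  for (b0 in seq.int(1L, length(centers), by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1L, length(centers))
    Xb <- gather_windows(features$body, centers[bi], w)
    Xm <- gather_windows(features$mouth, centers[bi], w)
    vals[bi] <- model_forward(model$params, Xb, Xm)$p
  }
  values <- numeric(n)
  values[centers + 1L] <- vals
  if (cmin > 0L) values[1:cmin] <- vals[1L]
  if (cmax < n - 1L) values[(cmax + 2L):n] <- vals[length(vals)]
  structure(list(values = values, fps = features$fps, meal = ""),
            class = "probability_signal")
}

#' @export
print.probability_signal <- function(x, ...) {
  cat(sprintf(
    "<probability_signal> %d frames @ %g fps; mean %.3f, max %.3f\n",
    length(x$values), x$fps, mean(x$values), max(x$values)))
  invisible(x)
}

#' Plot a bite-probability signal
#' @param x a \code{probability_signal}.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.probability_signal <- function(x, ...) {
  tt <- (seq_along(x$values) - 1) / x$fps
  graphics::plot(tt, x$values, type = "l", xlab = "time (s)",
                 ylab = "bite probability", ylim = c(0, 1), ...)
  invisible(x)
}

#' Post-processing configuration for bite extraction
#'
#' @param median_window_s width of the median filter in seconds (rounded
#'   to an odd frame count; 0.52 s is 13 frames at 25 fps).
#' @param threshold_k the detection threshold is
#'   \code{mean + threshold_k * SD} of the filtered signal (1 fixes it to
#'   the mean-plus-standard-deviation rule).
#' @param min_separation_s minimum separation between detected bites.
#' @return list of class \code{postprocess_config}.
#' @export
postprocess_config <- function(median_window_s = 0.52, threshold_k = 1.0,
                               min_separation_s = 1.0) {
  stopifnot(median_window_s > 0, threshold_k >= 0, min_separation_s > 0)
  structure(list(median_window_s = median_window_s,
                 threshold_k = threshold_k,
                 min_separation_s = min_separation_s),
            class = "postprocess_config")
}

# plateau-aware local maxima of a numeric vector: a maximal run of equal
# values strictly above both neighbouring values; reported at the middle
# frame of the run (0-based).  Signal ends never qualify.
local_maxima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  if (nr < 3L) return(integer(0))
  ok <- seq_len(nr)[-c(1L, nr)]
  ok <- ok[r$values[ok] > r$values[ok - 1L] & r$values[ok] > r$values[ok + 1L]]
  mids <- (starts[ok] + ends[ok]) %/% 2L
  mids - 1L
}

#' Extract bite events from a probability signal
#'
#' The signal is median-filtered (running median over an odd window;
#' frames closer than half a window to either end are kept unfiltered),
#' thresholded at the mean plus
#' \code{threshold_k} standard deviations of the filtered signal, and its
#' local maxima above the threshold become candidate bites; candidates are
#' then accepted from highest to lowest (ties to the earlier), discarding
#' any candidate within \code{min_separation_s} of an already accepted
#' bite, so maxima too close to a stronger one are removed.  The
#' procedure is invariant to
#' increasing affine rescaling of the signal.  An empty result is valid
#' (e.g., a constant signal has SD 0, so no value strictly exceeds the
#' threshold).
#'
#' @param signal a \code{\link{probability_signal}}.
#' @param cfg a \code{\link{postprocess_config}}.
#' @return An \code{\link{annotation_log}} of detected bites.
#' @export
extract_bites <- function(signal, cfg = postprocess_config()) {
  stopifnot(inherits(signal, "probability_signal"),
            inherits(cfg, "postprocess_config"))
  v <- signal$values
  if (!length(v)) stop("empty signal", call. = FALSE)
  k <- round(cfg$median_window_s * signal$fps)
  if (k %% 2L == 0L) k <- k + 1L
  k <- max(1L, min(k, if (length(v) %% 2L == 1L) length(v)
                      else length(v) - 1L))
  f <- if (k > 1L) as.numeric(runmed(v, k, endrule = "keep")) else v
  thr <- mean(f) + cfg$threshold_k * sd(f)
  peaks <- local_maxima(f)                       # 0-based frames
  peaks <- peaks[f[peaks + 1L] > thr]
  sep <- cfg$min_separation_s * signal$fps       # frames
  # greedy keep-highest (equivalent to iterated removal of the lower of
  # each too-close pair): ties to the earlier peak
  if (length(peaks) > 1L) {
    ord <- order(-f[peaks + 1L], peaks)
    kept <- integer(0)
    for (pk in peaks[ord]) {
      if (!length(kept) || min(abs(kept - pk)) >= sep)
        kept <- c(kept, pk)
    }
    peaks <- sort(kept)
  }
  annotation_log(peaks / signal$fps, rep("bite", length(peaks)),
                 source = "detected", fps = signal$fps)
}
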