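# Shared fixtures and independent brute-force oracles.  Each oracle is a
# deliberately naive, literal implementation kept separate from the package
# code paths it checks.

# sparse profile for short test meals (the default ~55-bite profile needs a
# long meal to respect the refractory gap)
sparse_profile <- c(0.5, 0, 0)

# short meals have short (duration/10) segments, so the refractory gap and
# gesture must shrink with them to stay satisfiable
short_meal_pars <- function(duration_s) {
  r <- min(1.5, 0.3 * duration_s / 10)
  list(refractory_s = r, gesture_duration_s = min(1.0, 0.9 * r))
}

make_meal <- function(duration_s = 60, seed = 1L, profile = sparse_profile,
                      ...) {
  sp <- short_meal_pars(duration_s)
  simulate_meal(do.call(sim_config, c(
    list(duration_s = duration_s, rate_profile = profile, seed = seed),
    sp, list(...))))
}

noise_free <- function(duration_s = 60, seed = 1L,
                       profile = sparse_profile) {
  make_meal(duration_s, seed, profile, jitter_px = 0, dropout_prob = 0,
            outlier_prob = 0)
}

# literal re-implementation of the bite-time sampling recipe
oracle_bite_times <- function(duration_s, profile, seed,
                              refractory_s = 1.5) {
  x <- 1:10
  mu <- profile[1] + profile[2] * x + profile[3] * x^2
  set.seed(seed)
  seg_len <- duration_s / 10
  counts <- rpois(10, mu)
  seg <- rep(x, counts)
  times <- runif(sum(counts), (seg - 1) * seg_len, seg * seg_len)
  o <- order(times); times <- times[o]; seg <- seg[o]
  while (length(times) > 1) {
    viol <- which(diff(times) < refractory_s)
    if (!length(viol)) break
    j <- viol[1]
    times[j + 1] <- runif(1, (seg[j + 1] - 1) * seg_len,
                          seg[j + 1] * seg_len)
    o <- order(times); times <- times[o]; seg <- seg[o]
  }
  times
}

# probability signal wrapper for hand-built vectors
as_signal <- function(values, fps = 25) {
  structure(list(values = values, fps = fps, meal = ""),
            class = "probability_signal")
}

# literal peak-extraction oracle: manual running median (edges kept),
# mean + k*SD threshold, plateau-aware maxima by scanning runs, then
# iterated removal of the lower of each too-close pair
oracle_extract_bites <- function(values, fps, median_window_s = 0.52,
                                 threshold_k = 1, min_separation_s = 1) {
  n <- length(values)
  k <- round(median_window_s * fps)
  if (k %% 2 == 0) k <- k + 1
  k <- max(1, min(k, if (n %% 2 == 1) n else n - 1))
  h <- (k - 1) / 2
  f <- values
  if (k > 1 && n >= k)
    for (i in (h + 1):(n - h)) {
      win <- sort(values[(i - h):(i + h)])
      f[i] <- win[h + 1]
    }
  thr <- mean(f) + threshold_k * sd(f)
  # runs of equal values
  peaks <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && f[j + 1] == f[i]) j <- j + 1
    if (i > 1 && j < n && f[i - 1] < f[i] && f[j + 1] < f[i] &&
        f[i] > thr)
      peaks <- c(peaks, (i + j) %/% 2 - 1)   # 0-based mid frame
    i <- j + 1
  }
  sep <- min_separation_s * fps
  # keep-highest pruning, coded literally: repeatedly accept the highest
  # remaining candidate (ties to the earlier) and discard every candidate
  # within the separation of an accepted bite
  alive <- rep(TRUE, length(peaks))
  kept <- rep(FALSE, length(peaks))
  repeat {
    cand <- which(alive & !kept)
    if (!length(cand)) break
    best <- cand[1]
    for (q in cand) {
      if (f[peaks[q] + 1] > f[peaks[best] + 1]) best <- q
    }
    kept[best] <- TRUE
    for (q in which(alive & !kept)) {
      if (abs(peaks[q] - peaks[best]) < sep) alive[q] <- FALSE
    }
  }
  sort(peaks[kept]) / fps
}

# exhaustive maximum-cardinality matching of two small point sets
oracle_match_count <- function(d, r, tol) {
  if (!length(d) || !length(r)) return(0L)
  best <- oracle_match_count(d[-1], r, tol)   # leave d[1] unmatched
  for (j in seq_along(r)) {
    if (abs(d[1] - r[j]) <= tol) {
      best <- max(best, 1L + oracle_match_count(d[-1], r[-j], tol))
    }
  }
  best
}

# brute-force per-segment membership counts
oracle_segment_counts <- function(bites, start, stop, n_seg = 10) {
  D <- stop - start
  counts <- integer(n_seg)
  for (b in bites) {
    for (i in seq_len(n_seg)) {
      lo <- start + (i - 1) * D / n_seg
      hi <- start + i * D / n_seg
      inside <- if (i < n_seg) b >= lo && b < hi else b >= lo && b <= hi
      if (inside) {
        counts[i] <- counts[i] + 1L
        break
      }
    }
  }
  counts
}

# quadratic OLS via explicit normal equations
oracle_quadratic <- function(y, x = seq_along(y)) {
  X <- cbind(1, x, x^2)
  drop(solve(crossprod(X), crossprod(X, y)))
}

# separable toy clip set: positives carry a mid-window bump in a few
# channels of both streams, mimicking the hand-to-mouth + aperture pattern
make_toy_clips <- function(n_pos = 20, n_neg = 30, w = 50, seed = 99) {
  set.seed(seed)
  n <- n_pos + n_neg
  body <- array(rnorm(n * w * 44, 0, 0.5), c(n, w, 44))
  mouth <- array(rnorm(n * w * 9, 0, 0.5), c(n, w, 9))
  bump <- exp(-((seq_len(w) - w / 2)^2) / 50)
  for (i in seq_len(n_pos)) {
    body[i, , 17] <- body[i, , 17] - 3 * bump    # wrist-nose distance drops
    mouth[i, , 7] <- mouth[i, , 7] + 3 * bump    # aperture opens
  }
  structure(list(body = body, mouth = mouth,
                 labels = factor(rep(c("bite", "not_bite"),
                                     c(n_pos, n_neg)),
                                 levels = c("bite", "not_bite")),
                 provenance = data.frame(meal = "toy",
                                         center_frame = seq_len(n)),
                 window = w, fps = 25),
            class = "clip_set")
}

# untrained model with the given dims (for inference-path tests)
random_model <- function(seed = 1, w = 50, c_body = 44, c_mouth = 9,
                         cfg = model_config(conv_filters = c(4L, 6L),
                                            lstm_units = 5L,
                                            fusion_units = 8L,
                                            seed = seed)) {
  set.seed(seed)
  structure(list(params = bitewise:::model_init(cfg, c_body, c_mouth),
                 config = cfg, history = NULL, window = w, fps = 25,
                 c_body = c_body, c_mouth = c_mouth),
            class = "bite_model")
}
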