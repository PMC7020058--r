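make_features_and_log <- function(duration_s = 60, seed = 1,
                                  profile = c(0.3, 0, 0)) {
  m <- make_meal(duration_s = duration_s, seed = seed, profile = profile)
  list(features = preprocess_sequence(m$sequence), log = m$log,
       bites = m$bite_times)
}

test_that("clip extraction matches a brute-force tiling scan", {
  fl <- make_features_and_log(seed = 31)
  cs <- extract_labeled_clips(fl$features, fl$log, window_s = 2,
                              negative_stride_s = 1)
  fps <- fl$features$fps
  n <- fl$features$n_frames
  w <- 50L
  # brute force: positives at in-range bite frames, negatives on the 1-s
  # grid at >= 2 s from every bite
  pos <- round(fl$bites * fps)
  pos <- pos[pos - 25 >= 0 & pos + 24 <= n - 1]
  neg <- c()
  for (c0 in seq(25L, n - 25L, by = 25L)) {
    if (min(abs(c0 / fps - fl$bites)) >= 2) neg <- c(neg, c0)
  }
  expect_equal(sum(cs$labels == "bite"), length(pos))
  expect_equal(sum(cs$labels == "not_bite"), length(neg))
  expect_equal(cs$provenance$center_frame, c(pos, neg))
  # clip contents are the windows they claim to be
  i <- which(cs$labels == "bite")[1L]
  c0 <- cs$provenance$center_frame[i]
  expect_equal(cs$body[i, , ],
               fl$features$body[(c0 - 25 + 1):(c0 + 24 + 1), ],
               ignore_attr = TRUE)
})

test_that("boundary positives are dropped with a warning", {
  fl <- make_features_and_log(seed = 32)
  early <- annotation_log(c(0.12, fl$bites),
                          rep("bite", length(fl$bites) + 1L))
  expect_warning(cs <- extract_labeled_clips(fl$features, early),
                 "boundary")
  expect_equal(sum(cs$labels == "bite"), length(fl$bites))
})

test_that("clip extraction preconditions are enforced", {
  fl <- make_features_and_log(seed = 33)
  no_bites <- annotation_log(5, "spoonful")
  expect_error(extract_labeled_clips(fl$features, no_bites), "no bites")
  expect_error(extract_labeled_clips(fl$features, fl$log, window_s = 120),
               "longer than the meal")
})

test_that("the 90/10 split reproduces the study arithmetic", {
  labels <- factor(rep(c("bite", "not_bite"), c(4149L, 7972L)),
                   levels = c("bite", "not_bite"))
  expect_equal(length(labels), 12121L)
  sp <- split_clips(labels, train_fraction = 0.9, seed = 1)
  expect_equal(length(sp$eval), 1212L)
  expect_equal(length(sp$train), 12121L - 1212L)
  expect_length(intersect(sp$train, sp$eval), 0L)
  # stratified: evaluation label shares close to the corpus shares
  eval_pos <- sum(labels[sp$eval] == "bite")
  expect_equal(eval_pos, 415L)  # ceil share by largest remainder
})

test_that("splits are deterministic and degrade gracefully", {
  labels <- factor(rep("bite", 10), levels = c("bite", "not_bite"))
  sp <- split_clips(labels, 0.9, seed = 4)
  expect_equal(length(sp$eval), 1L)
  l2 <- factor(rep(c("bite", "not_bite"), c(5, 7)))
  expect_identical(split_clips(l2, 0.9, seed = 9),
                   split_clips(l2, 0.9, seed = 9))
  cs <- make_toy_clips(6, 8)
  sp2 <- split_clips(cs, 0.5, seed = 2)
  expect_equal(bitewise:::n_clips(sp2$train) +
                 bitewise:::n_clips(sp2$eval), 14L)
})

test_that("the probability signal equals a naive per-window loop", {
  fl <- make_features_and_log(duration_s = 10, seed = 34)
  mdl <- random_model(seed = 6)
  sig <- probability_signal(mdl, fl$features, batch_size = 64L)
  n <- fl$features$n_frames
  expect_length(sig$values, n)
  expect_true(all(sig$values >= 0 & sig$values <= 1))
  naive <- numeric(n)
  for (c0 in 25:(n - 25)) {
    wb <- array(fl$features$body[(c0 - 24):(c0 + 25), ], c(1, 50, 44))
    wm <- array(fl$features$mouth[(c0 - 24):(c0 + 25), ], c(1, 50, 9))
    naive[c0 + 1] <- predict_bite_prob(mdl, list(body = wb, mouth = wm))
  }
  naive[1:25] <- naive[26]
  naive[(n - 23):n] <- naive[n - 24]
  expect_equal(sig$values, naive)
})

test_that("a constant-head model yields a constant signal", {
  fl <- make_features_and_log(duration_s = 6, seed = 35,
                              profile = c(0, 0, 0))
  mdl <- random_model(seed = 7)
  mdl$params$out$W[] <- 0
  mdl$params$out$b <- 0.7
  sig <- probability_signal(mdl, fl$features)
  expect_equal(sig$values, rep(1 / (1 + exp(-0.7)), fl$features$n_frames))
})

test_that("meals shorter than the window are rejected", {
  fl <- make_features_and_log(duration_s = 6, seed = 36,
                              profile = c(0, 0, 0))
  short <- fl$features
  short$body <- short$body[1:30, ]
  short$mouth <- short$mouth[1:30, ]
  short$n_frames <- 30L
  expect_error(probability_signal(random_model(seed = 1), short),
               "shorter than")
})

test_that("a flat signal yields zero detections", {
  det <- extract_bites(as_signal(rep(0.4, 500)))
  expect_equal(nrow(det), 0L)
})

test_that("isolated bumps are recovered at their apex frames", {
  v <- numeric(1001)   # 40 s at 25 fps
  bump <- c(seq(0, 1, length.out = 13), seq(1, 0, length.out = 13)[-1])
  for (apex in c(250, 500, 750)) v[(apex - 12):(apex + 12) + 1] <- bump
  det <- extract_bites(as_signal(v))
  expect_equal(bite_times(det), c(250, 500, 750) / 25)
})

test_that("maxima closer than the separation keep the higher peak", {
  v <- numeric(501)
  tri <- function(apex, height) {
    idx <- (apex - 8):(apex + 8)
    v[idx + 1] <<- pmax(v[idx + 1], height * (1 - abs(idx - apex) / 8))
  }
  tri(250, 0.9)
  tri(262, 0.8)   # 0.48 s later
  # short median window so the close bumps stay resolved before pruning
  det <- extract_bites(as_signal(v),
                       postprocess_config(median_window_s = 0.12,
                                          min_separation_s = 1))
  expect_equal(bite_times(det), 10)   # only the 0.9 apex at frame 250
})

test_that("peak extraction equals the exhaustive oracle on random signals", {
  set.seed(77)
  for (rep in 1:120) {
    n <- sample(80:400, 1)
    v <- pmin(1, pmax(0, stats::filter(runif(n)^3, rep(1 / 5, 5),
                                       sides = 2)))
    v[is.na(v)] <- 0
    v <- as.numeric(v)
    cfg <- postprocess_config(
      median_window_s = sample(c(0.2, 0.52, 1), 1),
      threshold_k = sample(c(0.5, 1), 1),
      min_separation_s = sample(c(0.5, 1, 2), 1))
    got <- bite_times(extract_bites(as_signal(v), cfg))
    want <- oracle_extract_bites(v, 25, cfg$median_window_s,
                                 cfg$threshold_k, cfg$min_separation_s)
    expect_equal(got, want)
  }
})

test_that("detected bites are increasing and respect the separation", {
  set.seed(5)
  for (rep in 1:20) {
    v <- pmin(1, abs(stats::filter(rnorm(600, 0.2, 0.3), rep(0.2, 5),
                                   sides = 2)))
    v[is.na(v)] <- 0
    det <- bite_times(extract_bites(as_signal(as.numeric(v))))
    if (length(det) > 1) {
      expect_true(all(diff(det) > 0))
      expect_true(all(diff(det) >= 1 - 1e-12))
    }
  }
})

test_that("peak extraction is invariant to increasing affine rescaling", {
  set.seed(6)
  v <- pmin(1, pmax(0, as.numeric(stats::filter(runif(400)^2,
                                                rep(0.25, 4),
                                                sides = 2))))
  v[is.na(v)] <- 0
  d1 <- bite_times(extract_bites(as_signal(v)))
  scaled <- as_signal(3.2 * v + 0.1)
  d2 <- bite_times(extract_bites(scaled))
  expect_equal(d1, d2)
})
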