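test_that("missing points are filled from the previous frame", {
  m <- noise_free(duration_s = 4, seed = 2, profile = c(0, 0, 0))
  s <- m$sequence
  # wrist missing at frames 5-7 (1-based 6-8), valid at frame 4 (1-based 5)
  s$body[6:8, "l_wrist", 1:2] <- NA
  s$body[6:8, "l_wrist", 3] <- 0
  cl <- clean_sequence(s)
  for (f in 6:8)
    expect_equal(cl$body[f, "l_wrist", 1:2], s$body[5, "l_wrist", 1:2])
  expect_false(anyNA(cl$body))
})

test_that("leading missing values are back-filled from the first valid frame", {
  m <- noise_free(duration_s = 4, seed = 2, profile = c(0, 0, 0))
  s <- m$sequence
  s$mouth[1:3, "B", 1:2] <- NA
  s$mouth[1:3, "B", 3] <- 0
  cl <- clean_sequence(s)
  expect_equal(cl$mouth[1, "B", 1:2], s$mouth[4, "B", 1:2])
})

test_that("a fully valid sequence is returned unchanged and cleaning is idempotent", {
  s <- noise_free(duration_s = 10, seed = 3)$sequence
  cl <- clean_sequence(s)
  expect_identical(cl, s)
  m <- make_meal(duration_s = 20, seed = 5, profile = c(0.3, 0, 0))
  c1 <- clean_sequence(m$sequence)
  expect_identical(clean_sequence(c1), c1)
})

test_that("one-frame spikes are flagged like a brute-force displacement scan", {
  s <- noise_free(duration_s = 4, seed = 7, profile = c(0, 0, 0))$sequence
  thr <- 0.15 * sqrt(sum(s$frame_size^2))
  # elbow jumps half the frame width for one frame
  spike_frame <- 50
  s$body[spike_frame, "r_elbow", 1] <-
    s$body[spike_frame, "r_elbow", 1] + s$frame_size[1] / 2
  # brute force: |displacement from previous frame| > threshold
  dx <- diff(s$body[, "r_elbow", 1])
  dy <- diff(s$body[, "r_elbow", 2])
  flagged <- which(sqrt(dx^2 + dy^2) > thr) + 1L
  expect_true(spike_frame %in% flagged)
  cl <- clean_sequence(s)
  expect_equal(cl$body[spike_frame, "r_elbow", 1:2],
               s$body[spike_frame - 1L, "r_elbow", 1:2])
  # all other frames untouched
  expect_equal(cl$body[-spike_frame, "r_elbow", ],
               s$body[-spike_frame, "r_elbow", ])
})

test_that("a never-detected point is an unrecoverable error naming it", {
  s <- noise_free(duration_s = 2, seed = 1, profile = c(0, 0, 0))$sequence
  s$body[, "r_wrist", 1:2] <- NA
  s$body[, "r_wrist", 3] <- 0
  expect_error(clean_sequence(s), "r_wrist")
})

test_that("smoothing honours its limits", {
  s <- noise_free(duration_s = 10, seed = 4)$sequence
  # smoothing 0: interpolation limit, identity at the frames
  cfg0 <- cleaning_config(spline_smoothing = 0)
  expect_identical(smooth_sequence(s, cfg0), s)
  # GCV on an exact quadratic trajectory reproduces it
  n <- n_frames(s)
  tq <- (seq_len(n) - 1) / n
  s2 <- s
  s2$body[, "r_wrist", 1] <- 200 + 80 * tq - 60 * tq^2
  sm <- smooth_sequence(s2)
  expect_lt(max(abs(sm$body[, "r_wrist", 1] - s2$body[, "r_wrist", 1])),
            1e-6)
  # white noise shrinks under any positive penalty
  s3 <- s
  set.seed(1)
  s3$mouth[, "B", 1] <- s3$mouth[, "B", 1] + rnorm(n)
  smn <- smooth_sequence(s3, cleaning_config(spline_smoothing = 1e-4))
  expect_lt(var(smn$mouth[, "B", 1]), var(s3$mouth[, "B", 1]))
  # too few frames
  short <- noise_free(duration_s = 0.12, seed = 1,
                      profile = c(0, 0, 0))$sequence
  expect_error(smooth_sequence(short), "too few frames|degree")
})

test_that("the visible mouth side is selected by corner confidence", {
  s <- noise_free(duration_s = 2, seed = 1, profile = c(0, 0, 0))$sequence
  s$mouth[, "A", 3] <- 0.9
  s$mouth[, "C", 3] <- 0.4
  expect_identical(select_mouth_side(s), "left")
  s$mouth[, "C", 3] <- 0.9      # exact tie -> left
  expect_identical(select_mouth_side(s), "left")
  s$mouth[, "A", 3] <- 0.2
  expect_identical(select_mouth_side(s), "right")
  s$mouth[, "A", 3] <- 0
  s$mouth[, "C", 3] <- 0
  expect_error(select_mouth_side(s), "corner")
})

test_that("generator-rendered sides are recovered from confidences", {
  hits <- 0L
  n_seeds <- 200L
  for (i in seq_len(n_seeds)) {
    side <- if (i %% 2 == 0) "left" else "right"
    m <- simulate_meal(sim_config(duration_s = 6, rate_profile = c(0, 0, 0),
                                  side = side, seed = 1000L + i))
    hits <- hits + (select_mouth_side(m$sequence) == side)
  }
  expect_gte(hits / n_seeds, 0.99)
})

test_that("features are exactly translation invariant", {
  s <- clean_sequence(make_meal(duration_s = 10, seed = 8,
                                profile = c(0.3, 0, 0))$sequence)
  f1 <- assemble_features(s, "left")
  s2 <- s
  s2$body[, , 1] <- s2$body[, , 1] + 40
  s2$body[, , 2] <- s2$body[, , 2] - 13
  s2$mouth[, , 1] <- s2$mouth[, , 1] + 40
  s2$mouth[, , 2] <- s2$mouth[, , 2] - 13
  f2 <- assemble_features(s2, "left")
  expect_equal(f1$body, f2$body)
  expect_equal(f1$mouth, f2$mouth)
})

test_that("a degenerate frame yields all-zero features", {
  s <- noise_free(duration_s = 2, seed = 1, profile = c(0, 0, 0))$sequence
  s$body[1, , 1] <- 100; s$body[1, , 2] <- 100
  s$mouth[1, , 1] <- 100; s$mouth[1, , 2] <- 100
  f <- assemble_features(s, "left")
  expect_equal(unname(f$body[1, ]), rep(0, 44))
  expect_equal(unname(f$mouth[1, ]), rep(0, 9))
})

test_that("pairwise distances agree with a brute-force double loop", {
  s <- noise_free(duration_s = 1, seed = 9, profile = c(0, 0, 0))$sequence
  set.seed(21)
  s$body[, , 1] <- matrix(runif(n_frames(s) * 8, 0, 720), n_frames(s))
  s$body[, , 2] <- matrix(runif(n_frames(s) * 8, 0, 576), n_frames(s))
  f <- assemble_features(s, "left")
  fr <- 7L
  expected <- c()
  for (i in 1:7) for (j in (i + 1):8)
    expected <- c(expected,
                  sqrt(sum((s$body[fr, i, 1:2] - s$body[fr, j, 1:2])^2)))
  expect_equal(unname(f$body[fr, 17:44]), expected)
})

test_that("assembling features requires a cleaned sequence", {
  m <- make_meal(duration_s = 10, seed = 10, profile = c(0.3, 0, 0),
                 dropout_prob = 0.3)
  expect_error(assemble_features(m$sequence, "left"), "clean")
  expect_error(smooth_sequence(m$sequence), "clean")
})

test_that("the preprocessing pipeline is deterministic", {
  m <- make_meal(duration_s = 12, seed = 11, profile = c(0.3, 0, 0))
  expect_identical(preprocess_sequence(m$sequence),
                   preprocess_sequence(m$sequence))
})
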