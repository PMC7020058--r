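test_that("keypoint sequences round-trip through both dialects", {
  m <- make_meal(duration_s = 8, seed = 6, profile = c(0.2, 0, 0))
  s <- m$sequence
  for (dialect in c("json_frames", "csv_flat")) {
    p1 <- withr::local_tempfile(fileext = ".kp")
    p2 <- withr::local_tempfile(fileext = ".kp")
    write_keypoints(s, p1, dialect)
    s2 <- read_keypoints(p1, dialect)
    expect_true(isTRUE(all.equal(s, s2)))
    write_keypoints(s2, p2, dialect)
    expect_identical(readLines(p1), readLines(p2))
  }
})

test_that("missing points survive a round trip explicitly", {
  m <- noise_free(duration_s = 4, seed = 1, profile = c(0, 0, 0))
  s <- m$sequence
  s$body[2, "l_wrist", 1:2] <- NA  # wrist undetected at frame 1 (0-based)
  s$body[2, "l_wrist", 3] <- 0
  for (dialect in c("json_frames", "csv_flat")) {
    p <- withr::local_tempfile(fileext = ".kp")
    write_keypoints(s, p, dialect)
    s2 <- read_keypoints(p, dialect)
    expect_true(is.na(s2$body[2, "l_wrist", 1]))
    expect_identical(s2$body[2, "l_wrist", 3], 0)
    expect_false(anyNA(s2$body[-2, , 1]))
  }
})

test_that("malformed keypoint files are rejected with clear errors", {
  m <- noise_free(duration_s = 2, seed = 1, profile = c(0, 0, 0))
  p <- withr::local_tempfile(fileext = ".csv")
  write_keypoints(m$sequence, p, "csv_flat")
  lines <- readLines(p)
  # non-monotone frame indices
  body_lines <- grep("^[0-9]", lines)
  swapped <- lines
  swapped[body_lines[1:12]] <- lines[body_lines[13:24]]
  swapped[body_lines[13:24]] <- lines[body_lines[1:12]]
  p_bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(swapped, p_bad)
  expect_error(read_keypoints(p_bad, "csv_flat"), "out of order")
  # missing fps metadata
  p_nofps <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines[!startsWith(lines, "# fps")], p_nofps)
  expect_error(read_keypoints(p_nofps, "csv_flat"), "fps")
  jp <- withr::local_tempfile(fileext = ".json")
  writeLines('{"frames": []}', jp)
  expect_error(read_keypoints(jp, "json_frames"), "fps")
  # inconsistent point counts
  p_short <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines[-body_lines[5]], p_short)
  expect_error(read_keypoints(p_short, "csv_flat"), "schema|point")
})

test_that("out-of-frame points are kept but flagged", {
  m <- noise_free(duration_s = 2, seed = 1, profile = c(0, 0, 0))
  s <- m$sequence
  s$body[3, "r_elbow", 1] <- -25
  p <- withr::local_tempfile(fileext = ".csv")
  write_keypoints(s, p, "csv_flat")
  s2 <- read_keypoints(p, "csv_flat")
  oob <- attr(s2, "out_of_bounds")
  expect_equal(nrow(oob), 1L)
  expect_equal(oob$frame, 2L)
  expect_equal(oob$point, "r_elbow")
  expect_equal(s2$body[3, "r_elbow", 1], -25)
})

test_that("annotation logs read, sort and validate", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,event", "0.0,meal_start", "5.2,bite"), p)
  log <- read_annotations(p)
  expect_s3_class(log, "annotation_log")
  expect_equal(nrow(log), 2L)
  expect_equal(bite_times(log), 5.2)

  writeLines(c("time_s,event", "5.2,bite", "0.0,meal_start"), p)
  expect_warning(log2 <- read_annotations(p), "sort")
  expect_equal(log2$time_s, c(0, 5.2))

  writeLines(c("time_s,event", "3.0,chew"), p)
  expect_error(read_annotations(p), "unknown event")
  writeLines(c("time_s,event", "-1.0,bite"), p)
  expect_error(read_annotations(p), "non-negative")
})

test_that("annotation log invariants hold", {
  expect_error(annotation_log(c(1, 2), c("meal_start", "meal_start")),
               "at most one")
  expect_error(annotation_log(c(5, 2), c("meal_start", "bite")),
               "meal_start")
  log <- annotation_log(c(2, 1), c("bite", "spoonful"))
  expect_equal(log$event, c("spoonful", "bite"))
})

test_that("behaviour logs report duration and survive byte round trips", {
  det <- annotation_log(c(10, 310), c("bite", "bite"), source = "detected")
  sm <- meal_summary(det)
  p <- withr::local_tempfile(fileext = ".csv")
  write_behavior_log(sm, det, p)
  back <- read_behavior_log(p)
  expect_equal(back$summary$duration_min, 5.0)
  expect_equal(back$summary$total_bites, 2L)
  expect_equal(bite_times(back$events), c(10, 310))
  # write -> read -> write is byte identical
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_behavior_log(meal_summary(back$events), back$events, p2)
  expect_identical(readLines(p), readLines(p2))
  expect_identical(readLines(bitewise:::summary_sidecar_path(p)),
                   readLines(bitewise:::summary_sidecar_path(p2)))
})

test_that("an empty event list yields a flagged zero-bite summary", {
  empty <- annotation_log(numeric(0), character(0), source = "detected")
  p <- withr::local_tempfile(fileext = ".csv")
  write_behavior_log(NULL, empty, p)
  back <- read_behavior_log(p)
  expect_equal(back$summary$total_bites, 0L)
  expect_true(back$summary$duration_undefined)
})

test_that("synthetic behaviour logs round-trip byte-identically", {
  m <- make_meal(duration_s = 60, seed = 3)
  p <- withr::local_tempfile(fileext = ".csv")
  write_behavior_log(meal_summary(m$log), m$log, p)
  back <- read_behavior_log(p)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_behavior_log(meal_summary(back$events), back$events, p2)
  expect_identical(readLines(p), readLines(p2))
})
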