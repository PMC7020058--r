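test_that("the published clip-level worked example is reproduced", {
  met <- confusion_metrics(confusion_matrix(tp = 374, fn = 27, fp = 30,
                                            tn = 781))
  expect_equal(round(met$kappa, 3), 0.894)
  expect_equal(round(met$recall, 3), 0.933)
  expect_equal(round(met$specificity, 3), 0.963)
  expect_equal(round(met$f1_rs, 3), 0.948)
  expect_equal(round(met$f1_bite, 3), 0.929)
  expect_equal(met$n, 1212)
})

test_that("kappa hits its landmark values", {
  perfect <- confusion_metrics(confusion_matrix(100, 0, 0, 100))
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$f1_bite, 1)
  expect_equal(perfect$f1_rs, 1)
  chance <- confusion_metrics(confusion_matrix(25, 25, 25, 25))
  expect_equal(chance$po, 0.5)
  expect_equal(chance$pe, 0.5)
  expect_equal(chance$kappa, 0)
  expect_error(confusion_metrics(confusion_matrix(50, 0, 0, 0)),
               "kappa undefined")
})

test_that("kappa is symmetric and matches a brute-force po/pe over random matrices", {
  set.seed(14)
  for (rep in 1:100) {
    cm <- confusion_matrix(sample(1:200, 1), sample(1:200, 1),
                           sample(1:200, 1), sample(1:200, 1))
    met <- confusion_metrics(cm)
    # brute force from first principles
    N <- cm$tp + cm$fn + cm$fp + cm$tn
    po <- (cm$tp + cm$tn) / N
    pe <- ((cm$tp + cm$fn) / N) * ((cm$tp + cm$fp) / N) +
      ((cm$fp + cm$tn) / N) * ((cm$fn + cm$tn) / N)
    expect_equal(met$kappa, (po - pe) / (1 - pe))
    # transpose (swap fn/fp) leaves kappa unchanged
    tmet <- confusion_metrics(confusion_matrix(cm$tp, cm$fp, cm$fn, cm$tn))
    expect_equal(tmet$kappa, met$kappa)
  }
})

test_that("event matching handles the worked examples", {
  mk <- function(t) annotation_log(t, rep("bite", length(t)),
                                   source = "detected")
  same <- match_events(mk(c(3, 9, 20)), mk(c(3, 9, 20)))
  expect_equal(same$precision, 1)
  expect_equal(same$recall, 1)

  r <- match_events(mk(c(10, 12, 30)), mk(c(10.4, 30.9)), tolerance_s = 1)
  expect_equal(r$tp, 2L)
  expect_equal(r$fp, 1L)
  expect_equal(r$fn, 0L)

  degen <- match_events(mk(numeric(0)), mk(5))
  expect_equal(degen$recall, 0)
  expect_true(is.na(degen$precision))
  expect_true(degen$precision_undefined)

  empty <- match_events(mk(numeric(0)), mk(numeric(0)))
  expect_equal(empty$precision, 1)
  expect_equal(empty$recall, 1)

  expect_error(match_events(annotation_log(1, "spoonful"), mk(2)),
               "bite-only")
})

test_that("greedy matching equals exhaustive maximum matching", {
  set.seed(15)
  mk <- function(t) annotation_log(t, rep("bite", length(t)),
                                   source = "detected")
  for (rep in 1:200) {
    nd <- sample(0:8, 1)
    nr <- sample(0:8, 1)
    d <- sort(runif(nd, 0, 30))
    r <- sort(runif(nr, 0, 30))
    tol <- sample(c(0.5, 1, 2), 1)
    got <- match_events(mk(d), mk(r), tol)$tp
    expect_identical(got, oracle_match_count(d, r, tol))
  }
})

test_that("correlations follow the textbook formula and its bands", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_measures(x, x)$r, 1.0)
  expect_equal(correlate_measures(x, 10 - 2 * x)$r, -1.0)

  set.seed(16)
  a <- rnorm(100)
  b <- 0.6 * a + rnorm(100, 0, 0.5)
  got <- correlate_measures(a, b)
  two_pass <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, two_pass, tolerance = 1e-12)
  expect_identical(correlate_measures(x, x)$band, "very high")

  expect_error(correlate_measures(c(1, 2), c(1, 2)), "3 pairs")
  expect_error(correlate_measures(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("matching refuses logs recorded at different frame rates", {
  a <- annotation_log(c(1, 2), c("bite", "bite"), source = "detected",
                      fps = 25)
  b <- annotation_log(c(1, 2), c("bite", "bite"), fps = 30)
  expect_error(match_events(a, b), "fps")
})
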