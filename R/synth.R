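# Synthetic meal generator: keypoint streams with embedded bite gestures
# plus the matching ground-truth annotation log.

#' Simulation configuration
#'
#' Study-like defaults: 25 fps PAL video at 720x576 pixels, a 10-minute
#' meal, and an expected per-10%-segment bite-count profile following the
#' quadratic y0 + a*x + b*x^2 over segment index x = 1..10 with
#' (6.909, -0.7409, 0.0683) -- about 55 expected bites per meal, denser at
#' the beginning and end than in the middle.
#'
#' @param duration_s meal duration in seconds.
#' @param fps frames per second.
#' @param frame_size \code{c(width, height)} pixels.
#' @param rate_profile numeric \code{c(y0, a, b)}: expected bites per
#'   10\%-of-meal segment as a quadratic in the segment index 1..10.
#' @param gesture_duration_s duration of one hand-to-mouth gesture
#'   (plate-mouth-plate), centred on the bite time.
#' @param spoonful_lead_s lead of the spoonful event before its bite.
#' @param refractory_s minimum spacing between consecutive bites; violating
#'   bite times are re-sampled.
#' @param jitter_px SD of Gaussian positional noise on every coordinate.
#' @param dropout_prob per-point, per-frame probability of a missing
#'   detection (confidence 0, no coordinates).
#' @param outlier_prob per-point, per-frame probability of a one-frame
#'   spike to a uniform random in-frame position (pose-estimator glitch).
#' @param aperture_px peak mouth opening (B-D distance increase) at the
#'   bite moment, pixels.
#' @param side which arm is camera-side and used for eating:
#'   \code{"left"} (joints 5-7) or \code{"right"}.
#' @param seed integer seed governing all randomness.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(duration_s = 600, fps = 25,
                       frame_size = c(720L, 576L),
                       rate_profile = c(y0 = 6.909, a = -0.7409, b = 0.0683),
                       gesture_duration_s = 1.0, spoonful_lead_s = 0.5,
                       refractory_s = 1.5, jitter_px = 1.5,
                       dropout_prob = 0.02, outlier_prob = 0.005,
                       aperture_px = 14, side = c("left", "right"),
                       seed = 1L) {
  side <- match.arg(side)
  stopifnot(duration_s > 0, fps > 0, jitter_px >= 0,
            dropout_prob >= 0, dropout_prob <= 1,
            outlier_prob >= 0, outlier_prob <= 1,
            gesture_duration_s > 0, refractory_s > 0,
            length(rate_profile) == 3L)
  structure(list(duration_s = duration_s, fps = fps,
                 frame_size = as.numeric(frame_size),
                 rate_profile = unname(as.numeric(rate_profile)),
                 gesture_duration_s = gesture_duration_s,
                 spoonful_lead_s = spoonful_lead_s,
                 refractory_s = refractory_s, jitter_px = jitter_px,
                 dropout_prob = dropout_prob, outlier_prob = outlier_prob,
                 aperture_px = aperture_px, side = side,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Posture prototype for the synthetic eater
#'
#' Rest positions for the 8 body joints and 4 mouth points of a seated
#' eater viewed from the front-left at 40-45 degrees, plus the plate and
#' mouth anchors between which the eating hand travels.  All positions lie
#' inside the frame; mouth points sit in a small neighbourhood of the nose.
#'
#' @param frame_size \code{c(width, height)} pixels.
#' @param side camera-side (eating) arm, \code{"left"} or \code{"right"}.
#' @return list of class \code{posture_prototype} with \code{rest_body}
#'   (8 x 2), \code{rest_mouth} (4 x 2), \code{plate_anchor},
#'   \code{mouth_anchor}.
#' @export
posture_prototype <- function(frame_size = c(720L, 576L),
                              side = c("left", "right")) {
  side <- match.arg(side)
  w <- frame_size[1L]; h <- frame_size[2L]
  sx <- w / 720; sy <- h / 576   # scale the canonical layout to the frame
  p <- function(x, y) c(x * sx, y * sy)
  nose <- p(390, 168)
  rest_body <- rbind(
    nose          = nose,
    neck          = p(390, 242),
    r_shoulder    = p(452, 250),
    r_elbow       = p(476, 330),
    r_wrist       = p(452, 408),
    l_shoulder    = p(328, 250),
    l_elbow       = p(296, 330),
    l_wrist       = p(322, 420)
  )
  mouth_c <- p(388, 196)
  rest_mouth <- rbind(
    A = mouth_c + c(-14 * sx, 1 * sy),
    B = mouth_c + c(-1 * sx, -4 * sy),
    C = mouth_c + c(12 * sx, 1 * sy),
    D = mouth_c + c(-1 * sx, 4 * sy)
  )
  plate_anchor <- p(340, 430)
  mouth_anchor <- mouth_c + c(-2 * sx, 10 * sy)
  wrist <- if (side == "left") "l_wrist" else "r_wrist"
  rest_body[wrist, ] <- plate_anchor
  stopifnot(all(rest_body[, 1L] >= 0 & rest_body[, 1L] <= w),
            all(rest_body[, 2L] >= 0 & rest_body[, 2L] <= h))
  structure(list(rest_body = rest_body, rest_mouth = rest_mouth,
                 plate_anchor = plate_anchor, mouth_anchor = mouth_anchor),
            class = "posture_prototype")
}

#' Draw bite times from a quadratic meal-progress rate profile
#'
#' The meal is split into ten equal segments.  The expected bite count of
#' segment \code{x} (1-based) is \code{y0 + a*x + b*x^2}; the realised count
#' is Poisson with that mean, bite times are placed uniformly within the
#' segment, pooled and sorted.  Pairs of consecutive bites closer than
#' \code{refractory_s} are resolved by re-sampling the later bite uniformly
#' within its own segment (first violating pair first, re-sorting after each
#' draw) until no violation remains.
#'
#' @param duration_s meal duration (seconds, positive).
#' @param rate_profile numeric \code{c(y0, a, b)}.
#' @param seed integer seed.
#' @param refractory_s minimum allowed gap between bites (seconds).
#' @param max_iter resampling iterations before giving up.
#' @return increasing numeric vector of bite times in \code{[0, duration_s]}.
#' @export
simulate_bite_times <- function(duration_s, rate_profile, seed,
                                refractory_s = 1.5, max_iter = 10000L) {
  stopifnot(duration_s > 0, length(rate_profile) == 3L)
  x <- 1:10
  mu <- rate_profile[1L] + rate_profile[2L] * x + rate_profile[3L] * x^2
  if (any(mu < 0))
    stop("rate profile yields a negative expected count at segment(s) ",
         paste(which(mu < 0), collapse = ", "), call. = FALSE)
  set.seed(seed)
  seg_len <- duration_s / 10
  counts <- rpois(10L, mu)
  seg <- rep.int(x, counts)
  times <- runif(sum(counts), (seg - 1) * seg_len, seg * seg_len)
  ord <- order(times); times <- times[ord]; seg <- seg[ord]
  it <- 0L
  while (length(times) > 1L) {
    gap <- diff(times)
    j <- which(gap < refractory_s)
    if (!length(j)) break
    it <- it + 1L
    if (it > max_iter)
      stop("cannot satisfy the refractory gap; profile too dense for ",
           "this duration", call. = FALSE)
    j <- j[1L]
    times[j + 1L] <- runif(1L, (seg[j + 1L] - 1) * seg_len,
                           seg[j + 1L] * seg_len)
    ord <- order(times); times <- times[ord]; seg <- seg[ord]
  }
  times
}

# cubic ease-in/ease-out (smoothstep)
smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  3 * t^2 - 2 * t^3
}

# gesture progress 0..1..0 over phase s in [0,1]: plate -> mouth -> plate
gesture_progress <- function(s) {
  ifelse(s <= 0.5, smoothstep(2 * s), smoothstep(2 * (1 - s)))
}

#' Simulate one videotaped meal as keypoints plus its annotation log
#'
#' Generates the deterministic kinematic model -- all points at their rest
#' pose except that, around each bite time, the eating wrist travels
#' plate-to-mouth-to-plate along a cubic ease-in/ease-out path (elbow
#' following at reduced amplitude) and the mouth aperture (B-D distance)
#' opens, both peaking exactly at the bite time -- then perturbs it with
#' Gaussian jitter, per-point dropouts, and one-frame outlier spikes to a
#' uniform in-frame position.  The camera-side mouth corner is rendered
#' with high detection confidence, the far corner with low confidence.
#' Each bite is preceded by a spoonful event \code{spoonful_lead_s} earlier
#' (clamped at 0); the log carries meal_start (first spoonful), all
#' spoonful/bite events, occasional food_addition events and meal_stop
#' (last bite).  All randomness derives from \code{config$seed}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param prototype a \code{\link{posture_prototype}}; defaults to the
#'   canonical layout for \code{config$frame_size} and \code{config$side}.
#' @return list with \code{sequence} (a \code{\link{keypoint_sequence}}),
#'   \code{log} (ground-truth \code{\link{annotation_log}}), and
#'   \code{bite_times}.
#' @export
simulate_meal <- function(config, prototype = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(prototype))
    prototype <- posture_prototype(config$frame_size, config$side)
  stopifnot(inherits(prototype, "posture_prototype"))

  bites <- simulate_bite_times(config$duration_s, config$rate_profile,
                               seed = config$seed,
                               refractory_s = config$refractory_s)
  if (length(bites) > 1L && min(diff(bites)) <= config$gesture_duration_s)
    stop("gesture_duration_s >= minimum inter-bite gap: gestures would ",
         "overlap; shorten the gesture or increase refractory_s",
         call. = FALSE)

  n <- round(config$duration_s * config$fps)
  tt <- (seq_len(n) - 1) / config$fps
  w <- config$frame_size[1L]; h <- config$frame_size[2L]

  body <- array(0, c(n, 8L, 2L))
  for (j in 1:8) body[, j, ] <- matrix(prototype$rest_body[j, ], n, 2L,
                                       byrow = TRUE)
  mouth <- array(0, c(n, 4L, 2L))
  for (j in 1:4) mouth[, j, ] <- matrix(prototype$rest_mouth[j, ], n, 2L,
                                        byrow = TRUE)

  arm <- if (config$side == "left") c(7L, 8L) else c(4L, 5L)  # elbow, wrist
  reach <- prototype$mouth_anchor - prototype$plate_anchor
  g <- config$gesture_duration_s
  for (tb in bites) {
    idx <- which(tt >= tb - g / 2 & tt <= tb + g / 2)
    if (!length(idx)) next
    p <- gesture_progress((tt[idx] - (tb - g / 2)) / g)
    body[idx, arm[2L], ] <- rep(prototype$plate_anchor, each = length(idx)) +
      outer(p, reach)
    body[idx, arm[1L], ] <- body[idx, arm[1L], , drop = FALSE] +
      array(outer(0.45 * p, reach), c(length(idx), 1L, 2L))
    # mouth opens: B moves up, D moves down (y grows downward)
    mouth[idx, 2L, 2L] <- mouth[idx, 2L, 2L] - p * config$aperture_px / 2
    mouth[idx, 4L, 2L] <- mouth[idx, 4L, 2L] + p * config$aperture_px / 2
  }

  # ---- noise; RNG stream continues from simulate_bite_times' seeding ----
  npts <- 12L
  coords <- array(0, c(n, npts, 2L))
  coords[, 1:8, ] <- body
  coords[, 9:12, ] <- mouth
  if (config$jitter_px > 0)
    coords <- coords + rnorm(length(coords), 0, config$jitter_px)

  conf <- matrix(runif(n * npts, 0.75, 0.98), n, npts)
  far_corner <- if (config$side == "left") 11L else 9L  # C if left-visible
  conf[, far_corner] <- runif(n, 0.15, 0.45)

  drop_mask <- matrix(runif(n * npts) < config$dropout_prob, n, npts)
  spike_mask <- matrix(runif(n * npts) < config$outlier_prob, n, npts) &
    !drop_mask
  nsp <- sum(spike_mask)
  if (nsp) {
    sx <- runif(nsp, 0, w); sy <- runif(nsp, 0, h)
    xs <- coords[, , 1L]; ys <- coords[, , 2L]
    xs[spike_mask] <- sx; ys[spike_mask] <- sy
    coords[, , 1L] <- xs; coords[, , 2L] <- ys
  }
  if (any(drop_mask)) {
    xs <- coords[, , 1L]; ys <- coords[, , 2L]
    xs[drop_mask] <- NA_real_; ys[drop_mask] <- NA_real_
    coords[, , 1L] <- xs; coords[, , 2L] <- ys
    conf[drop_mask] <- 0
  }

  body_out <- array(NA_real_, c(n, 8L, 3L))
  body_out[, , 1:2] <- coords[, 1:8, ]
  body_out[, , 3L] <- conf[, 1:8]
  mouth_out <- array(NA_real_, c(n, 4L, 3L))
  mouth_out[, , 1:2] <- coords[, 9:12, ]
  mouth_out[, , 3L] <- conf[, 9:12]

  seqc <- keypoint_sequence(body_out, mouth_out, fps = config$fps,
                            frame_size = config$frame_size,
                            meta = sprintf("synth seed %d", config$seed))

  # ---- ground-truth log ----
  ev_t <- numeric(0); ev_k <- character(0)
  if (length(bites)) {
    spoons <- pmax(0, bites - config$spoonful_lead_s)
    n_add <- rpois(1L, 1.5)
    adds <- if (n_add > 0) runif(n_add, 0, max(bites)) else numeric(0)
    ev_t <- c(spoons[1L], spoons, bites, adds, max(bites))
    ev_k <- c("meal_start", rep("spoonful", length(spoons)),
              rep("bite", length(bites)),
              rep("food_addition", length(adds)), "meal_stop")
  }
  log <- annotation_log(ev_t, ev_k, source = "manual", fps = config$fps)
  list(sequence = seqc, log = log, bite_times = bites)
}
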