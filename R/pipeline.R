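# Configuration plumbing and the staged pipeline tying the modules
# together: simulate -> preprocess -> make-clips -> train -> detect ->
# analyze -> evaluate.

PIPELINE_STAGES <- c("simulate", "preprocess", "make-clips", "train",
                     "detect", "analyze", "evaluate")

#' Pipeline configuration
#'
#' One nested configuration validated up front: per-stage blocks for the
#' simulator, cleaning, model and post-processing, plus corpus size,
#' evaluation tolerance and the global seed.  Meal \code{i} (1-based) of
#' the corpus is simulated with seed \code{seed + i - 1}.
#'
#' @param n_meals number of meals in the synthetic corpus.
#' @param sim a \code{\link{sim_config}} (its seed field is overridden per
#'   meal as above).
#' @param cleaning a \code{\link{cleaning_config}}.
#' @param model a \code{\link{model_config}}.
#' @param postprocess a \code{\link{postprocess_config}}.
#' @param window_s training/inference clip duration, seconds.
#' @param negative_stride_s negative-clip tiling stride, seconds.
#' @param train_fraction train share of the clip split.
#' @param match_tolerance_s event-matching tolerance, seconds.
#' @param seed global integer seed.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_meals = 5L, sim = sim_config(),
                            cleaning = cleaning_config(),
                            model = model_config(),
                            postprocess = postprocess_config(),
                            window_s = 2.0, negative_stride_s = 1.0,
                            train_fraction = 0.9,
                            match_tolerance_s = 1.0, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"),
            inherits(cleaning, "cleaning_config"),
            inherits(model, "model_config"),
            inherits(postprocess, "postprocess_config"),
            n_meals >= 1L, window_s > 0, negative_stride_s > 0,
            train_fraction > 0, train_fraction < 1, match_tolerance_s > 0)
  structure(list(n_meals = as.integer(n_meals), sim = sim,
                 cleaning = cleaning, model = model,
                 postprocess = postprocess, window_s = window_s,
                 negative_stride_s = negative_stride_s,
                 train_fraction = train_fraction,
                 match_tolerance_s = match_tolerance_s,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Each top-level block (\code{sim}, \code{cleaning}, \code{model},
#' \code{postprocess}) holds the arguments of the corresponding
#' \code{*_config()} constructor; scalars at the top level override the
#' remaining \code{\link{pipeline_config}} arguments.  Unknown keys are
#' errors, so typos fail before any stage runs.
#'
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(block, ctor) {
    args <- y[[block]]
    if (is.null(args)) return(ctor())
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      stop("unknown ", block, " config key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    do.call(ctor, args)
  }
  top <- y[setdiff(names(y), c("sim", "cleaning", "model", "postprocess"))]
  bad <- setdiff(names(top), names(formals(pipeline_config)))
  if (length(bad))
    stop("unknown pipeline config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config,
          c(top, list(sim = build("sim", sim_config),
                      cleaning = build("cleaning", cleaning_config),
                      model = build("model", model_config),
                      postprocess = build("postprocess",
                                          postprocess_config))))
}

meal_tag <- function(i) sprintf("meal_%03d", i)

artifact_paths <- function(out_dir) {
  list(keypoints = file.path(out_dir, "keypoints"),
       annotations = file.path(out_dir, "annotations"),
       features = file.path(out_dir, "features"),
       clips = file.path(out_dir, "clips.rds"),
       model = file.path(out_dir, "model.rds"),
       detections = file.path(out_dir, "detections"),
       summaries = file.path(out_dir, "summaries"),
       metrics = file.path(out_dir, "metrics.json"),
       manifest = file.path(out_dir, "manifest.json"))
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing artifact ", path, ": run the '", produced_by,
         "' stage first", call. = FALSE)
  path
}

#' Run the staged bite-detection pipeline
#'
#' Executes the requested stages in dependency order against an artifact
#' directory; each stage reads the artifacts of its upstream stage from
#' disk, so stages can be re-run individually.  A manifest recording the
#' full configuration, seed and package version is written alongside the
#' artifacts.  Re-running with an identical configuration and seed
#' reproduces identical summaries.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir artifact directory (created if needed).
#' @param stages subset of
#'   \code{simulate, preprocess, make-clips, train, detect, analyze,
#'   evaluate} (default: all, in order).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the per-meal summaries and, when the
#'   evaluate stage ran, the agreement metrics.
#' @export
run_pipeline <- function(config, out_dir, stages = PIPELINE_STAGES,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  pa <- artifact_paths(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  tags <- vapply(seq_len(config$n_meals), meal_tag, character(1L))
  result <- list()

  if ("simulate" %in% stages) {
    say("[simulate] %d meals of %.0f s", config$n_meals,
        config$sim$duration_s)
    dir.create(pa$keypoints, showWarnings = FALSE)
    dir.create(pa$annotations, showWarnings = FALSE)
    for (i in seq_len(config$n_meals)) {
      sc <- config$sim
      sc$seed <- config$seed + i - 1L
      m <- simulate_meal(sc)
      write_keypoints(m$sequence, file.path(pa$keypoints,
                                            paste0(tags[i], ".csv")),
                      dialect = "csv_flat")
      write_annotations(m$log, file.path(pa$annotations,
                                         paste0(tags[i], ".csv")))
    }
  }

  if ("preprocess" %in% stages) {
    say("[preprocess] cleaning, smoothing, feature assembly")
    dir.create(pa$features, showWarnings = FALSE)
    for (tg in tags) {
      kp <- require_artifact(file.path(pa$keypoints, paste0(tg, ".csv")),
                             "simulate")
      feats <- preprocess_sequence(read_keypoints(kp, "csv_flat"),
                                   config$cleaning)
      saveRDS(feats, file.path(pa$features, paste0(tg, ".rds")))
    }
  }

  if ("make-clips" %in% stages) {
    say("[make-clips] window %.1f s, negative stride %.1f s",
        config$window_s, config$negative_stride_s)
    sets <- lapply(tags, function(tg) {
      feats <- readRDS(require_artifact(
        file.path(pa$features, paste0(tg, ".rds")), "preprocess"))
      log <- read_annotations(require_artifact(
        file.path(pa$annotations, paste0(tg, ".csv")), "simulate"))
      extract_labeled_clips(feats, log, config$window_s,
                            config$negative_stride_s)
    })
    clips <- combine_clips(sets, meal_ids = tags)
    saveRDS(clips, pa$clips)
    say("[make-clips] %d clips (%d bite / %d not_bite)", n_clips(clips),
        sum(clips$labels == "bite"), sum(clips$labels == "not_bite"))
  }

  if ("train" %in% stages) {
    clips <- readRDS(require_artifact(pa$clips, "make-clips"))
    sp <- split_clips(clips, config$train_fraction, seed = config$seed)
    mc <- config$model
    mc$seed <- config$seed
    say("[train] %d train / %d eval clips, %d epochs",
        n_clips(sp$train), n_clips(sp$eval), mc$epochs)
    model <- train_model(sp$train, mc)
    eval_p <- predict_bite_prob(model, sp$eval)
    eval_cm <- confusion_from_labels(sp$eval$labels == "bite",
                                     eval_p > 0.5)
    saveRDS(list(model = model, eval_confusion = eval_cm), pa$model)
    result$eval_metrics <- confusion_metrics(eval_cm)
    say("[train] held-out clip kappa %.3f", result$eval_metrics$kappa)
  }

  if ("detect" %in% stages) {
    md <- readRDS(require_artifact(pa$model, "train"))
    dir.create(pa$detections, showWarnings = FALSE)
    say("[detect] sliding-window inference over %d meals", length(tags))
    for (tg in tags) {
      feats <- readRDS(require_artifact(
        file.path(pa$features, paste0(tg, ".rds")), "preprocess"))
      sig <- probability_signal(md$model, feats)
      det <- extract_bites(sig, config$postprocess)
      write_annotations(det, file.path(pa$detections, paste0(tg, ".csv")))
    }
  }

  if ("analyze" %in% stages) {
    say("[analyze] per-meal summaries")
    dir.create(pa$summaries, showWarnings = FALSE)
    result$summaries <- lapply(tags, function(tg) {
      out <- list()
      man <- read_annotations(require_artifact(
        file.path(pa$annotations, paste0(tg, ".csv")), "simulate"))
      out$manual <- meal_summary(man)
      dpath <- file.path(pa$detections, paste0(tg, ".csv"))
      if (file.exists(dpath)) {
        det <- read_annotations(dpath, source = "detected")
        if (sum(det$event == "bite") > 0) {
          out$detected <- meal_summary(det)
          write_behavior_log(out$detected, det,
                            file.path(pa$summaries, paste0(tg, ".csv")),
                            fit = fit_quadratic(out$detected$segment_counts))
        }
      }
      out
    })
    names(result$summaries) <- tags
  }

  if ("evaluate" %in% stages) {
    say("[evaluate] event matching and per-meal correlations")
    per_meal <- lapply(tags, function(tg) {
      man <- read_annotations(require_artifact(
        file.path(pa$annotations, paste0(tg, ".csv")), "simulate"))
      det <- read_annotations(require_artifact(
        file.path(pa$detections, paste0(tg, ".csv")), "detect"),
        source = "detected")
      ref <- annotation_log(bite_times(man),
                            rep("bite", length(bite_times(man))),
                            source = "manual", fps = attr(man, "fps"))
      mt <- match_events(det, ref, config$match_tolerance_s)
      list(match = mt, true_bites = length(bite_times(man)),
           detected_bites = length(bite_times(det)))
    })
    tp <- sum(vapply(per_meal, function(m) m$match$tp, numeric(1L)))
    fp <- sum(vapply(per_meal, function(m) m$match$fp, numeric(1L)))
    fn <- sum(vapply(per_meal, function(m) m$match$fn, numeric(1L)))
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    truth <- vapply(per_meal, function(m) m$true_bites, numeric(1L))
    found <- vapply(per_meal, function(m) m$detected_bites, numeric(1L))
    bite_cor <- if (length(truth) >= 3L && stats::var(truth) > 0 &&
                    stats::var(found) > 0)
      correlate_measures(truth, found) else NULL
    result$event_metrics <- list(tp = tp, fp = fp, fn = fn,
                                 precision = prec, recall = rec, f1 = f1,
                                 bite_count_correlation = bite_cor,
                                 per_meal = per_meal)
    metrics_out <- list(event_f1 = f1, event_precision = prec,
                        event_recall = rec,
                        bites_r = if (!is.null(bite_cor)) bite_cor$r
                                  else NA_real_)
    if (!is.null(result$eval_metrics))
      metrics_out$clip_kappa <- result$eval_metrics$kappa
    jsonlite::write_json(metrics_out, pa$metrics, auto_unbox = TRUE,
                         digits = NA)
    say("[evaluate] event F1 %.3f, bite-count r %s", f1,
        if (!is.null(bite_cor)) sprintf("%.3f", bite_cor$r) else "NA")
  }

  manifest <- list(package = "bitewise",
                   version = as.character(utils::packageVersion("bitewise")),
                   seed = config$seed,
                   stages = stages,
                   config = config_to_list(config))
  jsonlite::write_json(manifest, pa$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(result)
}

config_to_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(config)
}
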