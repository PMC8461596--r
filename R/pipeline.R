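# End-to-end pipeline: simulate -> preprocess -> split -> expand -> train ->
# score -> fit Hotelling -> detect -> evaluate.

#' Pipeline configuration
#'
#' Collects every stage's parameters with the study defaults: the hourly
#' 8:00-23:00 protocol, subA-like face, 0.8 degC periorbital breath-hold
#' response, 90/10 split with 60 test normals and 20 test anomalies, 10,000
#' learning patches, the standard patch VAE (latent 6, 15 epochs, batch 128), 100
#' scoring patches per image, and detection probabilities 30% down to 5%.
#'
#' @param subject_profile `"subA_like"` or `"subB_like"`.
#' @param protocol A [protocol_config()].
#' @param anomaly An [anomaly_model()].
#' @param vae A [vae_config()].
#' @param expansion_count Learning patches (default 10000 for subA-like,
#'   50000 for subB-like).
#' @param learning_fraction,test_count Normal-data split (defaults 0.9, 60).
#' @param n_test_anomaly Anomaly test samples (default 20, one session's
#'   anomaly window).
#' @param n_patches Scoring patches per test image (default 100).
#' @param p_targets Detection probabilities for the per-threshold confusion
#'   counts.
#' @param dof Chi-square degrees of freedom (default 2).
#' @param n_restarts Seed-grid size for best-model selection (default 3,
#'   see [select_best_vae()]; 1 = single training).
#' @param seed Master seed; every stage seed is derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(subject_profile = c("subA_like", "subB_like"),
                            protocol = protocol_config(),
                            anomaly = anomaly_model(),
                            vae = vae_config(),
                            expansion_count = NULL,
                            learning_fraction = 0.9,
                            test_count = 60L,
                            n_test_anomaly = 20L,
                            n_patches = 100L,
                            p_targets = c(0.30, 0.25, 0.20, 0.15, 0.10, 0.05),
                            dof = 2L,
                            n_restarts = 3L,
                            seed = 0L) {
  subject_profile <- match.arg(subject_profile)
  if (is.null(expansion_count)) {
    expansion_count <- if (subject_profile == "subA_like") 10000L else 50000L
  }
  structure(
    list(subject_profile = subject_profile, protocol = protocol,
         anomaly = anomaly, vae = vae,
         expansion_count = as.integer(expansion_count),
         learning_fraction = learning_fraction,
         test_count = as.integer(test_count),
         n_test_anomaly = as.integer(n_test_anomaly),
         n_patches = as.integer(n_patches), p_targets = p_targets,
         dof = as.integer(dof), n_restarts = as.integer(n_restarts),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

#' Run the full anomaly-detection pipeline
#'
#' Simulates the protocol for one synthetic subject, preprocesses the frames
#' into normalized FTIs, splits the normal data, expands the learning set
#' into 8x8 patches, trains the patch VAE, reduces the 60 + 20 test images
#' to log-scale score statistics, fits the Hotelling model on the normal
#' statistics, and evaluates detection (Shapiro-Wilk gate, per-probability
#' confusion counts, ROC/AUC).  Fully reproducible from the config.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return An object of class `fst_pipeline`: the fitted `model`
#'   (`trained_vae`), `hotelling` (`hotelling_model`), tibbles `stats` and
#'   `detections`, the `roc` (`roc_result`), `normality` gate row, and a
#'   `summary` list of scalar results.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  sd <- derive_seeds(config$seed, 6L)

  say("simulating protocol ...")
  face <- face_model(seed = sd[1], subject_profile = config$subject_profile)
  protocol <- config$protocol
  protocol$seed <- sd[2]
  frames <- simulate_protocol(face, protocol, config$anomaly)

  say("preprocessing ", nrow(frames), " frames ...")
  ftis <- preprocess_frames(frames)
  normal <- dplyr::filter(ftis, .data$label == "Normal")
  split <- split_normal(normal, config$learning_fraction, config$test_count,
                        seed = sd[3])

  # Test anomalies: the anomaly window of one randomly chosen session.
  anom_all <- dplyr::filter(ftis, .data$label == "Anomaly")
  hour_pick <- withr::with_seed(sd[4], sample(unique(anom_all$session_hour), 1L))
  anom_test <- dplyr::slice_tail(
    dplyr::filter(anom_all, .data$session_hour == hour_pick),
    n = config$n_test_anomaly
  )

  say("expanding ", config$expansion_count, " learning patches ...")
  learning <- build_learning_set(split$learning, config$expansion_count,
                                 seed = sd[5])

  say("training VAE (", config$vae$epochs, " epochs) ...")
  vae_cfg <- config$vae
  vae_cfg$seed <- sd[6] %% 2147480000L
  model <- if (config$n_restarts > 1L) {
    select_best_vae(learning, vae_cfg, config$n_restarts)
  } else {
    train_vae(learning, vae_cfg)
  }

  say("scoring test set ...")
  test_set <- dplyr::bind_rows(split$test, anom_test)
  stats <- score_dataset(test_set, model, n_patches = config$n_patches,
                         seed = sd[4])

  normal_stats <- dplyr::filter(stats, .data$label == "Normal")
  gate <- normality_gate(normal_stats, warn = FALSE)
  hot <- fit_hotelling(normal_stats, dof = config$dof)
  detections <- purrr::map_dfr(config$p_targets,
                               ~ detect_anomalies(stats, hot, .x))
  roc <- roc_auc(detect_anomalies(stats, hot, config$p_targets[1]))

  confusion <- detections |>
    dplyr::group_by(.data$p_target) |>
    dplyr::summarise(
      true_positive = sum(.data$label == "Anomaly" &
                            .data$decision == "Anomaly"),
      false_positive = sum(.data$label == "Normal" &
                             .data$decision == "Anomaly"),
      true_negative = sum(.data$label == "Normal" &
                            .data$decision == "Normal"),
      false_negative = sum(.data$label == "Anomaly" &
                             .data$decision == "Normal"),
      .groups = "drop"
    )

  summary <- list(
    subject_profile = config$subject_profile,
    n_frames = nrow(frames),
    n_normal_frames = sum(frames$label == "Normal"),
    n_learning = nrow(split$learning),
    n_test_normal = nrow(split$test),
    n_test_anomaly = nrow(anom_test),
    n_learning_patches = nrow(learning$x),
    final_loss = model$loss_history[length(model$loss_history)],
    shapiro_p_log_mean = gate$p_log_mean,
    shapiro_p_log_var = gate$p_log_var,
    shapiro_passed = gate$passed,
    auc = roc$auc,
    seed = config$seed
  )

  structure(
    list(config = config, model = model, hotelling = hot, stats = stats,
         detections = detections, confusion = confusion, roc = roc,
         normality = gate, summary = summary),
    class = "fst_pipeline"
  )
}

#' @export
print.fst_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<fst_pipeline>", s$subject_profile, "| seed", s$seed, "\n")
  cat("  frames:", s$n_frames, "(", s$n_normal_frames, "normal ) | learning FTIs:",
      s$n_learning, "| patches:", s$n_learning_patches, "\n")
  cat("  test: ", s$n_test_normal, "normal +", s$n_test_anomaly, "anomaly\n")
  cat("  final loss:", format(s$final_loss, digits = 5),
      "| Shapiro passed:", s$shapiro_passed,
      "| AUC:", format(s$auc, digits = 4), "\n")
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x An `fst_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble of the scalar summary fields.
#' @method glance fst_pipeline
#' @export
glance.fst_pipeline <- function(x, ...) {
  tibble::as_tibble(x$summary)
}

#' Plot a pipeline run's detection plane
#'
#' @param object An `fst_pipeline`.
#' @param ... Unused.
#' @return A ggplot object, see [plot_detection_plane()].
#' @method autoplot fst_pipeline
#' @export
autoplot.fst_pipeline <- function(object, ...) {
  plot_detection_plane(object$stats, object$hotelling,
                       object$config$p_targets)
}

#' Write the machine-readable pipeline summary
#'
#' Serializes the scalar summary plus the per-probability confusion counts
#' as JSON, alongside the resolved configuration.
#'
#' @param pipeline An `fst_pipeline`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_pipeline_summary <- function(pipeline, path) {
  jsonlite::write_json(
    list(summary = pipeline$summary,
         confusion = pipeline$confusion,
         config = serialize_config(pipeline$config)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

serialize_config <- function(config) {
  list(
    subject_profile = config$subject_profile,
    protocol = unclass(config$protocol),
    anomaly = list(delta_temp_c = config$anomaly$delta_temp_c,
                   onset_s = config$anomaly$onset_s,
                   spatial_profile = config$anomaly$spatial_profile),
    vae = unclass(config$vae),
    expansion_count = config$expansion_count,
    learning_fraction = config$learning_fraction,
    test_count = config$test_count,
    n_test_anomaly = config$n_test_anomaly,
    n_patches = config$n_patches,
    p_targets = config$p_targets,
    dof = config$dof,
    n_restarts = config$n_restarts,
    seed = config$seed
  )
}

#' Build a pipeline configuration from a YAML file
#'
#' Reads a YAML document whose top-level keys mirror the arguments of
#' [pipeline_config()] (nested `protocol`, `anomaly` and `vae` blocks are
#' passed to their constructors); missing keys keep their defaults.
#'
#' @param path Path to the YAML file.
#' @param overrides Named list applied on top of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  args <- raw
  if (!is.null(raw$protocol)) {
    args$protocol <- do.call(protocol_config, raw$protocol)
  }
  if (!is.null(raw$anomaly)) {
    args$anomaly <- do.call(anomaly_model, raw$anomaly)
  }
  if (!is.null(raw$vae)) args$vae <- do.call(vae_config, raw$vae)
  do.call(pipeline_config, args)
}
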