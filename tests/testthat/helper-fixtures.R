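# Shared fixtures, built lazily and memoized so expensive objects (trained
# models, pipeline runs) are constructed once per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Small face + short protocol used by unit tests.
tiny_face <- function(noise = 0.05, seed = 7L) {
  face_model(seed = seed, subject_profile = "subA_like",
             noise_sigma_c = noise)
}

tiny_protocol <- function(seed = 11L) {
  protocol_config(hours = c(9L, 15L, 21L), rest_duration_s = 40L,
                  task_duration_s = 30L, anomaly_window_s = 10L, seed = seed)
}

# A small VAE trained on patches from a few synthetic normal FTIs.
tiny_vae <- function() {
  memo("tiny_vae", {
    face <- tiny_face(seed = 3L)
    frames <- simulate_protocol(face, protocol_config(hours = c(10L, 18L),
                                                      rest_duration_s = 10L,
                                                      seed = 5L))
    ftis <- preprocess_frames(dplyr::filter(frames, label == "Normal"))
    patches <- build_learning_set(ftis, 1280L, seed = 2L)
    train_vae(patches, vae_config(epochs = 4L, batch_size = 64L, seed = 9L))
  })
}

# One normalized FTI not used for training.
tiny_fti <- function() {
  memo("tiny_fti", {
    face <- tiny_face(seed = 3L)
    withr::with_seed(21L, normalize_fti(render_frame(face, hour = 13)))
  })
}

# Reduced end-to-end pipeline configuration (sizes small enough for test
# runs; the default-scale pipeline is exercised by the acceptance tests).
small_pipeline_config <- function(seed = 1L, delta = 1.5, ...) {
  pipeline_config(
    protocol = tiny_protocol(),
    anomaly = anomaly_model(delta_temp_c = delta),
    vae = vae_config(epochs = 3L, batch_size = 64L),
    expansion_count = 1200L,
    test_count = 12L,
    n_test_anomaly = 10L,
    n_patches = 40L,
    n_restarts = 1L,
    seed = seed,
    ...
  )
}

# Full-scale pipeline runs shared between acceptance criteria.  A single
# training per seed (n_restarts = 1) keeps the suite's cost down; the
# criteria already aggregate over three independent pipeline seeds.
default_pipeline_run <- function(seed, delta = 0.8) {
  memo(sprintf("pipeline_%d_%g", seed, delta), {
    run_pipeline(pipeline_config(
      anomaly = anomaly_model(delta_temp_c = delta), seed = seed,
      n_restarts = 1L
    ))
  })
}
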