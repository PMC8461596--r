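# Synthetic facial thermal image time series.
#
# The generator emulates a day-long infrared thermography protocol: one
# session per hour, each with a resting segment (normal frames) followed by a
# breath-hold task whose tail is labelled anomalous.  A face is an elliptical
# warm region on a cool background, textured with curvilinear warm "vessels"
# (sub-patch-scale vascular pattern), modulated by a sinusoidal diurnal drift,
# and observed through i.i.d. Gaussian sensor noise.

#' Measurement-protocol configuration
#'
#' Defaults reproduce a 16-session day (hourly, 8:00-23:00) with 120 s of
#' rest at 1 Hz per session (1920 normal frames in total) and a 60 s
#' breath-hold task whose last 20 s are anomaly frames.
#'
#' @param hours Integer session hours (default `8:23`).
#' @param rest_duration_s Rest-segment length in seconds (default 120).
#' @param task_duration_s Task-segment length in seconds (default 60).
#' @param anomaly_window_s Seconds at the end of the task labelled Anomaly
#'   (default 20).
#' @param sampling_hz Frames per second (default 1).
#' @param seed Integer seed for the frame noise stream.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(hours = 8:23, rest_duration_s = 120L,
                            task_duration_s = 60L, anomaly_window_s = 20L,
                            sampling_hz = 1L, seed = 0L) {
  stopifnot(length(hours) >= 1L, rest_duration_s >= 1L, task_duration_s >= 1L,
            sampling_hz >= 1L, anomaly_window_s >= 0L,
            anomaly_window_s <= task_duration_s)
  structure(
    list(hours = as.integer(hours),
         rest_duration_s = as.integer(rest_duration_s),
         task_duration_s = as.integer(task_duration_s),
         anomaly_window_s = as.integer(anomaly_window_s),
         sampling_hz = as.integer(sampling_hz), seed = as.integer(seed)),
    class = "protocol_config"
  )
}

#' Breath-hold anomaly model
#'
#' The forced skin-temperature response is a smooth monotone ramp: zero until
#' `onset_s`, then the cubic smoothstep of rescaled task time, reaching
#' `delta_temp_c` at task end.  `spatial_profile` selects where the heat
#' appears: `"periorbital_focus"` concentrates it in two periorbital
#' Gaussian blobs (the default; a spatially uniform shift inside the face is
#' largely removed by per-image min-max normalization), `"global_shift"`
#' warms the whole face uniformly.
#'
#' @param delta_temp_c Peak temperature change in degC (default 0.8).
#' @param onset_s Seconds into the task before the response starts
#'   (default 10).
#' @param spatial_profile `"periorbital_focus"` or `"global_shift"`.
#' @return A list of class `anomaly_model` with a `ramp(t, duration)`
#'   function satisfying `ramp(0) = 0`, `ramp(duration) = 1`, non-decreasing.
#' @export
anomaly_model <- function(delta_temp_c = 0.8, onset_s = 10,
                          spatial_profile = c("periorbital_focus",
                                              "global_shift")) {
  spatial_profile <- match.arg(spatial_profile)
  stopifnot(delta_temp_c >= 0, onset_s >= 0)
  ramp <- function(t, duration) {
    u <- pmin(pmax((t - onset_s) / (duration - onset_s), 0), 1)
    3 * u^2 - 2 * u^3
  }
  structure(
    list(delta_temp_c = delta_temp_c, onset_s = onset_s,
         spatial_profile = spatial_profile, ramp = ramp),
    class = "anomaly_model"
  )
}

#' Generate a synthetic face model
#'
#' A reproducible per-subject face: an elliptical mask strictly inside the
#' image, a vessel field of random smooth warm curves (quadratic Bezier
#' centrelines with Gaussian cross-sections, amplitudes 0.3-0.6 degC, widths
#' 1-3 px), a sinusoidal diurnal drift and the anomaly spatial profile.
#' The two built-in profiles differ in FTI size: `"subA_like"` is 90 x 83
#' and `"subB_like"` 73 x 94 pixels.
#'
#' @param seed Non-negative integer seed; the model is a pure function of
#'   `(seed, subject_profile)`.
#' @param subject_profile `"subA_like"` or `"subB_like"`.
#' @param base_temp_c Mean facial temperature in degC (default 34).
#' @param background_temp_c Room-temperature background in degC
#'   (default 22.1).
#' @param diurnal_amplitude_c Amplitude of the sinusoidal diurnal component
#'   in degC (default 0.3).
#' @param diurnal_phase_h Phase in hours; the default 11 puts the diurnal
#'   peak at 17:00.
#' @param noise_sigma_c Per-pixel Gaussian sensor-noise standard deviation in
#'   degC (default 0.05, the sensor's temperature resolution); may be 0 for
#'   noise-free renders.
#' @param n_vessels Number of vessel curves (default 8).
#' @return A list of class `face_model` including the boolean `mask`, the
#'   precomputed `vessel_field` (degC) and the periorbital profile matrix.
#' @export
face_model <- function(seed = 0L,
                       subject_profile = c("subA_like", "subB_like"),
                       base_temp_c = 34.0, background_temp_c = 22.1,
                       diurnal_amplitude_c = 0.3, diurnal_phase_h = 11,
                       noise_sigma_c = 0.05, n_vessels = 8L) {
  subject_profile <- match.arg(subject_profile)
  stopifnot(seed >= 0, noise_sigma_c >= 0, diurnal_amplitude_c >= 0)
  dims <- switch(subject_profile,
                 subA_like = c(90L, 83L),
                 subB_like = c(73L, 94L))
  h <- dims[1]
  w <- dims[2]
  withr::with_seed(as.integer(seed), {
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    cy <- h / 2 + stats::runif(1, -1, 1)
    cx <- w / 2 + stats::runif(1, -1, 1)
    ay <- 0.44 * h
    ax <- 0.42 * w
    el <- ((rr - cy) / ay)^2 + ((cc - cx) / ax)^2
    mask <- el <= 1

    # Vessel field: max over curves of amplitude * exp(-d^2 / (2 width^2)),
    # d = distance to the sampled Bezier centreline.
    field <- matrix(0, h, w)
    for (v in seq_len(n_vessels)) {
      th <- stats::runif(3, 0, 2 * pi)
      rad <- stats::runif(3, 0.2, 0.85)
      py <- cy + rad * ay * sin(th)
      px <- cx + rad * ax * cos(th)
      tt <- seq(0, 1, length.out = 160L)
      by <- (1 - tt)^2 * py[1] + 2 * (1 - tt) * tt * py[2] + tt^2 * py[3]
      bx <- (1 - tt)^2 * px[1] + 2 * (1 - tt) * tt * px[2] + tt^2 * px[3]
      amp <- stats::runif(1, 0.3, 0.6)
      wid <- stats::runif(1, 1, 3)
      d2 <- matrix(Inf, h, w)
      for (s in seq_along(tt)) {
        d2 <- pmin(d2, (rr - by[s])^2 + (cc - bx[s])^2)
      }
      field <- pmax(field, amp * exp(-d2 / (2 * wid^2)))
    }
    field[!mask] <- 0

    # Periorbital anomaly profile: two Gaussian blobs, peak value 1.
    ey <- cy - 0.35 * ay
    ex1 <- cx - 0.40 * ax
    ex2 <- cx + 0.40 * ax
    sg <- 0.12 * min(h, w)
    blob <- exp(-((rr - ey)^2 + (cc - ex1)^2) / (2 * sg^2)) +
      exp(-((rr - ey)^2 + (cc - ex2)^2) / (2 * sg^2))
    blob <- blob / max(blob)
    blob[!mask] <- 0

    structure(
      list(height_px = h, width_px = w, subject_profile = subject_profile,
           seed = as.integer(seed), mask = mask, vessel_field = field,
           periorbital_profile = blob, base_temp_c = base_temp_c,
           background_temp_c = background_temp_c,
           diurnal_amplitude_c = diurnal_amplitude_c,
           diurnal_phase_h = diurnal_phase_h, noise_sigma_c = noise_sigma_c),
      class = "face_model"
    )
  })
}

anomaly_profile_matrix <- function(face, spatial_profile) {
  switch(spatial_profile,
         global_shift = face$mask * 1,
         periorbital_focus = face$periorbital_profile,
         stop("invalid argument: unknown spatial_profile '", spatial_profile,
              "'", call. = FALSE))
}

#' Render one thermal frame
#'
#' Deterministic scene plus sensor noise: background temperature outside the
#' face mask; inside the mask
#' `base + diurnal_amplitude * sin(2*pi*(hour - phase)/24) + vessel field +
#' anomaly_strength * delta_temp_c * spatial profile`; i.i.d. Gaussian noise
#' with sd `noise_sigma_c` everywhere.  Noise is drawn from R's current RNG
#' stream; seed the caller (or use [simulate_protocol()]) for
#' reproducibility.
#'
#' @param face A [face_model()].
#' @param hour Session hour (real; used by the diurnal sinusoid).
#' @param anomaly Optional [anomaly_model()]; required when
#'   `anomaly_strength > 0`.
#' @param anomaly_strength Scalar in \[0, 1\] scaling the anomaly term.
#' @return A matrix of temperatures in degC (`height_px` x `width_px`).
#' @export
render_frame <- function(face, hour, anomaly = NULL, anomaly_strength = 0) {
  stopifnot(anomaly_strength >= 0, anomaly_strength <= 1)
  px <- matrix(face$background_temp_c, face$height_px, face$width_px)
  diurnal <- face$diurnal_amplitude_c *
    sin(2 * pi * (hour - face$diurnal_phase_h) / 24)
  px[face$mask] <- face$base_temp_c + diurnal
  px <- px + face$vessel_field
  if (anomaly_strength > 0) {
    if (is.null(anomaly)) {
      stop("anomaly model required when anomaly_strength > 0", call. = FALSE)
    }
    px <- px + anomaly_strength * anomaly$delta_temp_c *
      anomaly_profile_matrix(face, anomaly$spatial_profile)
  }
  if (face$noise_sigma_c > 0) {
    px <- px + matrix(stats::rnorm(length(px), sd = face$noise_sigma_c),
                      nrow(px), ncol(px))
  }
  px
}

#' Simulate the full measurement protocol
#'
#' Emits, for every session hour, `rest_duration_s * sampling_hz` resting
#' frames labelled `Normal`, followed by `task_duration_s * sampling_hz`
#' breath-hold frames whose anomaly strength follows `anomaly$ramp`; task
#' frames in the final `anomaly_window_s` seconds are labelled `Anomaly`,
#' earlier task frames `Unlabeled`.  The whole sequence is a pure function of
#' `(face, protocol, anomaly)` including `protocol$seed`.
#'
#' @param face A [face_model()].
#' @param protocol A [protocol_config()].
#' @param anomaly An [anomaly_model()].
#' @return A tibble with one row per frame: `frame_id`, `subject_id`,
#'   `session_hour`, `segment` (`"Rest"`/`"Task"`), `t_offset_s`, `label`
#'   (`"Normal"`/`"Anomaly"`/`"Unlabeled"`) and the list-column `pixels`
#'   (degC matrices), in chronological order.
#' @export
simulate_protocol <- function(face, protocol = protocol_config(),
                              anomaly = anomaly_model()) {
  stopifnot(inherits(face, "face_model"),
            inherits(protocol, "protocol_config"),
            inherits(anomaly, "anomaly_model"))
  dt <- 1 / protocol$sampling_hz
  n_rest <- protocol$rest_duration_s * protocol$sampling_hz
  n_task <- protocol$task_duration_s * protocol$sampling_hz
  anom_start <- protocol$task_duration_s - protocol$anomaly_window_s
  withr::with_seed(protocol$seed, {
    rows <- vector("list", length(protocol$hours))
    for (k in seq_along(protocol$hours)) {
      hr <- protocol$hours[k]
      t_rest <- (seq_len(n_rest) - 1L) * dt
      t_task <- (seq_len(n_task) - 1L) * dt
      seg <- c(rep("Rest", n_rest), rep("Task", n_task))
      toff <- c(t_rest, t_task)
      strength <- c(rep(0, n_rest),
                    anomaly$ramp(t_task, protocol$task_duration_s))
      label <- c(rep("Normal", n_rest),
                 ifelse(t_task >= anom_start, "Anomaly", "Unlabeled"))
      pix <- vector("list", n_rest + n_task)
      for (i in seq_along(pix)) {
        pix[[i]] <- render_frame(face, hr, anomaly, strength[i])
      }
      rows[[k]] <- tibble::tibble(
        frame_id = sprintf("%s_h%02d_%s_%03d", face$subject_profile, hr,
                           tolower(seg),
                           c(seq_len(n_rest), seq_len(n_task)) - 1L),
        subject_id = face$subject_profile,
        session_hour = hr,
        segment = seg,
        t_offset_s = toff,
        label = label,
        pixels = pix
      )
    }
    dplyr::bind_rows(rows)
  })
}
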