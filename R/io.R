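# Plain-file interchange: 32-bit float TIFF frame stacks with a sidecar
# metadata CSV, and CSV score-statistic / detection tables.

#' Write a frame stack to disk
#'
#' One 32-bit float single-band TIFF per frame plus `metadata.csv`.  TIFF
#' samples are stored in \[0, 1\]; each frame's temperatures are packed
#' affinely and the per-frame `t_min_c` / `t_max_c` recorded in the sidecar
#' so [read_frames()] restores degC exactly (up to float32 precision).
#'
#' @param frames A frame tibble from [simulate_protocol()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(frames, dir) {
  stopifnot(is.data.frame(frames), "pixels" %in% names(frames))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t_min <- vapply(frames$pixels, min, numeric(1))
  t_max <- vapply(frames$pixels, max, numeric(1))
  for (i in seq_len(nrow(frames))) {
    rng <- t_max[i] - t_min[i]
    packed <- if (rng > 0) (frames$pixels[[i]] - t_min[i]) / rng
              else frames$pixels[[i]] * 0
    tiff::writeTIFF(packed, file.path(dir, paste0(frames$frame_id[i], ".tif")),
                    bits.per.sample = 32L)
  }
  meta <- dplyr::mutate(dplyr::select(frames, -"pixels"),
                        t_min_c = t_min, t_max_c = t_max,
                        file = paste0(.data$frame_id, ".tif"))
  readr::write_csv(meta, file.path(dir, "metadata.csv"))
  invisible(dir)
}

#' @rdname write_frames
#' @param dir Directory written by [write_frames()] (or user-supplied data
#'   in the same schema).
#' @return `read_frames()` returns the frame tibble with temperatures in
#'   degC.
#' @export
read_frames <- function(dir) {
  meta <- readr::read_csv(file.path(dir, "metadata.csv"),
                          show_col_types = FALSE)
  pixels <- purrr::pmap(
    list(meta$file, meta$t_min_c, meta$t_max_c),
    function(f, lo, hi) {
      m <- tiff::readTIFF(file.path(dir, f))
      lo + m * (hi - lo)
    }
  )
  meta$pixels <- pixels
  dplyr::select(meta, -"file", -"t_min_c", -"t_max_c")
}

#' Write / read score statistics as CSV
#'
#' @param stats A score-statistic tibble from [score_dataset()].
#' @param path CSV path.
#' @return The path (write) or the tibble (read).
#' @export
write_score_stats <- function(stats, path) {
  readr::write_csv(stats, path)
  invisible(path)
}

#' @rdname write_score_stats
#' @export
read_score_stats <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(frame_id = "c", label = "c"))
}
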