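# FTI preprocessing: cropping, per-image min-max normalization, and 8x8
# patch extraction/expansion for VAE learning and scoring.

PATCH_SIZE <- 8L

#' Crop a facial region from a thermal frame
#'
#' Coordinates are 0-based and half-open: the crop covers rows
#' `[row0, row0 + height)` and columns `[col0, col0 + width)`.
#'
#' @param pixels Temperature matrix in degC (or a one-row frame tibble's
#'   `pixels[[1]]`).
#' @param roi Integer vector `c(row0, col0, height, width)`; `NULL` keeps the
#'   full frame.
#' @return The cropped temperature matrix.
#' @export
crop_fti <- function(pixels, roi = NULL) {
  stopifnot(is.matrix(pixels))
  if (is.null(roi)) return(pixels)
  stopifnot(length(roi) == 4L)
  row0 <- roi[1]; col0 <- roi[2]; h <- roi[3]; w <- roi[4]
  if (h < PATCH_SIZE || w < PATCH_SIZE) {
    stop("invalid roi: smaller than one ", PATCH_SIZE, "x", PATCH_SIZE,
         " patch", call. = FALSE)
  }
  if (row0 < 0 || col0 < 0 || row0 + h > nrow(pixels) ||
      col0 + w > ncol(pixels)) {
    stop("invalid roi: outside the frame bounds", call. = FALSE)
  }
  pixels[(row0 + 1):(row0 + h), (col0 + 1):(col0 + w), drop = FALSE]
}

#' Min-max normalize a cropped facial thermal image
#'
#' Applies `(x - min) / (max - min)` so that the coldest pixel is exactly 0
#' and the hottest exactly 1; the map is affine and order-preserving, making
#' the FTI invariant to any affine transform of the input temperatures
#' (sensor offset/gain, room-temperature bias).
#'
#' @param pixels Temperature matrix in degC.
#' @return A matrix in \[0, 1\].
#' @export
normalize_fti <- function(pixels) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  rng <- range(pixels)
  if (rng[1] == rng[2]) {
    stop("degenerate image: constant temperature, min-max normalization ",
         "undefined", call. = FALSE)
  }
  (pixels - rng[1]) / (rng[2] - rng[1])
}

#' Crop and normalize a stack of frames
#'
#' Data-frame-in, data-frame-out wrapper: applies [crop_fti()] and
#' [normalize_fti()] to every frame of a [simulate_protocol()] tibble.
#'
#' @param frames A frame tibble with a `pixels` list-column.
#' @param roi Optional crop passed to [crop_fti()] (default: full frame, the
#'   synthetic frames being already face-sized).
#' @return The same tibble with `pixels` replaced by normalized FTIs in
#'   \[0, 1\].
#' @export
preprocess_frames <- function(frames, roi = NULL) {
  stopifnot(is.data.frame(frames), "pixels" %in% names(frames))
  dplyr::mutate(frames,
                pixels = purrr::map(.data$pixels,
                                    ~ normalize_fti(crop_fti(.x, roi))))
}

#' Extract random 8x8 patches from one FTI
#'
#' Patch corners are drawn uniformly (with replacement) over every valid
#' 0-based top-left position, i.e. `row0` in `0..(height-8)` and `col0` in
#' `0..(width-8)`; patch pixels are copied unchanged from the FTI.
#'
#' @param fti A normalized FTI matrix (at least 8x8).
#' @param count Number of patches to draw.
#' @param seed Integer seed making the draw reproducible.
#' @param frame_id Optional source identifier stored with the patches.
#' @param role `"learning"` or `"scoring"`.
#' @return A `patch_set`: list with `x` (count x 64 matrix of flattened
#'   patches, column-major within the 8x8 window), `coords` (tibble
#'   `source_frame_id`, `row0`, `col0`), `role` and `seed`.
#' @export
extract_patches <- function(fti, count, seed = 0L, frame_id = "fti",
                            role = c("scoring", "learning")) {
  role <- match.arg(role)
  stopifnot(is.matrix(fti), count >= 1L)
  if (nrow(fti) < PATCH_SIZE || ncol(fti) < PATCH_SIZE) {
    stop("invalid input: FTI smaller than ", PATCH_SIZE, "x", PATCH_SIZE,
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    nr <- nrow(fti) - PATCH_SIZE + 1L
    nc <- ncol(fti) - PATCH_SIZE + 1L
    row0 <- sample.int(nr, count, replace = TRUE) - 1L
    col0 <- sample.int(nc, count, replace = TRUE) - 1L
    x <- gather_patches(fti, row0, col0)
    new_patch_set(x,
                  tibble::tibble(source_frame_id = frame_id, row0 = row0,
                                 col0 = col0),
                  role, as.integer(seed))
  })
}

gather_patches <- function(fti, row0, col0) {
  n <- length(row0)
  x <- matrix(0, n, PATCH_SIZE * PATCH_SIZE)
  for (i in seq_len(n)) {
    x[i, ] <- fti[(row0[i] + 1L):(row0[i] + PATCH_SIZE),
                  (col0[i] + 1L):(col0[i] + PATCH_SIZE)]
  }
  x
}

new_patch_set <- function(x, coords, role, seed) {
  structure(list(x = x, coords = coords, role = role, seed = seed),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("<patch_set>", nrow(x$x), "patches | role =", x$role,
      "| sources =", length(unique(x$coords$source_frame_id)), "\n")
  invisible(x)
}

as_patch_matrix <- function(patches) {
  if (inherits(patches, "patch_set")) return(patches$x)
  if (is.matrix(patches) && all(dim(patches) == PATCH_SIZE)) {
    return(matrix(as.vector(patches), 1L))
  }
  if (is.matrix(patches) && ncol(patches) == PATCH_SIZE * PATCH_SIZE) {
    return(patches)
  }
  stop("invalid input: expected a patch_set, an 8x8 matrix, or an N x 64 ",
       "matrix", call. = FALSE)
}

#' Expand normal FTIs into a learning patch set
#'
#' Draws `expansion_count` patches in total, cycling uniformly over the
#' source FTIs (counts per image differ by at most one, assignment
#' shuffled), with uniformly random corners within each image.
#'
#' @param ftis A preprocessed FTI tibble (rows are Normal frames) with
#'   `frame_id` and `pixels` columns.
#' @param expansion_count Total number of patches, e.g. 10000 or 50000.
#' @param seed Integer seed.
#' @return A `patch_set` with `role = "learning"`.
#' @export
build_learning_set <- function(ftis, expansion_count, seed = 0L) {
  stopifnot(is.data.frame(ftis), expansion_count >= 1L)
  if (nrow(ftis) == 0L) {
    stop("invalid input: empty FTI list", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    n <- nrow(ftis)
    src <- sample(rep_len(seq_len(n), expansion_count))
    xs <- vector("list", n)
    coords <- vector("list", n)
    for (k in seq_len(n)) {
      cnt <- sum(src == k)
      if (cnt == 0L) next
      fti <- ftis$pixels[[k]]
      nr <- nrow(fti) - PATCH_SIZE + 1L
      nc <- ncol(fti) - PATCH_SIZE + 1L
      row0 <- sample.int(nr, cnt, replace = TRUE) - 1L
      col0 <- sample.int(nc, cnt, replace = TRUE) - 1L
      xs[[k]] <- gather_patches(fti, row0, col0)
      coords[[k]] <- tibble::tibble(source_frame_id = ftis$frame_id[k],
                                    row0 = row0, col0 = col0)
    }
    new_patch_set(do.call(rbind, xs), dplyr::bind_rows(coords),
                  "learning", as.integer(seed))
  })
}

#' Split normal FTIs into learning and test sets
#'
#' A seeded random disjoint split: `learning_fraction` of the images go to
#' the learning set, and `test_count` images are subsampled uniformly from
#' the held-out remainder.  With the default protocol (1920 normal FTIs,
#' fraction 0.9, 60 test images) this gives 1728 learning FTIs and 60 test
#' FTIs out of the 192 held out.
#'
#' @param ftis A preprocessed FTI tibble of normal frames.
#' @param learning_fraction Fraction used for learning (default 0.9).
#' @param test_count Number of held-out images kept for testing (default 60).
#' @param seed Integer seed.
#' @return A list with tibbles `learning` and `test` (disjoint by
#'   `frame_id`).
#' @export
split_normal <- function(ftis, learning_fraction = 0.9, test_count = 60L,
                         seed = 0L) {
  stopifnot(is.data.frame(ftis), learning_fraction > 0, learning_fraction < 1)
  n <- nrow(ftis)
  n_learn <- floor(learning_fraction * n)
  n_hold <- n - n_learn
  if (test_count > n_hold) {
    stop("invalid split: test_count (", test_count,
         ") exceeds the held-out size (", n_hold, ")", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    perm <- sample.int(n)
    learn_idx <- perm[seq_len(n_learn)]
    hold_idx <- perm[(n_learn + 1L):n]
    test_idx <- sort(sample(hold_idx, test_count))
    list(learning = ftis[sort(learn_idx), , drop = FALSE],
         test = ftis[test_idx, , drop = FALSE])
  })
}
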