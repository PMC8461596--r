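# Unregularized anomaly scoring: per-patch reconstruction error at z = mu_z,
# reduced per image to the log-scale (mean, variance) statistic vector.

#' Unregularized anomaly score of a reconstruction
#'
#' The reconstruction-error half of the VAE objective,
#' \eqn{L(x) = \sum_i (\mu_{xi} - x_i)^2 / (2 \sigma^2_{xi})},
#' with no KL regularization term and no log-variance term.
#'
#' @param x Observed pixel vector (or matrix, one observation per row).
#' @param mu_x Reconstruction mean, same shape as `x`.
#' @param sigma2_x Per-pixel reconstruction variance, same shape.
#' @return Numeric vector of non-negative scores, one per row.
#' @export
unregularized_score <- function(x, mu_x, sigma2_x) {
  if (is.null(dim(x))) {
    x <- matrix(x, 1L)
    mu_x <- matrix(mu_x, 1L)
    sigma2_x <- matrix(sigma2_x, 1L)
  }
  stopifnot(all(sigma2_x > 0))
  r <- mu_x - x
  v <- rowSums(0.5 * r * r / sigma2_x)
  if (!all(is.finite(v))) {
    stop("numerical failure: non-finite anomaly score", call. = FALSE)
  }
  v
}

#' Score patches with a trained VAE
#'
#' Deterministic evaluation of the unregularized anomaly score at
#' `z = mu_z`: each patch is encoded, its latent mean decoded (no sampling),
#' and [unregularized_score()] evaluated against the decoder's per-pixel
#' mean and variance (variance clamped at the model's floor).
#'
#' @param model A `trained_vae`.
#' @param patches A `patch_set`, an 8x8 matrix, or an N x 64 matrix.
#' @return Numeric vector of scores, one per patch.
#' @export
score_patches <- function(model, patches) {
  X <- as_patch_matrix(patches)
  enc <- vae_encode(model, X)
  dec <- vae_decode(model, enc$mu_z)
  unregularized_score(X, dec$mu_x, exp(dec$logvar_x))
}

#' @rdname score_patches
#' @export
score_patch <- function(model, patches) score_patches(model, patches)

#' Reduce one test FTI to its log-scale score statistic
#'
#' Draws `n_patches` random patches ([extract_patches()]), scores each, and
#' returns the natural logarithm of the sample mean and of the unbiased
#' sample variance of the patch scores — the 2-D statistic classified by the
#' Hotelling detector.  The log scale tames the score's heavy upper tail.
#'
#' @param model A `trained_vae`.
#' @param fti A normalized FTI matrix.
#' @param n_patches Number of patches per image (default 100; must be >= 2
#'   for the variance to exist).
#' @param seed Integer seed for the patch draw.
#' @param frame_id,label Metadata copied into the result.
#' @return A one-row tibble: `frame_id`, `label`, `n_patches`, `log_mean`,
#'   `log_var`.
#' @export
score_fti <- function(model, fti, n_patches = 100L, seed = 0L,
                      frame_id = "fti", label = "Unlabeled") {
  stopifnot(n_patches >= 2L)
  ps <- extract_patches(fti, n_patches, seed = seed, frame_id = frame_id)
  sc <- score_patches(model, ps)
  v <- stats::var(sc)
  # relative guard: numerically constant scores have no usable variance
  if (v <= .Machine$double.eps * mean(sc)^2) {
    stop("degenerate statistics: patch scores are constant for frame ",
         frame_id, call. = FALSE)
  }
  tibble::tibble(frame_id = frame_id, label = label,
                 n_patches = as.integer(n_patches),
                 log_mean = log(mean(sc)), log_var = log(v))
}

#' Score a set of test FTIs
#'
#' One [score_fti()] row per image, order-preserving; per-image seeds are
#' derived deterministically from `seed`.
#'
#' @param ftis A preprocessed FTI tibble (`frame_id`, `label`, `pixels`).
#' @param model A `trained_vae`.
#' @param n_patches Patches per image (default 100).
#' @param seed Master integer seed.
#' @return A tibble of score statistics, one row per FTI.
#' @export
score_dataset <- function(ftis, model, n_patches = 100L, seed = 0L) {
  stopifnot(is.data.frame(ftis))
  if (nrow(ftis) == 0L) {
    stop("invalid input: empty FTI list", call. = FALSE)
  }
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max, nrow(ftis)))
  purrr::map_dfr(seq_len(nrow(ftis)), function(i) {
    tryCatch(
      score_fti(model, ftis$pixels[[i]], n_patches = n_patches,
                seed = sub_seeds[i], frame_id = ftis$frame_id[i],
                label = ftis$label[i]),
      error = function(e) {
        stop("scoring failed for frame ", ftis$frame_id[i], ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
  })
}
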