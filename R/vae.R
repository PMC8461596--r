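#' Configuration for the patch VAE
#'
#' Hyperparameters of the convolutional variational autoencoder trained on
#' 8x8 normalized thermal-image patches: a two-convolution Gaussian encoder
#' (16 then 32 filters, 2x2 kernels, stride 2), a mirrored transposed-
#' convolution decoder, and two parallel 4x4 stride-1 output heads emitting
#' the per-pixel reconstruction mean and log-variance.
#'
#' @param latent_dim Dimension of the Gaussian latent variable (default 6).
#' @param epochs Number of training epochs (default 15).
#' @param batch_size Minibatch size (default 128).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed Integer seed controlling weight initialization and shuffling.
#' @param variance_floor Lower bound on the decoder's per-pixel variance;
#'   the log-variance head is clamped at `log(variance_floor)` so the
#'   anomaly score of [score_patches()] stays bounded.
#' @return A list of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 6L, epochs = 15L, batch_size = 128L,
                       learning_rate = 1e-3, seed = 0L,
                       variance_floor = 1e-4) {
  stopifnot(latent_dim >= 1L, batch_size >= 1L, epochs >= 1L,
            learning_rate > 0, variance_floor > 0)
  structure(
    list(latent_dim = as.integer(latent_dim), epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), learning_rate = learning_rate,
         seed = as.integer(seed), variance_floor = variance_floor),
    class = "vae_config"
  )
}

# Fixed 8x8 patch geometry shared by all models; built once per session.
vae_geoms <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(
        g1 = conv_geom(8L, 8L, 1L, 2L, 2L),           # 8x8x1  -> 4x4x16
        g2 = conv_geom(4L, 4L, 16L, 2L, 2L),          # 4x4x16 -> 2x2x32
        gt1 = conv_geom(4L, 4L, 32L, 2L, 2L),         # adjoint: 2x2x32 -> 4x4x32
        gt2 = conv_geom(8L, 8L, 16L, 2L, 2L),         # adjoint: 4x4x32 -> 8x8x16
        gh = conv_geom(8L, 8L, 16L, 4L, 1L,
                       pad = c(1L, 2L, 1L, 2L))       # 8x8x16 -> 8x8x1 heads
      )
    }
    cache
  }
})

vae_init_params <- function(latent_dim) {
  rn <- function(nr, nc, gain = 2) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(gain / nr)), nr, nc)
  }
  list(
    c1_W = rn(4L, 16L), c1_b = numeric(16L),
    bn1_g = rep(1, 16L), bn1_b = numeric(16L),
    c2_W = rn(64L, 32L), c2_b = numeric(32L),
    bn2_g = rep(1, 32L), bn2_b = numeric(32L),
    fc_mu_W = rn(128L, latent_dim, gain = 1), fc_mu_b = numeric(latent_dim),
    fc_lv_W = rn(128L, latent_dim, gain = 1), fc_lv_b = numeric(latent_dim),
    dfc_W = rn(latent_dim, 128L), dfc_b = numeric(128L),
    bn3_g = rep(1, 128L), bn3_b = numeric(128L),
    t1_W = rn(32L, 128L), t1_b = numeric(32L),
    bn4_g = rep(1, 32L), bn4_b = numeric(32L),
    t2_W = rn(32L, 64L), t2_b = numeric(16L),
    bn5_g = rep(1, 16L), bn5_b = numeric(16L),
    hm_W = rn(256L, 1L, gain = 1), hm_b = numeric(1L),
    hl_W = rn(256L, 1L, gain = 1), hl_b = numeric(1L)
  )
}

vae_init_bn_stats <- function() {
  st <- function(C) list(mean = numeric(C), var = rep(1, C))
  list(bn1 = st(16L), bn2 = st(32L), bn3 = st(128L), bn4 = st(32L),
       bn5 = st(16L))
}

# Encoder forward pass on an N x 64 patch matrix.  Returns mu_z, logvar_z
# and (when keep = TRUE) the caches needed for backpropagation.
enc_forward <- function(p, bn, X, training, keep = FALSE) {
  g <- vae_geoms()
  N <- nrow(X)
  x_cm <- matrix(as.vector(X), ncol = 1L)
  c1 <- conv_forward(x_cm, g$g1, p$c1_W, p$c1_b, N)
  b1 <- bn_forward(c1$out, p$bn1_g, p$bn1_b, bn$bn1, training)
  a1 <- relu(b1$out)
  c2 <- conv_forward(a1, g$g2, p$c2_W, p$c2_b, N)
  b2 <- bn_forward(c2$out, p$bn2_g, p$bn2_b, bn$bn2, training)
  a2 <- cm_to_flat(relu(b2$out), N)
  mu_z <- sweep(a2 %*% p$fc_mu_W, 2L, p$fc_mu_b, "+")
  lv_z <- sweep(a2 %*% p$fc_lv_W, 2L, p$fc_lv_b, "+")
  out <- list(mu_z = mu_z, logvar_z = lv_z,
              bn = list(bn1 = b1$stats, bn2 = b2$stats))
  if (keep) {
    out$cache <- list(N = N, c1 = c1, b1 = b1, b1_out = b1$out,
                      c2 = c2, b2 = b2, b2_out = b2$out, a2 = a2)
  }
  out
}

enc_backward <- function(p, cache, dmu_z, dlv_z) {
  g <- vae_geoms()
  N <- cache$N
  a2 <- cache$a2
  gr <- list(
    fc_mu_W = crossprod(a2, dmu_z), fc_mu_b = colSums(dmu_z),
    fc_lv_W = crossprod(a2, dlv_z), fc_lv_b = colSums(dlv_z)
  )
  da2 <- flat_to_cm(dmu_z %*% t(p$fc_mu_W) + dlv_z %*% t(p$fc_lv_W), 32L)
  da2 <- da2 * (cache$b2_out > 0)
  bb2 <- bn_backward(da2, cache$b2, p$bn2_g)
  gr$bn2_g <- bb2$dgamma; gr$bn2_b <- bb2$dbeta
  cb2 <- conv_backward(bb2$dX, cache$c2, g$g2, p$c2_W)
  gr$c2_W <- cb2$dW; gr$c2_b <- cb2$db
  da1 <- cb2$dX * (cache$b1_out > 0)
  bb1 <- bn_backward(da1, cache$b1, p$bn1_g)
  gr$bn1_g <- bb1$dgamma; gr$bn1_b <- bb1$dbeta
  cb1 <- conv_backward(bb1$dX, cache$c1, g$g1, p$c1_W)
  gr$c1_W <- cb1$dW; gr$c1_b <- cb1$db
  gr
}

# Decoder forward pass on an N x latent_dim matrix.  logvar_x is clamped to
# log(variance_floor) from below; `clamped` marks saturated entries so their
# gradient is zeroed in the backward pass.
dec_forward <- function(p, bn, Z, training, variance_floor, keep = FALSE) {
  g <- vae_geoms()
  N <- nrow(Z)
  h0 <- sweep(Z %*% p$dfc_W, 2L, p$dfc_b, "+")
  b3 <- bn_forward(h0, p$bn3_g, p$bn3_b, bn$bn3, training)
  a3 <- flat_to_cm(relu(b3$out), 32L)
  t1 <- tconv_forward(a3, g$gt1, p$t1_W, p$t1_b, N)
  b4 <- bn_forward(t1$out, p$bn4_g, p$bn4_b, bn$bn4, training)
  a4 <- relu(b4$out)
  t2 <- tconv_forward(a4, g$gt2, p$t2_W, p$t2_b, N)
  b5 <- bn_forward(t2$out, p$bn5_g, p$bn5_b, bn$bn5, training)
  a5 <- relu(b5$out)
  hm <- head_forward(a5, g$gh, p$hm_W, p$hm_b, N)
  hl <- head_forward(a5, g$gh, p$hl_W, p$hl_b, N)
  lv_floor <- log(variance_floor)
  mu_x <- hm$out
  lv_x <- hl$out
  clamped <- lv_x < lv_floor
  lv_x[clamped] <- lv_floor
  out <- list(mu_x = mu_x, logvar_x = lv_x,
              bn = list(bn3 = b3$stats, bn4 = b4$stats, bn5 = b5$stats))
  if (keep) {
    out$cache <- list(N = N, Z = Z, b3 = b3, b3_out = b3$out, t1 = t1,
                      b4 = b4, b4_out = b4$out, t2 = t2, b5 = b5,
                      b5_out = b5$out, hm = hm, hl = hl, clamped = clamped)
  }
  out
}

dec_backward <- function(p, cache, dmu_x, dlv_x) {
  g <- vae_geoms()
  N <- cache$N
  dlv_x[cache$clamped] <- 0
  ch_m <- head_backward(dmu_x, cache$hm, g$gh, p$hm_W)
  ch_l <- head_backward(dlv_x, cache$hl, g$gh, p$hl_W)
  gr <- list(hm_W = ch_m$dW, hm_b = ch_m$db, hl_W = ch_l$dW, hl_b = ch_l$db)
  da5 <- (ch_m$dX + ch_l$dX) * (cache$b5_out > 0)
  bb5 <- bn_backward(da5, cache$b5, p$bn5_g)
  gr$bn5_g <- bb5$dgamma; gr$bn5_b <- bb5$dbeta
  tb2 <- tconv_backward(bb5$dX, cache$t2, g$gt2, p$t2_W)
  gr$t2_W <- tb2$dW; gr$t2_b <- tb2$db
  da4 <- tb2$dX * (cache$b4_out > 0)
  bb4 <- bn_backward(da4, cache$b4, p$bn4_g)
  gr$bn4_g <- bb4$dgamma; gr$bn4_b <- bb4$dbeta
  tb1 <- tconv_backward(bb4$dX, cache$t1, g$gt1, p$t1_W)
  gr$t1_W <- tb1$dW; gr$t1_b <- tb1$db
  da3 <- cm_to_flat(tb1$dX, N) * (cache$b3_out > 0)
  bb3 <- bn_backward(da3, cache$b3, p$bn3_g)
  gr$bn3_g <- bb3$dgamma; gr$bn3_b <- bb3$dbeta
  gr$dfc_W <- crossprod(cache$Z, bb3$dX)
  gr$dfc_b <- colSums(bb3$dX)
  gr$dZ <- bb3$dX %*% t(p$dfc_W)
  gr
}

#' Evidence-lower-bound loss of the patch VAE
#'
#' Per-patch negative ELBO (up to the additive Gaussian constant):
#' reconstruction term
#' \eqn{\sum_i (\mu_{xi} - x_i)^2 / (2\sigma^2_{xi}) + \log(\sigma^2_{xi})/2}
#' plus the closed-form KL divergence of the diagonal-Gaussian posterior from
#' the standard-normal prior,
#' \eqn{\sum_j (\mu_{zj}^2 + e^{l_j} - l_j - 1)/2} with
#' \eqn{l_j = \log \sigma^2_{zj}}.
#'
#' @param x N x 64 matrix of flattened patches.
#' @param mu_x,logvar_x N x 64 reconstruction mean and log-variance.
#' @param mu_z,logvar_z N x d latent mean and log-variance.
#' @return A list with numeric vectors `recon`, `kl` and `total` (one entry
#'   per patch).
#' @export
vae_elbo <- function(x, mu_x, logvar_x, mu_z, logvar_z) {
  r <- mu_x - x
  recon <- rowSums(0.5 * r * r * exp(-logvar_x) + 0.5 * logvar_x)
  kl <- 0.5 * rowSums(mu_z^2 + exp(logvar_z) - logvar_z - 1)
  if (!all(is.finite(recon)) || !all(is.finite(kl))) {
    stop("numerical failure: non-finite ELBO terms", call. = FALSE)
  }
  list(recon = recon, kl = kl, total = recon + kl)
}

# One training step: forward, loss, full backward.  Returns mean loss and
# parameter gradients (mean over the batch).  eps is the N x d standard
# normal draw used by the reparameterization trick.
vae_step <- function(p, bn, X, eps, variance_floor) {
  N <- nrow(X)
  enc <- enc_forward(p, bn, X, training = TRUE, keep = TRUE)
  bn[c("bn1", "bn2")] <- enc$bn
  sd_z <- exp(0.5 * enc$logvar_z)
  Z <- enc$mu_z + sd_z * eps
  dec <- dec_forward(p, bn, Z, training = TRUE, variance_floor, keep = TRUE)
  bn[c("bn3", "bn4", "bn5")] <- dec$bn
  loss <- vae_elbo(X, dec$mu_x, dec$logvar_x, enc$mu_z, enc$logvar_z)
  r <- dec$mu_x - X
  inv_var <- exp(-dec$logvar_x)
  dmu_x <- r * inv_var / N
  dlv_x <- (0.5 - 0.5 * r * r * inv_var) / N
  grd <- dec_backward(p, dec$cache, dmu_x, dlv_x)
  dZ <- grd$dZ
  grd$dZ <- NULL
  # KL gradients plus reparameterization chain rule
  dmu_z <- dZ + enc$mu_z / N
  dlv_z <- dZ * eps * 0.5 * sd_z + 0.5 * (exp(enc$logvar_z) - 1) / N
  gre <- enc_backward(p, enc$cache, dmu_z, dlv_z)
  list(loss = mean(loss$total), grads = c(gre, grd), bn = bn)
}

#' Train the patch VAE on a learning set
#'
#' Minibatch Adam optimization of the negative ELBO ([vae_elbo()]) for a
#' fixed number of epochs.  Weight initialization, the per-epoch shuffle and
#' the reparameterization noise all flow from `config$seed`, so the returned
#' model and its loss history are reproducible bit for bit.
#'
#' @param patches A `patch_set` from [build_learning_set()] or
#'   [extract_patches()], or a plain numeric matrix with one flattened 8x8
#'   patch per row (64 columns, values in \[0, 1\]).
#' @param config A [vae_config()].
#' @return An object of class `trained_vae`: weights, batchnorm running
#'   statistics, the config, and `loss_history` with one mean per-patch loss
#'   per epoch.
#' @seealso [select_best_vae()] for seed-grid model selection,
#'   [score_patches()] for the anomaly score.
#' @export
train_vae <- function(patches, config = vae_config()) {
  X <- as_patch_matrix(patches)
  if (inherits(patches, "patch_set") && !identical(patches$role, "learning")) {
    warning("training on a patch set whose role is not 'learning'",
            call. = FALSE)
  }
  if (nrow(X) < config$batch_size) {
    stop("learning set smaller than one batch (", nrow(X), " < ",
         config$batch_size, ")", call. = FALSE)
  }
  d <- config$latent_dim
  withr::with_seed(config$seed, {
    p <- vae_init_params(d)
    bn <- vae_init_bn_stats()
    opt <- adam_init(p)
    n <- nrow(X)
    nb <- n %/% config$batch_size
    loss_history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      epoch_loss <- 0
      for (b in seq_len(nb)) {
        rows <- idx[((b - 1L) * config$batch_size + 1L):(b * config$batch_size)]
        Xb <- X[rows, , drop = FALSE]
        eps <- matrix(stats::rnorm(length(rows) * d), length(rows), d)
        st <- vae_step(p, bn, Xb, eps, config$variance_floor)
        if (!is.finite(st$loss)) {
          stop("training failure: non-finite loss at epoch ", epoch,
               call. = FALSE)
        }
        bn <- st$bn
        upd <- adam_step(p, st$grads, opt, config$learning_rate)
        p <- upd$params
        opt <- upd$state
        epoch_loss <- epoch_loss + st$loss
      }
      loss_history[epoch] <- epoch_loss / nb
    }
    structure(
      list(params = p, bn = bn, config = config,
           loss_history = loss_history),
      class = "trained_vae"
    )
  })
}

#' Train several VAEs and keep the best
#'
#' Trains one model per seed in a small grid (`config$seed + 0:(n_restarts-1)`)
#' and returns the model with the lowest final-epoch training loss, the
#' usual remedy for the optimization instability of small VAEs.
#'
#' @inheritParams train_vae
#' @param n_restarts Number of seeds in the grid (default 3).
#' @return The best `trained_vae`; the attribute `final_losses` records the
#'   final loss of every candidate.
#' @export
select_best_vae <- function(patches, config = vae_config(), n_restarts = 3L) {
  stopifnot(n_restarts >= 1L)
  fits <- lapply(seq_len(n_restarts) - 1L, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    train_vae(patches, cfg)
  })
  finals <- vapply(fits, function(f) f$loss_history[length(f$loss_history)],
                   numeric(1))
  best <- fits[[which.min(finals)]]
  attr(best, "final_losses") <- finals
  best
}

#' Encode patches to their latent Gaussian parameters
#'
#' Deterministic inference-mode forward pass through the encoder
#' (batchnorm uses running statistics).
#'
#' @param model A `trained_vae`.
#' @param patches A `patch_set`, a single 8x8 matrix, or an N x 64 matrix.
#' @return A list with matrices `mu_z` and `logvar_z` (N x latent_dim).
#' @export
vae_encode <- function(model, patches) {
  X <- as_patch_matrix(patches)
  enc <- enc_forward(model$params, model$bn, X, training = FALSE)
  list(mu_z = enc$mu_z, logvar_z = enc$logvar_z)
}

#' Decode latent vectors to per-pixel Gaussian parameters
#'
#' @param model A `trained_vae`.
#' @param z A latent vector of length `latent_dim` or an N x latent_dim
#'   matrix.
#' @return A list with matrices `mu_x` and `logvar_x` (N x 64; `logvar_x`
#'   is clamped at `log(variance_floor)`).
#' @export
vae_decode <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$config$latent_dim) {
    stop("invalid input: z must have length latent_dim = ",
         model$config$latent_dim, call. = FALSE)
  }
  dec <- dec_forward(model$params, model$bn, z, training = FALSE,
                     model$config$variance_floor)
  list(mu_x = dec$mu_x, logvar_x = dec$logvar_x)
}

#' Reparameterization draw from the latent posterior
#'
#' `z = mu_z + exp(logvar_z / 2) * eps` with `eps ~ N(0, I)`; used during
#' training only (scoring evaluates at `z = mu_z`).
#'
#' @param enc A list with `mu_z` and `logvar_z` (vectors or matrices).
#' @param seed Optional integer seed for a reproducible draw.
#' @return A matrix (or vector) of latent samples shaped like `mu_z`.
#' @export
vae_reparameterize <- function(enc, seed = NULL) {
  mu <- enc$mu_z
  lv <- enc$logvar_z
  vec <- is.null(dim(mu))
  if (vec) {
    mu <- matrix(mu, 1L)
    lv <- matrix(lv, 1L)
  }
  draw <- function() {
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
    mu + exp(0.5 * lv) * eps
  }
  z <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (vec) drop(z) else z
}

#' @export
print.trained_vae <- function(x, ...) {
  cat("<trained_vae> latent_dim =", x$config$latent_dim,
      "| epochs =", x$config$epochs,
      "| final loss =", format(x$loss_history[length(x$loss_history)],
                               digits = 5), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a patch VAE
#'
#' @param x A `trained_vae`.
#' @param ... Unused.
#' @return A tibble with columns `epoch` and `loss`.
#' @method tidy trained_vae
#' @export
tidy.trained_vae <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' One-row summary of a trained patch VAE
#'
#' @param x A `trained_vae`.
#' @param ... Unused.
#' @return A one-row tibble: latent dimension, epochs, batch size, number of
#'   parameters, and first/final epoch loss.
#' @method glance trained_vae
#' @export
glance.trained_vae <- function(x, ...) {
  tibble::tibble(
    latent_dim = x$config$latent_dim,
    epochs = x$config$epochs,
    batch_size = x$config$batch_size,
    n_parameters = sum(vapply(x$params, length, integer(1))),
    first_loss = x$loss_history[1],
    final_loss = x$loss_history[length(x$loss_history)]
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the training loss curve
#'
#' @param object A `trained_vae`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom rlang .data
#' @method autoplot trained_vae
#' @export
autoplot.trained_vae <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Epoch", y = "Mean per-patch loss",
                  title = "VAE training history")
}

#' Save / load a trained patch VAE
#'
#' The checkpoint is an RDS file of the weights plus a JSON sidecar holding
#' the configuration and loss history.
#'
#' @param model A `trained_vae`.
#' @param path Path of the `.rds` checkpoint; the sidecar is `path` with a
#'   `.json` extension appended.
#' @return `save_vae()` returns `path` invisibly; `load_vae()` the model.
#' @export
save_vae <- function(model, path) {
  saveRDS(model[c("params", "bn")], path)
  jsonlite::write_json(
    list(config = unclass(model$config), loss_history = model$loss_history),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  core <- readRDS(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(vae_config, as.list(side$config))
  structure(
    list(params = core$params, bn = core$bn, config = cfg,
         loss_history = as.numeric(side$loss_history)),
    class = "trained_vae"
  )
}
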