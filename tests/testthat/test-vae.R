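# Patch VAE: architecture shapes, ELBO closed forms, gradients, training.

test_that("encoder compresses 8x8 through the 4x4 / 2x2 chain to latent 6", {
  g <- thermovae:::vae_geoms()
  expect_equal(c(g$g1$oh, g$g1$ow), c(4L, 4L))
  expect_equal(c(g$g2$oh, g$g2$ow), c(2L, 2L))
  m <- tiny_vae()
  patch <- matrix(runif(64), 8, 8)
  enc <- vae_encode(m, patch)
  expect_equal(dim(enc$mu_z), c(1L, 6L))
  expect_equal(dim(enc$logvar_z), c(1L, 6L))
  expect_true(all(is.finite(enc$mu_z)) && all(is.finite(enc$logvar_z)))
  # deterministic inference pass
  expect_identical(enc, vae_encode(m, patch))
  expect_error(vae_encode(m, matrix(0, 5, 5)), "invalid")
})

test_that("decoder upsamples 2x2 -> 4x4 -> 8x8 into paired 8x8 heads", {
  g <- thermovae:::vae_geoms()
  expect_equal(c(g$gt1$h, g$gt1$w, g$gt1$P), c(4L, 4L, 4L))
  expect_equal(c(g$gt2$h, g$gt2$w, g$gt2$P), c(8L, 8L, 16L))
  expect_equal(c(g$gh$oh, g$gh$ow), c(8L, 8L))   # stride-1 heads keep 8x8
  m <- tiny_vae()
  dec <- vae_decode(m, rnorm(6))
  expect_equal(dim(dec$mu_x), c(1L, 64L))
  expect_equal(dim(dec$logvar_x), c(1L, 64L))
  expect_true(all(dec$logvar_x >= log(m$config$variance_floor)))
  expect_error(vae_decode(m, rnorm(5)), "latent_dim")
})

test_that("ELBO matches its closed forms", {
  x <- matrix(runif(64), 1, 64)
  zero6 <- matrix(0, 1, 6)
  # perfect reconstruction with unit variance and prior-matched posterior
  l <- vae_elbo(x, x, matrix(0, 1, 64), zero6, zero6)
  expect_equal(l$total, 0)
  # KL of N((1,0,...,0), I) from N(0, I) is 1/2
  mu <- matrix(c(1, rep(0, 5)), 1)
  expect_equal(vae_elbo(x, x, matrix(0, 1, 64), mu, zero6)$kl, 0.5)
  # reconstruction term is quadratic in the residual
  mu_x <- x + 0.1
  r1 <- vae_elbo(x, mu_x, matrix(0, 1, 64), zero6, zero6)$recon
  r2 <- vae_elbo(x, x + 0.2, matrix(0, 1, 64), zero6, zero6)$recon
  expect_equal(r2, 4 * r1)
  # KL is non-negative for random posteriors
  withr::with_seed(5, {
    for (i in 1:20) {
      kl <- vae_elbo(x, x, matrix(0, 1, 64),
                     matrix(rnorm(6), 1), matrix(rnorm(6), 1))$kl
      expect_gte(kl, 0)
    }
  })
})

test_that("reparameterization has standard-normal moments and collapses
           at zero variance", {
  enc <- list(mu_z = matrix(0, 1e5, 6), logvar_z = matrix(0, 1e5, 6))
  z <- vae_reparameterize(enc, seed = 1)
  expect_true(all(abs(colMeans(z)) < 4 / sqrt(1e5)))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 0.02))
  # variance -> 0 limit returns the mean
  enc0 <- list(mu_z = c(1, 2, 3, 4, 5, 6), logvar_z = rep(-80, 6))
  expect_equal(vae_reparameterize(enc0, seed = 2), c(1, 2, 3, 4, 5, 6),
               tolerance = 1e-12)
  expect_identical(vae_reparameterize(enc, seed = 3),
                   vae_reparameterize(enc, seed = 3))
})

test_that("analytic gradients agree with numerical differentiation", {
  ns <- asNamespace("thermovae")
  withr::with_seed(12, {
    X <- matrix(runif(6 * 64), 6, 64)
    p <- ns$vae_init_params(6L)
    bn <- ns$vae_init_bn_stats()
    eps <- matrix(rnorm(6 * 6), 6, 6)
  })
  st <- ns$vae_step(p, bn, X, eps, 1e-4)
  lossfn <- function(pp) {
    enc <- ns$enc_forward(pp, bn, X, training = TRUE)
    Z <- enc$mu_z + exp(0.5 * enc$logvar_z) * eps
    dec <- ns$dec_forward(pp, bn, Z, training = TRUE, 1e-4)
    mean(vae_elbo(X, dec$mu_x, dec$logvar_x, enc$mu_z, enc$logvar_z)$total)
  }
  h <- 1e-5
  for (nm in names(p)) {
    idx <- withr::with_seed(42, sample(length(p[[nm]]),
                                       min(3, length(p[[nm]]))))
    for (i in idx) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h; f1 <- lossfn(pp)
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] - h; f2 <- lossfn(pp)
      num <- (f1 - f2) / (2 * h)
      expect_equal(st$grads[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("training is seeded, records one loss per epoch, and improves", {
  m <- tiny_vae()
  expect_length(m$loss_history, m$config$epochs)
  expect_true(all(is.finite(m$loss_history)))
  expect_lte(m$loss_history[length(m$loss_history)], m$loss_history[1])
  # bit-identical retrain under the same seed and data
  face <- tiny_face(seed = 3L)
  frames <- simulate_protocol(face, protocol_config(hours = c(10L, 18L),
                                                    rest_duration_s = 10L,
                                                    seed = 5L))
  ftis <- preprocess_frames(dplyr::filter(frames, label == "Normal"))
  patches <- build_learning_set(ftis, 1280L, seed = 2L)
  m2 <- train_vae(patches, vae_config(epochs = 4L, batch_size = 64L,
                                      seed = 9L))
  expect_identical(m$loss_history, m2$loss_history)
  expect_identical(m$params, m2$params)
  expect_error(train_vae(patches$x[1:10, ], vae_config()), "batch")
})

test_that("on constant Gaussian texture the decoder learns mean and
           variance of the texture", {
  X <- withr::with_seed(99,
    matrix(pmin(pmax(rnorm(2000 * 64, 0.5, 0.05), 0), 1), 2000, 64))
  m <- memo("texture_vae",
            train_vae(X, vae_config(epochs = 6L, batch_size = 64L,
                                    seed = 1)))
  enc <- vae_encode(m, X[1:50, ])
  dec <- vae_decode(m, enc$mu_z)
  expect_equal(mean(dec$mu_x), 0.5, tolerance = 0.1)
  s2 <- stats::median(exp(dec$logvar_x))
  expect_gt(s2, 0.05^2 / 2)
  expect_lt(s2, 0.05^2 * 2)
})

test_that("seed-grid selection returns the lowest-final-loss candidate", {
  face <- tiny_face(seed = 3L)
  frames <- simulate_protocol(face, protocol_config(hours = 10L,
                                                    rest_duration_s = 8L,
                                                    seed = 5L))
  ftis <- preprocess_frames(dplyr::filter(frames, label == "Normal"))
  patches <- build_learning_set(ftis, 256L, seed = 2L)
  cfg <- vae_config(epochs = 2L, batch_size = 64L, seed = 100L)
  best <- select_best_vae(patches, cfg, n_restarts = 2L)
  finals <- attr(best, "final_losses")
  expect_length(finals, 2L)
  expect_equal(best$loss_history[length(best$loss_history)], min(finals))
})

test_that("checkpoints round-trip through save_vae/load_vae", {
  m <- tiny_vae()
  path <- withr::local_tempfile(fileext = ".rds")
  save_vae(m, path)
  m2 <- load_vae(path)
  patch <- tiny_fti()[1:8, 1:8]
  expect_equal(score_patches(m2, patch), score_patches(m, patch))
  expect_equal(m2$loss_history, m$loss_history)
})

test_that("tidy/glance/autoplot summarize a trained model", {
  m <- tiny_vae()
  td <- tidy(m)
  expect_equal(nrow(td), m$config$epochs)
  gl <- glance(m)
  expect_equal(gl$latent_dim, 6L)
  expect_gt(gl$n_parameters, 10000)
  expect_s3_class(autoplot(m), "ggplot")
})
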