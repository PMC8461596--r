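# Hotelling model: ML fit, Mahalanobis distance, chi-square thresholds.

stats_tbl <- function(m, v, label = "Normal") {
  tibble::tibble(frame_id = sprintf("f%d", seq_along(m)), label = label,
                 n_patches = 100L, log_mean = m, log_var = v)
}

test_that("ML fit reproduces the hand-computed mean and covariance", {
  st <- stats_tbl(c(0, 2, 0, 2), c(0, 0, 2, 2))
  h <- fit_hotelling(st)
  expect_equal(as.numeric(h$mu_hat), c(1, 1))
  expect_equal(unname(h$sigma), diag(c(1, 1)))
  expect_equal(h$n_fit, 4L)
  # permutation equivariance: swapping the axes swaps the estimates
  h2 <- fit_hotelling(stats_tbl(c(0, 0, 2, 2), c(0, 2, 0, 2)))
  expect_equal(as.numeric(h2$mu_hat), rev(as.numeric(h$mu_hat)))
  expect_equal(unname(h2$sigma), unname(h$sigma[2:1, 2:1]))
  expect_error(fit_hotelling(stats_tbl(rep(1, 5), rep(2, 5))),
               "degenerate covariance")
  expect_error(fit_hotelling(stats_tbl(1, 2)), "at least 3")
  expect_warning(fit_hotelling(stats_tbl(c(0, 2, 1), c(0, 2, 2),
                                         label = "Anomaly")),
                 "Normal")
})

test_that("Mahalanobis distance matches closed forms", {
  h <- structure(list(mu_hat = c(0, 0), sigma = diag(2), dof = 2L,
                      n_fit = 10L), class = "hotelling_model")
  expect_equal(mahalanobis_sq(h, c(3, 4)), 25)
  expect_equal(mahalanobis_sq(h, c(0, 0)), 0)
  hd <- h
  hd$sigma <- diag(c(4, 1))
  expect_equal(mahalanobis_sq(hd, c(2, 0)), 1)
  # batch form agrees with per-row evaluation
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(mahalanobis_sq(hd, X),
               vapply(seq_len(10), function(i) mahalanobis_sq(hd, X[i, ]),
                      numeric(1)))
})

test_that("thresholds agree with a tail-integration oracle", {
  for (dof in c(1L, 2L)) {
    for (p in c(0.30, 0.25, 0.20, 0.15, 0.10, 0.05)) {
      a <- threshold_from_probability(p, dof)
      tail_mass <- stats::integrate(function(u) stats::dchisq(u, dof),
                                    a, Inf, rel.tol = 1e-10)$value
      expect_equal(tail_mass, p, tolerance = 1e-6)
    }
  }
  # printed reference quantiles
  expect_equal(threshold_from_probability(0.05, 1), 3.8415, tolerance = 1e-4)
  expect_equal(threshold_from_probability(0.05, 2), 5.9915, tolerance = 1e-4)
  # strictly decreasing in p; whole distribution flagged as p -> 1
  ps <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(threshold_from_probability(ps, 2)) < 0))
  expect_lt(threshold_from_probability(0.999, 2), 0.01)
  expect_error(threshold_from_probability(0, 2), "p_target")
  expect_error(threshold_from_probability(1, 2), "p_target")
})

test_that("detection uses strict inequality and is monotone in p_target", {
  st <- stats_tbl(c(0, 2, 0, 2, 5), c(0, 0, 2, 2, 6))
  h <- fit_hotelling(st[1:4, ])
  det <- detect_anomalies(st, h, 0.05)
  expect_equal(det$decision, ifelse(det$a_value > det$threshold,
                                    "Anomaly", "Normal"))
  # the fitted centre is Normal at any p
  centre <- stats_tbl(h$mu_hat[1], h$mu_hat[2])
  for (p in c(0.05, 0.3, 0.9)) {
    expect_equal(detect_anomalies(centre, h, p)$decision, "Normal")
  }
  # flagged set at small p is nested in the flagged set at large p
  d05 <- detect_anomalies(st, h, 0.05)
  d30 <- detect_anomalies(st, h, 0.30)
  flagged05 <- d05$frame_id[d05$decision == "Anomaly"]
  flagged30 <- d30$frame_id[d30$decision == "Anomaly"]
  expect_true(all(flagged05 %in% flagged30))
})

test_that("the flagged fraction is chi-square calibrated under the null", {
  fit_sample <- withr::with_seed(10, {
    z <- matrix(rnorm(2000), 1000, 2) %*% chol(rbind(c(1, 0.6), c(0.6, 2)))
    stats_tbl(1 + z[, 1], -2 + z[, 2])
  })
  h <- fit_hotelling(fit_sample)
  draws <- withr::with_seed(11, {
    matrix(rnorm(4e4), 2e4, 2) %*% chol(h$sigma)
  })
  draws <- sweep(draws, 2L, h$mu_hat, "+")
  a <- mahalanobis_sq(h, draws)
  frac <- mean(a > threshold_from_probability(0.05, 2))
  expect_lt(abs(frac - 0.05), 0.006)  # binomial 4-sigma at n = 2e4
})

test_that("the detector is equivariant under affine maps of the plane", {
  st <- withr::with_seed(14, stats_tbl(rnorm(40, 2, 0.5),
                                       rnorm(40, -1, 0.8)))
  h <- fit_hotelling(st)
  a0 <- mahalanobis_sq(h, cbind(st$log_mean, st$log_var))
  withr::with_seed(15, {
    for (k in 1:5) {
      A <- matrix(rnorm(4), 2, 2)
      while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2, 2)
      b <- rnorm(2)
      Xt <- cbind(st$log_mean, st$log_var) %*% t(A) +
        matrix(b, 40, 2, byrow = TRUE)
      st_t <- stats_tbl(Xt[, 1], Xt[, 2])
      h_t <- fit_hotelling(st_t)
      expect_equal(mahalanobis_sq(h_t, Xt), a0, tolerance = 1e-8)
    }
  })
})

test_that("probability contours are nested ellipses with the right axes", {
  h <- structure(list(mu_hat = c(1, -1), sigma = rbind(c(2, 0.8),
                                                       c(0.8, 1)),
                      dof = 2L, n_fit = 60L), class = "hotelling_model")
  cl <- contour_levels(h, c(0.30, 0.05))
  # every contour point sits exactly on its level set
  for (p in c(0.30, 0.05)) {
    pts <- dplyr::filter(cl, p_target == p)
    a <- mahalanobis_sq(h, cbind(pts$log_mean, pts$log_var))
    expect_equal(a, rep(threshold_from_probability(p, 2), nrow(pts)),
                 tolerance = 1e-10)
  }
  # nesting: the 30% contour lies strictly inside the 5% ellipse
  inner <- dplyr::filter(cl, p_target == 0.30)
  a_outer <- threshold_from_probability(0.05, 2)
  expect_true(all(mahalanobis_sq(h, cbind(inner$log_mean, inner$log_var)) <
                    a_outer))
  # isotropic covariance gives circles of radius sqrt(threshold)
  hi <- h
  hi$sigma <- diag(2)
  ci <- contour_levels(hi, 0.05)
  r <- sqrt((ci$log_mean - 1)^2 + (ci$log_var + 1)^2)
  expect_equal(r, rep(sqrt(threshold_from_probability(0.05, 2)), nrow(ci)),
               tolerance = 1e-10)
})

test_that("hotelling models round-trip through JSON and summarize", {
  st <- withr::with_seed(20, stats_tbl(rnorm(30), rnorm(30)))
  h <- fit_hotelling(st)
  path <- withr::local_tempfile(fileext = ".json")
  write_hotelling(h, path)
  h2 <- read_hotelling(path)
  expect_equal(h2$mu_hat, as.numeric(h$mu_hat))
  expect_equal(h2$sigma, unname(h$sigma))
  td <- tidy(h)
  expect_equal(td$term, c("log_mean", "log_var"))
  expect_equal(glance(h)$n_fit, 30L)
})
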