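# Normality gate, ROC/AUC, and detection-plane plotting.

stats_tbl2 <- function(m, v) {
  tibble::tibble(frame_id = sprintf("f%d", seq_along(m)), label = "Normal",
                 n_patches = 100L, log_mean = m, log_var = v)
}

test_that("the Shapiro-Wilk gate accepts Gaussian statistics and rejects
           bimodal ones", {
  # type-I behaviour: both coordinates truly Gaussian, n = 80, 200 reps;
  # pass probability is (1 - 0.05)^2 ~ 0.90
  rate <- withr::with_seed(2026, mean(replicate(200, {
    normality_gate(stats_tbl2(rnorm(80), rnorm(80)), warn = FALSE)$passed
  })))
  expect_gt(rate, 0.85)
  # power: two well-separated modes must fail
  bim <- withr::with_seed(1, c(rnorm(40, -4, 0.3), rnorm(40, 4, 0.3)))
  gate <- normality_gate(stats_tbl2(bim, withr::with_seed(2, rnorm(80))),
                         warn = FALSE)
  expect_false(gate$passed)
  expect_lt(gate$p_log_mean, 0.05)
  expect_warning(normality_gate(stats_tbl2(bim, bim)), "Shapiro")
  expect_error(normality_gate(stats_tbl2(c(1, 2), c(1, 2))), "at least 3")
  expect_error(normality_gate(stats_tbl2(rep(1, 10),
                                         withr::with_seed(3, rnorm(10)))),
               "degenerate")
})

roc_tbl <- function(a, lab) tibble::tibble(a_value = a, label = lab)

# Brute-force pairwise oracle: P(a_anomaly > a_normal) + 0.5 P(tie).
auc_oracle <- function(a, lab) {
  pos <- a[lab == "Anomaly"]
  neg <- a[lab != "Anomaly"]
  g <- outer(pos, neg, ">")
  t <- outer(pos, neg, "==")
  (sum(g) + 0.5 * sum(t)) / (length(pos) * length(neg))
}

test_that("AUC equals the brute-force pair-counting oracle", {
  # ties between classes get half credit
  r <- roc_auc(roc_tbl(c(1, 2, 3, 2), c("Normal", "Normal", "Anomaly",
                                        "Anomaly")))
  expect_equal(r$auc, auc_oracle(c(1, 2, 3, 2),
                                 c("Normal", "Normal", "Anomaly",
                                   "Anomaly")))
  expect_equal(r$auc, 0.875)
  withr::with_seed(7, {
    for (k in 1:10) {
      n <- sample(10:60, 1)
      a <- sample(1:8, n, replace = TRUE) / 2   # plenty of ties
      lab <- sample(c("Normal", "Anomaly"), n, replace = TRUE)
      if (length(unique(lab)) < 2) next
      expect_equal(roc_auc(roc_tbl(a, lab))$auc, auc_oracle(a, lab))
    }
  })
})

test_that("AUC hits 1 under perfect separation and ~0.5 under chance", {
  perf <- roc_tbl(c(1, 2, 3, 10, 11, 12),
                  rep(c("Normal", "Anomaly"), each = 3))
  expect_equal(roc_auc(perf)$auc, 1.0)
  ch <- withr::with_seed(8, roc_tbl(rnorm(2000),
                                    sample(c("Normal", "Anomaly"), 2000,
                                           replace = TRUE)))
  expect_lt(abs(roc_auc(ch)$auc - 0.5), 0.05)
  expect_error(roc_auc(roc_tbl(1:4, rep("Normal", 4))), "both")
})

test_that("rank AUC equals the trapezoidal curve integral exactly", {
  withr::with_seed(9, {
    for (k in 1:10) {
      a <- c(rnorm(30), sample(1:4, 10, replace = TRUE))
      lab <- sample(c("Normal", "Anomaly"), 40, replace = TRUE)
      if (length(unique(lab)) < 2) next
      r <- roc_auc(roc_tbl(a, lab))
      expect_equal(r$auc, thermovae:::trapezoid_auc(r$curve),
                   tolerance = 1e-12)
      # curve endpoints and monotonicity
      expect_equal(r$curve$fpr[1], 0)
      expect_equal(r$curve$tpr[1], 0)
      expect_equal(r$curve$fpr[nrow(r$curve)], 1)
      expect_equal(r$curve$tpr[nrow(r$curve)], 1)
      expect_true(all(diff(r$curve$fpr) >= 0))
      expect_true(all(diff(r$curve$tpr) >= 0))
    }
  })
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::with_seed(10, {
    a <- rexp(50)
    lab <- sample(c("Normal", "Anomaly"), 50, replace = TRUE)
  })
  base <- roc_auc(roc_tbl(a, lab))$auc
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3,
                 function(x) rank(x))) {
    expect_equal(roc_auc(roc_tbl(f(a), lab))$auc, base)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  withr::with_seed(11, {
    a <- c(rnorm(40, 1), rnorm(25, 2.3))
    lab <- rep(c("Normal", "Anomaly"), c(40, 25))
  })
  ours <- roc_auc(roc_tbl(a, lab))$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = as.integer(lab == "Anomaly"), predictor = a,
    direction = "<", quiet = TRUE
  )))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("detection-plane and ROC plots build", {
  st <- withr::with_seed(12, tibble::tibble(
    frame_id = sprintf("f%d", 1:50),
    label = rep(c("Normal", "Anomaly"), c(40, 10)),
    log_mean = c(rnorm(40), rnorm(10, 3)),
    log_var = c(rnorm(40), rnorm(10, 2))
  ))
  h <- fit_hotelling(dplyr::filter(st, label == "Normal"))
  pl <- plot_detection_plane(st, h)
  expect_s3_class(pl, "ggplot")
  built <- ggplot2::ggplot_build(pl)
  # six nested contours by default, plus the scatter layer
  expect_equal(length(unique(built$data[[1]]$group)), 6L)
  pl3 <- plot_detection_plane(st, h, probabilities = c(0.30, 0.20, 0.10))
  expect_equal(length(unique(ggplot2::ggplot_build(pl3)$data[[1]]$group)),
               3L)
  # renders with normal points only
  pl_n <- plot_detection_plane(dplyr::filter(st, label == "Normal"), h)
  expect_s3_class(ggplot2::ggplot_build(pl_n), "ggplot_built")
  r <- roc_auc(detect_anomalies(st, h, 0.05))
  expect_s3_class(autoplot(r), "ggplot")
  expect_equal(glance(r)$n_anomaly, 10L)
})
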