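# Evaluation: Shapiro-Wilk normality gate for the parametric assumption,
# ROC/AUC over the Mahalanobis degree of anomaly, and the detection-plane
# contour plot.

#' Shapiro-Wilk gate for the Gaussian assumption
#'
#' Tests each coordinate of the score statistic (log-scale mean and
#' variance) for normality; the Hotelling model is parametric, so the gate
#' warns — without aborting — when either p-value falls at or below 0.05.
#'
#' @param stats A score-statistic tibble with `log_mean` and `log_var`
#'   (typically the Normal-labelled rows).
#' @param alpha Significance level of the gate (default 0.05).
#' @param warn Emit a warning when the gate fails (default `TRUE`).
#' @return A one-row tibble: `p_log_mean`, `p_log_var`, `passed`.
#' @export
normality_gate <- function(stats, alpha = 0.05, warn = TRUE) {
  stopifnot(is.data.frame(stats))
  if (nrow(stats) < 3L) {
    stop("invalid input: Shapiro-Wilk needs at least 3 statistics",
         call. = FALSE)
  }
  sw <- function(v) {
    if (stats::sd(v) == 0) {
      stop("degenerate statistics: constant sample, normality undefined",
           call. = FALSE)
    }
    stats::shapiro.test(v)$p.value
  }
  p1 <- sw(stats$log_mean)
  p2 <- sw(stats$log_var)
  passed <- min(p1, p2) > alpha
  if (!passed && warn) {
    warning("Shapiro-Wilk gate failed (p = ", format(p1, digits = 3), ", ",
            format(p2, digits = 3), "): the Gaussian assumption behind the ",
            "chi-square thresholds is doubtful", call. = FALSE)
  }
  tibble::tibble(p_log_mean = p1, p_log_var = p2, passed = passed)
}

#' ROC curve and AUC over the degree of anomaly
#'
#' Sweeps a threshold over the observed `a_value`s and computes the AUC by
#' the rank (Mann-Whitney) formulation with half credit for ties, which
#' equals the trapezoidal integral of the ROC curve exactly.
#'
#' @param results A tibble with columns `a_value` and `label`
#'   (`"Anomaly"` = positive class, anything else negative), e.g. from
#'   [detect_anomalies()].
#' @return An object of class `roc_result`: `auc`, `n_normal`, `n_anomaly`,
#'   and `curve` (tibble `threshold`, `fpr`, `tpr` from (0,0) to (1,1)).
#' @export
roc_auc <- function(results) {
  stopifnot(is.data.frame(results), all(c("a_value", "label") %in%
                                          names(results)))
  pos <- results$label == "Anomaly"
  if (!any(pos) || all(pos)) {
    stop("invalid input: ROC needs both Anomaly and non-Anomaly samples",
         call. = FALSE)
  }
  a <- results$a_value
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  # Mann-Whitney with midranks: ties between classes get half credit
  r <- rank(a)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # Explicit curve: decisions a > t for t descending through unique scores
  th <- c(Inf, sort(unique(a), decreasing = TRUE))
  tpr <- vapply(th, function(t) sum(a > t & pos) / n_pos, numeric(1))
  fpr <- vapply(th, function(t) sum(a > t & !pos) / n_neg, numeric(1))
  curve <- tibble::tibble(threshold = c(th, -Inf), fpr = c(fpr, 1),
                          tpr = c(tpr, 1))
  structure(
    list(auc = auc, n_normal = n_neg, n_anomaly = n_pos, curve = curve),
    class = "roc_result"
  )
}

# Trapezoidal integral of a ROC curve; used as an internal cross-check of
# the rank-based AUC (the two agree exactly for step curves with midrank
# tie handling).
trapezoid_auc <- function(curve) {
  o <- order(curve$fpr, curve$tpr)
  x <- curve$fpr[o]
  y <- curve$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC =", format(x$auc, digits = 4), "|", x$n_normal,
      "normal vs", x$n_anomaly, "anomaly\n")
  invisible(x)
}

#' Tidy a ROC result
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return The ROC curve tibble (`threshold`, `fpr`, `tpr`).
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' One-row summary of a ROC result
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return A one-row tibble: `auc`, `n_normal`, `n_anomaly`.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_normal = x$n_normal, n_anomaly = x$n_anomaly)
}

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc))
}

#' Detection-plane plot with probability contours
#'
#' Scatter of the per-image statistics in the (mean, variance) plane of the
#' log-scale unregularized anomaly score, coloured by label and overlaid
#' with the nested detection-probability ellipses of the fitted Hotelling
#' model (inner contours flag larger fractions).
#'
#' @param stats A score-statistic tibble (`log_mean`, `log_var`, `label`).
#' @param model A `hotelling_model`.
#' @param probabilities Contour probabilities, default
#'   `c(0.30, 0.25, 0.20, 0.15, 0.10, 0.05)`.
#' @return A ggplot object.
#' @export
plot_detection_plane <- function(stats, model,
                                 probabilities = c(0.30, 0.25, 0.20, 0.15,
                                                   0.10, 0.05)) {
  ell <- contour_levels(model, probabilities)
  ggplot2::ggplot(stats,
                  ggplot2::aes(x = .data$log_mean, y = .data$log_var)) +
    ggplot2::geom_path(
      data = ell,
      ggplot2::aes(group = factor(.data$p_target)),
      colour = "grey40", linewidth = 0.3
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label, shape = .data$label)) +
    ggplot2::labs(
      x = "Mean of unregularized anomaly score (log scale)",
      y = "Variance of unregularized anomaly score (log scale)",
      colour = NULL, shape = NULL,
      title = "Detection probability contours over score statistics"
    )
}
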