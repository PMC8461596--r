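# Hotelling-theory anomaly detection on the 2-D log-scale score statistics:
# maximum-likelihood Gaussian fit, squared Mahalanobis distance, and
# chi-square back-calculated thresholds.

#' Fit a Hotelling model to normal score statistics
#'
#' Maximum-likelihood estimates of the mean vector and covariance (divide by
#' n, no small-sample correction) of the `(log_mean, log_var)` statistics;
#' the squared Mahalanobis distance of a new statistic is then referred to a
#' chi-square distribution with `dof` degrees of freedom.
#'
#' Hotelling theory for a d-dimensional Gaussian statistic yields chi-square
#' with d degrees of freedom, so the default is `dof = 2` for the 2-D
#' statistic; `dof = 1` is accepted for compatibility with thresholding on a
#' single coordinate.
#'
#' @param stats A score-statistic tibble with columns `log_mean` and
#'   `log_var` (normal-state rows only; rows with other labels trigger a
#'   warning unless `fit_on_all = TRUE`).
#' @param dof Chi-square degrees of freedom (default 2).
#' @param fit_on_all Set `TRUE` to deliberately fit on a mixed-label set.
#' @return An object of class `hotelling_model` with `mu_hat`, `sigma`,
#'   `dof`, `n_fit`.
#' @export
fit_hotelling <- function(stats, dof = 2L, fit_on_all = FALSE) {
  stopifnot(is.data.frame(stats), dof >= 1L)
  if (nrow(stats) < 3L) {
    stop("invalid input: need at least 3 statistics to fit", call. = FALSE)
  }
  if (!fit_on_all && "label" %in% names(stats) &&
      any(stats$label != "Normal")) {
    warning("fitting set contains non-Normal statistics; the null model ",
            "should normally be fit on Normal data only", call. = FALSE)
  }
  X <- cbind(stats$log_mean, stats$log_var)
  stopifnot(all(is.finite(X)))
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sigma <- crossprod(Xc) / n
  if (!is.finite(rc <- rcond(sigma)) || rc < 1e-12) {
    stop("degenerate covariance: statistics have (numerically) zero spread",
         call. = FALSE)
  }
  structure(
    list(mu_hat = mu, sigma = sigma, dof = as.integer(dof), n_fit = n),
    class = "hotelling_model"
  )
}

#' Squared Mahalanobis distance under a Hotelling model
#'
#' The degree of anomaly
#' \eqn{a(x') = (x' - \hat\mu)^T \Sigma^{-1} (x' - \hat\mu)}.
#'
#' @param model A `hotelling_model`.
#' @param x A 2-vector or an N x 2 matrix of statistic vectors.
#' @return Numeric vector of non-negative distances.
#' @export
mahalanobis_sq <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  stopifnot(ncol(x) == 2L)
  stats::mahalanobis(x, center = model$mu_hat, cov = model$sigma)
}

#' Back-calculate the anomaly threshold from a detection probability
#'
#' Solves \eqn{P = \int_{a_{th}}^{\infty} \chi^2_{dof}(u)\,du} for the
#' threshold, i.e. the upper-tail quantile `qchisq(1 - p_target, dof)`:
#' under the fitted normal model a fraction `p_target` of statistics exceeds
#' it.  Strictly decreasing in `p_target`.
#'
#' @param p_target Desired flagged fraction under the null, in (0, 1).
#' @param dof Chi-square degrees of freedom.
#' @return The threshold on the squared Mahalanobis distance.
#' @export
threshold_from_probability <- function(p_target, dof = 2L) {
  if (any(p_target <= 0) || any(p_target >= 1)) {
    stop("invalid argument: p_target must lie in (0, 1)", call. = FALSE)
  }
  stats::qchisq(1 - p_target, df = dof)
}

#' Classify score statistics against a Hotelling threshold
#'
#' Each statistic's squared Mahalanobis distance is compared with the
#' chi-square threshold back-calculated from `p_target`; the decision is
#' `Anomaly` iff `a_value > threshold` (strict inequality, ties to Normal).
#'
#' @param stats A score-statistic tibble (`frame_id`, `label`, `log_mean`,
#'   `log_var`).
#' @param model A `hotelling_model`.
#' @param p_target Detection probability (flagged fraction under the null).
#' @return A tibble: `frame_id`, `label`, `a_value`, `threshold`,
#'   `p_target`, `decision`.
#' @export
detect_anomalies <- function(stats, model, p_target = 0.05) {
  stopifnot(is.data.frame(stats), length(p_target) == 1L)
  a <- mahalanobis_sq(model, cbind(stats$log_mean, stats$log_var))
  th <- threshold_from_probability(p_target, model$dof)
  tibble::tibble(
    frame_id = stats$frame_id,
    label = if ("label" %in% names(stats)) stats$label else "Unlabeled",
    a_value = a,
    threshold = th,
    p_target = p_target,
    decision = ifelse(a > th, "Anomaly", "Normal")
  )
}

#' Probability contours of the fitted normal region
#'
#' For each probability the level set `{x : a(x) = threshold(p)}` is the
#' ellipse centred at `mu_hat` with axes along the eigenvectors of `sigma`
#' and semi-axes `sqrt(lambda_k * threshold)`; smaller probabilities give
#' larger (nested) ellipses.
#'
#' @param model A `hotelling_model`.
#' @param probabilities Detection probabilities, default
#'   `c(0.30, 0.25, 0.20, 0.15, 0.10, 0.05)`.
#' @param n Number of points per ellipse.
#' @return A tibble with columns `p_target`, `threshold`, `log_mean`,
#'   `log_var` tracing each closed contour.
#' @export
contour_levels <- function(model,
                           probabilities = c(0.30, 0.25, 0.20, 0.15, 0.10,
                                             0.05),
                           n = 181L) {
  stopifnot(all(probabilities > 0), all(probabilities < 1))
  eg <- eigen(model$sigma, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = n)
  purrr::map_dfr(probabilities, function(p) {
    th <- threshold_from_probability(p, model$dof)
    pts <- cbind(sqrt(eg$values[1] * th) * cos(theta),
                 sqrt(eg$values[2] * th) * sin(theta)) %*% t(eg$vectors)
    tibble::tibble(p_target = p, threshold = th,
                   log_mean = model$mu_hat[1] + pts[, 1],
                   log_var = model$mu_hat[2] + pts[, 2])
  })
}

#' @export
print.hotelling_model <- function(x, ...) {
  cat("<hotelling_model> d = 2 | dof =", x$dof, "| n_fit =", x$n_fit, "\n")
  cat("  mu_hat =", format(x$mu_hat, digits = 4), "\n")
  invisible(x)
}

#' Tidy a Hotelling model
#'
#' @param x A `hotelling_model`.
#' @param ... Unused.
#' @return A tibble with one row per statistic dimension: mean and
#'   marginal ML variance.
#' @method tidy hotelling_model
#' @export
tidy.hotelling_model <- function(x, ...) {
  tibble::tibble(term = c("log_mean", "log_var"),
                 mean = as.numeric(x$mu_hat),
                 variance = diag(x$sigma))
}

#' One-row summary of a Hotelling model
#'
#' @param x A `hotelling_model`.
#' @param ... Unused.
#' @return A one-row tibble: fitting size, dof, covariance determinant and
#'   correlation.
#' @method glance hotelling_model
#' @export
glance.hotelling_model <- function(x, ...) {
  tibble::tibble(
    n_fit = x$n_fit,
    dof = x$dof,
    det_sigma = det(x$sigma),
    correlation = x$sigma[1, 2] / sqrt(x$sigma[1, 1] * x$sigma[2, 2])
  )
}

#' Persist a Hotelling model as JSON
#'
#' @param model A `hotelling_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly; `read_hotelling()` returns the model.
#' @export
write_hotelling <- function(model, path) {
  jsonlite::write_json(
    list(mu_hat = model$mu_hat, sigma = as.vector(model$sigma),
         dof = model$dof, n_fit = model$n_fit),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_hotelling
#' @export
read_hotelling <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(mu_hat = as.numeric(obj$mu_hat),
         sigma = matrix(as.numeric(obj$sigma), 2L, 2L),
         dof = as.integer(obj$dof), n_fit = as.integer(obj$n_fit)),
    class = "hotelling_model"
  )
}
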