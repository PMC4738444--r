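# Design matrices for the four scan models, least-squares fitting via
# rank-revealing pivoted QR, leverage, OLS/HC0/HC3 covariance estimates, and
# Wald t / nested F tests.
#
# Model I   : y ~ 1 + z                      (main effect of the genome SNP)
# Model II  : y ~ 1 + x + z                  (two-locus, no interaction)
# Model III : y ~ 1 + x + z + x*z            (product-term interaction)
# Model IV  : additive + dominance codings of both SNPs plus all four
#             products (4-df interaction test)
# x is the repeating SNP, z the non-repeating SNP, both 0/1/2 minor-allele
# dosages; dominance coding is 1 for heterozygotes, 0 otherwise.

model_k <- c(I = 2L, II = 3L, III = 4L, IV = 9L)

#' Build the design matrix for one scan model
#'
#' @param model_id one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param x_rep repeating-SNP dosage vector (ignored by model I).
#' @param z_nonrep non-repeating-SNP dosage vector.
#' @return a `design_matrix`: list with the numeric matrix `X`, column
#'   `labels`, and `model_id`. The first column is always the intercept.
#' @export
#' @examples
#' build_design("III", c(0, 1, 2, 0), c(2, 0, 1, 1))$X[, "product"]
build_design <- function(model_id, x_rep, z_nonrep) {
  model_id <- match.arg(as.character(model_id), c("I", "II", "III", "IV"))
  z <- as.numeric(z_nonrep)
  n <- length(z)
  if (model_id != "I" && length(x_rep) != n)
    stop_lambdascan("input", "x_rep and z_nonrep must have equal length")
  X <- switch(model_id,
    I = cbind(intercept = rep(1, n), nonrep_additive = z),
    II = cbind(intercept = rep(1, n), rep_additive = as.numeric(x_rep),
               nonrep_additive = z),
    III = {
      x <- as.numeric(x_rep)
      cbind(intercept = rep(1, n), rep_additive = x, nonrep_additive = z,
            product = x * z)
    },
    IV = {
      xa <- as.numeric(x_rep); xd <- as.numeric(x_rep == 1)
      zd <- as.numeric(z == 1)
      cbind(intercept = rep(1, n),
            rep_additive = xa, rep_dominance = xd,
            nonrep_additive = z, nonrep_dominance = zd,
            product_aa = xa * z, product_ad = xa * zd,
            product_da = xd * z, product_dd = xd * zd)
    })
  structure(list(X = X, labels = colnames(X), model_id = model_id),
            class = "design_matrix")
}

#' Fit ordinary least squares
#'
#' Solves the least-squares problem with a rank-revealing pivoted QR
#' decomposition (never an explicit normal-equations inverse) and returns
#' coefficients, residuals, leverage (hat-matrix diagonal), residual sum of
#' squares and the residual variance estimate `rss / (n - k)`.
#'
#' @param design a `design_matrix`.
#' @param y numeric response vector.
#' @return an `ols_fit` object.
#' @section Errors: a rank-deficient design signals a structured
#'   `lambdascan_singular_design` condition carrying the offending column
#'   labels; the scan engine converts it into a skip row.
#' @export
fit_ols <- function(design, y) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop_lambdascan("input", "y length must match design rows")
  if (n <= k) stop_lambdascan("insufficient_data",
                              sprintf("need more than k=%d observations, have %d", k, n))
  qd <- qr(X)
  if (qd$rank < k) {
    bad <- design$labels[qd$pivot[(qd$rank + 1L):k]]
    stop_lambdascan("singular_design",
                    paste("rank-deficient design; offending columns:",
                          paste(bad, collapse = ", ")),
                    offending = bad)
  }
  beta <- qr.coef(qd, y)
  res <- qr.resid(qd, y)
  h <- rowSums(qr.Q(qd)^2)
  rss <- sum(res^2)
  structure(list(beta = beta, residuals = res, leverage = h, rss = rss,
                 n_used = n, k = k, sigma2 = rss / (n - k), qr = qd,
                 X = X, labels = design$labels, model_id = design$model_id),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("ols_fit (model %s): n=%d, k=%d, sigma2=%.4g\n",
              x$model_id, x$n_used, x$k, x$sigma2))
  print(x$beta)
  invisible(x)
}

# (X'X)^-1 recovered from the pivoted QR factor.
xtx_inverse <- function(fit) {
  k <- fit$k
  R <- qr.R(fit$qr)
  Rinv <- backsolve(R, diag(k))
  Vp <- tcrossprod(Rinv)
  piv <- fit$qr$pivot
  V <- matrix(0, k, k)
  V[piv, piv] <- Vp
  V
}

#' Coefficient covariance: OLS or heteroskedasticity-consistent sandwich
#'
#' Computes `(X'X)^-1 X' W X (X'X)^-1` with the per-observation weight
#' matrix `W` chosen by `estimator`:
#' * `"OLS"`: pooled residual variance, reducing to `sigma2 * (X'X)^-1`;
#' * `"HC0"`: `W = diag(e_i^2)` (White's estimator);
#' * `"HC3"`: `W = diag(e_i^2 / (1 - h_ii)^2)`, the leverage-adjusted
#'   small-sample form.
#'
#' @param fit an `ols_fit`.
#' @param estimator `"OLS"`, `"HC0"`, or `"HC3"`.
#' @return a `covariance_estimate`: list with the symmetric `matrix` (labels
#'   on both dimensions) and `estimator`.
#' @section Errors: under HC3, an observation with leverage 1 fully
#'   determines a coefficient; this signals a structured
#'   `lambdascan_extreme_leverage` condition.
#' @export
covariance_estimate <- function(fit, estimator = c("OLS", "HC0", "HC3")) {
  stopifnot(inherits(fit, "ols_fit"))
  estimator <- match.arg(estimator)
  B <- xtx_inverse(fit)
  V <- if (estimator == "OLS") {
    fit$sigma2 * B
  } else {
    w <- fit$residuals^2
    if (estimator == "HC3") {
      one_minus_h <- 1 - fit$leverage
      if (any(one_minus_h < 1e-10))
        stop_lambdascan("extreme_leverage",
                        "HC3 undefined: an observation has leverage 1")
      w <- w / one_minus_h^2
    }
    meat <- crossprod(fit$X * w, fit$X)
    B %*% meat %*% B
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(fit$labels, fit$labels)
  structure(list(matrix = V, estimator = estimator),
            class = "covariance_estimate")
}

new_test_result <- function(statistic, df_num, df_den, p_value, test_id,
                            estimate = NA_real_, se = NA_real_) {
  structure(list(statistic = statistic, df_num = df_num, df_den = df_den,
                 p_value = p_value, test_id = test_id,
                 estimate = estimate, se = se),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic=%.4g, df=(%d, %d), p=%.4g\n",
              x$test_id, x$statistic, x$df_num, x$df_den, x$p_value))
  invisible(x)
}

#' Wald t test of a single coefficient
#'
#' `t = beta_hat / SE` with `SE` the square root of the matching diagonal
#' entry of the supplied covariance estimate; the two-sided P-value uses the
#' t distribution with `n - k` degrees of freedom for OLS and HC covariances
#' alike (the t reference under HC covariances is a documented
#' approximation, since the finite-sample distribution of an HC-based Wald
#' statistic is not exactly t).
#'
#' @param fit an `ols_fit`.
#' @param cov a `covariance_estimate` from the same fit.
#' @param coef_label coefficient to test, e.g. `"product"`.
#' @return a `test_result` with `df_num = 1`.
#' @export
wald_t_test <- function(fit, cov, coef_label) {
  stopifnot(inherits(fit, "ols_fit"), inherits(cov, "covariance_estimate"))
  if (!coef_label %in% fit$labels)
    stop_lambdascan("input", sprintf("no coefficient named '%s'", coef_label))
  v <- cov$matrix[coef_label, coef_label]
  if (!is.finite(v) || v <= 0)
    stop_lambdascan("degenerate_test",
                    sprintf("non-positive variance for '%s'", coef_label))
  est <- unname(fit$beta[coef_label])
  se <- sqrt(v)
  tval <- est / se
  df <- fit$n_used - fit$k
  new_test_result(statistic = tval, df_num = 1L, df_den = df,
                  p_value = 2 * stats::pt(-abs(tval), df),
                  test_id = paste0("t_", coef_label, "_", cov$estimator),
                  estimate = est, se = se)
}

#' Nested F test of a set of coefficients
#'
#' Residual-sum-of-squares F test comparing the full design against the
#' design with `constrained_labels` removed:
#' `F = [(RSS_reduced - RSS_full)/q] / [RSS_full/(n-k)]`.
#' Used for the 2-df joint tests and the 4-df interaction test; always based
#' on OLS residual variance.
#'
#' @param design_full a `design_matrix`.
#' @param y response vector.
#' @param constrained_labels labels of the coefficients set to zero under the
#'   null (must not include the intercept).
#' @return a `test_result` with `df_num = length(constrained_labels)`.
#' @export
f_test <- function(design_full, y, constrained_labels) {
  stopifnot(inherits(design_full, "design_matrix"))
  labs <- design_full$labels
  if (!all(constrained_labels %in% labs) || "intercept" %in% constrained_labels)
    stop_lambdascan("input",
                    "constrained labels must be non-intercept design columns")
  q <- length(constrained_labels)
  fit_full <- fit_ols(design_full, y)
  keep <- setdiff(labs, constrained_labels)
  reduced <- structure(list(X = design_full$X[, keep, drop = FALSE],
                            labels = keep, model_id = design_full$model_id),
                       class = "design_matrix")
  fit_red <- fit_ols(reduced, y)
  df_den <- fit_full$n_used - fit_full$k
  Fstat <- ((fit_red$rss - fit_full$rss) / q) / (fit_full$rss / df_den)
  new_test_result(statistic = Fstat, df_num = q, df_den = df_den,
                  p_value = stats::pf(Fstat, q, df_den, lower.tail = FALSE),
                  test_id = paste0("F_", paste(constrained_labels, collapse = "+")))
}
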