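# standardize columns to zero mean / unit variance, flagging constants
#' @noRd
standardize <- function(M) {
  M <- as.matrix(M)
  s <- apply(M, 2L, stats::sd)
  if (any(s <= .Machine$double.eps)) {
    tg_abort(sprintf("constant column(s): %s.",
                     paste(colnames(M)[s <= .Machine$double.eps],
                           collapse = ", ")),
             "tggpp_error_collinearity")
  }
  scale(M)
}

#' Multiple linear regression of GPP on its drivers
#'
#' Ordinary least squares on standardized response and predictors via
#' [stats::lm()]; coefficient p-values come from the usual t statistics.
#'
#' @param X an `n x p` numeric predictor matrix or data frame (columns
#'   named).
#' @param y numeric response of length `n`.
#' @return A list: `coefficients` (standardized), `p_values`, `r_squared`,
#'   `fitted` (on the standardized scale), `n`.
#' @export
mlr_fit <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) {
    tg_abort("need more observations than predictors + 1.",
             "tggpp_error_no_data")
  }
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1L) {
    drop_idx <- qrX$pivot[(qrX$rank + 1L):(p + 1L)] - 1L
    tg_abort(sprintf("rank-deficient predictors; offending column(s): %s.",
                     paste(colnames(X)[drop_idx[drop_idx > 0]],
                           collapse = ", ")),
             "tggpp_error_collinearity")
  }
  Xs <- standardize(X); ys <- as.numeric(standardize(matrix(y)))
  fit <- stats::lm(ys ~ Xs - 1)
  sm <- summary(fit)
  co <- sm$coefficients
  list(
    coefficients = stats::setNames(co[, 1L], colnames(X)),
    p_values = stats::setNames(co[, 4L], colnames(X)),
    r_squared = sm$r.squared,
    fitted = as.numeric(stats::fitted(fit)),
    n = n
  )
}

#' Johnson relative weights
#'
#' Decomposes the R-squared of the multiple regression of `y` on `X` into
#' non-negative per-predictor contributions. The predictors are replaced by
#' their closest orthogonal counterpart: with the predictor correlation
#' matrix eigendecomposed as `R_xx = Q L Q'`, the orthogonal scores are
#' `Z = X_std Q L^(-1/2) Q'` and the predictor-score correlations are
#' `Lstar = Q L^(1/2) Q'`. Regressing standardized `y` on `Z` gives
#' coefficients `beta`, and the raw weight of predictor j is
#' `eps_j = sum_k Lstar[j,k]^2 * beta_k^2`. The weights sum exactly to the
#' full-model R-squared; percentage weights are `eps_j / R^2 * 100`.
#'
#' @inheritParams mlr_fit
#' @return An object of class `rwa_result`: `predictors`, `raw_weights`,
#'   `pct_weights`, `r_squared`, `mlr_coefficients`, `p_values`, `n`.
#' @export
relative_weights <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2L) {
    tg_abort("relative weights need at least two predictors.",
             "tggpp_error_invalid_input")
  }
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  mlr <- mlr_fit(X, y)
  Xs <- standardize(X); ys <- as.numeric(standardize(matrix(y)))
  Rxx <- stats::cor(Xs)
  eig <- eigen(Rxx, symmetric = TRUE)
  if (any(eig$values < 1e-10)) {
    tg_abort("predictor correlation matrix is not positive definite.",
             "tggpp_error_collinearity")
  }
  Q <- eig$vectors
  Lhalf <- Q %*% (sqrt(eig$values) * t(Q))        # R_xx^(1/2) = Lstar
  Linvh <- Q %*% ((1 / sqrt(eig$values)) * t(Q))  # R_xx^(-1/2)
  Z <- Xs %*% Linvh
  n <- nrow(Xs)
  beta <- as.numeric(crossprod(Z, ys)) / (n - 1)  # Z columns orthonormal in r
  eps <- as.numeric((Lhalf^2) %*% beta^2)
  names(eps) <- colnames(X)
  structure(list(
    predictors = colnames(X),
    raw_weights = eps,
    pct_weights = 100 * eps / sum(eps),
    r_squared = mlr$r_squared,
    mlr_coefficients = mlr$coefficients,
    p_values = mlr$p_values,
    n = n
  ), class = "rwa_result")
}

#' @export
print.rwa_result <- function(x, ...) {
  cat(sprintf("<rwa_result> R^2 = %.3f over %d months\n", x$r_squared, x$n))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.rwa_result <- function(x, ...) {
  data.frame(predictor = x$predictors,
             raw_weight = x$raw_weights,
             pct_weight = x$pct_weights,
             mlr_coef = x$mlr_coefficients,
             p_value = x$p_values,
             r_squared = x$r_squared, n = x$n, row.names = NULL)
}

#' Variance attribution of GPP for a pooled PFT series
#'
#' Quantifies the relative contributions of greenness (EVI) and the three
#' climatic drivers (LST, PRC, RAD) to observed GPP for one PFT:
#' (a) the single-predictor R-squared of EVI alone, (b) the full
#' four-predictor [relative_weights()] decomposition, and (c) the
#' normalized Taylor statistics of the MLR prediction, comparable against
#' the TG model's own skill.
#'
#' @param series a [site_series()] or list of them, pooled per PFT.
#' @param min_months smallest pooled sample size accepted (default 30).
#' @return A list: `rwa` (`rwa_result`), `evi_r_squared`,
#'   `mlr_taylor` (`taylor_stats`), `n`.
#' @export
attribute_pft <- function(series, min_months = 30L) {
  pooled <- pool_series(series)
  keep <- !pooled$masked &
    is.finite(pooled$gpp) & is.finite(pooled$evi) & is.finite(pooled$lst) &
    is.finite(pooled$prc) & is.finite(pooled$rad)
  d <- pooled[keep, , drop = FALSE]
  if (nrow(d) < min_months) {
    tg_abort(sprintf("only %d usable months (< %d).", nrow(d), min_months),
             "tggpp_error_no_data")
  }
  X <- cbind(EVI = d$evi, LST = d$lst, PRC = d$prc, RAD = d$rad)
  rwa <- relative_weights(X, d$gpp)
  evi_only <- mlr_fit(X[, "EVI", drop = FALSE], d$gpp)
  full <- mlr_fit(X, d$gpp)
  # back-transform standardized fitted values to GPP units for Taylor stats
  mlr_pred <- full$fitted * stats::sd(d$gpp) + mean(d$gpp)
  list(
    rwa = rwa,
    evi_r_squared = evi_only$r_squared,
    mlr_taylor = taylor_stats(d$gpp, mlr_pred),
    n = nrow(d)
  )
}
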