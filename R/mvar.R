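#' Multivariate autoregressive (MVAR) model
#'
#' An order-p MVAR model for an n-channel signal:
#' `Y(t) = sum_{l=1}^{p} A_l Y(t-l) + eps(t)`, with `eps` zero-mean Gaussian
#' innovations with covariance `noise_cov`. The coefficient stack holds the
#' `A_l` as an `n x n x p` array; `coeffs[i, j, l]` is the influence of
#' channel j at lag l on channel i.
#'
#' @param coeffs Numeric `n x n x p` array of lag coefficient matrices.
#' @param noise_cov `n x n` innovation covariance (symmetric PSD).
#' @param fs Sampling rate in Hz the lags refer to.
#' @return An object of class `mvar_model`.
#' @export
mvar_model <- function(coeffs, noise_cov, fs) {
  if (length(dim(coeffs)) == 2L) coeffs <- array(coeffs, c(dim(coeffs), 1L))
  stopifnot(length(dim(coeffs)) == 3L, dim(coeffs)[1] == dim(coeffs)[2])
  n <- dim(coeffs)[1]
  if (!all(is.finite(coeffs))) stop("non-finite MVAR coefficients")
  if (!isTRUE(all.equal(noise_cov, t(noise_cov), tolerance = 1e-8)))
    stop("noise_cov must be symmetric")
  if (min(eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8 * max(abs(noise_cov)))
    stop("noise_cov must be positive semi-definite")
  structure(list(coeffs = coeffs, noise_cov = noise_cov,
                 order = dim(coeffs)[3], n_channels = n, fs = fs),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> order %d, %d channels @ %g Hz, companion spectral radius %.3f\n",
              x$order, x$n_channels, x$fs, companion_radius(x)))
  invisible(x)
}

#' Spectral radius of the MVAR companion matrix
#'
#' The model is (weakly) stationary iff this is < 1.
#'
#' @param model An [mvar_model()].
#' @return Largest eigenvalue modulus of the `np x np` companion matrix.
#' @export
companion_radius <- function(model) {
  n <- model$n_channels; p <- model$order
  C <- matrix(0, n * p, n * p)
  for (l in seq_len(p)) C[1:n, ((l - 1) * n + 1):(l * n)] <- model$coeffs[, , l]
  if (p > 1) C[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

# coefficient stack as the n x (n*p) matrix [A_1 ... A_p]
coeffs_wide <- function(model) {
  matrix(model$coeffs, nrow = model$n_channels)
}

#' Fit an MVAR model by multivariate least squares
#'
#' Solves, for each channel, the regression of the channel on the p lagged
#' values of all channels (one common lagged design matrix), and estimates
#' the innovation covariance from the residuals.
#'
#' @param x Numeric matrix, channels x samples.
#' @param p Model order (number of lags), a positive integer.
#' @param fs Sampling rate in Hz attached to the returned model.
#' @return An [mvar_model()] with an extra field `aic`, the Akaike
#'   information criterion `log det(Sigma_ML) + 2 p n^2 / T` of the fit.
#' @export
fit_mvar <- function(x, p, fs = 256) {
  x <- as.matrix(x)
  n <- nrow(x); Tn <- ncol(x)
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p))
    stop("order p must be a positive integer")
  p <- as.integer(p)
  Te <- Tn - p                       # effective sample count
  if (Te <= n * p)
    stop("too few samples (", Tn, ") for ", n, " channels at order ", p,
         "; use a lower p")
  # lagged design: row t = [x(t-1)', x(t-2)', ..., x(t-p)']
  Z <- matrix(0, Te, n * p)
  for (l in seq_len(p))
    Z[, ((l - 1) * n + 1):(l * n)] <- t(x[, (p - l + 1):(Tn - l), drop = FALSE])
  Y <- t(x[, (p + 1):Tn, drop = FALSE])    # Te x n
  G <- crossprod(Z)
  qrG <- qr(G)
  if (qrG$rank < ncol(Z))
    stop("rank-deficient lagged design; try a lower order p")
  B <- solve(qrG, crossprod(Z, Y))         # (n*p) x n
  resid <- Y - Z %*% B
  sigma_ml <- crossprod(resid) / Te
  coeffs <- array(0, c(n, n, p))
  for (l in seq_len(p)) coeffs[, , l] <- t(B[((l - 1) * n + 1):(l * n), ,
                                             drop = FALSE])
  m <- mvar_model(coeffs, (sigma_ml + t(sigma_ml)) / 2, fs)
  m$aic <- as.numeric(determinant(sigma_ml, logarithm = TRUE)$modulus) +
    2 * p * n^2 / Te
  m
}

#' Fit one MVAR model to all epochs of a subject (multi-trial estimation)
#'
#' Stacks the lagged-design normal equations across epochs (lags never
#' cross epoch boundaries), the standard multi-trial MVAR estimator. With
#' E epochs of T samples the effective sample count is `E (T - p)`, so the
#' coefficient noise floor shrinks by about `sqrt(E)` relative to a
#' single-epoch fit.
#'
#' @param es An [epoch_set()] (or a plain `epoch x channel x sample` array).
#' @param p Model order.
#' @param fs Sampling rate (taken from the epoch set when available).
#' @return An [mvar_model()].
#' @export
fit_mvar_epochs <- function(es, p, fs = NULL) {
  if (inherits(es, "eeg_epochs")) {
    if (is.null(fs)) fs <- es$fs
    ep <- es$epochs
  } else ep <- es
  if (is.null(fs)) fs <- 256
  stopifnot(length(dim(ep)) == 3L, p >= 1)
  p <- as.integer(p)
  ne <- dim(ep)[1]; n <- dim(ep)[2]; Tn <- dim(ep)[3]
  Te <- Tn - p
  if (ne * Te <= n * p) stop("too few samples across epochs for order ", p)
  G <- matrix(0, n * p, n * p); ZY <- matrix(0, n * p, n)
  YY <- matrix(0, n, n)
  for (e in seq_len(ne)) {
    x <- ep[e, , ]
    Z <- matrix(0, Te, n * p)
    for (l in seq_len(p))
      Z[, ((l - 1) * n + 1):(l * n)] <- t(x[, (p - l + 1):(Tn - l),
                                            drop = FALSE])
    Y <- t(x[, (p + 1):Tn, drop = FALSE])
    G <- G + crossprod(Z); ZY <- ZY + crossprod(Z, Y)
    YY <- YY + crossprod(Y)
  }
  qrG <- qr(G)
  if (qrG$rank < ncol(G))
    stop("rank-deficient pooled design; try a lower order p")
  B <- solve(qrG, ZY)
  rss <- YY - crossprod(ZY, B) - crossprod(B, ZY) + crossprod(B, G %*% B)
  sigma <- rss / (ne * Te)
  coeffs <- array(0, c(n, n, p))
  for (l in seq_len(p)) coeffs[, , l] <- t(B[((l - 1) * n + 1):(l * n), ,
                                             drop = FALSE])
  mvar_model(coeffs, (sigma + t(sigma)) / 2, fs)
}

#' Select MVAR model order by the Akaike information criterion
#'
#' Fits orders 1..p_max and returns the order minimizing
#' `AIC(p) = log det(Sigma_ML(p)) + 2 p n^2 / T`. Ties break toward the
#' smaller order.
#'
#' @param x Numeric matrix, channels x samples.
#' @param p_max Largest order to consider (>= 1).
#' @return The selected order (integer).
#' @export
select_order_aic <- function(x, p_max = 20) {
  stopifnot(p_max >= 1)
  aic <- rep(NA_real_, p_max)
  for (p in seq_len(p_max)) {
    fit <- tryCatch(fit_mvar(x, p), error = function(e) NULL)
    if (!is.null(fit)) aic[p] <- fit$aic
  }
  if (all(is.na(aic))) stop("no MVAR order in 1..", p_max, " could be fit")
  which.min(aic)                      # which.min takes the first minimum
}
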