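#' Squared-exponential kernel hyperparameters
#'
#' Bundle of the three hyperparameters of a squared-exponential (SE) Gaussian
#' process: the signal variance \eqn{\sigma_f^2} (amplitude of the latent
#' function), the length-scale \eqn{\ell} (smoothness; larger values give
#' smoother functions), and the observation-noise variance \eqn{\sigma_n^2}.
#'
#' The kernel length-scale is sometimes written \eqn{\tau} in the GP
#' literature; this package reserves `tau` for the Phased-LSTM gate period and
#' always calls the kernel parameter `length_scale`.
#'
#' @param signal_variance positive scalar \eqn{\sigma_f^2}.
#' @param length_scale positive scalar \eqn{\ell}, in the units of the input
#'   axis (hours throughout this package).
#' @param noise_variance non-negative scalar \eqn{\sigma_n^2}.
#' @return An object of class `se_kernel_params`.
#' @examples
#' se_kernel_params(1, 2, 0.1)
#' @export
se_kernel_params <- function(signal_variance = 1, length_scale = 1,
                             noise_variance = 0) {
  assert_number(signal_variance, "signal_variance", lower = 0,
                allow_equal_lower = FALSE)
  assert_number(length_scale, "length_scale", lower = 0,
                allow_equal_lower = FALSE)
  assert_number(noise_variance, "noise_variance", lower = 0)
  structure(list(signal_variance = signal_variance,
                 length_scale = length_scale,
                 noise_variance = noise_variance),
            class = "se_kernel_params")
}

#' @export
print.se_kernel_params <- function(x, ...) {
  cat(sprintf("SE kernel: signal_variance = %.4g, length_scale = %.4g, noise_variance = %.4g\n",
              x$signal_variance, x$length_scale, x$noise_variance))
  invisible(x)
}

#' Squared-exponential covariance
#'
#' \eqn{k(x, x') = \sigma_f^2 \exp(-(x - x')^2 / (2\ell^2))}. Vectorised over
#' `x` and `xp` (recycled to a common length).
#'
#' @param x,xp numeric vectors of input locations.
#' @param params an [se_kernel_params()] object.
#' @return numeric vector of covariances.
#' @examples
#' se_kernel(0, 1, se_kernel_params(1, 1, 0))  # exp(-0.5)
#' @export
se_kernel <- function(x, xp, params) {
  stopifnot(inherits(params, "se_kernel_params"))
  if (!all(is.finite(x)) || !all(is.finite(xp))) {
    stopf("se_kernel inputs must be finite")
  }
  d <- x - xp
  params$signal_variance * exp(-(d * d) / (2 * params$length_scale^2))
}

#' Cross-covariance matrix under the SE kernel
#'
#' Element `(i, j)` is `se_kernel(xs[i], ys[j], params)`. The noise variance is
#' *not* added here; callers add \eqn{\sigma_n^2 I} to square training
#' matrices where needed.
#'
#' @param xs,ys numeric vectors of input locations.
#' @inheritParams se_kernel
#' @return a `length(xs)` by `length(ys)` matrix.
#' @export
kernel_matrix <- function(xs, ys, params) {
  stopifnot(inherits(params, "se_kernel_params"))
  if (length(xs) == 0L || length(ys) == 0L) stopf("kernel_matrix inputs must be non-empty")
  d <- outer(xs, ys, "-")
  params$signal_variance * exp(-(d * d) / (2 * params$length_scale^2))
}

# Cholesky factor of K(x,x) + sigma_n^2 I + jitter. The jitter is
# 1e-8 * sigma_f^2, enough to keep duplicated or near-duplicated timestamps
# positive definite without visibly perturbing the posterior.
gp_chol <- function(xs, params) {
  n <- length(xs)
  K <- kernel_matrix(xs, xs, params) +
    diag(params$noise_variance + 1e-8 * params$signal_variance, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) {
    # escalate the jitter once before giving up
    K <- K + diag(1e-6 * params$signal_variance, n)
    L <- tryCatch(chol(K),
                  error = function(e) stopf(
                    "kernel system not positive definite (n = %d, length_scale = %g)",
                    n, params$length_scale))
  }
  L
}

#' Fit (condition) a GP regressor on observed points
#'
#' Conditions a zero-mean SE-kernel Gaussian process on observations after
#' subtracting a constant mean offset (by default the training mean, the
#' "centre to zero" convention), caching the Cholesky factor of
#' \eqn{K + \sigma_n^2 I} and the solve \eqn{\alpha = (K + \sigma_n^2 I)^{-1} y}.
#'
#' With zero training points the returned model is the prior: the posterior
#' mean is `mean_offset` everywhere and the variance is the prior variance.
#'
#' @param x numeric vector of training inputs (timestamps, hours).
#' @param y numeric vector of training observations, same length as `x`.
#' @param params an [se_kernel_params()] object.
#' @param mean_offset constant mean function value; defaults to `mean(y)`
#'   (0 when there are no observations).
#' @return An object of class `gp_regressor`.
#' @seealso [gp_posterior()], [fit_hyperparameters()]
#' @export
gp_fit <- function(x, y, params, mean_offset = NULL) {
  stopifnot(inherits(params, "se_kernel_params"))
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (anyNA(x) || anyNA(y)) stopf("gp_fit does not accept missing values")
  mean_offset <- mean_offset %||% (if (length(y)) mean(y) else 0)
  model <- list(params = params, train_x = x, train_y = y,
                mean_offset = mean_offset)
  if (length(x) > 0L) {
    L <- gp_chol(x, params)
    yc <- y - mean_offset
    model$chol <- L
    model$alpha <- backsolve(L, forwardsolve(t(L), yc))
  }
  structure(model, class = "gp_regressor")
}

#' @export
print.gp_regressor <- function(x, ...) {
  cat(sprintf("GP regressor: %d training points, mean offset %.4g\n",
              length(x$train_x), x$mean_offset))
  print(x$params)
  invisible(x)
}

#' GP posterior mean and variance at query points
#'
#' Computes \eqn{\bar f_* = k(x_*, x)(K + \sigma_n^2 I)^{-1} y} and
#' \eqn{\sigma^2(x_*) = k(x_*, x_*) - k(x_*, x)(K + \sigma_n^2 I)^{-1}
#' k(x, x_*)}, adding the constant mean offset back onto the returned mean.
#'
#' @param model a fitted [gp_fit()] object.
#' @param xstar numeric vector of query locations.
#' @return list with elements `mean` and `var` (each `length(xstar)`).
#' @export
gp_posterior <- function(model, xstar) {
  stopifnot(inherits(model, "gp_regressor"))
  if (!all(is.finite(xstar))) stopf("query locations must be finite")
  p <- model$params
  prior_var <- rep(p$signal_variance, length(xstar))
  if (length(model$train_x) == 0L) {
    return(list(mean = rep(model$mean_offset, length(xstar)), var = prior_var))
  }
  Ks <- kernel_matrix(xstar, model$train_x, p)      # n* x n
  mean <- model$mean_offset + drop(Ks %*% model$alpha)
  v <- forwardsolve(t(model$chol), t(Ks))           # n x n*
  var <- pmax(prior_var - colSums(v * v), 0)
  list(mean = mean, var = var)
}

# log-parameter packing used by the marginal-likelihood optimiser
pack_params <- function(p) log(c(p$signal_variance, p$length_scale,
                                 max(p$noise_variance, 1e-12)))
unpack_params <- function(theta) {
  se_kernel_params(signal_variance = exp(theta[1]),
                   length_scale = exp(theta[2]),
                   noise_variance = exp(theta[3]))
}

#' Negative log marginal likelihood of an SE-kernel GP
#'
#' \deqn{L(\theta) = \tfrac12 y^\top (K + \sigma_n^2 I)^{-1} y
#'   + \tfrac12 \log\det(K + \sigma_n^2 I) + \tfrac n2 \log 2\pi,}
#' evaluated through a Cholesky factorisation. `y` is used as given (centre it
#' first if a non-zero mean is intended).
#'
#' @param params an [se_kernel_params()] object.
#' @param xs,ys training inputs and (centred) observations.
#' @return scalar \eqn{L(\theta)}.
#' @export
negative_log_likelihood <- function(params, xs, ys) {
  stopifnot(inherits(params, "se_kernel_params"))
  n <- length(xs)
  if (n < 1L) stopf("need at least one observation")
  L <- gp_chol(xs, params)
  a <- forwardsolve(t(L), ys)
  0.5 * sum(a * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
}

#' Gradient of the negative log marginal likelihood
#'
#' Gradient with respect to the *log* hyperparameters
#' \eqn{(\log\sigma_f^2, \log\ell, \log\sigma_n^2)}, using
#' \eqn{\partial L/\partial\theta_i = \tfrac12\,\mathrm{tr}\!\left[(K^{-1} -
#' \alpha\alpha^\top)\, \partial K/\partial\theta_i\right]} with
#' \eqn{\alpha = K^{-1} y}, \eqn{K = K_f + \sigma_n^2 I}. Optimising in log
#' space keeps all parameters positive.
#'
#' @inheritParams negative_log_likelihood
#' @return numeric vector of length 3.
#' @export
nll_gradient <- function(params, xs, ys) {
  stopifnot(inherits(params, "se_kernel_params"))
  n <- length(xs)
  if (n < 1L) stopf("need at least one observation")
  L <- gp_chol(xs, params)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  Kinv <- chol2inv(L)
  A <- Kinv - tcrossprod(alpha)          # K^-1 - alpha alpha^T
  D2 <- outer(xs, xs, "-")^2
  Kf <- params$signal_variance * exp(-D2 / (2 * params$length_scale^2))
  # dK/dlog(sigma_f^2) = Kf ; dK/dlog(l) = Kf * D2 / l^2 ;
  # dK/dlog(sigma_n^2) = sigma_n^2 I
  g1 <- 0.5 * sum(A * Kf)
  g2 <- 0.5 * sum(A * (Kf * D2 / params$length_scale^2))
  g3 <- 0.5 * params$noise_variance * sum(diag(A))
  c(signal_variance = g1, length_scale = g2, noise_variance = g3)
}

#' Fit SE-kernel hyperparameters by marginal likelihood (ML-II)
#'
#' Minimises [negative_log_likelihood()] over the log hyperparameters with
#' L-BFGS-B (analytic gradient, [nll_gradient()]), from several starting
#' points to reduce the risk of poor local minima. Observations are centred
#' internally; the returned parameters refer to the centred series.
#'
#' With fewer than 3 distinct timestamps the data cannot identify the
#' hyperparameters; a default parameter set (variance of `y`, length-scale one
#' quarter of the input range) is returned with attribute `fitted = FALSE` and
#' a warning.
#'
#' @param xs,ys training inputs and observations.
#' @param init optional [se_kernel_params()] starting point (used as the first
#'   start).
#' @param n_starts number of multi-start initialisations (>= 1).
#' @param max_iter L-BFGS-B iteration cap per start.
#' @param tol relative convergence tolerance (mapped to `factr`).
#' @param seed integer seed controlling the randomised starts.
#' @return an [se_kernel_params()] object with attributes `nll` (achieved
#'   value) and `fitted`.
#' @export
fit_hyperparameters <- function(xs, ys, init = NULL, n_starts = 3,
                                max_iter = 100, tol = 1e-8, seed = 1) {
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  n <- length(xs)
  if (n == 0L) stopf("fit_hyperparameters needs at least one observation")
  rng_x <- diff(range(xs))
  fallback <- function() {
    vy <- if (n >= 2) stats::var(ys) else 1
    if (!is.finite(vy) || vy <= 0) vy <- 1
    p <- se_kernel_params(signal_variance = vy,
                          length_scale = max(rng_x / 4, 1e-3),
                          noise_variance = vy * 0.1)
    attr(p, "fitted") <- FALSE
    p
  }
  if (length(unique(xs)) < 3L) {
    warning("fewer than 3 distinct timestamps; returning default hyperparameters")
    return(fallback())
  }
  yc <- ys - mean(ys)
  vy <- max(stats::var(yc), 1e-10)
  med_dx <- stats::median(diff(sort(unique(xs))))
  base <- init %||% se_kernel_params(vy, max(med_dx * 3, 1e-3), vy * 0.1)
  starts <- list(pack_params(base))
  if (n_starts > 1) {
    extra <- with_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i) {
        pack_params(base) + stats::rnorm(3, 0, 1)
      })
    })
    starts <- c(starts, extra)
  }
  fn <- function(theta) {
    p <- unpack_params(theta)
    tryCatch(negative_log_likelihood(p, xs, yc), error = function(e) 1e10)
  }
  gr <- function(theta) {
    p <- unpack_params(theta)
    tryCatch(unname(nll_gradient(p, xs, yc)), error = function(e) rep(0, 3))
  }
  lower <- c(log(vy * 1e-4), log(max(med_dx / 10, 1e-4)), log(vy * 1e-6))
  upper <- c(log(vy * 1e4), log(rng_x * 10), log(vy * 1e2))
  best <- NULL
  for (th0 in starts) {
    th0 <- pmin(pmax(th0, lower), upper)
    fit <- tryCatch(
      stats::optim(th0, fn, gr, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = max_iter, factr = tol / 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    warning("hyperparameter optimisation failed; returning default parameters")
    return(fallback())
  }
  # never return a point worse than the supplied init
  if (fn(starts[[1]]) < best$value) best <- list(par = starts[[1]],
                                                 value = fn(starts[[1]]))
  p <- unpack_params(best$par)
  attr(p, "nll") <- best$value
  attr(p, "fitted") <- TRUE
  p
}
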