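test_that("SE kernel matches its closed form and decays monotonically", {
  p <- se_kernel_params(1, 1, 0)
  expect_equal(se_kernel(2, 2, p), 1)
  expect_equal(se_kernel(0, 1, p), exp(-0.5), tolerance = 1e-12)
  p2 <- se_kernel_params(2.5, 3, 0.1)
  expect_equal(se_kernel(0, 0, p2), 2.5)
  d <- seq(0, 50, by = 0.5)
  k <- se_kernel(0, d, p2)
  expect_true(all(diff(k) < 0))
  expect_lt(k[length(k)], 1e-10)
  expect_error(se_kernel_params(1, -1, 0), "length_scale")
  expect_error(se_kernel_params(0, 1, 0), "signal_variance")
})

test_that("kernel matrices agree with a brute-force double loop", {
  p <- se_kernel_params(1.7, 2.3, 0)
  xs <- c(-1.2, 0.4, 3.3)
  ys <- c(0.1, 2.2)
  K <- kernel_matrix(xs, ys, p)
  brute <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) {
    brute[i, j] <- p$signal_variance *
      exp(-(xs[i] - ys[j])^2 / (2 * p$length_scale^2))
  }
  expect_equal(K, brute, tolerance = 1e-12)
  Kxx <- kernel_matrix(xs, xs, p)
  expect_equal(Kxx, t(Kxx))
  expect_equal(diag(Kxx), rep(p$signal_variance, 3))
  expect_equal(kernel_matrix(1, 2, p)[1, 1], se_kernel(1, 2, p))
})

test_that("posterior matches closed forms: prior, one point, interpolation", {
  p <- se_kernel_params(1, 1, 0)
  # no training points: prior
  prior <- gp_posterior(gp_fit(numeric(0), numeric(0), p, mean_offset = 0.3),
                        c(0, 5))
  expect_equal(prior$mean, c(0.3, 0.3))
  expect_equal(prior$var, c(1, 1))
  # single point (x=0, y=1), query x*=1
  m <- gp_fit(0, 1, p, mean_offset = 0)
  post <- gp_posterior(m, 1)
  expect_equal(post$mean, exp(-0.5), tolerance = 1e-6)
  expect_equal(post$var, 1 - exp(-1), tolerance = 1e-6)
  # noise-free GP interpolates its training points
  xs <- c(0, 1, 2.5, 4)
  ys <- sin(xs)
  m2 <- gp_fit(xs, ys, se_kernel_params(1, 1.5, 0))
  post2 <- gp_posterior(m2, xs)
  expect_equal(post2$mean, ys, tolerance = 1e-6)
  expect_true(all(post2$var <= 1e-6))
})

test_that("posterior mean/variance equal the dense-inverse oracle", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      n <- sample(2:10, 1)
      xs <- sort(runif(n, 0, 10))
      ys <- rnorm(n)
      p <- se_kernel_params(exp(runif(1, -1, 1)), exp(runif(1, -0.5, 1)),
                            exp(runif(1, -5, -2)))
      xstar <- runif(4, 0, 10)
      model <- gp_fit(xs, ys, p)
      post <- gp_posterior(model, xstar)
      # oracle: direct dense inversion of the regularised kernel system
      K <- kernel_matrix(xs, xs, p) +
        diag(p$noise_variance + 1e-8 * p$signal_variance, n)
      Ks <- kernel_matrix(xstar, xs, p)
      mu <- mean(ys) + Ks %*% solve(K, ys - mean(ys))
      va <- p$signal_variance - rowSums((Ks %*% solve(K)) * Ks)
      expect_equal(post$mean, drop(mu), tolerance = 1e-8)
      expect_equal(post$var, pmax(va, 0), tolerance = 1e-8)
      # posterior variance never exceeds the prior variance
      expect_true(all(post$var <= p$signal_variance + 1e-12))
    }
  })
})

test_that("negative log likelihood matches hand and dense-inverse evaluation", {
  p <- se_kernel_params(1, 1, 0)
  expect_equal(negative_log_likelihood(p, 0, 0), 0.5 * log(2 * pi),
               tolerance = 1e-6)
  withr::with_seed(8, {
    xs <- sort(runif(5, 0, 6)); ys <- rnorm(5)
    pp <- se_kernel_params(1.4, 2.2, 0.3)
    K <- kernel_matrix(xs, xs, pp) +
      diag(pp$noise_variance + 1e-8 * pp$signal_variance, 5)
    oracle <- 0.5 * drop(ys %*% solve(K, ys)) +
      0.5 * determinant(K)$modulus[1] + 2.5 * log(2 * pi)
    expect_equal(negative_log_likelihood(pp, xs, ys), oracle,
                 tolerance = 1e-8)
    # zero observations: only the log-det and constant terms remain
    expect_equal(negative_log_likelihood(pp, xs, rep(0, 5)),
                 0.5 * determinant(K)$modulus[1] + 2.5 * log(2 * pi),
                 tolerance = 1e-8)
  })
})

test_that("analytic NLL gradient agrees with central finite differences", {
  withr::with_seed(13, {
    xs <- sort(runif(6, 0, 8)); ys <- sin(xs) + rnorm(6, 0, 0.2)
    theta <- log(c(1.3, 2.1, 0.05))
    g <- nll_gradient(icurisk:::unpack_params(theta), xs, ys)
    h <- 1e-5
    for (i in 1:3) {
      tp <- theta; tm <- theta
      tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
      fd <- (negative_log_likelihood(icurisk:::unpack_params(tp), xs, ys) -
               negative_log_likelihood(icurisk:::unpack_params(tm), xs, ys)) /
        (2 * h)
      expect_lt(abs(g[i] - fd) / max(abs(fd), 1e-8), 1e-4)
    }
    # alpha = 0 when y = 0: data-fit contribution to the gradient vanishes
    g0 <- nll_gradient(icurisk:::unpack_params(theta), xs, rep(0, 6))
    p <- icurisk:::unpack_params(theta)
    L <- icurisk:::gp_chol(xs, p)
    Kinv <- chol2inv(L)
    D2 <- outer(xs, xs, "-")^2
    Kf <- p$signal_variance * exp(-D2 / (2 * p$length_scale^2))
    expect_equal(unname(g0[1]), 0.5 * sum(Kinv * Kf), tolerance = 1e-10)
  })
})

test_that("hyperparameter fitting improves on its initialisation", {
  withr::with_seed(31, {
    xs <- sort(runif(40, 0, 20))
    K <- kernel_matrix(xs, xs, se_kernel_params(1, 2, 0)) + diag(1e-8, 40)
    ys <- drop(crossprod(chol(K), rnorm(40))) + rnorm(40, 0, 0.1)
  })
  init <- se_kernel_params(0.5, 0.5, 0.5)
  fit <- fit_hyperparameters(xs, ys, init = init, seed = 4)
  expect_true(attr(fit, "fitted"))
  yc <- ys - mean(ys)
  expect_lte(attr(fit, "nll"), negative_log_likelihood(init, xs, yc) + 1e-8)
  # degenerate inputs fall back with a warning
  expect_warning(f2 <- fit_hyperparameters(c(1, 1, 1), c(2, 2.1, 1.9)),
                 "distinct timestamps")
  expect_false(attr(f2, "fitted"))
  # constant y: fitted signal variance collapses, predictions near-constant
  fc <- fit_hyperparameters(1:10, rep(5, 10), seed = 2)
  m <- gp_fit(1:10, rep(5, 10), fc)
  expect_equal(gp_posterior(m, c(2.5, 7.5))$mean, c(5, 5), tolerance = 1e-3)
})

test_that("GP imputation fills gaps without touching observations", {
  x <- c(0, 1, 2, 3)
  y <- c(0, NA, 2, NA)
  r <- impute_series(x, y, n_starts = 1)
  expect_equal(r$mean[c(1, 3)], c(0, 2))
  expect_equal(r$observed, c(TRUE, FALSE, TRUE, FALSE))
  expect_true(all(r$var >= 0))
  # fully observed series: identity
  r0 <- impute_series(x, c(0, 1, 2, 3), n_starts = 1)
  expect_equal(r0$mean, c(0, 1, 2, 3))
  expect_error(impute_series(x, rep(NA_real_, 4)), "observed value")
  # far from the data the posterior reverts to the training mean
  p <- se_kernel_params(1, 1, 0)
  r1 <- impute_series(c(0, 1), c(0, 3), query_timestamps = c(2, 5, 30),
                      params = p)
  drift <- abs(r1$mean[3:5] - 1.5)        # training mean = 1.5
  expect_true(all(diff(drift) <= 1e-12))
  expect_equal(r1$mean[5], 1.5, tolerance = 1e-6)
})

test_that("GP beats mean substitution on smooth series with 30% MCAR gaps", {
  withr::with_seed(77, {
    errs <- matrix(0, 10, 2)
    for (r in 1:10) {
      x <- seq(0, 24, by = 0.5)
      truth <- 3 * sin(x / 3) + 0.3 * x
      y <- truth + rnorm(length(x), 0, 0.1)
      mask <- runif(length(x)) < 0.3
      yobs <- y; yobs[mask] <- NA
      gp <- impute_series(x, yobs, n_starts = 2, seed = r)
      ms <- baseline_impute(x, yobs, "mean_substitution")
      errs[r, 1] <- sqrt(mean((gp$mean[mask] - truth[mask])^2))
      errs[r, 2] <- sqrt(mean((ms$mean[mask] - truth[mask])^2))
    }
    expect_lt(mean(errs[, 1]), mean(errs[, 2]))
  })
})

test_that("regular resampling evaluates the posterior on the full grid", {
  p <- se_kernel_params(1, 2, 0)
  r <- resample_regular(c(0, 12), c(1, 1), step_hours = 12, horizon = 12,
                        params = p)
  expect_equal(nrow(r), 2L)
  expect_equal(r$time, c(0, 12))
  # constant series stays constant on the grid
  rc <- resample_regular(c(0, 3, 9), c(2, 2, 2), step_hours = 1.5,
                         horizon = 9, params = p)
  expect_equal(rc$value, rep(2, nrow(rc)), tolerance = 1e-6)
  # noise-free posterior hits the observations that lie on the grid
  x <- c(0, 2, 4, 6)
  y <- c(0.3, -0.1, 0.5, 0.2)
  rg <- resample_regular(x, y, step_hours = 2, horizon = 6, params = p)
  expect_equal(rg$value, y, tolerance = 1e-6)
  expect_error(resample_regular(x, y, step_hours = 0), "step_hours")
})

test_that("baseline imputers match their textbook behaviour", {
  expect_equal(baseline_impute(1:3, c(1, NA, 3), "mean_substitution")$mean,
               c(1, 2, 3))
  expect_equal(baseline_impute(1:4, c(1, NA, 3, NA), "locf")$mean,
               c(1, 1, 3, 3))
  expect_equal(baseline_impute(1:3, c(0, NA, 2), "linear")$mean, c(0, 1, 2))
  # LOCF before the first observation uses the first observation
  expect_equal(baseline_impute(1:3, c(NA, 5, NA), "locf")$mean, c(5, 5, 5))
  expect_error(baseline_impute(1:3, c(1, NA, 3), "cubic"), "arg")
})

test_that("imputer comparison is deterministic and saturates as delta grows", {
  coh <- small_cohort()
  t1 <- compare_imputers(coh, methods = c("mean_substitution", "locf"),
                         seed = 5)
  t2 <- compare_imputers(coh, methods = c("mean_substitution", "locf"),
                         seed = 5)
  expect_identical(t1, t2)
  expect_true(all(diff(t1$precision) <= 0))
  tinf <- compare_imputers(coh, methods = "locf", delta_factor = Inf)
  expect_equal(tinf$precision, 1)
  clean <- simulate_cohort(small_config(missing_rate = 0))
  expect_error(compare_imputers(clean, methods = "locf"), "no masked points")
})
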