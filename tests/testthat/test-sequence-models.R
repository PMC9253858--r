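# independent scalar-loop oracle for one peephole-LSTM step
lstm_step_oracle <- function(x, c_prev, h_prev, par) {
  H <- par$hidden_size
  idx <- icurisk:::gate_idx(H)
  sig <- function(z) 1 / (1 + exp(-z))
  i <- f <- o <- g <- cn <- hn <- numeric(H)
  for (u in seq_len(H)) {
    zi <- sum(par$W_x[, idx$i[u]] * x) + sum(par$W_h[, idx$i[u]] * h_prev) +
      par$w_ci[u] * c_prev[u] + par$b[idx$i[u]]
    zf <- sum(par$W_x[, idx$f[u]] * x) + sum(par$W_h[, idx$f[u]] * h_prev) +
      par$w_cf[u] * c_prev[u] + par$b[idx$f[u]]
    zg <- sum(par$W_x[, idx$g[u]] * x) + sum(par$W_h[, idx$g[u]] * h_prev) +
      par$b[idx$g[u]]
    zo <- sum(par$W_x[, idx$o[u]] * x) + sum(par$W_h[, idx$o[u]] * h_prev) +
      par$w_co[u] * c_prev[u] + par$b[idx$o[u]]
    i[u] <- sig(zi); f[u] <- sig(zf); g[u] <- tanh(zg); o[u] <- sig(zo)
    cn[u] <- f[u] * c_prev[u] + i[u] * g[u]
    hn[u] <- o[u] * tanh(cn[u])
  }
  list(c = cn, h = hn, i = i, f = f, o = o)
}

rand_params <- function(input, hidden, seed) {
  par <- lstm_params(input, hidden, seed = seed, forget_bias = 0)
  withr::with_seed(seed + 1, {
    for (nm in c("W_x", "W_h", "b", "w_ci", "w_cf", "w_co")) {
      v <- par[[nm]]; v[] <- rnorm(length(v), 0, 0.6); par[[nm]] <- v
    }
  })
  par
}

test_that("the zero-weight LSTM step gives half-open gates and zero state", {
  par <- lstm_params(3, 4, seed = 1)
  for (nm in c("W_x", "W_h")) par[[nm]][] <- 0
  par$b[] <- 0
  st <- lstm_step(c(1, -2, 3), list(c = rep(0, 4), h = rep(0, 4)), par)
  expect_equal(st$i, rep(0.5, 4))
  expect_equal(st$f, rep(0.5, 4))
  expect_equal(st$o, rep(0.5, 4))
  expect_equal(st$c, rep(0, 4))
  expect_equal(st$h, rep(0, 4))
})

test_that("a saturated forget gate carries the memory cell through", {
  par <- lstm_params(2, 3, seed = 2)
  for (nm in c("W_x", "W_h", "w_ci", "w_cf", "w_co")) par[[nm]][] <- 0
  par$b[] <- 0
  par$b[icurisk:::gate_idx(3)$f] <- 10      # f ~ 1
  par$b[icurisk:::gate_idx(3)$i] <- -10     # i ~ 0
  c0 <- c(0.7, -0.4, 1.2)
  st <- lstm_step(c(1, 1), list(c = c0, h = rep(0, 3)), par)
  expect_equal(st$c, c0, tolerance = 1e-4)
})

test_that("the vectorised LSTM step matches an independent scalar oracle", {
  withr::with_seed(5, {
    for (r in 1:5) {
      par <- rand_params(4, 3, seed = 100 + r)
      x <- rnorm(4); c0 <- rnorm(3); h0 <- rnorm(3)
      got <- lstm_step(x, list(c = c0, h = h0), par)
      want <- lstm_step_oracle(x, c0, h0, par)
      expect_equal(got$c, want$c, tolerance = 1e-10)
      expect_equal(got$h, want$h, tolerance = 1e-10)
      expect_equal(got$i, want$i, tolerance = 1e-10)
    }
  })
})

test_that("the time-gate phase wraps correctly, including negative arguments", {
  expect_equal(time_gate_phase(2, 4, 2), 0)
  expect_equal(time_gate_phase(4, 4, 2), 0.5)
  expect_equal(time_gate_phase(7, 4, 2), 0.25)
  expect_equal(time_gate_phase(-1, 4, 2), 0.25)   # (-3 mod 4)/4
  expect_true(all(time_gate_phase(seq(-20, 20, by = 0.37), 3.3, 1.1) >= 0))
  expect_true(all(time_gate_phase(seq(-20, 20, by = 0.37), 3.3, 1.1) < 1))
  expect_error(time_gate_phase(1, 0, 0), "tau")
})

test_that("the three-phase gate ramps up, ramps down, then leaks", {
  expect_equal(time_gate_openness(0, 0.5, 0.001), 0)
  expect_equal(time_gate_openness(0.25, 0.5, 0.001), 1)   # phi = r_on/2
  expect_equal(time_gate_openness(0.125, 0.5, 0.001), 0.5)
  expect_equal(time_gate_openness(0.375, 0.5, 0.001), 0.5) # downward ramp
  expect_equal(time_gate_openness(0.75, 0.5, 0.001), 0.00075)
  phis <- seq(0, 0.999, by = 0.001)
  for (r_on in c(0.05, 0.1, 0.5, 1)) {
    k <- time_gate_openness(phis, r_on, 0.001)
    expect_true(all(k >= 0 & k <= 1))
  }
  # periodicity through the phase map
  t <- seq(0, 10, by = 0.1)
  k1 <- time_gate_openness(time_gate_phase(t, 2.5, 0.3), 0.2, 0.01)
  k2 <- time_gate_openness(time_gate_phase(t + 2.5, 2.5, 0.3), 0.2, 0.01)
  expect_equal(k1, k2, tolerance = 1e-12)
  expect_error(time_gate_openness(1.2, 0.5, 0.001), "phi")
})

test_that("the phased step reduces to the LSTM when the gate is open, freezes when closed", {
  par <- rand_params(4, 3, seed = 9)
  gate <- phased_gate_params(3, horizon = 10, seed = 2)
  x <- c(0.3, -1, 0.5, 2); c0 <- rnorm(3); h0 <- rnorm(3)
  plain <- lstm_step(x, list(c = c0, h = h0), par)
  open <- phased_lstm_step(x, t = 1, list(c = c0, h = h0), par, gate,
                           k_override = 1)
  expect_equal(open$c, plain$c, tolerance = 1e-10)
  expect_equal(open$h, plain$h, tolerance = 1e-10)
  # closed phase with zero leak: state untouched
  gate0 <- phased_gate_params(3, horizon = 10, r_on = 0.1, leak = 0, seed = 2)
  gate0$tau <- rep(10, 3); gate0$s <- rep(0, 3)
  shut <- phased_lstm_step(x, t = 5, list(c = c0, h = h0), par, gate0)  # phi=0.5
  expect_equal(shut$c, c0)
  expect_equal(shut$h, h0)
  expect_equal(drop(shut$k), rep(0, 3))
  # gated state is a convex combination of proposal and previous state
  withr::with_seed(14, {
    for (r in 1:20) {
      tt <- runif(1, 0, 10)
      st <- phased_lstm_step(x, tt, list(c = c0, h = h0), par, gate)
      lo <- pmin(plain$c, c0); hi <- pmax(plain$c, c0)
      expect_true(all(st$c >= lo - 1e-12 & st$c <= hi + 1e-12))
    }
  })
  # event times must not decrease
  st1 <- phased_lstm_step(x, 5, list(c = c0, h = h0), par, gate)
  expect_error(phased_lstm_step(x, 4, st1, par, gate), "non-decreasing")
})

test_that("softmax is stable, normalised and permutation-equivariant", {
  expect_equal(softmax_output(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax_output(c(1000, 0)), c(1, 0), tolerance = 1e-12)
  expect_equal(softmax_output(c(1, 2)), c(0.268941, 0.731059),
               tolerance = 1e-6)
  z <- c(0.3, -1.2, 2.2)
  p <- softmax_output(z)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(softmax_output(rev(z)), rev(p), tolerance = 1e-12)
})

test_that("forward_sequence is stateless across patients and rejects empty masks", {
  tm <- tiny_model_and_batch(B = 3, L = 4)
  seqs <- structure(list(x = tm$X[c(1, 2, 1), , , drop = FALSE],
                         times = tm$Tm[c(1, 2, 1), ],
                         mask = matrix(1, 3, 4),
                         labels = c(0, 1, 0), patient_id = 1:3,
                         feature_names = paste0("f", 1:3), L = 4L, p = 0L),
                    class = "event_sequences")
  pred <- forward_sequence(tm$model, seqs)
  expect_equal(pred$p_death[1], pred$p_death[3], tolerance = 1e-12)
  expect_true(all(abs(pred$p_survival + pred$p_death - 1) < 1e-9))
  seqs$mask[2, ] <- 0
  expect_error(forward_sequence(tm$model, seqs), "empty validity mask")
})

test_that("a Phased-LSTM with gates forced open equals the LSTM on shared weights", {
  phased <- tiny_model_and_batch(cell = "phased_lstm", B = 2, L = 4)
  lstm <- tiny_model_and_batch(cell = "lstm", B = 2, L = 4)
  # identical layer/head weights by construction (same seeds); only the cell
  # type and gates differ
  seqs <- structure(list(x = phased$X, times = phased$Tm,
                         mask = matrix(1, 2, 4), labels = c(0, 1),
                         patient_id = 1:2, feature_names = paste0("f", 1:3),
                         L = 4L, p = 0L), class = "event_sequences")
  p_open <- forward_sequence(phased$model, seqs, force_open_gates = TRUE)
  p_lstm <- forward_sequence(lstm$model, seqs)
  expect_equal(p_open$p_death, p_lstm$p_death, tolerance = 1e-10)
})

test_that("hidden outputs stay within the sigmoid-tanh bound |h| <= 1", {
  tm <- tiny_model_and_batch(B = 4, L = 6, hidden = 5, seed = 33)
  fw <- icurisk:::forward_batch(tm$model, tm$X, tm$Tm, matrix(1, 4, 6))
  expect_true(all(abs(fw$h_final) <= 1))
})
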