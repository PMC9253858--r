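# Peephole LSTM and Phased-LSTM cells.
#
# The LSTM update (all products elementwise except the weight terms):
#   i_t = sigma(W_xi x_t + W_hi h_{t-1} + w_ci c_{t-1} + b_i)
#   f_t = sigma(W_xf x_t + W_hf h_{t-1} + w_cf c_{t-1} + b_f)
#   c_t = f_t c_{t-1} + i_t tanh(W_xc x_t + W_hc h_{t-1} + b_c)
#   o_t = sigma(W_xo x_t + W_ho h_{t-1} + w_co c_{t-1} + b_o)
#   h_t = o_t tanh(c_t)
# The output-gate peephole deliberately reads c_{t-1} (not the canonical c_t);
# this keeps all four pre-activations functions of (x_t, h_{t-1}, c_{t-1}).
#
# The Phased-LSTM wraps the same update in a periodic time gate k_t computed
# per hidden unit from the event time t, and blends:
#   c_t = k_t c*_t + (1 - k_t) c_{t-1},  h_t = k_t h*_t + (1 - k_t) h_{t-1}.
# A padded (masked) step is exactly k_t = 0: the state is carried through.

gate_idx <- function(H) list(i = 1:H, f = (H + 1):(2 * H),
                             g = (2 * H + 1):(3 * H), o = (3 * H + 1):(4 * H))

#' LSTM parameter bundle
#'
#' Input, recurrent and peephole weights and biases of a peephole LSTM layer,
#' stored with the four gate blocks (input `i`, forget `f`, candidate `g`,
#' output `o`) stacked column-wise in `W_x` (input x 4H) and `W_h` (H x 4H).
#' Initialisation is uniform Glorot for the weight matrices, zero for the
#' peepholes, and zero biases except the forget gate (+1, which stabilises
#' early training).
#'
#' @param input_size,hidden_size layer dimensions.
#' @param seed integer seed for the random initialisation.
#' @param forget_bias initial forget-gate bias.
#' @return object of class `lstm_params`.
#' @export
lstm_params <- function(input_size, hidden_size, seed = 1, forget_bias = 1) {
  H <- as.integer(hidden_size); In <- as.integer(input_size)
  with_seed(seed, {
    gx <- sqrt(6 / (In + H)); gh <- sqrt(6 / (H + H))
    b <- rep(0, 4 * H); b[gate_idx(H)$f] <- forget_bias
    structure(list(
      W_x = matrix(stats::runif(In * 4 * H, -gx, gx), In, 4 * H),
      W_h = matrix(stats::runif(H * 4 * H, -gh, gh), H, 4 * H),
      b = b,
      w_ci = rep(0, H), w_cf = rep(0, H), w_co = rep(0, H),
      input_size = In, hidden_size = H), class = "lstm_params")
  })
}

#' Phased-LSTM time-gate parameters
#'
#' Per hidden unit: oscillation period `tau` (hours, initialised log-uniform
#' over `[1, horizon]` so the bank of units covers short and long rhythms),
#' phase shift `s` (uniform over `[0, tau)`), open ratio `r_on` and leak
#' `alpha` (shared across units, fixed during training).
#'
#' @param hidden_size number of units.
#' @param horizon upper end of the period initialisation range (hours).
#' @param r_on fraction of the period the gate is open, in `(0, 1]`.
#' @param leak closed-phase leak rate in `[0, 1)`.
#' @param seed integer seed.
#' @return object of class `phased_gate_params` with vectors `tau`, `s` and
#'   scalars `r_on`, `leak`.
#' @export
phased_gate_params <- function(hidden_size, horizon = 72, r_on = 0.1,
                               leak = 0.001, seed = 1) {
  assert_number(r_on, "r_on", lower = 0, upper = 1, allow_equal_lower = FALSE)
  assert_number(leak, "leak", lower = 0, upper = 1, allow_equal_upper = FALSE)
  with_seed(seed, {
    tau <- exp(stats::runif(hidden_size, log(1), log(max(horizon, 1 + 1e-6))))
    s <- stats::runif(hidden_size, 0, tau)
    structure(list(tau = tau, s = s, r_on = r_on, leak = leak,
                   hidden_size = as.integer(hidden_size)),
              class = "phased_gate_params")
  })
}

#' Phase of the periodic time gate
#'
#' \eqn{\phi_t = ((t - s) \bmod \tau)/\tau \in [0, 1)}, the position of time
#' `t` inside the gate's cycle; the modulo maps negative arguments into
#' `[0, tau)`.
#'
#' @param t event time (hours); vectorised.
#' @param tau gate period, `> 0`.
#' @param s phase shift (hours).
#' @return phases in `[0, 1)`.
#' @examples
#' time_gate_phase(7, 4, 2)  # 0.25
#' @export
time_gate_phase <- function(t, tau, s) {
  if (any(tau <= 0)) stopf("gate period tau must be > 0")
  ((t - s) %% tau) / tau
}

#' Openness of the periodic time gate
#'
#' Three-phase schedule: the gate ramps linearly from 0 to 1 over the first
#' half of the open window (`phi < r_on/2`), back down from 1 to 0 over the
#' second half (`phi < r_on`), and is otherwise closed up to a small leak
#' `alpha * phi` that lets gradient through outside the open window.
#'
#' @param phi phase in `[0, 1)` ([time_gate_phase()]).
#' @param r_on open ratio in `(0, 1]`.
#' @param leak leak rate in `[0, 1)`.
#' @return gate openness `k` in `[0, 1]`.
#' @examples
#' time_gate_openness(0.125, r_on = 0.5, leak = 0.001)  # 0.5
#' @export
time_gate_openness <- function(phi, r_on, leak) {
  assert_number(r_on, "r_on", lower = 0, upper = 1, allow_equal_lower = FALSE)
  assert_number(leak, "leak", lower = 0, upper = 1, allow_equal_upper = FALSE)
  if (any(phi < 0 | phi >= 1)) stopf("phi must lie in [0, 1)")
  k <- leak * phi
  up <- phi < r_on / 2
  down <- !up & phi < r_on
  k[up] <- 2 * phi[up] / r_on
  k[down] <- 2 - 2 * phi[down] / r_on
  k
}

# branch derivative dk/dphi, matching time_gate_openness
time_gate_dk_dphi <- function(phi, r_on, leak) {
  d <- array(leak, dim = dim(phi) %||% length(phi))
  up <- phi < r_on / 2
  down <- !up & phi < r_on
  d[up] <- 2 / r_on
  d[down] <- -2 / r_on
  d
}

as_row <- function(x) if (is.matrix(x)) x else matrix(x, 1)

# shared gate computation; all arguments are B x * matrices
lstm_gates <- function(X, Hprev, Cprev, params) {
  H <- params$hidden_size
  B <- nrow(X)
  idx <- gate_idx(H)
  Z <- X %*% params$W_x + Hprev %*% params$W_h +
    matrix(params$b, B, 4 * H, byrow = TRUE)
  i <- 1 / (1 + exp(-(Z[, idx$i, drop = FALSE] + t(t(Cprev) * params$w_ci))))
  f <- 1 / (1 + exp(-(Z[, idx$f, drop = FALSE] + t(t(Cprev) * params$w_cf))))
  g <- tanh(Z[, idx$g, drop = FALSE])
  o <- 1 / (1 + exp(-(Z[, idx$o, drop = FALSE] + t(t(Cprev) * params$w_co))))
  c_star <- f * Cprev + i * g
  tc <- tanh(c_star)
  list(i = i, f = f, g = g, o = o, c_star = c_star, tc = tc,
       h_star = o * tc)
}

#' One peephole-LSTM step
#'
#' Applies the printed update equations once. `x` may be a single input
#' vector or a batch matrix (rows are independent sequences).
#'
#' @param x input vector (length `input_size`) or matrix (B x input_size).
#' @param state list with `c` and `h` (vectors or B x H matrices); `NULL`
#'   starts from zeros.
#' @param params an [lstm_params()] object.
#' @return list with the new `c`, `h` and the gate activations `i`, `f`, `o`.
#' @export
lstm_step <- function(x, state, params) {
  stopifnot(inherits(params, "lstm_params"))
  X <- as_row(x)
  vec <- !is.matrix(x)
  if (ncol(X) != params$input_size) stopf("input size mismatch: got %d, expected %d",
                                          ncol(X), params$input_size)
  H <- params$hidden_size
  Cprev <- as_row(state$c %||% matrix(0, nrow(X), H))
  Hprev <- as_row(state$h %||% matrix(0, nrow(X), H))
  g <- lstm_gates(X, Hprev, Cprev, params)
  out <- list(c = g$c_star, h = g$h_star, i = g$i, f = g$f, o = g$o)
  if (vec) out <- lapply(out, drop)
  out
}

#' One Phased-LSTM step
#'
#' Computes the proposed LSTM state and blends it with the previous state
#' through the per-unit time gate evaluated at event time `t`. Event times
#' must be non-decreasing within a sequence.
#'
#' @inheritParams lstm_step
#' @param t event time (scalar, or length-B vector for a batch).
#' @param gate_params a [phased_gate_params()] object.
#' @param state list with `c`, `h` and optionally `t` (previous event time).
#' @param k_override optional gate matrix/vector forcing `k` (test hook;
#'   `k_override = 1` reduces the step to [lstm_step()]).
#' @return list with new `c`, `h`, the gate `k`, and `t`.
#' @export
phased_lstm_step <- function(x, t, state, params, gate_params,
                             k_override = NULL) {
  stopifnot(inherits(params, "lstm_params"),
            inherits(gate_params, "phased_gate_params"))
  X <- as_row(x)
  vec <- !is.matrix(x)
  H <- params$hidden_size
  B <- nrow(X)
  Cprev <- as_row(state$c %||% matrix(0, B, H))
  Hprev <- as_row(state$h %||% matrix(0, B, H))
  if (!is.null(state$t) && any(t < state$t)) {
    stopf("event times must be non-decreasing (got %g after %g)",
          min(t), max(state$t))
  }
  g <- lstm_gates(X, Hprev, Cprev, params)
  if (is.null(k_override)) {
    Tm <- matrix(t, B, H)
    phi <- time_gate_phase(Tm, matrix(gate_params$tau, B, H, byrow = TRUE),
                           matrix(gate_params$s, B, H, byrow = TRUE))
    k <- matrix(time_gate_openness(phi, gate_params$r_on, gate_params$leak),
                B, H)
  } else {
    k <- matrix(k_override, B, H)
  }
  cnew <- k * g$c_star + (1 - k) * Cprev
  hnew <- k * g$h_star + (1 - k) * Hprev
  out <- list(c = cnew, h = hnew, k = k, t = t)
  if (vec) out[c("c", "h", "k")] <- lapply(out[c("c", "h", "k")], drop)
  out
}

#' Numerically stable softmax
#'
#' @param z logit vector, or matrix with one logit row per case.
#' @return probabilities summing to 1 per row.
#' @examples
#' softmax_output(c(1, 2))
#' @export
softmax_output <- function(z) {
  Z <- as_row(z)
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  if (!is.matrix(z)) drop(P) else P
}
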