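# The QuantClass decision head: a two-qubit circuit whose four basis-outcome
# probabilities serve as class scores, trained through the parameter-shift rule.
#
# Two circuit modes are provided.
#
# "literal" reproduces the reported circuit U = (H (x) H) . (RX(theta) (x)
# RX(theta)) acting on |00>. Each qubit then carries equal-magnitude
# amplitudes, so the four basis probabilities are exactly 1/4 for EVERY theta
# and the parameter-shift gradient vanishes identically. The mode is kept for
# fidelity checks; it cannot learn.
#
# "functional" (default) is the minimal trainable variant: H first, then an
# RY rotation per qubit, giving per-qubit P(1) = (1 + sin theta)/2. To make all
# four outcomes distinguishable the head drives each qubit with its own angle
# (a shared angle leaves p01 == p10 for every theta, capping 4-class accuracy);
# scalar theta is recycled to both qubits.

#' QuantClass configuration
#'
#' @param mode `"functional"` (default, trainable) or `"literal"` (the reported
#'   H-then-RX circuit, whose outcome distribution is flat in theta).
#' @param s parameter-shift amount in radians, in `(0, pi)`; default `pi/2`
#'   gives the shift-rule denominator 2.
#' @param jitter_sigma standard deviation of the optional random shift added to
#'   the encoded angle on the forward pass (default 0 = off).
#' @param shots shots for sampled evaluation (default 1024).
#' @param eval `"exact"` statevector probabilities (default) or `"sampled"`.
#' @param seed integer seed for jitter / sampling.
#' @return list of class `quantclass_config`.
#' @export
quantclass_config <- function(mode = c("functional", "literal"),
                              s = pi / 2, jitter_sigma = 0,
                              shots = 1024L, eval = c("exact", "sampled"),
                              seed = NULL) {
  if (!is.numeric(s) || s <= 0 || s >= pi) {
    qt_stop("shift s must lie in (0, pi)", class = "qtremor_domain_error")
  }
  if (jitter_sigma < 0) qt_stop("jitter_sigma must be >= 0", class = "qtremor_domain_error")
  structure(list(mode = match.arg(mode), s = s, jitter_sigma = jitter_sigma,
                 shots = as.integer(shots), eval = match.arg(eval), seed = seed),
            class = "quantclass_config")
}

#' Angle encoding of the penultimate layer output
#'
#' Squashed affine map `theta = pi * tanh(w1*x1 + w2*x2 + b)`, so the encoded
#' angle always lies in `(-pi, pi)` and is differentiable everywhere.
#'
#' @param x1,x2 the two penultimate-layer activations.
#' @param enc a [theta_encoding()].
#' @return encoded angle in radians.
#' @export
encode_theta <- function(x1, x2, enc = theta_encoding()) {
  pi * tanh(enc$w1 * x1 + enc$w2 * x2 + enc$b)
}

#' @rdname encode_theta
#' @param w1,w2,b affine weights and bias (defaults 1, 1, 0).
#' @export
theta_encoding <- function(w1 = 1, w2 = 1, b = 0) {
  list(w1 = w1, w2 = w2, b = b)
}

#' The two-qubit QuantClass unitary
#'
#' @param theta rotation angle(s) in radians; length 1 (shared by both qubits)
#'   or 2 (one per qubit).
#' @param mode `"literal"`: `(H (x) H) . (RX (x) RX)` exactly as reported;
#'   `"functional"`: `(RY (x) RY) . (H (x) H)` (H applied first).
#' @return complex 4x4 unitary.
#' @export
quantclass_unitary <- function(theta, mode = c("functional", "literal")) {
  mode <- match.arg(mode)
  if (!is.numeric(theta) || !all(is.finite(theta)) || !length(theta) %in% 1:2) {
    qt_stop("theta must be 1 or 2 finite angles", class = "qtremor_domain_error")
  }
  th <- rep(theta, length.out = 2)
  H2 <- kronecker(hadamard_gate(), hadamard_gate())
  if (mode == "literal") {
    H2 %*% kronecker(rx_gate(th[1]), rx_gate(th[2]))
  } else {
    kronecker(ry_gate(th[1]), ry_gate(th[2])) %*% H2
  }
}

#' Forward pass of the QuantClass head
#'
#' Applies the circuit to `|00>` and returns the probabilities of the four
#' outcomes `{00, 01, 10, 11}` (class indices 0..3 in that order).
#'
#' @param theta angle(s) in radians (length 1 or 2).
#' @param cfg a [quantclass_config()].
#' @return numeric probability vector of length 4.
#' @export
#' @examples
#' quantclass_forward(pi / 2)                     # concentrates on outcome 11
#' quantclass_forward(1, quantclass_config("literal"))   # flat 1/4 regardless
quantclass_forward <- function(theta, cfg = quantclass_config()) {
  if (!is.numeric(theta) || !all(is.finite(theta)) || !length(theta) %in% 1:2) {
    qt_stop("theta must be 1 or 2 finite angles", class = "qtremor_domain_error")
  }
  if (cfg$jitter_sigma > 0) {
    theta <- theta + with_seed(cfg$seed, rnorm(length(theta), 0, cfg$jitter_sigma))
  }
  st <- apply_unitary(statevector(2), quantclass_unitary(theta, cfg$mode))
  p <- basis_probabilities(st)
  if (cfg$eval == "sampled") {
    p <- sample_counts(p, cfg$shots, cfg$seed) / cfg$shots
  }
  p
}

#' Parameter-shift gradient of a circuit output
#'
#' Central estimator `(f(theta + s) - f(theta - s)) / (2 sin s)`; with the
#' default `s = pi/2` the denominator is 2. Exact (not approximate) for any
#' output with single-frequency dependence on the shifted parameter.
#'
#' @param circuit function mapping an angle vector to a numeric output vector.
#' @param theta angle(s) at which to differentiate.
#' @param s shift in radians (nonzero modulo pi).
#' @return if `theta` is scalar, the gradient vector d out / d theta; otherwise
#'   a Jacobian matrix with one column per component of `theta`.
#' @export
parameter_shift_grad <- function(circuit, theta, s = pi / 2) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || abs(sin(s)) < 1e-12) {
    qt_stop("shift s must be nonzero modulo pi", class = "qtremor_domain_error")
  }
  jac <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + s
    tm <- theta; tm[i] <- tm[i] - s
    (circuit(tp) - circuit(tm)) / (2 * sin(s))
  }, numeric(length(circuit(theta))))
  if (length(theta) == 1L) as.vector(jac) else jac
}

#' Backward pass of the hybrid head
#'
#' Contracts the upstream loss gradient with the parameter-shift Jacobian of
#' the outcome probabilities: `dL/dtheta_i = sum_c upstream[c] * dp_c/dtheta_i`.
#'
#' @param upstream_grad numeric vector of length 4 (`dL/dp`).
#' @param theta angle(s) at which the forward pass ran.
#' @param cfg a [quantclass_config()] (evaluated in exact mode for the shifts).
#' @return numeric gradient, one entry per component of `theta`.
#' @export
hybrid_backward <- function(upstream_grad, theta, cfg = quantclass_config()) {
  if (length(upstream_grad) != 4L) {
    qt_stop("upstream_grad must have length 4", class = "qtremor_structural_error")
  }
  exact_cfg <- quantclass_config(mode = cfg$mode, s = cfg$s)
  jac <- parameter_shift_grad(function(t) quantclass_forward(t, exact_cfg),
                              theta, cfg$s)
  as.vector(crossprod(matrix(jac, nrow = 4L), upstream_grad))
}

# Vectorised closed-form outcome probabilities of the functional circuit:
# per-qubit P(1) = (1 + sin theta)/2, joint = product (the circuit is a product
# state). Used by the network layer; equality with quantclass_forward is
# asserted in the tests.
qclass_prob_matrix <- function(theta1, theta2, mode = "functional") {
  n <- length(theta1)
  if (mode == "literal") return(matrix(0.25, 4L, n))
  q1 <- (1 + sin(theta1)) / 2
  q2 <- (1 + sin(theta2)) / 2
  rbind((1 - q1) * (1 - q2), (1 - q1) * q2, q1 * (1 - q2), q1 * q2)
}
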