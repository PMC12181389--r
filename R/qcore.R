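# Exact statevector simulation of small qubit registers.
#
# Basis convention used throughout the package: qubit 0 is the MOST significant
# bit of the computational-basis label, so for two qubits the basis order is
# |00>, |01>, |10>, |11> with the first bit belonging to qubit 0.

#' Create a computational-basis statevector
#'
#' @param n_qubits number of qubits (1..16).
#' @param basis_index integer in `0:(2^n_qubits - 1)`; the register is prepared
#'   in that computational-basis state (default `0`, i.e. `|0...0>`).
#' @return An object of class `statevector`: a list with `n_qubits` and the
#'   complex `amplitudes` vector of length `2^n_qubits`.
#' @export
#' @examples
#' s <- statevector(2)          # |00>
#' basis_probabilities(s)
statevector <- function(n_qubits, basis_index = 0L) {
  if (!is.numeric(n_qubits) || n_qubits < 1 || n_qubits > 16 ||
      n_qubits != round(n_qubits)) {
    qt_stop("n_qubits must be an integer in 1..16", class = "qtremor_domain_error")
  }
  n_qubits <- as.integer(n_qubits)
  dim <- 2L^n_qubits
  if (basis_index < 0 || basis_index >= dim) {
    qt_stop("basis_index out of range", class = "qtremor_domain_error")
  }
  amp <- complex(dim)
  amp[basis_index + 1L] <- 1 + 0i
  structure(list(n_qubits = n_qubits, amplitudes = amp), class = "statevector")
}

#' @export
print.statevector <- function(x, ...) {
  cat(sprintf("<statevector: %d qubit(s), %d amplitudes, norm %.12f>\n",
              x$n_qubits, length(x$amplitudes),
              sqrt(sum(Mod(x$amplitudes)^2))))
  invisible(x)
}

#' Elementary gate matrices
#'
#' Closed-form unitaries used by the circuit filters: the Hadamard gate,
#' single-qubit X/Y rotations, and the two-qubit Ising couplings
#' `XX(theta) = exp(-i theta/2 X(x)X)` and `ZZ(theta) = exp(-i theta/2 Z(x)Z)`.
#'
#' @param theta rotation angle in radians (finite).
#' @return A complex unitary matrix (2x2 for single-qubit gates, 4x4 for the
#'   Ising couplings).
#' @export
#' @examples
#' hadamard_gate() %*% hadamard_gate()   # identity
#' ising_zz_gate(pi)                     # diag(-i, i, i, -i)
hadamard_gate <- function() {
  matrix(c(1, 1, 1, -1), 2, 2, byrow = TRUE) / sqrt(2) + 0i
}

#' @rdname hadamard_gate
#' @export
rx_gate <- function(theta) {
  check_finite_scalar(theta, "theta")
  c <- cos(theta / 2); s <- sin(theta / 2)
  matrix(c(c + 0i, -1i * s, -1i * s, c + 0i), 2, 2, byrow = TRUE)
}

#' @rdname hadamard_gate
#' @export
ry_gate <- function(theta) {
  check_finite_scalar(theta, "theta")
  c <- cos(theta / 2); s <- sin(theta / 2)
  matrix(c(c, -s, s, c), 2, 2, byrow = TRUE) + 0i
}

#' @rdname hadamard_gate
#' @export
ising_xx_gate <- function(theta) {
  check_finite_scalar(theta, "theta")
  c <- cos(theta / 2); s <- sin(theta / 2)
  xx <- matrix(0, 4, 4)
  xx[cbind(1:4, 4:1)] <- 1          # X (x) X is the bit-reversal permutation
  diag(4) * (c + 0i) - 1i * s * xx
}

#' @rdname hadamard_gate
#' @export
ising_zz_gate <- function(theta) {
  check_finite_scalar(theta, "theta")
  diag(exp(-1i * theta / 2 * c(1, -1, -1, 1)))
}

# Bit position (from the least-significant end) of qubit `q` in an n-qubit
# register under the qubit-0-is-MSB convention.
bitpos <- function(q, n_qubits) n_qubits - 1L - as.integer(q)

#' Embed a gate into a larger register
#'
#' Returns the dense `2^n_qubits` unitary that acts as `gate` on the ordered
#' qubits `wires` (0-based, wire order = gate qubit order) and as the identity
#' elsewhere. Intended for small registers; use [apply_gate()] to act on a
#' statevector without materialising the full matrix.
#'
#' @param gate complex unitary of dimension `2^length(wires)`.
#' @param wires 0-based qubit indices, distinct, each in `0:(n_qubits-1)`.
#' @param n_qubits register size (dense construction capped at 12 qubits).
#' @return complex `2^n_qubits` x `2^n_qubits` matrix.
#' @export
embed_gate <- function(gate, wires, n_qubits) {
  n_qubits <- as.integer(n_qubits)
  wires <- as.integer(wires)
  k <- length(wires)
  if (n_qubits > 12L) {
    qt_stop("dense embedding capped at 12 qubits", class = "qtremor_structural_error")
  }
  if (anyDuplicated(wires) || any(wires < 0L | wires >= n_qubits)) {
    qt_stop("wires must be distinct and within 0:(n_qubits-1)",
            class = "qtremor_structural_error")
  }
  if (!is.matrix(gate) || nrow(gate) != 2L^k || ncol(gate) != 2L^k) {
    qt_stop("gate dimension does not match number of wires",
            class = "qtremor_structural_error")
  }
  d <- 2L^n_qubits
  idx <- 0:(d - 1L)
  # gate-subspace label of every basis index (wire order, first wire = MSB of
  # the gate label)
  glab <- integer(d)
  for (j in seq_len(k)) {
    bit <- bitwAnd(bitwShiftR(idx, bitpos(wires[j], n_qubits)), 1L)
    glab <- glab + bit * 2L^(k - j)
  }
  # residual label over the untouched qubits
  rest <- idx
  for (j in seq_len(k)) {
    rest <- rest - bitwAnd(idx, bitwShiftL(1L, bitpos(wires[j], n_qubits)))
  }
  U <- matrix(0 + 0i, d, d)
  ord <- order(glab, rest)         # indices grouped by gate label, aligned by rest
  m <- d %/% (2L^k)                # residual block size
  for (a in seq_len(2L^k)) {
    rows <- ord[seq.int((a - 1L) * m + 1L, a * m)]
    for (b in seq_len(2L^k)) {
      cols <- ord[seq.int((b - 1L) * m + 1L, b * m)]
      if (gate[a, b] != 0) U[cbind(rows, cols)] <- gate[a, b]
    }
  }
  U
}

#' Apply a full-register unitary to a statevector
#'
#' @param state a [statevector()].
#' @param U complex unitary whose dimension matches the state.
#' @return the transformed `statevector`.
#' @export
apply_unitary <- function(state, U) {
  if (!inherits(state, "statevector")) {
    qt_stop("state must be a statevector", class = "qtremor_structural_error")
  }
  d <- length(state$amplitudes)
  if (!is.matrix(U) || nrow(U) != d || ncol(U) != d) {
    qt_stop("unitary dimension does not match state", class = "qtremor_structural_error")
  }
  state$amplitudes <- as.vector(U %*% state$amplitudes)
  state
}

#' Apply a 1- or 2-qubit gate in place on named wires
#'
#' Acts on the statevector by index arithmetic, so it scales to the full
#' 16-qubit register used by the 4x4 Quantvolution window.
#'
#' @inheritParams apply_unitary
#' @param gate 2x2 or 4x4 complex gate matrix.
#' @param wires 0-based qubit indices (length 1 or 2, order = gate qubit order).
#' @return the transformed `statevector`.
#' @export
apply_gate <- function(state, gate, wires) {
  if (!inherits(state, "statevector")) {
    qt_stop("state must be a statevector", class = "qtremor_structural_error")
  }
  n <- state$n_qubits
  wires <- as.integer(wires)
  if (any(wires < 0L | wires >= n) || anyDuplicated(wires)) {
    qt_stop("wire index out of range", class = "qtremor_structural_error")
  }
  d <- length(state$amplitudes)
  idx <- 0:(d - 1L)
  amp <- state$amplitudes
  if (length(wires) == 1L) {
    if (!all(dim(gate) == c(2L, 2L))) {
      qt_stop("gate/wires mismatch", class = "qtremor_structural_error")
    }
    st <- bitwShiftL(1L, bitpos(wires, n))
    i0 <- which(bitwAnd(idx, st) == 0L)
    block <- gate %*% rbind(amp[i0], amp[i0 + st])
    amp[i0] <- block[1L, ]
    amp[i0 + st] <- block[2L, ]
  } else if (length(wires) == 2L) {
    if (!all(dim(gate) == c(4L, 4L))) {
      qt_stop("gate/wires mismatch", class = "qtremor_structural_error")
    }
    sa <- bitwShiftL(1L, bitpos(wires[1L], n))   # first wire = MSB of gate label
    sb <- bitwShiftL(1L, bitpos(wires[2L], n))
    i00 <- which(bitwAnd(idx, sa) == 0L & bitwAnd(idx, sb) == 0L)
    block <- gate %*% rbind(amp[i00], amp[i00 + sb], amp[i00 + sa], amp[i00 + sa + sb])
    amp[i00] <- block[1L, ]
    amp[i00 + sb] <- block[2L, ]
    amp[i00 + sa] <- block[3L, ]
    amp[i00 + sa + sb] <- block[4L, ]
  } else {
    qt_stop("only 1- and 2-qubit gates are supported", class = "qtremor_structural_error")
  }
  state$amplitudes <- amp
  state
}

#' Computational-basis outcome probabilities
#'
#' @param state a [statevector()].
#' @return numeric vector of `2^n` probabilities (squared amplitude moduli).
#' @export
basis_probabilities <- function(state) {
  if (!inherits(state, "statevector")) {
    qt_stop("state must be a statevector", class = "qtremor_structural_error")
  }
  Mod(state$amplitudes)^2
}

#' Per-qubit marginal probability of outcome 1
#'
#' @param state a [statevector()].
#' @return numeric vector of length `n_qubits`; entry `q+1` is `P(qubit q = 1)`.
#' @export
qubit_marginals <- function(state) {
  p <- basis_probabilities(state)
  n <- state$n_qubits
  idx <- 0:(length(p) - 1L)
  vapply(0:(n - 1L), function(q) {
    sum(p[bitwAnd(idx, bitwShiftL(1L, bitpos(q, n))) != 0L])
  }, numeric(1))
}

#' Multinomial shot sampling of a probability vector
#'
#' Emulates repeated measurement of a circuit: `shots` draws from the basis
#' distribution, reproducible for a fixed seed.
#'
#' @param p probability vector (non-negative, sums to 1 within 1e-9).
#' @param shots number of measurements (default 1024).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return integer vector of counts summing to `shots`.
#' @export
sample_counts <- function(p, shots = 1024L, seed = NULL) {
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-9) {
    qt_stop("p is not a probability vector", class = "qtremor_domain_error")
  }
  if (!is.numeric(shots) || shots < 1) {
    qt_stop("shots must be >= 1", class = "qtremor_domain_error")
  }
  p <- pmax(p, 0)
  with_seed(seed, as.integer(rmultinom(1L, size = as.integer(shots), prob = p)))
}
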