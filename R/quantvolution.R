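# The Quantvolution filter: every k x k pixel window becomes a ring graph over
# its k^2 pixels (row-major nodes), one qubit per ring edge. Each edge (j,k)
# contributes, in circuit order, H on both edge qubits, then IsingXX(pi*theta[j])
# and IsingZZ(pi*theta[j]) on the pair, where theta[j] = arccos(p_j) is taken
# from the normalized source pixel. The per-qubit marginal P(1) of the final
# state yields k^2 output channels per window.

#' Ring graph over a k x k pixel window
#'
#' Nodes are the window pixels in row-major order; edges form the ring
#' `(0,1), (1,2), ..., (k^2-1, 0)`, so every node has degree 2 and there are
#' exactly `k^2` edges (one qubit per edge).
#'
#' @param k window side length, 2 or 4.
#' @return list with `k`, `nodes` (0-based) and an `edges` matrix (k^2 x 2).
#' @export
#' @examples
#' window_graph(2)$edges   # the 2x2 node pairs (0,1),(1,2),(2,3),(3,0)
window_graph <- function(k) {
  if (!k %in% c(2L, 4L)) {
    qt_stop("window size k must be 2 or 4", class = "qtremor_domain_error")
  }
  m <- as.integer(k)^2
  list(k = as.integer(k),
       nodes = 0:(m - 1L),
       edges = cbind(0:(m - 1L), c(1:(m - 1L), 0L)))
}

#' Pixel-to-angle mapping
#'
#' A normalized gray value in `[0, 1]` is interpreted as the cosine of the
#' circuit angle: `theta = arccos(p)`, so bright pixels map to small angles.
#'
#' @param p normalized pixel value(s) in `[0, 1]`.
#' @return angle(s) in radians, in `[0, pi/2]`.
#' @export
pixel_to_theta <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    qt_stop("pixel values must lie in [0, 1]", class = "qtremor_domain_error")
  }
  acos(p)
}

#' Quantvolution configuration
#'
#' @param k window side length (2 or 4).
#' @param stride tiling stride (default `k`, i.e. non-overlapping windows;
#'   remainder rows/columns are dropped).
#' @param theta_source `"first"`: the edge angle comes from the pixel at the
#'   edge's first node (default); `"mean"`: from the mean of both endpoint
#'   pixels.
#' @param angle_mapping `"arccos"`: gate angle `pi * arccos(p)` (default);
#'   `"direct"`: gate angle `pi * p`.
#' @param mode `"exact"` statevector marginals (default) or `"sampled"`
#'   shot-estimated marginals.
#' @param shots shots per circuit in sampled mode (default 1024).
#' @param seed integer seed for sampled mode.
#' @return list of class `quantvolution_config`.
#' @export
quantvolution_config <- function(k = 2L, stride = k,
                                 theta_source = c("first", "mean"),
                                 angle_mapping = c("arccos", "direct"),
                                 mode = c("exact", "sampled"),
                                 shots = 1024L, seed = NULL) {
  if (!k %in% c(2L, 4L)) qt_stop("k must be 2 or 4", class = "qtremor_domain_error")
  if (stride < 1) qt_stop("stride must be >= 1", class = "qtremor_domain_error")
  structure(list(k = as.integer(k), stride = as.integer(stride),
                 theta_source = match.arg(theta_source),
                 angle_mapping = match.arg(angle_mapping),
                 mode = match.arg(mode),
                 shots = as.integer(shots), seed = seed),
            class = "quantvolution_config")
}

gate_angles <- function(p_first, p_second, cfg) {
  p <- if (cfg$theta_source == "mean") (p_first + p_second) / 2 else p_first
  if (cfg$angle_mapping == "arccos") pi * acos(p) else pi * p
}

#' Dense n-qubit unitary for one ring edge
#'
#' Circuit order per edge: H on both qubits, then `IsingXX(pi*theta_j)`, then
#' `IsingZZ(pi*theta_j)` on the pair, embedded into the full register.
#'
#' @param edge integer pair of 0-based qubit indices `(j, k)`.
#' @param theta_j edge angle (radians); the Ising gate angle is `pi * theta_j`.
#' @param n_qubits register size (dense construction, so at most 12).
#' @return complex `2^n_qubits` square matrix.
#' @export
edge_unitary <- function(edge, theta_j, n_qubits) {
  check_finite_scalar(theta_j, "theta_j")
  phi <- pi * theta_j
  H <- hadamard_gate()
  embed_gate(ising_zz_gate(phi), edge, n_qubits) %*%
    embed_gate(ising_xx_gate(phi), edge, n_qubits) %*%
    embed_gate(H, edge[2L], n_qubits) %*%
    embed_gate(H, edge[1L], n_qubits)
}

# Apply one edge circuit to a statevector (index arithmetic; works to 16 qubits).
apply_edge <- function(state, edge, phi) {
  H <- hadamard_gate()
  state <- apply_gate(state, H, edge[1L])
  state <- apply_gate(state, H, edge[2L])
  state <- apply_gate(state, ising_xx_gate(phi), edge)
  apply_gate(state, ising_zz_gate(phi), edge)
}

#' Quantvolve a single k x k window (statevector reference path)
#'
#' Initialises `|0...0>` on the k^2 edge qubits, applies the edge circuits in
#' ring order, and returns the per-qubit marginal probability of outcome 1.
#'
#' @param window numeric k x k matrix with values in `[0, 1]`.
#' @param cfg a [quantvolution_config()].
#' @return numeric channel vector of length `k^2`.
#' @export
quantvolve_window <- function(window, cfg = quantvolution_config()) {
  k <- cfg$k
  if (!is.matrix(window) || !all(dim(window) == k)) {
    qt_stop("window must be a ", k, "x", k, " matrix", class = "qtremor_structural_error")
  }
  if (any(window < 0 | window > 1)) {
    qt_stop("window values must lie in [0, 1]", class = "qtremor_domain_error")
  }
  g <- window_graph(k)
  px <- as.vector(t(window))                 # row-major node values
  m <- k^2
  state <- statevector(m)
  for (e in seq_len(m)) {
    edge <- g$edges[e, ]
    phi <- gate_angles(px[edge[1L] + 1L], px[edge[2L] + 1L], cfg)
    state <- apply_edge(state, edge, phi)
  }
  marg <- qubit_marginals(state)
  if (cfg$mode == "sampled") {
    marg <- with_seed(cfg$seed, rbinom(m, cfg$shots, marg)) / cfg$shots
  }
  marg
}

# --- ring contraction engine ------------------------------------------------
#
# The edge circuits are applied in ring order (0,1),(1,2),...,(m-1,0), so the
# circuit is a staircase: qubit j is never touched after edge j (j = 1..m-2),
# and qubit 0 only again by the closing edge. Single-qubit marginals therefore
# follow from a reduced density matrix over at most three qubits (qubit 0, the
# frontier pair), swept once around the ring -- O(m) work per window instead of
# O(2^m), and vectorised across all windows of an image.
#
# Density matrices are carried in vec (column-major) form, one column per
# window. Per edge, with A = H(x)H on the pair, P = X(x)X (index XOR), and the
# ZZ phase diag(exp(-i phi/2 s_b)):
#   rho <- A rho A'            (fixed real matrix in vec space)
#   rho <- c^2 rho + i c s (rho P - P rho) + s^2 P rho P     (XX conjugation)
#   rho <- D rho D*            (elementwise phase factors exp(-i phi g))

ring_vec_maps <- function(nq) {
  d <- 2L^nq
  v <- 0:(d * d - 1L)
  r <- v %% d
  cc <- v %/% d
  p <- function(b) bitwXor(b, 3L)            # flip the two least-significant bits
  sig <- function(b) ifelse(bitwAnd(b, 1L) == bitwAnd(b, 2L) %/% 2L, 1, -1)
  A1 <- if (nq == 2L) kronecker(hadamard_gate(), hadamard_gate())
        else kronecker(diag(2), kronecker(hadamard_gate(), hadamard_gate()))
  list(
    d = d,
    MA = Re(kronecker(A1, A1)),
    prow = p(r) + d * cc + 1L,
    pcol = r + d * p(cc) + 1L,
    pboth = p(r) + d * p(cc) + 1L,
    g = (sig(r) - sig(cc)) / 2
  )
}

# Conjugate every column of rho_v (d^2 x W) by the edge unitary with per-window
# angles phi (length W), acting on the two least-significant register qubits.
ring_apply_edge <- function(rho_v, phi, maps) {
  rho_v <- maps$MA %*% rho_v
  c2 <- cos(phi / 2)^2
  s2 <- sin(phi / 2)^2
  cs <- cos(phi / 2) * sin(phi / 2)
  n <- nrow(rho_v)
  sc <- function(vals) matrix(vals, n, length(phi), byrow = TRUE)
  rho_v <- sc(c2) * rho_v +
    (1i) * sc(cs) * (rho_v[maps$pcol, , drop = FALSE] - rho_v[maps$prow, , drop = FALSE]) +
    sc(s2) * rho_v[maps$pboth, , drop = FALSE]
  rho_v * exp(-1i * outer(maps$g, phi))
}

# Marginals of every ring qubit for a batch of windows.
# phi: m x W matrix of per-edge gate angles. Returns m x W marginals P(1).
ring_marginals <- function(phi) {
  m <- nrow(phi)
  W <- ncol(phi)
  stopifnot(m >= 3L)
  maps2 <- ring_vec_maps(2L)
  maps3 <- ring_vec_maps(3L)
  out <- matrix(0, m, W)

  # register (q0, q1): start in |00><00|, apply edge 0
  rho <- matrix(0 + 0i, 16L, W)
  rho[1L, ] <- 1
  rho <- ring_apply_edge(rho, phi[1L, ], maps2)

  # extension scatter (q0,qj) -> (q0,qj,qj+1=|0>), trace-out gathers, and the
  # diagonal indices of bit patterns, all 0-based index precomputation
  v4 <- 0:15L; r4 <- v4 %% 4L; c4 <- v4 %/% 4L
  ext_idx <- 2L * r4 + 16L * c4 + 1L                       # into the 64-vec
  r8 <- function(x) 4L * (x %/% 2L) + (x %% 2L)            # (q0,b0) -> (q0,m,b0)
  tr0 <- r8(r4) + 8L * r8(c4) + 1L
  tr1 <- (r8(r4) + 2L) + 8L * (r8(c4) + 2L) + 1L
  diag_j <- 9L * c(2L, 3L, 6L, 7L) + 1L                    # bit1 set, 3-qubit diag

  for (j in seq_len(m - 2L)) {                             # edges 1 .. m-2
    big <- matrix(0 + 0i, 64L, W)
    big[ext_idx, ] <- rho
    big <- ring_apply_edge(big, phi[j + 1L, ], maps3)
    out[j + 1L, ] <- colSums(Re(big[diag_j, , drop = FALSE]))
    rho <- big[tr0, , drop = FALSE] + big[tr1, , drop = FALSE]
  }

  # closing edge (m-1, 0) on register (q0, q_{m-1}); the edge circuit is
  # symmetric under qubit swap, so wire order is immaterial
  rho <- ring_apply_edge(rho, phi[m, ], maps2)
  dg <- rho[5L * (0:3L) + 1L, , drop = FALSE]              # 2-qubit diagonal
  out[1L, ] <- colSums(Re(dg[c(3L, 4L), , drop = FALSE]))   # q0 = bit1
  out[m, ] <- colSums(Re(dg[c(2L, 4L), , drop = FALSE]))    # q_{m-1} = bit0
  pmin(pmax(out, 0), 1)
}

#' Quantvolve a whole image
#'
#' Tiles the image with non-overlapping k x k windows (stride `k`, remainder
#' rows/columns dropped) and runs the ring circuit on every window, returning a
#' feature map with one channel per ring qubit.
#'
#' @param image numeric matrix with values in `[0, 1]` (a normalized tremor
#'   image), or a `tremor_image`.
#' @param cfg a [quantvolution_config()].
#' @return array of class `feature_map`, dim `(floor(H/k), floor(W/k), k^2)`,
#'   values in `[0, 1]`.
#' @export
#' @examples
#' img <- matrix(runif(20 * 16), 20, 16)
#' fm <- quantvolve_image(img, quantvolution_config(k = 2))
#' dim(fm)   # 10 x 8 x 4
quantvolve_image <- function(image, cfg = quantvolution_config()) {
  if (inherits(image, "tremor_image")) image <- normalized_pixels(image)
  if (!is.matrix(image)) {
    qt_stop("image must be a numeric matrix", class = "qtremor_structural_error")
  }
  k <- cfg$k
  if (nrow(image) < k || ncol(image) < k) {
    qt_stop("image smaller than the ", k, "x", k, " window",
            class = "qtremor_domain_error")
  }
  if (any(image < 0 | image > 1)) {
    qt_stop("image values must lie in [0, 1]", class = "qtremor_domain_error")
  }
  ho <- nrow(image) %/% k
  wo <- ncol(image) %/% k
  m <- k^2
  W <- ho * wo
  # node pixel values per window, windows ordered row-index fastest
  P <- matrix(0, m, W)
  for (nd in 0:(m - 1L)) {
    rows <- (0:(ho - 1L)) * k + nd %/% k + 1L
    cols <- (0:(wo - 1L)) * k + nd %% k + 1L
    P[nd + 1L, ] <- as.vector(image[rows, cols, drop = FALSE])
  }
  phi <- gate_angles(P, P[c(2:m, 1L), , drop = FALSE], cfg)
  marg <- ring_marginals(phi)
  if (cfg$mode == "sampled") {
    marg <- matrix(with_seed(cfg$seed, rbinom(length(marg), cfg$shots, marg)),
                   m, W) / cfg$shots
  }
  fm <- array(0, dim = c(ho, wo, m))
  for (ch in seq_len(m)) fm[, , ch] <- matrix(marg[ch, ], ho, wo)
  structure(fm, class = "feature_map", k = k, stride = cfg$stride,
            mode = cfg$mode, theta_source = cfg$theta_source,
            angle_mapping = cfg$angle_mapping)
}

#' Write a feature map as grayscale PNG channels plus a JSON sidecar
#'
#' @param fm a `feature_map` from [quantvolve_image()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the sidecar path.
#' @export
write_feature_map <- function(fm, dir, prefix = "channel") {
  if (!inherits(fm, "feature_map")) {
    qt_stop("fm must be a feature_map", class = "qtremor_structural_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nch <- dim(fm)[3]
  files <- character(nch)
  for (ch in seq_len(nch)) {
    files[ch] <- file.path(dir, sprintf("%s_%02d.png", prefix, ch))
    png::writePNG(round(fm[, , ch] * 255) / 255, files[ch])
  }
  sidecar <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(list(
    shape = dim(fm), k = attr(fm, "k"), stride = attr(fm, "stride"),
    mode = attr(fm, "mode"), theta_source = attr(fm, "theta_source"),
    angle_mapping = attr(fm, "angle_mapping"), files = basename(files)
  ), sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}
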