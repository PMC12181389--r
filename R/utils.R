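#' @importFrom stats rnorm runif rbinom rmultinom sd aov TukeyHSD pf
#' @importFrom utils write.csv read.csv
NULL

# Stop with a consistent error class so callers/tests can distinguish
# user errors from internal ones.
qt_stop <- function(..., class = "qtremor_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    qt_stop(name, " must be a finite numeric scalar", class = "qtremor_domain_error")
  }
  invisible(x)
}

# All randomness in the package flows through explicit seeds; the caller's
# global RNG state is left untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream-specific child seed from a base seed, kept < 2^31.
derive_seed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base)
  for (i in idx) s <- (s * 69069 + i * 12345 + 1) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
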