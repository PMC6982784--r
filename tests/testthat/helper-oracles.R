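# Independent oracles used across the suite.

# Naive O(N^4) centred unitary 2-D DFT: both spatial and frequency indices
# centred at floor(N/2), explicit double-loop summation.
naive_dft <- function(x, inverse = FALSE) {
  N <- nrow(x)
  sgn <- if (inverse) 2i else -2i
  idx <- seq_len(N) - 1 - floor(N / 2)
  out <- matrix(0 + 0i, N, N)
  for (ki in seq_len(N)) {
    for (kj in seq_len(N)) {
      s <- 0 + 0i
      for (ni in seq_len(N)) {
        for (nj in seq_len(N)) {
          s <- s + x[ni, nj] *
            exp(sgn * pi * (idx[ki] * idx[ni] + idx[kj] * idx[nj]) / N)
        }
      }
      out[ki, kj] <- s / N
    }
  }
  out
}

random_complex <- function(N, seed) {
  set.seed(seed)
  matrix(complex(real = rnorm(N^2), imaginary = rnorm(N^2)), N, N)
}

rel_diff <- function(a, b) {
  max(Mod(a - b)) / max(max(Mod(b)), .Machine$double.eps)
}

# complex inner product <a, b> = sum conj(a) * b
cip <- function(a, b) sum(Conj(a) * b)

# a small network spec for fast reconstruction tests
tiny_spec <- function(L = 2L, seed = 0L) {
  network_spec(L, nd = c(8L, 16L, 32L)[seq_len(L)], ns = 4L, seed = seed)
}
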