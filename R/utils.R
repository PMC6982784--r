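# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# user's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Validate a square, finite complex (or numeric) matrix and return it as
# complex. `min_n` guards against degenerate inputs.
as_complex_image <- function(x, min_n = 8L, arg = "image") {
  if (!is.matrix(x)) stop(sprintf("`%s` must be a matrix", arg))
  if (nrow(x) != ncol(x)) {
    stop(sprintf("`%s` must be square (got %d x %d)", arg, nrow(x), ncol(x)))
  }
  if (nrow(x) < min_n) {
    stop(sprintf("`%s` must be at least %d x %d", arg, min_n, min_n))
  }
  if (is.complex(x)) {
    if (any(!is.finite(Re(x))) || any(!is.finite(Im(x)))) {
      stop(sprintf("`%s` contains non-finite entries", arg))
    }
    x
  } else {
    if (any(!is.finite(x))) stop(sprintf("`%s` contains non-finite entries", arg))
    matrix(complex(real = x, imaginary = 0), nrow(x), ncol(x))
  }
}

# Circularly shift a matrix so the DC bin moves between corner and centre.
circ_shift <- function(x, s1, s2) {
  n1 <- nrow(x); n2 <- ncol(x)
  i <- ((seq_len(n1) - 1 - s1) %% n1) + 1
  j <- ((seq_len(n2) - 1 - s2) %% n2) + 1
  x[i, j, drop = FALSE]
}

fftshift2 <- function(x) circ_shift(x, floor(nrow(x) / 2), floor(ncol(x) / 2))
ifftshift2 <- function(x) circ_shift(x, ceiling(nrow(x) / 2), ceiling(ncol(x) / 2))

stopifnot_scalar_in <- function(x, lo, hi, name, lo_open = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite scalar", name))
  }
  bad_lo <- if (lo_open) x <= lo else x < lo
  if (bad_lo || x > hi) {
    stop(sprintf("`%s` must be in %s%g, %g]", name, if (lo_open) "(" else "[", lo, hi))
  }
  invisible(x)
}
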