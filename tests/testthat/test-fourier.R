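test_that("forward transform is unitary, centred, and matches the naive DFT", {
  # constant image: all energy in the DC bin at the array centre
  one <- matrix(1 + 0i, 8, 8)
  g <- forward_fft(one)
  expect_equal(g[5, 5], 8 + 0i)
  expect_lt(max(Mod(g[-(5 + 8 * 4)])), 1e-12)

  for (seed in 1:3) {
    x <- random_complex(16, seed)
    g <- forward_fft(x)
    # Parseval under unitary scaling
    expect_lt(abs(sqrt(sum(Mod(g)^2)) - sqrt(sum(Mod(x)^2))) /
                sqrt(sum(Mod(x)^2)), 1e-10)
    # against the O(N^4) double-loop oracle
    expect_lt(rel_diff(g, naive_dft(x)), 1e-8)
  }
})

test_that("inverse transform inverts the forward transform and the naive oracle", {
  x <- random_complex(32, 11)
  expect_lt(rel_diff(inverse_fft(forward_fft(x)), x), 1e-10)
  expect_lt(rel_diff(forward_fft(inverse_fft(x)), x), 1e-10)

  # DC-only grid gives a constant image
  g0 <- matrix(0 + 0i, 8, 8)
  g0[5, 5] <- 8
  expect_lt(rel_diff(inverse_fft(g0), matrix(1 + 0i, 8, 8)), 1e-12)

  g <- random_complex(12, 12)
  expect_lt(rel_diff(inverse_fft(g), naive_dft(g, inverse = TRUE)), 1e-8)
})

test_that("transforms are linear", {
  x <- random_complex(16, 1)
  y <- random_complex(16, 2)
  a <- 2.5 - 1.25i
  b <- -0.75 + 3i
  expect_lt(rel_diff(forward_fft(a * x + b * y),
                     a * forward_fft(x) + b * forward_fft(y)), 1e-10)
})

test_that("non-square and non-finite inputs are rejected", {
  expect_error(forward_fft(matrix(0 + 0i, 8, 10)), "square")
  bad <- matrix(1 + 0i, 8, 8)
  bad[3, 3] <- NaN + 0i
  expect_error(forward_fft(bad), "finite")
  expect_error(forward_fft(matrix(1 + 0i, 4, 4)), "at least")
})

test_that("undersample keeps grid values at sampled locations and the mask", {
  g <- random_complex(16, 5)
  full <- matrix(TRUE, 16, 16)
  meas <- undersample(g, full)
  expect_identical(meas$data, g)
  expect_equal(meas$n_sampled, 256L)

  empty <- undersample(g, matrix(FALSE, 16, 16))
  expect_equal(empty$n_sampled, 0L)
  expect_true(all(empty$data == 0))

  expect_error(undersample(g, matrix(TRUE, 8, 8)), "shapes differ")
})

test_that("the undersampled operator satisfies the adjoint identity", {
  # <F_u x, y> == <x, F_u^H y> for every mask family
  N <- 64L
  x <- random_complex(N, 21)
  y <- random_complex(N, 22)
  for (family in c("cartesian", "radial", "variable_density")) {
    mask <- make_mask(family, N, 0.2, seed = 3)
    m <- mask$data
    fu_x <- forward_fft(x)
    fu_x[!m] <- 0
    ym <- y
    ym[!m] <- 0
    fuh_y <- inverse_fft(ym)
    lhs <- cip(fu_x, ym)
    rhs <- cip(x, fuh_y)
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-8)
  }
})

test_that("zero filling inverts exactly under a full mask and matches a direct oracle", {
  x <- random_complex(32, 7)
  full <- undersample(forward_fft(x), matrix(TRUE, 32, 32))
  expect_lt(rel_diff(zero_fill(full), x), 1e-10)

  set.seed(8)
  m <- matrix(runif(32^2) < 0.5, 32, 32)
  meas <- undersample(forward_fft(x), m)
  direct <- inverse_fft(forward_fft(x) * m)  # independent masked-FFT oracle
  expect_lt(rel_diff(zero_fill(meas), direct), 1e-12)

  # empty measurement gives the zero image
  z <- zero_fill(undersample(forward_fft(x), matrix(FALSE, 32, 32)))
  expect_true(all(Mod(z) == 0))
})
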