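test_that("zero jitter with no lesion reproduces the reference exactly", {
  pair <- make_phantom_pair(N = 32, jitter_px = 0, jitter_intensity = 0,
                            lesion = FALSE, seed = 1)
  expect_identical(pair$reference, pair$target)
})

test_that("default pairs are similar but not identical, reproducibly", {
  a <- make_phantom_pair(N = 64, seed = 0)
  expect_gte(a$similarity, 0.55)
  expect_lte(a$similarity, 0.98)
  expect_false(identical(a$reference, a$target))
  b <- make_phantom_pair(N = 64, seed = 0)
  expect_identical(a$reference, b$reference)
  expect_identical(a$target, b$target)
  expect_false(identical(a$target, make_phantom_pair(N = 64, seed = 1)$target))
})

test_that("the similarity band holds across many seeds", {
  sims <- vapply(1:50, function(s) {
    make_phantom_pair(N = 64, seed = s)$similarity
  }, numeric(1))
  expect_true(all(sims >= 0.55 & sims <= 0.98))
})

test_that("smooth-phase pairs are genuinely complex with unchanged magnitude structure", {
  p0 <- make_phantom_pair(N = 32, seed = 3, phase = "none")
  pc <- make_phantom_pair(N = 32, seed = 3, phase = "smooth")
  expect_gt(max(abs(Im(pc$target))), 0.01)
  expect_equal(Mod(pc$target), Mod(p0$target), tolerance = 1e-12)
})

test_that("noiseless acquisition is exactly the masked Fourier transform", {
  pair <- make_phantom_pair(N = 32, seed = 2)
  full <- matrix(TRUE, 32, 32)
  meas <- simulate_acquisition(pair$target, full, noise_model(0))
  expect_lt(rel_diff(inverse_fft(meas$data), pair$target), 1e-10)

  mask <- make_cartesian(32, 0.5, seed = 1)
  meas2 <- simulate_acquisition(pair$target, mask, noise_model(0))
  oracle <- undersample(forward_fft(pair$target), mask)
  expect_identical(meas2$data, oracle$data)
})

test_that("noise realisations match the nominal standard deviation", {
  pair <- make_phantom_pair(N = 64, seed = 4)
  g <- forward_fft(pair$target)
  mask <- make_radial(64, 0.3, seed = 1)
  sds <- vapply(1:10, function(s) {
    meas <- simulate_acquisition(pair$target, mask,
                                 noise_model(0.05, "kspace_std"), seed = s)
    eps <- (meas$data - g)[mask$data]
    sqrt(mean(Mod(eps)^2))
  }, numeric(1))
  nominal <- 0.05 * sd(Mod(g))
  expect_lt(abs(mean(sds) - nominal) / nominal, 0.1)
})

test_that("noise is zero-mean and circularly symmetric", {
  pair <- make_phantom_pair(N = 64, seed = 5)
  g <- forward_fft(pair$target)
  full <- matrix(TRUE, 64, 64)
  nm <- noise_model(0.1, "kspace_std")
  # mean over replicates converges to the noiseless value (CLT)
  entry <- vapply(1:1000, function(s) {
    simulate_acquisition(pair$target, full, nm, seed = s)$data[5, 9]
  }, complex(1))
  sigma <- 0.1 * sd(Mod(g))
  se <- sigma / sqrt(2) / sqrt(1000)
  expect_lt(abs(Re(mean(entry)) - Re(g[5, 9])), 3 * se)
  expect_lt(abs(Im(mean(entry)) - Im(g[5, 9])), 3 * se)
  # real/imag components uncorrelated over many draws
  eps <- simulate_acquisition(pair$target, full, nm, seed = 123)$data - g
  expect_lt(abs(cor(c(Re(eps)), c(Im(eps)))), 0.05)
})

test_that("the Shepp-Logan fixture is deterministic and well formed", {
  p <- shepp_logan(64)
  expect_identical(dim(p), c(64L, 64L))
  expect_identical(p, shepp_logan(64))
  expect_gte(min(p), 0)
  expect_lte(max(p), 1)
  # skull shell bright, ventricles darker than surrounding brain tissue
  expect_equal(max(p), 1)
  expect_lt(p[32, 22], p[32, 32])
  # usable end-to-end: full sampling reconstructs it exactly
  meas <- simulate_acquisition(p + 0i, matrix(TRUE, 64, 64))
  expect_lt(rel_diff(zero_fill(meas), p + 0i), 1e-10)
})

test_that("acquisition noise is seeded deterministically", {
  pair <- make_phantom_pair(N = 32, seed = 6)
  mask <- make_cartesian(32, 0.4, seed = 2)
  nm <- noise_model(0.05)
  a <- simulate_acquisition(pair$target, mask, nm, seed = 7)
  b <- simulate_acquisition(pair$target, mask, nm, seed = 7)
  expect_identical(a$data, b$data)
})
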