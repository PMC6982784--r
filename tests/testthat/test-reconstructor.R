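test_that("configuration boundaries are enforced", {
  expect_error(recon_config(iterations = 0), "iterations")
  expect_error(recon_config(learning_rate = 0), "learning_rate")
  cfg <- recon_config(iterations = 1, eval_every = 100)
  expect_identical(cfg$iterations, 1L)
})

test_that("optimization reduces the data-fidelity loss on a fully sampled phantom", {
  pair <- make_phantom_pair(N = 64, seed = 1)
  meas <- simulate_acquisition(pair$target, matrix(TRUE, 64, 64))
  fit <- fit_dip(meas, pair$reference, tiny_spec(),
                 recon_config(iterations = 200, seed = 1))
  lt <- fit$loss_trace
  expect_identical(nrow(lt), 200L)
  expect_lt(lt$loss[200], lt$loss[1])
  expect_true(all(is.finite(lt$loss)))
})

test_that("a single iteration returns a one-step trace and an empty mask errors", {
  pair <- make_phantom_pair(N = 16, seed = 2)
  meas <- simulate_acquisition(pair$target, make_cartesian(16, 0.5, 1))
  fit <- fit_dip(meas, pair$reference, tiny_spec(1L),
                 recon_config(iterations = 1, seed = 0))
  expect_identical(nrow(fit$loss_trace), 1L)

  empty <- undersample(forward_fft(pair$target), matrix(FALSE, 16, 16))
  expect_error(
    fit_dip(empty, pair$reference, tiny_spec(1L), recon_config(iterations = 1)),
    "empty mask"
  )
})

test_that("final loss decreases from its initial value across seeded runs", {
  pair <- make_phantom_pair(N = 32, seed = 3)
  meas <- simulate_acquisition(pair$target, make_cartesian(32, 0.4, 1))
  improved <- vapply(1:10, function(s) {
    lt <- fit_dip(meas, pair$reference, tiny_spec(seed = s),
                  recon_config(iterations = 50, seed = s))$loss_trace
    lt$loss[nrow(lt)] < lt$loss[1]
  }, logical(1))
  expect_gte(mean(improved), 0.95)
})

test_that("data correction substitutes measurements exactly and keeps the rest", {
  x <- random_complex(32, 4)
  out <- random_complex(32, 5)
  # full mask: network output ignored entirely
  full <- undersample(forward_fft(x), matrix(TRUE, 32, 32))
  expect_identical(data_correct(out, full), full$data)
  # empty mask: pure network k-space
  empty <- undersample(forward_fft(x), matrix(FALSE, 32, 32))
  expect_identical(data_correct(out, empty), forward_fft(out))
  # 20% mask: exact split between measured and predicted
  set.seed(6)
  m <- matrix(runif(32^2) < 0.2, 32, 32)
  meas <- undersample(forward_fft(x), m)
  g <- data_correct(out, meas)
  expect_identical(g[m], meas$data[m])
  expect_identical(g[!m], forward_fft(out)[!m])
})

test_that("reconstruction is perfect at full sampling regardless of the network", {
  pair <- make_phantom_pair(N = 16, seed = 7)
  meas <- simulate_acquisition(pair$target, matrix(TRUE, 16, 16))
  # nearly untrained network: 2 iterations only
  res <- reconstruct(meas, pair$reference, tiny_spec(1L),
                     recon_config(iterations = 2, seed = 0))
  expect_lt(rel_diff(res$image, pair$target), 1e-10)
})

test_that("the final reconstruction satisfies exact data consistency and idempotence", {
  pair <- make_phantom_pair(N = 32, seed = 8)
  mask <- make_cartesian(32, 0.4, seed = 2)
  meas <- simulate_acquisition(pair$target, mask)
  res <- reconstruct(meas, pair$reference, tiny_spec(),
                     recon_config(iterations = 30, seed = 1),
                     truth = pair$target)
  m <- mask$data
  g <- forward_fft(res$image)
  expect_lt(max(Mod(g[m] - meas$data[m])) / max(Mod(meas$data[m])), 1e-10)
  # applying the correction to the reconstruction changes nothing beyond roundoff
  g2 <- data_correct(res$image, meas)
  expect_lt(rel_diff(inverse_fft(g2), res$image), 1e-10)
  # traces recorded
  expect_identical(nrow(res$loss_trace), 30L)
  expect_identical(res$metric_trace$iteration, 30L)
})

test_that("reconstruction is deterministic given seeds, and modes differ", {
  pair <- make_phantom_pair(N = 16, seed = 9)
  meas <- simulate_acquisition(pair$target, make_cartesian(16, 0.5, 1))
  cfg <- recon_config(iterations = 10, seed = 3)
  a <- reconstruct(meas, pair$reference, tiny_spec(1L), cfg)
  b <- reconstruct(meas, pair$reference, tiny_spec(1L), cfg)
  expect_identical(a$image, b$image)
  cfgn <- recon_config(iterations = 10, input_mode = "noise", seed = 3)
  n1 <- fit_dip(meas, pair$reference, tiny_spec(1L), cfgn)
  expect_false(identical(a$network_output, n1$output))
  # noise input is a fixed tensor of the configured scale
  expect_identical(dim(n1$input), c(16L, 16L, 2L))
  expect_gt(sd(n1$input), 0.05)
})
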