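test_that("network specs validate their fields", {
  expect_error(network_spec(0, nd = 4, ns = 4), "depth")
  expect_error(network_spec(2, nd = c(4, 8, 16), ns = 4), "length")
  expect_error(network_spec(1, nd = 4, ns = 4, kd = 2), "odd")
  s <- network_spec(3, nd = c(16, 32, 64), ns = 4)
  expect_identical(s$ns, rep(4L, 3))
  expect_identical(s$kd, rep(3L, 3))
})

test_that("packaged hyperparameter configs load and build", {
  a <- network_spec_from_yaml(refdip_example("networks/brain_a.yaml"))
  expect_identical(a$depth, 5L)
  expect_identical(a$nd, c(8L, 16L, 32L, 64L, 128L))
  expect_identical(a$ns, rep(8L, 5))
  b <- network_spec_from_yaml(refdip_example("networks/brain_b.yaml"))
  expect_identical(b$depth, 6L)
  expect_identical(b$nd, c(6L, 32L, 64L, 128L, 128L, 128L))
  net <- build_network(a)
  expect_s3_class(net, "dip_network")
  # yaml round trip
  tmp <- tempfile(fileext = ".yaml")
  network_spec_to_yaml(a, tmp)
  expect_identical(network_spec_from_yaml(tmp)[1:7], a[1:7])
})

test_that("the deepest published architecture preserves a 512x512 input", {
  spec <- network_spec_from_yaml(refdip_example("networks/brain_a.yaml"))
  net <- build_network(spec)
  out <- net_forward(net, array(0, c(512, 512, 2)))
  expect_identical(dim(out), c(512L, 512L, 2L))
  expect_true(all(is.finite(out)))
})

test_that("forward pass preserves spatial shape across depths and sizes", {
  for (L in 1:4) {
    for (N in c(16L, 32L)) {
      spec <- network_spec(L, nd = rep(4L, L), ns = 2L, seed = L)
      net <- build_network(spec)
      x <- array(rnorm(N * N * 2), c(N, N, 2))
      out <- net_forward(net, x)
      expect_identical(dim(out), c(N, N, 2L))
      expect_true(all(is.finite(out)))
    }
  }
})

test_that("invalid inputs are rejected at the forward pass", {
  net <- build_network(network_spec(3, nd = 4, ns = 2))
  expect_error(net_forward(net, array(0, c(20, 20, 2))), "divisible")
  bad <- array(0, c(16, 16, 2))
  bad[1] <- NA
  expect_error(net_forward(net, bad), "non-finite")
  expect_error(net_forward(net, array(0, c(16, 16, 3))), "channels")
})

test_that("zero input produces finite output through bias and normalisation paths", {
  net <- build_network(network_spec(2, nd = c(4, 8), ns = 2, seed = 5))
  out <- net_forward(net, array(0, c(16, 16, 2)))
  expect_true(all(is.finite(out)))
})

test_that("builds are deterministic in the seed", {
  spec <- network_spec(2, nd = c(4, 8), ns = 2, seed = 42)
  x <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
  expect_identical(net_forward(build_network(spec), x),
                   net_forward(build_network(spec), x))
  spec2 <- spec
  spec2$seed <- 43L
  expect_false(identical(net_forward(build_network(spec), x),
                         net_forward(build_network(spec2), x)))
})

test_that("parameter count matches a hand-computed total for the depth-1 toy", {
  # L=1, nd=nu=[4], ns=[4], kd=ku=3, ks=1, 2 channels in/out:
  #   down: 3*3*2*4+4 | bn 8 | 3*3*4*4+4 | bn 8            = 240
  #   skip: 1*1*2*4+4 | bn 8                               = 20
  #   up:   bn(8ch) 16 | 3*3*8*4+4 | bn 8 | 1*1*4*4+4 | bn 8 = 344
  #   final: 1*1*4*2+2                                     = 10
  spec <- network_spec(1, nd = 4, ns = 4)
  expect_identical(n_params(spec), 614L)
})

test_that("backpropagated gradients match finite differences", {
  spec <- network_spec(2, nd = c(4, 6), ns = 2, seed = 3)
  net <- build_network(spec)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  fwd <- net_forward(net, x, keep_cache = TRUE)
  bwd <- net_backward(net, fwd, fwd$out)  # loss = sum(out^2)/2
  loss_fn <- function(params) {
    net2 <- net
    net2$params <- params
    sum(net_forward(net2, x)^2) / 2
  }
  # conv weights at three depths of the graph (biases before batch norm have
  # an exactly zero gradient, so they are uninformative here); a small step
  # keeps the central difference inside the locally smooth region between
  # leaky-ReLU kinks
  picks <- grep("\\.w$", names(net$params), value = TRUE)[c(1, 4, 8)]
  h <- 1e-5
  for (nm in picks) {
    p1 <- net$params; p1[[nm]][1] <- p1[[nm]][1] + h
    p2 <- net$params; p2[[nm]][1] <- p2[[nm]][1] - h
    fd <- (loss_fn(p1) - loss_fn(p2)) / (2 * h)
    an <- bwd$grads[[nm]][1]
    expect_false(an == 0)
    expect_lt(abs(fd - an) / abs(fd), 1e-3, label = nm)
  }
})

test_that("complex/channel bridge round trips losslessly", {
  x <- random_complex(16, 9)
  t2 <- complex_to_channels(x)
  expect_identical(dim(t2), c(16L, 16L, 2L))
  expect_identical(channels_to_complex(t2), x)
  expect_equal(sqrt(sum(Mod(channels_to_complex(t2))^2)), sqrt(sum(Mod(x)^2)))
  # purely real image has a zero imaginary channel
  r <- matrix(1:256 + 0, 16, 16)
  expect_true(all(complex_to_channels(r + 0i)[, , 2] == 0))
  expect_error(channels_to_complex(array(0, c(8, 8, 3))), "N x N x 1 or N x N x 2")
})
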