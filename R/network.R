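# The untrained encoder-decoder ("hourglass") network with skip connections.
# Feature maps are H x W x C numeric arrays; parameters live in a flat named
# list so the optimizer can treat them uniformly. Forward/backward are
# written out explicitly (reverse-mode, one cache per primitive); the
# convolution kernels are in src/conv.cpp, everything else is plain R.
#
# Per depth i (input resolution halves at each level):
#   skip  : conv(ks, s1) -> BN -> lReLU                      [off the level input]
#   down  : conv(kd, s2) -> BN -> lReLU -> conv(kd, s1) -> BN -> lReLU
#   (recurse into depth i+1, or bottom out)
#   up    : bilinear x2 on the deeper features, concat with skip, then
#           BN -> conv(ku, s1) -> BN -> lReLU -> conv(1x1) -> BN -> lReLU
# followed by a final 1x1 convolution to the output channels.

#' Hourglass network specification
#'
#' Describes the architecture: maximal depth `L` and, per depth, the filter
#' counts for the downsampling path (`nd`), upsampling path (`nu`) and skip
#' connections (`ns`), with kernel sizes `kd`, `ku`, `ks`. Scalars are
#' recycled to length `L`. Downsampling is by stride-2 convolution,
#' upsampling by bilinear interpolation; all activations are leaky ReLU.
#'
#' @param depth maximal depth `L` (>= 1); inputs must have side length
#'   divisible by `2^L`.
#' @param nd,nu,ns integer filter counts per depth (length `L` or scalar).
#' @param kd,ku,ks odd kernel sizes per depth (length `L` or scalar).
#' @param input_channels,output_channels channels at the network boundary;
#'   the default 2 carries a complex image as (real, imaginary) channels.
#' @param leaky_slope negative slope of the leaky ReLU.
#' @param seed seed for parameter initialisation in [build_network()].
#' @return a `network_spec` object.
#' @export
network_spec <- function(depth, nd, nu = nd, ns, kd = 3L, ku = 3L, ks = 1L,
                         input_channels = 2L, output_channels = 2L,
                         leaky_slope = 0.1, seed = 0L) {
  L <- as.integer(depth)
  if (L < 1) stop("`depth` must be >= 1")
  rec <- function(v, name) {
    v <- as.integer(v)
    if (length(v) == 1) v <- rep(v, L)
    if (length(v) != L) stop(sprintf("`%s` must have length 1 or %d", name, L))
    if (any(v < 1)) stop(sprintf("`%s` entries must be >= 1", name))
    v
  }
  spec <- list(
    depth = L,
    nd = rec(nd, "nd"), nu = rec(nu, "nu"), ns = rec(ns, "ns"),
    kd = rec(kd, "kd"), ku = rec(ku, "ku"), ks = rec(ks, "ks"),
    input_channels = as.integer(input_channels),
    output_channels = as.integer(output_channels),
    leaky_slope = leaky_slope,
    seed = as.integer(seed)
  )
  for (nm in c("kd", "ku", "ks")) {
    if (any(spec[[nm]] %% 2 == 0)) stop(sprintf("`%s` kernel sizes must be odd", nm))
  }
  structure(spec, class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec> L=%d nd=[%s] nu=[%s] ns=[%s] k=%d/%d/%d io=%d/%d\n",
    x$depth, paste(x$nd, collapse = ","), paste(x$nu, collapse = ","),
    paste(x$ns, collapse = ","), x$kd[1], x$ku[1], x$ks[1],
    x$input_channels, x$output_channels
  ))
  invisible(x)
}

#' Read / write a network specification as YAML
#'
#' The package ships the three published hyperparameter sets as YAML files
#' under `inst/extdata/networks/` (`brain_a.yaml`, `brain_b.yaml`,
#' `brain_c.yaml`); `network_spec_from_yaml(refdip_example("networks/brain_a.yaml"))`
#' loads one.
#'
#' @param path YAML file path.
#' @return a `network_spec`.
#' @export
network_spec_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(network_spec, y)
}

#' @rdname network_spec_from_yaml
#' @param spec a `network_spec`.
#' @export
network_spec_to_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Path to a packaged example/config file
#'
#' @param file relative path under the package's `extdata/` directory; empty
#'   to list the directory.
#' @return absolute file path.
#' @export
refdip_example <- function(file = "") {
  system.file("extdata", file, package = "refdip", mustWork = nzchar(file))
}

# --- parameter containers ---------------------------------------------------

# PyTorch-default conv init: U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_conv <- function(k, cin, cout) {
  bound <- 1 / sqrt(k * k * cin)
  list(
    w = array(runif(k * k * cin * cout, -bound, bound), c(k, k, cin, cout)),
    b = runif(cout, -bound, bound)
  )
}

# A "block" is a list of primitive descriptors; conv/bn primitives carry the
# names of their parameter entries in the flat parameter list.
new_builder <- function() {
  env <- new.env()
  env$params <- list()
  env$counter <- 0L
  env$add_conv <- function(k, cin, cout, stride) {
    env$counter <- env$counter + 1L
    id <- sprintf("conv%03d", env$counter)
    p <- init_conv(k, cin, cout)
    env$params[[paste0(id, ".w")]] <- p$w
    env$params[[paste0(id, ".b")]] <- p$b
    list(type = "conv", w = paste0(id, ".w"), b = paste0(id, ".b"),
         stride = as.integer(stride), k = k, cin = cin, cout = cout)
  }
  env$add_bn <- function(c) {
    env$counter <- env$counter + 1L
    id <- sprintf("bn%03d", env$counter)
    env$params[[paste0(id, ".g")]] <- rep(1, c)
    env$params[[paste0(id, ".b")]] <- rep(0, c)
    list(type = "bn", g = paste0(id, ".g"), b = paste0(id, ".b"), c = c)
  }
  env
}

#' Build an hourglass network from a specification
#'
#' Allocates and seed-initialises all parameters (convolution weights from
#' the uniform fan-in rule, batch-norm scale 1 / shift 0). The same spec and
#' seed always produce the same parameters, hence identical outputs.
#'
#' @param spec a [network_spec()].
#' @return a `dip_network`: the spec, a flat parameter list, and the block
#'   structure used by [net_forward()].
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  L <- spec$depth
  net <- with_seed(spec$seed, {
    b <- new_builder()
    act <- list(type = "lrelu", slope = spec$leaky_slope)
    levels <- vector("list", L)
    for (i in seq_len(L)) {
      cin <- if (i == 1) spec$input_channels else spec$nd[i - 1]
      down <- list(
        b$add_conv(spec$kd[i], cin, spec$nd[i], stride = 2L),
        b$add_bn(spec$nd[i]), act,
        b$add_conv(spec$kd[i], spec$nd[i], spec$nd[i], stride = 1L),
        b$add_bn(spec$nd[i]), act
      )
      skip <- list(
        b$add_conv(spec$ks[i], cin, spec$ns[i], stride = 1L),
        b$add_bn(spec$ns[i]), act
      )
      c_deep <- if (i == L) spec$nd[L] else spec$nu[i + 1]
      c_cat <- spec$ns[i] + c_deep
      up <- list(
        b$add_bn(c_cat),
        b$add_conv(spec$ku[i], c_cat, spec$nu[i], stride = 1L),
        b$add_bn(spec$nu[i]), act,
        b$add_conv(1L, spec$nu[i], spec$nu[i], stride = 1L),
        b$add_bn(spec$nu[i]), act
      )
      levels[[i]] <- list(down = down, skip = skip, up = up)
    }
    final <- b$add_conv(1L, spec$nu[1], spec$output_channels, stride = 1L)
    list(spec = spec, params = b$params,
         arch = list(levels = levels, final = final))
  })
  structure(net, class = "dip_network")
}

#' @export
print.dip_network <- function(x, ...) {
  cat(sprintf("<dip_network> L=%d, %d parameters\n", x$spec$depth, n_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param x a `dip_network` or `network_spec`.
#' @return integer parameter count.
#' @export
n_params <- function(x) {
  if (inherits(x, "network_spec")) x <- build_network(x)
  sum(vapply(x$params, length, integer(1)))
}

# --- primitives -------------------------------------------------------------

prim_forward <- function(prim, params, x) {
  switch(
    prim$type,
    conv = {
      out <- .conv2d_fwd(x, params[[prim$w]], params[[prim$b]], prim$stride)
      list(out = out, cache = x)
    },
    bn = {
      r <- .bn_fwd(x, params[[prim$g]], params[[prim$b]])
      list(out = r$out, cache = list(xhat = r$xhat, invstd = r$invstd))
    },
    lrelu = {
      out <- .lrelu_fwd(x, prim$slope)
      list(out = out, cache = out)
    },
    stop("unknown primitive")
  )
}

prim_backward <- function(prim, params, cache, dy, grads) {
  switch(
    prim$type,
    conv = {
      r <- .conv2d_bwd(cache, params[[prim$w]], dy, prim$stride)
      grads[[prim$w]] <- r$dw
      grads[[prim$b]] <- r$db
      list(dx = r$dx, grads = grads)
    },
    bn = {
      r <- .bn_bwd(cache$xhat, cache$invstd, params[[prim$g]], dy)
      grads[[prim$g]] <- r$dg
      grads[[prim$b]] <- r$db
      list(dx = r$dx, grads = grads)
    },
    lrelu = {
      list(dx = .lrelu_bwd(cache, dy, prim$slope), grads = grads)
    }
  )
}

block_forward <- function(block, params, x) {
  caches <- vector("list", length(block))
  for (i in seq_along(block)) {
    r <- prim_forward(block[[i]], params, x)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

block_backward <- function(block, params, caches, dy, grads) {
  for (i in rev(seq_along(block))) {
    r <- prim_backward(block[[i]], params, caches[[i]], dy, grads)
    dy <- r$dx
    grads <- r$grads
  }
  list(dx = dy, grads = grads)
}

# --- bilinear x2 upsampling as separable linear maps ------------------------

.upsample_cache <- new.env(parent = emptyenv())

# 2n x n interpolation matrix, half-pixel-centre convention
upsample_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.upsample_cache[[key]])) return(.upsample_cache[[key]])
  A <- matrix(0, 2 * n, n)
  for (io in 0:(2 * n - 1)) {
    src <- (io + 0.5) / 2 - 0.5
    i0 <- floor(src)
    t <- src - i0
    i0c <- min(max(i0, 0), n - 1)
    i1c <- min(max(i0 + 1, 0), n - 1)
    A[io + 1, i0c + 1] <- A[io + 1, i0c + 1] + (1 - t)
    A[io + 1, i1c + 1] <- A[io + 1, i1c + 1] + t
  }
  .upsample_cache[[key]] <- A
  A
}

upsample2 <- function(x) {
  d <- dim(x)
  A1 <- upsample_matrix(d[1]); A2 <- upsample_matrix(d[2])
  out <- array(0, c(2 * d[1], 2 * d[2], d[3]))
  for (c in seq_len(d[3])) out[, , c] <- A1 %*% x[, , c] %*% t(A2)
  out
}

upsample2_backward <- function(dy, dims) {
  A1 <- upsample_matrix(dims[1]); A2 <- upsample_matrix(dims[2])
  dx <- array(0, dims)
  for (c in seq_len(dims[3])) dx[, , c] <- t(A1) %*% dy[, , c] %*% A2
  dx
}

# --- whole-network forward / backward ---------------------------------------

#' Run the network forward
#'
#' @param net a `dip_network` from [build_network()].
#' @param x real input tensor, `N x N x input_channels` array (a plain
#'   matrix is treated as one channel); `N` must be divisible by
#'   `2^depth`.
#' @param keep_cache keep the per-primitive caches needed by
#'   [net_backward()].
#' @return with `keep_cache = FALSE`, the `N x N x output_channels` output
#'   array; otherwise a list `(out, cache)`.
#' @export
net_forward <- function(net, x, keep_cache = FALSE) {
  stopifnot(inherits(net, "dip_network"))
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (any(!is.finite(x))) stop("non-finite network input")
  d <- dim(x)
  L <- net$spec$depth
  if (d[3] != net$spec$input_channels) {
    stop(sprintf("input has %d channels, spec expects %d", d[3],
                 net$spec$input_channels))
  }
  if (d[1] != d[2] || d[1] %% (2^L) != 0) {
    stop(sprintf("input side %d must be square and divisible by 2^%d", d[1], L))
  }
  params <- net$params
  arch <- net$arch

  level_fwd <- function(i, xin) {
    lv <- arch$levels[[i]]
    s <- block_forward(lv$skip, params, xin)
    dn <- block_forward(lv$down, params, xin)
    deeper <- if (i < L) level_fwd(i + 1, dn$out) else list(out = dn$out)
    u <- upsample2(deeper$out)
    z <- array(c(s$out, u), c(dim(s$out)[1:2], dim(s$out)[3] + dim(u)[3]))
    up <- block_forward(lv$up, params, z)
    list(
      out = up$out,
      cache = list(
        skip = s$caches, down = dn$caches, up = up$caches,
        deeper = deeper$cache, n_skip = dim(s$out)[3],
        deep_dims = dim(deeper$out)
      )
    )
  }
  top <- level_fwd(1L, x)
  fin <- prim_forward(arch$final, params, top$out)
  if (!keep_cache) return(fin$out)
  list(out = fin$out, cache = list(levels = top$cache, final = fin$cache,
                                   input_dim = d))
}

#' Backpropagate through the network
#'
#' @param net a `dip_network`.
#' @param fwd the list returned by `net_forward(net, x, keep_cache = TRUE)`.
#' @param dout gradient of the scalar loss with respect to the network
#'   output (same shape as the output).
#' @return list with `grads` (flat list parallel to `net$params`) and
#'   `dinput`.
#' @export
net_backward <- function(net, fwd, dout) {
  params <- net$params
  arch <- net$arch
  L <- net$spec$depth
  grads <- vector("list", length(params))
  names(grads) <- names(params)

  r <- prim_backward(arch$final, params, fwd$cache$final, dout, grads)
  grads <- r$grads

  level_bwd <- function(i, cache, dy, grads) {
    lv <- arch$levels[[i]]
    r <- block_backward(lv$up, params, cache$up, dy, grads)
    grads <- r$grads
    dz <- r$dx
    ns <- cache$n_skip
    ds <- dz[, , seq_len(ns), drop = FALSE]
    du <- dz[, , -seq_len(ns), drop = FALSE]
    ddeep <- upsample2_backward(du, cache$deep_dims)
    if (i < L) {
      r2 <- level_bwd(i + 1, cache$deeper, ddeep, grads)
      grads <- r2$grads
      ddn <- r2$dx
    } else {
      ddn <- ddeep
    }
    r3 <- block_backward(lv$down, params, cache$down, ddn, grads)
    grads <- r3$grads
    r4 <- block_backward(lv$skip, params, cache$skip, ds, grads)
    grads <- r4$grads
    list(dx = r3$dx + r4$dx, grads = grads)
  }
  rl <- level_bwd(1L, fwd$cache$levels, r$dx, grads)
  list(grads = rl$grads, dinput = rl$dx)
}

# --- complex <-> channel bridging -------------------------------------------

#' Convert between complex images and two-channel real tensors
#'
#' The network is real-valued while MR images are complex; channel 1 carries
#' the real part and channel 2 the imaginary part. The round trip is exact.
#'
#' @param image complex matrix.
#' @return `complex_to_channels`: an `N x N x 2` real array.
#' @export
complex_to_channels <- function(image) {
  x <- as_complex_image(image)
  array(c(Re(x), Im(x)), c(dim(x), 2L))
}

#' @rdname complex_to_channels
#' @param tensor an `N x N x 2` real array (or `N x N x 1` / matrix for a
#'   purely real image).
#' @return `channels_to_complex`: a complex matrix.
#' @export
channels_to_complex <- function(tensor) {
  if (is.matrix(tensor)) tensor <- array(tensor, c(dim(tensor), 1L))
  d <- dim(tensor)
  if (length(d) != 3 || !d[3] %in% c(1L, 2L)) {
    stop("expected an N x N x 1 or N x N x 2 array")
  }
  if (d[3] == 1L) {
    matrix(complex(real = tensor[, , 1], imaginary = 0), d[1], d[2])
  } else {
    matrix(complex(real = tensor[, , 1], imaginary = tensor[, , 2]), d[1], d[2])
  }
}
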