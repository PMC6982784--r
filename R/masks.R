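# Undersampling mask generators: Cartesian phase-encode lines, radial spokes,
# and pointwise variable-density sampling. All three are retrospective masks
# on the Cartesian k-space grid, centred (DC at floor(N/2)+1), binary, and
# deterministic given (family, N, rate, seed).

new_sampling_mask <- function(data, family, target_rate, seed, extra = list()) {
  obj <- c(
    list(
      data = data, family = family, target_rate = target_rate,
      achieved_rate = mean(data), seed = as.integer(seed)
    ),
    extra
  )
  structure(obj, class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf(
    "<sampling_mask> %s, %d x %d, target rate %.3f, achieved %.4f (seed %s)\n",
    x$family, nrow(x$data), ncol(x$data), x$target_rate, x$achieved_rate,
    as.character(x$seed)
  ))
  invisible(x)
}

# distance-from-centre grid (in pixels), centre at the DC bin
centre_dist <- function(N) {
  c0 <- floor(N / 2) + 1
  d1 <- (seq_len(N) - c0)
  sqrt(outer(d1^2, d1^2, `+`))
}

#' Cartesian (phase-encode line) undersampling mask
#'
#' Samples full rows of k-space. A centred band containing 32% of the
#' sampled lines (rounded, at least one) is always fully acquired — the
#' low-frequency region carries most of the image energy — and the remaining
#' lines are drawn without replacement with probability decaying with
#' distance from the centre row.
#'
#' @param N side length of the (square) k-space grid.
#' @param rate target sampling rate in (0, 1]: fraction of k-space measured.
#' @param seed integer seed; the same `(N, rate, seed)` always yields the
#'   same mask.
#' @param decay exponent of the line-selection density
#'   `(1 + d/(N/16))^(-decay)` at distance `d` from the centre row.
#' @return a `sampling_mask` with `family = "cartesian"`; the achieved rate
#'   is within 1/(2N) of the target.
#' @export
make_cartesian <- function(N, rate, seed = 0L, decay = 2) {
  N <- as.integer(N)
  stopifnot_scalar_in(rate, 0, 1, "rate")
  n_lines <- max(1L, as.integer(round(rate * N)))
  n_centre <- min(n_lines, max(1L, as.integer(round(0.32 * n_lines))))
  c0 <- floor(N / 2) + 1
  half <- (n_centre - 1L) %/% 2L
  centre_rows <- seq(c0 - half, length.out = n_centre)
  centre_rows <- centre_rows[centre_rows >= 1 & centre_rows <= N]
  n_rest <- n_lines - length(centre_rows)
  rows <- centre_rows
  if (n_rest > 0) {
    pool <- setdiff(seq_len(N), centre_rows)
    d <- abs(pool - c0)
    w <- (1 + d / (N / 16))^(-decay)
    rows <- c(rows, with_seed(seed, sample(pool, n_rest, prob = w)))
  }
  data <- matrix(FALSE, N, N)
  data[rows, ] <- TRUE
  new_sampling_mask(data, "cartesian", rate, seed, list(rows = sort(rows)))
}

# Rasterize n equiangular spokes through the DC bin; returns logical matrix.
rasterize_spokes <- function(N, n_spokes, offset = 0) {
  c0 <- floor(N / 2) + 1
  m <- matrix(FALSE, N, N)
  # long enough to reach the grid corners at any angle; clipped below
  t_steps <- seq(-0.75 * N, 0.75 * N, by = 0.5)
  for (s in seq_len(n_spokes)) {
    phi <- offset + pi * (s - 1) / n_spokes
    i <- round(c0 + t_steps * sin(phi))
    j <- round(c0 + t_steps * cos(phi))
    keep <- i >= 1 & i <= N & j >= 1 & j <= N
    m[cbind(i[keep], j[keep])] <- TRUE
  }
  m
}

#' Radial (spoke) undersampling mask
#'
#' Union of equiangular straight lines through the k-space centre, rasterised
#' onto the Cartesian grid (retrospective masking, not a true non-Cartesian
#' trajectory). The number of spokes is chosen by bisection so the achieved
#' rate comes as close as possible to the target; a seeded random angular
#' offset rotates the whole fan.
#'
#' @inheritParams make_cartesian
#' @return a `sampling_mask` with `family = "radial"`. The DC bin is always
#'   sampled (every spoke passes through it).
#' @export
make_radial <- function(N, rate, seed = 0L) {
  N <- as.integer(N)
  stopifnot_scalar_in(rate, 0, 1, "rate")
  offset <- with_seed(seed, runif(1, 0, pi))
  rate_of <- function(n) mean(rasterize_spokes(N, n, offset))
  n_max <- as.integer(ceiling(pi * N))
  r_min <- rate_of(1L)
  if (rate < 0.75 * r_min) {
    stop(sprintf(
      "rate %.3f infeasible for a radial mask of size %d: minimum achievable rate is %.3f",
      rate, N, r_min
    ))
  }
  lo <- 1L; hi <- n_max
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (rate_of(mid) < rate) lo <- mid else hi <- mid
  }
  n_spokes <- if (abs(rate_of(lo) - rate) <= abs(rate_of(hi) - rate)) lo else hi
  data <- rasterize_spokes(N, n_spokes, offset)
  new_sampling_mask(
    data, "radial", rate, seed,
    list(n_spokes = n_spokes, angle_offset = offset)
  )
}

#' Variable-density (pointwise) undersampling mask
#'
#' Independent Bernoulli sampling per k-space location with probability
#' proportional to `(1 + r/r0)^(-decay)` at distance `r` from the centre,
#' rescaled and clipped to the unit interval so the expected rate matches the target.
#' A central disk of radius `N/32` is always fully sampled.
#'
#' @inheritParams make_cartesian
#' @param decay positive decay exponent of the sampling density; larger
#'   values concentrate samples near the centre. As `decay` approaches 0 the
#'   density becomes uniform.
#' @param r0 density scale radius in pixels (default `N/16`).
#' @return a `sampling_mask` with `family = "variable_density"`.
#' @export
make_variable_density <- function(N, rate, seed = 0L, decay = 3, r0 = N / 16) {
  N <- as.integer(N)
  stopifnot_scalar_in(rate, 0, 1, "rate")
  if (!is.numeric(decay) || decay <= 0) stop("`decay` must be > 0")
  r <- centre_dist(N)
  w <- (1 + r / r0)^(-decay)
  forced <- r <= N / 32
  target_count <- rate * N^2
  n_forced <- sum(forced)
  if (n_forced >= target_count) {
    # the forced disk alone meets (or exceeds) the requested rate
    p <- ifelse(forced, 1, 0)
  } else {
    wf <- w[!forced]
    need <- target_count - n_forced
    # monotone in c: sum(pmin(1, c*wf)) == need
    f <- function(cc) sum(pmin(1, cc * wf)) - need
    hi <- 1 / min(wf)
    cc <- stats::uniroot(f, lower = 0, upper = hi, tol = 1e-12)$root
    p <- matrix(0, N, N)
    p[forced] <- 1
    p[!forced] <- pmin(1, cc * wf)
  }
  u <- with_seed(seed, matrix(runif(N^2), N, N))
  data <- u < p
  new_sampling_mask(data, "variable_density", rate, seed,
                    list(decay = decay, r0 = r0))
}

#' Generate an undersampling mask by family name
#'
#' @param family one of `"cartesian"`, `"radial"`, `"variable_density"`.
#' @inheritParams make_cartesian
#' @param ... passed to the family generator (`decay`, `r0`).
#' @return a `sampling_mask`.
#' @export
make_mask <- function(family, N, rate, seed = 0L, ...) {
  switch(
    match.arg(family, c("cartesian", "radial", "variable_density")),
    cartesian = make_cartesian(N, rate, seed, ...),
    radial = make_radial(N, rate, seed),
    variable_density = make_variable_density(N, rate, seed, ...)
  )
}
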