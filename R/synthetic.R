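# Synthetic (reference, target) phantom pairs and the k-space measurement
# noise model. The pair emulates two scans of the same anatomy: the same
# ellipse "structures" on a skull-like ring, with small geometric and
# intensity perturbations between reference and target, and one small
# structure present only in the target (a lesion analogue), so the reference
# is informative but never identical to the truth.

# Anti-aliased rotated ellipse coverage in [0,1] on an N x N pixel grid.
ellipse_layer <- function(N, cx, cy, a, b, angle, edge = 1) {
  xs <- seq_len(N)
  dx <- outer(rep(1, N), xs - cx)
  dy <- outer(xs - cy, rep(1, N))
  u <- (dx * cos(angle) + dy * sin(angle)) / a
  v <- (-dx * sin(angle) + dy * cos(angle)) / b
  q <- sqrt(u^2 + v^2)
  # approximate signed distance (pixels) from the boundary, smoothed over `edge`
  d <- (1 - q) * min(a, b)
  pmin(pmax(d / edge + 0.5, 0), 1)
}

# Draw the geometry of one phantom: ring plus n random ellipses. Returns the
# parameter table so the target can re-render a perturbed copy.
draw_structures <- function(N, n_structures) {
  data.frame(
    cx = runif(n_structures, 0.30 * N, 0.70 * N),
    cy = runif(n_structures, 0.30 * N, 0.70 * N),
    a = runif(n_structures, 0.04 * N, 0.16 * N),
    b = runif(n_structures, 0.04 * N, 0.16 * N),
    angle = runif(n_structures, 0, pi),
    intensity = runif(n_structures, -0.35, 0.5)
  )
}

render_phantom <- function(N, structs) {
  c0 <- (N + 1) / 2
  img <- 0.92 * ellipse_layer(N, c0, c0, 0.46 * N, 0.46 * N, 0) -
    0.72 * ellipse_layer(N, c0, c0, 0.42 * N, 0.42 * N, 0)  # skull ring
  img <- img + 0.35 * ellipse_layer(N, c0, c0, 0.42 * N, 0.42 * N, 0)  # brain
  for (i in seq_len(nrow(structs))) {
    s <- structs[i, ]
    img <- img + s$intensity * ellipse_layer(N, s$cx, s$cy, s$a, s$b, s$angle)
  }
  pmin(pmax(img, 0), 1)
}

# low-frequency random phase map in radians
smooth_phase <- function(N, amplitude = 0.5 * pi, n_modes = 3L) {
  xs <- (seq_len(N) - 1) / N
  ph <- matrix(0, N, N)
  for (m in seq_len(n_modes)) {
    fx <- sample(1:2, 1); fy <- sample(1:2, 1)
    ph <- ph + rnorm(1) * outer(
      sin(2 * pi * fx * xs + runif(1, 0, 2 * pi)),
      sin(2 * pi * fy * xs + runif(1, 0, 2 * pi))
    )
  }
  amplitude * ph / max(abs(ph), 1e-12)
}

#' Generate a (reference, target) phantom pair
#'
#' Builds two images of the same synthetic "anatomy": a skull-like outer
#' ring plus `n_structures` random ellipses with anti-aliased edges. The
#' target re-renders the same structures with centres and axes perturbed by
#' at most `jitter_px` pixels and intensities by at most `jitter_intensity`
#' (fractional), and adds one small structure absent from the reference.
#' This emulates a previously acquired high-resolution scan of similar — but
#' not identical — anatomy, the setting the reference-driven method assumes.
#'
#' The generated pair must be similar but not trivially so: the windowed
#' SSIM between the two magnitudes is required to fall in `[0.55, 0.98]`
#' (unless `jitter_px = 0`, `jitter_intensity = 0` and
#' `lesion = FALSE`, which reproduces the reference exactly). If a draw
#' violates the band the generator retries with a derived seed, up to 10
#' attempts, then errors.
#'
#' @param N side length (pixels); choose a multiple of `2^L` of the intended
#'   network depth.
#' @param n_structures number of random ellipses (>= 1).
#' @param jitter_px maximum geometric perturbation of centres/axes, pixels.
#' @param jitter_intensity maximum fractional intensity perturbation.
#' @param phase `"none"` for real-valued images, `"smooth"` to multiply each
#'   image by a smooth random phase map (genuinely complex data).
#' @param lesion add one structure present only in the target.
#' @param seed integer seed; pairs are reproducible from
#'   `(N, n_structures, jitter_px, jitter_intensity, phase, seed)`.
#' @return a `phantom_pair`: list with complex matrices `reference` and
#'   `target`, the `similarity` (windowed SSIM of the magnitudes), and the
#'   generation parameters.
#' @export
make_phantom_pair <- function(N = 64L, n_structures = 8L, jitter_px = 1.5,
                              jitter_intensity = 0.1,
                              phase = c("none", "smooth"),
                              lesion = TRUE, seed = 0L) {
  phase <- match.arg(phase)
  N <- as.integer(N)
  if (N < 8) stop("N must be at least 8")
  if (n_structures < 1) stop("n_structures must be >= 1")
  identical_pair <- jitter_px == 0 && jitter_intensity == 0 && !lesion
  for (attempt in 0:9) {
    pair <- with_seed(seed + 1000L * attempt, {
      structs <- draw_structures(N, n_structures)
      ref <- render_phantom(N, structs)
      tstructs <- structs
      n <- nrow(tstructs)
      tstructs$cx <- tstructs$cx + runif(n, -jitter_px, jitter_px)
      tstructs$cy <- tstructs$cy + runif(n, -jitter_px, jitter_px)
      tstructs$a <- pmax(0.25, tstructs$a + runif(n, -jitter_px, jitter_px))
      tstructs$b <- pmax(0.25, tstructs$b + runif(n, -jitter_px, jitter_px))
      tstructs$intensity <- tstructs$intensity *
        (1 + runif(n, -jitter_intensity, jitter_intensity))
      if (lesion) {
        tstructs <- rbind(tstructs, data.frame(
          cx = runif(1, 0.35 * N, 0.65 * N), cy = runif(1, 0.35 * N, 0.65 * N),
          a = runif(1, 0.03 * N, 0.06 * N), b = runif(1, 0.03 * N, 0.06 * N),
          angle = runif(1, 0, pi), intensity = 0.4
        ))
      }
      tgt <- render_phantom(N, tstructs)
      if (phase == "smooth") {
        ref <- ref * exp(1i * smooth_phase(N))
        tgt <- tgt * exp(1i * smooth_phase(N))
      }
      list(reference = ref + 0i, target = tgt + 0i)
    })
    sim <- ssim(pair$reference, pair$target, mode = "windowed")
    if (identical_pair || (sim >= 0.55 && sim <= 0.98)) {
      return(structure(
        list(
          reference = pair$reference, target = pair$target, similarity = sim,
          params = list(
            N = N, n_structures = n_structures, jitter_px = jitter_px,
            jitter_intensity = jitter_intensity, phase = phase,
            lesion = lesion, seed = as.integer(seed)
          )
        ),
        class = "phantom_pair"
      ))
    }
  }
  stop(sprintf(
    "could not draw a pair with windowed SSIM in [0.55, 0.98] (last %.3f); reduce jitter",
    sim
  ))
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf(
    "<phantom_pair> %d x %d, %d structures, SSIM(|ref|,|target|) = %.3f\n",
    nrow(x$target), ncol(x$target), x$params$n_structures, x$similarity
  ))
  invisible(x)
}

#' Complex Gaussian k-space noise model
#'
#' Circularly symmetric complex Gaussian noise added to the k-space
#' measurements. The standard deviation is interpreted relative to a named
#' statistic of the noiseless k-space magnitude (`"kspace_std"` or
#' `"kspace_max"`), or absolutely (`"absolute"`), since a bare sigma is
#' meaningless without a data scale. Real and imaginary parts are i.i.d.
#' with standard deviation `sigma * scale / sqrt(2)` each, so the complex
#' magnitude standard deviation is `sigma * scale`.
#'
#' @param sigma non-negative noise level.
#' @param relative_to `"kspace_std"`, `"kspace_max"`, or `"absolute"`.
#' @param mean complex mean (default 0).
#' @return a `noise_model` list.
#' @export
noise_model <- function(sigma = 0,
                        relative_to = c("kspace_std", "kspace_max", "absolute"),
                        mean = 0 + 0i) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  structure(
    list(sigma = sigma, relative_to = match.arg(relative_to),
         mean = as.complex(mean)),
    class = "noise_model"
  )
}

#' Simulate undersampled k-space acquisition of a target image
#'
#' Retrospective simulation of the scanner: the full 2-D discrete Fourier
#' transform of the target is corrupted by complex Gaussian noise (per the
#' [noise_model()]) and restricted to the sampled locations of the mask.
#' With `sigma = 0` this is exactly `undersample(forward_fft(target), mask)`.
#'
#' @param target complex (or real) square image matrix.
#' @param mask a `sampling_mask` of the same size.
#' @param noise a [noise_model()]; default noiseless.
#' @param seed integer seed for the noise draw.
#' @return a `kspace_measurement`.
#' @export
simulate_acquisition <- function(target, mask, noise = noise_model(0),
                                 seed = 0L) {
  tgt <- as_complex_image(target, arg = "target")
  g <- forward_fft(tgt)
  if (noise$sigma > 0) {
    scale <- switch(
      noise$relative_to,
      kspace_std = sd(Mod(g)),
      kspace_max = max(Mod(g)),
      absolute = 1
    )
    s <- noise$sigma * scale / sqrt(2)
    eps <- with_seed(seed, matrix(
      complex(real = rnorm(length(g), sd = s),
              imaginary = rnorm(length(g), sd = s)),
      nrow(g), ncol(g)
    ))
    g <- g + noise$mean + eps
  }
  undersample(g, mask)
}

#' Classic Shepp-Logan head phantom
#'
#' The standard ten-ellipse piecewise-constant phantom (modified-contrast
#' intensities), rendered on an N x N grid over the square from -1 to 1. Deterministic —
#' no random elements — which makes it a convenient regression fixture next
#' to the randomised pair generator.
#'
#' @param N side length in pixels.
#' @return real matrix with values between 0 and 1.
#' @export
shepp_logan <- function(N = 64L) {
  N <- as.integer(N)
  if (N < 8) stop("N must be at least 8")
  # columns: intensity, a, b, x0, y0, angle (degrees)
  e <- matrix(c(
     1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.80, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.20, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.20, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.10, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.10, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.10, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.10, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.10, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.10, 0.0230, 0.0460,  0.06, -0.6050,   0
  ), ncol = 6, byrow = TRUE)
  g <- seq(-1, 1, length.out = N)
  xg <- outer(rep(1, N), g)   # column coordinate
  yg <- outer(rev(g), rep(1, N))  # row coordinate, y up
  img <- matrix(0, N, N)
  for (i in seq_len(nrow(e))) {
    phi <- e[i, 6] * pi / 180
    dx <- xg - e[i, 4]
    dy <- yg - e[i, 5]
    u <- (dx * cos(phi) + dy * sin(phi)) / e[i, 2]
    v <- (-dx * sin(phi) + dy * cos(phi)) / e[i, 3]
    img <- img + e[i, 1] * (u^2 + v^2 <= 1)
  }
  pmin(pmax(img, 0), 1)
}
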