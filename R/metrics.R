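# Image-quality metrics for magnitude images: relative l2 error, PSNR, SSIM.
# Complex inputs are magnituded first, as is standard in CS-MRI evaluation.

mag <- function(x) {
  if (is.complex(x)) Mod(x) else x
}

check_pair <- function(xhat, x) {
  xhat <- mag(xhat); x <- mag(x)
  if (!is.matrix(xhat) || !is.matrix(x) || !all(dim(xhat) == dim(x))) {
    stop("reconstruction and truth must be matrices of the same size")
  }
  list(xhat = xhat, x = x)
}

#' Relative l2 reconstruction error
#'
#' `||xhat - x||_2 / ||x||_2` with the norms taken over all pixels of the
#' magnitude images. Reported as a fraction (multiply by 100 for the
#' percentage form used in benchmark tables).
#'
#' @param reconstruction,truth magnitude images (complex inputs are
#'   magnituded), same size.
#' @return non-negative scalar fraction.
#' @export
relative_error <- function(reconstruction, truth) {
  p <- check_pair(reconstruction, truth)
  denom <- sqrt(sum(p$x^2))
  if (denom == 0) stop("ground truth has zero norm")
  sqrt(sum((p$xhat - p$x)^2)) / denom
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10( MAX_x^2 / MSE )` where `MAX_x` is the largest value of the
#' ground truth and MSE is the mean squared difference. Identical images
#' return `Inf`.
#'
#' @inheritParams relative_error
#' @return PSNR in decibels (`Inf` for identical images).
#' @export
psnr <- function(reconstruction, truth) {
  p <- check_pair(reconstruction, truth)
  mse <- mean((p$xhat - p$x)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(p$x)^2 / mse)
}

#' Structural similarity index
#'
#' Two computation modes are provided. `"global"` evaluates the SSIM formula
#' once over whole-image means, standard deviations and cross-covariance,
#' with absolute stabilising constants `c1 = 0.01`, `c2 = 0.03` (no
#' dynamic-range scaling). `"windowed"` (the default reporting mode) is the
#' standard local form: the mean of the formula over 11 x 11 Gaussian
#' weighted windows (sigma 1.5), with constants `(0.01 D)^2` and `(0.03 D)^2`
#' where `D` is the joint dynamic range of the two images. Windowed SSIM is
#' bounded in magnitude by 1 and equals 1 only for identical images.
#'
#' @inheritParams relative_error
#' @param mode `"windowed"` (11x11 Gaussian local windows) or `"global"`
#'   (single whole-image evaluation).
#' @return unitless similarity between -1 and 1 (windowed mode).
#' @export
ssim <- function(reconstruction, truth, mode = c("windowed", "global")) {
  mode <- match.arg(mode)
  p <- check_pair(reconstruction, truth)
  if (mode == "global") {
    ssim_global(p$xhat, p$x)
  } else {
    ssim_windowed(p$xhat, p$x)
  }
}

# population moments; c1/c2 absolute, as sometimes printed without the
# dynamic-range convention
ssim_global <- function(xhat, x, c1 = 0.01, c2 = 0.03) {
  mx <- mean(x); mh <- mean(xhat)
  vx <- mean((x - mx)^2); vh <- mean((xhat - mh)^2)
  cxh <- mean((x - mx) * (xhat - mh))
  ((2 * mx * mh + c1) * (2 * cxh + c2)) /
    ((mx^2 + mh^2 + c1) * (vx + vh + c2))
}

# 1-D Gaussian window, normalized
gauss_win <- function(size = 11L, sigma = 1.5) {
  t <- seq_len(size) - (size + 1) / 2
  g <- exp(-t^2 / (2 * sigma^2))
  g / sum(g)
}

# 'valid' separable weighted local mean: returns (N-size+1)^2 matrix
local_mean <- function(x, g) {
  size <- length(g)
  n <- nrow(x)
  nv <- n - size + 1L
  A <- matrix(0, nv, n)
  for (i in seq_len(nv)) A[i, i:(i + size - 1L)] <- g
  A %*% x %*% t(A)
}

ssim_windowed <- function(xhat, x, size = 11L, sigma = 1.5,
                          K1 = 0.01, K2 = 0.03) {
  if (nrow(x) < size) stop("image smaller than the SSIM window")
  # joint dynamic range keeps the measure symmetric in its two arguments
  D <- diff(range(c(x, xhat)))
  if (D == 0) D <- max(abs(x), 1)  # degenerate constant images
  c1 <- (K1 * D)^2; c2 <- (K2 * D)^2
  g <- gauss_win(size, sigma)
  mu_x <- local_mean(x, g)
  mu_h <- local_mean(xhat, g)
  s_xx <- local_mean(x * x, g) - mu_x^2
  s_hh <- local_mean(xhat * xhat, g) - mu_h^2
  s_xh <- local_mean(x * xhat, g) - mu_x * mu_h
  num <- (2 * mu_x * mu_h + c1) * (2 * s_xh + c2)
  den <- (mu_x^2 + mu_h^2 + c1) * (s_xx + s_hh + c2)
  mean(num / den)
}

#' All three reconstruction metrics at once
#'
#' @inheritParams ssim
#' @param ssim_mode passed to [ssim()].
#' @return a list with `relative_error` (fraction), `psnr` (dB), `ssim`, and
#'   `ssim_mode`.
#' @export
metrics_report <- function(reconstruction, truth,
                           ssim_mode = c("windowed", "global")) {
  ssim_mode <- match.arg(ssim_mode)
  list(
    relative_error = relative_error(reconstruction, truth),
    psnr = psnr(reconstruction, truth),
    ssim = ssim(reconstruction, truth, ssim_mode),
    ssim_mode = ssim_mode
  )
}
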