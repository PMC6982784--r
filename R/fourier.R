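#' Centred, orthonormal 2-D Fourier transform
#'
#' Maps an N x N complex image to its k-space grid with the DC component at
#' the array centre. The transform is unitary (a factor 1/N is applied each
#' way for an N x N image), so Parseval's identity holds exactly:
#' `norm(forward_fft(x)) == norm(x)` up to floating-point roundoff. The
#' centred convention matches the usual visual layout of undersampling masks,
#' whose dense region sits in the middle of the array.
#'
#' @param image square complex (or real) matrix, side length at least 8.
#' @return complex matrix of the same size: the k-space grid, DC at centre
#'   (position `floor(N/2)+1` in both dimensions).
#' @seealso [inverse_fft()], [undersample()]
#' @examples
#' x <- matrix(1 + 0i, 8, 8)
#' g <- forward_fft(x)  # all energy in the DC bin: g[5, 5] == 8
#' @export
forward_fft <- function(image) {
  x <- as_complex_image(image)
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' Centred, orthonormal inverse 2-D Fourier transform
#'
#' Exact inverse of [forward_fft()] up to floating-point roundoff.
#'
#' @param grid square complex matrix: centred k-space grid.
#' @return complex image matrix of the same size.
#' @export
inverse_fft <- function(grid) {
  g <- as_complex_image(grid, arg = "grid")
  fftshift2(stats::fft(ifftshift2(g), inverse = TRUE)) / sqrt(length(g))
}

#' Restrict a k-space grid to the sampled locations of a mask
#'
#' Realises the undersampled Fourier operator: composing
#' `undersample(forward_fft(x), mask)` gives the masked measurements of image
#' `x`. Measurements are stored as a dense grid with zeros at unmeasured
#' locations, together with the mask, so that the data-correction step can
#' later substitute the stored values exactly (bit-for-bit).
#'
#' @param grid complex k-space matrix (centred, e.g. from [forward_fft()]).
#' @param mask a `sampling_mask` (or logical matrix) of the same size.
#' @return a `kspace_measurement` object: list with `data` (complex matrix,
#'   zero where unsampled), `mask`, and `n_sampled`. An all-false mask is
#'   representable (`n_sampled == 0`) but rejected by the reconstruction
#'   entry points.
#' @export
undersample <- function(grid, mask) {
  g <- as_complex_image(grid, arg = "grid")
  m <- mask_matrix(mask)
  if (!all(dim(m) == dim(g))) stop("mask and grid shapes differ")
  data <- g
  data[!m] <- 0 + 0i
  structure(
    list(data = data, mask = mask_as_object(mask, m), n_sampled = sum(m)),
    class = "kspace_measurement"
  )
}

#' @export
print.kspace_measurement <- function(x, ...) {
  cat(sprintf(
    "<kspace_measurement> %d x %d grid, %d sampled locations (%.1f%%)\n",
    nrow(x$data), ncol(x$data), x$n_sampled, 100 * x$n_sampled / length(x$data)
  ))
  invisible(x)
}

#' Zero-filling reconstruction
#'
#' The classical baseline: inverse Fourier transform of the measured k-space
#' with every unmeasured entry set to zero. With a full mask this recovers
#' the original image exactly; with aggressive undersampling it shows the
#' aliasing/blurring artefacts that model-based reconstruction must remove.
#'
#' @param measurement a `kspace_measurement` from [undersample()] or
#'   [simulate_acquisition()].
#' @return complex image matrix.
#' @export
zero_fill <- function(measurement) {
  stopifnot(inherits(measurement, "kspace_measurement"))
  inverse_fft(measurement$data)
}

# Accept either a sampling_mask object or a plain logical/0-1 matrix.
mask_matrix <- function(mask) {
  if (inherits(mask, "sampling_mask")) {
    return(mask$data)
  }
  if (is.matrix(mask) && (is.logical(mask) || all(mask %in% c(0, 1)))) {
    return(matrix(as.logical(mask), nrow(mask), ncol(mask)))
  }
  stop("`mask` must be a sampling_mask or a binary matrix")
}

mask_as_object <- function(mask, m) {
  if (inherits(mask, "sampling_mask")) mask else
    structure(
      list(
        data = m, family = "custom", target_rate = mean(m),
        achieved_rate = mean(m), seed = NA_integer_
      ),
      class = "sampling_mask"
    )
}
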