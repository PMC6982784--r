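# File interchange. Complex images travel as NIfTI with two volumes (real,
# imaginary); masks as PNG (0/255) or CSV; k-space measurements as a NIfTI
# real/imag pair plus the mask PNG beside it; traces and tables as CSV.

#' Read / write complex images as NIfTI
#'
#' Complex data is stored as a 3-D NIfTI with two volumes: volume 1 the real
#' part, volume 2 the imaginary part. A plain 2-D (or single-volume) NIfTI
#' is read as a purely real image.
#'
#' @param image complex matrix.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param pixel_spacing optional pixel spacing in mm, stored in the header.
#' @return `write_image_nifti`: the path, invisibly. `read_image_nifti`: a
#'   complex matrix.
#' @export
write_image_nifti <- function(image, path, pixel_spacing = NULL) {
  x <- as_complex_image(image)
  arr <- array(c(Re(x), Im(x)), c(dim(x), 2L))
  img <- RNifti::asNifti(arr)
  if (!is.null(pixel_spacing)) {
    RNifti::pixdim(img) <- c(pixel_spacing, pixel_spacing, 1)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_image_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 2) {
    return(as_complex_image(arr))
  }
  if (length(dim(arr)) == 3 && dim(arr)[3] == 1) {
    return(as_complex_image(arr[, , 1]))
  }
  if (length(dim(arr)) == 3 && dim(arr)[3] == 2) {
    return(matrix(complex(real = arr[, , 1], imaginary = arr[, , 2]),
                  dim(arr)[1], dim(arr)[2]))
  }
  stop("expected a 2-D NIfTI or one with 1 or 2 volumes (real, imaginary)")
}

#' Read / write sampling masks as PNG
#'
#' Sampled locations are white (255), unsampled black. Reading recovers the
#' binary mask; generator metadata (family, target rate, seed) is not stored
#' in the image, so a read-back mask has family `"custom"`.
#'
#' @param mask a `sampling_mask` or binary matrix.
#' @param path PNG file path.
#' @export
write_mask_png <- function(mask, path) {
  m <- mask_matrix(mask)
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- img > 0.5
  structure(
    list(data = m, family = "custom", target_rate = mean(m),
         achieved_rate = mean(m), seed = NA_integer_),
    class = "sampling_mask"
  )
}

#' Read / write k-space measurements
#'
#' The measurement grid is written as a two-volume NIfTI (real, imaginary)
#' and the mask as a PNG of the same stem (`<stem>_mask.png`).
#'
#' @param measurement a `kspace_measurement`.
#' @param path NIfTI path for the k-space grid.
#' @export
write_measurement <- function(measurement, path) {
  stopifnot(inherits(measurement, "kspace_measurement"))
  write_image_nifti(measurement$data, path)
  write_mask_png(measurement$mask, paste0(sub("\\.nii(\\.gz)?$", "", path),
                                          "_mask.png"))
  invisible(path)
}

#' @rdname write_measurement
#' @export
read_measurement <- function(path) {
  data <- read_image_nifti(path)
  mask <- read_mask_png(paste0(sub("\\.nii(\\.gz)?$", "", path), "_mask.png"))
  undersample(data, mask)
}
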