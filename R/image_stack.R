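#' 3D image stack with physical voxel spacing
#'
#' Container for a microscopy z-stack. Voxels are stored in an `(nx, ny, nz)`
#' numeric array (x fastest, matching the on-disk TIFF page layout after
#' transposition); `spacing` gives the physical voxel size in micrometers per
#' axis. The voxel `(i, j, k)` (1-based) has its center at
#' `((i - 0.5) * sx, (j - 0.5) * sy, (k - 0.5) * sz)` um.
#'
#' @param data numeric 3D array, dimensions `(nx, ny, nz)`.
#' @param spacing numeric length-3, voxel spacing in um (x, y, z), all > 0.
#' @param domain `"8bit"` (values in 0..255) or `"normalized"` (values in
#'   0..1).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, spacing, domain = c("8bit", "normalized")) {
  domain <- match.arg(domain)
  if (!is.array(data) || length(dim(data)) != 3) {
    stopf("parameter_error", "`data` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("parameter_error", "`spacing` must be 3 positive numbers (um)")
  }
  structure(list(data = data, spacing = spacing, domain = domain),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %s voxels, spacing %s um, domain %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "/"), x$domain))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Binary voxel mask
#'
#' @param data logical 3D array.
#' @param spacing voxel spacing in um (x, y, z).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stopf("parameter_error", "`data` must be a 3D array")
  }
  storage.mode(data) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stopf("parameter_error", "`spacing` must be 3 positive numbers (um)")
  }
  structure(list(data = data, spacing = spacing), class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$data)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Physical coordinates (um) of the foreground voxel centers of a mask
#' @param mask a [binary_mask()].
#' @return n x 3 matrix of um coordinates.
#' @export
mask_points <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  cbind((idx[, 1] - 0.5) * mask$spacing[1],
        (idx[, 2] - 0.5) * mask$spacing[2],
        (idx[, 3] - 0.5) * mask$spacing[3])
}

#' Write / read a stack as multi-page TIFF
#'
#' 8-bit stacks are written as 8-bit pages, normalized stacks as 32-bit
#' float. Spacing is not stored in the file and must be supplied on read.
#'
#' @param stack an [image_stack()].
#' @param path file path.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- stack$data
  pages <- lapply(seq_len(dim(d)[3]), function(k) t(d[, , k]))
  if (stack$domain == "8bit") {
    pages <- lapply(pages, function(m) m / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
  }
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param spacing voxel spacing (um) to attach to the stack read from disk.
#' @param domain intensity domain of the file content.
#' @export
read_stack_tiff <- function(path, spacing,
                            domain = c("8bit", "normalized")) {
  domain <- match.arg(domain)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  if (domain == "8bit") arr <- round(arr * 255)
  image_stack(arr, spacing, domain)
}

#' Dice overlap coefficient between two binary masks
#' @param a,b [binary_mask()] objects (or logical arrays) of equal shape.
#' @return Dice coefficient 2|A&B| / (|A|+|B|) in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  av <- if (inherits(a, "binary_mask")) a$data else a
  bv <- if (inherits(b, "binary_mask")) b$data else b
  stopifnot(identical(dim(av), dim(bv)))
  2 * sum(av & bv) / (sum(av) + sum(bv))
}
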