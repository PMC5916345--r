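#' 3D volumes with voxel dimensions
#'
#' Lightweight container for 3D grids: a numeric or integer array plus voxel
#' dimensions in mm and a quantity tag. Axis 1 is left-right, axis 2 is the
#' anterior-posterior (coronal-slice) axis with anterior at index 1, axis 3 is
#' inferior-superior; only the anterior-posterior identification is ever used
#' (by [posterior_cerebellum_mask()]).
#'
#' @param data 3D array (integer labels or float map).
#' @param voxdim voxel dimensions in mm, length 3, all `> 0`.
#' @param quantity tag, e.g. `"Ki"`, `"BPnd"`, `"t"`, `"mask"`, `"labels"`.
#' @param ap_axis index of the anterior-posterior axis (default 2).
#' @return A `pet_volume` (array with attributes).
#' @export
pet_volume <- function(data, voxdim = c(1, 1, 1), quantity = NA_character_,
                       ap_axis = 2L) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  voxdim <- as.numeric(voxdim)
  if (length(voxdim) != 3L || any(!is.finite(voxdim)) || any(voxdim <= 0)) {
    stop("voxdim must be 3 positive values (mm)")
  }
  structure(data, voxdim = voxdim, quantity = quantity,
            ap_axis = as.integer(ap_axis),
            class = c("pet_volume", class(data)))
}

#' @rdname pet_volume
#' @param x a `pet_volume`.
#' @export
voxdim <- function(x) {
  v <- attr(x, "voxdim")
  if (is.null(v)) rep(1, 3) else v
}

voxel_volume <- function(x) prod(voxdim(x))

same_grid <- function(a, b) {
  identical(dim(a), dim(b)) && isTRUE(all.equal(voxdim(a), voxdim(b)))
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("pet_volume [%s]: %s voxels, %s mm\n",
              attr(x, "quantity"),
              paste(dim(x), collapse = " x "),
              paste(signif(voxdim(x), 4), collapse = " x ")))
  invisible(x)
}

# rebuild a pet_volume preserving metadata
rewrap_volume <- function(data, template, quantity = attr(template, "quantity")) {
  pet_volume(data, voxdim(template), quantity,
             ap_axis = attr(template, "ap_axis") %||% 2L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write volumes as NIfTI
#'
#' Thin wrappers over RNifti. Voxel dimensions are taken from / written to the
#' NIfTI header (`pixdim`); no affine resampling is performed, so volumes that
#' are combined must already share a grid.
#'
#' @param x a [pet_volume()] (or plain 3D array) to write.
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param quantity quantity tag attached on read.
#' @return `read_volume_nifti()` returns a `pet_volume`; the writer returns
#'   `path` invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  img <- RNifti::asNifti(unclass(x))
  RNifti::pixdim(img) <- voxdim(x)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path, quantity = NA_character_) {
  img <- RNifti::readNifti(path)
  pet_volume(as.array(img), RNifti::pixdim(img)[1:3], quantity)
}
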