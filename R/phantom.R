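#' Specification of a labeled voxel phantom
#'
#' A phantom is a small labeled 3D grid with a true parametric value per
#' label, observed through a Gaussian point-spread function (PSF). Phantoms
#' exercise the partial-volume-correction and cluster machinery without scan
#' data.
#'
#' @param shape integer grid dimensions, length 3.
#' @param voxdim voxel size in mm, length 3, `> 0`.
#' @param labels integer 3D array of region labels (0 = background), same
#'   shape; regions are disjoint by construction of a label image.
#' @param values named numeric vector: true parametric value per label id
#'   (names are label ids as characters). Background defaults to 0 unless a
#'   `"0"` entry is given.
#' @param fwhm_mm PSF full width at half maximum in mm, `>= 0`.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape, voxdim = c(2, 2, 2), labels, values,
                         fwhm_mm = 4) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1))
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  labels <- as.array(labels)
  if (!identical(dim(labels), shape)) stop("labels shape mismatch")
  if (any(labels < 0)) stop("labels must be >= 0")
  ids <- sort(unique(as.integer(labels[labels > 0])))
  if (!all(as.character(ids) %in% names(values))) {
    stop("values must name every nonzero label")
  }
  structure(
    list(shape = shape, voxdim = as.numeric(voxdim), labels = labels,
         values = values, fwhm_mm = fwhm_mm),
    class = "phantom_spec"
  )
}

#' Simulate a labeled phantom and its PSF-blurred observation
#'
#' Builds the piecewise-constant true parametric map defined by a
#' [phantom_spec()] and the observed map obtained by convolving it with an
#' isotropic Gaussian PSF of the specified FWHM (mm). With `fwhm_mm = 0` the
#' observed map equals the truth.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `labels` (integer `pet_volume`), `truth` and `observed`
#'   (float `pet_volume`s).
#' @examples
#' lab <- array(0L, c(9, 9, 1)); lab[4:6, 4:6, 1] <- 1L
#' ph <- simulate_phantom(phantom_spec(c(9, 9, 1), c(2, 2, 2), lab,
#'                                     c("1" = 10), fwhm_mm = 4))
#' @export
simulate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- array(0, spec$shape)
  if ("0" %in% names(spec$values)) truth[] <- spec$values[["0"]]
  for (id in names(spec$values)) {
    if (id == "0") next
    truth[spec$labels == as.integer(id)] <- spec$values[[id]]
  }
  labels <- pet_volume(spec$labels, spec$voxdim, "labels")
  truth_v <- pet_volume(truth, spec$voxdim, "truth")
  observed <- smooth_map(truth_v, spec$fwhm_mm)
  attr(observed, "quantity") <- "observed"
  list(labels = labels, truth = truth_v, observed = observed)
}
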