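#' Gaussian smoothing of a parametric map
#'
#' Separable Gaussian smoothing with per-axis sigma `FWHM / (2 sqrt(2 ln 2))`
#' expressed in mm (so anisotropic voxels are handled). Missing voxels (`NA`)
#' are excluded by renormalization: the map with `NA` set to 0 and the
#' defined-voxel indicator are smoothed with the same kernel and their ratio
#' is taken, which also renormalizes at the volume boundary. Voxels that were
#' `NA` on input remain `NA`.
#'
#' @param x a [pet_volume()] (float map).
#' @param fwhm_mm full width at half maximum in mm, `>= 0` (0 = identity).
#' @return Smoothed `pet_volume`.
#' @export
smooth_map <- function(x, fwhm_mm) {
  stopifnot(inherits(x, "pet_volume"))
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(x)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vd <- voxdim(x)
  defined <- !is.na(x)
  num <- unclass(x); num[!defined] <- 0
  den <- array(as.numeric(defined), dim(x))
  for (axis in 1:3) {
    sig <- sigma_mm / vd[axis]
    if (dim(x)[axis] == 1L || sig == 0) next
    w <- gauss_kernel(sig)
    num <- conv_axis(num, w, axis)
    den <- conv_axis(den, w, axis)
  }
  out <- num / den
  out[den <= .Machine$double.eps] <- NA_real_
  out[!defined] <- NA_real_
  rewrap_volume(out, x)
}

# Bin-integrated Gaussian kernel: weight k is the Gaussian mass falling in
# voxel bin [k - 1/2, k + 1/2].  Convolving a piecewise-constant (voxelized)
# image with this kernel reproduces the continuous Gaussian blur evaluated at
# voxel centers exactly, so phantom results agree with closed-form erf
# overlap integrals.
gauss_kernel <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(6 * sigma_vox)))
  k <- stats::pnorm(((-r:r) + 0.5) / sigma_vox) -
    stats::pnorm(((-r:r) - 0.5) / sigma_vox)
  k / sum(k)
}

# zero-padded 1D convolution along one axis of a 3D array
conv_axis <- function(a, w, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(a, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1])
  r <- (length(w) - 1L) / 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(w)) {
    shift <- j - r - 1L
    src <- seq_len(n) + shift
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + w[j] * m[src[ok], ]
  }
  aperm(array(out, dm), order(perm))
}

#' Voxelwise kinetic parametric maps
#'
#' Applies [patlak_fit()] or [srtm_fit()] to every voxel of a dynamic 4D
#' volume, producing a `Ki` or `BPnd` map. Voxels whose time series is not
#' finite or is identically zero are set to `NA` (the missing-value sentinel).
#' The SRTM basis set is computed once per call and shared by all voxels.
#'
#' @param dynamic 4D array (x, y, z, frame), frame count matching the
#'   reference schedule.
#' @param ref reference [tac()].
#' @param model `"patlak"` or `"srtm"`.
#' @param voxdim_mm voxel dimensions of the output map.
#' @param t_star Patlak start time (min).
#' @param theta3,weights,refine SRTM settings (see [srtm_fit()]).
#' @return A `pet_volume` tagged `"Ki"` or `"BPnd"`.
#' @export
fit_parametric_map <- function(dynamic, ref, model = c("patlak", "srtm"),
                               voxdim_mm = c(1, 1, 1), t_star = 25,
                               theta3 = theta3_grid(), weights = NULL,
                               refine = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(ref, "tac"))
  d <- dim(dynamic)
  if (length(d) != 4L || d[4] != nrow(ref$schedule)) {
    stop("dynamic must be 4D with one volume per frame")
  }
  nvox <- prod(d[1:3])
  Y <- matrix(dynamic, nrow = nvox)
  valid <- apply(Y, 1L, function(y) all(is.finite(y)) && any(y != 0))
  out <- rep(NA_real_, nvox)
  if (model == "patlak") {
    mid <- ref$schedule$mid
    used <- mid >= t_star
    if (sum(used) < 3L) stop("need at least 3 frames with midpoint >= t_star")
    if (any(ref$activity[used] <= 0)) {
      stop("reference activity must be > 0 in the fit window")
    }
    xall <- patlak_ref_integral(ref) / ref$activity
    xu <- xall[used]
    mx <- mean(xu)
    sxx <- sum((xu - mx)^2)
    if (any(valid)) {
      yu <- Y[valid, used, drop = FALSE] /
        matrix(ref$activity[used], sum(valid), sum(used), byrow = TRUE)
      out[valid] <- (yu %*% (xu - mx)) / sxx
    }
    qty <- "Ki"
  } else {
    basis <- srtm_basis_set(ref, theta3)
    w <- resolve_weights(weights, ref$schedule)
    idx <- which(valid)
    for (v in idx) {
      fit <- try(srtm_fit_engine(Y[v, ], basis, w, refine), silent = TRUE)
      out[v] <- if (inherits(fit, "try-error")) NA_real_ else fit$BPnd
    }
    qty <- "BPnd"
  }
  pet_volume(array(out, d[1:3]), voxdim_mm, qty)
}

#' Voxelwise group t-maps
#'
#' One-sample (against zero) or paired voxelwise t statistics across
#' subjects' parametric maps, with `df = n - 1`. Voxels with zero variance or
#' any missing subject value are set to `NA`.
#'
#' @param maps_a list of `pet_volume`s (one per subject).
#' @param maps_b second condition for `mode = "paired"` (the test is on
#'   `a - b`), or `NULL`.
#' @param mode `"one_sample"` or `"paired"`.
#' @return A `pet_volume` tagged `"t"`, with attribute `df`.
#' @export
group_tmap <- function(maps_a, maps_b = NULL,
                       mode = c("one_sample", "paired")) {
  mode <- match.arg(mode)
  n <- length(maps_a)
  if (n < 2L) stop("need at least 2 subjects")
  for (m in maps_a) {
    if (!same_grid(m, maps_a[[1]])) stop("maps must share a grid")
  }
  nvox <- length(maps_a[[1]])
  A <- matrix(vapply(maps_a, function(m) as.numeric(m), numeric(nvox)),
              nrow = nvox)
  if (mode == "paired") {
    if (is.null(maps_b) || length(maps_b) != n) {
      stop("paired mode needs maps_b of the same length")
    }
    for (m in maps_b) {
      if (!same_grid(m, maps_a[[1]])) stop("maps must share a grid")
    }
    B <- matrix(vapply(maps_b, function(m) as.numeric(m), numeric(nvox)),
                nrow = nvox)
    A <- A - B
  }
  mu <- rowMeans(A)
  sd <- sqrt(rowSums((A - mu)^2) / (n - 1))
  t <- mu / (sd / sqrt(n))
  t[!is.finite(t)] <- NA_real_
  out <- rewrap_volume(array(t, dim(maps_a[[1]])), maps_a[[1]], "t")
  attr(out, "df") <- n - 1L
  out
}

#' Cluster configuration
#'
#' @param p cluster-forming p threshold in `(0, 1)` (default 0.001,
#'   two-tailed by default).
#' @param df degrees of freedom of the t-map.
#' @param k minimum cluster extent in voxels, `>= 1` (default 55).
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (all neighbours);
#'   default 6.
#' @param tails 1 or 2 (default 2).
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(p = 0.001, df, k = 55, connectivity = 6,
                           tails = 2) {
  stopifnot(p > 0, p < 1, k >= 1, connectivity %in% c(6, 18, 26),
            tails %in% c(1, 2), df >= 1)
  structure(list(p = p, df = df, k = as.integer(k),
                 connectivity = as.integer(connectivity),
                 tails = as.integer(tails)),
            class = "cluster_config")
}

neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

# label connected components of a logical 3D array; returns an integer array
label_components <- function(mask, connectivity = 6) {
  d <- dim(mask)
  offs <- neighbour_offsets(connectivity)
  lab <- array(0L, d)
  comp <- 0L
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  coords <- arrayInd(idx, d)
  pos <- array(0L, d); pos[idx] <- seq_along(idx)
  for (s in seq_along(idx)) {
    if (lab[idx[s]] != 0L) next
    comp <- comp + 1L
    queue <- s
    lab[idx[s]] <- comp
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      c0 <- coords[cur, ]
      for (o in seq_len(nrow(offs))) {
        ci <- c0[1] + offs[o, 1]; cj <- c0[2] + offs[o, 2]
        ck <- c0[3] + offs[o, 3]
        if (ci < 1L || cj < 1L || ck < 1L ||
            ci > d[1] || cj > d[2] || ck > d[3]) next
        li <- ci + d[1] * ((cj - 1L) + d[2] * (ck - 1L))
        p <- pos[li]
        if (p > 0L && lab[li] == 0L) {
          lab[li] <- comp
          queue <- c(queue, p)
        }
      }
    }
  }
  lab
}

#' Threshold a t-map into suprathreshold clusters
#'
#' Voxels whose (by default two-tailed) p-value falls below the
#' cluster-forming threshold are grouped into connected components under the
#' configured connectivity; components smaller than the extent threshold `k`
#' are discarded.
#'
#' @param tmap a `pet_volume` of t statistics (attribute `df` used unless
#'   `cc$df` given).
#' @param cc a [cluster_config()].
#' @return List: `mask` (binary `pet_volume`) and `table` (data frame with
#'   cluster id, size in voxels, volume mm^3, peak |t| and its voxel
#'   coordinates; peak ties resolved to the lowest linear index).
#' @export
threshold_clusters <- function(tmap, cc) {
  stopifnot(inherits(tmap, "pet_volume"), inherits(cc, "cluster_config"))
  tcrit <- if (cc$tails == 2) {
    stats::qt(1 - cc$p / 2, cc$df)
  } else {
    stats::qt(1 - cc$p, cc$df)
  }
  supra <- !is.na(tmap) &
    (if (cc$tails == 2) abs(unclass(tmap)) > tcrit else unclass(tmap) > tcrit)
  lab <- label_components(supra, cc$connectivity)
  keep <- integer(0)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab)
    keep <- which(sizes >= cc$k)
  }
  mask <- array(lab %in% keep & lab > 0L, dim(tmap))
  tab <- do.call(rbind, lapply(keep, function(id) {
    vox <- which(lab == id)
    tv <- abs(as.numeric(tmap)[vox])
    peak <- vox[which.max(tv)] # which.max -> first = lowest linear index
    pc <- arrayInd(peak, dim(tmap))
    data.frame(cluster = id, size = length(vox),
               volume_mm3 = length(vox) * voxel_volume(tmap),
               peak_t = as.numeric(tmap)[peak],
               peak_x = pc[1], peak_y = pc[2], peak_z = pc[3])
  }))
  if (is.null(tab)) {
    tab <- data.frame(cluster = integer(0), size = integer(0),
                      volume_mm3 = numeric(0), peak_t = numeric(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0))
  } else {
    tab <- tab[order(-tab$size, tab$cluster), , drop = FALSE]
    tab$cluster <- seq_len(nrow(tab))
    rownames(tab) <- NULL
  }
  list(mask = rewrap_volume(mask + 0, tmap, "mask"), table = tab)
}

#' Monte-Carlo calibration of the minimum cluster extent
#'
#' Estimates the smallest cluster extent `k` controlling the family-wise
#' error of suprathreshold clusters at level `alpha` under a smooth Gaussian
#' null, mirroring the AFNI 3dClustSim procedure: white-noise volumes are
#' smoothed to the stated FWHM, standardised to unit variance within the
#' search mask, thresholded at the cluster-forming `p` (two-tailed), and the
#' maximum cluster size per iteration is recorded; the result is the smallest
#' `k` with `P(max cluster >= k) <= alpha`.
#'
#' @param search_mask logical/binary `pet_volume` defining the search region.
#' @param fwhm_mm smoothing FWHM in mm (0 = unsmoothed noise).
#' @param p_thresh cluster-forming p threshold (two-tailed, on z).
#' @param alpha family-wise error level.
#' @param n_iter Monte-Carlo iterations, `>= 100`.
#' @param connectivity 6, 18 or 26.
#' @param seed integer seed (isolated RNG scope).
#' @return Integer `k_min`, with attribute `max_sizes` (the simulated null
#'   distribution of maximum cluster sizes).
#' @export
cluster_extent_mc <- function(search_mask, fwhm_mm, p_thresh = 0.001,
                              alpha = 0.05, n_iter = 1000, connectivity = 6,
                              seed = 1L) {
  stopifnot(inherits(search_mask, "pet_volume"))
  if (n_iter < 100) stop("n_iter must be >= 100")
  msk <- !is.na(search_mask) & unclass(search_mask) != 0
  if (!any(msk)) stop("empty search mask")
  zcrit <- stats::qnorm(1 - p_thresh / 2)
  d <- dim(search_mask)
  max_sizes <- withr::with_seed(seed, vapply(seq_len(n_iter), function(i) {
    noise <- array(stats::rnorm(prod(d)), d)
    if (fwhm_mm > 0) {
      noise <- unclass(smooth_map(rewrap_volume(noise, search_mask, "z"),
                                  fwhm_mm))
    }
    z <- noise[msk]
    noise <- (noise - mean(z)) / stats::sd(z)
    supra <- msk & abs(noise) > zcrit
    if (!any(supra)) return(0L)
    max(tabulate(label_components(supra, connectivity)))
  }, integer(1)))
  k <- 1L
  while (mean(max_sizes >= k) > alpha) k <- k + 1L
  structure(k, max_sizes = max_sizes)
}

#' Intersect binary masks
#'
#' Logical AND of two or more masks on a shared grid, with the resulting
#' volume in mm^3 (voxel count times voxel volume).
#'
#' @param masks list of binary/logical `pet_volume`s on the same grid.
#' @return List: `mask` (`pet_volume`) and `volume_mm3`.
#' @export
intersect_masks <- function(masks) {
  stopifnot(length(masks) >= 1)
  for (m in masks) {
    if (!same_grid(m, masks[[1]])) stop("masks must share a grid")
  }
  acc <- !is.na(masks[[1]]) & unclass(masks[[1]]) != 0
  for (m in masks[-1]) acc <- acc & !is.na(m) & unclass(m) != 0
  list(
    mask = rewrap_volume(acc + 0, masks[[1]], "mask"),
    volume_mm3 = sum(acc) * voxel_volume(masks[[1]])
  )
}

#' Posterior cerebellar reference-region mask
#'
#' Builds the reference-region mask used for striatal dopamine quantification
#' by removing the most anterior fraction of coronal slices from a cerebellar
#' gray-matter segmentation (limiting contamination from midbrain
#' dopaminergic nuclei). Among the coronal slices (along the volume's
#' anterior-posterior axis, anterior at index 1) that contain the cerebellum
#' label, the most anterior `round(fraction * n_slices)` slices are cleared
#' (round-half-up, so exactly 1/4 of slices for counts divisible by 4).
#'
#' @param labels `pet_volume` of integer labels.
#' @param label_id cerebellum label value (default 1).
#' @param fraction fraction of slices to remove, in `[0, 1)` (default 0.25).
#' @return Binary `pet_volume` of the retained cerebellar voxels.
#' @export
posterior_cerebellum_mask <- function(labels, label_id = 1L,
                                      fraction = 0.25) {
  stopifnot(inherits(labels, "pet_volume"))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  ap <- attr(labels, "ap_axis") %||% 2L
  cb <- unclass(labels) == label_id
  if (!any(cb)) stop("cerebellum label absent")
  slice_has <- apply(cb, ap, any)
  slices <- which(slice_has)
  n_remove <- floor(fraction * length(slices) + 0.5) # round half up
  if (n_remove > 0) {
    drop_slices <- slices[seq_len(n_remove)] # anterior = low index
    idx <- arrayInd(which(cb), dim(labels))
    kill <- idx[, ap] %in% drop_slices
    cb[which(cb)[kill]] <- FALSE
  }
  rewrap_volume(cb + 0, labels, "mask")
}

#' Extract a region-of-interest mean or TAC
#'
#' Mean over the voxels of one label, ignoring missing voxels: from a 3D map
#' this yields a scalar summary, from a dynamic 4D array a per-frame mean,
#' i.e. a regional [tac()].
#'
#' @param x 3D `pet_volume`, or 4D array (`schedule` then required).
#' @param labels `pet_volume` of integer labels on the same grid.
#' @param label_id label to extract.
#' @param schedule [frame_schedule()] for 4D input.
#' @return For 3D input a list `(value, volume_mm3, n_voxels)`; for 4D input
#'   a [tac()] with the same attributes attached.
#' @export
extract_roi <- function(x, labels, label_id, schedule = NULL) {
  stopifnot(inherits(labels, "pet_volume"))
  sel <- unclass(labels) == label_id
  if (!any(sel)) stop("label ", label_id, " absent")
  vol <- sum(sel) * voxel_volume(labels)
  if (length(dim(x)) == 3L) {
    vals <- as.numeric(x)[which(sel)]
    if (all(is.na(vals))) stop("ROI is entirely missing")
    list(value = mean(vals, na.rm = TRUE), volume_mm3 = vol,
         n_voxels = sum(sel))
  } else if (length(dim(x)) == 4L) {
    if (is.null(schedule)) stop("schedule required for dynamic input")
    d <- dim(x)
    Y <- matrix(x, nrow = prod(d[1:3]))[which(sel), , drop = FALSE]
    act <- colMeans(Y, na.rm = TRUE)
    if (any(!is.finite(act))) stop("ROI is entirely missing in some frame")
    tac(schedule, act, region = as.character(label_id))
  } else {
    stop("x must be a 3D map or 4D dynamic array")
  }
}

#' Sorensen-Dice overlap of two masks
#'
#' `2|A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b binary/logical `pet_volume`s on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!same_grid(mask_a, mask_b)) stop("masks must share a grid")
  a <- !is.na(mask_a) & unclass(mask_a) != 0
  b <- !is.na(mask_b) & unclass(mask_b) != 0
  if (!any(a) && !any(b)) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}
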