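#' Voxel grid geometry
#'
#' A minimal container pairing array dimensions with a voxel-to-world (mm)
#' affine in NIfTI convention: world = affine %*% c(i, j, k, 1) with
#' zero-based voxel indices.
#'
#' @param dim Integer vector of 3 array dimensions.
#' @param affine 4x4 voxel-to-mm matrix. Default: identity scaled by
#'   `voxel_mm` with zero origin.
#' @param voxel_mm Isotropic voxel size used when `affine` is missing.
#' @return An object of class `vox_grid`.
#' @export
vox_grid <- function(dim, affine = NULL, voxel_mm = 1) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1))
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_mm, 3), 1))
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)))
  structure(list(dim = dim, affine = affine), class = "vox_grid")
}

# world-space centers of all voxels, n x 3; idx is n x 3 of 1-based indices
voxel_centers_mm <- function(grid, idx) {
  v <- cbind(idx - 1, 1)
  t(grid$affine %*% t(v))[, 1:3, drop = FALSE]
}

#' Standardize a series to mean zero, variance one
#'
#' Population form: the variance denominator is `N`, so the output satisfies
#' `mean(x) == 0` and `mean(x^2) == 1` exactly (up to rounding). This is the
#' normalization applied to each extracted ROI series before lag embedding.
#'
#' @param series Numeric vector, length >= 2.
#' @param label Optional name used in the error message for constant input.
#' @return Standardized numeric vector.
#' @export
standardize_series <- function(series, label = NULL) {
  series <- as.numeric(series)
  if (length(series) < 2) stop("series must have length >= 2")
  if (anyNA(series)) stop("series contains missing values")
  m <- mean(series)
  v <- mean((series - m)^2)
  if (v <= .Machine$double.eps * max(1, m^2))
    stop("constant series cannot be standardized",
         if (!is.null(label)) paste0(" (ROI ", label, ")") else "")
  (series - m) / sqrt(v)
}

#' Mean time series over a voxel mask
#'
#' @param volume 4D numeric array (x, y, z, t).
#' @param mask Logical/0-1 3D array matching the spatial dimensions.
#' @return Numeric vector of length `T`: element `t` is the mean over masked
#'   voxels of volume `t`.
#' @export
extract_mean_timeseries <- function(volume, mask) {
  d <- dim(volume)
  if (length(d) != 4) stop("volume must be 4D (x, y, z, t)")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!all(dim(mask) == d[1:3])) stop("mask dimensions do not match volume")
  n <- sum(mask)
  if (n == 0) stop("mask is empty")
  V <- matrix(volume, prod(d[1:3]), d[4])
  colMeans(V[as.vector(mask), , drop = FALSE])
}

#' Spherical ROI mask around a peak coordinate
#'
#' Marks every voxel whose center lies within `diameter_mm / 2` of
#' `center_mm` (voxel-center membership rule), clipped at the grid edges.
#' With a 5 mm diameter and 4 mm isotropic voxels this reduces to the single
#' nearest voxel.
#'
#' @param center_mm Length-3 world coordinate of the sphere center.
#' @param diameter_mm Sphere diameter in mm (> 0).
#' @param grid A [vox_grid()] (or an object with `dim` and `affine`).
#' @return Logical 3D array.
#' @export
sphere_mask <- function(center_mm, diameter_mm, grid) {
  stopifnot(diameter_mm > 0, length(center_mm) == 3)
  r <- diameter_mm / 2
  d <- grid$dim
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  ctr <- voxel_centers_mm(grid, idx)
  dist2 <- rowSums(sweep(ctr, 2, as.numeric(center_mm))^2)
  mask <- array(dist2 <= r^2, dim = d)
  if (!any(mask)) {
    # distance from center to nearest voxel center
    warning(sprintf(
      "sphere at (%s) mm contains no voxel centers (nearest center %.1f mm away)",
      paste(round(center_mm, 1), collapse = ", "), sqrt(min(dist2))))
  }
  mask
}

#' Threshold a statistic map and filter clusters by extent
#'
#' Keeps connected components of the supra-threshold set `{z >= z_thresh}`
#' with at least `min_voxels` voxels. Connectivity defaults to 6
#' (face neighbours). This voxel-level threshold plus extent rule is the
#' documented approximation to cluster-corrected map thresholding; no
#' random-field correction is applied.
#'
#' @param zmap 3D numeric statistic map (finite values).
#' @param z_thresh Positive voxel-level threshold.
#' @param min_voxels Minimum cluster extent (>= 1); 15 mirrors the selection
#'   rule used for between-group activation maps.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full neighbourhood).
#' @param grid Optional [vox_grid()] for mm peak coordinates; defaults to a
#'   unit grid.
#' @return A `data.frame` of class `cluster_table` with one row per
#'   surviving cluster: `label`, `size`, `peak_z`, `peak_i/j/k` (1-based
#'   voxel) and `peak_x/y/z` (mm). Empty when nothing survives. Peak ties
#'   resolve to the first voxel in ascending scan order.
#' @export
threshold_and_cluster <- function(zmap, z_thresh, min_voxels = 15,
                                  connectivity = 6, grid = NULL) {
  d <- dim(zmap)
  if (length(d) != 3) stop("zmap must be a 3D array")
  if (!all(is.finite(zmap))) stop("zmap must be finite everywhere")
  if (z_thresh <= 0) stop("z_thresh must be > 0")
  if (min_voxels < 1) stop("min_voxels must be >= 1")
  if (is.null(grid)) grid <- vox_grid(d)
  offsets <- neighbour_offsets(connectivity)

  supra <- zmap >= z_thresh
  labels <- array(0L, dim = d)
  nxt <- 0L
  comp_members <- list()
  lin <- which(supra)
  for (start in lin) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    members <- flood_fill(start, supra, labels, nxt, d, offsets)
    labels[members] <- nxt
    comp_members[[nxt]] <- members
  }

  rows <- list()
  keep <- 0L
  for (c in seq_along(comp_members)) {
    members <- comp_members[[c]]
    if (length(members) < min_voxels) next
    keep <- keep + 1L
    zs <- zmap[members]
    peak_lin <- members[which.max(zs)]  # which.max: first max in scan order
    ijk <- arrayInd(peak_lin, d)
    mm <- voxel_centers_mm(grid, ijk)
    rows[[keep]] <- data.frame(label = keep, size = length(members),
                               peak_z = zmap[peak_lin],
                               peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
                               peak_x = mm[1], peak_y = mm[2], peak_z_mm = mm[3])
  }
  tab <- if (keep) do.call(rbind, rows) else
    data.frame(label = integer(), size = integer(), peak_z = numeric(),
               peak_i = integer(), peak_j = integer(), peak_k = integer(),
               peak_x = numeric(), peak_y = numeric(), peak_z_mm = numeric())
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  switch(as.character(connectivity),
         "6"  = g[ord == 1, , drop = FALSE],
         "18" = g[ord <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26"))
}

# breadth-first component collection over linear indices
flood_fill <- function(start, supra, labels, comp, d, offsets) {
  members <- integer(0)
  queue <- start
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(as.character(start), TRUE, envir = visited)
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    members <- c(members, cur)
    ijk <- arrayInd(cur, d)
    nb <- sweep(offsets, 2, as.numeric(ijk), `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    if (!nrow(nb)) next
    lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
    for (l in lin) {
      key <- as.character(l)
      if (supra[l] && is.null(visited[[key]])) {
        assign(key, TRUE, envir = visited)
        queue <- c(queue, l)
      }
    }
  }
  members
}

#' Write a cluster table as TSV
#' @param tab A `cluster_table`.
#' @param path Output file.
#' @export
write_cluster_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build a synthetic 4D volume and z-map with planted ROI signals
#'
#' Fixture generator for the extraction stage: the panel's first subject's
#' series are planted inside spheres at `roi_centers_mm` (scaled by
#' `sphere_effect`), Gaussian noise fills the rest; the companion 3D z-map
#' carries supra-threshold blobs at the planted centers so that
#' [threshold_and_cluster()] recovers them.
#'
#' @param roi_centers_mm List (or matrix rows) of world coordinates, one per
#'   panel ROI.
#' @param panel An `roi_panel`; subject 1's series are planted.
#' @param grid A [vox_grid()].
#' @param sphere_effect Multiplier applied to the planted series.
#' @param noise_sd Gaussian noise sd added everywhere (0 = noise-free).
#' @param sphere_mm Diameter of the planted signal spheres.
#' @param peak_z Height of the z-map blobs at the planted centers.
#' @param seed Seed for the noise.
#' @return List with `bold` (4D array), `zmap` (3D array), `grid`, and
#'   `masks` (list of planted sphere masks).
#' @export
make_synthetic_volume <- function(roi_centers_mm, panel, grid,
                                  sphere_effect = 1, noise_sd = 0,
                                  sphere_mm = 5, peak_z = 5, seed = 1L) {
  stopifnot(inherits(panel, "roi_panel"))
  if (is.matrix(roi_centers_mm))
    roi_centers_mm <- lapply(seq_len(nrow(roi_centers_mm)),
                             function(i) roi_centers_mm[i, ])
  R <- length(panel$roi_labels)
  if (length(roi_centers_mm) != R)
    stop("need one center per ROI (", R, ")")
  X <- panel$subjects[[1]]
  Tn <- nrow(X)
  d <- grid$dim
  # reject centers outside the grid bounding box (in voxel space)
  for (ct in roi_centers_mm) {
    v <- solve(grid$affine, c(as.numeric(ct), 1))[1:3] + 1
    if (any(v < 0.5) || any(v > d + 0.5))
      stop("ROI center (", paste(ct, collapse = ", "), ") lies outside the grid")
  }
  set.seed(seed)
  bold <- array(rnorm(prod(d) * Tn, sd = noise_sd), dim = c(d, Tn))
  zmap <- array(0, dim = d)
  masks <- vector("list", R)
  for (r in seq_len(R)) {
    mask <- sphere_mask(roi_centers_mm[[r]], sphere_mm, grid)
    masks[[r]] <- mask
    lin <- which(mask)
    for (t in seq_len(Tn)) {
      page <- (t - 1L) * prod(d)
      bold[page + lin] <- bold[page + lin] + sphere_effect * X[t, r]
    }
    # blob decays with distance so its z peak sits at the planted center
    ctr <- voxel_centers_mm(grid, arrayInd(lin, d))
    dist <- sqrt(rowSums(sweep(ctr, 2, as.numeric(roi_centers_mm[[r]]))^2))
    zmap[lin] <- pmax(zmap[lin], peak_z - dist)
  }
  names(masks) <- panel$roi_labels
  list(bold = bold, zmap = zmap, grid = grid, masks = masks)
}

#' Read and write NIfTI volumes with an explicit affine
#'
#' Thin wrappers over RNifti keeping the rest of the package array-based.
#'
#' @param data 3D or 4D array.
#' @param grid A [vox_grid()] supplying the affine.
#' @param path Output/input file (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a list with `data` (array) and `grid`.
#' @export
write_volume <- function(data, grid, path) {
  img <- RNifti::asNifti(data)
  # sform<- preserves the voxel scale, so set pixdim from the affine first
  scales <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- c(scales, rep(1, length(dim(data)) - 3))
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  d <- dim(img)
  list(data = array(as.numeric(img), dim = d),
       grid = vox_grid(d[1:3], affine = aff))
}

#' Extract a standardized ROI panel from a z-map and 4D volume
#'
#' Chains the selection rules: threshold the z-map, keep clusters with at
#' least `min_voxels` voxels, draw a `sphere_mm` diameter sphere at each
#' cluster's peak, average the 4D series over each sphere, and standardize.
#'
#' @param bold 4D array.
#' @param zmap 3D statistic map.
#' @param grid A [vox_grid()].
#' @param z_thresh Voxel threshold (default 2.3).
#' @param min_voxels Cluster extent threshold (default 15).
#' @param sphere_mm Sphere diameter in mm (default 5).
#' @param roi_labels Optional labels; default `clust<label>`.
#' @param ... Passed to [threshold_and_cluster()].
#' @return An `roi_panel` with one subject, plus the `cluster_table` as
#'   attribute `clusters`.
#' @export
extract_roi_panel <- function(bold, zmap, grid, z_thresh = 2.3,
                              min_voxels = 15, sphere_mm = 5,
                              roi_labels = NULL, ...) {
  tab <- threshold_and_cluster(zmap, z_thresh, min_voxels, grid = grid, ...)
  if (!nrow(tab)) stop("no clusters survive thresholding")
  if (is.null(roi_labels)) roi_labels <- paste0("clust", tab$label)
  series <- sapply(seq_len(nrow(tab)), function(i) {
    mask <- sphere_mask(c(tab$peak_x[i], tab$peak_y[i], tab$peak_z_mm[i]),
                        sphere_mm, grid)
    standardize_series(extract_mean_timeseries(bold, mask),
                       label = roi_labels[i])
  })
  colnames(series) <- roi_labels
  p <- roi_panel(list(series), roi_labels)
  attr(p, "clusters") <- tab
  p
}
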