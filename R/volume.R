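#' Construct a 3D volume with physical geometry
#'
#' A `volume3d` is a 3D scalar array together with its physical geometry:
#' positive voxel spacings in millimetres and the world position (mm) of the
#' centre of voxel index `(1,1,1)`.  The axis convention is fixed,
#' right-handed and axis-aligned: world coordinate = origin + (index-1) *
#' spacing.  Oblique orientations are not supported.
#'
#' @param data numeric 3D array (any physical units).
#' @param spacing numeric length-3 vector of strictly positive voxel sizes
#'   (mm).
#' @param origin numeric length-3 world position (mm) of the centre of the
#'   first voxel.
#' @return An object of class `volume3d` with fields `data`, `spacing`,
#'   `origin`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(dim(data))) dim(data) <- c(length(data), 1L, 1L)
  if (length(dim(data)) == 4L && dim(data)[4] == 1L)
    dim(data) <- dim(data)[1:3]
  if (length(dim(data)) != 3L)
    stop("volume3d: 'data' must be a 3D array")
  if (any(dim(data) < 1L))
    stop("volume3d: all dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume3d: 'spacing' must be 3 strictly positive values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("volume3d: 'origin' must be 3 finite values")
  structure(list(data = data + 0.0, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("volume3d: %s voxels, spacing %s mm, origin %s mm, range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Test whether an object is a volume3d
#' @param x object.
#' @return logical.
#' @export
is_volume3d <- function(x) inherits(x, "volume3d")

stopifnot_volume <- function(v, what = "volume") {
  if (!is_volume3d(v)) stop(sprintf("'%s' must be a volume3d", what))
  invisible(v)
}

#' Check that two volumes share an identical voxel grid
#'
#' Shape must match exactly; spacing and origin to within `tol` mm.
#'
#' @param a,b volume3d objects.
#' @param tol geometric tolerance in mm.
#' @return logical.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Construct a binary mask sharing a reference volume's geometry
#'
#' @param data array (or logical array) of 0/1 values.
#' @param reference volume3d supplying the geometry, or `NULL` to pass
#'   `spacing`/`origin` directly.
#' @param spacing,origin geometry when `reference` is `NULL`.
#' @return A `volume3d` that is also of class `binary_mask`; data strictly
#'   in {0, 1}.
#' @export
binary_mask <- function(data, reference = NULL, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  if (is.logical(data)) data <- data + 0.0
  if (!is.null(reference)) {
    stopifnot_volume(reference, "reference")
    spacing <- reference$spacing
    origin <- reference$origin
    if (!is.null(dim(data)) && !identical(dim(data), dim(reference$data)))
      stop("binary_mask: data shape does not match reference")
  }
  v <- volume3d(data, spacing, origin)
  if (!all(v$data %in% c(0, 1)))
    stop("binary_mask: values must be exactly 0 or 1")
  class(v) <- c("binary_mask", class(v))
  v
}

#' World coordinates of every voxel centre
#'
#' @param v volume3d.
#' @param mask optional binary mask (same grid); restricts to voxels where
#'   the mask is 1.
#' @return N x 3 matrix of world coordinates (mm), in array storage order.
#' @export
voxel_world_coords <- function(v, mask = NULL) {
  d <- dim(v$data)
  if (!is.null(mask)) {
    if (!same_grid(v, mask)) stop("voxel_world_coords: mask grid mismatch")
    keep <- which(mask$data != 0)
    if (length(keep) == 0L) stop("voxel_world_coords: empty mask domain")
    idx <- arrayInd(keep, d)
  } else {
    idx <- arrayInd(seq_len(prod(d)), d)
  }
  sweep(sweep(idx - 1, 2, v$spacing, `*`), 2, v$origin, `+`)
}

#' Physical centre of a volume (mm)
#' @param v volume3d.
#' @return length-3 world coordinate of the geometric centre of the grid.
#' @export
volume_center <- function(v) {
  v$origin + (dim(v$data) - 1) / 2 * v$spacing
}

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [volume3d], taking spacing from the
#' header voxel dimensions and the origin from the translation column of the
#' stored affine.  A 4D image whose fourth dimension has length 1 is
#' squeezed to 3D; any other non-3D image is rejected.
#'
#' @param path file path.
#' @return volume3d with data cast to double.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_volume: no such file '%s'", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))  # stored squeezed
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.numeric(img), dim = d)
  } else {
    stop(sprintf("read_volume: expected a 3D image, got %d dimensions", length(d)))
  }
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3L) spacing <- c(spacing, rep(1, 3L - length(spacing)))
  spacing <- spacing[1:3]
  spacing[!is.finite(spacing) | spacing <= 0] <- 1
  aff <- RNifti::xform(img)
  # only axis-aligned grids are supported; the translation column is the
  # world position of voxel (1,1,1)
  origin <- as.numeric(aff[1:3, 4])
  volume3d(img2, spacing = spacing, origin = origin)
}

#' Write a volume as NIfTI-1
#'
#' The header encodes the voxel spacing and an axis-aligned affine whose
#' translation is the world origin, so [read_volume] recovers geometry
#' exactly (within float32 header precision).
#'
#' @param v volume3d.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  stopifnot_volume(v)
  aff <- diag(c(v$spacing, 1))
  aff[1:3, 4] <- v$origin
  img <- RNifti::asNifti(v$data)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Min-max rescale a volume to [0, 1]
#'
#' Linear rescale `(v - min) / (max - min)` with the extrema taken over the
#' optional support mask (whole volume otherwise).  A constant volume (or
#' constant support) maps to all zeros; output is clipped to [0, 1].
#'
#' @param v volume3d with finite values.
#' @param support optional binary mask over which the extrema are computed.
#' @return volume3d with values in [0, 1].
#' @export
minmax_rescale <- function(v, support = NULL) {
  stopifnot_volume(v)
  if (any(!is.finite(v$data))) stop("minmax_rescale: non-finite values in input")
  if (!is.null(support)) {
    if (!same_grid(v, support)) stop("minmax_rescale: support grid mismatch")
    vals <- v$data[support$data != 0]
    if (length(vals) == 0L) stop("minmax_rescale: empty support")
  } else {
    vals <- v$data
  }
  lo <- min(vals); hi <- max(vals)
  out <- if (hi > lo) pmin(pmax((v$data - lo) / (hi - lo), 0), 1)
         else array(0, dim(v$data))
  volume3d(out, v$spacing, v$origin)
}

#' Separable correlation along one array axis
#'
#' Applies a 1D kernel along the given axis of a 3D array.  `taps` are
#' correlation weights for offsets `-r..r`.  Padding is either edge
#' replication (for scale-space derivatives) or zeros (for box sums).
#'
#' @keywords internal
conv_axis <- function(a, taps, axis, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  d <- dim(a)
  n <- d[axis]
  r <- (length(taps) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = n)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(taps)) {
    t_off <- j - r - 1L
    if (taps[j] == 0) next
    idx <- seq_len(n) + t_off
    if (pad == "replicate") {
      idx <- pmin.int(pmax.int(idx, 1L), n)
      out <- out + taps[j] * m[idx, , drop = FALSE]
    } else {
      ok <- idx >= 1L & idx <= n
      if (any(ok))
        out[ok, ] <- out[ok, ] + taps[j] * m[idx[ok], , drop = FALSE]
    }
  }
  aperm(array(out, d[perm]), order(perm))
}

#' Gaussian kernel taps, polynomial-calibrated
#'
#' Sampled Gaussian (or derivative-of-Gaussian) correlation taps over
#' offsets `-r..r` with `r = max(1, ceil(4*sigma))`.  Taps are calibrated so
#' that the response to polynomials is exact: order 0 preserves constants,
#' order 1 maps a unit ramp to exactly 1, order 2 maps x^2/2 to exactly 1.
#'
#' @keywords internal
gaussian_taps <- function(sigma, order = 0L) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  t <- seq.int(-r, r)
  g <- exp(-t^2 / (2 * sigma^2))
  if (order == 0L) {
    k <- g / sum(g)
  } else if (order == 1L) {
    k <- t * g
    k <- k - mean(k)          # sum zero
    k <- k / sum(t * k)       # unit ramp response
  } else if (order == 2L) {
    k <- (t^2 - sigma^2) * g
    k <- k - mean(k)          # sum zero (symmetric, so ramp response stays 0)
    k <- k * (2 / sum(t^2 * k))
  } else stop("gaussian_taps: order must be 0, 1 or 2")
  k
}

#' Gaussian smoothing of a volume (sigma in voxels)
#' @keywords internal
gaussian_smooth <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- gaussian_taps(sigma, 0L)
  for (ax in 1:3) a <- conv_axis(a, k, ax, pad = "replicate")
  a
}

#' Downsample a volume by an integer factor
#'
#' Anti-alias Gaussian smoothing (sigma = 0.5 * factor voxels) followed by
#' decimation at voxel indices 1, 1+factor, 1+2*factor, ...  Output spacing
#' is the input spacing times the factor, the shape is `ceiling(shape /
#' factor)` and the origin is unchanged (the first retained sample sits at
#' the same world point), so the physical field of view is preserved.
#'
#' @param v volume3d.
#' @param factor integer >= 1; factor 1 returns the input unchanged.
#' @return volume3d.
#' @export
downsample <- function(v, factor) {
  stopifnot_volume(v)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("downsample: factor must be >= 1")
  if (factor == 1L) return(v)
  a <- gaussian_smooth(v$data, 0.5 * factor)
  d <- dim(a)
  ix <- seq.int(1L, d[1], by = factor)
  iy <- seq.int(1L, d[2], by = factor)
  iz <- seq.int(1L, d[3], by = factor)
  volume3d(a[ix, iy, iz, drop = FALSE], v$spacing * factor, v$origin)
}

#' Trilinear interpolation of a 3D array at continuous 1-based indices
#'
#' @param arr 3D array.
#' @param idx N x 3 matrix of continuous 1-based voxel indices.
#' @param fill value for points outside the array support.
#' @return numeric vector of length N.
#' @keywords internal
interp_trilinear <- function(arr, idx, fill = 0) {
  d <- dim(arr)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep.int(fill, nrow(idx))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin.int(floor(x), max(d[1] - 1, 1)); fx <- x - x0
  y0 <- pmin.int(floor(y), max(d[2] - 1, 1)); fy <- y - y0
  z0 <- pmin.int(floor(z), max(d[3] - 1, 1)); fz <- z - z0
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  dx <- if (d[1] > 1) sx else 0L
  dy <- if (d[2] > 1) sy else 0L
  dz <- if (d[3] > 1) sz else 0L
  base <- (x0 - 1) * sx + (y0 - 1) * sy + (z0 - 1) * sz + 1
  v000 <- arr[base];           v100 <- arr[base + dx]
  v010 <- arr[base + dy];      v110 <- arr[base + dx + dy]
  v001 <- arr[base + dz];      v101 <- arr[base + dx + dz]
  v011 <- arr[base + dy + dz]; v111 <- arr[base + dx + dy + dz]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Resample a volume through a rigid transform onto a reference grid
#'
#' Each world point X of the reference grid is mapped by `transform` into
#' the moving volume's space and sampled by trilinear interpolation; points
#' outside the moving support take `fill` (default 0, the natural value for
#' probability maps with a limited field of view).
#'
#' @param moving volume3d to sample from.
#' @param transform [rigid_transform] mapping reference world coordinates
#'   into moving world coordinates.
#' @param reference volume3d whose grid defines the output.
#' @param fill scalar fill value outside the moving support.
#' @return volume3d on the reference grid.
#' @export
resample <- function(moving, transform, reference, fill = 0) {
  stopifnot_volume(moving, "moving")
  stopifnot_volume(reference, "reference")
  W <- voxel_world_coords(reference)
  M <- transform_matrix(transform)
  Xm <- W %*% t(M[1:3, 1:3]) +
    matrix(M[1:3, 4], nrow(W), 3, byrow = TRUE)
  idx <- sweep(sweep(Xm, 2, moving$origin, `-`), 2, moving$spacing, `/`) + 1
  vals <- interp_trilinear(moving$data, idx, fill = fill)
  volume3d(array(vals, dim(reference$data)), reference$spacing, reference$origin)
}
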