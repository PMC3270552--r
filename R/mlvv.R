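#' Gaussian scale-space derivative of a volume
#'
#' Separable correlation with sampled Gaussian-derivative kernels.  `sigma`
#' is the image scale in voxels; derivatives are expressed per voxel unit
#' (spacing is not folded into the kernels), matching the convention of
#' scale given in voxels.  Kernels are polynomial-calibrated, so a linear
#' ramp has exact unit first derivative and zero second derivative in the
#' interior.
#'
#' @param v volume3d.
#' @param sigma scale in voxels (> 0).
#' @param orders length-3 integer vector of per-axis derivative orders,
#'   each in 0..2, total order <= 2.
#' @return volume3d of the derivative field.
#' @export
gaussian_derivative <- function(v, sigma, orders) {
  stopifnot_volume(v)
  if (!is.finite(sigma) || sigma <= 0) stop("gaussian_derivative: sigma must be > 0")
  orders <- as.integer(orders)
  if (length(orders) != 3L || any(orders < 0L) || any(orders > 2L) ||
      sum(orders) > 2L)
    stop("gaussian_derivative: per-axis orders must be in 0..2 with total <= 2")
  a <- v$data
  for (ax in 1:3)
    a <- conv_axis(a, gaussian_taps(sigma, orders[ax]), ax, pad = "replicate")
  volume3d(a, v$spacing, v$origin)
}

#' Scale-space valley operator (MLvv) of a volume
#'
#' Second-order curvature operator built from the six first and second
#' Gaussian derivatives of the image.  With gradient `w = (Vx, Vy, Vz)`:
#'
#' \deqn{MLvv = \frac{1}{2\|w\|^2}\big[
#'    V_x^2 (V_{yy}+V_{zz}) - 2 V_y V_z V_{yz}
#'  + V_y^2 (V_{xx}+V_{zz}) - 2 V_x V_z V_{xz}
#'  + V_z^2 (V_{xx}+V_{yy}) - 2 V_x V_y V_{xy}\big]}
#'
#' The sign is fixed so that intensity valleys (sulci, falx in T1-weighted
#' MR) give positive values and crests give negative values: on the
#' continuous valley `V = x^2 + y^2` the operator evaluates to exactly +1
#' off-axis.  Voxels whose squared gradient falls below the degeneracy
#' floor `eps = 1e-12 * (dynamic range)^2` are set to 0 (the operator
#' divides by `\|w\|^2` and is meaningless on flat regions).
#'
#' @param v volume3d with finite values.
#' @param sigma image scale in voxels; default 2.
#' @return volume3d of signed MLvv values (class `mlvv_field` prepended).
#' @export
compute_mlvv <- function(v, sigma = 2) {
  stopifnot_volume(v)
  if (any(!is.finite(v$data))) stop("compute_mlvv: non-finite values in input")
  g <- function(ox, oy, oz) gaussian_derivative(v, sigma, c(ox, oy, oz))$data
  Vx <- g(1, 0, 0); Vy <- g(0, 1, 0); Vz <- g(0, 0, 1)
  Vxx <- g(2, 0, 0); Vyy <- g(0, 2, 0); Vzz <- g(0, 0, 2)
  Vxy <- g(1, 1, 0); Vxz <- g(1, 0, 1); Vyz <- g(0, 1, 1)
  w2 <- Vx^2 + Vy^2 + Vz^2
  num <- Vx^2 * (Vyy + Vzz) - 2 * Vy * Vz * Vyz +
         Vy^2 * (Vxx + Vzz) - 2 * Vx * Vz * Vxz +
         Vz^2 * (Vxx + Vyy) - 2 * Vx * Vy * Vxy
  rng <- max(v$data) - min(v$data)
  # degeneracy floor: 1e-12 of the squared dynamic range, plus a rounding
  # floor tied to the intensity magnitude so constant volumes are exact 0
  eps <- 1e-12 * rng^2 + (1e-12 * max(abs(v$data), 1))^2
  out <- num / (2 * pmax(w2, eps))
  out[w2 < eps] <- 0
  res <- volume3d(out, v$spacing, v$origin)
  class(res) <- c("mlvv_field", class(res))
  res
}

as_probability_map <- function(v) {
  if (any(v$data < -1e-9) || any(v$data > 1 + 1e-9))
    stop("probability map values outside [0,1]")
  v$data <- pmin(pmax(v$data, 0), 1)
  class(v) <- unique(c("probability_map", class(v)))
  v
}

#' Scale the positive part of an MLvv field to [0, 1]
#'
#' Negative (crest) values are discarded; the strictly positive values are
#' min-max scaled over their own support, so the background stays exactly 0
#' and the strongest valley voxel becomes 1.
#'
#' @param mlvv volume3d of signed MLvv values.
#' @return probability-map volume3d in [0, 1].
#' @export
scale_mlvv_positive <- function(mlvv) {
  stopifnot_volume(mlvv)
  a <- mlvv$data
  pos <- a > 0
  out <- array(0, dim(a))
  if (any(pos)) {
    vals <- a[pos]
    lo <- min(vals); hi <- max(vals)
    out[pos] <- if (hi > lo) (vals - lo) / (hi - lo) else 1
  }
  as_probability_map(volume3d(out, mlvv$spacing, mlvv$origin))
}

#' Hyperechogenic-structure probability map from a denoised MR volume
#'
#' The per-voxel probability that MR tissue appears bright in B-mode
#' ultrasound: the scaled positive part of the MLvv valley field (sulci and
#' cerebral falx) merged with the segmented lesion at probability `psi`.
#' The merge takes the voxel-wise maximum of the two terms, which preserves
#' probability semantics when a sulcus borders the lesion.
#'
#' @param denoised_mr volume3d (brain-masked, denoised MR).
#' @param lesion binary lesion mask on the MR grid, or `NULL` for none.
#' @param psi probability in [0, 1] assigned to lesion voxels; 1 for
#'   homogeneous hyperechogenic lesions (cavernoma, low-grade glioma).
#' @param sigma MLvv image scale in voxels; default 2.
#' @return probability-map volume3d in [0, 1].
#' @export
mr_probability_map <- function(denoised_mr, lesion = NULL, psi = 1,
                               sigma = 2) {
  stopifnot_volume(denoised_mr, "denoised_mr")
  if (!is.finite(psi) || psi < 0 || psi > 1)
    stop("mr_probability_map: psi must be in [0, 1]")
  scaled <- scale_mlvv_positive(compute_mlvv(denoised_mr, sigma))
  if (!is.null(lesion)) {
    if (!same_grid(denoised_mr, lesion))
      stop("mr_probability_map: lesion geometry mismatch")
    scaled$data <- pmax(scaled$data, psi * (lesion$data != 0))
  }
  as_probability_map(scaled)
}

#' Hyperechogenic-structure probability map from an ultrasound volume
#'
#' The ultrasound intensities serve directly as probabilities: the volume
#' is min-max rescaled to [0, 1] and nothing else is done, so acoustic
#' shadows (zeros) map to probability exactly 0.
#'
#' @param us volume3d of reconstructed 3D ultrasound intensities.
#' @return probability-map volume3d in [0, 1].
#' @export
us_probability_map <- function(us) {
  stopifnot_volume(us, "us")
  as_probability_map(minmax_rescale(us))
}
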