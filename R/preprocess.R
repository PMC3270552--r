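#' Non-local means parameters
#'
#' @param patch_radius patch half-width in voxels (patch is
#'   `(2r+1)^3`); default 1.
#' @param search_radius search-window half-width in voxels; default 3.
#' @param h filtering bandwidth in intensity units, or `"auto"` to derive
#'   it from a robust pseudo-residual estimate of the noise standard
#'   deviation (`h = sqrt(2) * sigma_hat`).
#' @return object of class `nlm_params`.
#' @export
nlm_params <- function(patch_radius = 1L, search_radius = 3L, h = "auto") {
  patch_radius <- as.integer(patch_radius)
  search_radius <- as.integer(search_radius)
  if (is.na(patch_radius) || patch_radius < 1L)
    stop("nlm_params: patch_radius must be >= 1")
  if (is.na(search_radius) || search_radius < 1L)
    stop("nlm_params: search_radius must be >= 1")
  if (!identical(h, "auto")) {
    h <- as.numeric(h)
    if (!is.finite(h) || h <= 0) stop("nlm_params: h must be positive or 'auto'")
  }
  structure(list(patch_radius = patch_radius, search_radius = search_radius,
                 h = h),
            class = "nlm_params")
}

#' Zero a volume outside a brain mask
#'
#' @param v volume3d.
#' @param mask binary mask on the same grid.
#' @return volume3d with outside-mask voxels set to 0.
#' @export
apply_brain_mask <- function(v, mask) {
  stopifnot_volume(v)
  if (!same_grid(v, mask)) stop("apply_brain_mask: mask geometry mismatch")
  volume3d(v$data * (mask$data != 0), v$spacing, v$origin)
}

#' Pseudo-residual noise estimate
#'
#' Estimates the standard deviation of additive noise from the 6-neighbour
#' pseudo-residuals `sqrt(6/7) * (v - mean of 6 neighbours)`, restricted to
#' the mask interior so structure edges and the mask boundary do not
#' inflate the estimate.
#'
#' @param v volume3d.
#' @param mask optional binary mask.
#' @return estimated noise sigma (intensity units).
#' @export
estimate_noise_sigma <- function(v, mask = NULL) {
  stopifnot_volume(v)
  a <- v$data
  d <- dim(a)
  nb <- conv_axis(a, c(1, 0, 1), 1, "replicate") +
        conv_axis(a, c(1, 0, 1), 2, "replicate") +
        conv_axis(a, c(1, 0, 1), 3, "replicate")
  res <- sqrt(6 / 7) * (a - nb / 6)
  if (!is.null(mask)) {
    if (!same_grid(v, mask)) stop("estimate_noise_sigma: mask grid mismatch")
    inside <- mask$data != 0
    # erode once so the residual stencil stays inside the mask
    er <- inside
    for (ax in 1:3)
      er <- er & (conv_axis(inside + 0, c(1, 1, 1), ax, "zero") >= 3 - 1e-9)
    vals <- res[er]
    if (length(vals) < 8) vals <- res[inside]
  } else {
    vals <- res
  }
  sqrt(mean(vals^2))
}

# zero-padded box sum over a cubic neighbourhood of half-width r
boxsum3 <- function(a, r) {
  taps <- rep(1, 2L * r + 1L)
  for (ax in 1:3) a <- conv_axis(a, taps, ax, pad = "zero")
  a
}

shift3 <- function(a, o) {
  # translate array content by integer offset o (zero fill): out[i] = a[i + o]
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- seq_len(d[ax]) + o[ax]
    ok <- s >= 1L & s <= d[ax]
    if (!any(ok)) return(out)
    src[[ax]] <- s[ok]
    dst[[ax]] <- seq_len(d[ax])[ok]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Non-local means denoising of a 3D volume
#'
#' Classical (non-blockwise) non-local means: each voxel is replaced by a
#' weight-normalized average of the voxels in its search window, with
#' weights `exp(-d2 / h^2)` where `d2` is the mean squared difference
#' between the two voxels' surrounding patches.  Weights sum to 1 at every
#' voxel (the offset-0 term has weight 1, so the normalizer is never
#' degenerate).  When a mask is given, voxels outside it are excluded from
#' all patch statistics and averages, and remain 0 in the output; this
#' avoids halos at the brain-mask boundary.
#'
#' @param v volume3d with finite values.
#' @param params [nlm_params].
#' @param mask optional binary mask restricting the computation.
#' @return denoised volume3d.
#' @export
nlm_denoise <- function(v, params = nlm_params(), mask = NULL) {
  stopifnot_volume(v)
  if (any(!is.finite(v$data))) stop("nlm_denoise: non-finite values in input")
  if (!inherits(params, "nlm_params")) stop("nlm_denoise: params must be nlm_params")
  a <- v$data
  d <- dim(a)
  if (!is.null(mask)) {
    if (!same_grid(v, mask)) stop("nlm_denoise: mask grid mismatch")
    m <- (mask$data != 0) + 0.0
    a <- a * m
  } else {
    m <- array(1, d)
  }
  h <- params$h
  if (identical(h, "auto")) {
    h <- sqrt(2) * estimate_noise_sigma(volume3d(a, v$spacing, v$origin),
                                        if (is.null(mask)) NULL else mask)
    if (h <= 0) h <- .Machine$double.eps  # noiseless input: degenerate to identity-dominated weights
  }
  pr <- params$patch_radius
  sr <- params$search_radius
  acc <- array(0, d)
  wsum <- array(0, d)
  offsets <- expand.grid(ox = -sr:sr, oy = -sr:sr, oz = -sr:sr)
  for (i in seq_len(nrow(offsets))) {
    o <- as.integer(offsets[i, ])
    if (all(o == 0L)) next
    ao <- shift3(a, o)
    mo <- shift3(m, o)
    joint <- m * mo
    num <- boxsum3((a - ao)^2 * joint, pr)
    den <- boxsum3(joint, pr)
    d2 <- num / pmax(den, 1e-12)
    w <- exp(-d2 / h^2) * joint
    acc <- acc + w * ao
    wsum <- wsum + w
  }
  # offset zero: weight 1, guarantees a convex average
  acc <- acc + a * m
  wsum <- wsum + m
  out <- (acc / pmax(wsum, 1e-300)) * m
  volume3d(out, v$spacing, v$origin)
}
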