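#' Specification of a synthetic MR/US phantom
#'
#' Describes a brain-like test object: a bright homogeneous tissue block
#' crossed by dark tubular valleys (sulci) with smooth random curvature, an
#' optional dark mid-plane sheet (cerebral falx) and a hypointense
#' spherical lesion.  The matched ultrasound volume is bright at the same
#' liquid interfaces and homogeneously bright inside the lesion, corrupted
#' by multiplicative speckle, an optional acoustic-shadow slab and an
#' optional limited field of view.
#'
#' Default levels are on a normalized 0-1 intensity scale: tissue 0.7,
#' valley floor about 0.15, lesion 0.35 in MR; the MR noise sigma of 0.02
#' corresponds to ~3% of the tissue level and the speckle variance of 0.2
#' is a moderate fully-developed-speckle surrogate.
#'
#' @param shape length-3 voxel dimensions; default `c(64, 64, 64)`.
#' @param spacing voxel size in mm; default 1 mm isotropic.
#' @param n_sulci number of dark tubes; default 6.
#' @param falx include the dark mid-plane sheet; default TRUE.
#' @param lesion list with `center` (mm, world), `radius` (mm),
#'   `mr_level` (hypointense MR intensity) and `echo_level` (US
#'   echogenicity); `NULL` for no lesion.
#' @param noise_sigma additive Gaussian MR noise sd (intensity units).
#' @param speckle_var variance of the unit-mean multiplicative US speckle.
#' @param shadow `NULL`, or a list with `axis` (1-3), `from` (fraction of
#'   the axis where the zeroed slab starts) and `frac` (fraction of the
#'   field of view it covers).
#' @param fov `NULL` for the full grid, or a list of `lo`/`hi` index
#'   fractions per axis defining the retained US box.
#' @param seed integer seed controlling all randomness of the phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         n_sulci = 6L, falx = TRUE,
                         lesion = list(center = NULL, radius = 8,
                                       mr_level = 0.35, echo_level = 0.9),
                         noise_sigma = 0.02, speckle_var = 0.2,
                         shadow = NULL, fov = NULL, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("phantom_spec: shape must be 3 dimensions of at least 8 voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("phantom_spec: spacing must be positive")
  if (!is.null(lesion)) {
    if (is.null(lesion$center))
      lesion$center <- (shape - 1) * spacing * c(0.62, 0.40, 0.58)
    if (is.null(lesion$mr_level)) lesion$mr_level <- 0.35
    if (is.null(lesion$echo_level)) lesion$echo_level <- 0.9
    extent <- (shape - 1) * spacing
    if (any(lesion$center - lesion$radius < 0) ||
        any(lesion$center + lesion$radius > extent))
      stop("phantom_spec: lesion does not fit inside the volume")
  }
  if (!is.null(shadow)) {
    if (is.null(shadow$axis)) shadow$axis <- 3L
    if (is.null(shadow$from)) shadow$from <- 0.8
    if (is.null(shadow$frac)) shadow$frac <- 0.2
  }
  if (!is.null(fov)) {
    if (is.null(fov$lo)) fov$lo <- c(0, 0, 0)
    if (is.null(fov$hi)) fov$hi <- c(1, 1, 1)
    if (any(fov$hi <= fov$lo)) stop("phantom_spec: empty fov box")
  }
  structure(list(shape = shape, spacing = spacing,
                 n_sulci = as.integer(n_sulci), falx = isTRUE(falx),
                 lesion = lesion, noise_sigma = noise_sigma,
                 speckle_var = speckle_var, shadow = shadow, fov = fov,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# index grids (1-based) for a shape
index_grid <- function(shape) {
  list(x = array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), shape),
       y = array(rep(rep(seq_len(shape[2]), each = shape[1]),
                     times = shape[3]), shape),
       z = array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape))
}

#' Generate a synthetic MR phantom with ground-truth masks
#'
#' Builds the bright-tissue block, carves `n_sulci` smoothly curved dark
#' tubes (half running predominantly along y, half along z so that all
#' rotations are geometrically constrained), subtracts the falx sheet,
#' inserts the hypointense lesion and adds Gaussian noise.  Ground truth
#' (1-voxel valley centreline skeleton, lesion mask, field-of-view mask)
#' is returned alongside.
#'
#' @param spec [phantom_spec].
#' @return list with `volume` (volume3d) and `truth` (list of class
#'   `phantom_truth`: `centerline`, `lesion_mask`, `shadow_mask`,
#'   `fov_mask` binary masks and `transform`, the applied ground-truth
#'   transform, identity at generation time).
#' @export
generate_mr_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("generate_mr_phantom: need phantom_spec")
  set.seed(spec$seed)
  d <- spec$shape
  g <- index_grid(d)
  tissue <- 0.7
  v <- array(tissue, d)
  skel <- array(0, d)
  depth <- 0.55
  r_tube <- 2.0  # Gaussian half-width of the valley profile, voxels;
                 # matches the sigma = 2 operator scale used for sulci
  # valley profiles combine as a smooth probabilistic union, so confluent
  # valleys saturate at the fluid level without intensity creases
  miss <- array(1, d)

  add_tube <- function(axis, base_frac) {
    # tube along `axis` with sinusoidal curvature in the two other axes;
    # base positions are stratified (sulci are quasi-regularly spaced)
    n_along <- d[axis]
    others <- setdiff(1:3, axis)
    base <- (base_frac + stats::runif(2, -0.05, 0.05)) * (d[others] - 1) + 1
    amp <- stats::runif(2, 1, 4)
    lam <- stats::runif(2, 0.8, 1.6) * n_along
    phase <- stats::runif(2, 0, 2 * pi)
    t_along <- seq_len(n_along)
    c1 <- base[1] + amp[1] * sin(2 * pi * t_along / lam[1] + phase[1])
    c2 <- base[2] + amp[2] * sin(2 * pi * t_along / lam[2] + phase[2])
    along <- switch(axis, g$x, g$y, g$z)
    o1 <- switch(others[1], g$x, g$y, g$z)
    o2 <- switch(others[2], g$x, g$y, g$z)
    d2 <- (o1 - array(c1[along], d))^2 + (o2 - array(c2[along], d))^2
    miss <<- miss * (1 - exp(-d2 / (2 * r_tube^2)))
    sk <- d2 <= 1.0  # voxels within 1 voxel of the centreline
    skel <<- pmax(skel, sk + 0)
  }
  if (spec$n_sulci > 0) {
    # alternate tube direction (y / z) so every rotation is constrained
    axes <- rep(c(2L, 3L), length.out = spec$n_sulci)
    for (ax in unique(axes)) {
      grp <- which(axes == ax)
      k <- length(grp)
      for (j in seq_along(grp)) {
        strat <- 0.2 + 0.6 * (j - 0.5) / k
        add_tube(ax, c(strat, stats::runif(1, 0.25, 0.75)))
      }
    }
  }
  if (spec$falx) {
    xf <- (d[1] + 1) / 2
    miss <- miss * (1 - exp(-(g$x - xf)^2 / (2 * 1.4^2)))
    skel <- pmax(skel, (abs(g$x - xf) <= 0.75) + 0)
  }
  v <- v - depth * (1 - miss)
  lesion_mask <- array(0, d)
  if (!is.null(spec$lesion)) {
    cidx <- spec$lesion$center / spec$spacing + 1
    rr <- spec$lesion$radius / spec$spacing
    q <- ((g$x - cidx[1]) / rr[1])^2 + ((g$y - cidx[2]) / rr[2])^2 +
         ((g$z - cidx[3]) / rr[3])^2
    inside <- q <= 1
    # soft edge over ~1 voxel so the lesion boundary is not a step
    blend <- pmin(pmax((1.15 - sqrt(q)) / 0.15, 0), 1)
    v <- v + (spec$lesion$mr_level - v) * blend
    lesion_mask[inside] <- 1
  }
  v <- pmax(v, 0)
  if (spec$noise_sigma > 0)
    v <- v + array(stats::rnorm(prod(d), 0, spec$noise_sigma), d)
  vol <- volume3d(v, spec$spacing, c(0, 0, 0))
  truth <- structure(list(
    centerline = binary_mask(skel, reference = vol),
    lesion_mask = binary_mask(lesion_mask, reference = vol),
    shadow_mask = binary_mask(array(0, d), reference = vol),
    fov_mask = binary_mask(array(1, d), reference = vol),
    transform = identity_transform(volume_center(vol)),
    spec = spec), class = "phantom_truth")
  list(volume = vol, truth = truth)
}

# 3^3 maximum filter (binary dilation by 1 voxel)
dilate1 <- function(a) {
  for (ax in 1:3) a <- pmin(conv_axis(a, c(1, 1, 1), ax, "zero"), 1)
  a
}

#' Simulate an ultrasound volume from phantom ground truth
#'
#' Builds an echogenicity field from the ground-truth geometry (not from
#' the MLvv of the MR phantom, so feature extraction and registration stay
#' independently testable): liquid interfaces are the valley centrelines
#' dilated by one voxel, bright and slightly smoothed; the lesion interior
#' is homogeneous and hyperechogenic; background tissue is weakly
#' echogenic.  The field is placed into the (possibly misaligned) US frame
#' through the inverse of `t_true`, multiplied by unit-mean gamma speckle,
#' zeroed inside the acoustic-shadow slab and cropped to the US field of
#' view.  The shadow and fov masks in `truth` are updated in place in the
#' returned attributes.
#'
#' @param truth `phantom_truth` from [generate_mr_phantom].
#' @param spec [phantom_spec] (noise/shadow/fov settings are read here).
#' @param t_true rigid_transform mapping US world coordinates to MR world
#'   coordinates; identity (default) gives a pre-aligned pair.
#' @return list with `volume` (the US volume3d) and `truth` (updated
#'   `phantom_truth` carrying `transform = t_true` and the realized shadow
#'   and fov masks on the US grid).
#' @export
simulate_us_from_mr <- function(truth, spec, t_true = NULL) {
  if (!inherits(truth, "phantom_truth")) stop("simulate_us_from_mr: need phantom_truth")
  d <- spec$shape
  set.seed(spec$seed + 104729L)  # independent stream from the MR noise
  iface <- dilate1(truth$centerline$data)
  echo <- 0.08 + 0.77 * iface
  if (!is.null(spec$lesion)) {
    echo <- pmax(echo, spec$lesion$echo_level * truth$lesion_mask$data)
  }
  echo <- gaussian_smooth(echo, 0.6)
  ref <- truth$centerline
  echo_vol <- volume3d(echo, ref$spacing, ref$origin)
  if (is.null(t_true)) t_true <- identity_transform(volume_center(echo_vol))
  if (max(abs(transform_params(t_true))) > 0) {
    # US frame value at X is the echogenicity at the aligned MR point
    echo_vol <- resample(echo_vol, t_true, echo_vol, fill = 0)
  }
  us <- echo_vol$data
  if (spec$speckle_var > 0) {
    shp <- 1 / spec$speckle_var
    us <- us * array(stats::rgamma(prod(d), shape = shp, scale = 1 / shp), d)
  }
  shadow_mask <- array(0, d)
  if (!is.null(spec$shadow)) {
    g <- index_grid(d)
    ax <- switch(spec$shadow$axis, g$x, g$y, g$z)
    n_ax <- d[spec$shadow$axis]
    lo <- spec$shadow$from * (n_ax - 1) + 1
    hi <- lo + spec$shadow$frac * (n_ax - 1)
    shadow_mask[ax >= lo & ax <= hi] <- 1
    us[shadow_mask == 1] <- 0
  }
  fov_mask <- array(1, d)
  if (!is.null(spec$fov)) {
    g <- index_grid(d)
    keep <- rep(TRUE, prod(d))
    for (ax in 1:3) {
      co <- switch(ax, g$x, g$y, g$z)
      lo <- spec$fov$lo[ax] * (d[ax] - 1) + 1
      hi <- spec$fov$hi[ax] * (d[ax] - 1) + 1
      keep <- keep & co >= lo & co <= hi
    }
    fov_mask[!keep] <- 0
    us[fov_mask == 0] <- 0
  }
  vol <- volume3d(us, ref$spacing, ref$origin)
  truth$shadow_mask <- binary_mask(shadow_mask, reference = vol)
  truth$fov_mask <- binary_mask(fov_mask, reference = vol)
  truth$transform <- t_true
  list(volume = vol, truth = truth)
}

#' One-call registration fixture
#'
#' Generates a pre-aligned MR/US phantom pair and everything needed to run
#' the full pipeline and score recovery against the known ground truth:
#' the MR volume, the US volume, the lesion and brain masks, the
#' ground-truth transform (identity: the pair is generated aligned, and
#' robustness protocols perturb it), and the truth masks.
#'
#' @param seed integer seed; the fixture is fully reproducible from it.
#' @param shape voxel dimensions; default 64^3 at 1 mm.
#' @param shadow,fov optional artifact settings forwarded to
#'   [phantom_spec].
#' @param speckle_var,noise_sigma noise settings forwarded to
#'   [phantom_spec].
#' @return list with `mr`, `us`, `lesion_mask`, `brain_mask`, `t_true`,
#'   `truth`, `spec`.
#' @export
make_registration_fixture <- function(seed = 1L, shape = c(64, 64, 64),
                                      shadow = NULL, fov = NULL,
                                      speckle_var = 0.2,
                                      noise_sigma = 0.02) {
  spec <- phantom_spec(shape = shape, shadow = shadow, fov = fov,
                       speckle_var = speckle_var,
                       noise_sigma = noise_sigma, seed = seed)
  mrp <- generate_mr_phantom(spec)
  usp <- simulate_us_from_mr(mrp$truth, spec)
  brain <- binary_mask(array(1, spec$shape), reference = mrp$volume)
  list(mr = mrp$volume, us = usp$volume,
       lesion_mask = mrp$truth$lesion_mask,
       brain_mask = brain,
       t_true = usp$truth$transform,
       truth = usp$truth, spec = spec)
}
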