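#' Paired homologous landmarks
#'
#' Ordered pairs of corresponding 3D world points (mm): `source` points
#' picked in the ultrasound volume and `target` points picked in the
#' resliced MR volume.
#'
#' @param source,target N x 3 numeric matrices of world coordinates (mm),
#'   equal row counts, N >= 3 for rigid fitting.
#' @return object of class `landmark_pairs`.
#' @export
landmark_pairs <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  storage.mode(source) <- storage.mode(target) <- "double"
  if (ncol(source) != 3L || ncol(target) != 3L)
    stop("landmark_pairs: points must have 3 columns")
  if (nrow(source) != nrow(target))
    stop("landmark_pairs: source and target counts differ")
  if (any(!is.finite(source)) || any(!is.finite(target)))
    stop("landmark_pairs: non-finite coordinates")
  structure(list(source = source, target = target, n = nrow(source)),
            class = "landmark_pairs")
}

#' Read landmark pairs from CSV
#'
#' Expected columns: `set` (`"source"`/`"us"` vs `"target"`/`"mr"`),
#' `point_id`, `x`, `y`, `z` in world mm.  Points are paired by
#' `point_id`.
#'
#' @param path CSV file.
#' @return landmark_pairs.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("set", "point_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("read_landmarks: CSV must have columns set,point_id,x,y,z")
  sets <- tolower(df$set)
  src <- df[sets %in% c("source", "us"), ]
  tgt <- df[sets %in% c("target", "mr"), ]
  src <- src[order(src$point_id), ]
  tgt <- tgt[order(tgt$point_id), ]
  if (!identical(src$point_id, tgt$point_id))
    stop("read_landmarks: unmatched point_id between sets")
  landmark_pairs(as.matrix(src[, c("x", "y", "z")]),
                 as.matrix(tgt[, c("x", "y", "z")]))
}

#' Write landmark pairs to CSV
#' @param pairs landmark_pairs.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_landmarks <- function(pairs, path) {
  df <- rbind(
    data.frame(set = "source", point_id = seq_len(pairs$n),
               x = pairs$source[, 1], y = pairs$source[, 2],
               z = pairs$source[, 3]),
    data.frame(set = "target", point_id = seq_len(pairs$n),
               x = pairs$target[, 1], y = pairs$target[, 2],
               z = pairs$target[, 3]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Least-squares rigid fit to paired landmarks
#'
#' Closed-form fit (centroid alignment plus rotation from the SVD of the
#' cross-covariance) minimizing the sum of squared distances between
#' transformed source points and target points.  Reflections are excluded
#' by the determinant-+1 correction.  The returned transform is
#' parameterized about the source centroid.
#'
#' @param pairs landmark_pairs with >= 3 non-collinear source points.
#' @return rigid_transform mapping source world coords onto targets.
#' @export
fit_rigid_landmarks <- function(pairs) {
  if (!inherits(pairs, "landmark_pairs")) stop("fit_rigid_landmarks: need landmark_pairs")
  if (pairs$n < 3L) stop("fit_rigid_landmarks: need at least 3 pairs")
  A <- pairs$source; B <- pairs$target
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  # collinearity check: second singular value of the centered source cloud
  sv <- svd(Ac)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("fit_rigid_landmarks: source points are (near-)collinear")
  H <- t(Ac) %*% Bc
  s <- svd(H)
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- cb - as.numeric(R %*% ca)
  transform_from_matrix(M, center = ca)
}

#' Initial landmark error before registration
#'
#' Per-point Euclidean distances between homologous points, with their
#' mean and sample standard deviation (n-1 denominator).
#'
#' @param pairs landmark_pairs.
#' @return list with `distances`, `mean`, `sd` (mm).
#' @export
initial_error <- function(pairs) {
  if (!inherits(pairs, "landmark_pairs")) stop("initial_error: need landmark_pairs")
  d <- sqrt(rowSums((pairs$target - pairs$source)^2))
  list(distances = d, mean = mean(d), sd = stats::sd(d))
}

#' Leave-one-out target registration error
#'
#' For each landmark i, a rigid transform is fitted to all other pairs and
#' applied to source point i; TRE_i is its distance to target point i.
#' The summary TRE is the mean over all points.
#'
#' @param pairs landmark_pairs with n >= 4.
#' @return list with `tre` (per point, mm), `mean`, `sd`.
#' @export
tre_leave_one_out <- function(pairs) {
  if (!inherits(pairs, "landmark_pairs")) stop("tre_leave_one_out: need landmark_pairs")
  if (pairs$n < 4L) stop("tre_leave_one_out: need at least 4 pairs")
  tre <- numeric(pairs$n)
  for (i in seq_len(pairs$n)) {
    sub <- landmark_pairs(pairs$source[-i, , drop = FALSE],
                          pairs$target[-i, , drop = FALSE])
    fit <- tryCatch(fit_rigid_landmarks(sub), error = function(e)
      stop(sprintf("tre_leave_one_out: degenerate fit leaving out point %d (%s)",
                   i, conditionMessage(e))))
    pred <- transform_points(fit, pairs$source[i, ])
    tre[i] <- sqrt(sum((pred - pairs$target[i, ])^2))
  }
  list(tre = tre, mean = mean(tre), sd = stats::sd(tre))
}

#' Warping index between two rigid transforms
#'
#' The mean over domain voxel world positions X of the Euclidean distance
#' between the two transforms' mappings, `mean ||T_true(X) - T_est(X)||`.
#' Both transforms are applied in the same direction, so the index is zero
#' exactly when they agree on the domain, is symmetric, and for a pure
#' translation difference equals that translation's norm on any domain.
#'
#' @param t_true,t_est rigid_transform objects.
#' @param domain volume3d (all voxels) or binary mask (voxels equal to 1)
#'   defining the averaging domain.
#' @return warping index in mm.
#' @export
warping_index <- function(t_true, t_est, domain) {
  stopifnot_volume(domain, "domain")
  X <- if (inherits(domain, "binary_mask"))
    voxel_world_coords(domain, mask = domain)
  else voxel_world_coords(domain)
  D <- transform_points(t_true, X) - transform_points(t_est, X)
  mean(sqrt(rowSums(D^2)))
}

#' Draw a random rigid transform
#'
#' Each translation component is Uniform[0, t_max] mm and each rotation
#' angle Uniform[0, r_max] degrees (the literal protocol); with
#' `symmetric = TRUE` the draws are Uniform[-t_max, t_max] and
#' Uniform[-r_max, r_max].  Uses R's global RNG stream: seed with
#' `set.seed()` for reproducibility.
#'
#' @param t_max maximum translation magnitude per axis (mm).
#' @param r_max maximum rotation magnitude per axis (degrees).
#' @param center rotation centre (world mm).
#' @param symmetric draw signed components instead of non-negative ones.
#' @return rigid_transform.
#' @export
random_rigid_transform <- function(t_max, r_max, center = c(0, 0, 0),
                                   symmetric = FALSE) {
  if (t_max < 0 || r_max < 0) stop("random_rigid_transform: bounds must be >= 0")
  lo_t <- if (symmetric) -t_max else 0
  lo_r <- if (symmetric) -r_max else 0
  rigid_transform(stats::runif(3, lo_t, t_max),
                  stats::runif(3, lo_r, r_max), center)
}

#' Randomized robustness study of the registration
#'
#' Repeats the convergence protocol: for each trial a random rigid
#' perturbation is drawn and composed into the MR map's frame (the MR map
#' is resampled through it on its own grid), the registration is run from
#' the reference initialization, and the warping index of the estimate
#' against the known composed truth is computed over the US-map domain.
#' A trial is a success when the warping index is below `threshold`.
#' Registration failures are recorded as non-successes, not raised.
#'
#' @param us_map,mr_map probability maps pre-aligned by `reference`.
#' @param reference rigid_transform giving the pre-alignment (identity for
#'   phantom fixtures).
#' @param n_trials number of random perturbations.
#' @param cfg [optimizer_config] used for each registration.
#' @param threshold success threshold on the warping index (mm);
#'   default 3.5.
#' @param t_max,r_max perturbation bounds (mm / degrees); default 5.
#' @param symmetric signed perturbation components; default FALSE
#'   (literal Uniform[0, max] protocol).
#' @param seed integer seed for the perturbation stream.
#' @param verbose print one line per trial.
#' @return object of class `robustness_report`: per-trial warping indices,
#'   applied true transforms, estimates, success flags, success rate (%),
#'   mean and sample sd of the warping index.
#' @export
robustness_study <- function(us_map, mr_map, reference = NULL,
                             n_trials = 100L, cfg = optimizer_config(),
                             threshold = 3.5, t_max = 5, r_max = 5,
                             symmetric = FALSE, seed = NULL,
                             verbose = FALSE) {
  stopifnot_volume(us_map, "us_map")
  stopifnot_volume(mr_map, "mr_map")
  center <- volume_center(us_map)
  if (is.null(reference)) reference <- identity_transform(center)
  if (!is.null(seed)) set.seed(seed)
  n_trials <- as.integer(n_trials)
  omega <- numeric(n_trials)
  success <- logical(n_trials)
  truths <- vector("list", n_trials)
  estimates <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    pert <- random_rigid_transform(t_max, r_max, center = volume_center(mr_map),
                                   symmetric = symmetric)
    mr_pert <- resample(mr_map, pert, mr_map, fill = 0)
    # MR'(X) = MR(pert(X)); the aligning transform satisfies
    # pert o T = reference, so the composed truth is pert^-1 o reference
    truth <- transform_compose(transform_invert(pert), reference,
                               center = center)
    est <- tryCatch(
      register(us_map, mr_pert, cfg, init = reference)$transform,
      error = function(e) NULL)
    if (is.null(est)) {
      omega[i] <- Inf
      success[i] <- FALSE
      estimates[i] <- list(NULL)
    } else {
      omega[i] <- warping_index(truth, est, us_map)
      success[i] <- omega[i] < threshold
      estimates[[i]] <- est
    }
    truths[[i]] <- truth
    if (verbose)
      message(sprintf("trial %d/%d: omega = %.3f mm (%s)", i, n_trials,
                      omega[i], if (success[i]) "success" else "failure"))
  }
  ok <- is.finite(omega)
  structure(list(omega = omega,
                 true_transforms = truths,
                 estimated_transforms = estimates,
                 success = success,
                 threshold = threshold,
                 n_trials = n_trials,
                 success_rate = if (n_trials > 0) 100 * sum(success) / n_trials
                                else NA_real_,
                 mean_omega = if (any(ok)) mean(omega[ok]) else NA_real_,
                 sd_omega = if (sum(ok) > 1) stats::sd(omega[ok]) else NA_real_),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf(
    "robustness_report: %d trials, success rate %.1f%% (omega < %.2f mm), mean omega %.3f (sd %.3f) mm\n",
    x$n_trials, x$success_rate, x$threshold, x$mean_omega, x$sd_omega))
  invisible(x)
}

#' Export a robustness report as JSON (and optionally CSV)
#'
#' @param report robustness_report.
#' @param path output JSON path.
#' @param csv_path optional per-trial CSV path.
#' @return invisibly, `path`.
#' @export
write_robustness_report <- function(report, path, csv_path = NULL) {
  obj <- list(
    n_trials = report$n_trials,
    threshold_mm = report$threshold,
    success_rate_percent = report$success_rate,
    mean_omega_mm = report$mean_omega,
    sd_omega_mm = report$sd_omega,
    omega_mm = report$omega,
    success = report$success
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(csv_path)) {
    utils::write.csv(
      data.frame(trial = seq_len(report$n_trials),
                 omega_mm = report$omega, success = report$success),
      csv_path, row.names = FALSE)
  }
  invisible(path)
}
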