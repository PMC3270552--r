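#' Optimizer configuration for rigid registration
#'
#' Defaults follow the method's stated settings: simplex tolerance 0.1,
#' stepsize 1.5, at most 100 iterations per level and a two-level pyramid
#' with downsampling factors 3 then 1 (original resolution).
#'
#' The stated tolerance carries no explicit units.  Both it and the
#' stepsize are read in the simplex's parameter units (mm for
#' translations, degrees for rotations): the optimizer stops once the
#' simplex has collapsed to a parameter-space diameter below `tolerance`
#' (every vertex within 0.1 mm / 0.1 deg of the best vertex, by default).
#' This keeps the criterion independent of the objective's magnitude,
#' which varies with how sparse the probability maps are.  Setting
#' `tolerance_type = "score"` instead stops on the objective-value spread
#' across the simplex falling below `tolerance * tolerance_scale`.
#'
#' @param tolerance convergence tolerance (see Details); default 0.1.
#' @param stepsize initial simplex perturbation: mm for translations,
#'   degrees for rotations; default 1.5.
#' @param max_iterations iteration cap per pyramid level; default 100.
#' @param pyramid_factors ordered integer downsampling factors, coarse to
#'   fine; default `c(3, 1)`.
#' @param tolerance_type `"param"` (simplex diameter in mm/degrees,
#'   default) or `"score"` (objective spread).
#' @param tolerance_scale multiplier converting `tolerance` to an absolute
#'   objective spread in `"score"` mode; default 1e-3.
#' @return object of class `optimizer_config`.
#' @export
optimizer_config <- function(tolerance = 0.1, stepsize = 1.5,
                             max_iterations = 100L,
                             pyramid_factors = c(3L, 1L),
                             tolerance_type = c("param", "score"),
                             tolerance_scale = 1e-3) {
  tolerance_type <- match.arg(tolerance_type)
  if (!is.finite(tolerance) || tolerance <= 0)
    stop("optimizer_config: tolerance must be > 0")
  if (!is.finite(stepsize) || stepsize <= 0)
    stop("optimizer_config: stepsize must be > 0")
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 0L)
    stop("optimizer_config: max_iterations must be >= 0")
  pyramid_factors <- as.integer(pyramid_factors)
  if (length(pyramid_factors) < 1L || any(is.na(pyramid_factors)) ||
      any(pyramid_factors < 1L))
    stop("optimizer_config: pyramid_factors must be integers >= 1")
  structure(list(tolerance = tolerance, stepsize = stepsize,
                 max_iterations = max_iterations,
                 pyramid_factors = pyramid_factors,
                 tolerance_type = tolerance_type,
                 tolerance_scale = tolerance_scale),
            class = "optimizer_config")
}

#' Joint-probability correlation objective
#'
#' Discretization of the correlation integral between the two probability
#' maps: the mean over ultrasound-grid voxels of `p_US(X) * p_MR(T(X))`,
#' where the MR map is trilinearly interpolated at the transformed world
#' point and takes 0 outside its support (partially missing information
#' contributes no probability mass).  Using the mean rather than the sum
#' makes scores comparable across pyramid levels.
#'
#' @param us_map probability-map volume3d (fixed; defines the grid).
#' @param mr_map probability-map volume3d (moving).
#' @param transform rigid_transform mapping US world coords into MR space.
#' @return scalar score in [0, 1].
#' @export
objective <- function(us_map, mr_map, transform) {
  f <- make_objective(us_map, mr_map)
  f(transform_params(transform))
}

# Closure evaluating the objective from a packed 6-parameter vector, with
# the US grid coordinates precomputed once.
make_objective <- function(us_map, mr_map, center = volume_center(us_map)) {
  stopifnot_volume(us_map, "us_map")
  stopifnot_volume(mr_map, "mr_map")
  W <- voxel_world_coords(us_map)
  pus <- as.numeric(us_map$data)
  arr <- mr_map$data
  orig <- mr_map$origin
  sp <- mr_map$spacing
  n <- length(pus)
  function(p) {
    M <- transform_matrix(transform_from_params(p, center))
    Xm <- W %*% t(M[1:3, 1:3]) + matrix(M[1:3, 4], n, 3, byrow = TRUE)
    idx <- sweep(sweep(Xm, 2, orig, `-`), 2, sp, `/`) + 1
    sum(pus * interp_trilinear(arr, idx, fill = 0)) / n
  }
}

#' Nelder-Mead simplex maximization over 6 rigid parameters
#'
#' Standard Nelder-Mead (reflection 1, expansion 2, contraction 0.5,
#' shrink 0.5), maximizing `f` by minimizing `-f`.  The initial simplex is
#' the start point plus six vertices, each perturbing one parameter by
#' `stepsize`.  Iteration stops when the simplex has collapsed below the
#' configured tolerance (see [optimizer_config]) or the iteration cap is
#' reached; a cap of 0 returns the start point unchanged with
#' `converged = FALSE`.  Fully deterministic.
#'
#' @param f function from a length-6 numeric vector (tx,ty,tz in mm,
#'   rx,ry,rz in degrees) to a scalar score.
#' @param x0 rigid_transform start point.
#' @param cfg [optimizer_config].
#' @return list of class `registration_result` with fields `transform`,
#'   `objective_trace`, `iterations`, `converged`, `score`.
#' @export
simplex_optimize <- function(f, x0, cfg = optimizer_config()) {
  if (!inherits(x0, "rigid_transform")) stop("simplex_optimize: x0 must be rigid_transform")
  p0 <- transform_params(x0)
  trace <- numeric(0)
  feval <- function(p) {
    val <- f(p)
    if (!is.finite(val)) stop("simplex_optimize: non-finite objective value")
    trace[length(trace) + 1L] <<- val
    -val
  }
  np <- 6L
  if (cfg$max_iterations == 0L) {
    return(structure(list(transform = x0, objective_trace = f(p0),
                          iterations = 0L, converged = FALSE,
                          score = f(p0)),
                     class = "registration_result"))
  }
  verts <- matrix(rep(p0, np + 1L), nrow = np + 1L, byrow = TRUE)
  for (i in seq_len(np)) verts[i + 1L, i] <- verts[i + 1L, i] + cfg$stepsize
  fv <- apply(verts, 1, feval)
  score_mode <- identical(cfg$tolerance_type, "score")
  tol <- if (score_mode) cfg$tolerance * cfg$tolerance_scale else cfg$tolerance
  iter <- 0L
  converged <- FALSE
  while (iter < cfg$max_iterations) {
    ord <- order(fv)
    verts <- verts[ord, , drop = FALSE]
    fv <- fv[ord]
    spread <- if (score_mode) max(fv) - min(fv)
              else max(abs(sweep(verts, 2, verts[1, ])))
    if (spread < tol) { converged <- TRUE; break }
    iter <- iter + 1L
    centroid <- colMeans(verts[seq_len(np), , drop = FALSE])
    xr <- centroid + (centroid - verts[np + 1L, ])
    fr <- feval(xr)
    if (fr < fv[1]) {
      xe <- centroid + 2 * (centroid - verts[np + 1L, ])
      fe <- feval(xe)
      if (fe < fr) { verts[np + 1L, ] <- xe; fv[np + 1L] <- fe }
      else { verts[np + 1L, ] <- xr; fv[np + 1L] <- fr }
    } else if (fr < fv[np]) {
      verts[np + 1L, ] <- xr; fv[np + 1L] <- fr
    } else {
      if (fr < fv[np + 1L]) {
        xc <- centroid + 0.5 * (xr - centroid)          # outside contraction
      } else {
        xc <- centroid - 0.5 * (centroid - verts[np + 1L, ])  # inside
      }
      fc <- feval(xc)
      if (fc < min(fr, fv[np + 1L])) {
        verts[np + 1L, ] <- xc; fv[np + 1L] <- fc
      } else {
        for (i in 2:(np + 1L)) {
          verts[i, ] <- verts[1, ] + 0.5 * (verts[i, ] - verts[1, ])
          fv[i] <- feval(verts[i, ])
        }
      }
    }
  }
  best <- which.min(fv)
  structure(list(transform = transform_from_params(verts[best, ], x0$center),
                 objective_trace = trace,
                 iterations = iter,
                 converged = converged,
                 score = -fv[best]),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: score %.6g after %d iterations (%s)\n",
              x$score, x$iterations,
              if (x$converged) "converged" else "iteration cap"))
  print(x$transform)
  invisible(x)
}

#' Multiresolution rigid registration of two probability maps
#'
#' For each pyramid factor in order (coarse to fine) both maps are
#' downsampled and the simplex optimizer is run, starting from `init` at
#' the coarsest level and from the previous level's result thereafter.
#' Factor 1 runs at the original resolution.  The transform maps US world
#' coordinates into MR space; its rotation centre is the physical centre
#' of the US map.
#'
#' @param us_map probability-map volume3d (fixed).
#' @param mr_map probability-map volume3d (moving).
#' @param cfg [optimizer_config].
#' @param init rigid_transform initialization (default identity about the
#'   US volume centre).
#' @return `registration_result` with per-level summaries in
#'   `level_results`.
#' @export
register <- function(us_map, mr_map, cfg = optimizer_config(), init = NULL) {
  stopifnot_volume(us_map, "us_map")
  stopifnot_volume(mr_map, "mr_map")
  center <- volume_center(us_map)
  if (is.null(init)) init <- identity_transform(center)
  if (length(cfg$pyramid_factors) == 0L) stop("register: empty pyramid")
  current <- rigid_transform(init$translation, init$rotation, center)
  levels <- list()
  trace <- numeric(0)
  for (k in seq_along(cfg$pyramid_factors)) {
    f <- cfg$pyramid_factors[k]
    us_l <- if (f == 1L) us_map else downsample(us_map, f)
    mr_l <- if (f == 1L) mr_map else downsample(mr_map, f)
    obj <- make_objective(us_l, mr_l, center)
    res <- simplex_optimize(obj, current, cfg)
    current <- res$transform
    trace <- c(trace, res$objective_trace)
    levels[[k]] <- list(factor = f, iterations = res$iterations,
                        score = res$score, converged = res$converged)
  }
  structure(list(transform = current,
                 objective_trace = trace,
                 level_results = levels,
                 converged = levels[[length(levels)]]$converged,
                 score = levels[[length(levels)]]$score),
            class = "registration_result")
}
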