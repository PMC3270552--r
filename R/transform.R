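#' Construct a 6-parameter rigid transform
#'
#' Parameterized by 3 translations (mm) and 3 Euler rotation angles
#' (degrees) about a stated centre of rotation (world mm).  A point X maps
#' to `R (X - c) + c + t` where `R = Rx Ry Rz` (intrinsic rotations applied
#' in z, then y, then x order to a column vector).  Any fixed convention
#' suffices for rigid recovery; this one keeps rotation/translation
#' coupling small when the centre is the volume centre.
#'
#' @param translation length-3 numeric, mm.
#' @param rotation length-3 numeric, degrees (about x, y, z).
#' @param center length-3 numeric, world mm; rotation centre.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  translation <- as.numeric(translation)
  rotation <- as.numeric(rotation)
  center <- as.numeric(center)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("rigid_transform: translation must be 3 finite values (mm)")
  if (length(rotation) != 3L || any(!is.finite(rotation)))
    stop("rigid_transform: rotation must be 3 finite values (degrees)")
  if (length(center) != 3L || any(!is.finite(center)))
    stop("rigid_transform: center must be 3 finite values (mm)")
  structure(list(translation = translation, rotation = rotation,
                 center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: t = (%s) mm, r = (%s) deg, center (%s) mm\n",
              paste(signif(x$translation, 5), collapse = ", "),
              paste(signif(x$rotation, 5), collapse = ", "),
              paste(signif(x$center, 5), collapse = ", ")))
  invisible(x)
}

#' Identity rigid transform
#' @param center rotation centre (mm).
#' @return rigid_transform.
#' @export
identity_transform <- function(center = c(0, 0, 0)) {
  rigid_transform(c(0, 0, 0), c(0, 0, 0), center)
}

rot3 <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

# Euler angles (deg) from a rotation matrix under the Rx Ry Rz convention.
# Unique for the middle angle in (-90, 90); at the gimbal singularity the
# x/z split is fixed by setting the z angle to 0.
euler_from_rot <- function(R) {
  sy <- max(-1, min(1, R[1, 3]))
  ry <- asin(sy)
  if (abs(abs(sy) - 1) > 1e-12) {
    rx <- atan2(-R[2, 3], R[3, 3])
    rz <- atan2(-R[1, 2], R[1, 1])
  } else {
    rx <- atan2(R[2, 1], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' 4x4 homogeneous matrix of a rigid transform
#' @param t rigid_transform.
#' @return 4x4 numeric matrix mapping homogeneous world coordinates.
#' @export
transform_matrix <- function(t) {
  if (!inherits(t, "rigid_transform")) stop("not a rigid_transform")
  R <- rot3(t$rotation)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t$center + t$translation - R %*% t$center
  M
}

#' Build a rigid transform from a 4x4 homogeneous matrix
#'
#' The rotation part must be a proper rotation (orthonormal, determinant
#' +1).  Euler angles are re-extracted under the package convention about
#' the requested centre.
#'
#' @param M 4x4 homogeneous matrix.
#' @param center rotation centre (mm) for the parameterization.
#' @return rigid_transform.
#' @export
transform_from_matrix <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6 || det(R) < 0)
    stop("transform_from_matrix: not a proper rigid matrix")
  rot <- euler_from_rot(R)
  tr <- M[1:3, 4] - center + as.numeric(R %*% center)
  rigid_transform(tr, rot, center)
}

#' Apply a rigid transform to world points
#' @param t rigid_transform.
#' @param X N x 3 matrix (or length-3 vector) of world points, mm.
#' @return transformed points, same shape.
#' @export
transform_points <- function(t, X) {
  M <- transform_matrix(t)
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, 1, 3)
  Y <- X %*% t(M[1:3, 1:3]) + matrix(M[1:3, 4], nrow(X), 3, byrow = TRUE)
  if (vec) as.numeric(Y) else Y
}

#' Compose two rigid transforms: (a o b)(X) = a(b(X))
#' @param a,b rigid_transform.
#' @param center rotation centre for the composed parameterization
#'   (defaults to a's centre).
#' @return rigid_transform.
#' @export
transform_compose <- function(a, b, center = a$center) {
  transform_from_matrix(transform_matrix(a) %*% transform_matrix(b), center)
}

#' Invert a rigid transform
#' @param t rigid_transform.
#' @return rigid_transform with the same centre.
#' @export
transform_invert <- function(t) {
  M <- transform_matrix(t)
  Ri <- t(M[1:3, 1:3])
  Mi <- diag(4)
  Mi[1:3, 1:3] <- Ri
  Mi[1:3, 4] <- -Ri %*% M[1:3, 4]
  transform_from_matrix(Mi, t$center)
}

#' Pack rigid parameters as a length-6 vector (tx,ty,tz,rx,ry,rz)
#' @keywords internal
transform_params <- function(t) c(t$translation, t$rotation)

#' @keywords internal
transform_from_params <- function(p, center) {
  rigid_transform(p[1:3], p[4:6], center)
}

#' Serialize a rigid transform to JSON
#'
#' Writes parameters, the 4x4 matrix and a conventions block.
#'
#' @param t rigid_transform.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_transform_json <- function(t, path) {
  obj <- list(
    translation_mm = t$translation,
    rotation_deg = t$rotation,
    center_mm = t$center,
    matrix = transform_matrix(t),
    conventions = list(
      rotation_order = "Rx*Ry*Rz (column vectors)",
      units = "mm / degrees",
      mapping = "X -> R (X - center) + center + translation"
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a rigid transform from its JSON serialization
#' @param path file written by [write_transform_json].
#' @return rigid_transform.
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(obj$translation_mm, obj$rotation_deg, obj$center_mm)
}
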