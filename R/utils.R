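`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

## distances from one point to each row of a coordinate matrix
point_dists <- function(xyz, p) {
  d <- xyz - matrix(p, nrow(xyz), 3, byrow = TRUE)
  sqrt(rowSums(d * d))
}

#' Rotation matrix about an axis
#'
#' Builds the 3x3 proper rotation matrix for a right-handed rotation of
#' `angle_deg` degrees about `axis` (Rodrigues formula).
#'
#' @param axis numeric length-3 direction (need not be unit length).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid transform constructor
#'
#' A rigid transform `x' = R x + t` with a proper rotation `R`.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t numeric length-3 translation in Angstrom.
#' @return an object of class `xlwalk_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("R is not a proper rotation matrix")
  structure(list(R = R, t = as.numeric(t)), class = "xlwalk_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix (or a length-3 vector).
#' @param tf an `xlwalk_transform`.
#' @return transformed coordinates, same shape as the input.
#' @export
apply_transform <- function(xyz, tf) {
  if (is.null(dim(xyz))) return(as.numeric(tf$R %*% xyz + tf$t))
  t(tf$R %*% t(xyz) + tf$t)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`.
#'
#' @param a,b `xlwalk_transform` objects.
#' @return an `xlwalk_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#'
#' @param tf an `xlwalk_transform`.
#' @return the inverse `xlwalk_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

#' @export
print.xlwalk_transform <- function(x, ...) {
  cat("Rigid transform (x' = R x + t)\n")
  cat("  rotation angle:", format(rotation_angle(x$R), digits = 6), "deg\n")
  cat("  translation:  ", paste(format(x$t, digits = 6), collapse = " "), "\n")
  invisible(x)
}

## rotation angle (deg) of a rotation matrix, robust near 0 and 180
rotation_angle <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  180 / pi * acos(min(1, max(-1, c_)))
}

## deterministic quasi-uniform points on the unit sphere (golden spiral);
## used by the Shrake-Rupley SASA sampler
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## small random rotation: uniform axis, N(0, sigma_deg) angle
random_rotation <- function(sigma_deg) {
  ax <- stats::rnorm(3)
  while (vec_norm(ax) < 1e-8) ax <- stats::rnorm(3)
  rotation_matrix(ax, stats::rnorm(1, 0, sigma_deg))
}

## lexicographic comparison of (protein, residue) endpoints
endpoint_leq <- function(p1, r1, p2, r2) {
  p1 < p2 | (p1 == p2 & r1 <= r2)
}
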