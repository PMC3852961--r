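## The 3-parameter rigid pose: rotation about x, rotation about y (degrees),
## translation along z (A). Applied as p' = R_y %*% R_x %*% p + (0,0,dz),
## right-handed rotations.

#' Construct a rigid membrane pose
#'
#' @param rot_x,rot_y Rotations about the x and y axes, degrees
#'   (reduced to \[0, 360)).
#' @param dz Translation along z, Angstrom.
#' @return Object of class `mem_transform`.
#' @export
transform_pose <- function(rot_x = 0, rot_y = 0, dz = 0) {
  stopifnot(is.finite(rot_x), is.finite(rot_y), is.finite(dz))
  structure(list(rot_x = rot_x %% 360, rot_y = rot_y %% 360, dz = dz),
            class = "mem_transform")
}

#' @export
print.mem_transform <- function(x, ...) {
  cat(sprintf("<mem_transform rot_x=%.3f deg rot_y=%.3f deg dz=%.3f A>\n",
              x$rot_x, x$rot_y, x$dz))
  invisible(x)
}

.rotation_matrix <- function(t) {
  a <- t$rot_x * pi / 180
  b <- t$rot_y * pi / 180
  rx <- matrix(c(1, 0, 0,
                 0, cos(a), -sin(a),
                 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b),
                 0, 1, 0,
                 -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  ry %*% rx
}

#' Apply a pose to a set of points
#'
#' @param points Numeric n x 3 matrix (or length-3 vector) of coordinates.
#' @param t A `mem_transform`.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(points, t) {
  stopifnot(inherits(t, "mem_transform"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  out <- points %*% t(.rotation_matrix(t))
  out[, 3] <- out[, 3] + t$dz
  dimnames(out) <- NULL
  out
}

#' Draw a random pose
#'
#' Rotations uniform on \[0, 360) degrees; dz uniform on `dz_bounds`.
#' Reproducible when `seed` is supplied.
#'
#' @param dz_bounds Length-2 numeric, translation bounds in Angstrom.
#' @param seed Optional integer seed.
#' @return A `mem_transform`.
#' @export
random_pose <- function(dz_bounds = c(-50, 50), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  transform_pose(runif(1, 0, 360), runif(1, 0, 360),
                 runif(1, dz_bounds[1], dz_bounds[2]))
}
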