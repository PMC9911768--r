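# Internal helpers shared across modules.

#' @noRd
stop_bv <- function(...) stop(..., call. = FALSE)

#' Stack an N x 3 vertex matrix into a 3N coordinate vector (x1,y1,z1,x2,...)
#' @noRd
stack_vertices <- function(v) as.numeric(t(v))

#' Inverse of [stack_vertices()]
#' @noRd
unstack_vertices <- function(x) matrix(x, ncol = 3L, byrow = TRUE)

#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Apply a rigid transform v %*% t(R) + t to an N x 3 matrix
#' @noRd
apply_rigid <- function(v, rotation, translation) {
  sweep(v %*% t(rotation), 2L, translation, "+")
}

#' Random rotation matrix (uniform axis, bounded angle in degrees)
#' @noRd
random_rotation <- function(max_angle_deg) {
  ax <- stats::rnorm(3L)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1L, -max_angle_deg, max_angle_deg) * pi / 180
  rotation_about_axis(ax, ang)
}

#' Rodrigues rotation about a unit axis by angle (radians)
#' @noRd
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3L], axis[2L],
                axis[3L], 0, -axis[1L],
                -axis[2L], axis[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Polyline arc length of an N x 3 coordinate matrix
#' @noRd
polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

#' Z-normalize a numeric vector (sample SD); errors on constant input
#' @noRd
znorm <- function(x, what = "variable") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop_bv("cannot z-normalize constant ", what)
  (x - mean(x)) / s
}
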