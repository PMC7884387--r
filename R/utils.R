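#' @keywords internal
#' @importFrom stats qt qnorm rnorm runif rlnorm sd prcomp lm pf pchisq
#' @importFrom utils read.csv write.csv head tail
#' @importFrom grDevices chull
"_PACKAGE"

# internal helpers shared across modules

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_finite <- function(x, what) {
  stop_if(!all(is.finite(x)), what, " must be finite")
  invisible(x)
}

# squared L2 norm of a vector
sq_norm <- function(v) sum(v * v)

unit <- function(v) {
  n <- sqrt(sq_norm(v))
  stop_if(n == 0, "cannot normalize a zero vector")
  v / n
}

# angle in radians between two direction vectors, sign-insensitive
axis_angle <- function(a, b) {
  ca <- abs(sum(unit(a) * unit(b)))
  acos(min(1, ca))
}

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all landmarks from their
#' centroid; the standard size measure in geometric morphometrics.
#'
#' @param coords numeric K x 3 matrix of landmark coordinates (mm).
#' @return centroid size, in the units of `coords`.
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  ctr <- colMeans(coords)
  sqrt(sum(sweep(coords, 2, ctr)^2))
}
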