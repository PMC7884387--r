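# --- curve resampling and Procrustes superimposition -------------------

#' Resample a curve to equally spaced semilandmarks
#'
#' Places `k` points equally spaced by arc length along an ordered 3D
#' polyline, preserving both endpoints. This is how digitized outline
#' curves are converted to comparable semilandmark sets; no sliding
#' (bending-energy or otherwise) is applied.
#'
#' @param polyline ordered m x 3 matrix of points (m >= 2, not all
#'   coincident).
#' @param k number of output points (>= 2).
#' @return k x 3 matrix of resampled points.
#' @export
resample_curve <- function(polyline, k) {
  polyline <- as.matrix(polyline)
  stop_if(ncol(polyline) != 3L, "polyline must be m x 3")
  stop_if(nrow(polyline) < 2L, "polyline needs at least 2 points")
  stop_if(k < 2L, "k must be at least 2")
  check_finite(polyline, "polyline")
  seg <- sqrt(rowSums(diff(polyline)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  stop_if(total == 0, "zero-length polyline")
  targets <- seq(0, total, length.out = k)
  out <- vapply(targets, function(t) {
    i <- findInterval(t, arc, rightmost.closed = TRUE)
    i <- min(i, nrow(polyline) - 1L)
    w <- if (seg[i] == 0) 0 else (t - arc[i]) / seg[i]
    (1 - w) * polyline[i, ] + w * polyline[i + 1L, ]
  }, numeric(3))
  t(out)
}

# rotation taking a centered configuration to its principal-axis frame,
# with deterministic axis signs and determinant +1
canonical_rotation <- function(coords) {
  v <- svd(coords)$v
  pr <- coords %*% v
  for (j in 1:3) {
    i <- which.max(abs(pr[, j]))
    if (pr[i, j] < 0) v[, j] <- -v[, j]
  }
  if (det(v) < 0) v[, 3] <- -v[, 3]
  v
}

# optimal rotation of X onto Y (both centered), reflections disallowed
kabsch_rotation <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# center and scale a configuration to unit centroid size
center_unit <- function(coords) {
  ctr <- sweep(coords, 2, colMeans(coords))
  cs <- sqrt(sum(ctr^2))
  stop_if(cs == 0, "degenerate configuration: all landmarks coincide")
  list(coords = ctr / cs, size = cs)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of landmark configurations: each is centered,
#' scaled to unit centroid size and rotated to the current consensus
#' (reflections disallowed); the consensus is recomputed until it changes
#' by less than `tol`. Centroid sizes are taken from the configurations
#' before scaling.
#'
#' @param configs list of [landmark_set]s sharing landmark count and curve
#'   structure, or a K x 3 x n array.
#' @param tol convergence tolerance on the consensus update (default
#'   1e-10).
#' @param max_iter iteration cap.
#' @return object of class `aligned_shapes`: list with
#'   `coords` (K x 3 x n aligned array), `centroid_sizes` (mm),
#'   `consensus` (K x 3, centroid at origin, unit size),
#'   `residuals` (n x 3K matrix of flattened deviations from consensus),
#'   `specimen_ids`, `curves`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 200L) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    arr <- configs
    ids <- dimnames(arr)[[3]] %||% paste0("specimen_", seq_len(dim(arr)[3]))
    curves <- list(all = seq_len(dim(arr)[1]))
  } else {
    stop_if(!is.list(configs) || length(configs) == 0,
            "configs must be a non-empty list of landmark_set objects")
    check_same_structure(configs)
    k <- n_landmarks(configs[[1]])
    arr <- array(NA_real_, dim = c(k, 3, length(configs)))
    for (i in seq_along(configs)) arr[, , i] <- configs[[i]]$coords
    ids <- vapply(configs, `[[`, character(1), "specimen_id")
    curves <- configs[[1]]$curves
  }
  n <- dim(arr)[3]
  k <- dim(arr)[1]
  sizes <- numeric(n)
  aligned <- array(NA_real_, dim = dim(arr))
  for (i in seq_len(n)) {
    cu <- center_unit(arr[, , i])
    aligned[, , i] <- cu$coords
    sizes[i] <- cu$size
  }
  consensus <- aligned[, , 1]
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n))
      aligned[, , i] <- aligned[, , i] %*% kabsch_rotation(aligned[, , i],
                                                           consensus)
    new_cons <- center_unit(apply(aligned, c(1, 2), mean))$coords
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) break
  }
  # canonical orientation: the GPA solution is defined only up to a global
  # rotation, so rotate everything to the consensus's principal axes (sign
  # fixed by the largest-magnitude coordinate, determinant kept at +1)
  rot <- canonical_rotation(consensus)
  consensus <- consensus %*% rot
  for (i in seq_len(n)) aligned[, , i] <- aligned[, , i] %*% rot
  res <- t(vapply(seq_len(n), function(i)
    as.vector(aligned[, , i] - consensus), numeric(3 * k)))
  structure(list(coords = aligned, centroid_sizes = sizes,
                 consensus = consensus, residuals = res,
                 specimen_ids = ids, curves = curves),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat("<aligned_shapes> ", dim(x$coords)[3], " specimens x ",
      dim(x$coords)[1], " landmarks (Procrustes-aligned)\n", sep = "")
  invisible(x)
}

#' Ordinary Procrustes alignment of one configuration to a consensus
#'
#' Centers the configuration, scales it to unit centroid size and rotates
#' it onto the consensus (no reflection). This is how an unknown specimen
#' is brought into the shape space of a trained sample before a-posteriori
#' projection.
#'
#' @param coords K x 3 matrix, or a [landmark_set].
#' @param consensus K x 3 consensus from [gpa()].
#' @return list with `coords` (aligned K x 3), `centroid_size` (mm) and
#'   `residual` (flattened deviation from the consensus, length 3K).
#' @export
opa_to_consensus <- function(coords, consensus) {
  if (inherits(coords, "landmark_set")) coords <- coords$coords
  coords <- as.matrix(coords)
  stop_if(!all(dim(coords) == dim(consensus)),
          "landmark count mismatch with the training consensus")
  cu <- center_unit(coords)
  rot <- kabsch_rotation(cu$coords, consensus)
  al <- cu$coords %*% rot
  list(coords = al, centroid_size = cu$size,
       residual = as.vector(al - consensus))
}

# full Procrustes distance between two configurations
procrustes_distance <- function(a, b) {
  fa <- opa_to_consensus(a, center_unit(if (inherits(b, "landmark_set"))
    b$coords else b)$coords)
  sqrt(sum((fa$coords - center_unit(if (inherits(b, "landmark_set"))
    b$coords else b)$coords)^2))
}
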