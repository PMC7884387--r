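#' Plane in signed-distance form
#'
#' A plane n . x = d with unit normal n; `d` is the signed distance of the
#' plane from the origin along the normal, in mm.
#'
#' @param normal 3-vector; normalized internally.
#' @param offset signed distance d, mm.
#' @return object of class `plane`.
#' @export
plane <- function(normal, offset) {
  normal <- unit(as.numeric(normal))
  stop_if(!is.finite(offset), "plane offset must be finite")
  structure(list(normal = normal, offset = as.numeric(offset)),
            class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane> n = (%.4f, %.4f, %.4f), d = %.4f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

#' Total-least-squares plane fit
#'
#' Fits the plane minimizing the sum of squared orthogonal distances to a
#' point cloud (SVD of the centered points; the normal is the singular
#' vector of the smallest singular value). Used to place the cervical
#' best-fit plane through points digitized around the tooth cervix.
#'
#' @param points numeric m x 3 matrix (m >= 3), mm.
#' @param orient optional 3-vector; the returned normal is flipped, if
#'   necessary, to have a positive component along it (e.g. the occlusal
#'   direction). Default `c(0, 0, 1)`.
#' @return a [plane].
#' @export
fit_plane <- function(points, orient = c(0, 0, 1)) {
  points <- as.matrix(points)
  stop_if(ncol(points) != 3L, "points must be m x 3")
  stop_if(nrow(points) < 3L, "at least 3 points are required")
  check_finite(points, "plane points")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))
  # collinear or coincident points leave the plane underdetermined
  stop_if(sv$d[2] < 1e-12 * max(sv$d[1], 1),
          "degenerate (collinear or coincident) points: plane undefined")
  n <- sv$v[, 3]
  if (sum(n * orient) < 0) n <- -n
  plane(n, sum(n * ctr))
}

#' Half-maximum-height segmentation threshold
#'
#' The midpoint between the characteristic grayscale intensities of two
#' materials, the standard threshold for segmenting CT data at a material
#' interface.
#'
#' @param mu_low,mu_high mean intensities of the darker and brighter
#'   material (`mu_low <= mu_high`).
#' @return threshold intensity `(mu_low + mu_high) / 2`.
#' @export
hmh_threshold <- function(mu_low, mu_high) {
  stop_if(!is.finite(mu_low) || !is.finite(mu_high),
          "intensities must be finite")
  stop_if(mu_low > mu_high, "mu_low must not exceed mu_high")
  (mu_low + mu_high) / 2
}

# iterate a function over z-slices of signed voxel-center distances from a
# plane, keeping memory at one slice: fn(k, s_slice) with s_slice nx x ny
walk_plane_slices <- function(vol, p, fn) {
  d <- dim(vol$labels)
  cx <- voxel_centers(d[1], vol$voxel_size)
  cy <- voxel_centers(d[2], vol$voxel_size)
  cz <- voxel_centers(d[3], vol$voxel_size)
  s_xy <- outer(cx * p$normal[1], cy * p$normal[2], `+`) - p$offset
  for (k in seq_len(d[3])) fn(k, s_xy + cz[k] * p$normal[3])
  invisible(NULL)
}

check_parallel <- function(lower, upper, tol = 1e-6) {
  ang <- axis_angle(lower$normal, upper$normal)
  stop_if(ang > tol, "planes are not parallel (angle ", signif(ang, 3),
          " rad)")
  # express both on the same oriented normal
  if (sum(lower$normal * upper$normal) < 0)
    upper <- plane(-upper$normal, -upper$offset)
  stop_if(upper$offset < lower$offset,
          "lower plane must lie below upper plane along the shared normal")
  upper
}

#' Crop a volume between two parallel planes
#'
#' Retains voxels whose centers lie in the half-open slab
#' (lower, upper]: strictly above the lower plane, and on or below the
#' upper plane (ties on a plane go to the lower side). This half-open rule
#' makes consecutive crops partition the volume exactly, voxel by voxel.
#' The input volume is not modified.
#'
#' @param vol a [labeled_volume].
#' @param lower,upper parallel [plane]s (angular tolerance 1e-6 rad).
#' @return a [labeled_volume] with voxels outside the slab set to
#'   background.
#' @export
crop_between_planes <- function(vol, lower, upper) {
  upper <- check_parallel(lower, upper)
  width <- upper$offset - lower$offset
  d <- dim(vol$labels)
  cx <- voxel_centers(d[1], vol$voxel_size)
  cy <- voxel_centers(d[2], vol$voxel_size)
  cz <- voxel_centers(d[3], vol$voxel_size)
  s_xy <- outer(cx * lower$normal[1], cy * lower$normal[2], `+`) -
    lower$offset
  labels <- vol$labels
  for (k in seq_len(d[3])) {
    s <- s_xy + cz[k] * lower$normal[3]
    sl <- labels[, , k]
    sl[!(s > 0 & s <= width)] <- 0L
    labels[, , k] <- sl
  }
  labeled_volume(labels, vol$voxel_size)
}

# --- EDJ surface area estimation ---------------------------------------

# separable box smoothing of a 3D numeric array (odd window w)
box_smooth3 <- function(a, w = 5L) {
  smooth_dim <- function(a, dim) {
    d <- dim(a)
    perm <- switch(dim, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    b <- aperm(a, perm)
    m <- dim(b)[1]
    mat <- matrix(b, nrow = m)
    # padded cumulative sum -> running mean along columns
    half <- (w - 1L) %/% 2L
    padded <- rbind(mat[rep(1L, half), , drop = FALSE], mat,
                    mat[rep(m, half), , drop = FALSE])
    cs <- apply(padded, 2, cumsum)
    run <- (cs[(w):(m + w - 1L), , drop = FALSE] -
              rbind(0, cs[seq_len(m - 1L), , drop = FALSE])) / w
    out <- array(run, dim = dim(b))
    aperm(out, order(perm))
  }
  for (dm in 1:3) a <- smooth_dim(a, dm)
  a
}

# area of the interface between voxels of mask_a and mask_b (logical 3D
# arrays). method "gradient": each boundary face weighted by |n . e| with n
# the smoothed-gradient normal of mask_a (converges to the true area for
# smooth surfaces). method "face_count": raw face count x correction.
interface_area <- function(mask_a, mask_b, voxel_size,
                           method = c("gradient", "face_count"),
                           face_correction = 2 / 3, smooth_window = 5L) {
  method <- match.arg(method)
  d <- dim(mask_a)
  if (method == "gradient") {
    u <- box_smooth3(array(as.numeric(mask_a), dim = d), w = smooth_window)
    gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
    gx[2:(d[1] - 1), , ] <- (u[3:d[1], , ] - u[1:(d[1] - 2), , ]) / 2
    gy[, 2:(d[2] - 1), ] <- (u[, 3:d[2], ] - u[, 1:(d[2] - 2), ]) / 2
    gz[, , 2:(d[3] - 1)] <- (u[, , 3:d[3]] - u[, , 1:(d[3] - 2)]) / 2
    gn <- sqrt(gx^2 + gy^2 + gz^2)
    gn[gn == 0] <- 1
  }
  total <- 0
  face_pairs <- function(axis) {
    # logical arrays of A|B adjacency along +axis; returns summed weights
    idx1 <- switch(axis,
      `1` = list(1:(d[1] - 1), 1:d[2], 1:d[3]),
      `2` = list(1:d[1], 1:(d[2] - 1), 1:d[3]),
      `3` = list(1:d[1], 1:d[2], 1:(d[3] - 1)))
    idx2 <- switch(axis,
      `1` = list(2:d[1], 1:d[2], 1:d[3]),
      `2` = list(1:d[1], 2:d[2], 1:d[3]),
      `3` = list(1:d[1], 1:d[2], 2:d[3]))
    a1 <- do.call(`[`, c(list(mask_a), idx1, drop = FALSE))
    b2 <- do.call(`[`, c(list(mask_b), idx2, drop = FALSE))
    a2 <- do.call(`[`, c(list(mask_a), idx2, drop = FALSE))
    b1 <- do.call(`[`, c(list(mask_b), idx1, drop = FALSE))
    hit <- (a1 & b2) | (a2 & b1)
    if (method == "face_count") return(sum(hit))
    g_ax <- switch(axis, `1` = gx, `2` = gy, `3` = gz)
    w1 <- abs(do.call(`[`, c(list(g_ax), idx1, drop = FALSE)) /
                do.call(`[`, c(list(gn), idx1, drop = FALSE)))
    w2 <- abs(do.call(`[`, c(list(g_ax), idx2, drop = FALSE)) /
                do.call(`[`, c(list(gn), idx2, drop = FALSE)))
    sum(((w1 + w2) / 2)[hit])
  }
  for (ax in 1:3) total <- total + face_pairs(ax)
  if (method == "face_count") total <- total * face_correction
  total * voxel_size^2
}

#' Lateral crown tissue proportions
#'
#' Computes, on a lateral (non-occlusal) crown volume already cropped
#' between the cervical plane and the plane of the last occlusal-basin
#' enamel, the lateral average enamel thickness and its scale-free
#' relative version:
#' \deqn{LAET = V_{enamel} / S_{EDJ}, \qquad
#'       LRET = 100 \cdot LAET / V_{dentine+pulp}^{1/3}}
#' where \eqn{S_{EDJ}} is the area of the enamel-dentine interface. LAET
#' is in mm; LRET is dimensionless. The EDJ area is estimated from the
#' voxel interface by gradient-weighted face counting (default) or plain
#' face counting with a correction factor; see Details.
#'
#' @details Plain face counting overestimates the area of an oblique or
#' curved surface (up to a factor sqrt(3)); the classical fixed correction
#' of 2/3 compensates on average over orientations. The default
#' `"gradient"` method instead weights each boundary face by the local
#' surface-normal direction estimated from a box-smoothed mask gradient,
#' which is exact for planar interfaces and accurate to ~1-2% on smooth
#' curved ones.
#'
#' @param vol_lateral a [labeled_volume] restricted to the lateral crown.
#' @param area_method `"gradient"` (default) or `"face_count"`.
#' @param face_correction correction factor for `"face_count"`.
#' @return list with `laet_3d` (mm), `lret_3d` (dimensionless),
#'   `v_enamel_lateral`, `v_dentine_pulp_lateral` (mm^3) and
#'   `s_edj_lateral` (mm^2).
#' @export
lateral_tissue_proportions <- function(vol_lateral,
                                       area_method = c("gradient",
                                                       "face_count"),
                                       face_correction = 2 / 3) {
  area_method <- match.arg(area_method)
  enamel <- vol_lateral$labels == 1L
  dentine <- vol_lateral$labels == 2L
  dp <- dentine | vol_lateral$labels == 3L
  stop_if(!any(enamel), "volume contains no enamel")
  stop_if(!any(dentine), "volume contains no dentine")
  vs <- vol_lateral$voxel_size
  v_en <- sum(enamel) * vs^3
  v_dp <- sum(dp) * vs^3
  s_edj <- interface_area(enamel, dentine, vs, method = area_method,
                          face_correction = face_correction)
  stop_if(s_edj <= 0, "zero enamel-dentine interface: EDJ surface undefined")
  laet <- v_en / s_edj
  list(laet_3d = laet, lret_3d = 100 * laet / v_dp^(1 / 3),
       v_enamel_lateral = v_en, v_dentine_pulp_lateral = v_dp,
       s_edj_lateral = s_edj)
}

#' Split the root at the bifurcation plane
#'
#' Divides the root tissue below the cervical plane into the stem volume
#' above the bifurcation (Vcervix) and the branch volume below it
#' (Vbranch), using a plane parallel to the cervical plane placed
#' `bifurcation_level` mm apically of it. The voxel-center half-open rule
#' makes `v_cervix + v_branch` equal the total root tissue volume exactly.
#'
#' @param vol a [labeled_volume] of the whole tooth.
#' @param cervical the cervical best-fit [plane]; its normal points
#'   occlusally, so root tissue lies at negative signed distance.
#' @param bifurcation_level distance (mm, >= 0) from the cervical plane to
#'   the interradicular surface, measured apically; `NULL` to locate it
#'   automatically with [find_bifurcation_level()].
#' @param tissue_labels labels counted as root tissue (default dentine and
#'   pulp, `c(2, 3)`).
#' @return list with `v_cervix` and `v_branch`, mm^3.
#' @export
split_root <- function(vol, cervical, bifurcation_level = NULL,
                       tissue_labels = c(2L, 3L)) {
  if (is.null(bifurcation_level))
    bifurcation_level <- find_bifurcation_level(vol, cervical,
                                                tissue_labels = tissue_labels)
  stop_if(!is.finite(bifurcation_level) || bifurcation_level < 0,
          "bifurcation_level must be a nonnegative distance (mm)")
  n_stem <- 0; n_branch <- 0; deepest <- -Inf
  labels <- vol$labels
  walk_plane_slices(vol, cervical, function(k, s) {
    tissue <- matrix(labels[, , k] %in% tissue_labels, nrow(s))
    below <- tissue & (s <= 0)
    if (!any(below)) return(invisible(NULL))
    deepest <<- max(deepest, -min(s[below]))
    # stem: (cervical - level, cervical]; branches below, ties stem-ward
    n_stem <<- n_stem + sum(below & (s > -bifurcation_level))
    n_branch <<- n_branch + sum(below & (s <= -bifurcation_level))
    invisible(NULL)
  })
  stop_if(!is.finite(deepest), "no root tissue below the cervical plane")
  # physical root extent reaches half a voxel beyond the deepest center
  apex_depth <- deepest + vol$voxel_size / 2
  stop_if(bifurcation_level > apex_depth,
          "bifurcation plane lies beyond the root apex (root depth ",
          signif(apex_depth, 4), " mm)")
  vs3 <- vol$voxel_size^3
  list(v_cervix = n_stem * vs3, v_branch = n_branch * vs3)
}

#' Locate the bifurcation level automatically
#'
#' Scans voxel slabs parallel to the cervical plane from the cervix toward
#' the apex and returns the depth (mm) of the most occlusal slab at which
#' the root cross-section splits into two or more connected components
#' (the interradicular surface). Requires the cervical normal to be
#' aligned with a grid axis; otherwise supply the level explicitly.
#'
#' @inheritParams split_root
#' @return depth below the cervical plane, mm.
#' @export
find_bifurcation_level <- function(vol, cervical, tissue_labels = c(2L, 3L)) {
  ax <- which(abs(abs(cervical$normal) - 1) < 1e-9)
  stop_if(length(ax) != 1L,
          "automatic bifurcation detection needs an axis-aligned cervical ",
          "plane; supply bifurcation_level explicitly")
  s_sign <- sign(cervical$normal[ax])
  d <- dim(vol$labels)
  centers <- voxel_centers(d[ax], vol$voxel_size)
  depth <- cervical$offset * s_sign - centers * s_sign  # >0 below cervix
  root_idx <- which(depth > 0)
  root_idx <- root_idx[order(depth[root_idx])]          # cervix -> apex
  slab <- function(i) {
    m <- switch(ax, `1` = vol$labels[i, , ], `2` = vol$labels[, i, ],
                `3` = vol$labels[, , i])
    matrix(m %in% tissue_labels, nrow = dim(vol$labels)[-ax][1])
  }
  for (i in root_idx) {
    m <- slab(i)
    if (!any(m)) next
    ncomp <- max(EBImage::bwlabel(EBImage::Image(m)))
    if (ncomp >= 2) return(depth[i])
  }
  stop("no bifurcation found: root cross-section never splits into ",
       ">= 2 connected components", call. = FALSE)
}

#' Volumetric bifurcation index
#'
#' Percentage of the total root volume held in the undivided stem above
#' the bifurcation: `VBI = 100 * v_cervix / (v_cervix + v_branch)`.
#' Larger values indicate a longer common stem, i.e. a greater degree of
#' taurodontism.
#'
#' @param v_cervix stem volume above the bifurcation, mm^3.
#' @param v_branch branch volume below the bifurcation, mm^3.
#' @return VBI, percent (in [0, 100]).
#' @examples
#' vbi(502.6, 234.2)  # 68.2
#' @export
vbi <- function(v_cervix, v_branch) {
  stop_if(!is.finite(v_cervix) || !is.finite(v_branch) ||
            v_cervix < 0 || v_branch < 0, "volumes must be nonnegative")
  stop_if(v_cervix + v_branch <= 0, "total root volume must be positive")
  100 * v_cervix / (v_cervix + v_branch)
}
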