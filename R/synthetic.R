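# --- synthetic generators -----------------------------------------------
# Every generator is a pure function of its parameters + seed, and every
# ground-truth quantity it returns is a closed form computed at
# construction, never measured from the generated object.

# run expr with a local RNG seeded at `seed`, restoring global state
with_seed <- function(seed, expr) {
  stop_if(!is.numeric(seed) || length(seed) != 1 || !is.finite(seed),
          "seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Synthetic EDJ marginal-outline template
#'
#' A closed 3D rim with five peaks (mimicking the dentine horns around a
#' lower molar's occlusal basin), sampled as five semilandmark curves.
#' Per-curve point counts default to 24, 23, 23, 23, 23 (116 points in
#' total); only the total is anchored in published protocols, the split
#' is a recorded free choice.
#'
#' @param curve_counts integer vector of per-curve point counts.
#' @param radius rim radius, mm.
#' @param horn_height dentine-horn peak height, mm.
#' @return a [landmark_set].
#' @export
edj_template <- function(curve_counts = c(24L, 23L, 23L, 23L, 23L),
                         radius = 5, horn_height = 1.5) {
  k <- sum(curve_counts)
  theta <- 2 * pi * (seq_len(k) - 1) / k
  r <- radius * (1 + 0.08 * cos(5 * theta))
  z <- horn_height * (0.5 + 0.5 * cos(5 * theta))^2
  coords <- cbind(r * cos(theta), r * sin(theta), z)
  ends <- cumsum(curve_counts)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  curves <- lapply(seq_along(curve_counts), function(i) starts[i]:ends[i])
  names(curves) <- paste0("curve", seq_along(curve_counts))
  landmark_set(coords, specimen_id = "template", curves = curves)
}

# basis of similarity-transform directions (translation x3, rotation x3,
# scaling x1) at a configuration; columns orthonormal
similarity_basis <- function(coords) {
  k <- nrow(coords)
  ctr <- sweep(coords, 2, colMeans(coords))
  cols <- list(
    c(rep(1, k), rep(0, 2 * k)),
    c(rep(0, k), rep(1, k), rep(0, k)),
    c(rep(0, 2 * k), rep(1, k)),
    as.vector(ctr))
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    rot <- t(apply(ctr, 1, function(p) c(ax[2] * p[3] - ax[3] * p[2],
                                         ax[3] * p[1] - ax[1] * p[3],
                                         ax[1] * p[2] - ax[2] * p[1])))
    cols[[length(cols) + 1]] <- as.vector(rot)
  }
  qr.Q(qr(do.call(cbind, cols)))
}

# project a flattened deformation vector into shape space (remove any
# translation/rotation/scale component) and set its norm to `magnitude`
orthogonalize_effect <- function(v, coords, magnitude = NULL) {
  q <- similarity_basis(coords)
  v <- v - q %*% crossprod(q, v)
  if (!is.null(magnitude)) v <- unit(as.numeric(v)) * magnitude
  as.numeric(v)
}

# circular running-mean smoothing of a flattened 3K vector, per coordinate
smooth_deformation <- function(v, k, window = 9L) {
  half <- (window - 1L) %/% 2L
  sm <- function(x) {
    n <- length(x)
    xx <- c(utils::tail(x, half), x, utils::head(x, half))
    stats::filter(xx, rep(1 / window, window))[(half + 1):(half + n)]
  }
  as.numeric(c(sm(v[1:k]), sm(v[(k + 1):(2 * k)]),
               sm(v[(2 * k + 1):(3 * k)])))
}

random_rotation3 <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Simulate grouped landmark samples
#'
#' Generates `n_per_group` specimens per group as
#' template + group deformation + allometric term + i.i.d. Gaussian
#' coordinate noise, each then given a random rotation, translation and
#' size. Group deformations are smooth random directions in shape space
#' (orthogonalized against translation, rotation and scaling), so the
#' injected between-group differences are pure shape effects of known
#' magnitude. Defaults emulate three comparative hominin groups with a
#' group shape offset ten times the landmark noise.
#'
#' @param groups character vector of group names (default three groups).
#' @param n_per_group specimens per group (>= 1; recycled).
#' @param effect_magnitude norm of each group's deformation vector, mm
#'   (default 0.1).
#' @param noise_sd per-coordinate Gaussian landmark noise SD, mm
#'   (default 0.01, i.e. effect 10x noise).
#' @param allometry_slope shape displacement (mm per unit log centroid
#'   size) along a fixed direction; 0 disables allometry.
#' @param template a [landmark_set] (default [edj_template()]).
#' @param size_sdlog log-SD of the lognormal centroid-size distribution.
#' @param seed integer seed; the sample is a pure function of the
#'   arguments and this seed.
#' @return list with `configs` (list of [landmark_set]), `labels`,
#'   `centroid_sizes`, and `truth` (template, per-group deformation
#'   vectors, allometry direction).
#' @export
simulate_shape_groups <- function(groups = c("NEA", "PMH", "HMH"),
                                  n_per_group = 20L,
                                  effect_magnitude = 0.1,
                                  noise_sd = 0.01,
                                  allometry_slope = 0,
                                  template = edj_template(),
                                  size_sdlog = 0.05,
                                  seed = 20210215) {
  stop_if(any(n_per_group < 1L), "n_per_group must be >= 1")
  stop_if(noise_sd < 0, "noise_sd must be nonnegative")
  n_per_group <- rep(as.integer(n_per_group), length.out = length(groups))
  k <- n_landmarks(template)
  with_seed(seed, {
    effects <- lapply(groups, function(g) {
      v <- smooth_deformation(stats::rnorm(3 * k), k)
      orthogonalize_effect(v, template$coords,
                           magnitude = effect_magnitude)
    })
    names(effects) <- groups
    allo_dir <- orthogonalize_effect(
      smooth_deformation(stats::rnorm(3 * k), k), template$coords,
      magnitude = 1)
    cs0 <- centroid_size(template$coords)
    configs <- list(); labels <- character(0); sizes <- numeric(0)
    for (gi in seq_along(groups)) {
      for (j in seq_len(n_per_group[gi])) {
        cs <- cs0 * stats::rlnorm(1, 0, size_sdlog)
        shape <- template$coords +
          matrix(effects[[gi]], k, 3) +
          allometry_slope * (log(cs) - log(cs0)) * matrix(allo_dir, k, 3) +
          matrix(stats::rnorm(3 * k, sd = noise_sd), k, 3)
        shape <- shape * (cs / centroid_size(shape))
        shape <- shape %*% random_rotation3() +
          matrix(stats::runif(3, -10, 10), k, 3, byrow = TRUE)
        id <- sprintf("%s_%02d", groups[gi], j)
        configs[[id]] <- landmark_set(shape, specimen_id = id,
                                      curves = template$curves)
        labels <- c(labels, groups[gi])
        sizes <- c(sizes, cs)
      }
    }
    list(configs = configs, labels = labels, centroid_sizes = sizes,
         truth = list(template = template, effects = effects,
                      allometry_direction = allo_dir,
                      noise_sd = noise_sd,
                      effect_magnitude = effect_magnitude))
  })
}

# --- voxel phantoms ------------------------------------------------------

#' Concentric cylindrical-shell crown phantom
#'
#' A vertical dentine cylinder of radius `inner_radius` wrapped in an
#' enamel shell out to `outer_radius`, of height `height` — the minimal
#' geometry with closed-form lateral tissue proportions:
#' LAET = (Ro^2 - Ri^2) / (2 Ri).
#'
#' @param outer_radius,inner_radius enamel outer and EDJ radius, mm.
#' @param height cylinder height, mm.
#' @param pulp_radius optional inner pulp cylinder radius, mm.
#' @param voxel_size isotropic voxel size, mm.
#' @return list with `volume` (a [labeled_volume]) and `truth`
#'   (closed-form `v_enamel`, `v_dentine_pulp`, `s_edj`, `laet_3d`,
#'   `lret_3d`).
#' @export
phantom_shell <- function(outer_radius = 5, inner_radius = 4, height = 4,
                          pulp_radius = NULL, voxel_size = 0.05) {
  stop_if(inner_radius <= 0 || outer_radius <= inner_radius,
          "need 0 < inner_radius < outer_radius")
  thinnest <- min(outer_radius - inner_radius,
                  if (is.null(pulp_radius)) Inf else pulp_radius)
  stop_if(voxel_size > thinnest / 3,
          "feature under-resolved: need voxel_size <= ",
          signif(thinnest / 3, 3), " mm")
  pad <- 2 * voxel_size
  half <- outer_radius + pad
  nx <- ceiling(2 * half / voxel_size)
  nz <- ceiling((height + 2 * pad) / voxel_size)
  cx <- voxel_centers(nx, voxel_size) - half
  cz <- voxel_centers(nz, voxel_size) - pad
  r2 <- outer(cx^2, cx^2, `+`)
  labels <- array(0L, dim = c(nx, nx, nz))
  in_z <- cz > 0 & cz <= height
  ring <- array(0L, dim = c(nx, nx))
  ring[r2 <= outer_radius^2] <- 1L
  ring[r2 <= inner_radius^2] <- 2L
  if (!is.null(pulp_radius)) ring[r2 <= pulp_radius^2] <- 3L
  for (kk in which(in_z)) labels[, , kk] <- ring
  v_en <- pi * (outer_radius^2 - inner_radius^2) * height
  v_dp <- pi * inner_radius^2 * height
  s_edj <- 2 * pi * inner_radius * height
  laet <- v_en / s_edj
  list(volume = labeled_volume(labels, voxel_size),
       truth = list(v_enamel = v_en, v_dentine_pulp = v_dp, s_edj = s_edj,
                    laet_3d = laet, lret_3d = 100 * laet / v_dp^(1 / 3)))
}

#' Voxelized tooth phantom with known compartment volumes
#'
#' Constructive-solid-geometry tooth: a hemispherical dentine crown core
#' with an enamel cap, a pulp cylinder, a root stem cylinder below the
#' cervical plane, and `n_branches` branch cylinders below the
#' bifurcation. All compartment volumes (and the true VBI) are exact
#' closed forms computed at construction. The cervical plane is returned
#' so the volume can be fed straight into [split_root()] and [vbi()].
#'
#' @param crown_radius dentine crown core radius, mm.
#' @param enamel_thickness enamel cap thickness, mm.
#' @param pulp_radius pulp cylinder radius, mm (inside crown and stem).
#' @param pulp_height pulp extent above the cervical plane, mm.
#' @param pulp_depth pulp extent below the cervical plane, mm (within the
#'   stem).
#' @param stem_radius,stem_height root stem cylinder, mm.
#' @param n_branches number of root branches below the bifurcation.
#' @param branch_radius,branch_height branch cylinders, mm.
#' @param branch_offset radial distance of branch axes from the tooth
#'   axis, mm (default: touching, `branch_radius / sin(pi/n)` apart).
#' @param voxel_size isotropic voxel size, mm.
#' @return list with `volume`, `cervical_plane`, `bifurcation_level`
#'   (mm below the cervical plane) and `truth` (closed-form volumes and
#'   `vbi`).
#' @export
simulate_tooth_phantom <- function(crown_radius = 5, enamel_thickness = 1,
                                   pulp_radius = 1.5, pulp_height = 2,
                                   pulp_depth = 2,
                                   stem_radius = 4, stem_height = 6,
                                   n_branches = 2L, branch_radius = 1.8,
                                   branch_height = 6,
                                   branch_offset = NULL,
                                   voxel_size = 0.05) {
  stop_if(pulp_radius >= crown_radius, "pulp must fit inside the crown")
  stop_if(pulp_height > sqrt(crown_radius^2 - pulp_radius^2),
          "pulp cylinder must fit inside the hemispherical crown core")
  stop_if(pulp_depth > stem_height, "pulp_depth must not exceed the stem")
  stop_if(n_branches < 1L, "need at least one branch")
  if (is.null(branch_offset))
    branch_offset <- if (n_branches == 1L) 0 else
      branch_radius / sin(pi / n_branches) + voxel_size
  thinnest <- min(enamel_thickness, pulp_radius, branch_radius)
  stop_if(voxel_size > thinnest / 3,
          "feature under-resolved: need voxel_size <= ",
          signif(thinnest / 3, 3), " mm")
  rmax <- max(crown_radius + enamel_thickness, stem_radius,
              branch_offset + branch_radius)
  pad <- 2 * voxel_size
  half <- rmax + pad
  z_below <- stem_height + branch_height + pad
  z_above <- crown_radius + enamel_thickness + pad
  nx <- ceiling(2 * half / voxel_size)
  nz <- ceiling((z_below + z_above) / voxel_size)
  cx <- voxel_centers(nx, voxel_size) - half
  cz <- voxel_centers(nz, voxel_size) - z_below  # cervical plane at z = 0
  labels <- array(0L, dim = c(nx, nx, nz))
  r2 <- outer(cx^2, cx^2, `+`)
  ang <- 2 * pi * (seq_len(n_branches) - 1) / n_branches
  bx <- branch_offset * cos(ang); by <- branch_offset * sin(ang)
  for (kk in seq_len(nz)) {
    z <- cz[kk]
    sl <- matrix(0L, nx, nx)
    if (z > 0) {                       # crown: hemisphere + enamel cap
      r3 <- r2 + z^2
      sl[r3 <= (crown_radius + enamel_thickness)^2] <- 1L
      sl[r3 <= crown_radius^2] <- 2L
      if (z <= pulp_height) sl[r2 <= pulp_radius^2 & sl == 2L] <- 3L
    } else if (z > -stem_height) {     # root stem
      sl[r2 <= stem_radius^2] <- 2L
      if (z > -pulp_depth) sl[r2 <= pulp_radius^2] <- 3L
    } else if (z > -(stem_height + branch_height)) {  # branches
      for (bb in seq_len(n_branches)) {
        d2 <- outer((cx - bx[bb])^2, (cx - by[bb])^2, `+`)
        sl[d2 <= branch_radius^2] <- 2L
      }
    }
    labels[, , kk] <- sl
  }
  truth <- list(
    v_enamel_crown = 2 * pi / 3 *
      ((crown_radius + enamel_thickness)^3 - crown_radius^3),
    v_dentine_crown = 2 * pi / 3 * crown_radius^3 -
      pi * pulp_radius^2 * pulp_height,
    v_pulp = pi * pulp_radius^2 * (pulp_height + pulp_depth),
    v_cervix = pi * stem_radius^2 * stem_height,
    v_branch = n_branches * pi * branch_radius^2 * branch_height)
  truth$vbi <- 100 * truth$v_cervix / (truth$v_cervix + truth$v_branch)
  list(volume = labeled_volume(labels, voxel_size),
       cervical_plane = plane(c(0, 0, 1), z_below),
       bifurcation_level = stem_height,
       truth = truth)
}

# --- lithic and dental-statistics generators ----------------------------

default_class_means <- function() {
  list(
    "Levallois point" = c(length = 55, proximal_width = 28,
                          medial_width = 32, distal_width = 18,
                          medial_thickness = 8, distal_thickness = 5,
                          platform_width = 20, platform_thickness = 8,
                          platform_angle = 75),
    "Nubian point" = c(length = 62, proximal_width = 30, medial_width = 28,
                       distal_width = 14, medial_thickness = 9,
                       distal_thickness = 5.5, platform_width = 18,
                       platform_thickness = 7, platform_angle = 80))
}

#' Simulate a lithic attribute table
#'
#' Lognormal metric draws around per-class means with a common
#' coefficient of variation (positive support matches callipered
#' artefact dimensions). With `noise_cv = 0` every artefact sits exactly
#' at its class means.
#'
#' @param n_per_class artefacts per class (recycled over classes).
#' @param class_means named list: class -> named vector of positive
#'   metric means (mm / degrees); default two Levallois point classes.
#' @param noise_cv coefficient of variation of the lognormal noise
#'   (>= 0; default 0.15).
#' @param assemblage assemblage label attached to every row.
#' @param seed integer seed.
#' @return data frame of metric columns plus `assemblage` and `class`.
#' @export
simulate_lithic_assemblages <- function(n_per_class = 30L,
                                        class_means = default_class_means(),
                                        noise_cv = 0.15,
                                        assemblage = "synthetic",
                                        seed = 20210215) {
  stop_if(noise_cv < 0, "noise_cv must be nonnegative")
  stop_if(any(unlist(class_means) <= 0), "class means must be positive")
  n_per_class <- rep(as.integer(n_per_class),
                     length.out = length(class_means))
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    rows <- lapply(seq_along(class_means), function(ci) {
      mu <- class_means[[ci]]
      n <- n_per_class[ci]
      draws <- vapply(mu, function(m)
        stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog),
        numeric(n))
      draws <- matrix(draws, nrow = n,
                      dimnames = list(NULL, names(mu)))
      data.frame(draws, assemblage = assemblage,
                 class = names(class_means)[ci], check.names = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a comparative sample and its summary statistics
#'
#' Normal draws plus the (mean, sample SD, n) summary actually computed
#' from them — the raw ingredient of adjusted-Z coverage experiments.
#'
#' @param mean,sd population mean and SD (sd >= 0).
#' @param n sample size (>= 2).
#' @param group,variable labels for the returned summary.
#' @param seed integer seed.
#' @return list with `draws` and `stats` (a [comparative_stats] row whose
#'   mean/sd are recomputed from the draws).
#' @export
simulate_comparative_sample <- function(mean, sd, n, group = "synthetic",
                                        variable = "var", seed = 20210215) {
  stop_if(sd < 0, "sd must be nonnegative")
  stop_if(!is.finite(n) || n < 2, "n must be >= 2")
  with_seed(seed, {
    draws <- stats::rnorm(n, mean, sd)
    list(draws = draws,
         stats = comparative_stats(group, variable, base::mean(draws),
                                   stats::sd(draws), n))
  })
}
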