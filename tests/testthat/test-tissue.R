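test_that("HMH threshold is the material-intensity midpoint", {
  expect_equal(hmh_threshold(0, 100), 50)
  expect_equal(hmh_threshold(42, 42), 42)
  expect_error(hmh_threshold(100, 0), "mu_low")
  # two-material volume: thresholding at HMH misclassifies < 1% of voxels
  set.seed(11)
  truth <- stats::runif(2e5) < 0.5
  intens <- ifelse(truth, 170, 30) + stats::rnorm(2e5, sd = 10)
  thr <- hmh_threshold(30, 170)
  expect_lt(mean((intens > thr) != truth), 0.01)
})

test_that("total-least-squares plane fit recovers known planes", {
  pts <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), rep(2.5, 4))
  p <- fit_plane(pts)
  expect_equal(p$normal, c(0, 0, 1))
  expect_equal(p$offset, 2.5)
  # exact fit on x + y + z = 3
  pts2 <- rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3), c(1, 1, 1))
  p2 <- fit_plane(pts2)
  expect_equal(p2$normal, rep(1 / sqrt(3), 3), tolerance = 1e-9)
  expect_equal(p2$offset, sqrt(3), tolerance = 1e-9)
  # noisy plane: normal within 1 degree of truth
  set.seed(4)
  base <- cbind(stats::runif(200, -3, 3), stats::runif(200, -3, 3), 0)
  p3 <- fit_plane(base + cbind(0, 0, stats::rnorm(200, sd = 0.01)))
  expect_lt(acos(min(1, abs(p3$normal[3]))) * 180 / pi, 1)
  expect_error(fit_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))), "degenerate")
})

test_that("plane cropping follows the half-open voxel-center rule", {
  ph <- phantom_shell(2, 1.5, 2, voxel_size = 0.1)
  vol <- ph$volume
  nz <- dim(vol$labels)[3] * vol$voxel_size
  # planes beyond the grid on both sides: identity crop
  same <- crop_between_planes(vol, plane(c(0, 0, 1), -1),
                              plane(c(0, 0, 1), nz + 1))
  expect_identical(same$labels, vol$labels)
  # coincident planes: empty volume
  empty <- crop_between_planes(vol, plane(c(0, 0, 1), 1),
                               plane(c(0, 0, 1), 1))
  expect_equal(sum(empty$labels != 0), 0)
  expect_error(crop_between_planes(vol, plane(c(0, 0, 1), 0),
                                   plane(c(0, 1, 0), 1)), "parallel")

  # unit cube cut at z = 0.25 / 0.75 keeps half the volume
  cube <- labeled_volume(array(2L, dim = c(20, 20, 20)), 0.05)
  slab <- crop_between_planes(cube, plane(c(0, 0, 1), 0.25),
                              plane(c(0, 0, 1), 0.75))
  slab_volume <- sum(slab$labels == 2L) * 0.05^3
  expect_equal(slab_volume, 0.5, tolerance = 0.11)  # +- one voxel layer
})

test_that("consecutive crops conserve voxel counts exactly", {
  ph <- simulate_tooth_phantom(voxel_size = 0.12)
  vol <- ph$volume
  n <- ph$cervical_plane$normal
  lo <- plane(n, 2.05); mid <- plane(n, 7.33); hi <- plane(n, 13.6)
  count <- function(v) sum(v$labels != 0L)
  expect_identical(
    count(crop_between_planes(vol, lo, mid)) +
      count(crop_between_planes(vol, mid, hi)),
    count(crop_between_planes(vol, lo, hi)))
})

test_that("lateral tissue proportions recover the analytic shell values", {
  ph <- phantom_shell(outer_radius = 2.5, inner_radius = 2, height = 2,
                      voxel_size = 0.04)
  tp <- lateral_tissue_proportions(ph$volume)
  expect_equal(tp$v_enamel_lateral, ph$truth$v_enamel, tolerance = 0.02)
  expect_equal(tp$v_dentine_pulp_lateral, ph$truth$v_dentine_pulp,
               tolerance = 0.02)
  expect_equal(tp$laet_3d, ph$truth$laet_3d, tolerance = 0.05)
  # doubling all linear dimensions doubles LAET, leaves LRET unchanged
  ph2 <- phantom_shell(outer_radius = 5, inner_radius = 4, height = 4,
                       voxel_size = 0.08)
  tp2 <- lateral_tissue_proportions(ph2$volume)
  expect_equal(tp2$laet_3d / tp$laet_3d, 2, tolerance = 0.02)
  expect_equal(tp2$lret_3d, tp$lret_3d, tolerance = 0.02)
  # enamel-free volume errors
  bare <- labeled_volume(array(2L, dim = c(5, 5, 5)), 0.1)
  expect_error(lateral_tissue_proportions(bare), "enamel")
})

test_that("root splitting is exact at the extremes and on phantoms", {
  ph <- simulate_tooth_phantom(stem_height = 6, branch_height = 6,
                               voxel_size = 0.06)
  vol <- ph$volume; cerv <- ph$cervical_plane
  sr <- split_root(vol, cerv, ph$bifurcation_level)
  expect_equal(sr$v_cervix, ph$truth$v_cervix, tolerance = 0.02)
  expect_equal(sr$v_branch, ph$truth$v_branch, tolerance = 0.02)
  # conservation: cervix + branch voxel counts sum to the total, exactly
  s_all <- split_root(vol, cerv, 0.01)
  vs3 <- vol$voxel_size^3
  expect_identical(round((sr$v_cervix + sr$v_branch) / vs3),
                   round((s_all$v_cervix + s_all$v_branch) / vs3))
  # plane at the cervix: empty stem; plane at the apex: empty branches
  expect_equal(split_root(vol, cerv, 0)$v_cervix, 0)
  apex <- split_root(vol, cerv, 11.99)  # just beyond the deepest tissue
  expect_equal(apex$v_branch, 0)
  expect_error(split_root(vol, cerv, 50), "apex")
  # automatic bifurcation detection lands on the built-in level
  lvl <- find_bifurcation_level(vol, cerv)
  expect_equal(lvl, ph$bifurcation_level, tolerance = 0.1)
})

test_that("VBI follows its definition and is scale invariant", {
  expect_equal(vbi(502.6, 234.2), 68.2, tolerance = 0.05 / 68.2)
  expect_equal(vbi(7, 7), 50)
  expect_equal(vbi(3.2, 0), 100)
  for (c_ in c(0.1, 2, 40))
    expect_equal(vbi(502.6 * c_, 234.2 * c_), vbi(502.6, 234.2))
  expect_error(vbi(0, 0), "positive")
  expect_error(vbi(-1, 5), "nonnegative")
})
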