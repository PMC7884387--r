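test_that("lithic indices follow their printed formulas", {
  tab <- data.frame(length = 60, proximal_width = 25, medial_width = 30,
                    distal_width = 20, medial_thickness = 10,
                    distal_thickness = 5)
  idx <- compute_indices(tab)
  expect_equal(idx$elongation, 2.0)
  expect_equal(idx$proximal_shape, 25 / 30)
  expect_equal(idx$distal_shape, 1.5)
  expect_equal(idx$flattening, 3.0)
  expect_equal(idx$tcsa, 100)
  expect_equal(compute_indices(tab, tcsa_half = TRUE)$tcsa_half, 50)
  # equal widths give unit shape ratios
  eq <- compute_indices(data.frame(proximal_width = 22, medial_width = 22,
                                   distal_width = 22))
  expect_equal(eq$proximal_shape, 1.0)
  expect_equal(eq$distal_shape, 1.0)
})

test_that("broken artefacts produce NA indices with warnings, not errors", {
  tab <- data.frame(length = c(60, 55), medial_width = c(0, 28),
                    distal_width = c(20, NA), distal_thickness = c(5, 6))
  warns <- capture_warnings(idx <- compute_indices(tab))
  expect_match(warns, "nonpositive", all = FALSE)
  expect_match(warns, "elongation", all = FALSE)
  expect_true(is.na(idx$elongation[1]))
  expect_equal(idx$elongation[2], 55 / 28)
  expect_true(is.na(idx$tcsa[2]))  # missing input propagates
})

test_that("shape indices are scale-free and TCSA scales as c^2", {
  set.seed(19)
  tab <- simulate_lithic_assemblages(n_per_class = 15, seed = 19)
  idx <- compute_indices(tab)
  for (c_ in c(0.4, 3)) {
    scaled <- tab
    mcols <- intersect(paleoattrib:::LITHIC_METRIC_COLS, names(tab))
    scaled[mcols] <- scaled[mcols] * c_
    idx2 <- compute_indices(scaled)
    for (nm in c("elongation", "proximal_shape", "distal_shape",
                 "flattening"))
      expect_equal(idx2[[nm]], idx[[nm]], tolerance = 1e-12)
    expect_equal(idx2$tcsa, idx$tcsa * c_^2, tolerance = 1e-12)
  }
})

test_that("ordered-quantile normalization gaussianizes and keeps ranks", {
  set.seed(23)
  ln <- stats::rlnorm(200, 0, 0.8)
  f <- ordernorm_fit(ln)
  y <- ordernorm_apply(f, ln)
  expect_lt(abs(sample_skewness(y)), 0.2)
  expect_identical(rank(y), rank(ln))  # strictly monotone
  # an already-normal column stays close to N(0,1)
  z <- stats::rnorm(300)
  yz <- ordernorm_apply(ordernorm_fit(z), z)
  ks_before <- stats::ks.test(z, "pnorm")$statistic
  ks_after <- stats::ks.test(yz, "pnorm")$statistic
  expect_lt(ks_after, ks_before + 0.05)
  # held-out values interpolate monotonically
  new_x <- sort(stats::runif(50, min(ln), max(ln)))
  expect_true(all(diff(ordernorm_apply(f, new_x)) >= 0))
  expect_error(ordernorm_fit(rep(3, 10)), "constant")
})

test_that("normalize_table standardizes columns and drops constants", {
  tab <- simulate_lithic_assemblages(n_per_class = 25, seed = 5)
  tab$flat_col <- 1
  expect_warning(norm <- normalize_table(tab, columns = c("length",
    "medial_width", "flat_col")), "flat_col")
  expect_null(norm$flat_col)
  expect_equal(mean(norm$length), 0, tolerance = 1e-12)
  expect_equal(stats::sd(norm$length), 1, tolerance = 1e-12)
  expect_identical(rank(norm$length), rank(tab$length))
})

test_that("attribute PCA handles correlation, duplication, missingness", {
  set.seed(31)
  a <- stats::rnorm(40)
  tab <- data.frame(u = a, v = 2 * a + 3)
  pc <- pca_table(tab, columns = c("u", "v"))
  expect_equal(pc$explained[1], 1, tolerance = 1e-9)
  # duplicated dataset: identical scores for the copies
  tab2 <- data.frame(u = c(a, a), v = c(2 * a + 3, 2 * a + 3))
  pc2 <- pca_table(tab2, columns = c("u", "v"))
  expect_equal(pc2$scores[1:40, ], pc2$scores[41:80, ])
  # row-order permutation leaves per-row scores unchanged
  perm <- sample(40)
  pc3 <- pca_table(tab[perm, ], columns = c("u", "v"))
  flip <- sign(sum(pc3$axes[, 1] * pc$axes[, 1]))
  expect_equal(unname(pc3$scores[, 1] * flip),
               unname(pc$scores[perm, 1]), tolerance = 1e-9)
  # complete-case policy with a count of exclusions
  tab$u[1:3] <- NA
  pc4 <- pca_table(tab, columns = c("u", "v"))
  expect_equal(pc4$n_excluded, 3)
  expect_error(pca_table(data.frame(u = c(1, 2, NA), v = c(1, NA, 2)),
                         c("u", "v")), "complete rows")
})

test_that("convex-hull overlap summarizes score-plane geometry", {
  set.seed(37)
  cloud <- matrix(stats::rnorm(60), 30, 2)
  ov <- assemblage_overlap(rbind(cloud, cloud),
                           rep(c("a", "b"), each = 30))
  expect_equal(ov$overlap_fraction, c(1, 1), tolerance = 1e-9)
  expect_equal(ov$centroid_distance, c(0, 0))
  # disjoint clusters far apart: zero overlap
  far <- rbind(cloud, cloud + 40)
  ov2 <- assemblage_overlap(far, rep(c("a", "b"), each = 30))
  expect_equal(ov2$overlap_fraction, c(0, 0))
  expect_false(any(ov2$falls_within))
  # nested clusters: the focal falls inside the reference hull
  nest <- rbind(cloud * 0.1, cloud * 3)
  ov3 <- assemblage_overlap(nest, rep(c("inner", "outer"), each = 30))
  inner_row <- ov3[ov3$focal == "inner", ]
  expect_true(inner_row$falls_within)
  expect_false(ov3[ov3$focal == "outer", ]$falls_within)
  # labels with < 3 points report NA overlap
  ov4 <- assemblage_overlap(rbind(cloud, c(0, 0)),
                            c(rep("a", 30), "tiny"))
  expect_true(all(is.na(ov4$overlap_fraction)))
})

test_that("ordination separation grows with the injected class offset", {
  seps <- vapply(c(0, 0.15, 0.35, 0.6), function(off) {
    means <- list(A = c(length = 50, medial_width = 28,
                        distal_width = 16, distal_thickness = 5),
                  B = c(length = 50 * (1 + off), medial_width = 28,
                        distal_width = 16 * (1 + off),
                        distal_thickness = 5))
    tab <- simulate_lithic_assemblages(n_per_class = 40,
                                       class_means = means,
                                       noise_cv = 0.1, seed = 77)
    idx <- compute_indices(tab)
    cols <- c("elongation", "distal_shape", "tcsa")
    norm <- normalize_table(idx, columns = cols)
    pc <- pca_table(norm, columns = cols)
    sc <- pc$scores[, 1]
    cls <- pc$score_table$class
    abs(mean(sc[cls == "A"]) - mean(sc[cls == "B"])) /
      stats::sd(c(sc[cls == "A"] - mean(sc[cls == "A"]),
                  sc[cls == "B"] - mean(sc[cls == "B"])))
  }, numeric(1))
  expect_true(all(diff(seps) > 0))
})
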