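test_that("arc-length curve resampling is exact on known geometries", {
  seg <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(resample_curve(seg, 3),
               rbind(c(0, 0, 0), c(0.5, 0, 0), c(1, 0, 0)))
  # resampling an equispaced polyline to the same k is the identity
  line <- cbind(seq(0, 2, length.out = 7), 0, seq(0, 1, length.out = 7))
  expect_equal(resample_curve(line, 7), line, tolerance = 1e-12)
  # quarter circle: adjacent chords equal by arc-length parameterization
  th <- seq(0, pi / 2, length.out = 2001)
  qc <- cbind(cos(th), sin(th), 0)
  rs <- resample_curve(qc, 5)
  chords <- sqrt(rowSums(diff(rs)^2))
  expect_lt(max(chords) - min(chords), 1e-6)
  expect_equal(rs[1, ], qc[1, ]); expect_equal(rs[5, ], qc[2001, ])
  expect_error(resample_curve(rbind(c(1, 1, 1), c(1, 1, 1)), 3),
               "zero-length")
})

test_that("GPA removes similarity transforms exactly", {
  tpl <- edj_template()
  # a single configuration aligns to itself, centered and unit-size
  one <- gpa(list(tpl))
  expect_equal(colMeans(one$consensus), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(centroid_size(one$coords[, , 1]), 1, tolerance = 1e-12)
  # two copies differing by a similarity transform: zero Procrustes distance
  set.seed(21)
  moved <- landmark_set(apply_rigid(tpl$coords, scale = 2.7),
                        "moved", curves = tpl$curves)
  al <- gpa(list(tpl, moved))
  expect_lt(sqrt(sum((al$coords[, , 1] - al$coords[, , 2])^2)), 1e-9)
  expect_equal(al$centroid_sizes[2] / al$centroid_sizes[1], 2.7,
               tolerance = 1e-9)
  expect_error(gpa(list(landmark_set(matrix(1, 4, 3) +
    matrix(0, 4, 3), "flat"))), "coincide")
})

test_that("GPA residuals are invariant under rigid motions of the input", {
  sim <- simulate_shape_groups(n_per_group = 6, groups = c("A", "B"),
                               seed = 33)
  al1 <- gpa(sim$configs)
  set.seed(5)
  moved <- lapply(sim$configs, function(s)
    landmark_set(apply_rigid(s$coords, scale = stats::runif(1, 0.5, 2)),
                 s$specimen_id, curves = s$curves))
  al2 <- gpa(moved)
  expect_lt(max(abs(al1$residuals - al2$residuals)), 1e-8)
})

test_that("shape PCA reproduces a hand-computed eigenstructure", {
  u1 <- c(1, 1) / sqrt(2); u2 <- c(1, -1) / sqrt(2)
  # four points whose sample covariance is exactly [[2,1],[1,2]]
  x <- rbind(sqrt(4.5) * u1, -sqrt(4.5) * u1, sqrt(1.5) * u2,
             -sqrt(1.5) * u2)
  expect_equal(stats::cov(x), matrix(c(2, 1, 1, 2), 2), tolerance = 1e-12)
  pc <- shape_pca(x)
  ev <- pc$explained * sum((sweep(x, 2, colMeans(x)))^2) / (nrow(x) - 1)
  expect_equal(ev, c(3, 1), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(abs(sum(pc$axes[, 1] * u1)), 1, tolerance = 1e-9)
  expect_equal(abs(sum(pc$axes[, 2] * u2)), 1, tolerance = 1e-9)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-9)
  # residuals on one direction: first axis explains everything
  r1 <- outer(stats::rnorm(8), c(1, 2, 3))
  expect_equal(shape_pca(r1)$explained[1], 1, tolerance = 1e-9)
  # full reconstruction from all axes
  sim <- simulate_shape_groups(n_per_group = 4, groups = c("A", "B"),
                               seed = 2)
  al <- gpa(sim$configs)
  pca <- shape_pca(al)
  rec <- sweep(pca$scores %*% t(pca$axes), 2, -pca$center)
  expect_lt(max(abs(rec - al$residuals)), 1e-9)
})

test_that("select_pcs returns the smallest count reaching the target", {
  expect_equal(select_pcs(c(0.5, 0.3, 0.1, 0.1), 0.9), 3)
  expect_equal(select_pcs(c(0.5, 0.3, 0.1, 0.1), 1.0), 4)
  expect_equal(select_pcs(1.0), 1)
  expect_error(select_pcs(numeric(0)), "empty")
  expect_error(select_pcs(c(0.1, 0.5)), "descending")
})

test_that("bgPCA axes and scores behave as the group-means PCA", {
  set.seed(9)
  d <- two_group_scores(25, 20, offset = 25)  # noise sd 1 << offset
  bg <- bgpca(d$x, d$labels)
  expect_equal(ncol(bg$axes), 1)  # g - 1 informative axes
  # first axis within 5 degrees of the true offset direction
  truth <- c(1, rep(0, 19))
  ang <- acos(min(1, abs(sum(bg$axes[, 1] * truth))))
  expect_lt(ang * 180 / pi, 5)
  # scores of the group means equal the PCA-of-means scores exactly
  means <- rbind(colMeans(d$x[1:25, ]), colMeans(d$x[26:50, ]))
  pm <- stats::prcomp(means, center = TRUE)
  expect_equal(abs(as.numeric(bg$group_scores)),
               abs(as.numeric(pm$x[, 1])), tolerance = 1e-9)
  # identical group means: all group-mean scores collapse at the origin
  x0 <- rbind(d$x[1:25, ], d$x[1:25, ])
  bg0 <- bgpca(x0, d$labels)
  expect_lt(max(abs(bg0$group_scores)), 1e-9)
  expect_error(bgpca(d$x, rep("A", 50)), "2 groups")
})

test_that("Mahalanobis classification yields calibrated posteriors", {
  set.seed(14)
  d <- two_group_scores(25, 4, offset = 10)  # 10x the within-group sd
  bg <- bgpca(d$x, d$labels)
  cls <- classify_scores(bg$scores, d$labels, bg$scores)
  expect_equal(unname(cls$correct_percent), c(100, 100))
  post <- attr(cls, "posterior")
  expect_equal(rowSums(post), rep(1, 50), tolerance = 1e-12)
  expect_true(all(post[1:25, "A"] > 0.99))
  # a specimen exactly between two symmetric groups ties at 0.5/0.5
  xs <- rbind(matrix(c(-3, 0, -4, 1, -5, -1), 3, 2, byrow = TRUE),
              matrix(c(3, 0, 4, 1, 5, -1), 3, 2, byrow = TRUE))
  cls2 <- classify_scores(xs, rep(c("L", "R"), each = 3),
                          matrix(c(0, 0), 1))
  expect_equal(cls2$assignments$posterior[1], 0.5, tolerance = 1e-9)
  expect_true(cls2$assignments$tie[1])
  # specimen at a group mean is assigned that group
  cls3 <- classify_scores(xs, rep(c("L", "R"), each = 3),
                          matrix(colMeans(xs[4:6, ]), 1))
  expect_equal(as.character(cls3$assignments$predicted[1]), "R")
})

test_that("leave-one-out bgPCA separates real groups and names tiny ones", {
  set.seed(3)
  d <- two_group_scores(20, 30, offset = 10)
  cv <- cv_bgpca(d$x, d$labels)
  expect_true(all(cv$correct_percent >= 95))
  expect_error(cv_bgpca(d$x, c("solo", d$labels[-1])), "solo")
  # duplicated specimens classify perfectly even at n = 2 per group
  base <- matrix(stats::rnorm(8), 2, 4)
  dup <- rbind(base[1, ], base[1, ], base[2, ] + 8, base[2, ] + 8)
  cvd <- cv_bgpca(dup, c("a", "a", "b", "b"))
  expect_equal(cvd$overall_percent, 100)
})

test_that("CVA matches theory and an independent LDA implementation", {
  # one variable, means +-5, sd 1: error rate ~ pnorm(-5), so LOO >= 99%
  set.seed(8)
  x1 <- matrix(c(stats::rnorm(50, -5), stats::rnorm(50, 5)), ncol = 1)
  labs <- rep(c("a", "b"), each = 50)
  cv1 <- cva(x1, labs)
  expect_true(all(cv1$cv_classification$correct_percent >= 99))
  expect_equal(ncol(cv1$axes), 1)
  # g groups on m variables: min(g-1, m) canonical axes
  set.seed(10)
  x3 <- matrix(stats::rnorm(60 * 5), 60, 5) +
    matrix(rep(c(0, 4, 8), each = 20), 60, 5)
  labs3 <- rep(c("a", "b", "c"), each = 20)
  cv3 <- cva(x3, labs3, loo = FALSE)
  expect_equal(ncol(cv3$axes), 2)
  expect_error(cva(matrix(stats::rnorm(60 * 58), 60, 58), labs3),
               "<= 57")
  # independent cross-check: MASS::lda resubstitution agrees
  lda_fit <- MASS::lda(x3, grouping = labs3)
  lda_pred <- stats::predict(lda_fit, x3)$class
  ours <- cv3$classification$assignments$predicted
  expect_gt(mean(as.character(lda_pred) == as.character(ours)), 0.95)
  # spherical within-group covariance: CVA axes parallel to bgPCA axes
  dev <- x3 - apply(x3, 2, function(col) stats::ave(col, labs3))
  w <- crossprod(dev) / (60 - 3)
  ew <- eigen(w, symmetric = TRUE)
  whiten <- ew$vectors %*% diag(1 / sqrt(ew$values)) %*% t(ew$vectors)
  xw <- (x3 - dev) + dev %*% whiten
  bgw <- bgpca(xw, labs3, weighted = TRUE)
  cvw <- cva(xw, labs3, loo = FALSE)
  for (j in 1:2) {
    a <- bgw$axes[, j]; b <- cvw$axes[, j]
    ang <- acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))))
    expect_lt(ang, 1e-6)
  }
})

test_that("a-posteriori projection is exact for training data", {
  sim <- simulate_shape_groups(n_per_group = 8, groups = c("A", "B"),
                               seed = 17)
  al <- gpa(sim$configs)
  bg <- bgpca(al, sim$labels)
  # projecting a training specimen returns its training scores
  fit <- opa_to_consensus(al$coords[, , 3], al$consensus)
  expect_lt(max(abs(project_unknown(bg, fit$residual) - bg$scores[3, ])),
            1e-9)
  # projecting the consensus lands at the center of the means
  sc0 <- project_unknown(bg, rep(0, length(bg$center)))
  expect_lt(max(abs(sc0 - colMeans(bg$group_scores))), 1e-9)
  expect_error(project_unknown(bg, rep(0, 10)), "does not match")
  # an unknown drawn from group A classifies as A under strong separation
  sim2 <- simulate_shape_groups(n_per_group = 9, groups = c("A", "B"),
                                seed = 17)
  unk_idx <- 9  # last A specimen of the larger sample
  al2 <- gpa(sim2$configs[-unk_idx])
  bg2 <- bgpca(al2, sim2$labels[-unk_idx])
  fit2 <- opa_to_consensus(sim2$configs[[unk_idx]], al2$consensus)
  cls <- classify_scores(bg2$scores, sim2$labels[-unk_idx],
                         project_unknown(bg2, fit2$residual))
  expect_equal(as.character(cls$assignments$predicted[1]), "A")
  expect_gt(cls$assignments$posterior[1], 0.9)
})

test_that("allometry regression reports slope, R2 and p per axis", {
  cs <- seq(40, 60, length.out = 30)
  sc <- cbind(2 * cs, stats::rnorm(30))
  res <- allometry_test(sc, cs)
  expect_equal(res$r_squared[1], 1, tolerance = 1e-9)
  expect_lt(res$p_value[1], 1e-12)
  expect_equal(res$slope[1], 2, tolerance = 1e-9)
  expect_true(res$exact_fit[1])
  expect_false(res$exact_fit[2])
  # three collinear specimens are flagged as an exact fit
  tri <- allometry_test(matrix(c(2, 4, 6), 3, 1), c(10, 20, 30))
  expect_true(tri$exact_fit[1])
  # size-independent scores rarely show R2 above 0.1
  set.seed(30)
  r2 <- replicate(20, {
    allometry_test(matrix(stats::rnorm(100), 100, 1),
                   stats::runif(100, 30, 70))$r_squared
  })
  expect_gt(mean(r2 < 0.1), 0.9)
  expect_error(allometry_test(sc, rep(50, 30)), "constant")
})
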