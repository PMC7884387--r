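# --- ordinations: PCA, between-group PCA, CVA ---------------------------

new_ordination <- function(kind, axes, center, scores, explained,
                           labels = NULL, extra = list()) {
  structure(c(list(kind = kind, axes = axes, center = center,
                   scores = scores, explained = explained,
                   labels = labels), extra),
            class = "ordination_model")
}

#' @export
print.ordination_model <- function(x, ...) {
  cat("<ordination_model> ", x$kind, ": ", ncol(x$axes), " axes, ",
      nrow(x$scores), " specimens\n", sep = "")
  ex <- utils::head(x$explained, 5)
  cat("  explained: ", paste(sprintf("%.1f%%", 100 * ex), collapse = ", "),
      if (length(x$explained) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# accept aligned_shapes or a plain n x p matrix
as_residual_matrix <- function(x) {
  if (inherits(x, "aligned_shapes")) x$residuals else as.matrix(x)
}

#' Principal component analysis of Procrustes residuals
#'
#' Eigendecomposition of the specimen covariance of the flattened
#' Procrustes residuals (via [stats::prcomp()]). Reconstruction from all
#' axes reproduces the residuals exactly.
#'
#' @param aligned an `aligned_shapes` object from [gpa()], or an n x p
#'   data matrix.
#' @return an `ordination_model` with orthonormal axes, per-specimen
#'   scores and per-axis explained variance fractions (summing to 1).
#' @export
shape_pca <- function(aligned) {
  x <- as_residual_matrix(aligned)
  stop_if(nrow(x) < 2L, "PCA needs at least 2 specimens")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > 0
  if (!any(keep)) keep[1] <- TRUE  # fully degenerate sample: keep one axis
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  new_ordination("pca", axes = pc$rotation[, keep, drop = FALSE],
                 center = pc$center,
                 scores = pc$x[, keep, drop = FALSE],
                 explained = expl[keep],
                 extra = list(
                   centroid_sizes = if (inherits(aligned, "aligned_shapes"))
                     aligned$centroid_sizes else NULL))
}

#' Number of leading components reaching a variance target
#'
#' @param explained nonnegative variance fractions in descending order.
#' @param target cumulative fraction to reach (default 0.90, the usual
#'   "components explaining ~90% of total variance" rule).
#' @return the smallest m whose cumulative fraction is >= target (all
#'   axes if the target is never reached).
#' @export
select_pcs <- function(explained, target = 0.90) {
  stop_if(length(explained) == 0, "empty variance-fraction vector")
  stop_if(any(explained < 0), "variance fractions must be nonnegative")
  stop_if(any(diff(explained) > 1e-12), "fractions must be descending")
  cum <- cumsum(explained)
  m <- which(cum >= target - 1e-12)
  if (length(m) == 0) length(explained) else m[1]
}

group_mean_matrix <- function(x, labels) {
  labels <- factor(labels)
  m <- vapply(levels(labels), function(g)
    colMeans(x[labels == g, , drop = FALSE]), numeric(ncol(x)))
  m <- matrix(m, ncol = nlevels(labels),
              dimnames = list(colnames(x), levels(labels)))
  t(m)
}

#' Between-group principal component analysis
#'
#' PCA of the group-mean residual vectors (each mean weighted equally by
#' default), with all specimens projected onto the resulting axes. With g
#' groups there are at most g - 1 informative axes. bgPCA separations can
#' be spurious when variables outnumber specimens; validate with
#' [cv_bgpca()].
#'
#' @param aligned `aligned_shapes` or n x p matrix.
#' @param labels group label per specimen (>= 2 groups, each non-empty).
#' @param weighted if `TRUE`, group means are weighted by group size when
#'   centering and decomposing (default `FALSE`: every group counts
#'   equally).
#' @return an `ordination_model` (kind `"bgpca"`); `explained` gives each
#'   axis's share of total specimen variance, `group_scores` the group
#'   means in score space.
#' @export
bgpca <- function(aligned, labels, weighted = FALSE) {
  x <- as_residual_matrix(aligned)
  labels <- factor(labels)
  stop_if(nlevels(labels) < 2L, "bgPCA needs at least 2 groups")
  stop_if(length(labels) != nrow(x), "labels/specimen count mismatch")
  means <- group_mean_matrix(x, labels)
  w <- if (weighted) as.vector(table(labels)) else rep(1, nlevels(labels))
  center <- colSums(means * w) / sum(w)
  mc <- sweep(means, 2, center) * sqrt(w)
  sv <- svd(mc)
  keep <- which(sv$d > max(sv$d) * 1e-10)
  if (length(keep) == 0) keep <- 1L  # coincident group means
  axes <- sv$v[, keep, drop = FALSE]
  colnames(axes) <- paste0("bgPC", seq_along(keep))
  scores <- sweep(x, 2, center) %*% axes
  colnames(scores) <- colnames(axes)
  xc <- sweep(x, 2, colMeans(x))
  total_var <- sum(xc^2)
  expl <- colSums(sweep(scores, 2, colMeans(scores))^2) / total_var
  new_ordination("bgpca", axes = axes, center = center, scores = scores,
                 explained = expl, labels = labels,
                 extra = list(
                   group_scores = sweep(means, 2, center) %*% axes,
                   weighted = weighted,
                   centroid_sizes = if (inherits(aligned, "aligned_shapes"))
                     aligned$centroid_sizes else NULL))
}

# ridge-regularized pooled within-group covariance
pooled_within_cov <- function(scores, labels, ridge_lambda = 1e-8) {
  labels <- factor(labels)
  n <- nrow(scores); g <- nlevels(labels); p <- ncol(scores)
  stop_if(n - g < 1L, "no within-group degrees of freedom")
  dev <- scores - group_mean_matrix(scores, labels)[labels, , drop = FALSE]
  w <- crossprod(dev) / (n - g)
  tr <- sum(diag(w)) / p
  # degenerate samples (e.g. exact duplicates) have zero within-group
  # scatter; fall back to the overall score scale so W stays invertible
  if (tr <= 0) tr <- max(mean(scores^2), .Machine$double.eps)
  w + diag(ridge_lambda * tr, p)
}

#' Canonical variate analysis
#'
#' Canonical axes from the eigendecomposition of W^-1 B, where W is the
#' ridge-regularized pooled within-group covariance and B the
#' between-group covariance of the group means, computed on the first m
#' principal component scores. Axes are scaled so within-group variance is
#' 1 along each (Mahalanobis scaling); there are min(g - 1, m) canonical
#' axes. Leave-one-out classification is reported via [classify_scores()]
#' with the CVA refit on every fold.
#'
#' @param pc_scores n x m matrix of PC scores (m >= 1).
#' @param labels group labels (>= 2 groups).
#' @param ridge_lambda ridge coefficient for W, as a fraction of
#'   trace(W)/m (default 1e-8).
#' @param loo if `TRUE` (default) also run leave-one-out classification.
#' @return an `ordination_model` (kind `"cva"`) with, additionally,
#'   `classification` (resubstitution [classify_scores()] result) and
#'   `cv_classification` (leave-one-out) when requested.
#' @export
cva <- function(pc_scores, labels, ridge_lambda = 1e-8, loo = TRUE) {
  x <- as.matrix(pc_scores)
  labels <- factor(labels)
  n <- nrow(x); m <- ncol(x); g <- nlevels(labels)
  stop_if(g < 2L, "CVA needs at least 2 groups")
  stop_if(m < 1L, "need at least one PC score column")
  stop_if(n - g < m,
          "too many variables for the within-group degrees of freedom: ",
          "m must be <= ", n - g, " (got ", m, ")")
  fit <- cva_fit(x, labels, ridge_lambda)
  scores <- sweep(x, 2, fit$center) %*% fit$axes
  cls <- classify_scores(scores, labels, scores, ridge_lambda = ridge_lambda)
  cv <- NULL
  if (loo) {
    pred <- character(n); post <- numeric(n)
    for (i in seq_len(n)) {
      f <- cva_fit(x[-i, , drop = FALSE], labels[-i], ridge_lambda)
      tr <- sweep(x[-i, , drop = FALSE], 2, f$center) %*% f$axes
      te <- sweep(x[i, , drop = FALSE], 2, f$center) %*% f$axes
      ci <- classify_scores(tr, labels[-i], te, ridge_lambda = ridge_lambda)
      pred[i] <- as.character(ci$assignments$predicted[1])
      post[i] <- ci$assignments$posterior[1]
    }
    cv <- classification_summary(labels, pred, post)
  }
  new_ordination("cva", axes = fit$axes, center = fit$center,
                 scores = scores,
                 explained = fit$eig / sum(fit$eig), labels = labels,
                 extra = list(classification = cls,
                              cv_classification = cv))
}

cva_fit <- function(x, labels, ridge_lambda = 1e-8) {
  labels <- factor(labels)
  g <- nlevels(labels)
  stop_if(any(table(labels) < 1L), "every group needs at least 1 specimen")
  w <- pooled_within_cov(x, labels, ridge_lambda)
  means <- group_mean_matrix(x, labels)
  ng <- as.vector(table(labels))
  center <- colSums(means * ng) / sum(ng)
  mb <- sweep(means, 2, center) * sqrt(ng)
  b <- crossprod(mb) / sum(ng)
  ew <- eigen(w, symmetric = TRUE)
  vals <- pmax(ew$values, max(ew$values) * 1e-12)
  w_half_inv <- ew$vectors %*% diag(1 / sqrt(vals), length(vals)) %*%
    t(ew$vectors)
  eb <- eigen(w_half_inv %*% b %*% w_half_inv, symmetric = TRUE)
  naxes <- min(g - 1L, ncol(x))
  axes <- w_half_inv %*% eb$vectors[, seq_len(naxes), drop = FALSE]
  colnames(axes) <- paste0("CV", seq_len(naxes))
  list(axes = axes, center = center,
       eig = pmax(eb$values[seq_len(naxes)], 0))
}
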