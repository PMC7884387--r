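# --- classification, cross-validation, projection, allometry -----------

classification_summary <- function(truth, predicted, posterior,
                                   unclassified = rep(FALSE, length(truth))) {
  truth <- factor(truth)
  correct <- as.character(truth) == predicted & !unclassified
  per_group <- vapply(levels(truth), function(g) {
    idx <- truth == g
    100 * sum(correct[idx]) / sum(idx)
  }, numeric(1))
  structure(list(
    assignments = data.frame(truth = truth, predicted = predicted,
                             posterior = posterior,
                             unclassified = unclassified),
    correct_percent = per_group,
    overall_percent = 100 * mean(correct),
    n_unclassified = sum(unclassified)),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> overall ",
      sprintf("%.1f%%", x$overall_percent), " correct\n", sep = "")
  for (g in names(x$correct_percent))
    cat(sprintf("  %-20s %.1f%%\n", g, x$correct_percent[g]))
  if (x$n_unclassified > 0)
    cat("  unclassified:", x$n_unclassified, "\n")
  invisible(x)
}

#' Mahalanobis group classification in ordination score space
#'
#' Computes, for each query specimen, the Mahalanobis distance to every
#' group mean using the ridge-regularized pooled within-group covariance
#' of the training scores, and converts distances to equal-prior Gaussian
#' posterior probabilities `posterior_g` proportional to `exp(-d_g^2/2)`.
#' Chi-square "typicality" probabilities (the tail probability of d^2 on
#' ncol degrees of freedom) are reported alongside, since either
#' convention appears in the morphometric literature. Ties in the maximal
#' posterior are broken deterministically by group-name order and
#' flagged.
#'
#' @param train_scores n x m training score matrix.
#' @param labels group labels of the training specimens.
#' @param new_scores query score matrix (may be the training scores for a
#'   resubstitution rate).
#' @param ridge_lambda ridge coefficient (fraction of trace(W)/m).
#' @param posterior_threshold specimens whose maximal posterior falls
#'   below this are flagged unclassified (default 0: never).
#' @param size_correction use the Gaussian predictive scaling
#'   `d_g^2 / (1 + 1/n_g)` instead of the plug-in distance (default
#'   `TRUE`). The predictive form accounts for the sampling error of
#'   each group mean; it matters in leave-one-out runs, where the
#'   held-out specimen's own group is one smaller than the others and
#'   plug-in distances are biased against it.
#' @return a `classification_result`; `assignments` carries predicted
#'   group, posterior, typicality and tie flag per query, plus the full
#'   distance and posterior matrices as attributes.
#' @export
classify_scores <- function(train_scores, labels, new_scores,
                            ridge_lambda = 1e-8, posterior_threshold = 0,
                            size_correction = TRUE) {
  train_scores <- as.matrix(train_scores)
  new_scores <- matrix(as.matrix(new_scores), ncol = ncol(train_scores))
  labels <- factor(labels)
  w <- pooled_within_cov(train_scores, labels, ridge_lambda)
  wi <- tryCatch(solve(w), error = function(e)
    stop("pooled within-group covariance is singular even after ",
         "regularization", call. = FALSE))
  means <- group_mean_matrix(train_scores, labels)
  ng <- as.vector(table(labels))
  scale_g <- if (size_correction) 1 + 1 / ng else rep(1, length(ng))
  d2 <- t(apply(new_scores, 1, function(x) {
    vapply(seq_len(nrow(means)), function(gi) {
      dv <- x - means[gi, ]
      as.numeric(dv %*% wi %*% dv) / scale_g[gi]
    }, numeric(1))
  }))
  d2 <- matrix(d2, ncol = nrow(means))
  colnames(d2) <- rownames(means)
  # equal-prior Gaussian posteriors via log-sum-exp
  lp <- -d2 / 2
  post <- exp(lp - apply(lp, 1, max))
  post <- post / rowSums(post)
  typ <- stats::pchisq(d2, df = ncol(train_scores), lower.tail = FALSE)
  best <- apply(post, 1, which.max)  # ties -> first (group-name order)
  top <- post[cbind(seq_len(nrow(post)), best)]
  second <- apply(post, 1, function(p) max(p[-which.max(p)]))
  tie <- (top - second) <= 1e-9 * pmax(top, 1e-300)
  uncl <- top < posterior_threshold
  out <- classification_summary(
    truth = if (nrow(new_scores) == length(labels) &&
                isTRUE(all.equal(new_scores, train_scores,
                                 check.attributes = FALSE)))
      labels else factor(rep(NA_character_, nrow(new_scores)),
                         levels = levels(labels)),
    predicted = colnames(d2)[best], posterior = top, unclassified = uncl)
  out$assignments$typicality <- typ[cbind(seq_len(nrow(typ)), best)]
  out$assignments$tie <- tie
  attr(out, "distance2") <- d2
  attr(out, "posterior") <- post
  attr(out, "typicality") <- typ
  out
}

#' Leave-one-out cross-validated between-group PCA classification
#'
#' For each specimen, the group means and bgPCA axes are re-estimated
#' without it, the specimen is projected onto the held-out axes and
#' classified by [classify_scores()]. The Procrustes alignment is, by
#' default, computed once on the full sample and not re-run per fold;
#' set `refit_gpa = TRUE` to re-superimpose the training set in every
#' fold. Cross-validation is the guard against the spurious group
#' separation that naive bgPCA can show when variables outnumber
#' specimens.
#'
#' @inheritParams bgpca
#' @param ridge_lambda ridge coefficient for the pooled covariance.
#' @param posterior_threshold see [classify_scores()].
#' @param refit_gpa re-run [gpa()] on the training fold and re-align the
#'   held-out specimen by OPA (slower; default `FALSE`).
#' @return a `classification_result` with per-group correct-classification
#'   percentages.
#' @export
cv_bgpca <- function(aligned, labels, weighted = FALSE, ridge_lambda = 1e-8,
                     posterior_threshold = 0, refit_gpa = FALSE) {
  labels <- factor(labels)
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  stop_if(length(small) > 0,
          "leave-one-out needs >= 2 specimens per group; too small: ",
          paste(small, collapse = ", "))
  n <- length(labels)
  x_full <- as_residual_matrix(aligned)
  stop_if(nrow(x_full) != n, "labels/specimen count mismatch")
  pred <- character(n); post <- numeric(n); uncl <- logical(n)
  for (i in seq_len(n)) {
    if (refit_gpa && inherits(aligned, "aligned_shapes")) {
      al <- gpa(aligned$coords[, , -i, drop = FALSE])
      xtr <- al$residuals
      xte <- matrix(opa_to_consensus(aligned$coords[, , i],
                                     al$consensus)$residual, nrow = 1)
    } else {
      xtr <- x_full[-i, , drop = FALSE]
      xte <- x_full[i, , drop = FALSE]
    }
    mod <- bgpca(xtr, labels[-i], weighted = weighted)
    str <- mod$scores
    ste <- sweep(xte, 2, mod$center) %*% mod$axes
    ci <- classify_scores(str, labels[-i], ste, ridge_lambda = ridge_lambda,
                          posterior_threshold = posterior_threshold)
    pred[i] <- as.character(ci$assignments$predicted[1])
    post[i] <- ci$assignments$posterior[1]
    uncl[i] <- ci$assignments$unclassified[1]
  }
  classification_summary(labels, pred, post, uncl)
}

#' Project an unknown specimen into a fitted ordination
#'
#' The unknown must first be aligned to the training consensus
#' ([opa_to_consensus()]); its residual against that consensus is then
#' projected onto the model axes. Training scores are not affected.
#'
#' @param model an `ordination_model` (pca/bgpca/cva on residuals).
#' @param residual flattened residual vector of the aligned unknown
#'   (length 3K), or the list returned by [opa_to_consensus()].
#' @return 1 x m score matrix.
#' @export
project_unknown <- function(model, residual) {
  if (is.list(residual) && !is.null(residual$residual))
    residual <- residual$residual
  residual <- as.numeric(residual)
  stop_if(length(residual) != nrow(model$axes),
          "residual length ", length(residual),
          " does not match the model's ", nrow(model$axes), " variables")
  matrix(residual - model$center, nrow = 1) %*% model$axes
}

#' Per-axis allometry regression
#'
#' Ordinary least-squares regression of each ordination axis score on
#' centroid size; reports slope, R-squared and the F-test p-value per
#' axis. A significant slope with non-trivial R-squared indicates that
#' the axis carries size-correlated shape variation (allometry).
#'
#' @param scores n x m score matrix (e.g. PC or bgPC scores).
#' @param centroid_sizes length-n centroid sizes, mm (non-constant).
#' @param log_size regress on log centroid size instead (default
#'   `FALSE`).
#' @return data frame with columns `axis`, `slope`, `r_squared`,
#'   `p_value`.
#' @export
allometry_test <- function(scores, centroid_sizes, log_size = FALSE) {
  scores <- as.matrix(scores)
  stop_if(nrow(scores) < 3L, "allometry regression needs >= 3 specimens")
  stop_if(length(centroid_sizes) != nrow(scores),
          "centroid_sizes length mismatch")
  cs <- if (log_size) log(centroid_sizes) else centroid_sizes
  stop_if(stats::sd(cs) == 0, "centroid size is constant: slope undefined")
  rows <- lapply(seq_len(ncol(scores)), function(j) {
    fit <- stats::lm(scores[, j] ~ cs)
    # summary.lm warns on numerically exact fits; we flag those instead
    sm <- suppressWarnings(summary(fit))
    p <- if (is.null(sm$fstatistic)) NA_real_ else
      stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE)
    data.frame(axis = colnames(scores)[j] %||% paste0("axis", j),
               slope = stats::coef(fit)[2], r_squared = sm$r.squared,
               p_value = as.numeric(p),
               exact_fit = sm$r.squared > 1 - 1e-12)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
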