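# --- lithic attribute analysis ------------------------------------------

LITHIC_METRIC_COLS <- c("length", "proximal_width", "medial_width",
                        "distal_width", "medial_thickness",
                        "distal_thickness", "platform_width",
                        "platform_thickness", "platform_angle")

#' Lithic morphological indices
#'
#' Computes the standard attribute indices per artefact row:
#' elongation = length / medial width; proximal shape = proximal width /
#' medial width; distal shape = medial width / distal width; flattening =
#' medial width / medial thickness; TCSA (tip cross-sectional area) =
#' distal width x distal thickness, mm^2. TCSA here is the plain product
#' of the distal dimensions; the conventional half-product variant
#' (0.5 x width x thickness, appropriate for a lenticular section) is
#' available via `tcsa_half = TRUE` and is reported as `tcsa_half`.
#'
#' Missing or zero denominators yield a missing index with a warning,
#' never an error, so assemblage-scale batch runs are not aborted by a
#' single broken artefact.
#'
#' @param table data frame of artefact attributes with (a subset of) the
#'   metric columns `length, proximal_width, medial_width, distal_width,
#'   medial_thickness, distal_thickness` in mm, plus any label columns
#'   (e.g. `assemblage`, `class`), which are carried through.
#' @param tcsa_half also compute the 0.5-product TCSA variant.
#' @return the input table with index columns `elongation,
#'   proximal_shape, distal_shape, flattening, tcsa` appended.
#' @export
compute_indices <- function(table, tcsa_half = FALSE) {
  table <- as.data.frame(table)
  col <- function(nm) if (nm %in% names(table)) table[[nm]] else
    rep(NA_real_, nrow(table))
  safe_ratio <- function(num, den, what) {
    out <- ifelse(!is.na(den) & den > 0 & !is.na(num), num / den, NA_real_)
    n_bad <- sum(!is.na(den) & den <= 0)
    if (n_bad > 0)
      warning(n_bad, " nonpositive denominator(s) for ", what,
              "; index set to NA", call. = FALSE)
    out
  }
  neg <- vapply(intersect(LITHIC_METRIC_COLS, names(table)), function(nm)
    any(table[[nm]] <= 0, na.rm = TRUE), logical(1))
  if (any(neg))
    warning("nonpositive metric value(s) in: ",
            paste(names(neg)[neg], collapse = ", "), call. = FALSE)
  table$elongation <- safe_ratio(col("length"), col("medial_width"),
                                 "elongation")
  table$proximal_shape <- safe_ratio(col("proximal_width"),
                                     col("medial_width"), "proximal shape")
  table$distal_shape <- safe_ratio(col("medial_width"), col("distal_width"),
                                   "distal shape")
  table$flattening <- safe_ratio(col("medial_width"),
                                 col("medial_thickness"), "flattening")
  table$tcsa <- col("distal_width") * col("distal_thickness")
  if (tcsa_half) table$tcsa_half <- 0.5 * table$tcsa
  table
}

# --- ordered-quantile (rank -> normal scores) normalization -------------

#' Fit a rank-based normal-scores transform to one column
#'
#' Maps observed values to standard-normal quantiles of their (average)
#' ranks, `qnorm((r - 0.5) / n)` — the ordered-quantile transform that a
#' "best normalizing transform" search almost always selects for skewed
#' metric data. The fit stores the observed value/score pairs so held-out
#' rows can be transformed by monotone interpolation (linear, with linear
#' tail extrapolation). The transform preserves ranks exactly.
#'
#' @param x numeric vector with >= 3 non-missing values, not all equal.
#' @return an object of class `ordernorm_fit`.
#' @export
ordernorm_fit <- function(x) {
  obs <- x[!is.na(x)]
  stop_if(length(obs) < 3L, "need >= 3 non-missing values")
  stop_if(stats::sd(obs) == 0, "constant column cannot be normalized")
  r <- rank(obs, ties.method = "average")
  sc <- stats::qnorm((r - 0.5) / length(obs))
  o <- order(obs)
  structure(list(x = obs[o], scores = sc[o], n = length(obs)),
            class = "ordernorm_fit")
}

#' Apply a fitted normal-scores transform
#'
#' @param fit an [ordernorm_fit()].
#' @param x numeric vector (may include values outside the training
#'   range; the mapping is extended linearly in the tails).
#' @return transformed vector, same length as `x`.
#' @export
ordernorm_apply <- function(fit, x) {
  ux <- fit$x[!duplicated(fit$x)]
  us <- fit$scores[!duplicated(fit$x)]
  if (length(ux) == 1L) return(rep(us, length(x)))
  out <- stats::approx(ux, us, xout = x, rule = 2)$y
  # linear tail extrapolation from the outermost two support points
  lo <- x < ux[1]; hi <- x > ux[length(ux)]
  if (any(lo, na.rm = TRUE)) {
    s <- (us[2] - us[1]) / (ux[2] - ux[1])
    out[which(lo)] <- us[1] + s * (x[which(lo)] - ux[1])
  }
  if (any(hi, na.rm = TRUE)) {
    m <- length(ux)
    s <- (us[m] - us[m - 1]) / (ux[m] - ux[m - 1])
    out[which(hi)] <- us[m] + s * (x[which(hi)] - ux[m])
  }
  out[is.na(x)] <- NA_real_
  out
}

#' Normalize the metric columns of an attribute table
#'
#' Applies the ordered-quantile normal-scores transform
#' ([ordernorm_fit()]) to each selected metric column, then centers to
#' mean 0 and scales to SD 1. Constant columns are dropped with a
#' warning. The fitted transforms and centering/scaling parameters are
#' stored in the `transforms` attribute so held-out rows can be mapped
#' into the same space.
#'
#' @param table data frame.
#' @param columns character vector of columns to normalize (default: all
#'   numeric columns present among the standard metric and index
#'   columns).
#' @param method `"orderNorm"` (default), `"log"` or `"none"` (center and
#'   scale only).
#' @return the table with selected columns replaced by their normalized
#'   versions; attribute `transforms` holds the per-column fits.
#' @export
normalize_table <- function(table, columns = NULL,
                            method = c("orderNorm", "log", "none")) {
  method <- match.arg(method)
  table <- as.data.frame(table)
  if (is.null(columns))
    columns <- intersect(c(LITHIC_METRIC_COLS, "elongation",
                           "proximal_shape", "distal_shape", "flattening",
                           "tcsa", "tcsa_half"), names(table))
  transforms <- list()
  for (nm in columns) {
    x <- table[[nm]]
    obs <- x[!is.na(x)]
    if (length(obs) < 3L || stats::sd(obs) == 0) {
      warning("dropping column '", nm,
              "' (constant or < 3 non-missing values)", call. = FALSE)
      table[[nm]] <- NULL
      next
    }
    y <- switch(method,
      orderNorm = {
        f <- ordernorm_fit(x)
        transforms[[nm]] <- f
        ordernorm_apply(f, x)
      },
      log = {
        stop_if(any(obs <= 0), "log transform needs positive values in '",
                nm, "'")
        log(x)
      },
      none = x)
    mu <- mean(y, na.rm = TRUE); sdv <- stats::sd(y, na.rm = TRUE)
    table[[nm]] <- (y - mu) / sdv
    transforms[[nm]] <- list(fit = transforms[[nm]], center = mu,
                             scale = sdv, method = method)
  }
  attr(table, "transforms") <- transforms
  table
}

#' PCA ordination of a lithic attribute table
#'
#' Principal component analysis (centered and scaled, via
#' [stats::prcomp()]) of the selected metric/index columns. Rows with any
#' missing selected value are excluded and counted (complete-case
#' policy); categorical columns are never entered.
#'
#' @param table data frame (typically normalized).
#' @param columns columns to ordinate.
#' @param label_cols label columns to carry onto the scores (default:
#'   `assemblage` and `class` where present).
#' @return an `ordination_model` (kind `"pca"`); `scores` has the labels
#'   attached as a data frame in `score_table`; `n_excluded` counts
#'   dropped incomplete rows.
#' @export
pca_table <- function(table, columns, label_cols = NULL) {
  table <- as.data.frame(table)
  miss <- setdiff(columns, names(table))
  stop_if(length(miss) > 0, "missing column(s): ",
          paste(miss, collapse = ", "))
  if (is.null(label_cols))
    label_cols <- intersect(c("assemblage", "class"), names(table))
  x <- as.matrix(table[, columns, drop = FALSE])
  complete <- stats::complete.cases(x)
  stop_if(sum(complete) < 3L, "fewer than 3 complete rows")
  pc <- stats::prcomp(x[complete, , drop = FALSE], center = TRUE,
                      scale. = TRUE)
  keep <- pc$sdev > max(pc$sdev) * 1e-10
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  st <- cbind(as.data.frame(pc$x[, keep, drop = FALSE]),
              table[complete, label_cols, drop = FALSE])
  new_ordination("pca", axes = pc$rotation[, keep, drop = FALSE],
                 center = pc$center, scores = pc$x[, keep, drop = FALSE],
                 explained = expl[keep],
                 extra = list(scale = pc$scale, score_table = st,
                              n_excluded = sum(!complete),
                              columns = columns))
}

# --- convex-hull overlap in a score plane --------------------------------

# area of a simple polygon (shoelace); vertices as m x 2 matrix
polygon_area <- function(p) {
  if (is.null(p) || nrow(p) < 3) return(0)
  i2 <- c(2:nrow(p), 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# Sutherland-Hodgman clip of convex polygon subj by convex polygon clip
convex_intersection <- function(subj, clip) {
  out <- subj
  m <- nrow(clip)
  # ensure counter-clockwise clip polygon
  if (sum((clip[c(2:m, 1), 1] - clip[, 1]) *
            (clip[c(2:m, 1), 2] + clip[, 2])) > 0)
    clip <- clip[m:1, , drop = FALSE]
  for (i in seq_len(nrow(clip))) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip[i, ]; b <- clip[if (i == nrow(clip)) 1 else i + 1, ]
    inside <- function(p)
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    inter <- function(p, q) {
      d1 <- c(q[1] - p[1], q[2] - p[2]); d2 <- c(b[1] - a[1], b[2] - a[2])
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / den
      p + t * d1
    }
    res <- list()
    for (j in seq_len(nrow(out))) {
      p <- out[j, ]; q <- out[if (j == nrow(out)) 1 else j + 1, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) res[[length(res) + 1]] <- p
      if (pin != qin) res[[length(res) + 1]] <- inter(p, q)
    }
    out <- if (length(res)) do.call(rbind, res) else NULL
  }
  out
}

# all points inside (or on) a convex hull
points_in_hull <- function(pts, hull) {
  m <- nrow(hull)
  if (sum((hull[c(2:m, 1), 1] - hull[, 1]) *
            (hull[c(2:m, 1), 2] + hull[, 2])) > 0)
    hull <- hull[m:1, , drop = FALSE]
  all(vapply(seq_len(m), function(i) {
    a <- hull[i, ]; b <- hull[if (i == m) 1 else i + 1, ]
    all((b[1] - a[1]) * (pts[, 2] - a[2]) -
          (b[2] - a[2]) * (pts[, 1] - a[1]) >= -1e-9)
  }, logical(1)))
}

#' Pairwise convex-hull overlap of labelled ordination scores
#'
#' For every ordered pair of labels in the chosen score plane: the
#' convex-hull overlap fraction (intersection area over union area, so
#' identical clouds give 1 and disjoint clouds 0), the distance between
#' label centroids, and a "falls within" flag that is `TRUE` when every
#' focal point lies inside the reference label's hull. Labels with fewer
#' than 3 points have no hull and are reported with `NA` overlap.
#'
#' @param scores n x >=2 score matrix (or `score_table` data frame).
#' @param labels label per row (>= 2 distinct).
#' @param axes which two score columns to use (default `c(1, 2)`).
#' @return data frame with columns `focal`, `reference`,
#'   `overlap_fraction`, `centroid_distance`, `falls_within`.
#' @export
assemblage_overlap <- function(scores, labels, axes = c(1, 2)) {
  scores <- as.matrix(scores[, axes, drop = FALSE])
  labels <- factor(labels)
  stop_if(nlevels(labels) < 2L, "need at least 2 labels")
  hulls <- lapply(levels(labels), function(g) {
    p <- scores[labels == g, , drop = FALSE]
    if (nrow(p) < 3) return(NULL)
    h <- p[grDevices::chull(p), , drop = FALSE]
    if (polygon_area(h) == 0) NULL else h
  })
  names(hulls) <- levels(labels)
  pairs <- expand.grid(focal = levels(labels), reference = levels(labels),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$focal != pairs$reference, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    f <- pairs$focal[i]; r <- pairs$reference[i]
    pf <- scores[labels == f, , drop = FALSE]
    pr <- scores[labels == r, , drop = FALSE]
    cd <- sqrt(sum((colMeans(pf) - colMeans(pr))^2))
    hf <- hulls[[f]]; hr <- hulls[[r]]
    if (is.null(hf) || is.null(hr)) {
      ov <- NA_real_
    } else {
      ai <- polygon_area(convex_intersection(hf, hr))
      ov <- ai / (polygon_area(hf) + polygon_area(hr) - ai)
    }
    fw <- if (is.null(hr)) NA else points_in_hull(pf, hr)
    data.frame(focal = f, reference = r, overlap_fraction = ov,
               centroid_distance = cd, falls_within = fw)
  })
  do.call(rbind, rows)
}
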