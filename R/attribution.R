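# --- end-to-end attribution report --------------------------------------

#' Validate an attribution run configuration
#'
#' A run configuration is a named list (or a YAML file) with global
#' parameters (`seed`, `alpha`, `target_variance`, `ridge_lambda`,
#' `out_dir`) and one section per requested stage: `zscore` (paths
#' `specimen`, `stats`), `tissue` (either precomputed `v_cervix`/
#' `v_branch`, or `volume` + `format` + `cervix_points` +
#' `occlusal_offset`), `gmm` (`landmarks`, `format`, `groups`,
#' `unknown_id`), `lithics` (`table`, optional `columns`). Every
#' referenced path must exist at validation time, before any
#' computation.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config list, with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    stop_if(!file.exists(config), "config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stop_if(!is.list(config), "config must be a list or YAML path")
  config$alpha <- config$alpha %||% 0.05
  config$target_variance <- config$target_variance %||% 0.90
  config$ridge_lambda <- config$ridge_lambda %||% 1e-8
  config$seed <- config$seed %||% 20210215
  paths <- c(config$zscore$specimen, config$zscore$stats,
             config$tissue$volume, config$tissue$cervix_points,
             config$gmm$landmarks, config$gmm$groups, config$lithics$table)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  stop_if(length(missing) > 0, "config references missing file(s): ",
          paste(missing, collapse = ", "))
  config
}

run_stage <- function(report, name, fun) {
  res <- tryCatch(list(status = "ok", result = fun()),
                  error = function(e) list(status = "failed",
                                           error = conditionMessage(e)))
  report$stages[[name]] <- res
  report
}

#' Run the full attribution pipeline
#'
#' Executes the configured stages — adjusted Z-score profile, 3D tissue
#' metrics (tissue proportions and/or VBI), EDJ shape classification
#' (GPA, bgPCA with leave-one-out cross-validation, CVA, a-posteriori
#' projection of the unknown, allometry), and lithic ordination — and
#' collects every intermediate quantity, parameter and seed into one
#' report. A stage failure is recorded in the report without discarding
#' completed stages. Identical config + inputs produce an identical
#' numeric payload.
#'
#' @param config see [validate_config()].
#' @return a `attribution_report` list; if `config$out_dir` is set, the
#'   report is also written as JSON (plus CSV score/profile tables).
#' @export
run_attribution <- function(config) {
  config <- validate_config(config)
  report <- list(
    package_version = as.character(utils::packageVersion("paleoattrib")),
    config = config, seed = config$seed, stages = list())

  if (!is.null(config$zscore)) {
    report <- run_stage(report, "zscore", function() {
      spec <- read_specimen_measurements(config$zscore$specimen)
      stats <- read_comparative_stats(config$zscore$stats)
      prof <- zscore_profile(spec, stats, alpha = config$alpha)
      list(profile = as.data.frame(prof),
           unmatched = attr(prof, "unmatched"))
    })
  }

  if (!is.null(config$tissue)) {
    report <- run_stage(report, "tissue", function() {
      tc <- config$tissue
      out <- list()
      if (!is.null(tc$v_cervix) && !is.null(tc$v_branch)) {
        out$v_cervix <- tc$v_cervix
        out$v_branch <- tc$v_branch
      } else {
        vol <- read_volume(tc$volume, format = tc$format %||% "nrrd",
                           voxel_size = tc$voxel_size)
        cerv <- fit_plane(as.matrix(utils::read.csv(tc$cervix_points)))
        if (!is.null(tc$occlusal_offset)) {
          occl <- plane(cerv$normal, cerv$offset + tc$occlusal_offset)
          lat <- crop_between_planes(vol, cerv, occl)
          out <- c(out, lateral_tissue_proportions(lat))
        }
        sr <- split_root(vol, cerv,
                         bifurcation_level = tc$bifurcation_level)
        out$v_cervix <- sr$v_cervix
        out$v_branch <- sr$v_branch
      }
      out$vbi <- vbi(out$v_cervix, out$v_branch)
      out
    })
  }

  if (!is.null(config$gmm)) {
    report <- run_stage(report, "gmm", function() {
      gc <- config$gmm
      sets <- read_landmarks(gc$landmarks, format = gc$format %||% "csv")
      grp <- utils::read.csv(gc$groups, stringsAsFactors = FALSE)
      stop_if(!all(c("specimen_id", "group") %in% names(grp)),
              "groups CSV needs columns specimen_id, group")
      ids <- vapply(sets, `[[`, character(1), "specimen_id")
      labels <- grp$group[match(ids, grp$specimen_id)]
      unknown_id <- gc$unknown_id
      is_unknown <- !is.na(unknown_id) & ids %in% unknown_id
      stop_if(any(is.na(labels[!is_unknown])),
              "specimens without a group label: ",
              paste(ids[is.na(labels) & !is_unknown], collapse = ", "))
      train <- sets[!is_unknown]
      al <- gpa(train)
      pc <- shape_pca(al)
      m <- select_pcs(pc$explained, target = config$target_variance)
      m <- min(m, length(labels[!is_unknown]) -
                 length(unique(labels[!is_unknown])))
      bg <- bgpca(al, labels[!is_unknown])
      cv <- cv_bgpca(al, labels[!is_unknown],
                     ridge_lambda = config$ridge_lambda)
      cv_model <- cva(pc$scores[, seq_len(m), drop = FALSE],
                      labels[!is_unknown],
                      ridge_lambda = config$ridge_lambda)
      allo <- allometry_test(bg$scores, al$centroid_sizes)
      out <- list(
        n_pcs_selected = m,
        bgpca_explained = bg$explained,
        cv_bgpca_correct_percent = cv$correct_percent,
        cva_correct_percent = cv_model$cv_classification$correct_percent,
        allometry = allo)
      if (any(is_unknown)) {
        unk <- sets[is_unknown][[1]]
        fit <- opa_to_consensus(unk, al$consensus)
        sc_bg <- project_unknown(bg, fit$residual)
        cls_bg <- classify_scores(bg$scores, labels[!is_unknown], sc_bg,
                                  ridge_lambda = config$ridge_lambda)
        sc_pc <- project_unknown(pc, fit$residual)[, seq_len(m),
                                                   drop = FALSE]
        sc_cv <- sweep(sc_pc, 2, cv_model$center) %*% cv_model$axes
        cls_cv <- classify_scores(cv_model$scores, labels[!is_unknown],
                                  sc_cv, ridge_lambda = config$ridge_lambda)
        out$unknown <- list(
          specimen_id = unk$specimen_id,
          bgpca_scores = as.numeric(sc_bg),
          bgpca_predicted = as.character(cls_bg$assignments$predicted[1]),
          bgpca_posterior = attr(cls_bg, "posterior")[1, ],
          cva_predicted = as.character(cls_cv$assignments$predicted[1]),
          cva_posterior = attr(cls_cv, "posterior")[1, ])
      }
      out
    })
  }

  if (!is.null(config$lithics)) {
    report <- run_stage(report, "lithics", function() {
      lc <- config$lithics
      tab <- utils::read.csv(lc$table, stringsAsFactors = FALSE,
                             check.names = FALSE)
      idx <- compute_indices(tab)
      cols <- lc$columns %||% intersect(
        c("elongation", "proximal_shape", "distal_shape", "flattening",
          "tcsa"), names(idx))
      norm <- normalize_table(idx, columns = cols)
      pc <- pca_table(norm, columns = cols)
      lab_col <- lc$group_col %||% "class"
      ov <- if (lab_col %in% names(pc$score_table))
        assemblage_overlap(pc$scores, pc$score_table[[lab_col]]) else NULL
      list(explained = pc$explained, n_excluded = pc$n_excluded,
           loadings = pc$axes, overlap = ov)
    })
  }

  class(report) <- "attribution_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("<attribution_report> package", x$package_version, "seed", x$seed,
      "\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-8s %s\n", nm, x$stages[[nm]]$status))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    strip_for_json(report), file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  z <- report$stages$zscore
  if (!is.null(z) && z$status == "ok")
    utils::write.csv(z$result$profile,
                     file.path(out_dir, "zscore_profile.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}

strip_for_json <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.matrix(x)) return(unclass(as.data.frame(x)))
  if (is.list(x)) return(lapply(x, strip_for_json))
  x
}
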