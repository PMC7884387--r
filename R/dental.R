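#' Adjusted Z-score of a single measurement against a comparative group
#'
#' Scales the deviation of one specimen from a comparative sample by the
#' half-width of the group's two-sided Student-t prediction interval:
#'
#' \deqn{z_{adj} = \frac{x - \bar{X}}{t_{1-\alpha/2,\; n-1}\,
#'       \sqrt{SD^2\,(1 + 1/n)}}}
#'
#' where \eqn{\bar{X}}, SD and n are the comparative sample mean, sample
#' standard deviation (denominator n - 1) and size. With the default
#' `alpha = 0.05` the interval between -1 and +1 covers 95% of the
#' variation expected of a new member of the comparative group, so
#' `|z| <= 1` reads "within 95% of the group's variation". The factor
#' `sqrt(1 + 1/n)` accounts for the uncertainty of the group mean itself;
#' as n grows the score approaches the classical z-score divided by the
#' 0.975 normal quantile.
#'
#' @param x the specimen's measurement (same units as the group mean).
#' @param stats a one-row `comparative_stats` entry, or any list with
#'   `mean`, `sd`, `n`.
#' @param alpha two-sided tail probability (default 0.05, i.e. a 95%
#'   prediction interval).
#' @return dimensionless adjusted Z-score; sign matches `x - mean`. If
#'   `sd = 0` and `x != mean` the score is signed infinity.
#' @examples
#' adjusted_z(10, list(mean = 8, sd = 1, n = 10))  # 0.843
#' @export
adjusted_z <- function(x, stats, alpha = 0.05) {
  stop_if(!is.finite(x), "measurement x must be finite")
  m <- stats$mean; s <- stats$sd; n <- stats$n
  stop_if(!is.finite(n) || n < 2, "comparative n must be >= 2")
  stop_if(s < 0, "comparative sd must be nonnegative")
  stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  half_width <- stats::qt(1 - alpha / 2, df = n - 1) * sqrt(s^2 * (1 + 1 / n))
  if (half_width == 0) return(sign(x - m) * Inf)
  (x - m) / half_width
}

#' Adjusted Z-score profile of a specimen across groups
#'
#' Scores every variable of a specimen against every comparative group
#' that reports that variable. Variables without any matching group entry
#' are reported in the `unmatched` attribute, never silently dropped.
#'
#' @param spec a [specimen_measurements] object.
#' @param stats a `comparative_stats` data frame ([read_comparative_stats()]).
#' @inheritParams adjusted_z
#' @return data frame with columns `group`, `variable`, `adjusted_z`
#'   (class `zscore_profile`); attribute `unmatched` lists specimen
#'   variables absent from `stats`.
#' @export
zscore_profile <- function(spec, stats, alpha = 0.05) {
  vars <- names(spec$values)
  hit <- stats[stats$variable %in% vars, , drop = FALSE]
  stop_if(nrow(hit) == 0,
          "no (group, variable) pair in stats matches the specimen")
  out <- data.frame(
    group = hit$group, variable = hit$variable,
    adjusted_z = vapply(seq_len(nrow(hit)), function(i)
      adjusted_z(spec$values[[hit$variable[i]]], hit[i, ], alpha = alpha),
      numeric(1)))
  attr(out, "unmatched") <- setdiff(vars, stats$variable)
  attr(out, "specimen_id") <- spec$specimen_id
  class(out) <- c("zscore_profile", "data.frame")
  out
}

#' Crown index
#'
#' Crown breadth divided by crown length, times 100. Values below 100
#' describe mesiodistally elongated (narrow) crowns.
#'
#' @param breadth buccolingual crown breadth, mm (> 0).
#' @param length mesiodistal crown length, mm (> 0); where crowns are
#'   interproximally worn, a wear-adjusted length should be supplied by
#'   the caller.
#' @return crown index, percent.
#' @export
crown_index <- function(breadth, length) {
  stop_if(!is.finite(length) || length <= 0, "crown length must be > 0")
  stop_if(!is.finite(breadth) || breadth <= 0, "crown breadth must be > 0")
  100 * breadth / length
}

#' Crown area
#'
#' Mesiodistal length times buccolingual breadth, a standard proxy for
#' occlusal crown size.
#'
#' @inheritParams crown_index
#' @return crown area, mm^2.
#' @export
crown_area <- function(length, breadth) {
  stop_if(!is.finite(length) || length <= 0, "crown length must be > 0")
  stop_if(!is.finite(breadth) || breadth <= 0, "crown breadth must be > 0")
  length * breadth
}

#' Optional checks against supplementary comparative tables
#'
#' Some published single-specimen scores can only be recomputed with the
#' source study's supplementary comparative tables, which are not freely
#' deposited. Given such a table this helper recomputes the specimen's
#' adjusted Z-scores and crown index; given none it reports the checks as
#' unavailable rather than failing.
#'
#' @param spec a [specimen_measurements] object.
#' @param stats_path optional path to a comparative-stats CSV; `NULL` when
#'   the supplementary tables are not available.
#' @param crown_length,crown_breadth optional crown dimensions (mm) for the
#'   crown-index check.
#' @return list with `available` flag and, when available, the recomputed
#'   `profile` and `crown_index`.
#' @export
si_checks <- function(spec, stats_path = NULL, crown_length = NULL,
                      crown_breadth = NULL) {
  if (is.null(stats_path) || !file.exists(stats_path %||% "")) {
    return(list(available = FALSE,
                reason = "supplementary comparative tables not available"))
  }
  stats <- read_comparative_stats(stats_path)
  out <- list(available = TRUE, profile = zscore_profile(spec, stats))
  if (!is.null(crown_length) && !is.null(crown_breadth))
    out$crown_index <- crown_index(crown_breadth, crown_length)
  out
}
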