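#' Comparative group statistics
#'
#' Per-group, per-variable summary (mean, sample SD, n) of a comparative
#' sample, the reference against which a single specimen is scored with
#' [adjusted_z()]. SD is the sample standard deviation (denominator n - 1)
#' and n must be at least 2 so that the Student-t quantile with n - 1
#' degrees of freedom exists.
#'
#' @param group,variable character scalars.
#' @param mean,sd summary statistics in the variable's units; `sd >= 0`.
#' @param n sample size (>= 2).
#' @return a one-row `data.frame` with class `comparative_stats`.
#' @export
comparative_stats <- function(group, variable, mean, sd, n) {
  stop_if(!is.finite(mean) || !is.finite(sd), "mean and sd must be finite")
  stop_if(sd < 0, "sd must be nonnegative")
  stop_if(!is.finite(n) || n < 2,
          "n must be >= 2 (the Student-t quantile needs n - 1 >= 1 df)")
  out <- data.frame(group = as.character(group),
                    variable = as.character(variable),
                    mean = mean, sd = sd, n = as.integer(n))
  class(out) <- c("comparative_stats", "data.frame")
  out
}

#' Read comparative statistics from CSV
#'
#' Expects columns `group, variable, mean, sd, n`, one row per
#' (group, variable) pair; duplicate pairs are rejected.
#'
#' @param path CSV file path.
#' @return a `comparative_stats` data frame.
#' @export
read_comparative_stats <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "variable", "mean", "sd", "n")
  miss <- setdiff(need, names(df))
  stop_if(length(miss) > 0, "stats CSV missing column(s): ",
          paste(miss, collapse = ", "))
  key <- paste(df$group, df$variable, sep = "\r")
  dup <- key[duplicated(key)]
  stop_if(length(dup) > 0, "duplicate (group, variable) pair(s): ",
          paste(unique(gsub("\r", "/", dup)), collapse = ", "))
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    comparative_stats(df$group[i], df$variable[i], df$mean[i], df$sd[i],
                      df$n[i])))
  class(out) <- c("comparative_stats", "data.frame")
  out
}

#' Single-specimen measurement vector
#'
#' @param specimen_id character scalar.
#' @param values named numeric vector of measurements (units documented per
#'   variable, e.g. MD_length mm, BL_breadth mm, LAET mm, VBI percent).
#' @return an object of class `specimen_measurements`.
#' @export
specimen_measurements <- function(specimen_id, values) {
  stop_if(is.null(names(values)) || any(names(values) == ""),
          "values must be a fully named numeric vector")
  check_finite(values, "specimen measurements")
  structure(list(specimen_id = as.character(specimen_id),
                 values = values),
            class = "specimen_measurements")
}

#' Read specimen measurements from CSV
#'
#' Expects columns `specimen_id, variable, value`; one specimen per file.
#'
#' @param path CSV file path.
#' @return a [specimen_measurements] object.
#' @export
read_specimen_measurements <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "variable", "value")
  miss <- setdiff(need, names(df))
  stop_if(length(miss) > 0, "specimen CSV missing column(s): ",
          paste(miss, collapse = ", "))
  stop_if(length(unique(df$specimen_id)) != 1L,
          "specimen CSV must describe exactly one specimen")
  specimen_measurements(df$specimen_id[1],
                        stats::setNames(df$value, df$variable))
}
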