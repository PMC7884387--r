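#' Landmark configuration for one specimen
#'
#' A `landmark_set` stores one specimen's ordered 3D semilandmark
#' configuration together with its partition into named curves. Coordinates
#' are in mm, right-handed axes; no implicit unit conversion is ever applied.
#'
#' @param coords numeric K x 3 matrix, K >= 4 finite points (mm).
#' @param specimen_id character scalar identifying the specimen.
#' @param curves named list of integer index vectors partitioning
#'   `1:K` into curves; every index must belong to exactly one curve.
#'   Defaults to a single curve `all` spanning the configuration.
#' @param side optional side metadata (e.g. "L", "R").
#' @param tooth optional tooth-position metadata (e.g. "M1").
#' @return an object of class `landmark_set`.
#' @examples
#' lms <- landmark_set(matrix(rnorm(12), 4, 3), "spec1")
#' @export
landmark_set <- function(coords, specimen_id = "unknown", curves = NULL,
                         side = NA_character_, tooth = NA_character_) {
  coords <- as.matrix(coords)
  stop_if(ncol(coords) != 3L, "coords must have 3 columns (x, y, z)")
  stop_if(nrow(coords) < 4L, "at least 4 landmarks are required in 3D")
  check_finite(coords, "landmark coordinates")
  k <- nrow(coords)
  if (is.null(curves)) curves <- list(all = seq_len(k))
  idx <- sort(unlist(curves, use.names = FALSE))
  stop_if(!identical(as.integer(idx), seq_len(k)),
          "curves must partition landmark indices 1:", k,
          " with each index in exactly one curve")
  structure(
    list(specimen_id = as.character(specimen_id), coords = unname(coords),
         curves = lapply(curves, as.integer), side = side, tooth = tooth),
    class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", x$specimen_id, ": ", nrow(x$coords),
      " landmarks in ", length(x$curves), " curve(s)\n", sep = "")
  invisible(x)
}

n_landmarks <- function(x) nrow(x$coords)

check_same_structure <- function(configs) {
  ks <- vapply(configs, n_landmarks, integer(1))
  stop_if(length(unique(ks)) != 1L,
          "inconsistent landmark count across specimens: ",
          paste(unique(ks), collapse = ", "))
  invisible(ks[1])
}

#' Read landmark configurations
#'
#' Reads a TPS file or a long-format CSV into a list of [landmark_set]s.
#' The TPS dialect supported is minimal: `LM3=`/`LM=` records followed by
#' coordinate lines, plus optional `IMAGE=` and `ID=` keys; other keys
#' produce a warning and are ignored. The CSV dialect has columns
#' `specimen_id, curve, x, y, z` with points in file order.
#' Point order and curve assignment are preserved exactly.
#'
#' @param path file path.
#' @param format `"tps"` or `"csv"`.
#' @return list of [landmark_set] objects.
#' @seealso [write_landmarks()]
#' @export
read_landmarks <- function(path, format = c("tps", "csv")) {
  format <- match.arg(format)
  stop_if(!file.exists(path), "file not found: ", path)
  out <- if (format == "tps") read_tps(path) else read_landmark_csv(path)
  if (length(out) > 1) check_same_structure(out)
  out
}

read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  specs <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    m <- regmatches(ln, regexec("^(LM3|LM)=([0-9]+)$", ln, ignore.case = TRUE))[[1]]
    if (length(m) == 0)
      stop("TPS parse error at line ", i, ": expected LM=/LM3= record, got '",
           ln, "'", call. = FALSE)
    k <- as.integer(m[3])
    stop_if(i + k > length(lines), "TPS parse error: record at line ", i,
            " declares ", k, " landmarks but file ends early")
    coord_lines <- lines[(i + 1L):(i + k)]
    vals <- lapply(seq_along(coord_lines), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(coord_lines[j]), "[ \t]+")[[1]]))
      if (length(v) != 3L || anyNA(v))
        stop("TPS parse error at line ", i + j,
             ": expected 3 numeric coordinates", call. = FALSE)
      v
    })
    coords <- do.call(rbind, vals)
    i <- i + k + 1L
    id <- NA_character_
    # trailing keys until next LM record
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "") { i <- i + 1L; next }
      if (grepl("^(LM3|LM)=", ln, ignore.case = TRUE)) break
      kv <- regmatches(ln, regexec("^([A-Za-z0-9_]+)=(.*)$", ln))[[1]]
      if (length(kv) == 0)
        stop("TPS parse error at line ", i, ": '", ln, "'", call. = FALSE)
      key <- toupper(kv[2])
      if (key == "ID") id <- kv[3]
      else if (key != "IMAGE")
        warning("ignoring unsupported TPS key '", key, "' at line ", i,
                call. = FALSE)
      i <- i + 1L
    }
    if (is.na(id)) id <- paste0("specimen_", length(specs) + 1L)
    specs[[length(specs) + 1L]] <- landmark_set(coords, specimen_id = id)
  }
  stop_if(length(specs) == 0, "no landmark records found in ", path)
  specs
}

read_landmark_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "curve", "x", "y", "z")
  miss <- setdiff(need, names(df))
  stop_if(length(miss) > 0, "landmark CSV missing column(s): ",
          paste(miss, collapse = ", "))
  bad <- which(!stats::complete.cases(df[, c("x", "y", "z")]))
  stop_if(length(bad) > 0, "landmark CSV parse error: missing coordinate in ",
          "data row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  split_ids <- unique(df$specimen_id)  # preserve file order
  lapply(split_ids, function(id) {
    sub <- df[df$specimen_id == id, , drop = FALSE]
    curves <- split(seq_len(nrow(sub)), factor(sub$curve, levels = unique(sub$curve)))
    landmark_set(as.matrix(sub[, c("x", "y", "z")]), specimen_id = id,
                 curves = curves)
  })
}

#' Write landmark configurations
#'
#' Inverse of [read_landmarks()]: a write/read round trip preserves point
#' order, curve assignment and coordinates exactly.
#'
#' @param sets a [landmark_set] or list of them.
#' @inheritParams read_landmarks
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(sets, path, format = c("tps", "csv")) {
  format <- match.arg(format)
  if (inherits(sets, "landmark_set")) sets <- list(sets)
  if (format == "tps") {
    lines <- unlist(lapply(sets, function(s) {
      c(sprintf("LM3=%d", n_landmarks(s)),
        apply(s$coords, 1, function(p)
          paste(sprintf("%.17g", p), collapse = " ")),
        sprintf("ID=%s", s$specimen_id))
    }))
    writeLines(lines, path)
  } else {
    rows <- do.call(rbind, lapply(sets, function(s) {
      curve_of <- character(n_landmarks(s))
      for (nm in names(s$curves)) curve_of[s$curves[[nm]]] <- nm
      data.frame(specimen_id = s$specimen_id, curve = curve_of,
                 x = sprintf("%.17g", s$coords[, 1]),
                 y = sprintf("%.17g", s$coords[, 2]),
                 z = sprintf("%.17g", s$coords[, 3]))
    }))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
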