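VOL_LABELS <- c(background = 0L, enamel = 1L, dentine = 2L, pulp = 3L)

#' Labeled voxel volume
#'
#' A 3D integer grid of tissue labels (0 = background, 1 = enamel,
#' 2 = dentine, 3 = pulp) with an isotropic physical voxel size in mm.
#' Voxel indices are interpreted with 0-based, half-open semantics: voxel
#' (i, j, k) (1-based in R) has its center at ((i - 0.5) vs, (j - 0.5) vs,
#' (k - 0.5) vs) and volume vs^3.
#'
#' @param labels 3D integer array of labels.
#' @param voxel_size isotropic voxel edge length, mm (> 0).
#' @return an object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, voxel_size) {
  stop_if(length(dim(labels)) != 3L, "labels must be a 3D array")
  stop_if(!is.numeric(voxel_size) || length(voxel_size) != 1L ||
            !is.finite(voxel_size) || voxel_size <= 0,
          "voxel_size must be a single positive number (mm)")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), VOL_LABELS)
  stop_if(length(bad) > 0, "unknown label value(s): ",
          paste(bad, collapse = ", "), " (allowed: 0, 1, 2, 3)")
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  counts <- table(factor(x$labels, levels = VOL_LABELS,
                         labels = names(VOL_LABELS)))
  cat("<labeled_volume> ", paste(d, collapse = " x "), " voxels @ ",
      x$voxel_size, " mm\n", sep = "")
  for (nm in names(counts))
    cat(sprintf("  %-10s %d voxels (%.3f mm^3)\n", nm, counts[[nm]],
                counts[[nm]] * x$voxel_size^3))
  invisible(x)
}

# centers of all voxels along one dimension, mm
voxel_centers <- function(n, voxel_size) (seq_len(n) - 0.5) * voxel_size

# total physical volume of a tissue label set, mm^3
label_volume <- function(vol, labels) {
  sum(vol$labels %in% labels) * vol$voxel_size^3
}

#' Read a labeled volume
#'
#' Supports NRRD (text header; `ascii`/`txt` encodings) and multi-page TIFF
#' stacks. TIFF carries no physical voxel size, so `voxel_size` must be
#' supplied for that format. Anisotropic NRRD spacings are rejected unless
#' `voxel_size` overrides them, because all downstream tissue formulas
#' assume isotropic physical units.
#'
#' @param path file path.
#' @param format `"nrrd"` or `"tiff_stack"`.
#' @param voxel_size isotropic voxel size in mm; required for TIFF,
#'   optional override for NRRD.
#' @return a [labeled_volume].
#' @export
read_volume <- function(path, format = c("nrrd", "tiff_stack"),
                        voxel_size = NULL) {
  format <- match.arg(format)
  stop_if(!file.exists(path), "file not found: ", path)
  if (format == "nrrd") read_nrrd(path, voxel_size)
  else read_tiff_stack(path, voxel_size)
}

read_nrrd <- function(path, voxel_size = NULL) {
  con <- file(path, "r")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  stop_if(!grepl("^NRRD", magic), "not an NRRD file: ", path)
  hdr <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || ln == "") break
    if (grepl("^#", ln)) next
    kv <- regmatches(ln, regexec("^([^:]+): *(.*)$", ln))[[1]]
    stop_if(length(kv) == 0, "malformed NRRD header line: ", ln)
    hdr[[trimws(kv[2])]] <- trimws(kv[3])
  }
  stop_if(is.null(hdr$dimension) || as.integer(hdr$dimension) != 3L,
          "NRRD volume must be 3-dimensional")
  sizes <- as.integer(strsplit(hdr$sizes, " +")[[1]])
  enc <- tolower(hdr$encoding %||% "ascii")
  stop_if(!enc %in% c("ascii", "txt", "text"),
          "unsupported NRRD encoding '", enc, "' (text encodings only)")
  vals <- scan(con, what = integer(), quiet = TRUE)
  stop_if(length(vals) != prod(sizes), "NRRD data length ", length(vals),
          " does not match sizes ", paste(sizes, collapse = " x "))
  if (is.null(voxel_size)) {
    sp <- hdr$spacings
    stop_if(is.null(sp),
            "NRRD header has no spacings; supply voxel_size explicitly")
    sp <- as.numeric(strsplit(trimws(sp), " +")[[1]])
    stop_if(length(unique(sp)) != 1L,
            "anisotropic voxel spacings (", paste(sp, collapse = ", "),
            "); tissue formulas assume isotropic mm voxels - pass ",
            "voxel_size to override")
    voxel_size <- sp[1]
  }
  labeled_volume(array(vals, dim = sizes), voxel_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_tiff_stack <- function(path, voxel_size) {
  stop_if(is.null(voxel_size),
          "TIFF stacks carry no voxel size; supply voxel_size (mm)")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0L, dim = c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- as.integer(pages[[k]])
  labeled_volume(arr, voxel_size)
}

#' Write a labeled volume
#'
#' @param vol a [labeled_volume].
#' @inheritParams read_volume
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("nrrd", "tiff_stack")) {
  format <- match.arg(format)
  if (format == "nrrd") {
    d <- dim(vol$labels)
    hdr <- c("NRRD0004",
             "# labeled tissue volume (0 bg, 1 enamel, 2 dentine, 3 pulp)",
             "type: int", "dimension: 3",
             paste("sizes:", paste(d, collapse = " ")),
             paste("spacings:", paste(rep(vol$voxel_size, 3), collapse = " ")),
             "encoding: ascii", "")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    write(as.vector(vol$labels), con, ncolumns = 16)
  } else {
    pages <- lapply(seq_len(dim(vol$labels)[3]), function(k)
      vol$labels[, , k] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
  }
  invisible(path)
}
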