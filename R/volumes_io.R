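#' Read a 3D volume from NIfTI or NRRD
#'
#' Spacing and origin are taken from the file header; intensities are passed
#' through unchanged. The format is chosen from the file extension
#' (`.nii`/`.nii.gz` vs `.nrrd`). Arrays follow the `(x, y, z)` convention of
#' [image_volume()].
#'
#' @param path Path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @return An [image_volume()].
#' @seealso [read_mask()], [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    read_nrrd(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    read_nifti(path)
  } else {
    stop("unsupported volume format (expected .nii, .nii.gz or .nrrd): ",
         path, call. = FALSE)
  }
}

#' Read a binary mask volume
#'
#' Like [read_volume()] but thresholds at 0.5 and returns a [binary_mask()]
#' (masks are stored as unsigned 8-bit on disk, boolean in memory).
#'
#' @inheritParams read_volume
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$voxels > 0.5, spacing = v$spacing, origin = v$origin)
}

#' Write a volume or mask to NIfTI or NRRD
#'
#' Images are written as double precision; masks as unsigned 8-bit. The
#' format follows the file extension.
#'
#' @param vol An [image_volume()] or [binary_mask()].
#' @param path Destination path (`.nii`, `.nii.gz` or `.nrrd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume") || inherits(vol, "binary_mask"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(vol, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    write_nifti(vol, path)
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
  invisible(path)
}

read_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("failed to read NIfTI file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(arr)), "D",
         call. = FALSE)
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))  # column norms of the affine
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NIfTI header carries no valid voxel spacing", call. = FALSE)
  origin <- xf[1:3, 4]
  is_mask <- all(arr %in% c(0, 1))
  v <- array(as.numeric(arr), dim(arr))
  if (is_mask && any(v > 0))
    binary_mask(v > 0.5, spacing = spacing, origin = origin)
  else
    image_volume(v, spacing = spacing, origin = origin)
}

write_nifti <- function(vol, path) {
  arr <- if (inherits(vol, "binary_mask")) {
    a <- array(as.integer(vol$voxels), dim(vol$voxels))
    storage.mode(a) <- "integer"
    a
  } else {
    vol$voxels
  }
  affine <- diag(4)
  affine[1, 1] <- vol$spacing[1]
  affine[2, 2] <- vol$spacing[2]
  affine[3, 3] <- vol$spacing[3]
  affine[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing  # qform scales are taken from pixdim
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  datatype <- if (inherits(vol, "binary_mask")) "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# --- NRRD ------------------------------------------------------------------
# Minimal NRRD reader/writer: 3D, little-endian, raw or gzip encodings,
# double / float / uchar-uint8 sample types. Covers the files this package
# writes and the plain NRRDs produced by common converters.

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!length(magic) || !grepl("^NRRD000", magic))
    stop("not an NRRD file (bad magic): ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line))
      stop("truncated NRRD header in ", path, call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1L]]
    if (length(kv) != 3L)
      stop("malformed NRRD header line: ", line, call. = FALSE)
    fields[[tolower(trimws(kv[2L]))]] <- trimws(kv[3L])
  }
  need <- function(key) {
    if (is.null(fields[[key]]))
      stop("NRRD header missing required field '", key, "'", call. = FALSE)
    fields[[key]]
  }
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1L]])
  if (length(sizes) != 3L)
    stop("only 3D NRRD volumes are supported", call. = FALSE)
  type <- need("type")
  encoding <- need("encoding")

  spacing <- rep(NA_real_, 3L)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    vecs <- parse_nrrd_vectors(fields[["space directions"]])
    if (length(vecs) != 3L)
      stop("NRRD 'space directions' must have 3 vectors", call. = FALSE)
    spacing <- vapply(vecs, function(v) sqrt(sum(v^2)), 0)
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1L]])
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NRRD header carries no valid voxel spacing", call. = FALSE)
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1L]]

  n <- prod(sizes)
  payload <- readBin(con, "raw", n = file.size(path))
  if (encoding %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    stop("unsupported NRRD encoding: ", encoding, call. = FALSE)
  }
  vox <- switch(type,
    "double" = readBin(payload, "double", n = n, size = 8, endian = "little"),
    "float" = readBin(payload, "double", n = n, size = 4, endian = "little"),
    "uchar" = ,
    "uint8" = ,
    "unsigned char" = as.numeric(readBin(payload, "integer", n = n, size = 1,
                                         signed = FALSE)),
    "short" = ,
    "int16" = as.numeric(readBin(payload, "integer", n = n, size = 2,
                                 endian = "little")),
    "int" = ,
    "int32" = as.numeric(readBin(payload, "integer", n = n, size = 4,
                                 endian = "little")),
    stop("unsupported NRRD sample type: ", type, call. = FALSE))
  if (length(vox) < n)
    stop("truncated NRRD data block in ", path, call. = FALSE)
  arr <- array(vox[seq_len(n)], sizes)
  if (all(arr %in% c(0, 1)) && any(arr > 0))
    binary_mask(arr > 0.5, spacing = spacing, origin = origin)
  else
    image_volume(arr, spacing = spacing, origin = origin)
}

parse_nrrd_vectors <- function(txt) {
  m <- regmatches(txt, gregexpr("\\(([^)]*)\\)", txt))[[1L]]
  lapply(m, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1L]]))
}

write_nrrd <- function(vol, path) {
  is_mask <- inherits(vol, "binary_mask")
  d <- dim(vol$voxels)
  hdr <- c(
    "NRRD0004",
    "# produced by segstab",
    paste0("type: ", if (is_mask) "uchar" else "double"),
    "dimension: 3",
    "space dimension: 3",
    paste0("sizes: ", paste(d, collapse = " ")),
    paste0("space directions: ",
           sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   vol$spacing[1], vol$spacing[2], vol$spacing[3])),
    paste0("space origin: ",
           sprintf("(%.17g,%.17g,%.17g)",
                   vol$origin[1], vol$origin[2], vol$origin[3])),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (is_mask)
    writeBin(as.raw(as.integer(vol$voxels)), con)
  else
    writeBin(as.numeric(vol$voxels), con, size = 8, endian = "little")
  invisible(path)
}

# --- resampling ------------------------------------------------------------

#' Resample a volume or mask to an isotropic grid
#'
#' Images are trilinearly interpolated, masks use nearest-neighbor (so the
#' output stays strictly boolean). The physical extent is preserved to
#' within one voxel; the origin (center of the first voxel) is kept. Calling
#' with the grid already isotropic at `target_mm` returns the input
#' unchanged, which makes the operation idempotent.
#'
#' @param vol An [image_volume()] or [binary_mask()].
#' @param target_mm Target isotropic spacing in mm (> 0).
#' @return The same kind of object on a `(target_mm, target_mm, target_mm)`
#'   grid.
#' @export
resample_isotropic <- function(vol, target_mm = 1) {
  stopifnot(inherits(vol, "image_volume") || inherits(vol, "binary_mask"))
  if (!is.finite(target_mm) || target_mm <= 0)
    stop("`target_mm` must be > 0", call. = FALSE)
  if (max(abs(vol$spacing - target_mm)) < 1e-9) return(vol)

  is_mask <- inherits(vol, "binary_mask")
  d <- dim(vol$voxels)
  n_new <- pmax(1L, as.integer(round(d * vol$spacing / target_mm)))

  # fractional source index (1-based) of each target voxel center, per axis
  src_idx <- lapply(1:3, function(ax) {
    (seq_len(n_new[ax]) - 1) * target_mm / vol$spacing[ax] + 1
  })
  grid <- expand_grid3(src_idx[[1L]], src_idx[[2L]], src_idx[[3L]], n_new)

  vox <- if (is_mask) {
    idx <- mapply(function(f, ax) pmin(pmax(round(f), 1L), d[ax]),
                  grid, 1:3, SIMPLIFY = FALSE)
    src <- vol$voxels
    out <- src[cbind(idx[[1L]], idx[[2L]], idx[[3L]])]
    array(out, n_new)
  } else {
    array(trilinear(vol$voxels, grid[[1L]], grid[[2L]], grid[[3L]]), n_new)
  }

  if (is_mask) {
    if (!any(vox))
      stop("degenerate mask: resampling removed all foreground voxels",
           call. = FALSE)
    binary_mask(vox, spacing = rep(target_mm, 3), origin = vol$origin)
  } else {
    image_volume(vox, spacing = rep(target_mm, 3), origin = vol$origin)
  }
}

expand_grid3 <- function(x, y, z, n) {
  list(rep(x, times = n[2L] * n[3L]),
       rep(rep(y, each = n[1L]), times = n[3L]),
       rep(z, each = n[1L] * n[2L]))
}

trilinear <- function(src, fx, fy, fz) {
  d <- dim(src)
  clamp <- function(f, n) pmin(pmax(f, 1), n)
  fx <- clamp(fx, d[1L]); fy <- clamp(fy, d[2L]); fz <- clamp(fz, d[3L])
  x0 <- pmin(floor(fx), d[1L] - ifelse(d[1L] > 1, 1, 0))
  y0 <- pmin(floor(fy), d[2L] - ifelse(d[2L] > 1, 1, 0))
  z0 <- pmin(floor(fz), d[3L] - ifelse(d[3L] > 1, 1, 0))
  x1 <- pmin(x0 + 1, d[1L]); y1 <- pmin(y0 + 1, d[2L]); z1 <- pmin(z0 + 1, d[3L])
  tx <- fx - x0; ty <- fy - y0; tz <- fz - z0
  at <- function(i, j, k) src[cbind(i, j, k)]
  c00 <- at(x0, y0, z0) * (1 - tx) + at(x1, y0, z0) * tx
  c10 <- at(x0, y1, z0) * (1 - tx) + at(x1, y1, z0) * tx
  c01 <- at(x0, y0, z1) * (1 - tx) + at(x1, y0, z1) * tx
  c11 <- at(x0, y1, z1) * (1 - tx) + at(x1, y1, z1) * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  c0 * (1 - tz) + c1 * tz
}

# --- tables ----------------------------------------------------------------

#' Read a per-patient survival table
#'
#' Expects CSV columns `patient_id`, `time_days`, `event` (0 = censored,
#' 1 = death observed). Rows with missing time or event are dropped with a
#' warning, mirroring the usual cohort exclusions; duplicate patient ids or
#' unparseable values are errors.
#'
#' @param path CSV file path.
#' @return A data.frame with columns `patient_id` (character), `time_days`
#'   (numeric), `event` (integer 0/1), one row per patient.
#' @export
read_survival_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  req <- c("patient_id", "time_days", "event")
  if (!all(req %in% names(raw)))
    stop("survival CSV must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  blank <- function(x) is.na(x) | trimws(x) == "" | toupper(trimws(x)) == "NA"
  time <- suppressWarnings(as.numeric(raw$time_days))
  event <- suppressWarnings(as.numeric(raw$event))
  if (any(is.na(time) & !blank(raw$time_days)))
    stop("non-numeric values in `time_days`", call. = FALSE)
  if (any(is.na(event) & !blank(raw$event)))
    stop("non-numeric values in `event`", call. = FALSE)
  keep <- !is.na(time) & !is.na(event)
  if (any(!keep))
    warning(sum(!keep), " row(s) dropped for missing time or event",
            call. = FALSE)
  out <- data.frame(patient_id = raw$patient_id[keep],
                    time_days = time[keep],
                    event = as.integer(event[keep]),
                    stringsAsFactors = FALSE)
  if (!all(out$event %in% c(0L, 1L)))
    stop("`event` must be 0 (censored) or 1 (event)", call. = FALSE)
  if (anyDuplicated(out$patient_id))
    stop("duplicate patient_id in survival table", call. = FALSE)
  if (any(out$time_days <= 0))
    stop("`time_days` must be positive", call. = FALSE)
  out
}

#' Read / write per-realization feature tables
#'
#' Long format has columns `patient_id, realization_idx, feature_name, value`
#' (realization 0 = original mask); wide format has `patient_id,
#' realization_idx` plus one column per feature.
#'
#' @param path CSV file path.
#' @param format `"long"` or `"wide"`.
#' @return `read_feature_table()` returns a [feature_realizations()];
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "long") {
    req <- c("patient_id", "realization_idx", "feature_name", "value")
    if (!all(req %in% names(df)))
      stop("long feature CSV must have columns: ",
           paste(req, collapse = ", "), call. = FALSE)
    pats <- unique(df$patient_id)
    reals <- sort(unique(df$realization_idx))
    feats <- unique(df$feature_name)
    arr <- array(NA_real_, c(length(pats), length(reals), length(feats)),
                 dimnames = list(pats, as.character(reals), feats))
    arr[cbind(match(df$patient_id, pats),
              match(df$realization_idx, reals),
              match(df$feature_name, feats))] <- df$value
  } else {
    req <- c("patient_id", "realization_idx")
    if (!all(req %in% names(df)))
      stop("wide feature CSV must have columns patient_id, realization_idx",
           call. = FALSE)
    feats <- setdiff(names(df), req)
    pats <- unique(df$patient_id)
    reals <- sort(unique(df$realization_idx))
    arr <- array(NA_real_, c(length(pats), length(reals), length(feats)),
                 dimnames = list(pats, as.character(reals), feats))
    for (f in feats)
      arr[cbind(match(df$patient_id, pats),
                match(df$realization_idx, reals),
                match(f, feats))] <- df[[f]]
  }
  if (any(is.na(arr)))
    stop("feature table is not complete: every patient needs a value for ",
         "every (realization, feature) pair", call. = FALSE)
  feature_realizations(arr)
}

#' @rdname read_feature_table
#' @param fr A [feature_realizations()] object.
#' @export
write_feature_table <- function(fr, path, format = c("long", "wide")) {
  format <- match.arg(format)
  v <- fr$values
  dn <- dimnames(v)
  if (format == "long") {
    df <- data.frame(
      patient_id = rep(dn[[1L]], times = dim(v)[2L] * dim(v)[3L]),
      realization_idx = rep(rep(as.integer(dn[[2L]]), each = dim(v)[1L]),
                            times = dim(v)[3L]),
      feature_name = rep(dn[[3L]], each = dim(v)[1L] * dim(v)[2L]),
      value = as.vector(v),
      stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      patient_id = rep(dn[[1L]], times = dim(v)[2L]),
      realization_idx = rep(as.integer(dn[[2L]]), each = dim(v)[1L]),
      stringsAsFactors = FALSE)
    for (f in dn[[3L]]) df[[f]] <- as.vector(v[, , f])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
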