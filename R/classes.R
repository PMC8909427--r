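#' Construct an image volume
#'
#' A 3D scalar grid (CT intensities in HU) with physical voxel spacing and
#' origin, the reference image from which radiomic features are extracted.
#' Arrays are indexed `(x, y, z)`; voxel `(1,1,1)` has its center at `origin`
#' and voxel `(i,j,k)` at `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @param voxels 3D numeric array of intensities (finite).
#' @param spacing Numeric length-3, mm per voxel along x, y, z; all positive.
#' @param origin Numeric length-3, mm coordinates of the first voxel center.
#' @return An object of class `image_volume` with fields `voxels`, `spacing`,
#'   `origin`.
#' @examples
#' v <- image_volume(array(rnorm(8), c(2, 2, 2)), spacing = c(1, 1, 1))
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as_array3d(voxels, "voxels")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  if (any(!is.finite(voxels)))
    stop("image intensities must be finite", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Construct a binary mask
#'
#' A 3D boolean grid on the same lattice convention as [image_volume()]. A
#' valid mask has at least one foreground voxel.
#'
#' @param voxels 3D logical (or coercible 0/1) array.
#' @inheritParams image_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as_array3d(voxels, "voxels")
  if (!is.logical(voxels)) {
    if (any(!voxels %in% c(0, 1)))
      stop("mask voxels must be logical or 0/1", call. = FALSE)
    storage.mode(voxels) <- "logical"
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  if (!any(voxels))
    stop("degenerate mask: no foreground voxels", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "binary_mask")
}

as_array3d <- function(x, what) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L)
    stop("`", what, "` must be a 3D array", call. = FALSE)
  x
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm\n", sep = "")
  cat("  intensity range [", signif(min(x$voxels), 5), ", ",
      signif(max(x$voxels), 5), "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, ", sum(x$voxels), " foreground\n", sep = "")
  invisible(x)
}

# Same grid shape, spacing and origin (within a strict tolerance).
same_grid <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    max(abs(a$spacing - b$spacing)) < 1e-9 &&
    max(abs(a$origin - b$origin)) < 1e-9
}

check_aligned <- function(img, mask) {
  if (!same_grid(img, mask))
    stop("image and mask are not on the same grid (shape/spacing/origin)",
         call. = FALSE)
  invisible(TRUE)
}

#' Run configuration
#'
#' Bundles the pipeline parameters: the surface-distance tolerance used for
#' mask perturbation, the number of mask realizations per patient, the
#' fixed-bin-size discretization width, the isotropic voxel size, and the
#' number of cohort-resampling simulations. Defaults are the standard choices
#' for lung CT radiomics: tolerance 1.18 mm (a clinically observed
#' interobserver surface-distance bound), 300 realizations, 25 HU bins,
#' 1 mm^3 voxels.
#'
#' @param tolerance_mm Max symmetric surface distance tolerance tau (> 0), mm.
#' @param n_realizations Perturbed masks per patient (>= 1).
#' @param bin_width_hu Fixed bin size for intensity discretization (> 0), HU.
#' @param voxel_size_mm Isotropic resampling target, mm.
#' @param n_simulations Cohort-resampling pipeline iterations.
#' @param seed Integer seed driving all randomness.
#' @param feature_list Character vector of feature names to extract, or NULL
#'   for the full supported set.
#' @return A `run_config` list.
#' @export
run_config <- function(tolerance_mm = 1.18, n_realizations = 300L,
                       bin_width_hu = 25, voxel_size_mm = 1,
                       n_simulations = 1000L, seed = 1L,
                       feature_list = NULL) {
  if (!is.finite(tolerance_mm) || tolerance_mm <= 0)
    stop("`tolerance_mm` must be > 0", call. = FALSE)
  if (n_realizations < 1) stop("`n_realizations` must be >= 1", call. = FALSE)
  if (!is.finite(bin_width_hu) || bin_width_hu <= 0)
    stop("`bin_width_hu` must be > 0", call. = FALSE)
  if (!is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be > 0", call. = FALSE)
  structure(list(tolerance_mm = tolerance_mm,
                 n_realizations = as.integer(n_realizations),
                 bin_width_hu = bin_width_hu,
                 voxel_size_mm = voxel_size_mm,
                 n_simulations = as.integer(n_simulations),
                 seed = as.integer(seed),
                 feature_list = feature_list),
            class = "run_config")
}

#' Per-patient, per-realization feature values
#'
#' The central container for uncertainty analysis: a 3D array
#' `[patient, realization, feature]` of feature values, where realization
#' index 1 (named `"0"`) is the value extracted from the original
#' (unperturbed) mask and the remaining realizations come from perturbed
#' masks.
#'
#' @param values 3D numeric array `[patient, realization, feature]`, no
#'   missing values. Dimnames are used if present; defaults are generated
#'   otherwise (realizations named `"0", "1", ...`).
#' @return A `feature_realizations` object.
#' @export
feature_realizations <- function(values) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array [patient, realization, feature]",
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("feature realizations must be finite (no missing values)",
         call. = FALSE)
  dn <- dimnames(values)
  if (is.null(dn)) dn <- vector("list", 3L)
  if (is.null(dn[[1L]])) dn[[1L]] <- paste0("P", seq_len(dim(values)[1L]))
  if (is.null(dn[[2L]])) dn[[2L]] <- as.character(seq_len(dim(values)[2L]) - 1L)
  if (is.null(dn[[3L]])) dn[[3L]] <- paste0("feature_", seq_len(dim(values)[3L]))
  dimnames(values) <- dn
  structure(list(values = values), class = "feature_realizations")
}

#' @export
print.feature_realizations <- function(x, ...) {
  d <- dim(x$values)
  cat("<feature_realizations> ", d[1], " patients x ", d[2],
      " realizations x ", d[3], " features\n", sep = "")
  invisible(x)
}

#' @rdname feature_realizations
#' @param fr A `feature_realizations` object.
#' @export
fr_patients <- function(fr) dimnames(fr$values)[[1L]]

#' @rdname feature_realizations
#' @export
fr_features <- function(fr) dimnames(fr$values)[[3L]]

#' @rdname feature_realizations
#' @export
fr_n_realizations <- function(fr) dim(fr$values)[2L]

#' Subset the feature dimension of a realization table
#' @param fr A `feature_realizations` object.
#' @param features Character vector of feature names to keep.
#' @return A `feature_realizations` with only the requested features.
#' @export
fr_select <- function(fr, features) {
  missing <- setdiff(features, fr_features(fr))
  if (length(missing))
    stop("unknown features: ", paste(missing, collapse = ", "), call. = FALSE)
  feature_realizations(fr$values[, , features, drop = FALSE])
}
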