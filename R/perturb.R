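#' Perturbation configuration
#'
#' Parameters for the Monte Carlo mask sampler: the surface-distance
#' tolerance `tolerance_mm` (the hard constraint every realization must
#' satisfy relative to the original mask), the number of realizations, and
#' the correlation length `smoothness_mm` of the random offset field that
#' shapes the deformation front (default: equal to the tolerance, giving
#' deformations whose spatial scale matches their amplitude).
#'
#' @param tolerance_mm Max symmetric surface distance tolerance tau, mm (> 0).
#' @param n_realizations Number of perturbed masks to draw (>= 1).
#' @param smoothness_mm Gaussian correlation length of the offset field, mm.
#' @param max_attempts_per_mask Redraws allowed before sampling fails.
#' @param seed Integer seed.
#' @return A `perturbation_config` list.
#' @export
perturbation_config <- function(tolerance_mm = 1.18, n_realizations = 300L,
                                smoothness_mm = tolerance_mm,
                                max_attempts_per_mask = 25L, seed = 1L) {
  if (!is.finite(tolerance_mm) || tolerance_mm <= 0)
    stop("`tolerance_mm` must be > 0", call. = FALSE)
  if (!is.finite(smoothness_mm) || smoothness_mm <= 0)
    stop("`smoothness_mm` must be > 0", call. = FALSE)
  if (n_realizations < 1) stop("`n_realizations` must be >= 1", call. = FALSE)
  structure(list(tolerance_mm = tolerance_mm,
                 n_realizations = as.integer(n_realizations),
                 smoothness_mm = smoothness_mm,
                 max_attempts_per_mask = as.integer(max_attempts_per_mask),
                 seed = as.integer(seed)),
            class = "perturbation_config")
}

#' Signed distance to the mask surface
#'
#' Euclidean distance (mm) from each voxel center to the nearest surface
#' voxel center of the mask, negative inside the mask and positive outside
#' (surface voxels are at 0). Computed with an exact separable distance
#' transform honoring anisotropic spacing.
#'
#' @param mask A [binary_mask()].
#' @return A numeric 3D array of signed distances, mm.
#' @export
signed_distance_field <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  surf <- surface_voxels(mask$voxels)
  d2 <- .cpp_sq_edt(as.vector(surf), dim(mask$voxels), mask$spacing)
  d <- array(sqrt(d2), dim(mask$voxels))
  d[mask$voxels] <- -d[mask$voxels]
  d
}

#' Uncertainty ring of a mask
#'
#' The shell of voxels whose signed distance to the original surface lies
#' within `[-tau, tau]` — the support on which perturbed contours may differ
#' from the original. Voxels with distance below `-tau` (the core) stay
#' foreground in every realization; voxels beyond `+tau` stay background.
#'
#' @param mask A [binary_mask()].
#' @param tau Tolerance in mm (> 0).
#' @return A list of class `uncertainty_ring` with `ring` (logical array),
#'   `signed_distance` (mm array), and `tau`.
#' @export
build_ring <- function(mask, tau = 1.18) {
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  sdf <- signed_distance_field(mask)
  ring <- abs(sdf) <= tau
  if (!any(ring))
    stop("degenerate ring: no voxels within tolerance of the surface",
         call. = FALSE)
  structure(list(ring = ring, signed_distance = sdf, tau = tau),
            class = "uncertainty_ring")
}

# Periodic Gaussian smoothing via FFT; sigma in voxels per axis.
smooth_gaussian_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  kern1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1)))
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  kern <- outer(outer(kern1(d[1], sigma_vox[1]), kern1(d[2], sigma_vox[2])),
                kern1(d[3], sigma_vox[3]))
  dim(kern) <- d
  Re(stats::fft(stats::fft(arr) * stats::fft(kern), inverse = TRUE)) / prod(d)
}

largest_component_26 <- function(vox) {
  labels <- .cpp_label_components(as.vector(vox), dim(vox), 26L)
  if (max(labels) <= 1L) return(vox)
  tab <- tabulate(labels)
  keep <- which.max(tab)
  array(labels == keep, dim(vox))
}

# Fill internal holes: background components (6-connected) not touching the
# grid border become foreground.
fill_holes <- function(vox) {
  d <- dim(vox)
  labels <- array(.cpp_label_components(as.vector(!vox), d, 6L), d)
  if (max(labels) == 0L) return(vox)
  border_labels <- unique(c(labels[c(1, d[1]), , ], labels[, c(1, d[2]), ],
                            labels[, , c(1, d[3])]))
  border_labels <- setdiff(border_labels, 0L)
  vox | (labels != 0L & !(labels %in% border_labels))
}

#' Draw one perturbed mask realization
#'
#' Draws a spatially correlated random offset field (white noise smoothed
#' with a Gaussian kernel of width `smoothness_mm`) and moves the contour
#' front to the level set `signed_distance <= offset + h/2`, where `h` is
#' the mean voxel spacing: the half-voxel term places the decision at the
#' physical interface between voxel centers rather than on the (foreground)
#' surface voxels themselves, which keeps the realized volume changes
#' symmetric around zero. The offset field is normalized to unit SD, scaled
#' to `0.99 (tau - h/2)` and clipped at that amplitude, so every retained
#' voxel stays within `tau` mm of the original surface while typical
#' offsets remain a sizable fraction of the tolerance. The result is cleaned to a single 26-connected
#' component with no internal holes and validated against the hard
#' tolerance contract ([within_tolerance()]); invalid draws are rejected
#' and redrawn up to `max_attempts_per_mask` times. Randomness is taken
#' from R's current RNG stream.
#'
#' @param mask The original [binary_mask()].
#' @param cfg A [perturbation_config()].
#' @param sdf Optional precomputed [signed_distance_field()] of `mask`
#'   (computed if omitted; pass it when drawing many realizations).
#' @return A [binary_mask()] within tolerance of `mask`.
#' @export
sample_mask <- function(mask, cfg = perturbation_config(), sdf = NULL) {
  stopifnot(inherits(mask, "binary_mask"), inherits(cfg, "perturbation_config"))
  if (is.null(sdf)) sdf <- signed_distance_field(mask)
  tau <- cfg$tolerance_mm
  half <- mean(mask$spacing) / 2
  if (tau <= half)
    stop("tolerance must exceed half the voxel spacing (", signif(half, 3),
         " mm) for a voxel-grid perturbation", call. = FALSE)
  sigma_vox <- cfg$smoothness_mm / mask$spacing
  d <- dim(mask$voxels)
  surf_idx <- which(surface_voxels(mask$voxels))
  surf_pts <- as_points(extract_surface(mask))
  for (attempt in seq_len(cfg$max_attempts_per_mask)) {
    noise <- array(stats::rnorm(prod(d)), d)
    field <- smooth_gaussian_3d(noise, sigma_vox)
    # unit-SD field clipped to the amplitude limit: typical offsets are a
    # sizable fraction of the tolerance instead of vanishing with grid size
    lim <- 0.99 * (tau - half)
    offset <- field / stats::sd(field) * lim
    offset <- pmin(pmax(offset, -lim), lim)
    vox <- sdf <= offset + half
    if (!any(vox)) next
    vox <- fill_holes(largest_component_26(vox))
    # repair pass: where an eroded patch is diagonally oriented, an original
    # surface voxel can be left > tau from the new surface; re-add such
    # voxels (they are on the original surface, so they cost no tolerance)
    for (repair in 1:3) {
      cand <- binary_mask(vox, spacing = mask$spacing, origin = mask$origin)
      dists <- .cpp_min_dists(surf_pts, as_points(extract_surface(cand)))
      bad <- dists > tau
      if (!any(bad)) break
      vox[surf_idx[bad]] <- TRUE
      vox <- fill_holes(largest_component_26(vox))
    }
    cand <- binary_mask(vox, spacing = mask$spacing, origin = mask$origin)
    if (within_tolerance(mask, cand, tau)) return(cand)
  }
  stop("mask sampling failed after ", cfg$max_attempts_per_mask,
       " attempts: tolerance/smoothness mismatch for this mask",
       call. = FALSE)
}

#' Generate a set of perturbed mask realizations
#'
#' Draws `cfg$n_realizations` independent perturbed masks (the original mask
#' is NOT included in the returned list — callers prepend it as realization
#' 0). Reproducible: per-realization RNG streams are derived from
#' `cfg$seed` and the realization index, so realization `i` is identical
#' whatever `n_realizations` is.
#'
#' @inheritParams sample_mask
#' @return A list of [binary_mask()] of length `cfg$n_realizations`.
#' @export
generate_realizations <- function(mask, cfg = perturbation_config()) {
  sdf <- signed_distance_field(mask)
  lapply(seq_len(cfg$n_realizations), function(i) {
    set.seed(derive_seed(cfg$seed, i))
    sample_mask(mask, cfg, sdf = sdf)
  })
}

# Deterministic stream seed for iteration i under master seed; kept < 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}
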