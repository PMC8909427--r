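#' Extract the surface of a binary mask
#'
#' The surface is the set of foreground voxels having at least one 6-connected
#' neighbor that is background or outside the grid, reported as physical
#' (mm) coordinates of the voxel centers. This voxel-center convention is
#' used consistently by every surface-distance metric in the package.
#'
#' @param mask A [binary_mask()].
#' @return A matrix with one row per surface point and columns `x, y, z` (mm),
#'   of class `surface_points`.
#' @export
extract_surface <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  surf <- surface_voxels(mask$voxels)
  idx <- which(surf, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
  colnames(pts) <- c("x", "y", "z")
  class(pts) <- c("surface_points", class(pts))
  pts
}

# logical array of surface voxels (foreground with a 6-neighbor outside the
# foreground or outside the grid)
surface_voxels <- function(vox) {
  d <- dim(vox)
  shift_bg <- function(ax, by) {
    out <- array(TRUE, d)  # outside the grid counts as background
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (n == 1) return(out)  # every voxel borders the outside along this axis
    if (by == 1) {
      idx_src[[ax]] <- 1:(n - 1); idx_dst[[ax]] <- 2:n
    } else {
      idx_src[[ax]] <- 2:n; idx_dst[[ax]] <- 1:(n - 1)
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      !vox[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  has_bg_nb <- array(FALSE, d)
  for (ax in 1:3)
    for (by in c(-1, 1))
      has_bg_nb <- has_bg_nb | shift_bg(ax, by)
  vox & has_bg_nb
}

#' Directed maximum surface distance
#'
#' `max` over points of `A` of the distance to the nearest point of `B`
#' (one side of the Hausdorff distance), in mm.
#'
#' @param A,B Surface point sets from [extract_surface()] (or plain
#'   n-by-3 matrices of mm coordinates).
#' @return Distance in mm.
#' @export
directed_max_distance <- function(A, B) {
  A <- as_points(A); B <- as_points(B)
  max(.cpp_min_dists(A, B))
}

as_points <- function(p) {
  p <- unclass(p)
  if (!is.matrix(p) || ncol(p) != 3L || nrow(p) == 0L)
    stop("degenerate surface: expected a non-empty n x 3 point matrix",
         call. = FALSE)
  storage.mode(p) <- "double"
  p
}

#' Surface-distance summary between two masks
#'
#' Reports both directed maximum distances, their maximum (the symmetric
#' Hausdorff distance over boundary voxel centers), the symmetric mean
#' surface distance, and the surface dice at tolerance `tau`.
#'
#' @param A,B [binary_mask()] objects on the same grid.
#' @param tau Tolerance in mm (>= 0) for the surface-dice fraction.
#' @return A list of class `surface_distance_summary` with fields
#'   `max_AB_mm`, `max_BA_mm`, `max_symmetric_mm`, `mean_symmetric_mm`,
#'   `surface_dice`.
#' @export
surface_distance_summary <- function(A, B, tau = 1.18) {
  check_same_grid_masks(A, B)
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  sa <- extract_surface(A)
  sb <- extract_surface(B)
  dab <- .cpp_min_dists(as_points(sa), as_points(sb))
  dba <- .cpp_min_dists(as_points(sb), as_points(sa))
  structure(list(
    max_AB_mm = max(dab),
    max_BA_mm = max(dba),
    max_symmetric_mm = max(max(dab), max(dba)),
    mean_symmetric_mm = mean(c(dab, dba)),
    surface_dice = (sum(dab <= tau) + sum(dba <= tau)) /
      (length(dab) + length(dba))
  ), class = "surface_distance_summary")
}

#' @export
print.surface_distance_summary <- function(x, ...) {
  cat(sprintf(
    "<surface_distance_summary> max A->B %.3f mm, max B->A %.3f mm\n",
    x$max_AB_mm, x$max_BA_mm))
  cat(sprintf("  max symmetric %.3f mm, mean symmetric %.3f mm, surface dice %.4f\n",
              x$max_symmetric_mm, x$mean_symmetric_mm, x$surface_dice))
  invisible(x)
}

#' Surface dice at tolerance
#'
#' Fraction of the two masks' surface points lying within `tau` mm of the
#' other mask's surface, weighted by surface-point counts:
#' `(|{a : d(a, S_B) <= tau}| + |{b : d(b, S_A) <= tau}|) / (|S_A| + |S_B|)`.
#'
#' @inheritParams surface_distance_summary
#' @return A fraction in `[0, 1]`.
#' @export
surface_dice_at_tolerance <- function(A, B, tau) {
  surface_distance_summary(A, B, tau = tau)$surface_dice
}

#' Tolerance check between two masks
#'
#' `TRUE` iff the maximum symmetric surface distance between the masks'
#' boundary voxel centers is at most `tau` mm — the hard constraint the
#' perturbation sampler guarantees (equivalently, surface dice at `tau`
#' equals 1).
#'
#' @inheritParams surface_distance_summary
#' @return Logical scalar.
#' @export
within_tolerance <- function(A, B, tau) {
  surface_distance_summary(A, B, tau = tau)$max_symmetric_mm <= tau
}

check_same_grid_masks <- function(A, B) {
  stopifnot(inherits(A, "binary_mask"), inherits(B, "binary_mask"))
  if (!same_grid(A, B))
    stop("masks are not on the same grid (shape/spacing/origin)",
         call. = FALSE)
  invisible(TRUE)
}
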