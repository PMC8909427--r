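#' Fixed-bin-size intensity discretization of an ROI
#'
#' Bins ROI intensities with a fixed bin width anchored at the ROI minimum:
#' `level(v) = floor((I(v) - min_ROI) / W) + 1`. This is the standard
#' fixed-bin-size (FBS) scheme for CT radiomics; the number of gray levels is
#' the level of the ROI maximum.
#'
#' @param img An [image_volume()].
#' @param mask A [binary_mask()] on the same grid.
#' @param bin_width Bin width in HU (> 0).
#' @return A `discretized_roi`: `levels` (integer array, 0 outside the ROI),
#'   `n_levels`, `bin_width`, `roi_voxel_count`, `spacing`.
#' @export
discretize <- function(img, mask, bin_width = 25) {
  stopifnot(inherits(img, "image_volume"))
  check_aligned(img, mask)
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("`bin_width` must be > 0", call. = FALSE)
  roi <- mask$voxels
  if (!any(roi)) stop("degenerate ROI: empty mask", call. = FALSE)
  vals <- img$voxels[roi]
  lv <- array(0L, dim(img$voxels))
  lv[roi] <- as.integer(floor((vals - min(vals)) / bin_width)) + 1L
  structure(list(levels = lv,
                 n_levels = max(lv),
                 bin_width = bin_width,
                 roi_voxel_count = sum(roi),
                 spacing = img$spacing),
            class = "discretized_roi")
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat("<discretized_roi> ", x$roi_voxel_count, " voxels, ", x$n_levels,
      " gray levels (bin width ", x$bin_width, ")\n", sep = "")
  invisible(x)
}

# The eight features whose segmentation sensitivity the eta analysis ranks,
# four robust (low eta) and four texture features that react strongly to
# contour changes (high eta).
#' Names of the core ranked feature set
#' @return Character vector of the eight headline feature names.
#' @export
core_feature_names <- function() {
  c("firstorder_Maximum", "gldm_GrayLevelNonUniformity",
    "glrlm_GrayLevelNonUniformity", "ngtdm_Coarseness",
    "glszm_GrayLevelVariance", "glrlm_RunEntropy",
    "glcm_MCC", "glszm_GrayLevelNonUniformityNormalized")
}

log2p <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' First-order intensity statistics
#'
#' Standard moment statistics over the raw ROI intensities: Maximum, Minimum,
#' Mean, Median, Variance (population), Skewness, Kurtosis (non-excess),
#' Energy, RootMeanSquared, and Entropy over the fixed-bin-size histogram.
#' Skewness and Kurtosis of a constant ROI are 0 by convention.
#'
#' @inheritParams discretize
#' @return Named numeric vector (`firstorder_*`).
#' @export
first_order_features <- function(img, mask, bin_width = 25) {
  check_aligned(img, mask)
  x <- img$voxels[mask$voxels]
  if (!length(x)) stop("degenerate ROI: empty mask", call. = FALSE)
  n <- length(x)
  m <- mean(x)
  v <- sum((x - m)^2) / n
  skew <- if (v > 0) (sum((x - m)^3) / n) / v^1.5 else 0
  kurt <- if (v > 0) (sum((x - m)^4) / n) / v^2 else 0
  d <- discretize(img, mask, bin_width)
  p_hist <- tabulate(d$levels[d$levels > 0], nbins = d$n_levels) / n
  c(firstorder_Maximum = max(x),
    firstorder_Minimum = min(x),
    firstorder_Mean = m,
    firstorder_Median = stats::median(x),
    firstorder_Variance = v,
    firstorder_Skewness = skew,
    firstorder_Kurtosis = kurt,
    firstorder_Energy = sum(x^2),
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Entropy = log2p(p_hist))
}

#' Shape features of a binary mask
#'
#' `VoxelVolume` is voxel count times voxel volume; `SurfaceAreaApprox`
#' sums exposed voxel faces (each weighted by its physical face area);
#' `Sphericity = pi^(1/3) (6 V)^(2/3) / A`; `Maximum3DDiameter` is the
#' largest pairwise distance between surface voxel centers.
#'
#' @param mask A [binary_mask()].
#' @return Named numeric vector (`shape_*`).
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sp <- mask$spacing
  vol <- sum(mask$voxels) * prod(sp)
  area <- exposed_face_area(mask$voxels, sp)
  pts <- as_points(extract_surface(mask))
  # max pairwise distance; surface sets are small enough for a dense pass
  maxdiam <- if (nrow(pts) == 1L) 0 else max(stats::dist(pts))
  c(shape_VoxelVolume = vol,
    shape_SurfaceAreaApprox = area,
    shape_Sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / area,
    shape_Maximum3DDiameter = maxdiam)
}

exposed_face_area <- function(vox, sp) {
  d <- dim(vox)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  total <- 0
  for (ax in 1:3) {
    n <- d[ax]
    idx <- lapply(d, seq_len)
    lo <- idx; lo[[ax]] <- 1L
    hi <- idx; hi[[ax]] <- n
    # faces against the grid border
    total <- total + face_area[ax] *
      (sum(vox[lo[[1]], lo[[2]], lo[[3]]]) + sum(vox[hi[[1]], hi[[2]], hi[[3]]]))
    if (n > 1) {
      a <- idx; a[[ax]] <- 1:(n - 1)
      b <- idx; b[[ax]] <- 2:n
      boundary_faces <- sum(vox[a[[1]], a[[2]], a[[3]]] !=
                              vox[b[[1]], b[[2]], b[[3]]])
      total <- total + face_area[ax] * boundary_faces
    }
  }
  total
}

# 13 unique distance-1 directions (matches the C++ counting kernels)
texture_directions <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

#' Gray level co-occurrence (GLCM) features
#'
#' Symmetric co-occurrence at distance 1 over the 13 unique 3D directions;
#' each feature is computed per direction and averaged (directions with no
#' co-occurring pairs are skipped). `MCC` is the maximal correlation
#' coefficient: the square root of the second-largest eigenvalue of
#' `Q(i,j) = sum_k p(i,k) p(j,k) / (p_x(i) p_y(k))`. For a single-level ROI
#' the degenerate conventions are Contrast 0, Correlation 1, MCC 1.
#'
#' @param d A [discretize()]d ROI.
#' @return Named numeric vector (`glcm_*`).
#' @export
glcm_features <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  ng <- d$n_levels
  counts <- .cpp_glcm_counts(as.vector(d$levels), dim(d$levels), ng)
  dim(counts) <- c(ng, ng, 13L)
  if (ng == 1L)
    message("GLCM on single-level ROI: Contrast = 0, Correlation = MCC = 1")
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  per_dir <- lapply(seq_len(13L), function(k) {
    P <- counts[, , k, drop = FALSE]
    dim(P) <- c(ng, ng)
    tot <- sum(P)
    if (tot == 0) return(NULL)
    p <- P / tot
    px <- rowSums(p)
    mu <- sum(seq_len(ng) * px)
    sig2 <- sum((seq_len(ng) - mu)^2 * px)
    corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1
    c(JointEntropy = log2p(p),
      Contrast = sum((i - j)^2 * p),
      Correlation = corr,
      MCC = glcm_mcc(p, px))
  })
  per_dir <- do.call(cbind, per_dir[!vapply(per_dir, is.null, TRUE)])
  stats::setNames(rowMeans(per_dir), paste0("glcm_", rownames(per_dir)))
}

glcm_mcc <- function(p, px) {
  present <- which(px > 0)
  if (length(present) < 2L) return(1)
  pp <- p[present, present, drop = FALSE]
  pxp <- px[present]
  # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)); symmetric p so py = px
  Q <- (pp / pxp) %*% t(sweep(pp, 2, pxp, "/"))
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(ev[2L], 0))
}

#' Gray level run length (GLRLM) features
#'
#' Run-length matrices per the 13 directions, features averaged over
#' directions: `GrayLevelNonUniformity = sum_i (sum_j R(i,j))^2 / N_runs`
#' and `RunEntropy` over the normalized matrix.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector (`glrlm_*`).
#' @export
glrlm_features <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  ng <- d$n_levels
  counts <- .cpp_glrlm_counts(as.vector(d$levels), dim(d$levels), ng)
  nd <- length(counts) / (13L * ng)
  dim(counts) <- c(ng, nd, 13L)
  per_dir <- lapply(seq_len(13L), function(k) {
    R <- counts[, , k, drop = FALSE]
    dim(R) <- c(ng, nd)
    nr <- sum(R)
    if (nr == 0) return(NULL)
    c(GrayLevelNonUniformity = sum(rowSums(R)^2) / nr,
      RunEntropy = log2p(R / nr))
  })
  per_dir <- per_dir[!vapply(per_dir, is.null, TRUE)]
  out <- rowMeans(do.call(cbind, per_dir))
  stats::setNames(out, paste0("glrlm_", names(out)))
}

#' Gray level size zone (GLSZM) features
#'
#' Zones are 26-connected components of equal gray level (a single matrix,
#' no directions). `GrayLevelVariance = sum p(i,s) (i - mu)^2`;
#' `GrayLevelNonUniformityNormalized = sum_i (sum_s Z(i,s))^2 / N_z^2`.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector (`glszm_*`).
#' @export
glszm_features <- function(d) {
  z <- glszm_zones(d)
  nz <- nrow(z)
  p_level <- tabulate(z$level, nbins = d$n_levels) / nz
  mu <- sum(seq_len(d$n_levels) * p_level)
  c(glszm_GrayLevelVariance = sum((z$level - mu)^2) / nz,
    glszm_GrayLevelNonUniformityNormalized =
      sum(tabulate(z$level, nbins = d$n_levels)^2) / nz^2)
}

# data.frame of zones: gray level and size of each 26-connected equal-level
# component
glszm_zones <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  lv <- d$levels
  zones <- list()
  for (g in seq_len(d$n_levels)) {
    sel <- lv == g
    if (!any(sel)) next
    labels <- .cpp_label_components(as.vector(sel), dim(lv), 26L)
    sizes <- tabulate(labels)
    zones[[length(zones) + 1L]] <-
      data.frame(level = g, size = sizes[sizes > 0])
  }
  do.call(rbind, zones)
}

#' Gray level dependence (GLDM) features
#'
#' A voxel's dependence is the number of its 26-neighbors inside the ROI
#' with the same gray level (tolerance alpha = 0).
#' `GrayLevelNonUniformity = sum_i (sum_j D(i,j))^2 / N_d` where `N_d` is
#' the ROI voxel count.
#'
#' @inheritParams glcm_features
#' @param alpha Gray-level difference tolerance for dependence (default 0).
#' @return Named numeric vector (`gldm_*`).
#' @export
gldm_features <- function(d, alpha = 0L) {
  stopifnot(inherits(d, "discretized_roi"))
  D <- .cpp_gldm_counts(as.vector(d$levels), dim(d$levels), d$n_levels,
                        as.integer(alpha))
  nd <- sum(D)
  c(gldm_GrayLevelNonUniformity = sum(rowSums(D)^2) / nd)
}

#' Neighboring gray tone difference (NGTDM) features
#'
#' `s_i` sums `|i - mean gray level of in-ROI 26-neighbors|` over voxels of
#' level `i` (voxels with no in-ROI neighbor are excluded);
#' `Coarseness = 1 / sum_i p_i s_i`, capped at 1e6 when the denominator is
#' zero (e.g., a constant ROI).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector (`ngtdm_*`).
#' @export
ngtdm_features <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  sums <- .cpp_ngtdm_sums(as.vector(d$levels), dim(d$levels), d$n_levels)
  nv <- sum(sums$n)
  denom <- if (nv > 0) sum(sums$n / nv * sums$s) else 0
  coarse <- if (denom > 0) min(1 / denom, 1e6) else 1e6
  if (denom <= 0)
    message("NGTDM Coarseness denominator is 0 (uniform ROI); capped at 1e6")
  c(ngtdm_Coarseness = coarse)
}

#' Extract all supported radiomic features
#'
#' Runs every feature family (first-order, shape, GLCM, GLRLM, GLSZM, GLDM,
#' NGTDM) on an image--mask pair after fixed-bin-size discretization at
#' `cfg$bin_width_hu`. The pair must be on a common grid; if the grid is not
#' isotropic at `cfg$voxel_size_mm`, both image and mask are resampled first
#' (trilinear / nearest). Deterministic: identical inputs give identical
#' vectors.
#'
#' @param img An [image_volume()].
#' @param mask A [binary_mask()] on the same grid.
#' @param cfg A [run_config()]; `feature_list` restricts the output if set.
#' @return Named numeric vector of features.
#' @export
extract_all <- function(img, mask, cfg = run_config()) {
  check_aligned(img, mask)
  if (max(abs(img$spacing - cfg$voxel_size_mm)) >= 1e-9) {
    img <- resample_isotropic(img, cfg$voxel_size_mm)
    mask <- resample_isotropic(mask, cfg$voxel_size_mm)
  }
  d <- discretize(img, mask, cfg$bin_width_hu)
  out <- c(first_order_features(img, mask, cfg$bin_width_hu),
           shape_features(mask),
           suppressMessages(glcm_features(d)),
           glrlm_features(d),
           glszm_features(d),
           gldm_features(d),
           suppressMessages(ngtdm_features(d)))
  if (!is.null(cfg$feature_list)) {
    missing <- setdiff(cfg$feature_list, names(out))
    if (length(missing))
      stop("unsupported features requested: ",
           paste(missing, collapse = ", "), call. = FALSE)
    out <- out[cfg$feature_list]
  }
  if (any(!is.finite(out)))
    stop("non-finite feature value(s): ",
         paste(names(out)[!is.finite(out)], collapse = ", "), call. = FALSE)
  out
}
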