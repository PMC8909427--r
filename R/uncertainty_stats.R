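#' Cohen's d effect size
#'
#' Standardized absolute mean difference between two groups of biomarker
#' values, with the pooled standard deviation weighted by `(n - 1)`:
#' `|mean(A) - mean(B)| / sqrt(((nA-1) sA^2 + (nB-1) sB^2) / (nA+nB-2))`.
#' Symmetric in its arguments and non-negative.
#'
#' @param A,B Numeric vectors of biomarker values (each of length >= 2).
#' @return Non-negative effect size.
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))  # pooled SD 1, d = 2
#' @export
cohens_d <- function(A, B) {
  A <- as.numeric(A); B <- as.numeric(B)
  nA <- length(A); nB <- length(B)
  if (nA < 2 || nB < 2)
    stop("both groups need at least 2 values", call. = FALSE)
  pooled <- ((nA - 1) * stats::var(A) + (nB - 1) * stats::var(B)) /
    (nA + nB - 2)
  if (pooled <= 0)
    stop("undefined effect size: zero pooled variance", call. = FALSE)
  abs(mean(A) - mean(B)) / sqrt(pooled)
}

#' Total intra-patient variance from protocol components
#'
#' Combines the variance contributions of the acquisition, segmentation and
#' processing protocols, including their pairwise covariances:
#' `s2_total = s2_acq + s2_seg + s2_proc
#'             + 2 cov_acq_seg + 2 cov_acq_proc + 2 cov_seg_proc`.
#' Only the segmentation component is simulated by this package; the others
#' are accepted as externally estimated inputs.
#'
#' @param s2_acq,s2_seg,s2_proc Component variances (>= 0).
#' @param cov_acq_seg,cov_acq_proc,cov_seg_proc Pairwise covariances.
#' @return Total intra-patient variance (>= 0).
#' @export
combine_variances <- function(s2_acq = 0, s2_seg = 0, s2_proc = 0,
                              cov_acq_seg = 0, cov_acq_proc = 0,
                              cov_seg_proc = 0) {
  if (any(c(s2_acq, s2_seg, s2_proc) < 0))
    stop("component variances must be >= 0", call. = FALSE)
  total <- s2_acq + s2_seg + s2_proc +
    2 * (cov_acq_seg + cov_acq_proc + cov_seg_proc)
  if (total < 0)
    stop("inconsistent covariances: total variance is negative",
         call. = FALSE)
  total
}

#' General uncertainty-to-effect ratio
#'
#' The ratio of the expected intra-patient dispersion of a biomarker to its
#' between-patient effect, the latter measured as the 0.25--0.75
#' interquartile range of the cohort values (under a median stratification
#' the two class medians sit near those quartiles). A value near 1 means
#' protocol-induced uncertainty is comparable to the effect the biomarker is
#' supposed to detect. Note the general form divides an SD-like numerator by
#' an IQR denominator (heterogeneous dispersion measures, reported as
#' defined); the segmentation-specific [eta_segmentation()] is an IQR/IQR
#' ratio and therefore internally consistent.
#'
#' @param expected_intrapat_sd Expected intra-patient dispersion (>= 0).
#' @param effect_iqr Between-patient interquartile range (> 0).
#' @return eta >= 0.
#' @export
eta_general <- function(expected_intrapat_sd, effect_iqr) {
  if (!is.finite(effect_iqr) || effect_iqr <= 0)
    stop("undefined eta: effect IQR must be > 0", call. = FALSE)
  if (expected_intrapat_sd < 0)
    stop("intra-patient dispersion must be >= 0", call. = FALSE)
  expected_intrapat_sd / effect_iqr
}

#' Segmentation uncertainty-to-effect ratio per feature
#'
#' For one feature over a cohort of mask realizations:
#' numerator = median over patients of the within-patient IQR across
#' realizations (original mask included as realization 0); denominator = IQR
#' over patients of the within-patient medians; eta is their ratio.
#' Quantiles use linear interpolation (type 7). For Gaussian
#' within/between structure the 1.349 normal-IQR factors cancel and eta
#' estimates the ratio of within-patient to between-patient SD. A zero
#' denominator (no between-patient effect) yields a flagged undefined
#' estimate, never a silent 0 or Inf.
#'
#' @param fr A [feature_realizations()] with >= 2 patients and >= 2
#'   realizations per patient.
#' @param feature Feature name (or index) to evaluate.
#' @return An `eta_estimate`: `eta`, `numerator_uncertainty`,
#'   `denominator_effect`, `defined`, `feature`.
#' @export
eta_segmentation <- function(fr, feature) {
  stopifnot(inherits(fr, "feature_realizations"))
  d <- dim(fr$values)
  if (d[1L] < 2L) stop("eta needs >= 2 patients", call. = FALSE)
  if (d[2L] < 2L) stop("eta needs >= 2 realizations per patient", call. = FALSE)
  x <- fr$values[, , feature, drop = TRUE]  # patients x realizations
  per_pat_iqr <- apply(x, 1L, function(v) stats::IQR(v, type = 7))
  per_pat_med <- apply(x, 1L, stats::median)
  num <- stats::median(per_pat_iqr)
  den <- stats::IQR(per_pat_med, type = 7)
  feature_name <- if (is.character(feature)) feature
                  else fr_features(fr)[feature]
  structure(list(eta = if (den > 0) num / den else NA_real_,
                 numerator_uncertainty = num,
                 denominator_effect = den,
                 defined = den > 0,
                 feature = feature_name),
            class = "eta_estimate")
}

#' @export
print.eta_estimate <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<eta_estimate> %s: eta = %.4f (uncertainty %.4g / effect %.4g)\n",
                x$feature, x$eta, x$numerator_uncertainty,
                x$denominator_effect))
  else
    cat(sprintf("<eta_estimate> %s: undefined (zero between-patient effect)\n",
                x$feature))
  invisible(x)
}

#' eta for every feature of a realization table
#'
#' @inheritParams eta_segmentation
#' @return A data.frame with columns `feature`, `eta`, `numerator`,
#'   `denominator`, `defined`, sorted by descending eta (undefined last).
#' @export
eta_table <- function(fr) {
  rows <- lapply(fr_features(fr), function(f) {
    e <- eta_segmentation(fr, f)
    data.frame(feature = f, eta = e$eta, numerator = e$numerator_uncertainty,
               denominator = e$denominator_effect, defined = e$defined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$eta, out$feature, na.last = TRUE), , drop = FALSE]
}

#' Select the k most and least perturbation-sensitive features
#'
#' Ranks features by eta and returns the `k` smallest (robust, "low eta"
#' setup) and `k` largest (sensitive, "high eta" setup). Ties are broken by
#' feature name (lexicographic); features with undefined eta are excluded
#' with a warning.
#'
#' @param etas An [eta_table()] data.frame, or a named numeric vector of eta
#'   values.
#' @param k Number of features per list.
#' @return A list with `low` (ascending eta) and `high` (descending eta)
#'   character vectors of feature names.
#' @export
rank_features <- function(etas, k = 4L) {
  if (is.numeric(etas) && !is.null(names(etas)))
    etas <- data.frame(feature = names(etas), eta = as.numeric(etas),
                       defined = is.finite(etas), stringsAsFactors = FALSE)
  if (any(!etas$defined)) {
    warning("excluding ", sum(!etas$defined),
            " feature(s) with undefined eta from ranking", call. = FALSE)
    etas <- etas[etas$defined, , drop = FALSE]
  }
  if (nrow(etas) < 2L * k)
    stop("need at least 2k = ", 2L * k, " features with defined eta",
         call. = FALSE)
  asc <- etas[order(etas$eta, etas$feature), , drop = FALSE]
  list(low = asc$feature[seq_len(k)],
       high = rev(asc$feature)[seq_len(k)])
}

#' Per-patient stratification agreement delta
#'
#' From the class labels assigned to one patient's mask realizations under a
#' fixed model: `delta = (#majority - #minority) / (#majority + #minority)`,
#' where the minority count pools every non-majority label. 1 means the
#' model labels the patient identically across all realizations; 0 means an
#' even split. An agreement rate of 80% corresponds to delta = 0.6.
#'
#' @param labels Vector of class labels (any atomic type), one per
#'   realization.
#' @return An `agreement_record`: `n_majority`, `n_minority`, `delta`.
#' @export
agreement_delta <- function(labels) {
  if (!length(labels)) stop("empty label list", call. = FALSE)
  counts <- table(labels)
  n_maj <- max(counts)
  n_min <- sum(counts) - n_maj
  structure(list(n_majority = as.integer(n_maj),
                 n_minority = as.integer(n_min),
                 delta = (n_maj - n_min) / (n_maj + n_min)),
            class = "agreement_record")
}

#' @export
print.agreement_record <- function(x, ...) {
  cat(sprintf("<agreement_record> %d majority / %d minority, delta = %.4f\n",
              x$n_majority, x$n_minority, x$delta))
  invisible(x)
}
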