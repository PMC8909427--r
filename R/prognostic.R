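#' Preprocess feature tables for Cox modeling
#'
#' Per feature: if the training minimum is <= 0, shift by
#' `1 - min_train`; log-transform; standardize by the training mean and SD.
#' Patients with any `|z| > 3` (an outlier in any covariate) are flagged for
#' exclusion from that realization's fit or scoring. Test values are
#' transformed with the training parameters only; test values that are
#' non-positive after the training shift are clamped to a tiny positive
#' value (they end up as extreme z and are excluded as outliers).
#'
#' @param train,test Numeric matrices `patients x features` of raw feature
#'   values (test may be NULL).
#' @return A list: `train_z`, `test_z` (standardized matrices), `train_keep`,
#'   `test_keep` (logical, FALSE = excluded outlier), `params` (per-feature
#'   `shift`, `mean`, `sd`).
#' @export
preprocess_features <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2L) stop("need >= 2 training patients", call. = FALSE)
  shift <- apply(train, 2L, function(x) if (min(x) <= 0) 1 - min(x) else 0)
  lg_train <- log(sweep(train, 2L, shift, "+"))
  mu <- colMeans(lg_train)
  sd <- apply(lg_train, 2L, stats::sd)
  if (any(sd <= 0 | !is.finite(sd)))
    stop("degenerate feature (zero training SD): ",
         paste(colnames(train)[sd <= 0 | !is.finite(sd)], collapse = ", "),
         call. = FALSE)
  params <- list(shift = shift, mean = mu, sd = sd)
  train_z <- transform_with_params(train, params)
  out <- list(train_z = train_z,
              train_keep = rowSums(abs(train_z) > 3) == 0,
              params = params)
  if (!is.null(test)) {
    test_z <- transform_with_params(as.matrix(test), params)
    out$test_z <- test_z
    out$test_keep <- rowSums(abs(test_z) > 3) == 0
  }
  out
}

transform_with_params <- function(X, params) {
  xs <- sweep(as.matrix(X), 2L, params$shift, "+")
  xs[xs <= 0] <- 1e-8
  sweep(sweep(log(xs), 2L, params$mean, "-"), 2L, params$sd, "/")
}

#' Fit a Cox model and derive the median-stratification threshold
#'
#' Fits a Cox proportional-hazards model (partial likelihood, via
#' [survival::coxph()]) on the standardized training covariates, and sets the
#' stratification threshold to the median linear predictor (log relative
#' hazard) over the training patients. Thresholding the linear predictor at
#' its median is identical to thresholding the hazard ratio at its median,
#' by monotonicity of `exp`.
#'
#' @param train_z Standardized covariate matrix `patients x features`.
#' @param surv Survival data.frame (`time_days`, `event`) aligned with the
#'   rows of `train_z`.
#' @param params Optional preprocessing parameters to carry along for later
#'   scoring of raw feature values.
#' @return A `cox_model_fit`: `coefficients`, `training_median_score`,
#'   `preprocessing_params`.
#' @export
fit_and_threshold <- function(train_z, surv, params = NULL) {
  train_z <- as.matrix(train_z)
  if (nrow(train_z) != nrow(surv))
    stop("covariates and survival rows do not match", call. = FALSE)
  if (sum(surv$event) == 0)
    stop("no events in training data", call. = FALSE)
  df <- data.frame(time = surv$time_days, event = surv$event,
                   train_z, check.names = FALSE)
  fit <- survival::coxph(
    survival::Surv(time, event) ~ .,
    data = df[, c("time", "event", colnames(train_z))])
  beta <- stats::coef(fit)
  if (any(is.na(beta)))
    stop("Cox fit failed (singular covariates): ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  scores <- as.vector(train_z %*% beta)
  structure(list(coefficients = beta,
                 training_median_score = stats::median(scores),
                 preprocessing_params = params),
            class = "cox_model_fit")
}

#' @export
print.cox_model_fit <- function(x, ...) {
  cat("<cox_model_fit> coefficients:\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("  training median score: %.4f\n", x$training_median_score))
  invisible(x)
}

# linear predictor of raw feature values under a fitted model
score_raw <- function(model, X_raw) {
  z <- transform_with_params(X_raw, model$preprocessing_params)
  as.vector(z %*% model$coefficients)
}

#' Stratify a test cohort and run the log-rank test
#'
#' Labels a patient high-risk iff the linear predictor exceeds the model's
#' training median score, then compares the survival of the two strata with
#' the two-sample log-rank test ([survival::survdiff()]). If all patients
#' fall in one stratum the result is flagged degenerate (statistic and p
#' are NA).
#'
#' @param model A [fit_and_threshold()] result.
#' @param test_z Standardized test covariates.
#' @param surv Test survival data.frame aligned with `test_z` rows.
#' @return A list: `logrank_statistic`, `p_value`, `labels` (logical
#'   high-risk), `degenerate`.
#' @export
stratify_and_test <- function(model, test_z, surv) {
  scores <- as.vector(as.matrix(test_z) %*% model$coefficients)
  labels <- scores > model$training_median_score
  if (length(unique(labels)) < 2L)
    return(list(logrank_statistic = NA_real_, p_value = NA_real_,
                labels = labels, degenerate = TRUE))
  lr <- logrank_test(surv$time_days, surv$event, labels)
  list(logrank_statistic = lr$statistic, p_value = lr$p_value,
       labels = labels, degenerate = FALSE)
}

# two-sample log-rank via survdiff; chi-square statistic on 1 df
logrank_test <- function(time, event, group) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = sd$chisq,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Sample one feature-table realization per patient
#'
#' Independently for each patient, picks one realization index uniformly at
#' random (with replacement across iterations) from the patient's available
#' realizations and returns the corresponding `patients x features` matrix.
#' Randomness is taken from R's current RNG stream.
#'
#' @param fr A [feature_realizations()].
#' @return Numeric matrix `patients x features` (rownames = patients).
#' @export
sample_realization <- function(fr) {
  v <- fr$values
  d <- dim(v)
  idx <- sample.int(d[2L], d[1L], replace = TRUE)
  out <- matrix(NA_real_, d[1L], d[3L],
                dimnames = list(dimnames(v)[[1L]], dimnames(v)[[3L]]))
  for (p in seq_len(d[1L])) out[p, ] <- v[p, idx[p], ]
  out
}

#' Keep only the original (unperturbed) realization
#'
#' @param fr A [feature_realizations()].
#' @return A [feature_realizations()] with a single realization (index 0).
#' @export
fr_original <- function(fr) {
  feature_realizations(fr$values[, 1L, , drop = FALSE])
}

align_survival <- function(surv, patients) {
  m <- match(patients, surv$patient_id)
  if (any(is.na(m)))
    stop("survival table is missing patients: ",
         paste(patients[is.na(m)], collapse = ", "), call. = FALSE)
  surv[m, , drop = FALSE]
}

#' Run the prognostic-model stability simulation
#'
#' The core stress test: for each of `n_sim` iterations, draw one mask
#' realization per patient in both cohorts, preprocess (log, standardize,
#' 3-sigma outlier exclusion), fit the Cox model with median-threshold on
#' the training cohort, stratify the test cohort and record the log-rank
#' statistic and p-value. Reports the fraction of iterations with p below
#' `alpha`, selects the ensemble model (the iteration whose coefficients are
#' closest in least squares to the element-wise coefficient medians), scores
#' it on `n_sim` fresh test-cohort realizations with per-patient score
#' averaging, and measures every test patient's stratification agreement
#' delta under the fixed ensemble model.
#'
#' Per-iteration RNG streams are derived from `seed` and the iteration
#' index, so changing `n_sim` never reshuffles earlier iterations.
#' Individual iteration failures (degenerate features, empty strata) are
#' recorded, not fatal; more than 10% failures aborts the run.
#'
#' @param fr_train,fr_test [feature_realizations()] for the two cohorts.
#' @param surv_train,surv_test Survival data.frames
#'   (`patient_id`, `time_days`, `event`).
#' @param features Character vector of covariate feature names (typically 4).
#' @param n_sim Number of pipeline iterations.
#' @param seed Master seed.
#' @param alpha Significance level for the "significant realization" count.
#' @return A `simulation_result`: `records` (per-iteration data.frame),
#'   `fraction_significant`, `ensemble_model`, `ensembled` (averaged-score
#'   result), `agreement` (per-patient delta data.frame), `n_simulations`.
#' @export
run_simulation <- function(fr_train, surv_train, fr_test, surv_test,
                           features, n_sim = 1000L, seed = 1L,
                           alpha = 0.05) {
  fr_train <- fr_select(fr_train, features)
  fr_test <- fr_select(fr_test, features)
  surv_train <- align_survival(surv_train, fr_patients(fr_train))
  surv_test <- align_survival(surv_test, fr_patients(fr_test))

  models <- vector("list", n_sim)
  records <- data.frame(iteration = seq_len(n_sim),
                        logrank_statistic = NA_real_, p_value = NA_real_,
                        ok = FALSE)
  coefs <- matrix(NA_real_, n_sim, length(features),
                  dimnames = list(NULL, features))
  for (i in seq_len(n_sim)) {
    set.seed(derive_seed(seed, i))
    res <- tryCatch({
      x_train <- sample_realization(fr_train)
      x_test <- sample_realization(fr_test)
      pp <- preprocess_features(x_train, x_test)
      model <- fit_and_threshold(pp$train_z[pp$train_keep, , drop = FALSE],
                                 surv_train[pp$train_keep, , drop = FALSE],
                                 params = pp$params)
      st <- stratify_and_test(model,
                              pp$test_z[pp$test_keep, , drop = FALSE],
                              surv_test[pp$test_keep, , drop = FALSE])
      if (st$degenerate) stop("degenerate stratification (single stratum)")
      list(model = model, st = st)
    }, error = function(e) e)
    if (!inherits(res, "error")) {
      models[[i]] <- res$model
      records$logrank_statistic[i] <- res$st$logrank_statistic
      records$p_value[i] <- res$st$p_value
      records$ok[i] <- TRUE
      coefs[i, ] <- res$model$coefficients
    }
  }
  n_fail <- sum(!records$ok)
  if (n_fail > 0.1 * n_sim)
    stop("simulation aborted: ", n_fail, "/", n_sim,
         " iterations failed", call. = FALSE)

  ok <- which(records$ok)
  ensemble <- select_ensemble(models[ok])
  ens <- ensembled_scores(ensemble, fr_test, surv_test,
                          n_sim = n_sim, seed = derive_seed(seed, n_sim + 1L))
  agreement <- do.call(rbind, lapply(fr_patients(fr_test), function(p) {
    a <- patient_agreement(ensemble, fr_test, p)
    data.frame(patient_id = p, n_majority = a$n_majority,
               n_minority = a$n_minority, delta = a$delta,
               stringsAsFactors = FALSE)
  }))

  structure(list(records = records,
                 coefficients = coefs,
                 fraction_significant = mean(records$p_value[ok] < alpha),
                 ensemble_model = ensemble,
                 ensembled = ens,
                 agreement = agreement,
                 n_simulations = as.integer(n_sim),
                 alpha = alpha),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", x$n_simulations, " pipeline iterations (",
      sum(!x$records$ok), " failed)\n", sep = "")
  cat(sprintf("  fraction significant (p < %.2f): %.3f\n",
              x$alpha, x$fraction_significant))
  cat(sprintf("  ensembled model log-rank p: %.4g\n", x$ensembled$p_value))
  cat(sprintf("  median patient agreement delta: %.3f\n",
              stats::median(x$agreement$delta)))
  invisible(x)
}

#' Select the ensemble model
#'
#' Takes the element-wise median of the coefficient vectors across the
#' fitted models and returns the model minimizing the sum of squared
#' deviations from those medians (first index on ties).
#'
#' @param models Non-empty list of [fit_and_threshold()] results with equal
#'   covariate sets.
#' @return One member of `models`.
#' @export
select_ensemble <- function(models) {
  if (!length(models)) stop("empty model list", call. = FALSE)
  coefs <- do.call(rbind, lapply(models, function(m) m$coefficients))
  med <- apply(coefs, 2L, stats::median)
  ss <- rowSums(sweep(coefs, 2L, med, "-")^2)
  models[[which.min(ss)]]
}

#' Ensembled per-patient scoring
#'
#' Scores `n_sim` sampled test-cohort realizations with one fixed model
#' (its preprocessing parameters and threshold included), averages the
#' linear predictor per patient, labels patients against the model's
#' training median score, and reports the log-rank test of the resulting
#' stratification. Averaging on the linear-predictor scale reduces the
#' per-patient score variance relative to single realizations.
#'
#' @param model A fixed [fit_and_threshold()] result carrying preprocessing
#'   parameters.
#' @param fr Test-cohort [feature_realizations()] (restricted to the model's
#'   covariates).
#' @param surv Test survival data.frame.
#' @param n_sim Number of realization draws to average.
#' @param seed Seed for the draws.
#' @return A list: `scores` (named per-patient averaged linear predictor),
#'   `labels`, `logrank_statistic`, `p_value`, `degenerate`.
#' @export
ensembled_scores <- function(model, fr, surv, n_sim = 1000L, seed = 1L) {
  fr <- fr_select(fr, names(model$coefficients))
  surv <- align_survival(surv, fr_patients(fr))
  acc <- numeric(length(fr_patients(fr)))
  for (i in seq_len(n_sim)) {
    set.seed(derive_seed(seed, i))
    acc <- acc + score_raw(model, sample_realization(fr))
  }
  scores <- stats::setNames(acc / n_sim, fr_patients(fr))
  labels <- scores > model$training_median_score
  if (length(unique(labels)) < 2L)
    return(list(scores = scores, labels = labels,
                logrank_statistic = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  lr <- logrank_test(surv$time_days, surv$event, labels)
  list(scores = scores, labels = labels,
       logrank_statistic = lr$statistic, p_value = lr$p_value,
       degenerate = FALSE)
}

#' Per-patient agreement under a fixed model
#'
#' Classifies every mask realization of one patient with a fixed model and
#' threshold and summarizes the label counts as an [agreement_delta()]
#' record. No outlier exclusion is applied here: every realization receives
#' a label.
#'
#' @inheritParams ensembled_scores
#' @param patient Patient id present in `fr`.
#' @return An `agreement_record`.
#' @export
patient_agreement <- function(model, fr, patient) {
  fr <- fr_select(fr, names(model$coefficients))
  if (!patient %in% fr_patients(fr))
    stop("unknown patient: ", patient, call. = FALSE)
  X <- fr$values[patient, , , drop = TRUE]
  if (is.null(dim(X))) X <- matrix(X, ncol = dim(fr$values)[3L])
  colnames(X) <- fr_features(fr)
  scores <- score_raw(model, X)
  agreement_delta(scores > model$training_median_score)
}
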