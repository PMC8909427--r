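# small reusable synthetic cohort
make_cohort <- function(n, seed, sw = 0.2) {
  feats <- data.frame(name = paste0("f", 1:4), mean = 10, sigma_b = 1,
                      sigma_w = sw)
  make_feature_table(n, 40, feats, seed = seed)
}

test_that("preprocessing shifts, logs, standardizes and flags outliers", {
  set.seed(2)
  train <- cbind(f1 = rnorm(50, 10), f2 = exp(rnorm(50)))
  pp <- preprocess_features(train)
  expect_equal(colMeans(pp$train_z), c(f1 = 0, f2 = 0), tolerance = 1e-12)
  expect_equal(apply(pp$train_z, 2, sd), c(f1 = 1, f2 = 1), tolerance = 1e-12)
  # positive training minimum -> no shift; value at the mean gives z = 0
  expect_equal(unname(pp$params$shift), c(0, 0))

  # features crossing zero get shifted so the log is defined
  train2 <- cbind(f1 = rnorm(50, 0, 1))
  pp2 <- preprocess_features(train2)
  expect_equal(unname(pp2$params$shift), 1 - min(train2[, 1]))
  expect_true(all(is.finite(pp2$train_z)))

  # planted extreme outlier is flagged for exclusion
  mu <- pp$params$mean; sdv <- pp$params$sd; sh <- pp$params$shift
  planted <- c(exp(mu[1] + 4 * sdv[1]) - sh[1], 10)
  pp3 <- preprocess_features(train, rbind(planted, c(10, 1.2)))
  expect_false(pp3$test_keep[1])

  expect_error(preprocess_features(cbind(f1 = rep(2, 10))), "degenerate")
})

test_that("Cox fit matches an independent partial-likelihood optimizer", {
  set.seed(8)
  n <- 80
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  lp <- X %*% c(0.8, -0.5)
  time <- rexp(n, exp(lp) / 50)
  surv <- data.frame(time_days = time, event = 1L)
  fit <- fit_and_threshold(X, surv)
  ref <- oracle_cox_fit(X, time, rep(1, n))
  expect_equal(unname(fit$coefficients), ref, tolerance = 1e-4)
  expect_equal(fit$training_median_score,
               median(as.vector(X %*% fit$coefficients)))
})

test_that("Cox fit recovers designed coefficients and nulls", {
  set.seed(91)
  n <- 500
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
  surv <- make_survival(X, beta = 1, censor_rate = 0, seed = 14)
  fit <- fit_and_threshold(X, surv)
  expect_equal(unname(fit$coefficients), 1, tolerance = 0.15)

  # pure-noise covariate: coefficient near zero
  surv0 <- make_survival(X, beta = 0, censor_rate = 0, seed = 15)
  Xn <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "noise"))
  fit0 <- fit_and_threshold(Xn, surv0)
  expect_lt(abs(unname(fit0$coefficients)), 0.15)
})

test_that("log-rank agrees with the observed-minus-expected oracle", {
  # textbook fixture: group 1 times {3+, 5, 7}, group 2 {1, 4, 8+}
  time <- c(3, 5, 7, 1, 4, 8)
  event <- c(0, 1, 1, 1, 1, 0)
  group <- c(1, 1, 1, 2, 2, 2)
  got <- segstab:::logrank_test(time, event, group)
  want <- oracle_logrank(time, event, group)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-9)

  set.seed(33)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    time <- round(rexp(n, 0.1), 1) + 0.1
    event <- rbinom(n, 1, 0.7)
    group <- c(rep(1, 3), rbinom(n - 3, 1, 0.5))  # guarantee two groups
    if (length(unique(group)) < 2 || sum(event) == 0) next
    got <- segstab:::logrank_test(time, event, group)
    want <- oracle_logrank(time, event, group)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  }
})

test_that("identical survival in both strata gives a null log-rank", {
  base <- data.frame(time_days = c(5, 8, 12, 20), event = c(1, 1, 0, 1))
  surv <- rbind(base, base)
  model <- structure(list(coefficients = c(f = 1),
                          training_median_score = 0),
                     class = "cox_model_fit")
  z <- matrix(c(rep(-1, 4), rep(1, 4)), ncol = 1,
              dimnames = list(NULL, "f"))
  res <- stratify_and_test(model, z, surv)
  expect_equal(res$logrank_statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
})

test_that("strongly separated groups are detected nearly always", {
  set.seed(55)
  hits <- 0
  for (i in 1:20) {
    n <- 200
    x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
    surv <- make_survival(x, beta = log(3), censor_rate = 0.2,
                          seed = 1000 + i)
    model <- structure(list(coefficients = c(x = 1),
                            training_median_score = median(x)),
                       class = "cox_model_fit")
    res <- stratify_and_test(model, x, surv)
    if (res$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("realization sampling is uniform, deterministic and degenerate-safe", {
  fr <- make_cohort(30, seed = 21)
  set.seed(5); s1 <- sample_realization(fr)
  set.seed(5); s2 <- sample_realization(fr)
  expect_identical(s1, s2)
  expect_equal(rownames(s1), fr_patients(fr))

  # single-realization table always returns the original
  fr0 <- fr_original(fr)
  expect_equal(sample_realization(fr0), fr$values[, 1, ], tolerance = 0)

  # index frequencies are roughly uniform over many draws
  feats <- data.frame(name = "f", mean = 0, sigma_b = 0, sigma_w = 1)
  tiny <- make_feature_table(1, 9, feats, seed = 3)
  tiny$values[1, , 1] <- 1:10  # identify realizations by value
  set.seed(9)
  draws <- replicate(5000, sample_realization(tiny)[1, 1])
  freq <- table(draws) / 5000
  expect_lt(suppressWarnings(
    chisq.test(table(factor(draws, levels = 1:10)))$statistic), 27)
})

test_that("select_ensemble picks the coefficient-median least-squares model", {
  mk <- function(b) structure(list(coefficients = b,
                                   training_median_score = 0),
                              class = "cox_model_fit")
  models <- list(mk(c(x = 0.9)), mk(c(x = 1.0)), mk(c(x = 5.0)))
  expect_equal(select_ensemble(models)$coefficients, c(x = 1.0))
  expect_identical(select_ensemble(models[1]), models[[1]])
  # ties -> first index
  dup <- list(mk(c(x = 2)), mk(c(x = 2)))
  expect_identical(select_ensemble(dup), dup[[1]])
  expect_error(select_ensemble(list()), "empty")
  # always a member of its input
  set.seed(3)
  many <- lapply(1:9, function(i) mk(c(x = rnorm(1), y = rnorm(1))))
  got <- select_ensemble(many)
  expect_true(any(vapply(many, identical, TRUE, got)))
})

test_that("simulation with originals only reproduces the baseline exactly", {
  fr_tr <- make_cohort(60, seed = 41)
  fr_te <- make_cohort(40, seed = 42)
  sv_tr <- make_survival(fr_tr, beta = rep(0.4, 4), seed = 43)
  sv_te <- make_survival(fr_te, beta = rep(0.4, 4), seed = 44)
  sim <- run_simulation(fr_original(fr_tr), sv_tr, fr_original(fr_te), sv_te,
                        paste0("f", 1:4), n_sim = 1, seed = 77)
  # baseline pipeline assembled by hand from the module operations
  pp <- preprocess_features(fr_tr$values[, 1, ], fr_te$values[, 1, ])
  model <- fit_and_threshold(pp$train_z[pp$train_keep, , drop = FALSE],
                             sv_tr[pp$train_keep, , drop = FALSE],
                             pp$params)
  st <- stratify_and_test(model, pp$test_z[pp$test_keep, , drop = FALSE],
                          sv_te[pp$test_keep, , drop = FALSE])
  expect_identical(sim$records$p_value[1], st$p_value)
  expect_identical(sim$records$logrank_statistic[1], st$logrank_statistic)
  expect_identical(unname(sim$coefficients[1, ]),
                   unname(model$coefficients))
})

test_that("zero intra-patient noise collapses all realization p-values", {
  fr_tr <- make_cohort(60, seed = 51, sw = 0)
  fr_te <- make_cohort(40, seed = 52, sw = 0)
  sv_tr <- make_survival(fr_tr, beta = rep(0.4, 4), seed = 53)
  sv_te <- make_survival(fr_te, beta = rep(0.4, 4), seed = 54)
  sim <- run_simulation(fr_tr, sv_tr, fr_te, sv_te, paste0("f", 1:4),
                        n_sim = 8, seed = 5)
  expect_equal(length(unique(sim$records$p_value)), 1L)
  expect_true(sim$fraction_significant %in% c(0, 1))
})

test_that("run_simulation is reproducible and stream-stable in n_sim", {
  fr_tr <- make_cohort(50, seed = 61)
  fr_te <- make_cohort(35, seed = 62)
  sv_tr <- make_survival(fr_tr, beta = rep(0.3, 4), seed = 63)
  sv_te <- make_survival(fr_te, beta = rep(0.3, 4), seed = 64)
  s1 <- run_simulation(fr_tr, sv_tr, fr_te, sv_te, paste0("f", 1:4),
                       n_sim = 6, seed = 12)
  s2 <- run_simulation(fr_tr, sv_tr, fr_te, sv_te, paste0("f", 1:4),
                       n_sim = 6, seed = 12)
  expect_identical(s1$records, s2$records)
  s3 <- run_simulation(fr_tr, sv_tr, fr_te, sv_te, paste0("f", 1:4),
                       n_sim = 3, seed = 12)
  expect_identical(s3$records$p_value, s1$records$p_value[1:3])
})

test_that("ensembled scoring averages per patient and reduces variance", {
  fr_te <- make_cohort(40, seed = 71, sw = 0.5)
  sv_te <- make_survival(fr_te, beta = rep(0.4, 4), seed = 72)
  pp <- preprocess_features(fr_te$values[, 1, ])
  model <- fit_and_threshold(pp$train_z, sv_te, pp$params)

  # zero noise: averaged score equals the single-realization score
  fr0 <- make_cohort(40, seed = 71, sw = 0)
  ens0 <- ensembled_scores(model, fr0, sv_te, n_sim = 5, seed = 3)
  single <- segstab:::score_raw(model, fr0$values[, 1, ])
  expect_equal(unname(ens0$scores), single, tolerance = 1e-12)

  # averaging shrinks the spread relative to single draws
  ens <- ensembled_scores(model, fr_te, sv_te, n_sim = 200, seed = 3)
  set.seed(4)
  one <- segstab:::score_raw(model, sample_realization(fr_te))
  base <- segstab:::score_raw(model, fr_te$values[, 1, ])
  expect_lt(sd(unname(ens$scores) - base), sd(one - base))

  # determinism
  ens2 <- ensembled_scores(model, fr_te, sv_te, n_sim = 200, seed = 3)
  expect_identical(ens$scores, ens2$scores)
})

test_that("patient agreement reflects distance from the threshold", {
  fr <- make_cohort(20, seed = 81, sw = 0.3)
  sv <- make_survival(fr, beta = rep(0.4, 4), seed = 82)
  pp <- preprocess_features(fr$values[, 1, ])
  model <- fit_and_threshold(pp$train_z, sv, pp$params)
  scores <- segstab:::score_raw(model, fr$values[, 1, ])
  far <- fr_patients(fr)[which.max(abs(scores - model$training_median_score))]
  a_far <- patient_agreement(model, fr, far)
  expect_equal(a_far$delta, 1)
  expect_equal(a_far$n_majority + a_far$n_minority, 41L)

  # a patient constructed to straddle the threshold 50/50
  fr2 <- fr
  z_at <- function(q) exp(model$preprocessing_params$mean +
                            q * model$preprocessing_params$sd) -
    model$preprocessing_params$shift
  lohi <- rbind(z_at(-2), z_at(2))
  fr2$values[1, , ] <- lohi[rep(1:2, length.out = 41), ]
  a <- patient_agreement(model, fr2, fr_patients(fr2)[1])
  expect_lt(a$delta, 0.1)
  expect_error(patient_agreement(model, fr, "nobody"), "unknown")
})
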