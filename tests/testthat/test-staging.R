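make_panel <- function(n = 400, p = 60, n_inf = 8, effect = 1.0,
                       seed = 50) {
  co <- simulate_cohort(n, c(0.3),
                        disease_model = list(intercept = 0, exact = TRUE),
                        seed = seed)
  list(panel = simulate_proteome(co, p, n_inf, effect, seed = seed + 1),
       cohort = co)
}

test_that("protein-disease association flags planted analytes", {
  mp <- make_panel(400, 40, 3, effect = 1.0)
  res <- protein_disease_assoc(mp$panel, age = mp$cohort$covariates$age,
                               sex = mp$cohort$covariates$sex)
  expect_equal(attr(res, "bonferroni"), 0.05 / 40)
  expect_true(all(res$significant[1:3]))
  expect_lt(sum(res$significant[-(1:3)]), 3)
  expect_error(
    protein_disease_assoc(mp$panel, diagnosis = rep(TRUE, 400),
                          age = mp$cohort$covariates$age,
                          sex = mp$cohort$covariates$sex),
    "cases")
})

test_that("preprocessing is fitted on training data only", {
  tr <- withr::with_seed(1, matrix(rnorm(300 * 5), 300, 5))
  te <- withr::with_seed(2, matrix(rnorm(100 * 5), 100, 5))
  colnames(tr) <- colnames(te) <- paste0("p", 1:5)

  pp <- preprocess_panel(tr, te)
  # already-normal input: transform close to identity
  expect_lt(max(abs(pp$params$lambda - 1)), 0.35)
  expect_lt(max(abs(pp$params$center)), 0.2)
  expect_equal(colMeans(pp$train), rep(0, 5), ignore_attr = TRUE,
               tolerance = 1e-12)

  # shifting the test partition must not change the fitted parameters
  pp_shift <- preprocess_panel(tr, te + 5)
  expect_identical(pp$params, pp_shift$params)

  # right-skewed input gets less skewed
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  xs <- withr::with_seed(3, matrix(rexp(500), 500, 1))
  colnames(xs) <- "s1"
  pp2 <- preprocess_panel(xs)
  expect_lt(abs(skew(pp2$train[, 1])), abs(skew(xs[, 1])) / 2)

  expect_error(preprocess_panel(xs - 5, log_first = TRUE), "positive")
})

test_that("shadow-feature selection finds signal and controls noise", {
  mp <- make_panel(400, 100, 10, effect = 1.0, seed = 70)
  sel <- shadow_feature_select(mp$panel$levels, mp$panel$labels,
                               n_iter = 40, seed = 71)
  expect_gte(length(intersect(sel, mp$panel$informative_ids)), 9L)
  expect_lte(length(setdiff(sel, mp$panel$informative_ids)), 2L)

  # pure-noise panel: almost nothing survives the FDR gate
  null_p <- make_panel(300, 80, 0, effect = 0, seed = 72)
  sel0 <- shadow_feature_select(null_p$panel$levels, null_p$panel$labels,
                                n_iter = 40, seed = 73)
  expect_lte(length(sel0), 2L)

  expect_error(shadow_feature_select(mp$panel$levels, mp$panel$labels,
                                     n_iter = 5, seed = 1), "20")
  expect_error(shadow_feature_select(mp$panel$levels,
                                     rep(TRUE, 400), n_iter = 20,
                                     seed = 1), "degenerate")
})

test_that("selection is stable across seeds on a strong-signal panel", {
  mp <- make_panel(400, 80, 10, effect = 1.0, seed = 90)
  s1 <- shadow_feature_select(mp$panel$levels, mp$panel$labels,
                              n_iter = 30, seed = 91)
  s2 <- shadow_feature_select(mp$panel$levels, mp$panel$labels,
                              n_iter = 30, seed = 92)
  jacc <- length(intersect(s1, s2)) / length(union(s1, s2))
  expect_gt(jacc, 0.6)
})

test_that("average precision matches a hand-computed enumeration", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  labels <- c(1, 0, 1, 1, 0)
  # by definition: precision at each positive hit, weighted by recall step
  # hits at ranks 1, 3, 4 -> AP = (1/1 + 2/3 + 3/4) / 3
  expect_equal(average_precision(scores, labels), (1 + 2 / 3 + 3 / 4) / 3)
  expect_equal(average_precision(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_lt(average_precision(c(1, 2, 3), c(1, 1, 0)), 1)
})

test_that("cross-validated evaluation is seed-deterministic", {
  mp <- make_panel(200, 25, 5, effect = 1.0, seed = 110)
  spec <- staging_model_spec(select = FALSE, alphas = 0.5,
                             tune_folds = 5)
  r1 <- evaluate_cv(spec, mp$panel, n_repeats = 2, folds = 5, seed = 111)
  r2 <- evaluate_cv(spec, mp$panel, n_repeats = 2, folds = 5, seed = 111)
  expect_identical(r1$per_repeat_aucs, r2$per_repeat_aucs)
  expect_gt(r1$mean_auc, 0.8)
  expect_error(evaluate_cv(spec, mp$panel, n_repeats = 1, seed = 1),
               "n_repeats")
})

test_that("the AUC s.e.m. shrinks with more repeats", {
  mp <- make_panel(200, 20, 4, effect = 0.6, seed = 130)
  spec <- staging_model_spec(select = FALSE, alphas = 0.5,
                             tune_folds = 5)
  r_small <- evaluate_cv(spec, mp$panel, n_repeats = 4, folds = 5,
                         seed = 131)
  r_big <- evaluate_cv(spec, mp$panel, n_repeats = 16, folds = 5,
                       seed = 131)
  expect_lt(r_big$sem_auc, r_small$sem_auc)
  expect_equal(r_big$sem_auc,
               sd(r_big$per_repeat_aucs) / sqrt(16), tolerance = 1e-12)
})

test_that("final staging model reports features, transforms and tuning", {
  mp <- make_panel(300, 40, 6, effect = 1.0, seed = 150)
  m <- fit_staging_model(mp$panel, spec = staging_model_spec(
    select = TRUE, select_n_iter = 25, alphas = c(0.5, 0.9),
    tune_folds = 5), seed = 151)
  expect_gte(length(intersect(m$selected_features,
                              mp$panel$informative_ids)), 5L)
  expect_true(all(is.finite(m$coefficients)))
  expect_true(m$tuning$alpha %in% c(0.5, 0.9))
  expect_length(m$transform_params$lambda, length(m$selected_features))

  # global-null panel collapses to an intercept-only model
  np <- make_panel(300, 40, 0, effect = 0, seed = 152)
  m0 <- fit_staging_model(np$panel, spec = staging_model_spec(
    select = TRUE, select_n_iter = 25), seed = 153)
  expect_length(m0$selected_features, 0L)
  expect_named(m0$coefficients, "(Intercept)")
})

test_that("baseline enzyme model tracks its planted signal", {
  co <- simulate_cohort(400, c(0.3),
                        disease_model = list(intercept = 0, exact = TRUE),
                        enzyme_effect = 0.8, seed = 170)
  cv <- baseline_model(co$covariates$age, co$covariates$sex,
                       co$covariates$bmi, co$traits$alt, co$traits$ast,
                       co$traits$ggt, co$diagnoses$disease,
                       n_repeats = 4, seed = 171)
  expect_gt(cv$mean_auc, 0.5 + 2 * cv$sem_auc)

  # labels independent of the covariates: chance-level AUC
  co0 <- simulate_cohort(400, c(0.3),
                         disease_model = list(intercept = 0, exact = TRUE),
                         enzyme_effect = 0, seed = 172)
  cv0 <- baseline_model(co0$covariates$age, co0$covariates$sex,
                        co0$covariates$bmi, co0$traits$alt,
                        co0$traits$ast, co0$traits$ggt,
                        co0$diagnoses$disease, n_repeats = 4,
                        seed = 173)
  expect_lt(abs(cv0$mean_auc - 0.5), 0.08)

  expect_error(baseline_model(co$covariates$age[-1], co$covariates$sex,
                              co$covariates$bmi, co$traits$alt,
                              co$traits$ast, co$traits$ggt,
                              co$diagnoses$disease, n_repeats = 2,
                              seed = 1),
               "mismatch")
})

test_that("out-of-fold protein scores separate cases from controls", {
  mp <- make_panel(200, 25, 5, effect = 1.0, seed = 190)
  sc <- oof_protein_scores(mp$panel,
                           spec = staging_model_spec(select = FALSE,
                                                     alphas = 0.5,
                                                     tune_folds = 5),
                           seed = 191)
  expect_gt(mean(sc[mp$panel$labels]), mean(sc[!mp$panel$labels]))
})
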