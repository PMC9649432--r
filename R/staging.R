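#' Per-analyte protein-disease association with Bonferroni control
#'
#' Logistic regression of the diagnosis on each standardised analyte with
#' age and sex as covariates; analytes are flagged significant at the
#' Bonferroni threshold `alpha / n_analytes`.
#'
#' @param panel An `hf_protein_panel` (or bare matrix of levels).
#' @param diagnosis Binary outcome (defaults to the panel's labels).
#' @param age,sex Covariate vectors.
#' @param alpha Family-wise error target (default 0.05).
#' @return Data frame: analyte, beta (log-OR per s.d.), se, p_value,
#'   separation flag, significant (Bonferroni), with the threshold in
#'   attribute `"bonferroni"`.
#' @export
protein_disease_assoc <- function(panel, diagnosis = NULL, age, sex,
                                  alpha = 0.05) {
  levels <- if (inherits(panel, "hf_protein_panel")) panel$levels else panel
  if (is.null(diagnosis) && inherits(panel, "hf_protein_panel")) {
    diagnosis <- panel$labels
  }
  y <- as.integer(diagnosis)
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("need at least 2 cases and 2 controls", call. = FALSE)
  }
  p <- ncol(levels)
  out <- data.frame(analyte = colnames(levels), beta = NA_real_,
                    se = NA_real_, p_value = NA_real_,
                    separation = FALSE)
  base <- data.frame(.y = y, age = as.numeric(age), sex = as.numeric(sex))
  for (j in seq_len(p)) {
    base$.x <- as.numeric(scale(levels[, j]))
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(.y ~ .x + age + sex, data = base,
                 family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    cf <- summary(fit)$coefficients[".x", ]
    out$beta[j] <- cf[1]; out$se[j] <- cf[2]; out$p_value[j] <- cf[4]
    out$separation[j] <- sep
  }
  thr <- alpha / p
  out$significant <- out$p_value < thr
  attr(out, "bonferroni") <- thr
  out
}

#' Train-fitted panel preprocessing (Yeo-Johnson + standardisation)
#'
#' Optionally log-transforms the levels, fits a per-feature Yeo-Johnson
#' power transform (lambda by maximum likelihood) and centering/scaling
#' on the TRAINING partition only, then applies the frozen parameters to
#' both partitions. Test data never influence the transform parameters.
#'
#' @param train_levels Training matrix (individuals x analytes).
#' @param test_levels Optional matrix with the same columns.
#' @param log_first Log-transform first (requires positive levels);
#'   mirrors the handling of raw fluorescence-unit panels.
#' @return List: `train`, `test` (or `NULL`), `params` (per-feature
#'   `lambda`, `center`, `scale`, plus `log_first`).
#' @export
preprocess_panel <- function(train_levels, test_levels = NULL,
                             log_first = FALSE) {
  train_levels <- as.matrix(train_levels)
  if (log_first) {
    if (any(train_levels <= 0) ||
        (!is.null(test_levels) && any(test_levels <= 0))) {
      stop("log_first requires strictly positive levels", call. = FALSE)
    }
    train_levels <- log(train_levels)
    if (!is.null(test_levels)) test_levels <- log(as.matrix(test_levels))
  } else if (!is.null(test_levels)) {
    test_levels <- as.matrix(test_levels)
  }
  p <- ncol(train_levels)
  lambda <- numeric(p)
  for (j in seq_len(p)) {
    lambda[j] <- .yj_lambda(train_levels[, j])
    train_levels[, j] <- .yj_apply(train_levels[, j], lambda[j])
    if (!is.null(test_levels)) {
      test_levels[, j] <- .yj_apply(test_levels[, j], lambda[j])
    }
  }
  center <- colMeans(train_levels)
  scale_ <- apply(train_levels, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  train_out <- sweep(sweep(train_levels, 2, center), 2, scale_, `/`)
  test_out <- if (is.null(test_levels)) NULL else
    sweep(sweep(test_levels, 2, center), 2, scale_, `/`)
  list(train = train_out, test = test_out,
       params = list(lambda = lambda, center = center, scale = scale_,
                     log_first = log_first))
}

# Yeo-Johnson MLE for one feature via car; falls back to lambda = 1
# (identity) when the likelihood optimisation fails or is degenerate.
.yj_lambda <- function(x) {
  if (stats::sd(x) == 0) return(1)
  lam <- tryCatch(
    suppressWarnings(
      unname(stats::coef(car::powerTransform(x, family = "yjPower")))),
    error = function(e) 1
  )
  # an occasional optimizer non-convergence (flagged by car as a
  # warning) still returns a usable lambda; non-finite values fall back
  # to the identity
  if (!is.finite(lam)) 1 else lam
}

.yj_apply <- function(x, lambda) {
  car::yjPower(x, lambda)
}

#' Shadow-feature selection of informative analytes
#'
#' A permutation-based relevance filter in the style of Boruta: each
#' iteration appends a permuted ("shadow") copy of every feature, fits an
#' L1-penalised logistic model on the combined standardised matrix, and
#' scores each real feature by whether its absolute coefficient exceeds
#' the best shadow coefficient. Features whose hit proportion over
#' iterations is significantly above 0.5 (one-sided binomial test,
#' Benjamini-Hochberg FDR across features) are selected.
#'
#' @param levels Matrix (individuals x analytes).
#' @param labels Binary outcome with both classes present.
#' @param n_iter Number of shadow iterations (>= 20).
#' @param seed Integer seed.
#' @param fdr FDR level for the selection test (default 0.05).
#' @param lambda_frac Penalty as a fraction of the smallest
#'   all-zero-coefficient penalty (default 0.1).
#' @return Character vector of selected analyte ids (possibly empty).
#' @export
shadow_feature_select <- function(levels, labels, n_iter = 50L, seed,
                                  fdr = 0.05, lambda_frac = 0.1) {
  levels <- as.matrix(levels)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("degenerate labels", call. = FALSE)
  if (n_iter < 20L) stop("n_iter must be at least 20", call. = FALSE)
  p <- ncol(levels)
  X <- scale(levels)
  X[!is.finite(X)] <- 0
  # lambda_max: smallest penalty with all coefficients zero
  n <- nrow(X)
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
  lam <- lambda_frac * lambda_max

  hits <- integer(p)
  withr::with_seed(seed, {
    for (it in seq_len(n_iter)) {
      shadows <- apply(X, 2, sample)
      fit <- glmnet::glmnet(cbind(X, shadows), y, family = "binomial",
                            alpha = 1, lambda = lam, standardize = FALSE)
      cf <- abs(as.vector(fit$beta))
      thr <- max(cf[(p + 1):(2 * p)])
      hits <- hits + (cf[1:p] > thr)
    }
  })
  # one-sided binomial test of the hit proportion against 0.5
  pvals <- stats::pbinom(hits - 1L, n_iter, 0.5, lower.tail = FALSE)
  padj <- stats::p.adjust(pvals, method = "BH")
  ids <- colnames(levels)
  if (is.null(ids)) ids <- paste0("f", seq_len(p))
  ids[padj < fdr & hits > n_iter / 2]
}

#' Average precision of a ranking
#'
#' Area under the precision-recall curve by the step-wise estimator
#' \eqn{\sum_k (R_k - R_{k-1}) P_k} over descending score thresholds.
#'
#' @param scores Predicted scores.
#' @param labels Binary outcome.
#' @return Average precision in \eqn{[0, 1]}.
#' @export
average_precision <- function(scores, labels) {
  y <- as.integer(labels)[order(scores, decreasing = TRUE)]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  sum(diff(c(0, recall)) * precision)
}

#' Model specification for the staging classifiers
#'
#' Bundles the design choices of one classifier arm: which inputs it
#' uses, whether shadow-feature selection runs inside each training
#' partition, and the elastic-net tuning grid.
#'
#' @param type `"proteins"` (elastic-net on the panel), `"baseline"`
#'   (plain logistic on age/sex/BMI/ALT/AST/GGT), or `"proteins_grs"`
#'   (panel plus extra fixed columns such as a genetic risk score).
#' @param select Run shadow-feature selection on each training partition
#'   (`"proteins"` arms only).
#' @param select_n_iter Shadow iterations per partition.
#' @param alphas Elastic-net mixing grid.
#' @param tune_folds Inner CV folds for the penalty grid search.
#' @param tune_metric `"average_precision"` (maximised) or `"auc"`.
#' @param log_first Log-transform levels before the power transform.
#' @return A list of class `hf_model_spec`.
#' @export
staging_model_spec <- function(type = c("proteins", "baseline",
                                        "proteins_grs"),
                               select = TRUE, select_n_iter = 20L,
                               alphas = c(0.1, 0.5, 0.9),
                               tune_folds = 10L,
                               tune_metric = c("average_precision", "auc"),
                               log_first = FALSE) {
  structure(list(type = match.arg(type), select = select,
                 select_n_iter = as.integer(select_n_iter),
                 alphas = alphas, tune_folds = as.integer(tune_folds),
                 tune_metric = match.arg(tune_metric),
                 log_first = log_first),
            class = "hf_model_spec")
}

# Stratified fold assignment: within each class, shuffled indices are
# dealt round-robin so every fold keeps the class proportions.
.stratified_folds <- function(labels, k) {
  y <- as.integer(labels)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Elastic-net grid search on one training partition: inner stratified CV
# over alphas x shared lambda path, scored by the model spec's tune metric;
# returns the refit model at the winning setting.
.tune_enet <- function(X, y, spec) {
  path <- glmnet::glmnet(X, y, family = "binomial", alpha = max(spec$alphas),
                         nlambda = 30)
  lambdas <- path$lambda
  fold <- .stratified_folds(y, spec$tune_folds)
  best <- list(score = -Inf, alpha = spec$alphas[1], lambda = lambdas[1])
  for (a in spec$alphas) {
    preds <- matrix(NA_real_, length(y), length(lambdas))
    for (f in seq_len(spec$tune_folds)) {
      tr <- fold != f
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                            family = "binomial", alpha = a,
                            lambda = lambdas)
      preds[!tr, ] <- stats::predict(fit, X[!tr, , drop = FALSE],
                                     type = "link")
    }
    for (l in seq_along(lambdas)) {
      sc <- if (spec$tune_metric == "average_precision") {
        average_precision(preds[, l], y)
      } else {
        .auc(preds[, l], y)
      }
      if (sc > best$score) {
        best <- list(score = sc, alpha = a, lambda = lambdas[l])
      }
    }
  }
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = best$alpha,
                        lambda = best$lambda)
  list(fit = fit, alpha = best$alpha, lambda = best$lambda,
       score = best$score)
}

.auc <- function(scores, labels) {
  as.numeric(pROC::auc(pROC::roc(as.integer(labels), as.numeric(scores),
                                 quiet = TRUE, direction = "<")))
}

# Fit one arm on a training partition and score a test partition.
# extra: optional fixed covariate matrix (baseline columns, GRS).
.fit_score_arm <- function(spec, levels, extra, labels, train_idx,
                           test_idx, seed_sel) {
  y_tr <- labels[train_idx]
  if (spec$type == "baseline") {
    dat <- as.data.frame(extra)
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = cbind(y = as.integer(y_tr),
                                     dat[train_idx, , drop = FALSE]),
                 family = stats::binomial()))
    return(as.vector(
      stats::predict(fit, dat[test_idx, , drop = FALSE], type = "link")))
  }

  lv_tr <- levels[train_idx, , drop = FALSE]
  lv_te <- levels[test_idx, , drop = FALSE]
  keep <- colnames(levels)
  if (spec$select) {
    keep <- shadow_feature_select(lv_tr, y_tr,
                                  n_iter = spec$select_n_iter,
                                  seed = seed_sel)
    if (!length(keep)) {           # nothing informative: constant score
      return(rep(mean(as.integer(y_tr)), length(test_idx)))
    }
  }
  pp <- preprocess_panel(lv_tr[, keep, drop = FALSE],
                         lv_te[, keep, drop = FALSE],
                         log_first = spec$log_first)
  X_tr <- pp$train; X_te <- pp$test
  if (spec$type == "proteins_grs" && !is.null(extra)) {
    X_tr <- cbind(X_tr, as.matrix(extra)[train_idx, , drop = FALSE])
    X_te <- cbind(X_te, as.matrix(extra)[test_idx, , drop = FALSE])
  }
  if (ncol(X_tr) == 1L) {          # glmnet needs >= 2 columns
    X_tr <- cbind(X_tr, 0); X_te <- cbind(X_te, 0)
  }
  tuned <- .tune_enet(X_tr, as.integer(y_tr), spec)
  as.vector(stats::predict(tuned$fit, X_te, type = "link"))
}

#' Repeated stratified cross-validated AUC of a staging model
#'
#' Repeats tenfold-stratified cross-validation `n_repeats` times. Within
#' every training partition the full pipeline is re-run -- shadow-feature
#' selection, Yeo-Johnson + scaling, elastic-net grid search -- so no
#' information leaks from the held-out fold. Each repeat's ROC AUC is
#' computed from the pooled out-of-fold scores; the report carries their
#' mean and standard error of the mean.
#'
#' @param model_spec An [staging_model_spec()].
#' @param panel An `hf_protein_panel` (or matrix; may be `NULL` for the
#'   baseline arm).
#' @param labels Binary outcome (defaults to the panel's labels).
#' @param extra Optional fixed covariate data frame/matrix (baseline
#'   columns or GRS), aligned with the labels.
#' @param n_repeats Number of CV repeats (>= 2; 1,000 reproduces the
#'   full evaluation protocol, 25 is the desk-scale default).
#' @param folds Folds per repeat (default 10).
#' @param seed Integer seed controlling fold assignment and selection.
#' @return An object of class `hf_cv_report`: `mean_auc`, `sem_auc`,
#'   `n_repeats`, `folds`, `per_repeat_aucs`.
#' @export
evaluate_cv <- function(model_spec, panel, labels = NULL, extra = NULL,
                        n_repeats = 25L, folds = 10L, seed) {
  stopifnot(inherits(model_spec, "hf_model_spec"))
  levels <- if (inherits(panel, "hf_protein_panel")) panel$levels else panel
  if (is.null(labels) && inherits(panel, "hf_protein_panel")) {
    labels <- panel$labels
  }
  y <- as.integer(labels)
  if (n_repeats < 2L) stop("n_repeats must be at least 2", call. = FALSE)
  if (min(table(y)) < folds) {
    stop("fold count exceeds the size of the smaller class", call. = FALSE)
  }
  aucs <- numeric(n_repeats)
  withr::with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      fold <- .stratified_folds(y, folds)
      scores <- numeric(length(y))
      for (f in seq_len(folds)) {
        te <- which(fold == f)
        tr <- which(fold != f)
        scores[te] <- .fit_score_arm(
          model_spec, levels, extra, y, tr, te,
          seed_sel = sample.int(.Machine$integer.max, 1))
      }
      aucs[r] <- .auc(scores, y)
    }
  })
  structure(
    list(mean_auc = mean(aucs),
         sem_auc = stats::sd(aucs) / sqrt(n_repeats),
         n_repeats = as.integer(n_repeats), folds = as.integer(folds),
         per_repeat_aucs = aucs),
    class = "hf_cv_report"
  )
}

#' @export
print.hf_cv_report <- function(x, ...) {
  cat(sprintf("<hf_cv_report: AUC %.3f +/- %.3f (sem, %d x %d-fold CV)>\n",
              x$mean_auc, x$sem_auc, x$n_repeats, x$folds))
  invisible(x)
}

#' Fit the final proteomic staging model on all data
#'
#' Shadow-feature selection on the full data, Yeo-Johnson +
#' standardisation, elastic-net grid search by inner cross-validated
#' average precision, and a final refit at the winning penalty. Use
#' [evaluate_cv()] for an unbiased performance estimate; this function
#' produces the deployable model.
#'
#' @param panel An `hf_protein_panel` or matrix.
#' @param labels Binary outcome (defaults to the panel's labels).
#' @param spec An [staging_model_spec()].
#' @param seed Integer seed.
#' @return An object of class `hf_staging_model`: `selected_features`,
#'   `transform_params`, `coefficients` (named, plus intercept),
#'   `tuning` (alpha, lambda, inner-CV score).
#' @export
fit_staging_model <- function(panel, labels = NULL,
                              spec = staging_model_spec(), seed) {
  levels <- if (inherits(panel, "hf_protein_panel")) panel$levels else panel
  if (is.null(labels) && inherits(panel, "hf_protein_panel")) {
    labels <- panel$labels
  }
  y <- as.integer(labels)
  keep <- colnames(levels)
  sel_seed <- withr::with_seed(seed, sample.int(.Machine$integer.max, 1))
  if (spec$select) {
    keep <- shadow_feature_select(levels, y, n_iter = spec$select_n_iter,
                                  seed = sel_seed)
    if (!length(keep)) {
      return(structure(list(selected_features = character(0),
                            transform_params = NULL,
                            coefficients = c(`(Intercept)` =
                                               stats::qlogis(mean(y))),
                            tuning = NULL),
                       class = "hf_staging_model"))
    }
  }
  pp <- preprocess_panel(levels[, keep, drop = FALSE],
                         log_first = spec$log_first)
  X <- pp$train
  if (ncol(X) == 1L) X <- cbind(X, 0)
  tuned <- withr::with_seed(seed, .tune_enet(X, y, spec))
  cf <- as.vector(stats::coef(tuned$fit))
  names(cf) <- c("(Intercept)", colnames(X))
  structure(
    list(selected_features = keep, transform_params = pp$params,
         coefficients = cf,
         tuning = list(alpha = tuned$alpha, lambda = tuned$lambda,
                       score = tuned$score)),
    class = "hf_staging_model"
  )
}

#' Liver-enzyme baseline classifier
#'
#' Repeated stratified CV of a plain logistic model on the six fixed
#' covariates age, sex, BMI, ALT, AST and GGT -- the clinical-chemistry
#' baseline against which the protein panel is compared.
#'
#' @param age,sex,bmi,alt,ast,ggt Covariate vectors (all required).
#' @param labels Binary outcome.
#' @param n_repeats,folds,seed As in [evaluate_cv()].
#' @return An `hf_cv_report`.
#' @export
baseline_model <- function(age, sex, bmi, alt, ast, ggt, labels,
                           n_repeats = 25L, folds = 10L, seed) {
  covs <- list(age = age, sex = sex, bmi = bmi, alt = alt, ast = ast,
               ggt = ggt)
  lens <- lengths(covs)
  if (any(lens != length(labels))) {
    bad <- names(covs)[lens != length(labels)]
    stop("covariate length mismatch: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  evaluate_cv(staging_model_spec(type = "baseline", select = FALSE),
              panel = NULL, labels = labels,
              extra = as.data.frame(covs),
              n_repeats = n_repeats, folds = folds, seed = seed)
}

#' Out-of-fold protein scores for model combination
#'
#' Tenfold out-of-fold linear scores of the protein arm, usable as a
#' "protein score" column in combined protein + enzymes + GRS models
#' without leaking training labels.
#'
#' @param panel An `hf_protein_panel` or matrix.
#' @param labels Binary outcome (defaults to the panel's labels).
#' @param spec An [staging_model_spec()].
#' @param folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return Numeric vector of out-of-fold scores.
#' @export
oof_protein_scores <- function(panel, labels = NULL,
                               spec = staging_model_spec(), folds = 10L,
                               seed) {
  levels <- if (inherits(panel, "hf_protein_panel")) panel$levels else panel
  if (is.null(labels) && inherits(panel, "hf_protein_panel")) {
    labels <- panel$labels
  }
  y <- as.integer(labels)
  scores <- numeric(length(y))
  withr::with_seed(seed, {
    fold <- .stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      te <- which(fold == f)
      tr <- which(fold != f)
      scores[te] <- .fit_score_arm(
        spec, levels, NULL, y, tr, te,
        seed_sel = sample.int(.Machine$integer.max, 1))
    }
  })
  scores
}
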