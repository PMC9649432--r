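#' Rank-based inverse normal transform after covariate adjustment
#'
#' Residualises the trait on the covariates by least squares, then maps
#' residual ranks to normal quantiles with the Blom offset
#' \eqn{\Phi^{-1}((k - 3/8) / (n + 1/4))}; ties receive average ranks.
#' This is the standardisation applied to quantitative traits before
#' association and interaction testing.
#'
#' @param values Numeric trait vector, n >= 10.
#' @param covariates Optional data frame or matrix of covariates.
#' @return Standardised trait vector (mean ~0, s.d. ~1).
#' @export
inverse_normal_transform <- function(values, covariates = NULL) {
  values <- as.numeric(values)
  if (length(values) < 10L) stop("need at least 10 values", call. = FALSE)
  if (stats::var(values) == 0) stop("constant input", call. = FALSE)
  if (!is.null(covariates)) {
    # lm.fit pivots away aliased covariate columns (e.g. year of birth
    # given age) instead of failing
    X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    values <- stats::lm.fit(X, values)$residuals
  }
  r <- rank(values, ties.method = "average")
  n <- length(values)
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

.assoc_result <- function(beta, se, p, n, separation = FALSE) {
  structure(list(beta = beta, se = se, p_value = p, n = n,
                 separation = separation),
            class = "hf_assoc_result")
}

#' Additive association of a variant with a trait
#'
#' Linear regression for quantitative traits, logistic regression for
#' binary traits (0/1 or logical), genotype coded additively as the
#' allele count 0/1/2, covariates included as nuisance terms. Wald test.
#'
#' @param genotypes Integer vector in 0/1/2 with positive variance.
#' @param trait Quantitative vector, or binary (logical / 0-1).
#' @param covariates Optional data frame of covariates.
#' @return An `hf_assoc_result`: `beta` (s.d. units per allele, or log-OR
#'   for binary traits), `se`, `p_value`, `n`, `separation` flag.
#' @export
additive_assoc <- function(genotypes, trait, covariates = NULL) {
  g <- as.numeric(genotypes)
  if (stats::var(g) == 0) {
    stop("monomorphic variant: genotype has no variance", call. = FALSE)
  }
  dat <- data.frame(.g = g, .y = trait)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  binary <- is.logical(trait) || all(trait %in% c(0, 1))
  separation <- FALSE
  if (binary) {
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (separation) {
      warning("possible separation in logistic model; estimates unstable")
    }
  } else {
    fit <- stats::lm(.y ~ ., data = dat)
  }
  cf <- summary(fit)$coefficients[".g", ]
  p <- if (binary) cf[4] else cf[4]
  .assoc_result(unname(cf[1]), unname(cf[2]), unname(p), nrow(dat),
                separation)
}

#' Genotype-genotype interaction likelihood-ratio test
#'
#' Splits the population into three groups by the primary-variant
#' genotype \eqn{g_p \in \{0, 1, 2\}}, estimates the secondary variant's
#' effect \eqn{\beta_{g_p}} (with standard error) in each group by least
#' squares on the standardised trait, and fits the trend model
#' \deqn{\beta_{g_p} = b + \gamma g_p}
#' by weighted least squares with weights \eqn{1 / se^2}. Significance of
#' \eqn{\gamma} is a likelihood-ratio test against the constant-effect
#' null (\eqn{\beta_0 = \beta_1 = \beta_2}): treating the group estimates
#' as Gaussian with known standard errors, the statistic is the weighted
#' residual sum of squares under the null minus under the trend model,
#' referred to chi-square with 1 df.
#'
#' @param primary_genotypes,secondary_genotypes Vectors in 0/1/2.
#' @param trait Standardised quantitative trait.
#' @param min_group Minimum individuals per primary-genotype group
#'   (default 30).
#' @return An `hf_interaction_result`: `group_betas`, `group_ses`
#'   (length 3, groups 0/1/2), `b`, `gamma`, `gamma_se`, `lrt_stat`,
#'   `p_value`, `df = 1`, `n`.
#' @export
interaction_lrt <- function(primary_genotypes, secondary_genotypes, trait,
                            min_group = 30L) {
  gp <- as.integer(primary_genotypes)
  gs <- as.numeric(secondary_genotypes)
  y <- as.numeric(trait)
  stopifnot(length(gp) == length(gs), length(gp) == length(y))

  betas <- ses <- numeric(3)
  for (k in 0:2) {
    idx <- gp == k
    nk <- sum(idx)
    if (nk < min_group) {
      stop(sprintf("primary genotype group %d has %d individuals (< %d)",
                   k, nk, min_group), call. = FALSE)
    }
    x <- gs[idx]
    if (stats::var(x) == 0) {
      stop(sprintf("secondary variant monomorphic in group %d", k),
           call. = FALSE)
    }
    yk <- y[idx]
    sxx <- sum((x - mean(x))^2)
    b1 <- sum((x - mean(x)) * yk) / sxx
    res <- yk - mean(yk) - b1 * (x - mean(x))
    s2 <- sum(res^2) / (nk - 2)
    betas[k + 1] <- b1
    ses[k + 1] <- sqrt(s2 / sxx)
  }

  w <- 1 / ses^2
  g <- 0:2
  # weighted LS of beta_g on g (trend model) and on 1 (null model)
  sw <- sum(w); swg <- sum(w * g); swg2 <- sum(w * g^2)
  swb <- sum(w * betas); swgb <- sum(w * g * betas)
  det <- sw * swg2 - swg^2
  gamma <- (sw * swgb - swg * swb) / det
  b <- (swg2 * swb - swg * swgb) / det
  gamma_se <- sqrt(sw / det)
  rss1 <- sum(w * (betas - b - gamma * g)^2)
  b0 <- swb / sw
  rss0 <- sum(w * (betas - b0)^2)
  lrt <- max(rss0 - rss1, 0)
  structure(
    list(group_betas = betas, group_ses = ses, b = b, gamma = gamma,
         gamma_se = gamma_se, lrt_stat = lrt,
         p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
         df = 1L, n = length(y)),
    class = "hf_interaction_result"
  )
}

#' Genotype-by-covariate interaction (product-term model)
#'
#' Linear model `trait ~ genotype * covariate (+ extra covariates)`;
#' returns the Wald test of the product term, supporting genotype-by-BMI
#' style interaction scans.
#'
#' @param genotypes Vector in 0/1/2 with positive variance.
#' @param covariate Numeric covariate with positive variance.
#' @param trait Quantitative trait.
#' @param covariates Optional extra covariates.
#' @return An `hf_assoc_result` for the product term.
#' @export
covariate_interaction <- function(genotypes, covariate, trait,
                                  covariates = NULL) {
  g <- as.numeric(genotypes)
  x <- as.numeric(covariate)
  if (stats::var(g) == 0) stop("monomorphic variant", call. = FALSE)
  if (stats::var(x) == 0) stop("constant covariate", call. = FALSE)
  dat <- data.frame(.g = g, .x = x, .y = as.numeric(trait))
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- stats::lm(.y ~ . + .g:.x, data = dat)
  cf <- summary(fit)$coefficients[".g:.x", ]
  .assoc_result(unname(cf[1]), unname(cf[2]), unname(cf[4]), nrow(dat))
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines per-study effect estimates with weights \eqn{w_i = 1/se_i^2}:
#' combined effect \eqn{\sum w_i \beta_i / \sum w_i} with standard error
#' \eqn{1/\sqrt{\sum w_i}}. Between-study heterogeneity is quantified by
#' Cochran's Q with k-1 df.
#'
#' @param effects Per-study effect estimates.
#' @param ses Per-study standard errors (> 0), same length.
#' @return An `hf_meta_result`: `effect`, `se`, `p_value`, `q_stat`,
#'   `p_het` (`NA` for k = 1), `k`.
#' @export
ivw_meta <- function(effects, ses) {
  effects <- as.numeric(effects); ses <- as.numeric(ses)
  if (length(effects) != length(ses)) {
    stop("effects and ses must have the same length", call. = FALSE)
  }
  k <- length(effects)
  if (k < 1L) stop("need at least one study", call. = FALSE)
  if (any(ses <= 0)) stop("standard errors must be positive", call. = FALSE)
  w <- 1 / ses^2
  eff <- sum(w * effects) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (effects - eff)^2)
  structure(
    list(effect = eff, se = se,
         p_value = 2 * stats::pnorm(-abs(eff / se)),
         q_stat = q,
         p_het = if (k > 1) stats::pchisq(q, k - 1, lower.tail = FALSE)
                 else NA_real_,
         k = k),
    class = "hf_meta_result"
  )
}

#' Tiered genome-wide significance threshold by functional impact
#'
#' Fixed per-class thresholds from a weighted Bonferroni adjustment that
#' up-weights variant classes enriched for true associations: high-impact
#' (stop gained/lost, frameshift, splice donor/acceptor, initiator codon)
#' 1.8e-7; moderate (missense, splice region, in-frame indel) 3.5e-8;
#' low (synonymous, UTR, up/downstream) 3.2e-9; DNase I hypersensitivity
#' sites 1.6e-9; all other variants 5.3e-10.
#'
#' @param impact_class One of `"high"`, `"moderate"`, `"low"`, `"dhs"`,
#'   `"other"`.
#' @return The p-value threshold.
#' @export
gws_threshold <- function(impact_class) {
  tiers <- c(high = 1.8e-7, moderate = 3.5e-8, low = 3.2e-9,
             dhs = 1.6e-9, other = 5.3e-10)
  if (!impact_class %in% names(tiers)) {
    stop("unknown impact class: ", impact_class, call. = FALSE)
  }
  unname(tiers[impact_class])
}

#' Genetic risk score
#'
#' Per-individual weighted sum of effect-allele counts,
#' \eqn{\sum_k w_k g_k}. Every weighted variant must be present in the
#' genotype table; unmatched variants raise an error rather than being
#' dropped. When both the weights and the genotype table carry allele
#' annotations, mismatched effect alleles are an error unless
#' `allow_flip = TRUE`, in which case the genotype is counted on the
#' other allele (g -> 2 - g).
#'
#' @param genotypes n x variants matrix in 0/1/2 with variant ids as
#'   column names.
#' @param weights Data frame with columns `variant`, `weight` and
#'   optionally `effect_allele`.
#' @param counted_alleles Optional named character vector giving the
#'   allele counted by each genotype column.
#' @param allow_flip Permit automatic re-orientation (default `FALSE`).
#' @return Numeric score per individual.
#' @export
grs <- function(genotypes, weights, counted_alleles = NULL,
                allow_flip = FALSE) {
  stopifnot(is.data.frame(weights),
            all(c("variant", "weight") %in% names(weights)))
  if (!all(is.finite(weights$weight))) {
    stop("weights must be finite", call. = FALSE)
  }
  missing_v <- setdiff(weights$variant, colnames(genotypes))
  if (length(missing_v)) {
    stop("variants absent from genotype table: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }
  G <- genotypes[, weights$variant, drop = FALSE]
  if (!is.null(counted_alleles) && "effect_allele" %in% names(weights)) {
    counted <- counted_alleles[weights$variant]
    flip <- counted != weights$effect_allele
    if (any(flip) && !allow_flip) {
      stop("effect-allele mismatch for: ",
           paste(weights$variant[flip], collapse = ", "),
           " (set allow_flip = TRUE to re-orient)", call. = FALSE)
    }
    G[, flip] <- 2 - G[, flip]
  }
  as.vector(G %*% weights$weight)
}

#' Mendelian randomization: IVW and Egger regression
#'
#' Inverse-variance-weighted estimate: weighted regression of the
#' instruments' outcome effects on their exposure effects through the
#' origin, weights \eqn{1/se_{out}^2}; Egger: the same regression with a
#' free intercept (a non-zero intercept indicates directional
#' pleiotropy). Standard errors use the multiplicative random-effects
#' convention (residual dispersion floored at 1); p-values are normal.
#'
#' @param exposure_effects,exposure_ses Instrument effects on the
#'   exposure (ses currently unused by the estimators but part of the
#'   summary-data contract).
#' @param outcome_effects,outcome_ses Instrument effects on the outcome.
#' @return List with `ivw` (estimate, se, p_value) and `egger`
#'   (intercept, intercept_se, intercept_p, slope, slope_se, slope_p;
#'   `NULL` with fewer than 3 instruments), plus `n_instruments`.
#' @export
mr_ivw_egger <- function(exposure_effects, exposure_ses,
                         outcome_effects, outcome_ses) {
  bx <- as.numeric(exposure_effects)
  by <- as.numeric(outcome_effects)
  syse <- as.numeric(outcome_ses)
  k <- length(bx)
  if (k < 2L) stop("IVW requires at least 2 instruments", call. = FALSE)
  if (length(by) != k || length(syse) != k) {
    stop("instrument vectors must have equal length", call. = FALSE)
  }
  if (any(syse <= 0)) stop("outcome ses must be positive", call. = FALSE)
  w <- 1 / syse^2

  est <- sum(w * bx * by) / sum(w * bx^2)
  resid <- by - est * bx
  disp <- max(1, sqrt(sum(w * resid^2) / (k - 1)))
  se <- disp / sqrt(sum(w * bx^2))
  ivw <- list(estimate = est, se = se,
              p_value = 2 * stats::pnorm(-abs(est / se)))

  egger <- NULL
  if (k >= 3L) {
    X <- cbind(1, bx)
    V <- solve(crossprod(X, w * X))
    cf <- as.vector(V %*% crossprod(X, w * by))
    resid_e <- by - as.vector(X %*% cf)
    disp_e <- max(1, sqrt(sum(w * resid_e^2) / (k - 2)))
    ses_e <- sqrt(diag(V)) * disp_e
    egger <- list(intercept = cf[1], intercept_se = ses_e[1],
                  intercept_p = 2 * stats::pnorm(-abs(cf[1] / ses_e[1])),
                  slope = cf[2], slope_se = ses_e[2],
                  slope_p = 2 * stats::pnorm(-abs(cf[2] / ses_e[2])))
  }
  list(ivw = ivw, egger = egger, n_instruments = k)
}
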