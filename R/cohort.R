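#' Simulate a genotype/phenotype cohort
#'
#' Generates `n` individuals with independent Hardy-Weinberg genotypes
#' (counts of the minor allele, `Binomial(2, maf)` per variant),
#' covariates (sex, age, year of birth, BMI), one quantitative trait with
#' planted additive and interaction effects, liver-enzyme traits with a
#' planted case shift, and a binary diagnosis from a logistic model.
#'
#' The trait model is
#' \deqn{y = \sum_k \beta_k g_k + \gamma \, g_p g_s + 0.02\,(\mathrm{BMI}
#'   - 27) + \epsilon,\quad \epsilon \sim N(0, \mathrm{noise\_sd}^2)}
#' where \eqn{g_p, g_s} are the designated primary/secondary interaction
#' pair. Diagnosis probability is
#' `plogis(intercept + sum(slopes * genotypes))`; liver enzymes (ALT,
#' AST, GGT, standardised units) are shifted by `enzyme_effect` s.d. in
#' cases, emulating their real but modest diagnostic signal.
#'
#' @param n Number of individuals (>= 50).
#' @param mafs Named or unnamed vector of minor-allele frequencies in
#'   (0, 0.5]; one variant per entry.
#' @param beta Per-variant additive trait effects (s.d. units per
#'   allele), recycled/zero-padded to `length(mafs)`.
#' @param gamma Interaction coefficient for the designated variant pair.
#' @param interaction_pair Indices `c(primary, secondary)` of the
#'   interacting variants (default first two).
#' @param noise_sd Trait noise s.d.
#' @param disease_model List with `intercept` (logistic scale), optional
#'   `slopes` (per-variant log-odds per allele) and optional
#'   `exact = TRUE` to fix the case count at `round(n * plogis(intercept))`
#'   (cases then assigned by the largest latent risks).
#' @param enzyme_effect Case shift of ALT/AST/GGT in s.d. units
#'   (default 0.3).
#' @param seed Integer seed.
#' @return An object of class `hf_cohort`: `genotypes` (n x variants
#'   integer matrix in 0/1/2), `mafs`, `covariates` (data frame:
#'   sample_id, sex, age, year_of_birth, bmi), `traits` (data frame:
#'   trait, alt, ast, ggt), `diagnoses` (data frame: disease logical).
#' @export
simulate_cohort <- function(n, mafs, beta = 0, gamma = 0,
                            interaction_pair = c(1L, 2L), noise_sd = 1,
                            disease_model = list(intercept = -2,
                                                 slopes = NULL),
                            enzyme_effect = 0.3, seed) {
  n <- as.integer(n)
  if (n < 50L) stop("n must be at least 50", call. = FALSE)
  mafs <- as.numeric(mafs)
  if (any(mafs <= 0) || any(mafs > 0.5)) {
    stop("mafs must lie in (0, 0.5]", call. = FALSE)
  }
  m <- length(mafs)
  beta <- rep_len(as.numeric(beta), m)
  if (!all(is.finite(beta)) || !is.finite(gamma)) {
    stop("effects must be finite", call. = FALSE)
  }
  variant_ids <- if (!is.null(names(mafs))) names(mafs) else
    paste0("v", seq_len(m))

  withr::with_seed(seed, {
    G <- matrix(stats::rbinom(n * m, 2L, rep(mafs, each = n)), n, m)
    sex <- stats::rbinom(n, 1L, 0.5)
    age <- round(stats::rnorm(n, 55, 17))
    age <- pmin(pmax(age, 18), 95)
    bmi <- stats::rnorm(n, 27, 4.5)
    eps <- stats::rnorm(n, 0, noise_sd)

    inter <- 0
    if (gamma != 0) {
      if (max(interaction_pair) > m) {
        stop("interaction_pair indexes beyond the available variants",
             call. = FALSE)
      }
      inter <- gamma * G[, interaction_pair[1]] * G[, interaction_pair[2]]
    }
    trait <- as.vector(G %*% beta) + inter + 0.02 * (bmi - 27) + eps

    slopes <- disease_model$slopes
    if (is.null(slopes)) slopes <- rep(0, m)
    lin <- disease_model$intercept + as.vector(G %*% rep_len(slopes, m))
    if (isTRUE(disease_model$exact)) {
      latent <- lin + stats::rlogis(n)
      n_cases <- round(n * stats::plogis(disease_model$intercept))
      disease <- rank(-latent, ties.method = "first") <= n_cases
    } else {
      disease <- stats::runif(n) < stats::plogis(lin)
    }

    shift <- enzyme_effect * disease
    alt <- stats::rnorm(n) + shift
    ast <- stats::rnorm(n) + shift
    ggt <- stats::rnorm(n) + shift
  })

  colnames(G) <- variant_ids
  structure(
    list(
      genotypes = G,
      mafs = stats::setNames(mafs, variant_ids),
      covariates = data.frame(
        sample_id = sprintf("S%05d", seq_len(n)), sex = sex, age = age,
        year_of_birth = 2026L - age, bmi = bmi
      ),
      traits = data.frame(trait = trait, alt = alt, ast = ast, ggt = ggt),
      diagnoses = data.frame(disease = disease)
    ),
    class = "hf_cohort"
  )
}

#' Simulate a protein panel with planted disease shifts
#'
#' Analyte levels are standard normal noise per individual; the first
#' `n_informative` analytes are shifted by `effect` standard deviations
#' in individuals whose diagnosis is `TRUE`. Optional confounding adds
#' age/sex/BMI loadings to every analyte, mimicking the demographic
#' structure of real plasma panels.
#'
#' @param cohort An `hf_cohort` supplying the disease labels (and the
#'   covariates when `confound = TRUE`).
#' @param n_proteins Number of analytes.
#' @param n_informative Number of analytes carrying the planted shift
#'   (<= `n_proteins`).
#' @param effect Case shift in s.d. units.
#' @param confound Add age/sex/BMI loadings (default `FALSE`).
#' @param seed Integer seed.
#' @return An object of class `hf_protein_panel`: `levels` (n x
#'   n_proteins matrix, analyte ids as column names), `informative_ids`,
#'   `labels` (logical).
#' @export
simulate_proteome <- function(cohort, n_proteins, n_informative = 0L,
                              effect = 0, confound = FALSE, seed) {
  stopifnot(inherits(cohort, "hf_cohort"))
  n_proteins <- as.integer(n_proteins)
  n_informative <- as.integer(n_informative)
  if (n_informative > n_proteins) {
    stop("n_informative must not exceed n_proteins", call. = FALSE)
  }
  labels <- cohort$diagnoses$disease
  n <- length(labels)
  ids <- sprintf("prot%04d", seq_len(n_proteins))

  withr::with_seed(seed, {
    levels <- matrix(stats::rnorm(n * n_proteins), n, n_proteins)
    if (n_informative > 0L) {
      levels[, seq_len(n_informative)] <-
        levels[, seq_len(n_informative)] + effect * labels
    }
    if (confound) {
      load_age <- stats::rnorm(n_proteins, 0, 0.1)
      load_sex <- stats::rnorm(n_proteins, 0, 0.1)
      load_bmi <- stats::rnorm(n_proteins, 0, 0.1)
      z_age <- as.numeric(scale(cohort$covariates$age))
      z_bmi <- as.numeric(scale(cohort$covariates$bmi))
      levels <- levels + outer(z_age, load_age) +
        outer(cohort$covariates$sex - 0.5, load_sex) +
        outer(z_bmi, load_bmi)
    }
  })
  colnames(levels) <- ids
  structure(
    list(levels = levels,
         informative_ids = ids[seq_len(n_informative)],
         labels = labels),
    class = "hf_protein_panel"
  )
}
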