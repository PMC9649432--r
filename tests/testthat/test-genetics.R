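test_that("inverse normal transform standardises and preserves ranks", {
  x <- withr::with_seed(1, rexp(10000))
  z <- inverse_normal_transform(x)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sd(z) - 1), 1e-3)
  expect_identical(order(z), order(x))              # rank preservation
  # idempotent up to ties
  expect_equal(inverse_normal_transform(z), z, tolerance = 1e-12)
  expect_error(inverse_normal_transform(rep(1, 20)), "constant")
  expect_error(inverse_normal_transform(1:5), "10")

  # covariate adjustment removes a linear confounder
  age <- withr::with_seed(2, rnorm(500, 50, 10))
  y <- 0.1 * age + withr::with_seed(3, rnorm(500))
  z2 <- inverse_normal_transform(y, data.frame(age = age))
  expect_lt(abs(cor(z2, age)), 0.05)
})

test_that("additive association recovers planted effects and is calibrated", {
  co <- simulate_cohort(2000, c(0.3), beta = 0.3, seed = 10)
  a <- additive_assoc(co$genotypes[, 1],
                      inverse_normal_transform(co$traits$trait))
  expect_lt(abs(a$beta - 0.3), 3 * a$se)
  expect_lt(a$p_value, 1e-10)

  expect_error(additive_assoc(rep(0L, 100), rnorm(100)), "monomorphic")

  # binary outcome runs through logistic regression (log-OR scale)
  co2 <- simulate_cohort(3000, c(0.3),
                         disease_model = list(intercept = -1,
                                              slopes = 0.4), seed = 11)
  ab <- additive_assoc(co2$genotypes[, 1], co2$diagnoses$disease)
  expect_lt(abs(ab$beta - 0.4), 3 * ab$se)

  # null calibration at alpha = 0.05 (binomial bound for 200 replicates)
  rej <- mean(sapply(1:200, function(r) {
    co <- simulate_cohort(300, c(0.3), beta = 0, seed = 1000 + r)
    additive_assoc(co$genotypes[, 1], co$traits$trait)$p_value < 0.05
  }))
  expect_gt(rej, 0.05 - 3 * sqrt(0.05 * 0.95 / 200))
  expect_lt(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("interaction LRT is exactly null on a constructed fixture", {
  # identical (gs, residual) pattern in all three primary groups:
  # group slopes agree exactly, so gamma-hat = 0 and LRT = 0
  gs_block <- rep(c(0, 1, 2), each = 40)
  e_block <- rep(c(-1, 0.5, 0.5), 40)
  gp <- rep(0:2, each = 120)
  gs <- rep(gs_block, 3)
  y <- rep(0.5 * gs_block + e_block, 3)
  r <- interaction_lrt(gp, gs, y)
  expect_equal(r$group_betas, rep(r$group_betas[1], 3))
  expect_lt(abs(r$gamma), 1e-12)
  expect_lt(r$lrt_stat, 1e-20)
  expect_equal(r$df, 1L)

  expect_error(interaction_lrt(rep(0:2, c(500, 490, 10)),
                               rbinom(1000, 2, 0.4), rnorm(1000)),
               "group 2")
})

test_that("interaction LRT recovers a planted interaction coefficient", {
  gammas <- sapply(1:50, function(r) {
    co <- simulate_cohort(2000, c(0.3, 0.3), beta = c(0.2, 0.2),
                          gamma = 0.1, seed = 3000 + r)
    interaction_lrt(co$genotypes[, 1], co$genotypes[, 2],
                    inverse_normal_transform(co$traits$trait))$gamma
  })
  mc_se <- sd(gammas) / sqrt(length(gammas))
  expect_lt(abs(mean(gammas) - 0.1), 3 * mc_se + 0.01)
})

test_that("interaction LRT statistic ignores affine trait rescaling", {
  co <- simulate_cohort(1500, c(0.3, 0.3), beta = c(0.2, 0.1),
                        gamma = 0.15, seed = 77)
  y <- inverse_normal_transform(co$traits$trait)
  r1 <- interaction_lrt(co$genotypes[, 1], co$genotypes[, 2], y)
  r2 <- interaction_lrt(co$genotypes[, 1], co$genotypes[, 2], 3 * y + 7)
  expect_equal(r1$lrt_stat, r2$lrt_stat, tolerance = 1e-10)
})

test_that("covariate interaction model recovers a genotype-by-BMI term", {
  co <- simulate_cohort(3000, c(0.3), beta = 0.2, seed = 21)
  bmi_z <- as.numeric(scale(co$covariates$bmi))
  y <- co$traits$trait + 0.1 * co$genotypes[, 1] * bmi_z
  r <- covariate_interaction(co$genotypes[, 1], bmi_z, y)
  expect_lt(abs(r$beta - 0.1), 3 * r$se)
  expect_error(covariate_interaction(co$genotypes[, 1], rep(2, 3000), y),
               "constant")
})

test_that("IVW meta-analysis equals the closed-form weighted average", {
  b <- c(0.12, -0.05, 0.30, 0.08)
  s <- c(0.04, 0.10, 0.15, 0.05)
  m <- ivw_meta(b, s)
  w <- 1 / s^2
  expect_equal(m$effect, sum(w * b) / sum(w), tolerance = 1e-14)
  expect_equal(m$se, 1 / sqrt(sum(w)), tolerance = 1e-14)
  expect_equal(m$q_stat, sum(w * (b - m$effect)^2), tolerance = 1e-12)
  expect_true(m$effect >= min(b) && m$effect <= max(b))
  expect_lte(m$se, min(s))

  # independent oracle: fixed-effects model in metafor
  skip_if_not_installed("metafor")
  rma <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(m$effect, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(m$se, rma$se, tolerance = 1e-10)
  expect_equal(m$q_stat, rma$QE, tolerance = 1e-10)

  # k = 1 identity and equal-se closed forms
  m1 <- ivw_meta(0.2, 0.05)
  expect_equal(m1$effect, 0.2)
  expect_equal(m1$se, 0.05)
  expect_true(is.na(m1$p_het))
  m2 <- ivw_meta(c(0.1, 0.3), c(0.05, 0.05))
  expect_equal(m2$effect, 0.2)
  expect_equal(m2$se, 0.05 / sqrt(2))

  # order invariance
  o <- sample(4)
  mo <- ivw_meta(b[o], s[o])
  expect_equal(mo$effect, m$effect)
  expect_equal(mo$q_stat, m$q_stat)
  expect_error(ivw_meta(c(1, 2), 1), "length")
  expect_error(ivw_meta(0.1, 0), "positive")
})

test_that("tiered significance thresholds match the published values", {
  expect_equal(gws_threshold("high"), 1.8e-7)
  expect_equal(gws_threshold("moderate"), 3.5e-8)
  expect_equal(gws_threshold("low"), 3.2e-9)
  expect_equal(gws_threshold("dhs"), 1.6e-9)
  expect_equal(gws_threshold("other"), 5.3e-10)
  expect_error(gws_threshold("modifier"), "unknown")
})

test_that("genetic risk scores are exact weighted allele sums", {
  G <- withr::with_seed(4, matrix(rbinom(500, 2, 0.3), 50, 10))
  colnames(G) <- paste0("v", 1:10)
  w <- data.frame(variant = paste0("v", 1:10),
                  weight = withr::with_seed(5, rnorm(10)))
  s <- grs(G, w)
  brute <- sapply(seq_len(50), function(i) sum(G[i, ] * w$weight))
  expect_equal(s, brute, tolerance = 1e-14)

  # linearity in the weights
  w2 <- w; w2$weight <- withr::with_seed(6, rnorm(10))
  w12 <- w; w12$weight <- w$weight + w2$weight
  expect_equal(grs(G, w12), grs(G, w) + grs(G, w2), tolerance = 1e-12)

  expect_equal(grs(G, transform(w, weight = 0)), rep(0, 50))
  expect_equal(grs(matrix(2L, 3, 10,
                          dimnames = list(NULL, paste0("v", 1:10))), w),
               rep(2 * sum(w$weight), 3))

  w_bad <- rbind(w, data.frame(variant = "v99", weight = 1))
  expect_error(grs(G, w_bad), "v99")

  # allele orientation: mismatch errors unless flipping is allowed
  w$effect_allele <- rep("A", 10)
  counted <- setNames(rep("A", 10), w$variant)
  counted["v3"] <- "G"
  expect_error(grs(G, w, counted_alleles = counted), "v3")
  s_flip <- grs(G, w, counted_alleles = counted, allow_flip = TRUE)
  manual <- G; manual[, "v3"] <- 2 - manual[, "v3"]
  expect_equal(s_flip, as.vector(manual %*% w$weight))
})

test_that("MR estimators handle proportional and noisy instruments", {
  bx <- c(0.1, 0.2, 0.35, 0.15)
  m <- mr_ivw_egger(bx, rep(0.01, 4), 2 * bx, rep(0.02, 4))
  expect_equal(m$ivw$estimate, 2, tolerance = 1e-12)
  expect_equal(m$egger$intercept, 0, tolerance = 1e-12)
  expect_equal(m$egger$slope, 2, tolerance = 1e-12)

  set.seed(31)
  bx2 <- runif(30, 0.05, 0.4)
  by2 <- 1.5 * bx2 + rnorm(30, 0, 0.02)
  m2 <- mr_ivw_egger(bx2, rep(0.01, 30), by2, rep(0.02, 30))
  expect_lt(abs(m2$ivw$estimate - 1.5), 4 * m2$ivw$se)
  expect_lt(m2$ivw$p_value, 1e-6)

  expect_error(mr_ivw_egger(0.1, 0.01, 0.2, 0.02), "2 instruments")
  m3 <- mr_ivw_egger(c(0.1, 0.2), c(0.01, 0.01), c(0.2, 0.4),
                     c(0.02, 0.02))
  expect_null(m3$egger)    # Egger needs >= 3
})
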