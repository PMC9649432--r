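test_that("protocol constructors carry the standard echo trains", {
  g <- gre_protocol()
  expect_length(g$echo_times, 10L)
  expect_equal(g$echo_times_ms[1], 2.38)
  expect_equal(g$echo_times_ms[4], 9.53)
  expect_equal(g$echo_times_ms[10], 23.82)
  i <- ideal_protocol()
  expect_equal(i$echo_times_ms, c(1.2, 3.2, 5.2, 7.2, 9.2, 11.2))
  # ms in config, seconds internally
  expect_equal(i$echo_times, i$echo_times_ms / 1000)
  expect_error(hf_protocol(c(2, 1, 3)), "strictly increasing")
  expect_error(hf_protocol(c(1, 2, 3), noise_sd = -1), "non-negative")
})

test_that("parameter-map generator honours the pdff distribution", {
  # point mass at 0: no fat anywhere
  m0 <- flat_phantom(0, seed = 1)
  expect_true(all(m0$rho_f == 0))
  expect_true(all(m0$r2star >= 0))
  expect_true(any(m0$mask))

  # uniform(0, 0.4): mean inside mask within 3 s.e. of 0.2, judged
  # against direct resampling of the same distribution
  m <- simulate_parameter_maps(c(64, 64),
                               list(kind = "uniform", min = 0, max = 0.4),
                               seed = 42)
  pd <- true_pdff(m)[m$mask]
  se <- sqrt(0.4^2 / 12 / length(pd))
  expect_lt(abs(mean(pd) - 0.2), 3 * se)
  draws <- withr::with_seed(7, runif(length(pd), 0, 0.4))
  expect_lt(abs(mean(pd) - mean(draws)), 6 * se)

  # zero polynomial -> flat field
  expect_true(all(flat_phantom(0.1, seed = 3, field = c(0))$field_map == 0))
  expect_error(simulate_parameter_maps(c(16, 16), seed = 1), "32")
  expect_error(simulate_parameter_maps(c(64, 64),
                                       r2star_range = c(0, 900), seed = 1),
               "500")
})

test_that("forward model is exact without noise", {
  p <- ideal_protocol()
  maps <- simulate_parameter_maps(
    c(32, 32), list(kind = "uniform", min = 0, max = 0.5),
    r2star_range = c(10, 100), field_poly = c(5, 20, -10), seed = 9)
  img <- simulate_multiecho(maps, p, seed = 1)
  expected <- wf_signal_model(as.vector(maps$rho_w), as.vector(maps$rho_f),
                              as.vector(maps$field_map),
                              as.vector(maps$r2star),
                              p$echo_times, p$fat_shift_hz)
  expect_equal(as.vector(img$data), as.vector(expected), tolerance = 0)

  # water-only, no decay, no field: magnitude equals rho_w at every echo
  y <- voxel_signal(0.8, 0, 0, 0, p)
  expect_equal(Mod(y), rep(0.8, 6))

  # opposed-phase cancellation: W = F and half-cycle fat phase
  proto <- hf_protocol(c(1, 2, 3) / 0.217 * 0.5, fat_shift_hz = 217)
  y2 <- voxel_signal(0.5, 0.5, 0, 0, proto)
  expect_lt(Mod(y2[1]), 1e-12)
})

test_that("noise is calibrated, circular and seed-deterministic", {
  maps <- flat_phantom(0.2, seed = 5, shape = c(128L, 128L))
  p <- gre_protocol(noise_sd = 0.05)
  img <- simulate_multiecho(maps, p, seed = 77)
  img0 <- simulate_multiecho(maps, gre_protocol(noise_sd = 0), seed = 77)
  res <- img$data - img0$data   # >= 1e4 mask voxels x 10 echoes
  expect_lt(abs(sd(Re(res)) / 0.05 - 1), 0.05)
  expect_lt(abs(sd(Im(res)) / 0.05 - 1), 0.05)
  expect_lt(abs(cor(as.vector(Re(res)), as.vector(Im(res)))), 0.02)

  # bit-identical under the same seed; caller's RNG untouched
  set.seed(1); before <- runif(1)
  img2 <- simulate_multiecho(maps, p, seed = 77)
  expect_identical(img$data, img2$data)
  set.seed(1)
  expect_identical(before, runif(1))
})

test_that("swap injection shifts the field by half the fat shift", {
  maps <- flat_phantom(0.2, seed = 11, shape = c(64L, 64L), field = c(3))
  expect_identical(inject_swap_region(maps, NULL), maps)

  region <- c(20L, 40L, 20L, 40L)
  out <- inject_swap_region(maps, region, fat_shift_hz = 217)
  inside <- matrix(FALSE, 64, 64)
  inside[20:40, 20:40] <- TRUE
  expect_equal(out$field_map[inside], maps$field_map[inside] + 217 / 2)
  expect_equal(out$field_map[!inside], maps$field_map[!inside])
  expect_identical(out$rho_w, maps$rho_w)

  expect_error(inject_swap_region(maps, c(1L, 5L, 1L, 5L)),
               "does not intersect")
  expect_error(inject_swap_region(maps, c(1L, 80L, 1L, 80L)), "outside")
})

test_that("swap-offset region corrupts Dixon PDFF only inside the region", {
  sp <- swap_phantom(seed = 301)
  fit <- dixon_pdff_map(sp$image)
  truth <- true_pdff(sp$maps)
  inside <- matrix(FALSE, 64, 64)
  inside[sp$region[1]:sp$region[2], sp$region[3]:sp$region[4]] <- TRUE
  err_in <- mean(abs(fit$pdff - truth)[sp$maps$mask & inside])
  err_out <- mean(abs(fit$pdff - truth)[sp$maps$mask & !inside])
  expect_gt(err_in, 5 * err_out)
  expect_lt(err_out, 0.05)
})

test_that("cohort genotypes follow Hardy-Weinberg at the requested maf", {
  co <- simulate_cohort(10000, c(a = 0.5, b = 0.1), seed = 123)
  # empirical allele frequency within 3 binomial s.e.
  for (k in 1:2) {
    maf <- co$mafs[k]
    fhat <- mean(co$genotypes[, k]) / 2
    expect_lt(abs(fhat - maf), 3 * sqrt(maf * (1 - maf) / (2 * 10000)))
  }
  # chi-square GOF against Binomial(2, maf) counts
  p_gof <- sapply(1:2, function(k) {
    obs <- tabulate(co$genotypes[, k] + 1L, 3L)
    expd <- stats::dbinom(0:2, 2, co$mafs[k]) * 10000
    stats::pchisq(sum((obs - expd)^2 / expd), df = 2, lower.tail = FALSE)
  })
  expect_true(all(p_gof > 0.01))
  expect_error(simulate_cohort(100, c(0.7), seed = 1), "0.5")
  expect_error(simulate_cohort(10, c(0.3), seed = 1), "at least 50")
})

test_that("null cohort traits are independent of genotypes", {
  pvals <- sapply(1:40, function(r) {
    co <- simulate_cohort(300, c(0.3), beta = 0, gamma = 0, seed = r)
    additive_assoc(co$genotypes[, 1], co$traits$trait)$p_value
  })
  # p-values roughly uniform: KS test should not reject strongly
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
  expect_lt(mean(pvals < 0.05), 0.2)
})

test_that("proteome generator plants shifts only in informative analytes", {
  co <- simulate_cohort(600, c(0.3),
                        disease_model = list(intercept = 0, exact = TRUE),
                        seed = 5)
  pan <- simulate_proteome(co, 50, 5, effect = 1.0, seed = 6)
  expect_identical(pan$informative_ids, colnames(pan$levels)[1:5])
  d <- colMeans(pan$levels[pan$labels, ]) -
    colMeans(pan$levels[!pan$labels, ])
  expect_true(all(d[1:5] > 0.6))
  expect_lt(max(abs(d[6:50])), 0.4)

  # effect 0: label permutation leaves analytes exchangeable
  pan0 <- simulate_proteome(co, 30, 0, effect = 0, seed = 7)
  expect_identical(pan0$informative_ids, character(0))
  p <- apply(pan0$levels, 2, function(x) {
    stats::t.test(x[pan0$labels], x[!pan0$labels])$p.value
  })
  expect_lt(mean(p < 0.05), 0.2)
  expect_error(simulate_proteome(co, 10, 11, 1, seed = 1),
               "exceed")
})

test_that("informative analytes reach the analytic power of the z-test", {
  # effect 0.8 s.d. with 300/300: two-sample z power essentially 1;
  # check rejection in every one of 30 replicates
  hits <- sapply(1:30, function(r) {
    co <- simulate_cohort(600, c(0.3),
                          disease_model = list(intercept = 0, exact = TRUE),
                          seed = 100 + r)
    pan <- simulate_proteome(co, 20, 1, effect = 0.8, seed = 200 + r)
    stats::t.test(pan$levels[pan$labels, 1],
                  pan$levels[!pan$labels, 1])$p.value < 0.05
  })
  power <- stats::pnorm(0.8 / sqrt(1 / 300 + 1 / 300) -
                          stats::qnorm(0.975))
  expect_gt(power, 0.95)            # analytic oracle
  expect_gte(mean(hits), 0.95)      # simulated power matches
})
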