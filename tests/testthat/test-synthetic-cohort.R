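test_that("genotype draws follow Hardy-Weinberg proportions", {
  set.seed(101)
  expect_true(all(draw_genotypes(0, 100) == "AA"))
  expect_true(all(draw_genotypes(1, 100) == "aa"))
  expect_error(draw_genotypes(-0.1, 10), "\\[0, 1\\]")
  expect_error(draw_genotypes(1.2, 10), "\\[0, 1\\]")

  # carrier fraction at q = 0.36: 2pq + q^2 = 0.5904
  g <- draw_genotypes(0.36, 1e5)
  carrier <- mean(g != "AA")
  se <- sqrt(0.5904 * (1 - 0.5904) / 1e5)
  expect_lt(abs(carrier - 0.5904), 3 * se)

  # genotype frequencies pass a chi-square GOF against HWE at the nominal
  # rate: at least 94% non-significant across replicates at n = 1e4
  q <- 0.2
  expected <- c(AA = (1 - q)^2, Aa = 2 * (1 - q) * q, aa = q^2)
  pvals <- replicate(1000, {
    tab <- table(factor(draw_genotypes(q, 1e4), c("AA", "Aa", "aa")))
    suppressWarnings(stats::chisq.test(tab, p = expected)$p.value)
  })
  expect_gte(mean(pvals > 0.05), 0.94)
})

test_that("cohort simulation is deterministic given the seed", {
  a <- simulate_cohort(sim_config(), seed = 7)
  b <- simulate_cohort(sim_config(), seed = 7)
  expect_identical(a, b)
  c2 <- simulate_cohort(sim_config(), seed = 8)
  expect_false(identical(a$fat_kg, c2$fat_kg))
})

test_that("simulated cohorts satisfy the input contract", {
  coh <- simulate_cohort(sim_config(), seed = 3)
  expect_equal(nrow(coh), 202L)
  expect_equal(sum(coh$fh == "FH-"), 122L)
  expect_equal(sum(coh$fh == "FH+"), 80L)
  expect_true(all(coh$gender %in% c("F", "M")))
  expect_true(all(coh$genotype %in% c("AA", "Aa", "aa")))
  meas <- as.matrix(coh[, c("height_m", "waist_cm", "hip_cm", "lean_kg",
                            "bone_kg", "fat_kg")])
  expect_true(all(is.finite(meas)) && all(meas > 0))
  expect_false(anyNA(coh))
})

test_that("config validation rejects invalid parameters", {
  expect_error(sim_config(q_fh_plus = 1.3), "\\[0, 1\\]")
  expect_error(sim_config(d2 = -0.1), "d2")
  expect_error(sim_config(s = 0), "s must be")
  bad <- default_loadings(); bad[1, ] <- c(0.9, 0.9)
  expect_error(sim_config(loading_matrix = bad), "sum to <= 1")
  expect_error(sim_config(uniquenesses = rep(0.5, 6)),
               "1 - communality")
  # default m1 centres the pooled latent Adiposity at ~0
  cfg <- sim_config()
  coh <- simulate_cohort(cfg, seed = 5)
  lat <- attr(coh, "latent")
  expect_lt(abs(mean(lat$adiposity)), 0.15)
})

test_that("no genetic effect means identical latent distributions", {
  cfg <- sim_config(d2 = 0, n_fh_minus = 500, n_fh_plus = 500)
  coh <- simulate_cohort(cfg, seed = 11)
  lat <- attr(coh, "latent")
  ks <- stats::ks.test(lat$adiposity[coh$fh == "FH+"],
                       lat$adiposity[coh$fh == "FH-"])
  expect_gt(ks$p.value, 0.05)
})

test_that("latent group difference equals d2 times the carrier-fraction gap", {
  cfg <- sim_config(n_fh_minus = 2e4, n_fh_plus = 2e4)
  coh <- simulate_cohort(cfg, seed = 13)
  lat <- attr(coh, "latent")
  diff_obs <- mean(lat$adiposity[coh$fh == "FH+"]) -
    mean(lat$adiposity[coh$fh == "FH-"])
  diff_expected <- cfg$d2 * (alpha_from_q(cfg$q_fh_plus) -
                               alpha_from_q(cfg$q_fh_minus))  # ~0.39
  expect_lt(abs(diff_obs - diff_expected), 0.03)
  expect_lt(abs(diff_expected - 0.40), 0.02)
})

test_that("log-measure correlations converge to Lambda Lambda' + Psi", {
  cfg <- unit_config(n_fh_minus = 5e4, n_fh_plus = 5e4)
  coh <- simulate_cohort(cfg, seed = 17)
  R_obs <- cor(log(as.matrix(coh[, c("height_m", "waist_cm", "hip_cm",
                                     "lean_kg", "bone_kg", "fat_kg")])))
  L <- cfg$loading_matrix
  R_gen <- L %*% t(L) + diag(cfg$uniquenesses)
  expect_lt(max(abs(R_obs - R_gen)), 0.05)
})

test_that("configuration JSON round-trips", {
  cfg <- sim_config(q_fh_plus = 0.25, seed = 42L)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$q_fh_plus, 0.25)
  expect_equal(cfg2$m1, cfg$m1)
  expect_equal(cfg2$loading_matrix, cfg$loading_matrix,
               ignore_attr = TRUE)
  expect_equal(simulate_cohort(cfg, seed = 1)$fat_kg,
               simulate_cohort(cfg2, seed = 1)$fat_kg, tolerance = 1e-12)
})
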