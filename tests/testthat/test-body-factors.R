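toy_cohort <- function(height = c(1, exp(1), exp(2))) {
  n <- length(height)
  set.seed(99)
  data.frame(id = as.character(seq_len(n)), gender = rep("F", n),
             age = seq(20, 60, length.out = n), fh = rep("FH+", n),
             height_m = height,
             waist_cm = exp(rnorm(n, 4.4, 0.2)),
             hip_cm = exp(rnorm(n, 4.6, 0.2)),
             lean_kg = exp(rnorm(n, 3.8, 0.2)),
             bone_kg = exp(rnorm(n, 1.0, 0.2)),
             fat_kg = exp(rnorm(n, 3.2, 0.2)))
}

test_that("standardize_log centres and scales log measurements", {
  z <- standardize_log(toy_cohort())
  # log(1, e, e^2) standardized with the sample-SD convention
  expect_equal(unname(z[, "height"]), c(-1, 0, 1), tolerance = 1e-12)

  coh <- simulate_cohort(sim_config(), seed = 2)
  z <- standardize_log(coh)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-12)

  bad <- toy_cohort(); bad$fat_kg[2] <- -1
  expect_error(standardize_log(bad), "row 2, column 'fat_kg'")
  const <- toy_cohort(); const$hip_cm <- rep(100, 3)
  expect_error(standardize_log(const), "zero variance")
})

test_that("ML factor fit recovers a known generating model", {
  cfg <- unit_config(n_fh_minus = 5e4, n_fh_plus = 5e4)
  coh <- simulate_cohort(cfg, seed = 21)
  z <- standardize_log(coh)
  fit <- ml_factor_fit(z, 2L)
  fitted_R <- fit$loadings %*% t(fit$loadings) + diag(fit$uniquenesses)
  L <- cfg$loading_matrix
  gen_R <- L %*% t(L) + diag(cfg$uniquenesses)
  expect_lt(max(abs(fitted_R - gen_R)), 0.02)
  expect_lt(max(abs(rowSums(fit$loadings^2) + fit$uniquenesses - 1)), 1e-6)
  expect_error(ml_factor_fit(z, 0L), "factors")
})

test_that("the fitted common-variance structure is rotation invariant", {
  # rotate the generating loadings; Lambda Lambda' (hence the fit) is
  # unchanged
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  L0 <- default_loadings()
  cfg <- unit_config(n_fh_minus = 2e4, n_fh_plus = 2e4,
                     loading_matrix = L0 %*% R)
  coh <- simulate_cohort(cfg, seed = 23)
  fit <- ml_factor_fit(standardize_log(coh), 2L)
  fitted_LLt <- fit$loadings %*% t(fit$loadings)
  expect_lt(max(abs(fitted_LLt - L0 %*% t(L0))), 0.03)
})

test_that("varimax rotation matches the exhaustive angle-grid oracle", {
  th <- 0.5
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sets <- list(
    default_loadings() %*% R,
    matrix(c(0.8, -0.6, 0.6, 0.8), 2, 2) * 0.9,
    matrix(c(0.7, 0.6, 0.5, 0.1, -0.3, 0.6, 0.2, 0.6, -0.5, 0.4, 0.3,
             0.2), 6, 2),
    default_loadings() %*% matrix(c(cos(pi / 4), sin(pi / 4),
                                    -sin(pi / 4), cos(pi / 4)), 2, 2),
    matrix(c(0.9, 0.1, 0.5, 0.4, 0.2, 0.8, 0.3, 0.6), 4, 2)
  )
  for (L in sets) {
    model <- make_model(L)
    rot <- varimax_rotate(model)
    oracle <- varimax_grid_oracle(L)
    expect_lt(align_diff(rot$loadings, oracle$loadings), 1e-4)
    # criterion is non-decreasing and matches the oracle optimum
    expect_gte(varimax_criterion(rot$loadings) + 1e-10,
               varimax_criterion(L))
    expect_lt(abs(varimax_criterion(rot$loadings) - oracle$criterion),
              1e-6)
    # communalities are invariant under rotation
    expect_lt(max(abs(rowSums(rot$loadings^2) - rowSums(L^2))), 1e-10)
    # orthonormal accumulated rotation
    expect_lt(max(abs(crossprod(rot$rotation) - diag(2))), 1e-8)
  }
})

test_that("varimax leaves an already-optimal pattern in place", {
  # perfect simple structure is a varimax fixed point
  L <- rbind(c(0.9, 0), c(0.8, 0), c(0.7, 0),
             c(0, 0.9), c(0, 0.8), c(0, 0.7))
  rot <- varimax_rotate(make_model(L))
  expect_lt(align_diff(rot$loadings, L), 1e-6)
  # the near-simple default pattern moves very little
  rot2 <- varimax_rotate(make_model(default_loadings()))
  expect_lt(align_diff(rot2$loadings, default_loadings()), 0.05)
})

test_that("Bartlett scores invert the noise-free factor model exactly", {
  set.seed(31)
  L <- default_loadings()
  F_true <- matrix(rnorm(400), 200, 2)
  z <- F_true %*% t(L)
  model <- make_model(L)
  scores <- bartlett_scores(z, model)
  expect_lt(max(abs(scores - F_true)), 1e-6)
  # linearity: an all-zero row scores zero
  expect_equal(unname(bartlett_scores(rbind(rep(0, 6)), model)[1, ]),
               c(0, 0))
})

test_that("Bartlett scores are unbiased for the latent factors", {
  cfg <- unit_config(n_fh_minus = 5e3, n_fh_plus = 5e3)
  coh <- simulate_cohort(cfg, seed = 33)
  lat <- attr(coh, "latent")
  bf <- fit_body_factors(coh)
  for (pair in list(c("frame", "frame"), c("adiposity", "adiposity"))) {
    slope <- coef(lm(bf$scores[[pair[1]]] ~ lat[[pair[2]]]))[2]
    expect_lt(abs(slope - 1), 0.05)
  }
})

test_that("labels and signs follow the Frame/Adiposity convention", {
  L <- default_loadings()
  L[, 2] <- -L[, 2]                   # fat loads negatively
  set.seed(35)
  sc <- matrix(rnorm(20), 10, 2)
  out <- label_and_sign(make_model(L), sc)
  expect_identical(colnames(out$model$loadings), c("Frame", "Adiposity"))
  expect_gt(out$model$loadings["height", "Frame"], 0)
  expect_gt(out$model$loadings["fat", "Adiposity"], 0)
  expect_equal(out$scores[, 2], -sc[, 2])

  # swapped column order yields the identical labelled output
  swapped <- label_and_sign(make_model(L[, 2:1]), sc[, 2:1])
  expect_equal(swapped$model$loadings, out$model$loadings)
  expect_equal(swapped$scores, out$scores, ignore_attr = TRUE)

  amb <- default_loadings()
  amb["height", ] <- c(0.5, 0.52)
  expect_warning(label_and_sign(make_model(amb), sc), "ambiguous")
})

test_that("default cohorts give interpretable factors explaining ~80%", {
  coh <- simulate_cohort(sim_config(n_fh_minus = 1220, n_fh_plus = 800),
                         seed = 37)
  bf <- fit_body_factors(coh)
  expect_lt(abs(bf$model$var_explained$total - 0.80), 0.05)
  # Frame is the skeletal factor, Adiposity the fat-store factor
  L <- bf$model$loadings
  expect_gt(L["height", "Frame"], 0.6)
  expect_gt(L["fat", "Adiposity"], 0.6)
  expect_gt(cor(bf$scores$frame, log(coh$height_m)), 0)
  expect_gt(cor(bf$scores$adiposity, log(coh$fat_kg)), 0)
})
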