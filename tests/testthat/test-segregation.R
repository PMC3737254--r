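test_that("pooled deciles partition the sample into tenths", {
  d <- pooled_deciles(1:100)
  b <- findInterval(1:100, d$edges, rightmost.closed = TRUE)
  expect_equal(unname(tabulate(b, 10)), rep(10L, 10))
  expect_equal(d$midpoints, (d$edges[-11] + d$edges[-1]) / 2)
  expect_equal(d$widths, diff(d$edges))

  expect_error(pooled_deciles(rep(1:5, 10)), "at least 20 distinct")
  expect_error(pooled_deciles(c(rep(0, 60), 1:40)), "tied decile edges")

  set.seed(51)
  d <- pooled_deciles(rnorm(1e5))
  expect_lt(max(d$widths[5:6]), min(d$widths[c(1, 10)]))
})

test_that("decile densities integrate to one within each group", {
  set.seed(53)
  x <- c(rnorm(122, -0.1), rnorm(80, 0.4))
  g <- rep(c("FH-", "FH+"), c(122, 80))
  p <- decile_relative_risk(x, g)
  expect_equal(sum(p$density_fh_plus * p$widths), 1, tolerance = 1e-9)
  expect_equal(sum(p$density_fh_minus * p$widths), 1, tolerance = 1e-9)
  expect_equal(unname(colSums(p$counts)), c(80L, 122L))
})

test_that("identical groups give unit relative risks", {
  set.seed(55)
  x0 <- rnorm(100)
  p <- decile_relative_risk(c(x0, x0), rep(c("FH+", "FH-"), each = 100))
  expect_equal(p$rr, rep(1, 10), tolerance = 1e-12)
})

test_that("relative-risk arithmetic matches the hand-computed example", {
  ci <- rr_ci(12, 80, 5, 122)
  expect_equal(round(ci$rr, 2), 3.66)
  expect_equal(ci$se, sqrt(1 / 12 - 1 / 80 + 1 / 5 - 1 / 122))
  expect_equal(ci$lo, ci$rr * exp(-1.96 * ci$se))
  expect_equal(ci$hi, ci$rr * exp(1.96 * ci$se))
})

test_that("deciles empty in one group get a flagged continuity correction", {
  set.seed(57)
  # FH+ shifted far right: the lowest pooled deciles contain no FH+
  x <- c(rnorm(122, 0), rnorm(80, 5))
  p <- decile_relative_risk(x, rep(c("FH-", "FH+"), c(122, 80)))
  expect_true(any(p$corrected))
  expect_true(all(is.finite(p$rr[!p$undefined])))
  expect_true(all(p$rr[!p$undefined] > 0))
})

test_that("the bimodal fit recovers exact mixture densities", {
  truth <- c(m1 = -0.30, d2 = 0.93, s = 0.30, alpha = 0.59)
  mid <- seq(-0.9, 1.2, length.out = 10)
  dens <- bimodal_density(mid, truth[1], truth[2], truth[3], truth[4])
  fit <- fit_bimodal(mid, dens)
  expect_true(fit$converged)
  expect_lt(abs(fit$m1 - truth[1]), 1e-4)
  expect_lt(abs(fit$d2 - truth[2]), 1e-4)
  expect_lt(abs(fit$s - truth[3]), 1e-4)
  expect_lt(abs(fit$alpha - truth[4]), 1e-4)
  expect_lt(fit$sse, 1e-10)
})

test_that("unimodal densities produce a flagged degenerate fit", {
  mid <- seq(-2, 2, length.out = 10)
  fit <- fit_bimodal(mid, dnorm(mid))
  expect_true(fit$degenerate)
  expect_lt(fit$sse, 1e-6)
})

test_that("the optimizer beats every multistart initial point", {
  set.seed(59)
  x <- rmix(200, -0.3, 0.93, 0.3, 0.59)
  d <- pooled_deciles(x)
  b <- pmin(pmax(findInterval(x, d$edges, rightmost.closed = TRUE), 1), 10)
  dens <- (tabulate(b, 10) / length(x)) / d$widths
  fit <- fit_bimodal(d$midpoints, dens, d$widths)
  obj <- function(p) sum((dens - bimodal_density(d$midpoints, p[1], p[2],
                                                 p[3], p[4]))^2)
  for (a in c(0.2, 0.5, 0.8)) for (dd in c(0.3, 0.9, 1.5))
    expect_lte(fit$sse, obj(c(mean(x) - a * dd, dd, sd(x), a)) + 1e-12)
})

test_that("the bimodal fit matches a brute-force lattice search", {
  mid <- seq(-1.2, 1.5, length.out = 10)
  cases <- list(c(-0.3, 0.93, 0.3, 0.59), c(0, 0.5, 0.2, 0.3),
                c(-0.8, 1.5, 0.4, 0.7), c(-0.2, 0, 0.5, 0.5),
                c(-0.5, 1.0, 0.15, 0.2))
  for (p in cases) {
    dens <- bimodal_density(mid, p[1], p[2], p[3], p[4])
    fit <- fit_bimodal(mid, dens)
    oracle <- bimodal_grid_oracle(mid, dens)
    expect_lte(fit$sse, oracle$sse + 1e-10)
  }
})

test_that("heritability follows 1 - s^2 with covariate rescaling", {
  h <- heritability(0.30, 0.12)
  expect_equal(h$h2_adjusted, 0.91)
  expect_equal(h$h2_unadjusted, 0.8008)
  expect_equal(h$h2_unadjusted, h$h2_adjusted * (1 - h$r2_covariates),
               tolerance = 1e-9)
  expect_equal(heritability(1, 0.5)$h2_adjusted, 0)
  expect_equal(heritability(0.4, 0)$h2_unadjusted,
               heritability(0.4, 0)$h2_adjusted)
  expect_warning(h2 <- heritability(1.2, 0.1), "clamped")
  expect_equal(h2$h2_adjusted, 0)
  expect_error(heritability(-1, 0.1), "s must be")
  expect_error(heritability(0.3, 1), "r2_covariates")
})
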