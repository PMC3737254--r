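# Independent oracles and small builders shared across tests.

# paper-like study conditions (defaults of sim_config), scaled where noted
paper_config <- function(...) sim_config(...)

# a configuration whose latent factors have unit variance, so the
# measurement-model loadings are exactly the variable-factor correlations
unit_config <- function(n_fh_minus = 122L, n_fh_plus = 80L, ...) {
  sim_config(n_fh_minus = n_fh_minus, n_fh_plus = n_fh_plus,
             d2 = 0, s = 1, adiposity_age_slope = 0,
             frame_gender_effect = 0, frame_sd = 1, ...)
}

# minimal factor_model builder for unit tests of rotation/scoring
make_model <- function(L) {
  L <- as.matrix(L)
  uniq <- pmax(1 - rowSums(L^2), 0.005)
  structure(list(loadings = L, uniquenesses = uniq, rotation = diag(ncol(L)),
                 var_explained = list(per_factor = colSums(L^2) / nrow(L),
                                      total = sum(L^2) / nrow(L)),
                 cov_explained = NA_real_,
                 variable_names = rownames(L), factor_labels = NULL,
                 n_obs = 1000L, R = L %*% t(L) + diag(uniq),
                 converged = TRUE),
            class = "factor_model")
}

# raw varimax criterion of Kaiser row-normalized loadings
varimax_criterion <- function(L) {
  h <- sqrt(rowSums(L^2))
  Ln <- L / h
  sum(Ln^4) - sum(colSums(Ln^2)^2) / nrow(Ln)
}

# exhaustive oracle for the k = 2 varimax optimum: two-stage grid over the
# single rotation angle (period pi/2 up to column permutation/sign)
varimax_grid_oracle <- function(L) {
  h <- sqrt(rowSums(L^2))
  Ln <- L / h
  crit_at <- function(theta) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    varimax_criterion((Ln %*% R) * h)
  }
  th <- seq(0, pi / 2, by = 1e-3)
  c1 <- vapply(th, crit_at, 0)
  best <- th[which.max(c1)]
  th2 <- seq(best - 2e-3, best + 2e-3, by = 1e-6)
  c2 <- vapply(th2, crit_at, 0)
  theta <- th2[which.max(c2)]
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  list(theta = theta, loadings = (Ln %*% R) * h, criterion = max(c2))
}

# max |A - B| after the best column permutation / sign alignment
align_diff <- function(A, B) {
  best <- Inf
  for (perm in list(1:2, 2:1))
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
      d <- max(abs(sweep(A[, perm, drop = FALSE], 2, c(s1, s2), "*") - B))
      best <- min(best, d)
    }
  best
}

# draw from the equal-variance two-component normal mixture
rmix <- function(n, m1, d2, s, alpha) {
  upper <- stats::runif(n) < alpha
  stats::rnorm(n, m1 + d2 * upper, s)
}

# decile-bin a sample on its own edges and fit the bimodal model,
# mirroring the production binning (half-open bins, last closed)
fit_mixture_sample <- function(x, n_starts = 20L) {
  d <- pooled_deciles(x)
  b <- findInterval(x, d$edges, rightmost.closed = TRUE)
  b <- pmin(pmax(b, 1L), 10L)
  dens <- (tabulate(b, nbins = 10L) / length(x)) / d$widths
  fit_bimodal(d$midpoints, dens, d$widths, n_starts = n_starts)
}

# brute-force lattice minimizer of the binned-density SSE
bimodal_grid_oracle <- function(midpoints, densities,
                                m1 = seq(-1.5, 0.5, by = 0.1),
                                d2 = seq(0, 2, by = 0.1),
                                s = seq(0.1, 1.2, by = 0.1),
                                alpha = seq(0, 1, by = 0.1)) {
  best <- list(sse = Inf)
  for (a in alpha) for (dd in d2) for (ss in s) {
    pred_hi <- outer(midpoints, m1 + dd, function(x, m)
      stats::dnorm(x, m, ss))
    pred_lo <- outer(midpoints, m1, function(x, m) stats::dnorm(x, m, ss))
    sse <- colSums((densities - ((1 - a) * pred_lo + a * pred_hi))^2)
    i <- which.min(sse)
    if (sse[i] < best$sse)
      best <- list(sse = sse[i], m1 = m1[i], d2 = dd, s = ss, alpha = a)
  }
  best
}
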