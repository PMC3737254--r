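# Decile density profiles, FH+/FH- relative risks, the constrained
# equal-variance bimodal normal fit, and heritability.

#' Decile bin edges of the pooled sample
#'
#' Edges are the 0%, 10%, ..., 100% sample quantiles of the pooled trait.
#' Bins are half-open `[e_i, e_{i+1})` with the last bin closed.
#'
#' @param values Numeric vector (>= 20 distinct values).
#' @return A list with `edges` (11), `midpoints` (10) and `widths` (10).
#' @export
pooled_deciles <- function(values) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 20L)
    stop("need at least 20 distinct values for decile binning",
         call. = FALSE)
  edges <- stats::quantile(values, seq(0, 1, 0.1), names = FALSE)
  dup <- which(diff(edges) <= 0)
  if (length(dup))
    stop(sprintf("tied decile edges at the %d%% quantile", 10L * dup[1]),
         call. = FALSE)
  list(edges = edges,
       midpoints = (edges[-11] + edges[-1]) / 2,
       widths = diff(edges))
}

# bin membership: [e_i, e_{i+1}) with the last bin closed; values outside
# the edge range (possible for group subsets of resampled data) clamp to
# the outer bins
.decile_bin <- function(x, edges) {
  b <- findInterval(x, edges, rightmost.closed = TRUE)
  pmin(pmax(b, 1L), length(edges) - 1L)
}

#' Per-decile relative risks between FH+ and FH- groups
#'
#' Bins the trait by deciles of the pooled sample and computes, per decile,
#' the occupancy probabilities `p_i = n_i / N` for each group, empirical
#' densities `p_i / width_i`, and the relative risk
#' `RR_i = p_i(FH+) / p_i(FH-)` with a 95% CI from the standard error of
#' `log(RR)` assuming normality:
#' `SE = sqrt(1/n_i+ - 1/N+ + 1/n_i- - 1/N-)`.
#' A decile empty in one group gets the Haldane-Anscombe correction (0.5
#' added to all four counts of that decile only) and is flagged; a decile
#' empty in both groups yields `NA` and is flagged undefined.
#'
#' @param values Numeric trait vector (e.g. adjusted Adiposity scores).
#' @param group Vector of group labels aligned with `values`.
#' @param positive,negative The labels of the FH+ and FH- groups.
#' @return An object of class `"decile_profile"`.
#' @examples
#' set.seed(1)
#' x <- rnorm(202)
#' g <- rep(c("FH-", "FH+"), c(122, 80))
#' decile_relative_risk(x, g)
#' @export
decile_relative_risk <- function(values, group, positive = "FH+",
                                 negative = "FH-") {
  keep <- is.finite(values) & group %in% c(positive, negative)
  values <- values[keep]; group <- group[keep]
  n_plus <- sum(group == positive)
  n_minus <- sum(group == negative)
  if (n_plus == 0L || n_minus == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  d <- pooled_deciles(values)
  bin <- .decile_bin(values, d$edges)
  cp <- tabulate(bin[group == positive], nbins = 10L)
  cm <- tabulate(bin[group == negative], nbins = 10L)

  undefined <- cp == 0L & cm == 0L
  corrected <- (cp == 0L | cm == 0L) & !undefined
  ci <- rr_ci(cp + 0.5 * corrected, n_plus + 1 * corrected,
              cm + 0.5 * corrected, n_minus + 1 * corrected)
  rr <- ci$rr; lo <- ci$lo; hi <- ci$hi
  rr[undefined] <- lo[undefined] <- hi[undefined] <- NA_real_

  structure(list(
    edges = d$edges, midpoints = d$midpoints, widths = d$widths,
    counts = cbind(fh_plus = cp, fh_minus = cm),
    density_fh_plus = (cp / n_plus) / d$widths,
    density_fh_minus = (cm / n_minus) / d$widths,
    rr = rr, ci_lo = lo, ci_hi = hi,
    corrected = corrected, undefined = undefined,
    N_plus = n_plus, N_minus = n_minus
  ), class = "decile_profile")
}

#' @export
print.decile_profile <- function(x, digits = 2, ...) {
  cat(sprintf("Decile profile (N+ = %d, N- = %d)\n", x$N_plus, x$N_minus))
  tab <- data.frame(decile = 1:10, n_plus = x$counts[, 1],
                    n_minus = x$counts[, 2],
                    RR = round(x$rr, digits),
                    lo = round(x$ci_lo, digits),
                    hi = round(x$ci_hi, digits))
  print(tab, row.names = FALSE)
  if (any(x$corrected))
    cat("(0.5 continuity correction applied to decile(s): ",
        paste(which(x$corrected), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Relative risk with a log-normal 95% confidence interval
#'
#' `RR = (n_plus/N_plus) / (n_minus/N_minus)` with
#' `CI = exp(log(RR) +/- 1.96 * SE)`,
#' `SE = sqrt(1/n_plus - 1/N_plus + 1/n_minus - 1/N_minus)`.
#'
#' @param n_plus,N_plus Occupancy count and group size for the FH+ group.
#' @param n_minus,N_minus Same for the FH- group. All vectorized.
#' @return A list with components `rr`, `lo`, `hi`, `se`.
#' @examples
#' rr_ci(12, 80, 5, 122)   # RR 3.66
#' @export
rr_ci <- function(n_plus, N_plus, n_minus, N_minus) {
  rr <- (n_plus / N_plus) / (n_minus / N_minus)
  se <- sqrt(1 / n_plus - 1 / N_plus + 1 / n_minus - 1 / N_minus)
  list(rr = rr, lo = exp(log(rr) - 1.96 * se),
       hi = exp(log(rr) + 1.96 * se), se = se)
}

#' Equal-variance bimodal normal density
#'
#' `(1 - alpha) * dnorm(x, m1, s) + alpha * dnorm(x, m1 + d2, s)`: a
#' two-component normal mixture with a common SD, lower-mode mean `m1`,
#' mode separation `d2 >= 0`, and upper-mode fraction `alpha`.
#'
#' @param x Numeric vector of evaluation points.
#' @param m1,d2,s,alpha Mixture parameters.
#' @export
bimodal_density <- function(x, m1, d2, s, alpha) {
  (1 - alpha) * stats::dnorm(x, m1, s) +
    alpha * stats::dnorm(x, m1 + d2, s)
}

# number of local maxima of the fitted mixture density: a fitted
# "bimodal" model whose density has a single mode is effectively unimodal
.n_modes <- function(m1, d2, s, alpha) {
  xs <- seq(m1 - 4 * s, m1 + d2 + 4 * s, length.out = 1024L)
  d <- diff(bimodal_density(xs, m1, d2, s, alpha))
  sum(d[-length(d)] > 0 & d[-1] <= 0)
}

#' Fit the bimodal normal model to binned densities
#'
#' Minimizes the unweighted sum of squared differences between the
#' empirical bin densities and the bimodal model evaluated at the bin
#' midpoints, using bounded quasi-Newton (`optim` method `"L-BFGS-B"`) with
#' `alpha` constrained to \[0, 1\], `d2 >= 0` and `s >= 0.01`, from
#' multiple starting points (the 4-parameter surface is multimodal).
#'
#' @param midpoints Bin midpoints.
#' @param densities Empirical bin densities.
#' @param widths Optional bin widths, used only to form moment-based
#'   starting values; uniform weights if omitted.
#' @param n_starts Number of starting points (>= 1; the default start grid
#'   crosses alpha in {0.2, 0.5, 0.8}, d2 in {0.3, 0.9, 1.5} and two
#'   moment-based spreads, truncated or recycled to `n_starts`).
#' @return An object of class `"bimodal_fit"` with elements `m1`, `d2`,
#'   `s`, `alpha`, `sse`, `converged`, `degenerate` (the fit is effectively
#'   unimodal: mode separation or mixing fraction at a boundary, or the
#'   fitted mixture density has a single local maximum), `n_starts`.
#' @export
fit_bimodal <- function(midpoints, densities, widths = NULL,
                        n_starts = 20L) {
  stopifnot(length(midpoints) == length(densities), length(midpoints) >= 5L)
  if (any(!is.finite(midpoints)) || any(!is.finite(densities)))
    stop("midpoints and densities must be finite", call. = FALSE)
  w <- if (is.null(widths)) rep(1, length(midpoints)) else
    densities * widths
  if (sum(w) <= 0) w <- rep(1, length(midpoints))
  w <- w / sum(w)
  mu <- sum(w * midpoints)
  sig <- sqrt(max(sum(w * (midpoints - mu)^2), 1e-4))

  obj <- function(par)
    sum((densities - bimodal_density(midpoints, par[1], par[2], par[3],
                                     par[4]))^2)
  lower <- c(-Inf, 0, 0.01, 0)
  upper <- c(Inf, Inf, Inf, 1)

  starts <- expand.grid(alpha = c(0.2, 0.5, 0.8), d2 = c(0.3, 0.9, 1.5),
                        s = c(0.5 * sig, sig))
  starts <- rbind(starts,
                  data.frame(alpha = 0.5, d2 = 2 * sig, s = 0.5 * sig),
                  data.frame(alpha = 0.5, d2 = sig, s = 0.75 * sig))
  starts$m1 <- mu - starts$alpha * starts$d2
  idx <- rep_len(seq_len(nrow(starts)), max(1L, as.integer(n_starts)))
  starts <- starts[idx, , drop = FALSE]

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- pmax(c(starts$m1[i], starts$d2[i], starts$s[i],
                   starts$alpha[i]), lower)
    par0 <- pmin(par0, upper)
    res <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = 1e2, pgtol = 1e-12,
                                  maxit = 500L, ndeps = rep(1e-7, 4L))),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(structure(list(m1 = mu, d2 = 0, s = sig, alpha = 0.5,
                          sse = obj(c(mu, 0, sig, 0.5)), converged = FALSE,
                          degenerate = TRUE, n_starts = nrow(starts)),
                     class = "bimodal_fit"))
  par <- best$par
  structure(list(m1 = par[1], d2 = par[2], s = par[3], alpha = par[4],
                 sse = best$value, converged = best$convergence == 0L,
                 degenerate = par[2] < 0.05 || par[4] < 0.02 ||
                   par[4] > 0.98 ||
                   .n_modes(par[1], par[2], par[3], par[4]) < 2L,
                 n_starts = nrow(starts)),
            class = "bimodal_fit")
}

#' @export
print.bimodal_fit <- function(x, digits = 3, ...) {
  cat("Bimodal normal fit (equal variance)\n")
  cat(sprintf("  m1 = %.*f, d2 = %.*f, s = %.*f, alpha = %.*f\n",
              digits, x$m1, digits, x$d2, digits, x$s, digits, x$alpha))
  cat(sprintf("  SSE = %.3g, converged = %s%s\n", x$sse, x$converged,
              if (x$degenerate) " (degenerate/unimodal)" else ""))
  invisible(x)
}

#' Heritability from the bimodal-fit residual SD
#'
#' On the adjusted scale (trait in SD units) the within-mode variance `s^2`
#' is the error-variance proportion, so `h2_adjusted = 1 - s^2`. Expressed
#' in terms of the unadjusted trait, the gender + age covariates reclaim a
#' proportion `r2_covariates` of total variance:
#' `h2_unadjusted = (1 - s^2) * (1 - r2_covariates)`.
#'
#' @param fit A `"bimodal_fit"` object, or the numeric within-mode SD `s`.
#' @param r2_covariates R-squared of the gender + age-tertile model on the
#'   unadjusted trait (in \[0, 1)).
#' @return An object of class `"heritability"` with `h2_adjusted`,
#'   `h2_unadjusted`, `e2` and `r2_covariates`.
#' @examples
#' heritability(0.30, 0.12)
#' @export
heritability <- function(fit, r2_covariates = 0) {
  s <- if (inherits(fit, "bimodal_fit")) fit$s else as.numeric(fit)
  if (!is.finite(s) || s <= 0) stop("s must be > 0", call. = FALSE)
  if (r2_covariates < 0 || r2_covariates >= 1)
    stop("r2_covariates must lie in [0, 1)", call. = FALSE)
  e2 <- s^2
  if (e2 > 1) {
    warning("s^2 > 1: heritability clamped to 0 (trait should be in SD ",
            "units)", call. = FALSE)
    e2 <- 1
  }
  h2 <- 1 - e2
  structure(list(h2_adjusted = h2,
                 h2_unadjusted = h2 * (1 - r2_covariates),
                 e2 = e2, r2_covariates = r2_covariates),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("Heritability: %.0f%% (adjusted scale), %.0f%% (unadjusted, ",
              100 * x$h2_adjusted, 100 * x$h2_unadjusted))
  cat(sprintf("covariate R^2 = %.2f)\n", x$r2_covariates))
  invisible(x)
}
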