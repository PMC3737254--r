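# Dominant bi-allelic Hardy-Weinberg machinery: inversion of phenotypic
# fractions to risk-allele frequencies, spouse-pool inference for the
# unobserved T2DM-affected relatives, and the sensitivity/risk arithmetic.

.check01 <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    stop(name, " must lie in [0, 1]", call. = FALSE)
  x
}

.clamp01 <- function(x, what) {
  if (x < 0 || x > 1) {
    warning(what, " clamped to [0, 1]", call. = FALSE)
    x <- min(max(x, 0), 1)
  }
  x
}

#' Risk-allele frequency from a dominant phenotype fraction
#'
#' Under Hardy-Weinberg equilibrium with dominant expression, the fraction
#' of a population showing the phenotype is `alpha = 2*p*q + q^2` (carriers
#' Aa plus aa). Inverting: `q = 1 - sqrt(1 - alpha)`.
#'
#' @param alpha Phenotypic (upper-mode) fraction in \[0, 1\]; vectorized.
#' @return Risk-allele frequency `q`.
#' @examples
#' q_from_alpha(0.59)   # ~0.36
#' @export
q_from_alpha <- function(alpha) {
  .check01(alpha, "alpha")
  1 - sqrt(1 - alpha)
}

#' @rdname q_from_alpha
#' @param q Risk-allele frequency in \[0, 1\]; vectorized. `alpha_from_q()`
#'   is the exact inverse: `alpha = 2*(1-q)*q + q^2`.
#' @export
alpha_from_q <- function(q) {
  .check01(q, "q")
  2 * (1 - q) * q + q^2
}

#' Hardy-Weinberg genotype frequencies
#'
#' @param q Risk-allele frequency.
#' @return Named vector `(AA, Aa, aa) = (p^2, 2pq, q^2)`, `p = 1 - q`.
#' @export
genotype_freqs <- function(q) {
  .check01(q, "q")
  p <- 1 - q
  c(AA = p^2, Aa = 2 * p * q, aa = q^2)
}

#' FH- upper-mode fraction from the 8th-decile relative risk
#'
#' The FH- group's own bimodal structure is too weak to fit directly; its
#' upper-mode fraction is recovered from the FH+ fraction and the relative
#' risk of 8th-decile occupancy, `alpha_fh_minus = alpha_fh_plus / rr_8`
#' (the decile where upper-mode enrichment concentrates), clamped to
#' \[0, 1\] with a warning if needed.
#'
#' @param alpha_fh_plus FH+ upper-mode fraction in \[0, 1\].
#' @param rr_8 Relative risk (FH+/FH-) in the 8th decile (> 0).
#' @examples
#' fh_minus_upper_fraction(0.59, 3.6)   # ~0.16
#' @export
fh_minus_upper_fraction <- function(alpha_fh_plus, rr_8) {
  .check01(alpha_fh_plus, "alpha_fh_plus")
  if (!is.finite(rr_8) || rr_8 <= 0)
    stop("rr_8 must be > 0", call. = FALSE)
  .clamp01(alpha_fh_plus / rr_8, "alpha_fh_minus")
}

#' Risk-allele frequency in unobserved T2DM-affected relatives
#'
#' Assuming the FH- group represents the pool of spouses in the parental
#' generation and random mating, the offspring (FH+) allele frequency is
#' the mean of the affected-parent and spouse pools, so
#' `q_t2dm = 2*q_fh_plus - q_fh_minus`, clamped to \[0, 1\] with a warning
#' if needed.
#'
#' @param q_fh_minus,q_fh_plus Group risk-allele frequencies in \[0, 1\].
#' @examples
#' t2dm_allele_freq(0.09, 0.36)   # ~0.63
#' @export
t2dm_allele_freq <- function(q_fh_minus, q_fh_plus) {
  .check01(q_fh_minus, "q_fh_minus")
  .check01(q_fh_plus, "q_fh_plus")
  .clamp01(2 * q_fh_plus - q_fh_minus, "q_t2dm")
}

#' T2DM risk bounds for FH+ individuals
#'
#' If adiposity- and T2DM-susceptibility variants are inherited
#' independently, about half of the FH+ carriers of the high-Adiposity
#' genotype also carry T2DM susceptibility, giving risk `alpha * 0.5`; with
#' full pleiotropy the risk is `alpha` itself.
#'
#' @param alpha_fh_plus FH+ upper-mode fraction in \[0, 1\].
#' @return Named vector `(risk_independent, risk_pleiotropic)`.
#' @examples
#' t2dm_risk_bounds(0.59)   # 0.295, 0.59
#' @export
t2dm_risk_bounds <- function(alpha_fh_plus) {
  .check01(alpha_fh_plus, "alpha_fh_plus")
  c(risk_independent = alpha_fh_plus * 0.5,
    risk_pleiotropic = alpha_fh_plus)
}

#' Dominant-model allele estimates for FH-, FH+ and affected relatives
#'
#' Chains the dominant Hardy-Weinberg inversion: the FH- upper-mode
#' fraction comes from `alpha_fh_plus / rr_8` (unless given directly), each
#' fraction is inverted to an allele frequency, the affected-relative
#' frequency follows from the spouse-pool relation, and genotype
#' frequencies are tabulated for all three groups.
#'
#' @param alpha_fh_plus FH+ upper-mode fraction.
#' @param rr_8 8th-decile relative risk (used if `alpha_fh_minus` is NULL).
#' @param alpha_fh_minus Optional FH- upper-mode fraction, overriding the
#'   RR-based estimate.
#' @return An object of class `"allele_estimates"` with per-group `alpha`,
#'   `q` and a 3 x 3 genotype-frequency matrix.
#' @examples
#' allele_estimates(0.59, rr_8 = 3.6)
#' @export
allele_estimates <- function(alpha_fh_plus, rr_8 = NULL,
                             alpha_fh_minus = NULL) {
  .check01(alpha_fh_plus, "alpha_fh_plus")
  if (is.null(alpha_fh_minus)) {
    if (is.null(rr_8))
      stop("supply either rr_8 or alpha_fh_minus", call. = FALSE)
    alpha_fh_minus <- fh_minus_upper_fraction(alpha_fh_plus, rr_8)
  } else .check01(alpha_fh_minus, "alpha_fh_minus")
  q_minus <- q_from_alpha(alpha_fh_minus)
  q_plus <- q_from_alpha(alpha_fh_plus)
  q_t2dm <- t2dm_allele_freq(q_minus, q_plus)
  alpha_t2dm <- alpha_from_q(q_t2dm)
  geno <- rbind(fh_minus = genotype_freqs(q_minus),
                fh_plus = genotype_freqs(q_plus),
                t2dm = genotype_freqs(q_t2dm))
  structure(list(alpha_fh_minus = alpha_fh_minus,
                 alpha_fh_plus = alpha_fh_plus,
                 alpha_t2dm = alpha_t2dm,
                 q_fh_minus = q_minus, q_fh_plus = q_plus,
                 q_t2dm = q_t2dm,
                 genotype_freqs = geno, rr_8 = rr_8),
            class = "allele_estimates")
}

#' Sensitivity analysis: substitute the FH- phenotype fraction
#'
#' Replaces the FH- upper-mode fraction (e.g. with an external obesity
#' prevalence), recomputes `q_fh_minus`, and propagates through the
#' spouse-pool relation holding `q_fh_plus` fixed.
#'
#' @param alpha_fh_minus_new Replacement FH- fraction in \[0, 1\].
#' @param baseline An `"allele_estimates"` object.
#' @return A new `"allele_estimates"` object.
#' @examples
#' base <- allele_estimates(0.59, rr_8 = 3.6)
#' sensitivity_substitute_alpha(0.28, base)
#' @export
sensitivity_substitute_alpha <- function(alpha_fh_minus_new, baseline) {
  stopifnot(inherits(baseline, "allele_estimates"))
  allele_estimates(baseline$alpha_fh_plus,
                   alpha_fh_minus = .check01(alpha_fh_minus_new,
                                             "alpha_fh_minus_new"))
}

#' @export
print.allele_estimates <- function(x, digits = 2, ...) {
  cat("Dominant-model allele estimates (Hardy-Weinberg equilibrium)\n")
  tab <- rbind(alpha = c(x$alpha_fh_minus, x$alpha_fh_plus, x$alpha_t2dm),
               q = c(x$q_fh_minus, x$q_fh_plus, x$q_t2dm))
  colnames(tab) <- c("FH-", "FH+", "T2DM")
  print(round(tab, digits))
  if (!is.null(x$rr_8))
    cat(sprintf("(alpha FH- derived from RR_8 = %.2f)\n", x$rr_8))
  invisible(x)
}
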