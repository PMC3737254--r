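# Synthetic cohorts with known genetic ground truth.
#
# Forward model: a dominantly expressed bi-allelic genotype under
# Hardy-Weinberg equilibrium shifts a latent Adiposity factor in carriers;
# a gendered latent Frame factor drives skeletal size; six observed
# measurements arise from a two-factor linear model on the log scale.

#' Default factor loading pattern of the six log-measurements
#'
#' Frame loads the skeletal measures (height, lean mass, bone mass) heavily
#' and the circumferences lightly; Adiposity loads fat mass and the
#' circumferences heavily and the masses lightly. Each row's squared
#' loadings sum to less than 1, leaving positive uniquenesses.
#'
#' @return A 6 x 2 numeric matrix with rows height, waist, hip, lean, bone,
#'   fat and columns Frame, Adiposity.
#' @export
default_loadings <- function() {
  m <- rbind(
    height = c(0.90, 0.00),
    waist  = c(0.30, 0.85),
    hip    = c(0.10, 0.85),
    lean   = c(0.90, 0.35),
    bone   = c(0.90, 0.35),
    fat    = c(0.00, 0.95)
  )
  colnames(m) <- c("Frame", "Adiposity")
  m
}

# Log-scale location constants (typical adult values from the cohort
# summaries: height ~1.69 m, waist ~87 cm, hip ~102 cm, lean ~47 kg,
# bone ~2.8 kg, fat ~25 kg).
.default_measure_means <- function() {
  c(height = log(1.69), waist = log(87), hip = log(102),
    lean = log(47), bone = log(2.8), fat = log(25))
}

# Log-scale spread constants (approximately the observed CVs).
.default_measure_scales <- function() {
  c(height = 0.06, waist = 0.15, hip = 0.10,
    lean = 0.22, bone = 0.17, fat = 0.45)
}

#' Configuration for the synthetic-cohort generator
#'
#' Bundles and validates every parameter of the forward model. Defaults
#' reproduce the study conditions of the motivating cohort: 122 FH- and 80
#' FH+ individuals, risk-allele frequencies 0.09 (FH-) and 0.36 (FH+), a
#' dominant carrier shift of `d2 = 0.93` SD on latent Adiposity with
#' within-mode SD `s = 0.30`, a large gender effect on Frame and a positive
#' age trend on Adiposity.
#'
#' @param n_fh_minus,n_fh_plus Group sizes (FH-, FH+).
#' @param q_fh_minus,q_fh_plus Risk-allele frequencies in each group; the
#'   carrier (upper-mode) fraction of each group is `2*p*q + q^2`.
#' @param m1 Lower-mode mean of latent Adiposity (SD units). Default `NULL`
#'   chooses `m1` so the pooled latent mean is 0.
#' @param d2 Carrier shift on latent Adiposity (SD units, >= 0).
#' @param s Within-mode SD of latent Adiposity (> 0).
#' @param frame_gender_effect Mean Frame difference, males minus females
#'   (SD units).
#' @param frame_sd Within-gender SD of latent Frame.
#' @param adiposity_age_slope Adiposity change per age tertile (SD units).
#' @param age_range Numeric length-2, min and max age in years; ages are
#'   drawn uniformly.
#' @param p_female Probability an individual is female.
#' @param loading_matrix 6 x 2 loadings of the log-measurements on
#'   (Frame, Adiposity); rows in order height, waist, hip, lean, bone, fat.
#' @param uniquenesses Six positive unique variances; default
#'   `1 - rowSums(loading_matrix^2)` (the complement of the communalities,
#'   which the configuration also enforces to within 1e-6).
#' @param measure_means,measure_scales Six log-scale location and scale
#'   constants mapping factor-model scores to natural measurement units.
#' @param seed Optional integer seed stored with the configuration.
#'
#' @return A list of class `"adiposeg_config"`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_fh_minus = 122L, n_fh_plus = 80L,
                       q_fh_minus = 0.09, q_fh_plus = 0.36,
                       m1 = NULL, d2 = 0.93, s = 0.30,
                       frame_gender_effect = 1.75, frame_sd = 0.5,
                       adiposity_age_slope = 0.30,
                       age_range = c(20, 70), p_female = 0.6,
                       loading_matrix = default_loadings(),
                       uniquenesses = NULL,
                       measure_means = .default_measure_means(),
                       measure_scales = .default_measure_scales(),
                       seed = NULL) {
  n_fh_minus <- as.integer(n_fh_minus)
  n_fh_plus <- as.integer(n_fh_plus)
  if (n_fh_minus < 1L || n_fh_plus < 1L)
    stop("group sizes must be at least 1", call. = FALSE)
  for (q in list(q_fh_minus = q_fh_minus, q_fh_plus = q_fh_plus,
                 p_female = p_female))
    if (!is.finite(q) || q < 0 || q > 1)
      stop("frequencies must lie in [0, 1]", call. = FALSE)
  if (!is.finite(d2) || d2 < 0) stop("d2 must be >= 0", call. = FALSE)
  if (!is.finite(s) || s <= 0) stop("s must be > 0", call. = FALSE)
  if (frame_sd <= 0) stop("frame_sd must be > 0", call. = FALSE)
  if (length(age_range) != 2L || diff(age_range) <= 0)
    stop("age_range must be (min, max) with min < max", call. = FALSE)

  loading_matrix <- as.matrix(loading_matrix)
  if (!identical(dim(loading_matrix), c(6L, 2L)))
    stop("loading_matrix must be 6 x 2", call. = FALSE)
  rownames(loading_matrix) <- names(.measure_cols)
  colnames(loading_matrix) <- c("Frame", "Adiposity")
  comm <- rowSums(loading_matrix^2)
  if (any(comm > 1))
    stop("squared loadings in each row must sum to <= 1", call. = FALSE)
  if (is.null(uniquenesses)) uniquenesses <- 1 - comm
  if (length(uniquenesses) != 6L || any(uniquenesses <= 0))
    stop("uniquenesses must be 6 positive values", call. = FALSE)
  if (max(abs(uniquenesses - (1 - comm))) > 1e-6)
    stop("uniqueness_j must equal 1 - communality_j (tolerance 1e-6)",
         call. = FALSE)
  names(uniquenesses) <- names(.measure_cols)

  for (v in list(measure_means, measure_scales))
    if (length(v) != 6L) stop("measure constants must have length 6",
                              call. = FALSE)
  if (any(measure_scales <= 0))
    stop("measure_scales must be positive", call. = FALSE)

  # Pooled carrier fraction; the age-tertile trend is centred, so the pooled
  # latent mean is m1 + d2 * mean carrier fraction.
  alpha_minus <- alpha_from_q(q_fh_minus)
  alpha_plus <- alpha_from_q(q_fh_plus)
  alpha_bar <- (n_fh_minus * alpha_minus + n_fh_plus * alpha_plus) /
    (n_fh_minus + n_fh_plus)
  if (is.null(m1)) m1 <- -d2 * alpha_bar

  structure(list(
    n_fh_minus = n_fh_minus, n_fh_plus = n_fh_plus,
    q_fh_minus = q_fh_minus, q_fh_plus = q_fh_plus,
    m1 = m1, d2 = d2, s = s,
    frame_gender_effect = frame_gender_effect, frame_sd = frame_sd,
    adiposity_age_slope = adiposity_age_slope,
    age_range = as.numeric(age_range), p_female = p_female,
    loading_matrix = loading_matrix,
    uniquenesses = as.numeric(uniquenesses),
    measure_means = stats::setNames(as.numeric(measure_means),
                                    names(.measure_cols)),
    measure_scales = stats::setNames(as.numeric(measure_scales),
                                     names(.measure_cols)),
    seed = seed
  ), class = "adiposeg_config")
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' Genotypes AA, Aa, aa are drawn i.i.d. with probabilities `p^2`, `2*p*q`,
#' `q^2` where `q` is the risk-allele frequency and `p = 1 - q`.
#'
#' @param q Risk-allele frequency in \[0, 1\].
#' @param n Number of individuals.
#' @return Character vector of `"AA"`, `"Aa"`, `"aa"`. Uses the current R
#'   random number stream; call `set.seed()` for reproducibility.
#' @examples
#' set.seed(1)
#' table(draw_genotypes(0.36, 1000))
#' @export
draw_genotypes <- function(q, n) {
  if (!is.finite(q) || q < 0 || q > 1)
    stop("q must lie in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  p <- 1 - q
  sample(c("AA", "Aa", "aa"), n, replace = TRUE,
         prob = c(p^2, 2 * p * q, q^2))
}

# Population age terciles of the uniform age distribution; the generator's
# age trend is expressed per tertile, centred at the middle tertile.
.age_tercile_pop <- function(age, range) {
  cuts <- range[1] + diff(range) * c(1, 2) / 3
  1L + (age > cuts[1]) + (age > cuts[2])
}

#' Simulate a cohort from the two-factor genetic forward model
#'
#' Draws, in documented order from a single RNG stream: gender, age,
#' genotype (HWE within each FH group), latent Frame, latent Adiposity, and
#' six measurement errors. Latent Frame is the gender effect plus
#' within-gender noise; latent Adiposity is `m1 + d2` for carriers (Aa/aa)
#' plus a centred age-tertile trend plus within-mode noise. Each
#' log-measurement is `mean_j + scale_j * (l_j1*Frame + l_j2*Adiposity +
#' sqrt(psi_j)*e_j)`, exponentiated to natural units.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed; overrides `config$seed`. Results are
#'   deterministic given the seed.
#' @return A data frame (the cohort table) with columns id, gender, age, fh,
#'   genotype, height_m, waist_cm, hip_cm, lean_kg, bone_kg, fat_kg, plus
#'   attributes `latent` (data frame of the true Frame/Adiposity values and
#'   carrier status) and `config`. The genotype column is ground truth only:
#'   the analysis pipeline never reads it.
#' @examples
#' coh <- simulate_cohort(sim_config(), seed = 1)
#' table(coh$fh)
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  if (!inherits(config, "adiposeg_config"))
    stop("config must be created by sim_config()", call. = FALSE)
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)

  n <- config$n_fh_minus + config$n_fh_plus
  fh <- rep(c("FH-", "FH+"), c(config$n_fh_minus, config$n_fh_plus))

  gender <- ifelse(stats::runif(n) < config$p_female, "F", "M")
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  genotype <- character(n)
  genotype[fh == "FH-"] <- draw_genotypes(config$q_fh_minus,
                                          config$n_fh_minus)
  genotype[fh == "FH+"] <- draw_genotypes(config$q_fh_plus,
                                          config$n_fh_plus)
  carrier <- genotype != "AA"

  frame <- ifelse(gender == "M", config$frame_gender_effect / 2,
                  -config$frame_gender_effect / 2) +
    stats::rnorm(n, 0, config$frame_sd)
  tert <- .age_tercile_pop(age, config$age_range)
  adiposity <- config$m1 + config$d2 * carrier +
    config$adiposity_age_slope * (tert - 2L) +
    stats::rnorm(n, 0, config$s)

  lam <- config$loading_matrix
  psi <- config$uniquenesses
  eps <- matrix(stats::rnorm(n * 6L), n, 6L)
  common <- cbind(frame, adiposity) %*% t(lam)
  logm <- sweep(common + sweep(eps, 2, sqrt(psi), "*"),
                2, config$measure_scales, "*")
  logm <- sweep(logm, 2, config$measure_means, "+")
  meas <- exp(logm)
  colnames(meas) <- .measure_cols

  cohort <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    gender = gender, age = age, fh = fh, genotype = genotype,
    meas, stringsAsFactors = FALSE, row.names = NULL
  )
  attr(cohort, "latent") <- data.frame(frame = frame, adiposity = adiposity,
                                       carrier = carrier)
  attr(cohort, "config") <- config
  cohort
}

#' @export
print.adiposeg_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  N: %d FH- + %d FH+\n", x$n_fh_minus, x$n_fh_plus))
  cat(sprintf("  risk allele q: %.3f (FH-), %.3f (FH+)\n",
              x$q_fh_minus, x$q_fh_plus))
  cat(sprintf("  latent Adiposity: m1 = %.3f, d2 = %.3f, s = %.3f\n",
              x$m1, x$d2, x$s))
  cat(sprintf("  Frame gender effect %.2f SD, age slope %.2f SD/tertile\n",
              x$frame_gender_effect, x$adiposity_age_slope))
  invisible(x)
}

#' Write or read a simulation configuration as JSON
#'
#' @param config An [sim_config()] object.
#' @param path File path.
#' @return `read_sim_config()` returns the validated configuration.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "adiposeg_config"))
  x <- unclass(config)
  x$loading_matrix <- unname(x$loading_matrix)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$loading_matrix <- matrix(as.numeric(as.matrix(x$loading_matrix)), 6, 2)
  do.call(sim_config, x)
}
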