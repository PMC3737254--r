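# Two-factor measurement model: maximum-likelihood extraction, varimax
# rotation, Bartlett scoring, and the Frame/Adiposity labelling convention.

#' Log-transform and standardize the six measurements
#'
#' Log-transformation accommodates the geometric relationship between
#' measurements in one linear dimension (height, circumferences) and masses,
#' which scale with volume. Each log column is then centred and scaled to
#' mean 0, SD 1 using the sample-SD (n - 1) convention.
#'
#' @param cohort A cohort data frame (see [read_cohort()]).
#' @return An n x 6 matrix with columns height, waist, hip, lean, bone, fat
#'   and attributes `center` and `scale` (log-scale constants).
#' @export
standardize_log <- function(cohort) {
  for (j in seq_along(.measure_cols)) {
    col <- .measure_cols[[j]]
    v <- cohort[[col]]
    if (is.null(v)) stop("cohort is missing column '", col, "'",
                         call. = FALSE)
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad))
      stop(sprintf("non-positive measurement in row %d, column '%s'",
                   bad[1], col), call. = FALSE)
  }
  x <- log(as.matrix(cohort[, unname(.measure_cols)]))
  colnames(x) <- names(.measure_cols)
  sds <- apply(x, 2, stats::sd)
  if (any(sds < .Machine$double.eps^0.5))
    stop("column '", names(.measure_cols)[which.min(sds)],
         "' has (near) zero variance after log transform", call. = FALSE)
  z <- scale(x)
  attr(z, "center") <- attr(z, "scaled:center")
  attr(z, "scale") <- attr(z, "scaled:scale")
  z
}

.new_factor_model <- function(loadings, uniquenesses, rotation, n_obs, R,
                              converged = TRUE, factor_labels = NULL) {
  p <- nrow(loadings)
  per_factor <- colSums(loadings^2) / p
  fitted <- loadings %*% t(loadings) + diag(uniquenesses)
  off <- upper.tri(R)
  structure(list(
    loadings = loadings,
    uniquenesses = uniquenesses,
    rotation = rotation,
    var_explained = list(per_factor = per_factor, total = sum(per_factor)),
    cov_explained = 1 - sum((R - fitted)[off]^2) / sum(R[off]^2),
    variable_names = rownames(loadings),
    factor_labels = factor_labels,
    n_obs = n_obs, R = R, converged = converged
  ), class = "factor_model")
}

#' Maximum-likelihood factor model (unrotated)
#'
#' Fits the Gaussian factor model to the sample correlation matrix by
#' maximum likelihood (via [stats::factanal()], profile likelihood over the
#' uniquenesses), so the fitted model reproduces `R ~ Lambda Lambda' + Psi`.
#' Uniquenesses are floored at 0.005; a fit at the floor (Heywood case)
#' raises a warning.
#'
#' @param z Standardized data matrix from [standardize_log()].
#' @param factors Number of factors (default 2).
#' @return An object of class `"factor_model"`: loadings (correlations of
#'   variables with factors), uniquenesses, accumulated rotation matrix,
#'   proportions of standardized variance and of off-diagonal covariance
#'   explained.
#' @export
ml_factor_fit <- function(z, factors = 2L) {
  factors <- as.integer(factors)
  if (factors < 1L) stop("factors must be >= 1", call. = FALSE)
  z <- as.matrix(z)
  if (nrow(z) <= ncol(z))
    stop("need more observations than variables", call. = FALSE)
  R <- stats::cor(z)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
    stop("correlation matrix is not positive definite", call. = FALSE)
  fit <- stats::factanal(covmat = R, factors = factors, rotation = "none",
                         n.obs = nrow(z))
  L <- unclass(fit$loadings)
  psi <- fit$uniquenesses
  if (any(psi <= 0.005 + 1e-8))
    warning("Heywood case: uniqueness clamped at floor 0.005",
            call. = FALSE)
  dimnames(L) <- list(colnames(z), paste0("Factor", seq_len(factors)))
  names(psi) <- colnames(z)
  .new_factor_model(L, psi, diag(factors), nrow(z), R,
                    converged = fit$converged)
}

# raw varimax criterion of Kaiser row-normalized loadings
.varimax_crit <- function(L) {
  Ln <- L / sqrt(rowSums(L^2))
  sum(Ln^4) - sum(colSums(Ln^2)^2) / nrow(Ln)
}

# closed-form varimax angle for two factors (Kaiser): the criterion is a
# sinusoid in 4*theta of the planar rotation angle, so the optimum is
# analytic; the iterative routine in stats::varimax can stall at a saddle
# for symmetric patterns
.varimax_angle_k2 <- function(L) {
  Ln <- L / sqrt(rowSums(L^2))
  p <- nrow(Ln)
  u <- Ln[, 1]^2 - Ln[, 2]^2
  v <- 2 * Ln[, 1] * Ln[, 2]
  num <- 2 * (sum(u * v) - sum(u) * sum(v) / p)
  den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / p
  theta0 <- atan2(num, den) / 4
  # stationary points alternate max/min every pi/4
  cand <- theta0 + c(0, pi / 4)
  rotm <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  crit <- vapply(cand, function(th) .varimax_crit(L %*% rotm(th)), 0)
  rotm(cand[which.max(crit)])
}

#' Varimax rotation of a fitted factor model
#'
#' Rotates the loadings by the orthonormal matrix maximizing the varimax
#' criterion (variance of squared, Kaiser row-normalized loadings),
#' producing the most parsimonious orthogonal factors. For two factors the
#' rotation reduces to a single planar angle with an analytic optimum,
#' which is used directly; more factors delegate to the iterative
#' [stats::varimax()]. Communalities are unchanged.
#'
#' @param model A `"factor_model"` object.
#' @return The rotated `"factor_model"`.
#' @export
varimax_rotate <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  if (ncol(model$loadings) == 2L) {
    rotmat <- .varimax_angle_k2(model$loadings)
    L <- model$loadings %*% rotmat
  } else {
    v <- stats::varimax(model$loadings, normalize = TRUE, eps = 1e-10)
    rotmat <- v$rotmat
    L <- unclass(v$loadings)
  }
  dimnames(L) <- dimnames(model$loadings)
  .new_factor_model(L, model$uniquenesses,
                    model$rotation %*% rotmat, model$n_obs, model$R,
                    converged = model$converged,
                    factor_labels = model$factor_labels)
}

#' Bartlett (weighted-least-squares) factor scores
#'
#' Computes per-individual factor scores
#' `F = (L' Psi^-1 L)^-1 L' Psi^-1 z'`, the WLS estimator that is unbiased
#' for the latent factors under the model.
#'
#' @param z Standardized data matrix (same variables the model was fitted
#'   on).
#' @param model A `"factor_model"` object.
#' @return An n x k matrix of scores in SD units.
#' @export
bartlett_scores <- function(z, model) {
  stopifnot(inherits(model, "factor_model"))
  z <- as.matrix(z)
  if (ncol(z) != nrow(model$loadings))
    stop("z and model have different variable counts", call. = FALSE)
  L <- model$loadings
  Lw <- L / model$uniquenesses              # Psi^-1 L
  M <- crossprod(L, Lw)                     # L' Psi^-1 L
  if (rcond(M) < 1e-12)
    stop("L' Psi^-1 L is singular; scores are not identified",
         call. = FALSE)
  scores <- z %*% Lw %*% solve(M)
  colnames(scores) <- colnames(L)
  scores
}

#' Fix factor labels and signs to the Frame/Adiposity convention
#'
#' The factor with the larger absolute loading on height is labelled Frame
#' and ordered first, the other Adiposity. Signs are flipped so height loads
#' positively on Frame and fat mass positively on Adiposity. The same
#' permutation and signs are applied to the scores.
#'
#' @param model A rotated two-factor `"factor_model"`.
#' @param scores Matrix of scores from [bartlett_scores()].
#' @return `list(model, scores)` with columns named Frame and Adiposity.
#' @export
label_and_sign <- function(model, scores) {
  stopifnot(inherits(model, "factor_model"), ncol(model$loadings) == 2L)
  L <- model$loadings
  h <- match("height", rownames(L))
  f <- match("fat", rownames(L))
  if (is.na(h) || is.na(f))
    stop("model must include 'height' and 'fat' variables", call. = FALSE)
  ah <- abs(L[h, ])
  if (abs(ah[1] - ah[2]) < 0.05) {
    warning("ambiguous loading pattern on height; keeping fit order",
            call. = FALSE)
    perm <- 1:2
  } else perm <- order(ah, decreasing = TRUE)
  L <- L[, perm, drop = FALSE]
  scores <- scores[, perm, drop = FALSE]
  rot <- model$rotation[, perm, drop = FALSE]
  sgn <- c(if (L[h, 1] < 0) -1 else 1, if (L[f, 2] < 0) -1 else 1)
  L <- sweep(L, 2, sgn, "*")
  scores <- sweep(scores, 2, sgn, "*")
  rot <- sweep(rot, 2, sgn, "*")
  colnames(L) <- colnames(scores) <- c("Frame", "Adiposity")
  out <- .new_factor_model(L, model$uniquenesses, rot, model$n_obs, model$R,
                           converged = model$converged,
                           factor_labels = c("Frame", "Adiposity"))
  list(model = out, scores = scores)
}

#' Fit the Frame/Adiposity factor model to a cohort
#'
#' Convenience wrapper: [standardize_log()], [ml_factor_fit()] with two
#' factors, [varimax_rotate()], [bartlett_scores()], [label_and_sign()].
#'
#' @param cohort A cohort data frame.
#' @return A list with elements `model` (labelled `"factor_model"`),
#'   `scores` (data frame id, frame, adiposity) and `z` (the standardized
#'   log matrix).
#' @examples
#' coh <- simulate_cohort(sim_config(), seed = 1)
#' bf <- fit_body_factors(coh)
#' bf$model
#' @export
fit_body_factors <- function(cohort) {
  z <- standardize_log(cohort)
  fit <- varimax_rotate(ml_factor_fit(z, 2L))
  sc <- bartlett_scores(z, fit)
  ls <- label_and_sign(fit, sc)
  scores <- data.frame(id = cohort$id, frame = ls$scores[, "Frame"],
                       adiposity = ls$scores[, "Adiposity"],
                       stringsAsFactors = FALSE)
  list(model = ls$model, scores = scores, z = z)
}

#' @export
print.factor_model <- function(x, digits = 3, ...) {
  cat(sprintf("Maximum-likelihood factor model (%d variables, %d factors)\n",
              nrow(x$loadings), ncol(x$loadings)))
  cat("Loadings:\n")
  print(round(x$loadings, digits))
  cat("Uniquenesses:\n")
  print(round(x$uniquenesses, digits))
  cat(sprintf("Standardized variance explained: %.1f%% (covariance: %.1f%%)\n",
              100 * x$var_explained$total, 100 * x$cov_explained))
  invisible(x)
}
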