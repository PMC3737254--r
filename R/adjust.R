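# Gender + age-tertile adjustment: traits are analysed as residuals from
# the additive two-way linear model trait ~ gender + tertile.

#' Age tertiles of the pooled sample
#'
#' Cuts ages at the 33.3% and 66.7% sample quantiles into tertile labels
#' 1, 2, 3. Intervals are lower-closed; values equal to a cut point go to
#' the lower tertile.
#'
#' @param ages Numeric vector of ages in years (length >= 3).
#' @return Integer vector of tertile labels.
#' @examples
#' age_tertiles(1:9)
#' @export
age_tertiles <- function(ages) {
  if (length(ages) < 3L) stop("need at least 3 ages", call. = FALSE)
  if (anyNA(ages)) stop("ages contain missing values", call. = FALSE)
  if (diff(range(ages)) == 0)
    stop("all ages identical; tertiles undefined", call. = FALSE)
  cuts <- stats::quantile(ages, c(1, 2) / 3, names = FALSE)
  1L + (ages > cuts[1]) + (ages > cuts[2])
}

#' Adjust a trait for gender and age tertile
#'
#' Fits the additive two-way linear model `trait ~ gender + tertile` (no
#' interaction) by least squares and returns the residuals — the "gender-
#' and age-adjusted" trait — together with the model R-squared and fitted
#' cell means. Residuals are invariant to the factor coding.
#'
#' @param trait Numeric vector.
#' @param gender Factor-like vector (e.g. "F"/"M").
#' @param tertile Factor-like vector (e.g. from [age_tertiles()]).
#' @return An object of class `"adjusted_trait"`: `residuals`,
#'   `r_squared`, `cell_means` (gender x tertile matrix of fitted values),
#'   `fitted`.
#' @export
adjust_gender_age <- function(trait, gender, tertile) {
  n <- length(trait)
  if (length(gender) != n || length(tertile) != n)
    stop("trait, gender and tertile must have equal length", call. = FALSE)
  if (anyNA(trait) || anyNA(gender) || anyNA(tertile))
    stop("inputs contain missing values", call. = FALSE)
  g <- if (is.factor(gender)) gender else factor(gender)
  t <- if (is.factor(tertile)) tertile else factor(tertile)
  for (f in list(gender = g, tertile = t)) {
    empty <- setdiff(levels(f), unique(as.character(f)))
    if (length(empty))
      warning("dropping empty level(s): ", paste(empty, collapse = ", "),
              call. = FALSE)
  }
  g <- droplevels(g); t <- droplevels(t)
  # single-level factors contribute nothing and are omitted from the model
  terms <- c(if (nlevels(g) > 1L) "g", if (nlevels(t) > 1L) "t")
  d <- data.frame(trait = trait, g = g, t = t)
  form <- if (length(terms))
    stats::reformulate(terms, response = "trait") else trait ~ 1
  fit <- stats::lm(form, data = d)
  tot <- sum((trait - mean(trait))^2)
  r2 <- if (tot > 0) 1 - sum(stats::resid(fit)^2) / tot else 0
  grid <- expand.grid(g = levels(g), t = levels(t))
  cell <- matrix(stats::predict(fit, grid), nrow = nlevels(g),
                 dimnames = list(levels(g), levels(t)))
  structure(list(residuals = unname(stats::resid(fit)),
                 r_squared = r2, cell_means = cell,
                 fitted = unname(stats::fitted(fit))),
            class = "adjusted_trait")
}

#' @export
print.adjusted_trait <- function(x, ...) {
  cat(sprintf("Gender + age-tertile adjusted trait (n = %d, R^2 = %.3f)\n",
              length(x$residuals), x$r_squared))
  cat("Cell means (gender x tertile):\n")
  print(round(x$cell_means, 3))
  invisible(x)
}
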