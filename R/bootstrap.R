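# Stratified bootstrap over individuals.

#' Stratified bootstrap of a cohort-level statistic
#'
#' Resamples individuals with replacement within each stratum (default: the
#' FH groups) at the original stratum sizes, re-runs `statistic` on each
#' resampled cohort, and summarizes each returned parameter by its
#' bootstrap median and 2.5%/97.5% percentiles. Draws in which `statistic`
#' errors or returns non-finite values are dropped and counted; if more
#' than 20% fail, the summary is flagged unreliable with a warning.
#'
#' @param cohort A data frame of individuals.
#' @param statistic Function mapping a cohort to a named numeric vector.
#' @param n_draws Number of bootstrap draws (the reference analysis used
#'   1000).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param strata Column name to stratify on, or a vector of stratum labels.
#' @return An object of class `"bootstrap_summary"`: `summary` (data frame
#'   with point, median, ci_lo, ci_hi per parameter), `draws` (matrix of
#'   successful draws), `n_draws`, `n_failed`, `unreliable`, `seed`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_fh_minus = 30, n_fh_plus = 20),
#'                        seed = 1)
#' cohort_bootstrap(coh, function(d) c(mean_age = mean(d$age)),
#'                  n_draws = 50, seed = 2)
#' @export
cohort_bootstrap <- function(cohort, statistic, n_draws = 1000L,
                             seed = NULL, strata = "fh") {
  stopifnot(is.function(statistic), n_draws >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lab <- if (length(strata) == 1L && is.character(strata) &&
             strata %in% names(cohort)) cohort[[strata]] else strata
  if (length(lab) != nrow(cohort))
    stop("strata must name a column or match the cohort length",
         call. = FALSE)
  idx_by <- split(seq_len(nrow(cohort)), lab)

  point <- statistic(cohort)
  if (!is.numeric(point) || is.null(names(point)))
    stop("statistic must return a named numeric vector", call. = FALSE)

  draws <- matrix(NA_real_, n_draws, length(point),
                  dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (b in seq_len(n_draws)) {
    take <- unlist(lapply(idx_by, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]),
      use.names = FALSE)
    val <- tryCatch(suppressWarnings(statistic(cohort[take, , drop = FALSE])),
                    error = function(e) NULL)
    if (is.null(val) || length(val) != length(point) ||
        any(!is.finite(val))) {
      n_failed <- n_failed + 1L
    } else draws[b, ] <- val
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  unreliable <- n_failed > 0.2 * n_draws
  if (unreliable)
    warning(sprintf("bootstrap unreliable: %d of %d draws failed",
                    n_failed, n_draws), call. = FALSE)
  qs <- if (nrow(draws) == 0L)
    matrix(NA_real_, 3L, length(point)) else
      apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
            names = FALSE)
  structure(list(
    summary = data.frame(parameter = names(point), point = unname(point),
                         median = qs[2, ], ci_lo = qs[1, ], ci_hi = qs[3, ],
                         row.names = NULL),
    draws = draws, n_draws = n_draws, n_failed = n_failed,
    unreliable = unreliable, seed = seed
  ), class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Stratified bootstrap (%d draws, %d failed%s)\n",
              x$n_draws, x$n_failed,
              if (x$unreliable) ", UNRELIABLE" else ""))
  tab <- x$summary
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
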