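# Cohort table I/O and validation.

.required_cols <- c("id", "gender", "age", "fh", unname(.measure_cols))

# plausible adult ranges; violations warn, never fail
.range_heuristics <- list(
  height_m = c(1.2, 2.2), waist_cm = c(40, 200), hip_cm = c(50, 200),
  lean_kg = c(20, 120), bone_kg = c(1, 6), fat_kg = c(2, 120),
  age = c(15, 100)
)

#' Read and validate a cohort table
#'
#' The pipeline's sole input: a CSV with columns id, gender (F/M), age
#' (years), fh (FH+/FH-), height_m, waist_cm, hip_cm, lean_kg, bone_kg,
#' fat_kg, and optionally genotype. Missing columns, non-numeric
#' measurements and missing values are errors naming the offending column;
#' measurements outside plausible adult ranges only warn.
#'
#' @param path Path to a CSV file.
#' @return A validated cohort data frame.
#' @seealso [write_cohort()], [simulate_cohort()]
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(x)
}

#' @rdname read_cohort
#' @param cohort A cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  cols <- intersect(c("id", "gender", "age", "fh", "genotype",
                      unname(.measure_cols)), names(cohort))
  utils::write.csv(cohort[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
validate_cohort <- function(cohort) {
  missing <- setdiff(.required_cols, names(cohort))
  if (length(missing))
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c("age", unname(.measure_cols))) {
    v <- cohort[[col]]
    if (!is.numeric(v))
      stop("column '", col, "' must be numeric", call. = FALSE)
    if (anyNA(v))
      stop("column '", col, "' contains missing values", call. = FALSE)
  }
  for (col in unname(.measure_cols))
    if (any(cohort[[col]] <= 0))
      stop("column '", col, "' must be strictly positive", call. = FALSE)
  if (anyNA(cohort$gender) || !all(cohort$gender %in% c("F", "M")))
    stop("column 'gender' must be 'F' or 'M'", call. = FALSE)
  fh <- normalize_fh(cohort$fh)
  if (anyNA(fh))
    stop("column 'fh' must be 'FH+' or 'FH-'", call. = FALSE)
  cohort$fh <- fh
  for (col in names(.range_heuristics)) {
    r <- .range_heuristics[[col]]
    n_out <- sum(cohort[[col]] < r[1] | cohort[[col]] > r[2])
    if (n_out)
      warning(sprintf("%d value(s) of '%s' outside plausible range [%g, %g]",
                      n_out, col, r[1], r[2]), call. = FALSE)
  }
  cohort
}

# accept ASCII hyphen and Unicode minus spellings of the FH- label
normalize_fh <- function(fh) {
  out <- rep(NA_character_, length(fh))
  out[fh %in% c("FH+", "FH plus", "FHplus")] <- "FH+"
  out[fh %in% c("FH-", "FH−", "FH–", "FH minus")] <- "FH-"
  out
}
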