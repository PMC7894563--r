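#' Read and validate a breeding records CSV
#'
#' Expects columns `year`, `nest_id`, `lay_date`, `n_fledged` and
#' optionally `attempt`. Rows with `attempt > 1` (replacement clutches)
#' are dropped with a message reporting the count. Validation errors name
#' the offending row. Dates are integer ordinal days (January 1st = 0).
#'
#' @param path CSV file path.
#' @return data.frame of nest records (first clutches only).
#' @export
read_breeding_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("year", "nest_id", "lay_date", "n_fledged")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if ("attempt" %in% names(x)) {
    drop <- x$attempt > 1
    if (any(drop))
      message(sprintf("%s: dropped %d replacement-clutch row(s)", path,
                      sum(drop)))
    x <- x[!drop, setdiff(names(x), "attempt"), drop = FALSE]
  }
  bad <- which(!is.finite(x$n_fledged) | x$n_fledged != round(x$n_fledged))
  if (length(bad) > 0)
    stop(sprintf("%s: non-integer n_fledged at row %d", path, bad[1]))
  bad <- which(x$n_fledged < 0 | x$n_fledged > 4)
  if (length(bad) > 0)
    stop(sprintf("%s: n_fledged outside 0..4 at row %d", path, bad[1]))
  dup <- duplicated(x[, c("year", "nest_id")])
  if (any(dup))
    stop(sprintf("%s: duplicate (year, nest_id) at row %d", path,
                 which(dup)[1]))
  x
}

#' Read and validate an annual environment CSV
#'
#' Expects columns `year`, `sst`, `sst_prev`, `population_size` with one
#' row per year.
#'
#' @param path CSV file path.
#' @return data.frame of annual covariates.
#' @export
read_env_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("year", "sst", "sst_prev", "population_size")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(x$year))
    stop(sprintf("%s: duplicate year rows", path))
  x
}

#' Read and validate a diet samples CSV
#'
#' Expects columns `year`, `sample_date`, `prop_oneplus` with proportions
#' in [0, 1].
#'
#' @param path CSV file path.
#' @return data.frame of diet samples.
#' @export
read_diet_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("year", "sample_date", "prop_oneplus")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  bad <- which(x$prop_oneplus < 0 | x$prop_oneplus > 1)
  if (length(bad) > 0)
    stop(sprintf("%s: prop_oneplus outside [0, 1] at row %d", path, bad[1]))
  x
}

#' Assemble the annual context table
#'
#' One row per breeding year: mean lay date from the nest records, merged
#' with the environmental covariates (and, when diet samples are given,
#' the annual mean collection date).
#'
#' @param breeding nest records.
#' @param env annual environment table.
#' @param diet optional diet samples.
#' @return data.frame with `year`, `mean_lay_date`, `sst`, `sst_prev`,
#'   `population_size` and optionally `mean_sample_date`.
#' @export
build_year_context <- function(breeding, env, diet = NULL) {
  years <- sort(unique(breeding$year))
  missing_years <- setdiff(years, env$year)
  if (length(missing_years) > 0)
    stop(sprintf("environment table missing year(s): %s",
                 paste(missing_years, collapse = ", ")))
  out <- data.frame(year = years,
                    mean_lay_date = as.numeric(
                      tapply(breeding$lay_date, breeding$year, mean)))
  out <- merge(out, env, by = "year", all.x = TRUE)
  if (!is.null(diet)) {
    ds <- data.frame(year = as.integer(names(
      tapply(diet$sample_date, diet$year, mean))),
      mean_sample_date = as.numeric(tapply(diet$sample_date, diet$year,
                                           mean)))
    out <- merge(out, ds, by = "year", all.x = TRUE)
  }
  out[order(out$year), , drop = FALSE]
}
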