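AREA_COLUMNS <- c("species", "sex", "specimen", "hook", "position",
                  "length", "base", "measured_area", "estimated_area")

#' Read a hook-area validation CSV
#'
#' Reads the nine-column dialect pairing digitizing-tablet measurements of
#' hook cross-sectional area with the triangular estimate
#' `length * base / 2`: columns `species, sex, specimen, hook, position,
#' length, base, measured_area, estimated_area`. The stored estimate is
#' recomputed from length and base; rows deviating by more than 0.5% raise
#' a warning naming the row.
#'
#' @param path Path to the CSV file.
#' @param species Optional species label to filter to.
#' @return A tibble of area records.
#' @export
read_area_csv <- function(path, species = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "meristo_io_error")
  }
  first_line <- readLines(path, n = 1)
  header <- if (length(first_line) == 0) character(0) else
    trimws(strsplit(first_line, ",", fixed = TRUE)[[1]])
  if (!identical(header, AREA_COLUMNS)) {
    abort(sprintf("header of %s does not match the nine area-record columns",
                  path), class = "meristo_format_error")
  }
  rec <- readr::read_csv(path, col_types = readr::cols(
    species = readr::col_character(), sex = readr::col_character(),
    specimen = readr::col_character(), .default = readr::col_double()))
  if (nrow(rec) == 0) {
    abort(sprintf("%s contains no records", path),
          class = "meristo_format_error")
  }
  recomputed <- rec$length * rec$base / 2
  off <- abs(rec$estimated_area - recomputed) > 0.005 * recomputed
  if (any(off)) {
    i <- which(off)[1]
    warn(sprintf(
      "estimated_area deviates >0.5%% from length*base/2 in %d row(s), first: specimen '%s' hook %s",
      sum(off), rec$specimen[i], rec$hook[i]))
  }
  if (!is.null(species)) {
    rec <- filter(rec, .data$species == !!species)
  }
  rec
}

#' Regress estimated hook area on measured area
#'
#' Ordinary least-squares validation of the triangular area approximation:
#' the estimate `length * base / 2` is the response and the digitized area
#' the predictor, so the fitted line reads
#' `estimated = slope * measured + intercept`. A slope near 1 with a small
#' intercept and high R-squared indicates the approximation tracks the
#' true area; a slope above 1 means systematic over-estimation.
#'
#' @param records Area records (e.g. from [read_area_csv()]), needing
#'   columns `measured_area` and `estimated_area`; at least 3 records with
#'   non-degenerate measured-area variance.
#' @return An `area_regression` object; see [tidy.area_regression()] and
#'   [glance.area_regression()].
#' @export
area_regression <- function(records) {
  if (nrow(records) < 3) {
    abort("need at least 3 records for the area regression",
          class = "meristo_usage_error")
  }
  if (any(records$measured_area <= 0)) {
    abort("measured areas must be positive", class = "meristo_value_error")
  }
  if (stats::var(records$measured_area) == 0) {
    abort("measured areas are constant; regression is degenerate",
          class = "meristo_value_error")
  }
  fit <- stats::lm(estimated_area ~ measured_area, data = records)
  structure(list(fit = fit,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n = nrow(records)),
            class = "area_regression")
}

#' @export
print.area_regression <- function(x, ...) {
  cat(sprintf("estimated = %.3f x measured + %.3f  (R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @rdname area_regression
#' @param x An `area_regression`.
#' @param ... Unused.
#' @export
tidy.area_regression <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = summary(x$fit)$coefficients[, "Std. Error"])
}

#' @rdname area_regression
#' @export
glance.area_regression <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n = x$n)
}
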