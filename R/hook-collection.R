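#' @importFrom rlang .data %||% abort warn
#' @importFrom dplyr group_by summarise mutate arrange filter select n bind_rows
#'   bind_cols distinct across ungroup first
#' @importFrom tibble tibble as_tibble new_tibble
NULL

HOOK_COLUMNS <- c("specimen", "hook", "length", "base")

#' Construct a hook collection
#'
#' A hook collection is a tibble of per-hook measurements from one or more
#' worms, the unit of data a meristogram is computed from. Each row is one
#' hook: its specimen identifier, ordinal position in the longitudinal row
#' counted from the distal end of the proboscis (1-based), blade length and
#' base width in micrometres, plus sex and proboscis-surface tags. One
#' longitudinal hook row is the set of records sharing a
#' (specimen, sex, surface) key; ordinals within a row must run 1..n with no
#' gaps or duplicates.
#'
#' @param x A data frame with columns `specimen`, `hook`, `length`, `base`,
#'   and optionally `sex` and `surface`.
#' @param label Collection label (e.g. a taxon name) carried through to
#'   meristograms and comparative analyses.
#' @param sex,surface Default tags applied where `x` lacks the column:
#'   one of `"female"`, `"male"`, `"unknown"` and `"dorsal"`, `"ventral"`,
#'   `"unknown"` respectively.
#' @return A `hook_collection`: a tibble with the six columns above and a
#'   `label` attribute.
#' @export
#' @examples
#' hooks <- hook_collection(
#'   data.frame(specimen = "w1", hook = 1:3,
#'              length = c(60, 70, 55), base = c(20, 25, 24)),
#'   label = "example")
#' n_hook_rows(hooks)
hook_collection <- function(x, label = "collection",
                            sex = "unknown", surface = "unknown") {
  x <- as_tibble(x)
  missing_cols <- setdiff(HOOK_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("hook data lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "meristo_format_error")
  }
  if (!"sex" %in% names(x)) x$sex <- sex
  if (!"surface" %in% names(x)) x$surface <- surface
  x$sex <- check_tag(as.character(x$sex), c("unknown", "female", "male"), "sex")
  x$surface <- check_tag(as.character(x$surface),
                         c("unknown", "dorsal", "ventral"), "surface")
  x <- x[c("specimen", "hook", "length", "base", "sex", "surface")]
  x$specimen <- as.character(x$specimen)
  x$hook <- as.integer(x$hook)
  x <- arrange(x, .data$specimen, .data$sex, .data$surface, .data$hook)
  out <- new_tibble(x, label = label, class = "hook_collection")
  validate_hook_collection(out)
  out
}

#' @export
#' @rdname hook_collection
collection_label <- function(x) attr(x, "label", exact = TRUE) %||% "collection"

#' Validate hook-collection invariants
#'
#' Checks positivity of measurements and that within every longitudinal row
#' (a `(specimen, sex, surface)` group) the hook ordinals are exactly
#' `1..n`. Rows with fewer than 3 hooks are accepted with a warning, since
#' smoothing such rows is statistically weak.
#'
#' @param x A `hook_collection`.
#' @return `x`, invisibly, or an error describing the first violation.
#' @export
validate_hook_collection <- function(x) {
  if (nrow(x) == 0) {
    abort("hook collection contains no measurements",
          class = "meristo_format_error")
  }
  bad <- !is.finite(x$length) | !is.finite(x$base) |
    x$length <= 0 | x$base <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "non-positive or non-numeric measurement for specimen '%s', hook %s (length=%s, base=%s)",
      x$specimen[i], x$hook[i], x$length[i], x$base[i]),
      class = "meristo_value_error")
  }
  rows <- split(x$hook, row_key(x))
  for (key in names(rows)) {
    ords <- sort(rows[[key]])
    n <- length(ords)
    if (anyDuplicated(ords)) {
      abort(sprintf("duplicate hook ordinal in row %s", key),
            class = "meristo_integrity_error")
    }
    if (!identical(ords, seq_len(n))) {
      abort(sprintf("hook ordinals of row %s do not form 1..n (found: %s)",
                    key, paste(ords, collapse = ",")),
            class = "meristo_integrity_error")
    }
    if (n < 3) {
      warn(sprintf("row %s has only %d hook(s); smoothing will be weak",
                   key, n))
    }
  }
  invisible(x)
}

check_tag <- function(values, choices, what) {
  bad <- setdiff(unique(values), choices)
  if (length(bad) > 0) {
    abort(sprintf("invalid %s tag(s): %s (must be one of %s)", what,
                  paste(bad, collapse = ", "), paste(choices, collapse = ", ")),
          class = "meristo_usage_error")
  }
  values
}

row_key <- function(x) {
  paste(x$specimen, x$sex, x$surface, sep = "/")
}

#' Per-row summary of a hook collection
#'
#' @param x A `hook_collection`.
#' @return A tibble with one row per longitudinal hook row: `specimen`,
#'   `sex`, `surface` and hook count `n`.
#' @export
hook_rows <- function(x) {
  summarise(group_by(as_tibble(x), .data$specimen, .data$sex, .data$surface),
            n = dplyr::n(), .groups = "drop")
}

#' @rdname hook_rows
#' @export
n_hook_rows <- function(x) nrow(hook_rows(x))

#' @export
print.hook_collection <- function(x, ...) {
  rows <- hook_rows(x)
  cat(sprintf("<hook_collection '%s': %d rows, %d hooks>\n",
              collection_label(x), nrow(rows), nrow(x)))
  NextMethod()
}
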