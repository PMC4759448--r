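#' Read a hook-measurement CSV
#'
#' Reads the four-column comma-separated dialect used for hook morphometric
#' data: header exactly `specimen,hook,length,base`, one record per hook,
#' lengths and base widths in micrometres, hooks numbered from the distal
#' end of the proboscis. Sex and proboscis surface are supplied per file,
#' mirroring how such data sets are deposited (one file per sex, and per
#' surface for radially asymmetric taxa).
#'
#' @param path Path to the CSV file.
#' @param sex,surface Tags attached to every row read:
#'   `"female"`/`"male"`/`"unknown"` and `"dorsal"`/`"ventral"`/`"unknown"`.
#' @param label Collection label; defaults to the file name without
#'   extension.
#' @return A [hook_collection()].
#' @export
read_hooks <- function(path, sex = "unknown", surface = "unknown",
                       label = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "meristo_io_error")
  }
  first_line <- readLines(path, n = 1)
  header <- if (length(first_line) == 0) character(0) else
    trimws(strsplit(first_line, ",", fixed = TRUE)[[1]])
  if (!identical(header, HOOK_COLUMNS)) {
    abort(sprintf(
      "header of %s is '%s'; expected 'specimen,hook,length,base'",
      path, paste(header, collapse = ",")),
      class = "meristo_format_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    specimen = readr::col_character(),
    hook = readr::col_double(),
    length = readr::col_double(),
    base = readr::col_double()))
  raw <- raw[rowSums(is.na(raw)) < ncol(raw), , drop = FALSE]  # blank lines
  if (any(is.na(raw$hook)) || any(raw$hook != round(raw$hook))) {
    abort(sprintf("non-integer hook ordinal in %s", path),
          class = "meristo_value_error")
  }
  if (any(is.na(raw$length)) || any(is.na(raw$base))) {
    i <- which(is.na(raw$length) | is.na(raw$base))[1]
    abort(sprintf("non-numeric length/base for specimen '%s', hook %s in %s",
                  raw$specimen[i], raw$hook[i], path),
          class = "meristo_value_error")
  }
  dup <- duplicated(raw[c("specimen", "hook")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("duplicate (specimen, hook) pair ('%s', %s) in %s",
                  raw$specimen[i], raw$hook[i], path),
          class = "meristo_integrity_error")
  }
  if (is.null(label)) {
    label <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  }
  hook_collection(raw, label = label, sex = sex, surface = surface)
}

#' Pool hook collections
#'
#' Concatenates several collections under a new label, preserving every
#' input row. This is how data from females and males, or from dorsal and
#' ventral hook rows, are pooled before computing a single meristogram for
#' a taxon. No deduplication is performed: the same specimen may legitimately
#' contribute one dorsal and one ventral row, which remain distinct through
#' their surface tag.
#'
#' @param ... `hook_collection` objects (or a single list of them).
#' @param label Label for the pooled collection.
#' @return A [hook_collection()] containing all rows of all parts.
#' @export
pool_hooks <- function(..., label = "pooled") {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  if (length(parts) == 0) {
    abort("no collections supplied to pool", class = "meristo_usage_error")
  }
  pooled <- bind_rows(lapply(parts, as_tibble))
  hook_collection(pooled, label = label)
}

#' Write and read meristogram curves as CSV
#'
#' `write_meristogram_csv()` saves the curve points of a meristogram as a
#' five-column CSV (`position,L,B,A,R`) with 6-significant-digit numeric
#' formatting; `read_meristogram_csv()` reads such a file back into a plain
#' tibble of curve points.
#'
#' @param m A [meristogram()] with at least one curve point.
#' @param path Output (input) file path.
#' @return `write_meristogram_csv()` returns `path` invisibly;
#'   `read_meristogram_csv()` returns a tibble with columns
#'   `position`, `L`, `B`, `A`, `R`.
#' @export
write_meristogram_csv <- function(m, path) {
  pts <- curve_points(m)
  if (nrow(pts) == 0) {
    abort("meristogram has no curve points", class = "meristo_usage_error")
  }
  out <- tibble(position = signif(pts$x, 6),
                L = signif(pts$L, 6), B = signif(pts$B, 6),
                A = signif(pts$A, 6), R = signif(pts$R, 6))
  tryCatch(readr::write_csv(out, path),
           error = function(e) abort(
             sprintf("cannot write %s: %s", path, conditionMessage(e)),
             class = "meristo_io_error"))
  invisible(path)
}

#' @rdname write_meristogram_csv
#' @export
read_meristogram_csv <- function(path) {
  pts <- readr::read_csv(path, col_types = "ddddd")
  if (!identical(names(pts), c("position", "L", "B", "A", "R"))) {
    abort(sprintf("%s is not a meristogram CSV (header %s)",
                  path, paste(names(pts), collapse = ",")),
          class = "meristo_format_error")
  }
  pts
}
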