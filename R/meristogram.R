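#' Percent-position of a hook along its row
#'
#' Standardizes hook position so that homologous regions of the proboscis
#' can be compared across rows with different hook counts: ordinal position
#' `i` in a row of `n` hooks maps to `i * 100 / (n + 1)`. The `+ 1` centres
#' the points, so a single hook sits at 50 rather than 100 and positions
#' never reach the interval ends.
#'
#' @param ordinal Integer hook position(s), counted from the distal end
#'   (1-based).
#' @param n Total number of hooks in the row.
#' @return Percent-position(s) in the open interval (0, 100).
#' @export
#' @examples
#' percent_position(1:5, 5)
percent_position <- function(ordinal, n) {
  stopifnot(all(ordinal >= 1), all(ordinal <= n), n >= 1)
  ordinal * 100 / (n + 1)
}

#' Derived hook variables: area and robustness ratio
#'
#' The cross-sectional area of a hook viewed in profile is approximated by
#' a triangle, `area = length * base / 2` (square micrometres). Robustness
#' (stoutness) is `ratio = base * 100 / length`; higher values indicate
#' stouter hooks.
#'
#' @param length Blade length, micrometres (> 0).
#' @param base Base width, micrometres (> 0).
#' @return `hook_area()`: the triangular area estimate; `hook_ratio()`: the
#'   robustness ratio.
#' @export
#' @examples
#' hook_area(60, 20)   # 600
#' hook_ratio(60, 20)  # 33.33
hook_area <- function(length, base) {
  check_positive_dims(length, base)
  length * base / 2
}

#' @rdname hook_area
#' @export
hook_ratio <- function(length, base) {
  check_positive_dims(length, base)
  base * 100 / length
}

check_positive_dims <- function(length, base) {
  if (any(!is.finite(length) | length <= 0)) {
    abort("blade length must be positive", class = "meristo_value_error")
  }
  if (any(!is.finite(base) | base <= 0)) {
    abort("base width must be positive", class = "meristo_value_error")
  }
  invisible(NULL)
}

#' Standardize a hook collection
#'
#' Applies the row-level standardization steps that precede smoothing:
#' positions become percent-positions via [percent_position()]; area and
#' ratio are derived from each hook's length and base; then all four
#' variables are expressed as percentages of their own row maximum, so that
#' within every row each standardized variable attains 100 at (at least)
#' one hook. Row maxima of the four variables may fall at different
#' ordinals. Because each row is scaled by its own maxima, overall size
#' differences between worms (e.g. sexual size dimorphism or allometry)
#' are eliminated, leaving only the positional pattern.
#'
#' @param hooks A [hook_collection()].
#' @return A tibble with one row per hook: the row key (`specimen`, `sex`,
#'   `surface`), row hook count `n`, percent-position `p`, and standardized
#'   variables `l`, `b`, `a`, `r`, each in (0, 100].
#' @export
standardize_hooks <- function(hooks) {
  validate_hook_collection(hooks)
  df <- as_tibble(hooks)
  df <- mutate(group_by(df, .data$specimen, .data$sex, .data$surface),
               n = dplyr::n(),
               p = percent_position(.data$hook, dplyr::n()),
               area = .data$length * .data$base / 2,
               ratio = .data$base * 100 / .data$length,
               l = .data$length * 100 / max(.data$length),
               b = .data$base * 100 / max(.data$base),
               a = .data$area * 100 / max(.data$area),
               r = .data$ratio * 100 / max(.data$ratio))
  select(ungroup(df), "specimen", "sex", "surface", "n", "p",
         "l", "b", "a", "r")
}

#' Minimum moving-average interval (MMAI)
#'
#' The smallest admissible smoothing window for a collection. With a window
#' of `ceiling(100 / (n_min + 1))` percent, where `n_min` is the hook count
#' of the shortest row, every worm in the collection contributes at least
#' one hook to every window in the interior of the position axis, so no
#' segment mean is driven by a subset of specimens.
#'
#' @param hooks A [hook_collection()].
#' @return Integer percent.
#' @export
#' @examples
#' \dontrun{minimum_mai(hooks)}
minimum_mai <- function(hooks) {
  if (nrow(hooks) == 0) {
    abort("empty hook collection", class = "meristo_usage_error")
  }
  n_min <- min(hook_rows(hooks)$n)
  as.integer(ceiling(100 / (n_min + 1)))
}

#' Moving-average smoothing of standardized hooks
#'
#' Slides a window of width `w` percent along the percent-position axis in
#' 1% increments, from the distal towards the proximal end. Windows are
#' half-open intervals `[s, s + w)` with left edge `s` in `0, 1, ..., 100 - w`;
#' for every window containing at least one hook, one curve point is
#' emitted whose x-coordinate is the arithmetic mean of the hook
#' percent-positions in the window (not the window midpoint — hence the
#' non-uniform point spacing of raw meristograms) and whose `L`, `B`, `A`,
#' `R` values are the means of the standardized variables over those hooks.
#' Consecutive windows that capture the identical hook set yield identical
#' points, which are collapsed to one.
#'
#' @param std Standardized hooks from [standardize_hooks()].
#' @param w Window width, integer percent; must be at least the MMAI of the
#'   collection (checked from the `n` column) and at most 100.
#' @return A tibble of curve points `x`, `L`, `B`, `A`, `R`, sorted by
#'   strictly increasing `x`.
#' @export
moving_average <- function(std, w) {
  if (nrow(std) == 0) {
    abort("no hooks to smooth", class = "meristo_usage_error")
  }
  if (length(w) != 1 || !is.finite(w) || w != round(w)) {
    abort("window width must be a single integer percent",
          class = "meristo_parameter_error")
  }
  w <- as.integer(w)
  mmai <- as.integer(ceiling(100 / (min(std$n) + 1)))
  if (w < mmai) {
    abort(sprintf(
      "window %d%% is below the minimum moving-average interval %d%% for this collection",
      w, mmai), class = "meristo_parameter_error")
  }
  if (w > 100) {
    abort("window width cannot exceed 100%", class = "meristo_parameter_error")
  }
  pts <- lapply(0:(100L - w), function(s) {
    in_win <- std$p >= s & std$p < s + w
    if (!any(in_win)) return(NULL)
    tibble(x = mean(std$p[in_win]),
           L = mean(std$l[in_win]), B = mean(std$b[in_win]),
           A = mean(std$a[in_win]), R = mean(std$r[in_win]))
  })
  pts <- bind_rows(pts)
  pts <- distinct(pts)
  # distinct windows can share a mean position with different means; average
  pts <- summarise(group_by(pts, .data$x),
                   across(c("L", "B", "A", "R"), mean), .groups = "drop")
  arrange(pts, .data$x)
}

#' Linear interpolation of curve points onto the integer position grid
#'
#' Resamples the four smoothed curves by piecewise-linear interpolation at
#' every integer percent-position inside the observed range
#' `[ceiling(min x), floor(max x)]`. No extrapolation is performed. Putting
#' meristograms on a common integer grid is what makes them comparable by
#' multivariate statistics.
#'
#' @param points Curve points from [moving_average()] (columns
#'   `x`, `L`, `B`, `A`, `R`) with at least two distinct `x`.
#' @return Curve points on the integer grid, same columns.
#' @export
interpolate_curves <- function(points) {
  if (nrow(points) < 2 || length(unique(points$x)) < 2) {
    abort(paste0("need at least 2 distinct positions to interpolate; ",
                 "disable interpolation for this collection"),
          class = "meristo_parameter_error")
  }
  grid <- seq(ceiling(min(points$x)), floor(max(points$x)))
  out <- tibble(x = as.numeric(grid))
  for (v in c("L", "B", "A", "R")) {
    out[[v]] <- stats::approx(points$x, points[[v]], xout = grid,
                              ties = mean)$y
  }
  out
}

#' Rescale curves to the collection maximum
#'
#' Each of the four curves is independently multiplied by 100 and divided
#' by its largest value over the curve points, so every final curve peaks
#' at exactly 100 ("percent-max-collection-value"). Monotone scaling leaves
#' the position of every maximum unchanged.
#'
#' @param points Curve points (columns `x`, `L`, `B`, `A`, `R`).
#' @return Rescaled curve points.
#' @export
rescale_to_max <- function(points) {
  if (nrow(points) == 0) {
    abort("no curve points to rescale", class = "meristo_usage_error")
  }
  for (v in c("L", "B", "A", "R")) {
    points[[v]] <- points[[v]] * 100 / max(points[[v]])
  }
  points
}

#' Compute a meristogram
#'
#' Runs the full pipeline on a hook collection: row-level standardization
#' ([standardize_hooks()]), moving-average smoothing ([moving_average()]),
#' optional linear interpolation onto the integer grid
#' ([interpolate_curves()]), and rescaling so each curve's maximum is 100
#' ([rescale_to_max()]) — in that order, interpolation sitting between
#' smoothing and rescaling so that every final curve attains exactly 100
#' somewhere on the reported grid.
#'
#' @param hooks A [hook_collection()].
#' @param mai Moving-average interval, integer percent, or `"auto"` to use
#'   the collection's [minimum_mai()].
#' @param interpolate Resample onto the integer grid (default `TRUE`).
#' @return A `meristogram`: a tibble of curve points (`x`, `L`, `B`, `A`,
#'   `R`) with attributes `label`, `mai`, `interpolated`, `n_rows`,
#'   `n_hooks`.
#' @export
#' @examples
#' hooks <- synthetic_hooks(synthetic_spec(seed = 1))
#' m <- meristogram(hooks, mai = "auto")
#' peak_positions(m)
meristogram <- function(hooks, mai = "auto", interpolate = TRUE) {
  std <- standardize_hooks(hooks)
  mmai <- minimum_mai(hooks)
  if (identical(mai, "auto")) mai <- mmai
  pts <- moving_average(std, mai)
  if (interpolate) pts <- interpolate_curves(pts)
  pts <- rescale_to_max(pts)
  new_tibble(pts,
             label = collection_label(hooks),
             mai = as.integer(mai),
             interpolated = isTRUE(interpolate),
             n_rows = n_hook_rows(hooks),
             n_hooks = nrow(hooks),
             class = "meristogram")
}

#' @export
#' @rdname meristogram
curve_points <- function(m) {
  tibble(x = m$x, L = m$L, B = m$B, A = m$A, R = m$R)
}

#' Peak positions of the four meristogram curves
#'
#' @param m A [meristogram()].
#' @return A tibble with one row per variable (`L`, `B`, `A`, `R`): the
#'   percent-position `position` of the curve maximum and the maximal
#'   `value` (100 after rescaling). Ties are broken towards the smallest
#'   position, i.e. the most distal hook region.
#' @export
peak_positions <- function(m) {
  pts <- curve_points(m)
  if (nrow(pts) == 0) {
    abort("meristogram has no curve points", class = "meristo_usage_error")
  }
  bind_rows(lapply(c("L", "B", "A", "R"), function(v) {
    i <- which(pts[[v]] >= max(pts[[v]]) - 1e-12)[1]
    tibble(variable = v, position = pts$x[i], value = pts[[v]][i])
  }))
}

#' @export
print.meristogram <- function(x, ...) {
  cat(sprintf(
    "<meristogram '%s': MAI %d%%%s, %d points from %d rows / %d hooks>\n",
    attr(x, "label"), attr(x, "mai"),
    if (isTRUE(attr(x, "interpolated"))) ", interpolated" else "",
    nrow(x), attr(x, "n_rows"), attr(x, "n_hooks")))
  NextMethod()
}
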