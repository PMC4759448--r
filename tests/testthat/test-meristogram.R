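test_that("percent-position centres ordinals in (0, 100)", {
  expect_equal(percent_position(1:5, 5),
               c(16.667, 33.333, 50, 66.667, 83.333), tolerance = 1e-4)
  expect_equal(percent_position(1, 1), 50)
  expect_equal(percent_position(1, 9), 10)
  expect_error(percent_position(0, 5))
  expect_error(percent_position(6, 5))
})

test_that("derived variables follow the triangular-area and ratio formulas", {
  expect_equal(hook_area(60, 20), 600)
  expect_equal(hook_ratio(60, 20), 100 / 3, tolerance = 1e-9)
  expect_equal(hook_area(90, 30), 1350)
  expect_equal(hook_ratio(90, 30), 100 / 3, tolerance = 1e-9)
  expect_error(hook_area(100, 0), class = "meristo_value_error")
  expect_error(hook_ratio(0, 10), class = "meristo_value_error")
  # identity ratio * length = 100 * base, exactly
  set.seed(42)
  l <- runif(50, 20, 120); b <- runif(50, 5, 50)
  expect_equal(hook_ratio(l, b) * l, 100 * b)
})

test_that("row standardization scales each variable to its own row maximum", {
  hooks <- mk_hooks(w = list(length = c(50, 100, 75), base = c(20, 20, 20)))
  std <- standardize_hooks(hooks)
  expect_equal(std$l, c(50, 100, 75))
  expect_equal(std$b, c(100, 100, 100))
  # every variable attains 100 somewhere in every row
  set.seed(7)
  std2 <- standardize_hooks(random_hooks(n_rows = 6))
  by_row <- dplyr::group_by(std2, specimen)
  mx <- dplyr::summarise(by_row, dplyr::across(c(l, b, a, r), max))
  expect_equal(unname(as.matrix(mx[-1])),
               matrix(100, nrow(mx), 4))
})

test_that("standardization is invariant to per-row scalar allometry", {
  set.seed(11)
  hooks <- random_hooks(n_rows = 5)
  df <- tibble::as_tibble(hooks)
  scaled <- dplyr::group_by(df, specimen)
  scaled <- dplyr::ungroup(dplyr::mutate(
    scaled, c = runif(1, 0.2, 5),
    length = length * c, base = base * c))
  scaled$c <- NULL
  std1 <- standardize_hooks(hooks)
  std2 <- standardize_hooks(hook_collection(scaled, label = "scaled"))
  expect_equal(std1[c("p", "l", "b", "a", "r")],
               std2[c("p", "l", "b", "a", "r")], tolerance = 1e-12)
})

test_that("the minimum moving-average interval follows the shortest row", {
  mk_n <- function(n) mk_hooks(w = list(length = seq(50, 50 + n - 1),
                                        base = rep(20, n)))
  expect_equal(minimum_mai(mk_n(5)), 17L)
  expect_equal(minimum_mai(mk_n(9)), 10L)
  expect_equal(minimum_mai(mk_n(99)), 1L)
  # the shortest row governs a mixed collection
  mixed <- pool_hooks(mk_n(5), hook_collection(dplyr::mutate(
    tibble::as_tibble(mk_n(12)), specimen = "w2")), label = "mixed")
  expect_equal(minimum_mai(mixed), 17L)
})

test_that("moving average emits mean-position, mean-value points", {
  one <- mk_hooks(w = list(length = 60, base = 20))
  std <- suppressWarnings(standardize_hooks(one))  # 1-hook row warns
  pts <- moving_average(std, 51)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$x, 50)
  expect_equal(unlist(pts[c("L", "B", "A", "R")], use.names = FALSE),
               rep(100, 4))
  # constant standardized values -> all curves equal
  const <- mk_hooks(w = list(length = rep(70, 6), base = rep(25, 6)))
  cpts <- moving_average(standardize_hooks(const), 20)
  expect_true(all(cpts$L == 100 & cpts$B == 100 &
                  cpts$A == 100 & cpts$R == 100))
})

test_that("moving average agrees exactly with the brute-force window oracle", {
  set.seed(101)
  for (rep in 1:6) {
    hooks <- random_hooks(n_rows = sample(2:8, 1), n_range = 3:25)
    std <- standardize_hooks(hooks)
    expect_lte(nrow(std), 200)
    w <- max(minimum_mai(hooks), sample(10:40, 1))
    got <- moving_average(std, w)
    want <- brute_moving_average(std, w)
    expect_equal(got$x, want$x, tolerance = 1e-12)
    expect_equal(got$L, want$L, tolerance = 1e-12)
    expect_equal(got$B, want$B, tolerance = 1e-12)
    expect_equal(got$A, want$A, tolerance = 1e-12)
    expect_equal(got$R, want$R, tolerance = 1e-12)
    expect_true(all(diff(got$x) > 0))
  }
})

test_that("window width is validated against the MMAI and the axis", {
  hooks <- mk_hooks(w = list(length = c(50, 60, 70, 65, 55),
                             base = c(15, 18, 22, 20, 16)))
  std <- standardize_hooks(hooks)
  expect_error(moving_average(std, 9), "17",
               class = "meristo_parameter_error")
  expect_error(moving_average(std, 101), class = "meristo_parameter_error")
  expect_error(moving_average(std, 17.5), class = "meristo_parameter_error")
  expect_silent(moving_average(std, 17))
})

test_that("interpolation is linear, exact at knots, and never extrapolates", {
  pts <- tibble::tibble(x = c(10.5, 12.5), L = c(50, 60), B = c(50, 60),
                        A = c(50, 60), R = c(50, 60))
  out <- interpolate_curves(pts)
  expect_equal(out$x, c(11, 12))
  expect_equal(out$L, c(52.5, 57.5))
  # a point already at integer x keeps its value exactly
  pts2 <- tibble::tibble(x = c(7, 9.5), L = c(80, 40), B = c(80, 40),
                         A = c(80, 40), R = c(80, 40))
  expect_equal(interpolate_curves(pts2)$L[1], 80)
  # reconstruction of a piecewise-linear curve sampled at its own knots
  set.seed(55)
  knots <- sort(runif(8, 5, 95))
  vals <- runif(8, 10, 100)
  pw <- tibble::tibble(x = knots, L = vals, B = vals, A = vals, R = vals)
  direct <- stats::approx(knots, vals,
                          xout = seq(ceiling(min(knots)),
                                     floor(max(knots))))$y
  expect_equal(interpolate_curves(pw)$L, direct)
  # convex-combination bound
  ip <- interpolate_curves(pw)
  expect_true(all(ip$L >= min(vals) - 1e-12 & ip$L <= max(vals) + 1e-12))
  expect_error(interpolate_curves(pw[1, ]),
               class = "meristo_parameter_error")
})

test_that("rescaling sets each curve maximum to 100 and preserves argmax", {
  pts <- tibble::tibble(x = c(10, 20), L = c(50, 25), B = c(10, 40),
                        A = c(70, 35), R = c(1, 2))
  out <- rescale_to_max(pts)
  expect_equal(out$L, c(100, 50))
  expect_equal(out$B, c(25, 100))
  expect_equal(rescale_to_max(out), out)  # idempotent
  for (v in c("L", "B", "A", "R")) {
    expect_equal(which.max(out[[v]]), which.max(pts[[v]]))
  }
})

test_that("the full pipeline yields curves with maxima of exactly 100", {
  set.seed(202)
  for (rep in 1:5) {
    hooks <- random_hooks(n_rows = sample(2:6, 1))
    m <- meristogram(hooks, mai = "auto",
                     interpolate = sample(c(TRUE, FALSE), 1))
    pts <- curve_points(m)
    for (v in c("L", "B", "A", "R")) {
      expect_equal(max(pts[[v]]), 100, tolerance = 1e-9)
    }
  }
})

test_that("a single row of identical hooks gives flat curves at 100", {
  hooks <- mk_hooks(w = list(length = rep(64, 8), base = rep(21, 8)))
  m <- meristogram(hooks, mai = "auto")
  pts <- curve_points(m)
  expect_true(all(abs(as.matrix(pts[c("L", "B", "A", "R")]) - 100) < 1e-9))
})

test_that("meristograms are invariant to row order and specimen labels", {
  set.seed(303)
  hooks <- random_hooks(n_rows = 5)
  df <- tibble::as_tibble(hooks)
  shuffled <- df[sample(nrow(df)), ]
  renames <- stats::setNames(paste0("zz_", rev(sort(unique(df$specimen)))),
                             sort(unique(df$specimen)))
  relabeled <- dplyr::mutate(shuffled,
                             specimen = unname(renames[specimen]))
  m1 <- meristogram(hooks, mai = 20)
  m2 <- meristogram(hook_collection(shuffled, label = "random"), mai = 20)
  m3 <- meristogram(hook_collection(relabeled, label = "random"), mai = 20)
  expect_equal(curve_points(m1), curve_points(m2), tolerance = 1e-12)
  expect_equal(curve_points(m1), curve_points(m3), tolerance = 1e-12)
})

test_that("meristograms are invariant to per-row allometric scaling", {
  set.seed(304)
  hooks <- random_hooks(n_rows = 4)
  df <- dplyr::group_by(tibble::as_tibble(hooks), specimen)
  scaled <- dplyr::ungroup(dplyr::mutate(df, c = runif(1, 0.1, 10),
                                         length = length * c,
                                         base = base * c))
  scaled$c <- NULL
  m1 <- meristogram(hooks, mai = 25)
  m2 <- meristogram(hook_collection(scaled, label = "scaled"), mai = 25)
  expect_equal(curve_points(m1), curve_points(m2), tolerance = 1e-9)
})

test_that("peak positions take the most distal position on ties", {
  flat <- tibble::tibble(x = c(10, 20, 30), L = c(100, 100, 100),
                         B = c(50, 100, 100), A = c(50, 60, 100),
                         R = c(100, 50, 100))
  m <- tibble::new_tibble(flat, label = "t", mai = 20L, interpolated = TRUE,
                          n_rows = 1L, n_hooks = 3L, class = "meristogram")
  pk <- peak_positions(m)
  expect_equal(pk$position[pk$variable == "L"], 10)
  expect_equal(pk$position[pk$variable == "B"], 20)
  expect_equal(pk$position[pk$variable == "A"], 30)
  expect_equal(pk$position[pk$variable == "R"], 10)
})

test_that("with w = MMAI every interior window catches every row", {
  set.seed(404)
  for (rep in 1:4) {
    hooks <- random_hooks(n_rows = sample(2:5, 1), n_range = 3:15)
    std <- standardize_hooks(hooks)
    w <- minimum_mai(hooks)
    nmin <- min(hook_rows(hooks)$n)
    lo <- 100 / (nmin + 1); hi <- 100 * nmin / (nmin + 1)
    keys <- unique(paste(std$specimen, std$sex, std$surface))
    for (s in 0:(100 - w)) {
      if (s >= lo && s + w <= hi) {
        hit <- std$p >= s & std$p < s + w
        got_keys <- unique(paste(std$specimen, std$sex,
                                 std$surface)[hit])
        expect_setequal(got_keys, keys)
      }
    }
  }
})

test_that("tidy and glance summarize a meristogram", {
  hooks <- mk_hooks(w = list(length = c(50, 90, 60, 45),
                             base = c(15, 25, 28, 14)))
  m <- meristogram(hooks, mai = 25)
  td <- tidy(m)
  expect_equal(nrow(td), 4 * nrow(m))
  expect_setequal(levels(td$variable), c("L", "B", "A", "R"))
  gl <- glance(m)
  expect_equal(gl$mai, 25L)
  expect_equal(gl$n_hooks, 4L)
  expect_true(all(c("peak_L", "peak_R") %in% names(gl)))
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
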