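# Small in-code fixtures and file builders shared across tests.

# a hook collection built directly from vectors; one row per specimen
mk_hooks <- function(..., label = "fixture") {
  rows <- list(...)
  df <- dplyr::bind_rows(lapply(names(rows), function(sp) {
    lens <- rows[[sp]]$length
    tibble::tibble(specimen = sp, hook = seq_along(lens),
                   length = lens, base = rows[[sp]]$base)
  }))
  suppressWarnings(hook_collection(df, label = label))
}

# plain tibble comparison, ignoring collection-level attributes
plain_df <- function(x) {
  x <- tibble::as_tibble(x)
  attr(x, "label") <- NULL
  attr(x, "generator") <- NULL
  x
}

# write a hook CSV to a temp file, returning its path
write_hook_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

# a random valid collection for property tests (plain tibble construction,
# independent of the synthetic generator)
random_hooks <- function(n_rows = 5, n_range = 4:12, label = "random") {
  df <- dplyr::bind_rows(lapply(seq_len(n_rows), function(i) {
    n <- sample(n_range, 1)
    tibble::tibble(specimen = sprintf("r%02d", i), hook = seq_len(n),
                   length = stats::runif(n, 30, 120),
                   base = stats::runif(n, 10, 45))
  }))
  suppressWarnings(hook_collection(df, label = label))
}

# study supplementary files, if the user has deposited them in the package
supp_file <- function(name) {
  installed <- system.file("extdata", "supplementary", name,
                           package = "meristo")
  if (nzchar(installed) && file.exists(installed)) return(installed)
  local <- testthat::test_path("..", "..", "inst", "extdata",
                               "supplementary", name)
  if (file.exists(local)) return(local)
  NA_character_
}

# Table-1 layout: taxon -> supplementary hook files with their tags
study_file_map <- function() {
  list(
    "E. bothniensis" = list(files = c("oo_63705.csv", "oo_63706.csv"),
                            sex = c("female", "male"),
                            surface = c("unknown", "unknown")),
    "E. 'bothniensis'" = list(files = "oo_63707.csv", sex = "female",
                              surface = "unknown"),
    "E. brayi" = list(files = c("oo_63694.csv", "oo_63695.csv"),
                      sex = c("female", "male"),
                      surface = c("unknown", "unknown")),
    "E. gadi sp. A" = list(files = c("oo_63710.csv", "oo_63711.csv"),
                           sex = c("female", "male"),
                           surface = c("unknown", "unknown")),
    "E. gadi sp. B" = list(files = c("oo_63712.csv", "oo_63713.csv"),
                           sex = c("female", "male"),
                           surface = c("unknown", "unknown")),
    "E. gadi sp. I" = list(files = c("oo_63714.csv", "oo_63715.csv"),
                           sex = c("female", "male"),
                           surface = c("unknown", "unknown")),
    "E. salmonis" = list(files = c("oo_63696.csv", "oo_63699.csv",
                                   "oo_63701.csv", "oo_63703.csv"),
                         sex = c("female", "female", "male", "male"),
                         surface = c("dorsal", "ventral",
                                     "dorsal", "ventral")),
    "E. truttae Drummore" = list(files = c("oo_68461.csv", "oo_68463.csv"),
                                 sex = c("female", "male"),
                                 surface = c("unknown", "unknown")),
    "E. truttae Carron" = list(files = c("oo_68464.csv", "oo_68466.csv"),
                               sex = c("female", "male"),
                               surface = c("unknown", "unknown")))
}

# TRUE when every deposited hook file of the study is available
study_files_available <- function() {
  fmap <- study_file_map()
  all(!is.na(vapply(unlist(lapply(fmap, `[[`, "files")), supp_file, "")))
}

load_study_collection <- function(taxon) {
  info <- study_file_map()[[taxon]]
  parts <- lapply(seq_along(info$files), function(i) {
    read_hooks(supp_file(info$files[i]), sex = info$sex[i],
               surface = info$surface[i])
  })
  pool_hooks(parts, label = taxon)
}
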