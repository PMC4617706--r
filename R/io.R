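# Reading and writing the wide intensity / profile / module table formats.

#' Read a wide intensity table
#'
#' Expects a TSV (or CSV) with an accession column followed by one intensity
#' column per (replicate, elution step), named `<replicate>__<step>`. A
#' proteinGroups-style dialect is supported through `col_prefix`: columns
#' starting with the prefix (e.g. `"Intensity "`) are selected and the prefix
#' stripped before parsing the `<replicate>__<step>` name; other columns are
#' ignored. The declared `steps` give the elution order; every
#' (replicate, step) combination must be present exactly once. Unparseable
#' numeric cells become missing values and their count is reported.
#'
#' @param path Path to the table (UTF-8, decimal point `.`).
#' @param steps Character vector of step labels in elution order; by default
#'   the order of first appearance in the header.
#' @param col_prefix Optional prefix selecting intensity columns
#'   (proteinGroups dialect).
#' @param accession_col Name of the accession column; default the first
#'   column.
#' @param delim Field delimiter; `"\t"` by default, use `","` for CSV.
#' @return Long intensity tibble (`accession`, `replicate`, `step`,
#'   `intensity`) with `step` an ordered-level factor.
#' @export
read_intensity_table <- function(path, steps = NULL, col_prefix = NULL,
                                 accession_col = NULL, delim = "\t") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (is.null(accession_col)) accession_col <- names(raw)[1L]
  if (!accession_col %in% names(raw)) {
    abort(sprintf("Accession column '%s' not found.", accession_col))
  }
  value_cols <- setdiff(names(raw), accession_col)
  if (!is.null(col_prefix)) {
    value_cols <- value_cols[startsWith(value_cols, col_prefix)]
    if (length(value_cols) == 0L) {
      abort(sprintf("No column starts with prefix '%s'.", col_prefix))
    }
  }
  bare <- if (is.null(col_prefix)) value_cols else
    substring(value_cols, nchar(col_prefix) + 1L)
  parts <- strsplit(bare, "__", fixed = TRUE)
  bad <- value_cols[lengths(parts) != 2L]
  if (length(bad)) {
    abort(paste0("Column(s) not named `<replicate>__<step>`: ",
                 paste(bad, collapse = ", "), "."))
  }
  replicate <- vapply(parts, `[`, character(1), 1L)
  step <- vapply(parts, `[`, character(1), 2L)
  if (anyDuplicated(bare)) {
    abort(paste0("Duplicated (replicate, step) column(s): ",
                 paste(unique(bare[duplicated(bare)]), collapse = ", "), "."))
  }
  if (is.null(steps)) steps <- unique(step)
  if (!setequal(step, steps)) {
    abort(paste0("Header steps (", paste(unique(step), collapse = ", "),
                 ") do not match the declared steps (",
                 paste(steps, collapse = ", "), ")."))
  }
  expected <- tidyr::expand_grid(replicate = unique(replicate), step = steps)
  have <- paste(replicate, step, sep = "__")
  missing_cols <- setdiff(paste(expected$replicate, expected$step, sep = "__"),
                          have)
  if (length(missing_cols)) {
    abort(paste0("Incomplete replicate x step grid; missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  dup_acc <- raw[[accession_col]][duplicated(raw[[accession_col]])]
  if (length(dup_acc)) {
    abort(paste0("Duplicated accession(s): ",
                 paste(unique(dup_acc), collapse = ", "), "."))
  }
  long <- raw |>
    tidyr::pivot_longer(dplyr::all_of(value_cols), names_to = "column",
                        values_to = "raw_value") |>
    dplyr::mutate(
      replicate = replicate[match(.data$column, value_cols)],
      step = factor(step[match(.data$column, value_cols)], levels = steps),
      intensity = suppressWarnings(as.numeric(.data$raw_value))
    )
  # A column with no parseable numeric cell at all is a structural problem
  # (e.g. a text column caught by the prefix); scattered bad cells are data.
  parse_rate <- long |>
    dplyr::filter(!is.na(.data$raw_value), .data$raw_value != "") |>
    dplyr::summarise(ok = any(!is.na(.data$intensity)), .by = "column")
  dead <- parse_rate$column[!parse_rate$ok]
  if (length(dead)) {
    abort(paste0("Non-numeric intensity column(s): ",
                 paste(dead, collapse = ", "), "."))
  }
  n_bad <- sum(!is.na(long$raw_value) & long$raw_value != "" &
                 is.na(long$intensity))
  if (n_bad > 0) {
    inform(sprintf("%d unparseable cell(s) treated as missing.", n_bad))
  }
  long |>
    dplyr::transmute(accession = .data[[accession_col]], .data$replicate,
                     .data$step, .data$intensity) |>
    check_intensity_data()
}

#' Write a long intensity tibble as a wide TSV
#'
#' Inverse of [read_intensity_table()]: columns `accession` then
#' `<replicate>__<step>`.
#'
#' @inheritParams presence_filter
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(data, path) {
  data <- check_intensity_data(data)
  steps <- levels(factor(data$step, levels = levels(data$step)))
  wide <- data |>
    dplyr::mutate(column = paste(.data$replicate, .data$step, sep = "__"),
                  column = factor(.data$column, levels = unique(.data$column))) |>
    dplyr::select("accession", "column", "intensity") |>
    tidyr::pivot_wider(names_from = "column", values_from = "intensity")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Write averaged elution profiles as TSV
#'
#' One row per protein: accession, one column per elution step, plus the
#' number of replicates that contributed.
#'
#' @param profiles An `epasis_profiles` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  wide <- profiles |>
    tidyr::pivot_wider(names_from = "step", values_from = "cumulative") |>
    dplyr::relocate("n_replicates_used", .after = dplyr::last_col())
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read averaged elution profiles from TSV
#'
#' @param path A file written by [write_profiles()] (accession column, one
#'   column per step in elution order, optional `n_replicates_used`).
#' @return An `epasis_profiles` tibble.
#' @export
read_profiles <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  steps <- setdiff(names(wide), c("accession", "n_replicates_used"))
  if (!"n_replicates_used" %in% names(wide)) wide$n_replicates_used <- NA_real_
  long <- wide |>
    tidyr::pivot_longer(dplyr::all_of(steps), names_to = "step",
                        values_to = "cumulative") |>
    dplyr::mutate(step = factor(.data$step, levels = steps)) |>
    dplyr::select("accession", "step", "cumulative", "n_replicates_used")
  new_epasis_profiles(long, steps)
}

#' Read a curated module-definition table
#'
#' TSV/CSV with columns `module` and `accession` (an optional
#' `source_reference` column is carried through).
#'
#' @param path Path to the table.
#' @param delim Field delimiter (default tab).
#' @return Tibble of curated members.
#' @export
read_modules <- function(path, delim = "\t") {
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  check_modules(out)
  as_tibble(out)
}
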