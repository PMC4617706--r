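# Module assignment at a fixed EPD threshold, and accuracy against a
# simulated ground truth.

#' Assign proteins to consensus sub-complex modules
#'
#' Curated members whose EPD to their own module is at or below the threshold
#' form the module's reference group and keep the bare module label; the
#' curated label governs even when the data place the member nearer another
#' module (both readings stay visible through `nearest_module`). Non-members
#' whose minimum EPD is at or below the threshold become `<module>_cand`
#' candidates of their nearest module (lexicographic tie-break). Everything
#' else is `unknown`.
#'
#' @param epd An `epasis_epd` tibble from [epd_table()].
#' @param modules Curated module table (`module`, `accession`).
#' @param threshold Nonnegative EPD threshold; proteins are assigned when
#'   EPD <= threshold.
#' @return A tibble of class `epasis_assignment`, ordered by accession, with
#'   columns `accession`, `category`, `curated_module`, `nearest_module`,
#'   `epd_min` and one `epd_<module>` column per consensus module.
#' @export
assign_modules <- function(epd, modules, threshold) {
  check_modules(modules)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    abort("`threshold` must be a single nonnegative EPD value.")
  }
  nearest <- epd_nearest(epd)
  wide <- epd |>
    tidyr::pivot_wider(names_from = "module", values_from = "epd",
                       names_prefix = "epd_")
  own <- dplyr::inner_join(
    epd, dplyr::rename(modules[, c("module", "accession")],
                       curated_module = "module"),
    by = "accession"
  ) |>
    dplyr::filter(.data$module == .data$curated_module) |>
    dplyr::transmute(.data$accession, .data$curated_module,
                     epd_own = .data$epd)
  out <- nearest |>
    dplyr::left_join(own, by = "accession") |>
    dplyr::mutate(
      category = dplyr::case_when(
        !is.na(.data$curated_module) & .data$epd_own <= threshold ~
          .data$curated_module,
        is.na(.data$curated_module) & .data$epd_min <= threshold ~
          paste0(.data$nearest_module, "_cand"),
        .default = "unknown"
      )
    ) |>
    dplyr::left_join(wide, by = "accession") |>
    dplyr::select("accession", "category", "curated_module",
                  "nearest_module", "epd_min", dplyr::starts_with("epd_"),
                  -"epd_own") |>
    dplyr::arrange(.data$accession)
  structure(as_tibble(out), threshold = threshold,
            class = c("epasis_assignment", class(tibble())))
}

#' @export
print.epasis_assignment <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Module assignment at EPD threshold %.4g: %d reference, %d candidate, %d unknown\n",
    attr(x, "threshold"), g$n_reference, g$n_candidate, g$n_unknown))
  NextMethod()
}

#' One-row summary of a module assignment
#'
#' @param x An `epasis_assignment` tibble.
#' @param ... Unused.
#' @return One-row tibble with the threshold and the counts of reference
#'   (curated members below threshold), candidate and unknown proteins.
#' @method glance epasis_assignment
#' @export
glance.epasis_assignment <- function(x, ...) {
  tibble(
    threshold = attr(x, "threshold"),
    n_reference = sum(!is.na(x$curated_module) & x$category != "unknown"),
    n_candidate = sum(endsWith(x$category, "_cand")),
    n_unknown = sum(x$category == "unknown"),
    n_proteins = nrow(x)
  )
}

#' Assignment accuracy against a known ground truth
#'
#' Maps each assignment category to a module claim (`<module>` and
#' `<module>_cand` claim that module; `unknown` claims background) and
#' reports the fraction of proteins whose claim matches the simulated truth.
#'
#' @param assignment An `epasis_assignment` tibble.
#' @param truth Data frame with columns `accession` and `module` (module name
#'   or `"background"`), e.g. the `truth` component of
#'   [simulate_experiment()].
#' @return A single accuracy in \[0, 1\], computed over the proteins present
#'   in both tables.
#' @export
assignment_accuracy <- function(assignment, truth) {
  joined <- dplyr::inner_join(
    dplyr::select(as_tibble(assignment), "accession", "category"),
    dplyr::select(as_tibble(truth), "accession", truth_module = "module"),
    by = "accession"
  )
  if (nrow(joined) == 0L) {
    abort("No shared accessions between `assignment` and `truth`.")
  }
  claimed <- ifelse(joined$category == "unknown", "background",
                    sub("_cand$", "", joined$category))
  mean(claimed == joined$truth_module)
}

#' Write an assignment table to TSV
#'
#' @param assignment An `epasis_assignment` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  readr::write_tsv(as_tibble(assignment), path)
  invisible(path)
}
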