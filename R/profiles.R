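# Elution profile construction: presence filtering, cumulative relative
# abundance per replicate, and averaging across replicates.

#' Filter proteins by presence across replicates
#'
#' Retains proteins detected in at least `ceiling(min_fraction * n_replicates)`
#' replicates. A protein counts as present in a replicate when it has at least
#' one positive, non-missing intensity across that replicate's elution steps.
#' The study design behind the default requires presence in 4 of 7 bait
#' replicates (4/7 = 57%).
#'
#' @param data Long intensity tibble with columns `accession`, `replicate`,
#'   `step` (factor; levels give the elution order) and `intensity`
#'   (nonnegative; `NA` = missing).
#' @param min_fraction Minimum fraction of replicates, in (0, 1]. Default 4/7.
#' @return The input tibble restricted to retained proteins, original row
#'   order preserved.
#' @examples
#' m <- simulate_experiment(synth_config(seed = 1))$intensities
#' nrow(presence_filter(m))
#' @export
presence_filter <- function(data, min_fraction = 4 / 7) {
  data <- check_intensity_data(data)
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      is.na(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    abort("`min_fraction` must be a single number in (0, 1].")
  }
  n_rep <- dplyr::n_distinct(data$replicate)
  need <- ceiling(min_fraction * n_rep)
  present <- data |>
    dplyr::summarise(
      present = any(.data$intensity > 0, na.rm = TRUE),
      .by = c("accession", "replicate")
    ) |>
    dplyr::summarise(n_present = sum(.data$present), .by = "accession") |>
    dplyr::filter(.data$n_present >= need)
  dplyr::filter(data, .data$accession %in% present$accession)
}

#' Cumulative relative-abundance profile of one replicate
#'
#' Converts a step-ordered intensity vector into a cumulative relative
#' abundance profile: the running sum divided by the total recovered
#' intensity. Missing values are treated as zero intensity. A replicate with
#' zero total intensity has no defined profile and returns all `NA` so that it
#' is excluded from averaging rather than entering as silent zeros.
#'
#' @param intensities Numeric vector of step-ordered intensities (`NA`
#'   allowed).
#' @return Numeric vector of the same length: non-decreasing, ending at 1; or
#'   all `NA` when the total intensity is zero.
#' @examples
#' cumulative_profile(c(2, 2, 2, 2, 2))
#' cumulative_profile(c(1, 3, 0, 0, 0))
#' @export
cumulative_profile <- function(intensities) {
  if (!is.numeric(intensities) || length(intensities) == 0L) {
    abort("`intensities` must be a non-empty numeric vector.")
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    abort("Intensities must be nonnegative.")
  }
  x <- ifelse(is.na(intensities), 0, intensities)
  total <- sum(x)
  if (total == 0) {
    return(rep(NA_real_, length(x)))
  }
  cumsum(x) / total
}

#' Average per-replicate profiles of one protein
#'
#' Element-wise arithmetic mean over replicates with a defined profile.
#' Undefined replicates (all-`NA` rows, i.e. zero total intensity) are
#' excluded from the mean.
#'
#' @param profiles Numeric matrix, one row per replicate profile, one column
#'   per elution step.
#' @return Numeric vector: the mean profile, with attribute
#'   `n_replicates_used`.
#' @export
average_replicates <- function(profiles) {
  if (!is.matrix(profiles) || !is.numeric(profiles)) {
    abort("`profiles` must be a numeric matrix (replicates x steps).")
  }
  defined <- !apply(profiles, 1L, function(r) all(is.na(r)))
  if (!any(defined)) {
    abort("No replicate has a defined profile; the protein should have been filtered out.")
  }
  out <- colMeans(profiles[defined, , drop = FALSE])
  attr(out, "n_replicates_used") <- sum(defined)
  out
}

#' Build averaged elution profiles for every protein
#'
#' For each protein, normalizes every replicate to a cumulative
#' relative-abundance profile (each replicate carries equal weight regardless
#' of its yield) and averages the defined replicate profiles. Proteins with no
#' defined replicate (zero intensity everywhere) raise an error; run
#' [presence_filter()] first.
#'
#' @inheritParams presence_filter
#' @return A tibble of class `epasis_profiles` with columns `accession`,
#'   `step` (factor), `cumulative` and `n_replicates_used`; one row per
#'   (protein, step).
#' @examples
#' m <- simulate_experiment(synth_config(seed = 1))$intensities
#' prof <- m |> presence_filter() |> elution_profiles()
#' head(prof)
#' @export
elution_profiles <- function(data) {
  data <- check_intensity_data(data)
  steps <- levels(factor(data$step, levels = levels(data$step)))
  per_rep <- data |>
    dplyr::arrange(.data$step) |>
    dplyr::summarise(
      profile = list(cumulative_profile(.data$intensity[match(steps, as.character(.data$step))])),
      .by = c("accession", "replicate")
    )
  averaged <- per_rep |>
    dplyr::summarise(
      profile = list(average_replicates(do.call(rbind, .data$profile))),
      .by = "accession"
    )
  out <- averaged |>
    dplyr::mutate(
      n_replicates_used = purrr::map_dbl(.data$profile, ~ attr(.x, "n_replicates_used")),
      step = list(factor(steps, levels = steps))
    ) |>
    tidyr::unnest(c("step", "profile")) |>
    dplyr::rename(cumulative = "profile") |>
    dplyr::select("accession", "step", "cumulative", "n_replicates_used")
  new_epasis_profiles(out, steps)
}

new_epasis_profiles <- function(x, steps) {
  structure(as_tibble(x), steps = steps,
            class = c("epasis_profiles", class(tibble())))
}

#' @export
print.epasis_profiles <- function(x, ...) {
  steps <- attr(x, "steps")
  cat(sprintf("Elution profiles: %d proteins x %d steps (%s)\n",
              dplyr::n_distinct(x$accession), length(steps),
              paste(steps, collapse = " < ")))
  NextMethod()
}

# steps x accessions matrix view used by distance computations
profiles_matrix <- function(profiles) {
  wide <- profiles |>
    dplyr::select("accession", "step", "cumulative") |>
    tidyr::pivot_wider(names_from = "step", values_from = "cumulative")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$accession
  m
}

#' Plot elution profiles
#'
#' One cumulative relative-abundance curve per protein over the ordered
#' elution steps, optionally coloured by a module label.
#'
#' @param object An `epasis_profiles` tibble from [elution_profiles()].
#' @param labels Optional data frame with columns `accession` and `module`
#'   used to colour the curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epasis_profiles
#' @export
autoplot.epasis_profiles <- function(object, labels = NULL, ...) {
  df <- object
  if (!is.null(labels)) {
    df <- dplyr::left_join(df, labels[, c("accession", "module")], by = "accession") |>
      dplyr::mutate(module = dplyr::coalesce(.data$module, "unassigned"))
  }
  p <- ggplot(df, aes(x = .data$step, y = .data$cumulative,
                      group = .data$accession)) +
    labs(x = "Elution step (increasing SDS, final FLAG elution)",
         y = "Cumulative relative abundance") +
    theme_minimal()
  if (is.null(labels)) {
    p + geom_line(alpha = 0.4)
  } else {
    p + geom_line(aes(colour = .data$module), alpha = 0.6)
  }
}
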