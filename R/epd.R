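# Consensus sub-complex profiles and the elution profile distance (EPD).

#' Build a consensus profile for one curated sub-complex
#'
#' The consensus profile is the unweighted element-wise mean of the curated
#' members' averaged elution profiles. Members without a profile in the set
#' (e.g. removed by the presence filter) are reported via a warning, never
#' silently dropped.
#'
#' @param profiles An `epasis_profiles` tibble from [elution_profiles()].
#' @param members Character vector of curated member accessions.
#' @param name Module label (e.g. `"DCTN"`, `"DYN"`).
#' @return A tibble of class `epasis_consensus` with columns `module`, `step`,
#'   `cumulative` and `n_members_used`.
#' @export
build_consensus <- function(profiles, members, name) {
  if (length(members) == 0L) {
    abort("`members` is empty: a consensus module needs at least one member.")
  }
  have <- intersect(members, unique(profiles$accession))
  absent <- setdiff(members, have)
  if (length(have) == 0L) {
    abort(sprintf("No member of module '%s' has a profile.", name))
  }
  if (length(absent)) {
    warn(sprintf("Module '%s': %d member(s) without a profile: %s",
                 name, length(absent), paste(absent, collapse = ", ")))
  }
  steps <- attr(profiles, "steps") %||% levels(factor(profiles$step))
  out <- profiles |>
    dplyr::filter(.data$accession %in% have) |>
    dplyr::summarise(cumulative = mean(.data$cumulative), .by = "step") |>
    dplyr::mutate(module = name, n_members_used = length(have)) |>
    dplyr::select("module", "step", "cumulative", "n_members_used")
  structure(as_tibble(out), steps = steps,
            class = c("epasis_consensus", class(tibble())))
}

#' Build consensus profiles for a curated module table
#'
#' @param profiles An `epasis_profiles` tibble.
#' @param modules Data frame with columns `module` and `accession` listing the
#'   curated members of each sub-complex.
#' @return An `epasis_consensus` tibble covering all modules.
#' @export
consensus_profiles <- function(profiles, modules) {
  check_modules(modules)
  out <- unique(modules$module) |>
    purrr::map(~ build_consensus(profiles, modules$accession[modules$module == .x], .x)) |>
    purrr::list_rbind()
  structure(as_tibble(out), steps = attr(profiles, "steps"),
            class = c("epasis_consensus", class(tibble())))
}

check_modules <- function(modules, call = rlang::caller_env()) {
  if (!is.data.frame(modules) || !all(c("module", "accession") %in% names(modules))) {
    abort("`modules` must be a data frame with columns `module` and `accession`.",
          call = call)
  }
  dup <- modules$accession[duplicated(modules$accession)]
  if (length(dup)) {
    abort(paste0("Accession(s) curated in more than one module: ",
                 paste(unique(dup), collapse = ", "), "."), call = call)
  }
  invisible(modules)
}

#' Elution profile distance between two profiles
#'
#' Plain Euclidean (L2) distance between two cumulative elution profiles
#' sharing the same step axis. The normalized dialect divides by
#' `sqrt(n_steps)` so distances are comparable across step counts.
#'
#' @param p,q Numeric profile vectors of equal length.
#' @param normalized Use the normalized dialect? Default `FALSE` (plain L2).
#' @return A single nonnegative distance.
#' @examples
#' compute_epd(c(0, 1), c(1, 1)) # 1
#' @export
compute_epd <- function(p, q, normalized = FALSE) {
  if (!is.numeric(p) || !is.numeric(q) || length(p) != length(q)) {
    abort("`p` and `q` must be numeric profiles on the same step axis.")
  }
  d <- sqrt(sum((p - q)^2))
  if (normalized) d <- d / sqrt(length(p))
  d
}

#' EPD of every protein to every consensus module
#'
#' Computes the full protein x module distance table. With
#' `leave_one_out = TRUE` a curated member is scored against the consensus of
#' the *other* members of its own module (requires `modules`); all other
#' (protein, module) pairs use the full consensus.
#'
#' @param profiles An `epasis_profiles` tibble.
#' @param consensus An `epasis_consensus` tibble from [consensus_profiles()].
#' @param normalized Passed to [compute_epd()].
#' @param leave_one_out Exclude a member's own profile from its module
#'   consensus when scoring it.
#' @param modules Curated module table; required for `leave_one_out` and used
#'   to annotate membership.
#' @return A tibble of class `epasis_epd` with columns `accession`, `module`
#'   and `epd`, one row per (protein, module).
#' @export
epd_table <- function(profiles, consensus, normalized = FALSE,
                      leave_one_out = FALSE, modules = NULL) {
  if (length(unique(consensus$module)) < 1L) {
    abort("At least one consensus module is required.")
  }
  if (leave_one_out && is.null(modules)) {
    abort("`leave_one_out = TRUE` requires the curated `modules` table.")
  }
  steps_p <- attr(profiles, "steps")
  steps_c <- attr(consensus, "steps")
  if (!is.null(steps_p) && !is.null(steps_c) && !identical(steps_p, steps_c)) {
    abort("Profiles and consensus were built on different step axes.")
  }
  pm <- profiles_matrix(profiles)
  cm <- consensus |>
    dplyr::select("accession" = "module", "step", "cumulative") |>
    new_epasis_profiles(steps = steps_c) |>
    profiles_matrix()
  grid <- tidyr::expand_grid(accession = rownames(pm), module = rownames(cm))
  epd <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    acc <- grid$accession[i]
    mod <- grid$module[i]
    target <- cm[mod, ]
    if (leave_one_out && acc %in% modules$accession[modules$module == mod]) {
      others <- setdiff(intersect(modules$accession[modules$module == mod],
                                  rownames(pm)), acc)
      if (length(others) == 0L) {
        abort(sprintf(
          "Leave-one-out consensus for module '%s' is empty when holding out %s.",
          mod, acc))
      }
      target <- colMeans(pm[others, , drop = FALSE])
    }
    compute_epd(pm[acc, ], target, normalized = normalized)
  })
  out <- grid |>
    dplyr::mutate(epd = epd) |>
    dplyr::arrange(.data$accession, .data$module)
  structure(as_tibble(out), normalized = normalized,
            class = c("epasis_epd", class(tibble())))
}

#' Nearest consensus module per protein
#'
#' @param epd An `epasis_epd` tibble.
#' @return Tibble with columns `accession`, `nearest_module` and `epd_min`.
#'   Ties are broken toward the lexicographically smallest module name;
#'   output ordered by accession.
#' @export
epd_nearest <- function(epd) {
  epd |>
    dplyr::arrange(.data$accession, .data$epd, .data$module) |>
    dplyr::slice_head(n = 1L, by = "accession") |>
    dplyr::transmute(.data$accession, nearest_module = .data$module,
                     epd_min = .data$epd) |>
    dplyr::arrange(.data$accession)
}
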