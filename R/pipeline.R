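# End-to-end orchestration: presence filter -> profiles -> consensus -> EPD
# -> threshold -> assignment -> QC, with a provenance record.

#' Pipeline configuration
#'
#' Validates the options for [run_pipeline()]. Exactly one of
#' `threshold` (fixed EPD cutoff) or `auto_threshold` (stepwise
#' sensitivity/specificity search) must be active.
#'
#' @param intensities Long intensity tibble, or a path to a wide TSV readable
#'   by [read_intensity_table()].
#' @param modules Curated module table (`module`, `accession`), or a path
#'   readable by [read_modules()].
#' @param min_fraction Presence-filter fraction (default 4/7).
#' @param normalized Use the normalized EPD dialect (default `FALSE`).
#' @param leave_one_out Leave-one-out consensus dialect (default `FALSE`).
#' @param n_steps Grid size for the threshold search (default 1000).
#' @param threshold Optional fixed EPD threshold; disables the search.
#' @param auto_threshold Run the threshold search (default `TRUE` when no
#'   fixed threshold is given).
#' @param seed Integer seed (used by the NMDS restarts).
#' @param out_dir Optional output directory; when given, assignment, profile
#'   and QC TSVs plus a provenance JSON are written there.
#' @return A validated list of class `epasis_pipeline_config`.
#' @export
pipeline_config <- function(intensities, modules, min_fraction = 4 / 7,
                            normalized = FALSE, leave_one_out = FALSE,
                            n_steps = 1000L, threshold = NULL,
                            auto_threshold = is.null(threshold),
                            seed = 1L, out_dir = NULL) {
  if (!is.null(threshold) && auto_threshold) {
    abort("Give either a fixed `threshold` or `auto_threshold = TRUE`, not both.")
  }
  if (is.null(threshold) && !auto_threshold) {
    abort("Either a fixed `threshold` or `auto_threshold = TRUE` is required.")
  }
  if (is.character(intensities) && !file.exists(intensities)) {
    abort(sprintf("Intensity file not found: %s", intensities))
  }
  if (is.character(modules) && !file.exists(modules)) {
    abort(sprintf("Module file not found: %s", modules))
  }
  structure(
    list(intensities = intensities, modules = modules,
         min_fraction = min_fraction, normalized = normalized,
         leave_one_out = leave_one_out, n_steps = as.integer(n_steps),
         threshold = threshold, auto_threshold = auto_threshold,
         seed = as.integer(seed), out_dir = out_dir),
    class = "epasis_pipeline_config"
  )
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full sub-complex deconvolution pipeline
#'
#' Executes presence filtering, profile construction, consensus building,
#' EPD scoring, threshold calibration (or a fixed threshold), module
#' assignment, replicate QC and NMDS ordination, logging per-stage protein
#' counts. With `out_dir` set, results are written as TSVs together with a
#' provenance JSON (configuration, seed, package version, stage counts) from
#' which the run can be reproduced.
#'
#' @param cfg An `epasis_pipeline_config` from [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return List of class `epasis_pipeline` with components `profiles`,
#'   `consensus`, `epd`, `threshold` (NULL when fixed), `assignment`, `qc`,
#'   `ordination`, `counts` and `provenance`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (!inherits(cfg, "epasis_pipeline_config")) {
    abort("`cfg` must come from `pipeline_config()`.")
  }
  say <- function(...) if (!quiet) inform(sprintf(...))

  intensities <- pipeline_stage("read_intensities",
    if (is.character(cfg$intensities)) read_intensity_table(cfg$intensities)
    else check_intensity_data(cfg$intensities))
  modules <- pipeline_stage("read_modules",
    if (is.character(cfg$modules)) read_modules(cfg$modules)
    else check_modules(cfg$modules))
  n_input <- dplyr::n_distinct(intensities$accession)
  say("Input: %d proteins, %d replicates", n_input,
      dplyr::n_distinct(intensities$replicate))

  filtered <- pipeline_stage("presence_filter",
                             presence_filter(intensities, cfg$min_fraction))
  n_filtered <- dplyr::n_distinct(filtered$accession)
  say("Presence filter (>= %.0f%% of replicates): %d proteins retained",
      100 * cfg$min_fraction, n_filtered)

  profiles <- pipeline_stage("elution_profiles", elution_profiles(filtered))
  consensus <- pipeline_stage("consensus_profiles",
                              consensus_profiles(profiles, modules))
  epd <- pipeline_stage("epd_table",
    epd_table(profiles, consensus, normalized = cfg$normalized,
              leave_one_out = cfg$leave_one_out, modules = modules))

  search <- NULL
  if (cfg$auto_threshold) {
    search <- pipeline_stage("threshold_search",
                             threshold_search(epd, modules, cfg$n_steps))
    thr <- search$threshold
    say("Threshold search (%d steps): selected %.4g", cfg$n_steps, thr)
  } else {
    thr <- cfg$threshold
    say("Fixed threshold: %.4g", thr)
  }
  assignment <- pipeline_stage("assign_modules",
                               assign_modules(epd, modules, thr))
  qc <- pipeline_stage("replicate_qc", replicate_qc(filtered))
  ordination <- pipeline_stage("nmds_ordination",
    nmds_ordination(profile_distance_matrix(profiles,
                                            normalized = cfg$normalized),
                    dims = 2L, seed = cfg$seed))
  counts <- tibble(
    stage = c("input", "presence_filter", "profiles"),
    n_proteins = c(n_input, n_filtered, dplyr::n_distinct(profiles$accession))
  )
  g <- glance(assignment)
  say("Assignment: %d reference, %d candidate, %d unknown (stress %.3f)",
      g$n_reference, g$n_candidate, g$n_unknown, ordination$stress)

  provenance <- list(
    package = "epasis",
    version = as.character(packageVersion("epasis")),
    seed = cfg$seed,
    config = cfg[c("min_fraction", "normalized", "leave_one_out", "n_steps",
                   "auto_threshold")],
    threshold = thr,
    counts = as.list(setNames(counts$n_proteins, counts$stage)),
    assignment_counts = as.list(g[c("n_reference", "n_candidate",
                                    "n_unknown")]),
    nmds_stress = ordination$stress
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profiles(profiles, file.path(cfg$out_dir, "profiles.tsv"))
    write_assignment(assignment, file.path(cfg$out_dir, "assignment.tsv"))
    readr::write_tsv(qc$replicate_pairs,
                     file.path(cfg$out_dir, "replicate_qc.tsv"))
    readr::write_tsv(qc$step_correlations,
                     file.path(cfg$out_dir, "step_correlations.tsv"))
    readr::write_tsv(epd, file.path(cfg$out_dir, "epd.tsv"))
    jsonlite::write_json(provenance,
                         file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("Outputs written to %s", cfg$out_dir)
  }

  structure(
    list(profiles = profiles, consensus = consensus, epd = epd,
         threshold = search, selected_threshold = thr,
         assignment = assignment, qc = qc, ordination = ordination,
         counts = counts, provenance = provenance),
    class = "epasis_pipeline"
  )
}

#' @export
print.epasis_pipeline <- function(x, ...) {
  cat("EPASIS pipeline run\n")
  cat(sprintf("  proteins: %s\n",
              paste(sprintf("%s=%d", x$counts$stage, x$counts$n_proteins),
                    collapse = ", ")))
  cat(sprintf("  threshold: %.4g%s\n", x$selected_threshold,
              if (is.null(x$threshold)) " (fixed)" else " (search)"))
  g <- glance(x$assignment)
  cat(sprintf("  assignment: %d reference, %d candidate, %d unknown\n",
              g$n_reference, g$n_candidate, g$n_unknown))
  cat(sprintf("  NMDS stress: %.4f\n", x$ordination$stress))
  invisible(x)
}
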