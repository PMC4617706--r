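# Seeded generator of synthetic stepwise-destabilization experiments with
# ground-truth module labels.

#' Configuration for a synthetic destabilization experiment
#'
#' The defaults emulate a stepwise SDS-destabilization design: 5 ordered
#' elution steps (four increasing SDS concentrations, then a final FLAG
#' elution), 7 bait replicates, two true sub-complex modules of 10 members
#' each with logistic release curves — one eluting early (dynein-like,
#' midpoint 1.0 on the 0-based step axis) and one released later and more
#' stably bound (dynactin-like, midpoint 2.0) — plus 20 background proteins
#' with uninformative Dirichlet elution, log-normal total intensities,
#' multiplicative log-normal cell noise (sd 0.2 on the log scale) and a 10%
#' per-(protein, replicate) dropout probability.
#'
#' @param n_steps Number of ordered elution steps (default 5).
#' @param step_labels Labels for the steps; default the four SDS
#'   concentrations (% w/v) and the final FLAG elution.
#' @param modules Data frame with columns `name`, `n_members`, `midpoint`
#'   (release midpoint on the 0-based step axis) and `sharpness` (> 0).
#' @param n_background Number of background proteins (default 20).
#' @param n_replicates Number of replicates (default 7).
#' @param total_log_mean,total_log_sd Log-normal parameters of per-protein
#'   total intensity (natural-log scale; defaults 16 and 1, i.e. a median
#'   total around 9e6 arbitrary LFQ units).
#' @param sigma Multiplicative noise sd on the log scale (default 0.2).
#' @param dropout Per-(protein, replicate) dropout probability in \[0, 1)
#'   (default 0.1).
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @return A validated list of class `epasis_synth_config`.
#' @export
synth_config <- function(n_steps = 5L,
                         step_labels = c("SDS_0.001", "SDS_0.005",
                                         "SDS_0.01", "SDS_0.02", "FLAG"),
                         modules = tibble(
                           name = c("DYN", "DCTN"),
                           n_members = c(10L, 10L),
                           midpoint = c(1.0, 2.0),
                           sharpness = c(6, 6)),
                         n_background = 20L,
                         n_replicates = 7L,
                         total_log_mean = 16,
                         total_log_sd = 1,
                         sigma = 0.2,
                         dropout = 0.1,
                         seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` is mandatory for a reproducible experiment.")
  }
  if (n_steps < 2L) abort("`n_steps` must be at least 2.")
  if (length(step_labels) != n_steps) {
    abort("`step_labels` must have length `n_steps`.")
  }
  needed <- c("name", "n_members", "midpoint", "sharpness")
  if (!is.data.frame(modules) || !all(needed %in% names(modules))) {
    abort(paste0("`modules` must have columns: ",
                 paste(needed, collapse = ", "), "."))
  }
  if (any(modules$sharpness <= 0)) abort("Module `sharpness` must be > 0.")
  if (any(modules$n_members < 0) || n_background < 0 || n_replicates < 1L) {
    abort("Counts must be nonnegative (and at least one replicate).")
  }
  if (sigma < 0) abort("`sigma` must be nonnegative.")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1).")
  structure(
    list(n_steps = as.integer(n_steps), step_labels = step_labels,
         modules = as_tibble(modules), n_background = as.integer(n_background),
         n_replicates = as.integer(n_replicates),
         total_log_mean = total_log_mean, total_log_sd = total_log_sd,
         sigma = sigma, dropout = dropout, seed = as.integer(seed)),
    class = "epasis_synth_config"
  )
}

#' Logistic release curve over ordered elution steps
#'
#' Per-step release fractions from a logistic CDF over the 0-based step
#' index: fraction k is proportional to the CDF increment between steps
#' k-1 and k, normalized so the fractions sum to 1. Large `sharpness`
#' approaches all-in-one-step release at the step just above the midpoint;
#' small `sharpness` approaches uniform release.
#'
#' @param midpoint Release midpoint on the 0-based step axis.
#' @param sharpness Steepness of the release transition (> 0).
#' @param n_steps Number of steps (>= 2).
#' @return Numeric vector of `n_steps` nonnegative fractions summing to 1.
#' @examples
#' module_release_curve(1.5, 100, 5)
#' @export
module_release_curve <- function(midpoint, sharpness, n_steps = 5L) {
  if (sharpness <= 0) abort("`sharpness` must be > 0.")
  if (n_steps < 2L) abort("`n_steps` must be at least 2.")
  k <- seq(-1L, n_steps - 1L)
  cdf <- plogis((k - midpoint) * sharpness)
  inc <- diff(cdf)
  inc / sum(inc)
}

# Stream splitting: each protein draws from its own seeded stream, derived
# from the experiment seed and the protein's global index. Extending the
# configuration with more proteins therefore never changes the draws of
# existing proteins.
protein_seed <- function(seed, index) {
  as.integer((as.double(seed) + 104729 * as.double(index)) %% 2147483647)
}

#' Generate a synthetic destabilization experiment
#'
#' Each module member's per-step intensity is its log-normal total times the
#' module's release fraction times multiplicative log-normal noise
#' `exp(N(0, sigma^2))` per cell; background proteins draw an individual
#' symmetric Dirichlet(1) release curve. Dropout removes a protein from a
#' whole replicate (all steps `NA`) with the configured probability. With
#' `sigma = 0` and `dropout = 0` every member's cumulative profile equals its
#' module's release CDF exactly, so its EPD to its own consensus is 0. A
#' fixed config and seed reproduce the output bit for bit.
#'
#' @param cfg An `epasis_synth_config` from [synth_config()].
#' @return List of class `epasis_synth` with components `intensities` (long
#'   tibble: `accession`, `replicate`, `step`, `intensity`), `truth` (tibble:
#'   `accession`, `module`, `"background"` for background proteins),
#'   `modules` (curated member table for the true modules) and `config`.
#' @examples
#' sim <- simulate_experiment(synth_config(seed = 42))
#' head(sim$truth)
#' @export
simulate_experiment <- function(cfg) {
  if (!inherits(cfg, "epasis_synth_config")) {
    abort("`cfg` must come from `synth_config()`.")
  }
  release <- purrr::map(seq_len(nrow(cfg$modules)), function(i) {
    module_release_curve(cfg$modules$midpoint[i], cfg$modules$sharpness[i],
                         cfg$n_steps)
  })
  names(release) <- cfg$modules$name
  labels <- c(
    unlist(purrr::map(seq_len(nrow(cfg$modules)), function(i) {
      rep(cfg$modules$name[i], cfg$modules$n_members[i])
    })),
    rep("background", cfg$n_background)
  )
  width <- max(2L, nchar(as.character(length(labels))))
  accession <- sprintf("%s_%0*d", ifelse(labels == "background", "BG", labels),
                       width, stats::ave(seq_along(labels), labels,
                                         FUN = seq_along))
  reps <- sprintf("R%d", seq_len(cfg$n_replicates))
  steps <- factor(cfg$step_labels, levels = cfg$step_labels)

  rows <- purrr::map(seq_along(labels), function(i) {
    set.seed(protein_seed(cfg$seed, i))
    total <- rlnorm(1, cfg$total_log_mean, cfg$total_log_sd)
    frac <- if (labels[i] == "background") {
      g <- rgamma(cfg$n_steps, shape = 1)
      g / sum(g)
    } else {
      release[[labels[i]]]
    }
    per_rep <- purrr::map(seq_len(cfg$n_replicates), function(r) {
      dropped <- runif(1) < cfg$dropout
      noise <- exp(rnorm(cfg$n_steps, 0, cfg$sigma))
      vals <- if (dropped) rep(NA_real_, cfg$n_steps) else
        total * frac * noise
      tibble(replicate = reps[r], step = steps, intensity = vals)
    }) |> purrr::list_rbind()
    dplyr::mutate(per_rep, accession = accession[i], .before = 1L)
  }) |> purrr::list_rbind()

  truth <- tibble(accession = accession, module = labels)
  structure(
    list(
      intensities = rows,
      truth = truth,
      modules = dplyr::filter(truth, .data$module != "background"),
      config = cfg
    ),
    class = "epasis_synth"
  )
}

#' @export
print.epasis_synth <- function(x, ...) {
  cat(sprintf(
    "Synthetic experiment: %d proteins (%s), %d replicates x %d steps, seed %d\n",
    nrow(x$truth),
    paste(sprintf("%s: %d", names(table(x$truth$module)),
                  table(x$truth$module)), collapse = ", "),
    x$config$n_replicates, x$config$n_steps, x$config$seed))
  invisible(x)
}

#' Mask a protein in chosen replicates
#'
#' Applies a targeted dropout pattern: for each requested protein, all steps
#' of `n_drop` replicates (chosen reproducibly from `seed`) are set to
#' missing. Everything else is untouched. Useful for exercising the presence
#' filter at its boundary.
#'
#' @inheritParams presence_filter
#' @param pattern Data frame with columns `accession` and `n_drop`.
#' @param seed Integer seed for the choice of replicates.
#' @return The intensity tibble with the requested cells masked.
#' @export
corrupt_with_missingness <- function(data, pattern, seed = 1L) {
  data <- check_intensity_data(data)
  if (nrow(pattern) == 0L) return(data)
  if (!all(c("accession", "n_drop") %in% names(pattern))) {
    abort("`pattern` must have columns `accession` and `n_drop`.")
  }
  reps <- unique(as.character(data$replicate))
  if (any(pattern$n_drop > length(reps))) {
    abort("Cannot drop a protein in more replicates than exist.")
  }
  set.seed(as.integer(seed))
  for (i in seq_len(nrow(pattern))) {
    drop_reps <- sample(reps, pattern$n_drop[i])
    hit <- data$accession == pattern$accession[i] &
      data$replicate %in% drop_reps
    data$intensity[hit] <- NA_real_
  }
  data
}
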