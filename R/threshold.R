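# Calibration of the EPD assignment threshold by a stepwise
# sensitivity/specificity search over curated module members.

#' Stepwise sensitivity/specificity search for the EPD threshold
#'
#' Positives are curated members scored by their EPD to their own module's
#' consensus; negatives are curated members scored by their EPD to the other
#' module(s). Unlabelled proteins never enter the calibration — their status
#' is what the threshold is later used to infer. Over `n_steps` equally
#' spaced candidate thresholds from 0 to the largest calibration EPD,
#' sensitivity(t) is the fraction of positives with EPD <= t and
#' specificity(t) the fraction of negatives with EPD > t. The operating
#' threshold maximizes Youden's J = sensitivity + specificity - 1, ties
#' resolved toward the smallest threshold.
#'
#' @param epd An `epasis_epd` tibble from [epd_table()].
#' @param modules Curated module table (`module`, `accession`).
#' @param n_steps Number of grid points (default 1000).
#' @return An object of class `epasis_threshold`: list with `grid` (tibble of
#'   threshold, sensitivity, specificity, youden_j), `threshold`,
#'   `n_reference` and `n_candidates` at the selected threshold, `n_positives`,
#'   `n_negatives`.
#' @seealso [assign_modules()], [tidy.epasis_threshold()],
#'   [autoplot.epasis_threshold()]
#' @export
threshold_search <- function(epd, modules, n_steps = 1000L) {
  check_modules(modules)
  if (!is.numeric(n_steps) || n_steps < 2L) {
    abort("`n_steps` must be at least 2.")
  }
  labelled <- dplyr::inner_join(
    epd,
    dplyr::rename(modules[, c("module", "accession")], own_module = "module"),
    by = "accession"
  )
  pos <- labelled$epd[labelled$module == labelled$own_module]
  neg <- labelled$epd[labelled$module != labelled$own_module]
  if (length(pos) == 0L) {
    abort("No positives: no curated member has an EPD to its own module.")
  }
  if (length(neg) == 0L) {
    abort("No negatives: calibration needs members of at least two modules.")
  }
  grid <- seq(0, max(c(pos, neg)), length.out = n_steps)
  sens <- vapply(grid, function(t) mean(pos <= t), numeric(1))
  spec <- vapply(grid, function(t) mean(neg > t), numeric(1))
  j <- sens + spec - 1
  sel <- grid[which.max(j)] # which.max returns the first (smallest) maximum
  asn <- assign_modules(epd, modules, threshold = sel)
  counts <- glance(asn)
  structure(
    list(
      grid = tibble(threshold = grid, sensitivity = sens,
                    specificity = spec, youden_j = j),
      threshold = sel,
      sensitivity = sens[which.max(j)],
      specificity = spec[which.max(j)],
      n_reference = counts$n_reference,
      n_candidates = counts$n_candidate,
      n_positives = length(pos),
      n_negatives = length(neg),
      n_steps = as.integer(n_steps)
    ),
    class = "epasis_threshold"
  )
}

#' @export
print.epasis_threshold <- function(x, ...) {
  cat(sprintf(
    "EPD threshold search (%d grid points, %d positives / %d negatives)\n",
    x$n_steps, x$n_positives, x$n_negatives))
  cat(sprintf(
    "Selected threshold %.4g (sensitivity %.3f, specificity %.3f)\n",
    x$threshold, x$sensitivity, x$specificity))
  cat(sprintf("At this threshold: %d reference, %d candidate protein(s)\n",
              x$n_reference, x$n_candidates))
  invisible(x)
}

#' Tidy the threshold-search grid
#'
#' @param x An `epasis_threshold` object.
#' @param ... Unused.
#' @return Tibble with one row per candidate threshold: `threshold`,
#'   `sensitivity`, `specificity`, `youden_j`.
#' @method tidy epasis_threshold
#' @export
tidy.epasis_threshold <- function(x, ...) x$grid

#' One-row summary of a threshold search
#'
#' @param x An `epasis_threshold` object.
#' @param ... Unused.
#' @return One-row tibble: selected threshold, sensitivity and specificity at
#'   the threshold, reference/candidate counts, calibration sizes.
#' @method glance epasis_threshold
#' @export
glance.epasis_threshold <- function(x, ...) {
  tibble(
    threshold = x$threshold, sensitivity = x$sensitivity,
    specificity = x$specificity, n_reference = x$n_reference,
    n_candidates = x$n_candidates, n_positives = x$n_positives,
    n_negatives = x$n_negatives, n_steps = x$n_steps
  )
}

#' Plot sensitivity/specificity against the candidate threshold
#'
#' @param object An `epasis_threshold` object.
#' @param ... Unused.
#' @return A ggplot object with both operating curves and the selected
#'   threshold marked.
#' @method autoplot epasis_threshold
#' @export
autoplot.epasis_threshold <- function(object, ...) {
  df <- tidyr::pivot_longer(object$grid, c("sensitivity", "specificity"),
                            names_to = "measure", values_to = "value")
  ggplot(df, aes(x = .data$threshold, y = .data$value,
                 colour = .data$measure)) +
    geom_line() +
    geom_vline(xintercept = object$threshold, linetype = "dashed",
               colour = "grey40") +
    scale_colour_manual(values = c(sensitivity = "#2166ac",
                                   specificity = "black")) +
    labs(x = "EPD threshold", y = "Proportion", colour = NULL) +
    theme_minimal()
}
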