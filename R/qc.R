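# Replicate reproducibility statistics: per-pair Pearson correlation with
# Fisher-z confidence intervals and orthogonal regression on log2 protein
# intensities, plus a Spearman correlation matrix across elution steps.

#' Replicate and step reproducibility statistics
#'
#' Per-protein intensities are summed across elution steps within each
#' replicate; for every replicate pair, Pearson's r with a Fisher-z 95%
#' confidence interval and an orthogonal (total-least-squares) regression are
#' computed on the log2 intensities of proteins quantified (positive) in both
#' replicates. Step-level reproducibility is the Spearman correlation matrix
#' of per-step log2 intensities (summed across replicates), computed on
#' pairwise-complete positive values. Pairs with fewer than 3 shared proteins
#' are reported with `NA` statistics.
#'
#' @inheritParams presence_filter
#' @param conf_level Confidence level for the Pearson interval (default 0.95).
#' @return An object of class `epasis_qc`: list with `replicate_pairs`
#'   (tibble: `replicate_a`, `replicate_b`, `n_shared`, `pearson_r`,
#'   `ci_lower`, `ci_upper`, `slope`, `intercept`) and `step_correlations`
#'   (tibble: `step_a`, `step_b`, `spearman_rho`).
#' @export
replicate_qc <- function(data, conf_level = 0.95) {
  data <- check_intensity_data(data)
  reps <- sort(unique(as.character(data$replicate)))
  if (length(reps) < 2L) abort("At least two replicates are required.")

  totals <- data |>
    dplyr::summarise(total = sum(.data$intensity, na.rm = TRUE),
                     .by = c("accession", "replicate")) |>
    dplyr::filter(.data$total > 0) |>
    dplyr::mutate(log2_total = log2(.data$total))

  pairs <- tidyr::expand_grid(replicate_a = reps, replicate_b = reps) |>
    dplyr::filter(.data$replicate_a < .data$replicate_b)
  pair_stats <- purrr::map(seq_len(nrow(pairs)), function(i) {
    a <- totals[totals$replicate == pairs$replicate_a[i], ]
    b <- totals[totals$replicate == pairs$replicate_b[i], ]
    shared <- dplyr::inner_join(a, b, by = "accession",
                                suffix = c("_a", "_b"))
    if (nrow(shared) < 3L) {
      return(tibble(n_shared = nrow(shared), pearson_r = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    slope = NA_real_, intercept = NA_real_))
    }
    ct <- cor.test(shared$log2_total_a, shared$log2_total_b,
                   conf.level = conf_level)
    tls <- orthogonal_regression(shared$log2_total_a, shared$log2_total_b)
    tibble(n_shared = nrow(shared), pearson_r = unname(ct$estimate),
           ci_lower = ct$conf.int[1], ci_upper = ct$conf.int[2],
           slope = tls$slope, intercept = tls$intercept)
  }) |> purrr::list_rbind()
  replicate_pairs <- dplyr::bind_cols(pairs, pair_stats)

  step_sums <- data |>
    dplyr::summarise(total = sum(.data$intensity, na.rm = TRUE),
                     .by = c("accession", "step")) |>
    dplyr::mutate(log2_total = ifelse(.data$total > 0, log2(.data$total),
                                      NA_real_)) |>
    dplyr::select("accession", "step", "log2_total") |>
    tidyr::pivot_wider(names_from = "step", values_from = "log2_total")
  rho <- suppressWarnings(
    cor(as.matrix(step_sums[, -1, drop = FALSE]),
        method = "spearman", use = "pairwise.complete.obs"))
  step_correlations <- as_tibble(rho, rownames = "step_a") |>
    tidyr::pivot_longer(-"step_a", names_to = "step_b",
                        values_to = "spearman_rho")

  structure(list(replicate_pairs = replicate_pairs,
                 step_correlations = step_correlations,
                 conf_level = conf_level),
            class = "epasis_qc")
}

# Total-least-squares line through a 2-D point cloud: the first principal
# axis of the centred data; minimizes perpendicular residuals.
orthogonal_regression <- function(x, y) {
  cx <- x - mean(x)
  cy <- y - mean(y)
  cv <- cbind(cx, cy)
  e <- eigen(crossprod(cv) / (length(x) - 1), symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (abs(v[1L]) < .Machine$double.eps) {
    abort("Orthogonal regression undefined: no variance along x.")
  }
  slope <- v[2L] / v[1L]
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' @export
print.epasis_qc <- function(x, ...) {
  cat(sprintf("Replicate QC: %d replicate pairs, %d elution steps\n",
              nrow(x$replicate_pairs),
              dplyr::n_distinct(x$step_correlations$step_a)))
  print(x$replicate_pairs)
  invisible(x)
}

#' Tidy replicate QC statistics
#'
#' @param x An `epasis_qc` object.
#' @param ... Unused.
#' @return The per-replicate-pair statistics tibble.
#' @method tidy epasis_qc
#' @export
tidy.epasis_qc <- function(x, ...) x$replicate_pairs

#' Summary of replicate QC
#'
#' @param x An `epasis_qc` object.
#' @param ... Unused.
#' @return One-row tibble with the range of pairwise Pearson r and the
#'   minimum step-level Spearman rho.
#' @method glance epasis_qc
#' @export
glance.epasis_qc <- function(x, ...) {
  off_diag <- x$step_correlations$spearman_rho[
    x$step_correlations$step_a != x$step_correlations$step_b]
  tibble(
    n_pairs = nrow(x$replicate_pairs),
    min_pearson_r = min(x$replicate_pairs$pearson_r, na.rm = TRUE),
    max_pearson_r = max(x$replicate_pairs$pearson_r, na.rm = TRUE),
    min_step_rho = min(off_diag, na.rm = TRUE)
  )
}

#' Heatmap of step-level Spearman correlations
#'
#' @param object An `epasis_qc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epasis_qc
#' @export
autoplot.epasis_qc <- function(object, ...) {
  ggplot(object$step_correlations,
         aes(x = .data$step_a, y = .data$step_b,
             fill = .data$spearman_rho)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0, limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Spearman rho") +
    theme_minimal()
}
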