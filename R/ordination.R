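# Nonmetric multidimensional scaling of elution-profile distances.

#' Pairwise elution-profile distance matrix
#'
#' All pairwise distances between averaged elution profiles, using the same
#' metric as [compute_epd()].
#'
#' @param profiles An `epasis_profiles` tibble with at least two proteins.
#' @param normalized Use the normalized EPD dialect.
#' @return A [stats::dist] object labelled by accession.
#' @export
profile_distance_matrix <- function(profiles, normalized = FALSE) {
  m <- profiles_matrix(profiles)
  if (nrow(m) < 2L) {
    abort("At least two profiles are required for a distance matrix.")
  }
  d <- dist(m, method = "euclidean")
  if (normalized) d <- d / sqrt(ncol(m))
  d
}

#' NMDS ordination of a profile distance matrix
#'
#' Nonmetric multidimensional scaling (global model, Kruskal stress-1 with
#' primary tie handling) via [vegan::monoMDS()]. The configuration with the
#' lowest stress over one metric (principal-coordinate) start and
#' `n_restarts - 1` random starts is returned; all restarts are seeded
#' deterministically from `seed`, so results are reproducible for a fixed
#' `(seed, n_restarts)`.
#'
#' @param d A [stats::dist] object, e.g. from [profile_distance_matrix()].
#' @param dims Number of embedding dimensions (default 2).
#' @param seed Integer seed controlling the random starts.
#' @param n_restarts Number of starting configurations (default 8).
#' @return An object of class `epasis_ordination`: list with `points` (tibble
#'   of `accession` and `axis1..axisK` coordinates), `stress`, `dims`,
#'   `seed`, `n_restarts`.
#' @export
nmds_ordination <- function(d, dims = 2L, seed = 1L, n_restarts = 8L) {
  if (!inherits(d, "dist")) abort("`d` must be a `dist` object.")
  if (dims < 1L) abort("`dims` must be at least 1.")
  if (all(d == 0)) {
    abort("Degenerate distance matrix: all pairwise distances are zero.")
  }
  n <- attr(d, "Size")
  if (n < dims + 1L) {
    abort("Too few points for the requested number of dimensions.")
  }
  starts <- vector("list", n_restarts)
  starts[[1L]] <- suppressWarnings(cmdscale(d, k = dims))
  if (ncol(starts[[1L]]) < dims) { # degenerate PCoA, pad with zeros
    starts[[1L]] <- cbind(starts[[1L]],
                          matrix(0, n, dims - ncol(starts[[1L]])))
  }
  if (n_restarts > 1L) {
    withr_seed <- seed
    set.seed(withr_seed)
    for (i in 2:n_restarts) {
      starts[[i]] <- matrix(rnorm(n * dims), n, dims)
    }
  }
  fits <- purrr::map(starts, function(y) {
    vegan::monoMDS(d, y = y, k = dims, model = "global", maxit = 500)
  })
  best <- which.min(purrr::map_dbl(fits, "stress"))
  fit <- fits[[best]]
  pts <- as_tibble(fit$points, .name_repair = ~ paste0("axis", seq_along(.x)))
  pts <- dplyr::mutate(pts, accession = labels(d), .before = 1L)
  structure(
    list(points = pts, stress = fit$stress, dims = as.integer(dims),
         seed = as.integer(seed), n_restarts = as.integer(n_restarts),
         best_start = best),
    class = "epasis_ordination"
  )
}

#' @export
print.epasis_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d points in %d dimensions, stress %.4f\n",
              nrow(x$points), x$dims, x$stress))
  invisible(x)
}

#' Tidy NMDS coordinates
#'
#' @param x An `epasis_ordination` object.
#' @param ... Unused.
#' @return Tibble of per-protein embedding coordinates.
#' @method tidy epasis_ordination
#' @export
tidy.epasis_ordination <- function(x, ...) x$points

#' One-row NMDS summary
#'
#' @param x An `epasis_ordination` object.
#' @param ... Unused.
#' @return One-row tibble with stress, dimensions and restart settings.
#' @method glance epasis_ordination
#' @export
glance.epasis_ordination <- function(x, ...) {
  tibble(stress = x$stress, dims = x$dims, n_points = nrow(x$points),
         n_restarts = x$n_restarts, seed = x$seed)
}

#' Plot an NMDS ordination
#'
#' @param object An `epasis_ordination` object.
#' @param labels Optional data frame (`accession`, `module`) to colour points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epasis_ordination
#' @export
autoplot.epasis_ordination <- function(object, labels = NULL, ...) {
  df <- object$points
  if (!is.null(labels)) {
    df <- dplyr::left_join(df, labels[, c("accession", "module")],
                           by = "accession") |>
      dplyr::mutate(module = dplyr::coalesce(.data$module, "unassigned"))
  }
  p <- ggplot(df, aes(x = .data$axis1, y = .data$axis2)) +
    labs(x = "NMDS1", y = "NMDS2",
         subtitle = sprintf("stress %.3f", object$stress)) +
    theme_minimal()
  if (is.null(labels)) p + geom_point() else
    p + geom_point(aes(colour = .data$module))
}
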