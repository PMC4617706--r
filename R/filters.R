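# Affinity-purification evidence filters and the significance-A outlier
# statistic for SILAC log-ratios.

check_evidence <- function(evidence, call = rlang::caller_env()) {
  needed <- c("accession", "run", "run_class", "unique_peptides")
  if (!is.data.frame(evidence) || !all(needed %in% names(evidence))) {
    abort(paste0("`evidence` must have columns: ",
                 paste(needed, collapse = ", "), "."), call = call)
  }
  if (!all(evidence$run_class %in% c("bait", "control"))) {
    abort('`run_class` must be "bait" or "control".', call = call)
  }
  if (any(evidence$unique_peptides < 0)) {
    abort("`unique_peptides` must be nonnegative integers.", call = call)
  }
  evidence
}

#' Bait/control replicate filter for pull-down evidence
#'
#' Retains proteins detected in at least `min_bait_runs` bait runs and in at
#' most `max_control_runs` control runs. The defaults encode the rule used
#' for GST pull-downs from retinal extracts: proteins found in fewer than 3
#' of 4 bait experiments, or in any control experiment, are removed. A
#' protein counts as detected in a run when it appears there with at least
#' one unique peptide (or when a logical `detected` column says so).
#'
#' @param evidence Data frame with columns `accession`, `run`, `run_class`
#'   (`"bait"` or `"control"`) and `unique_peptides`; an optional logical
#'   `detected` column overrides the peptide-based detection call.
#' @param min_bait_runs Minimum number of bait runs with detection
#'   (default 3).
#' @param max_control_runs Maximum tolerated control runs with detection
#'   (default 0: any control detection removes the protein).
#' @return Tibble of retained proteins ordered by accession, with columns
#'   `accession`, `n_bait_runs`, `n_control_runs`.
#' @export
pulldown_filter <- function(evidence, min_bait_runs = 3L,
                            max_control_runs = 0L) {
  evidence <- check_evidence(evidence)
  n_bait <- dplyr::n_distinct(evidence$run[evidence$run_class == "bait"])
  if (n_bait < 1L) abort("At least one bait run is required.")
  if (min_bait_runs > n_bait) {
    abort(sprintf("`min_bait_runs` (%d) exceeds the number of bait runs (%d).",
                  min_bait_runs, n_bait))
  }
  detected <- if ("detected" %in% names(evidence)) evidence$detected else
    evidence$unique_peptides >= 1L
  evidence |>
    dplyr::mutate(detected = detected) |>
    dplyr::filter(.data$detected) |>
    dplyr::summarise(
      n_bait_runs = dplyr::n_distinct(.data$run[.data$run_class == "bait"]),
      n_control_runs = dplyr::n_distinct(.data$run[.data$run_class == "control"]),
      .by = "accession"
    ) |>
    dplyr::filter(.data$n_bait_runs >= min_bait_runs,
                  .data$n_control_runs <= max_control_runs) |>
    dplyr::arrange(.data$accession) |>
    as_tibble()
}

#' Unique-peptide acceptance rule
#'
#' Accepts a protein identification in a run only when it is supported by at
#' least `min_peptides` unique peptides (default 2, the conventional
#' two-peptide rule for quantified proteins).
#'
#' @inheritParams pulldown_filter
#' @param min_peptides Minimum unique peptides per run (default 2).
#' @return Tibble of accepted (accession, run) rows with their peptide
#'   counts, ordered by accession then run.
#' @export
two_peptide_rule <- function(evidence, min_peptides = 2L) {
  evidence <- check_evidence(evidence)
  if (min_peptides < 1L) abort("`min_peptides` must be at least 1.")
  evidence |>
    dplyr::filter(.data$unique_peptides >= min_peptides) |>
    dplyr::select("accession", "run", "run_class", "unique_peptides") |>
    dplyr::arrange(.data$accession, .data$run) |>
    as_tibble()
}

#' Significance A: robust outlier p-values for log-ratios
#'
#' Detects proteins whose (log) abundance ratio is an outlier relative to the
#' bulk of the ratio distribution. The spread on each side of the median is
#' estimated robustly from the 15.87th and 84.13th percentiles (the points
#' one standard deviation from the mean in a normal distribution), giving an
#' asymmetric robust z-score
#' \deqn{z = (r - P_{50}) / (P_{84.13} - P_{50})}{z = (r - P50)/(P84.13 - P50)}
#' above the median and the mirrored form below. The p-value is the outward
#' normal tail probability \eqn{p = 0.5\,\mathrm{erfc}(z/\sqrt{2})}; with
#' `tail = "two.sided"` it is doubled (capped at 1), which makes p uniform on
#' (0, 1) for ratios drawn from the null.
#'
#' @param ratios Numeric vector of log2 ratios, or a data frame with columns
#'   `accession` and `log2_ratio`. At least 5 finite ratios are required.
#' @param tail `"one.sided"` (default; outward tail, p in (0, 0.5]) or
#'   `"two.sided"`.
#' @param adjust Add a Benjamini-Hochberg adjusted column `p_adj`?
#' @return Tibble with columns `log2_ratio`, `z`, `p` (and `accession`,
#'   `p_adj` when available), in input order.
#' @examples
#' significance_a(c(-2, -1, 0, 1, 2, 10))
#' @export
significance_a <- function(ratios, tail = c("one.sided", "two.sided"),
                           adjust = FALSE) {
  tail <- match.arg(tail)
  acc <- NULL
  if (is.data.frame(ratios)) {
    if (!all(c("accession", "log2_ratio") %in% names(ratios))) {
      abort("A data-frame input needs columns `accession` and `log2_ratio`.")
    }
    acc <- ratios$accession
    ratios <- ratios$log2_ratio
  }
  if (!is.numeric(ratios)) abort("`ratios` must be numeric log2 ratios.")
  finite <- is.finite(ratios)
  if (sum(finite) < 5L) {
    abort("At least 5 finite ratios are required to estimate the percentiles.")
  }
  q <- quantile(ratios[finite], c(0.1587, 0.5, 0.8413), names = FALSE)
  spread_lo <- q[2] - q[1]
  spread_hi <- q[3] - q[2]
  if (spread_lo <= 0 || spread_hi <= 0) {
    abort("Degenerate ratio spread: a percentile coincides with the median.")
  }
  z <- ifelse(ratios >= q[2],
              (ratios - q[2]) / spread_hi,
              (q[2] - ratios) / spread_lo)
  p <- pnorm(z, lower.tail = FALSE) # = 0.5 * erfc(z / sqrt(2))
  if (tail == "two.sided") p <- pmin(1, 2 * p)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  p[!finite] <- NA_real_
  z[!finite] <- NA_real_
  out <- tibble(log2_ratio = ratios, z = z, p = p)
  if (!is.null(acc)) out <- dplyr::mutate(out, accession = acc, .before = 1L)
  if (adjust) out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
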