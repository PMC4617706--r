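# Small in-code fixtures shared across tests.

# Long intensity tibble from a named list of replicate matrices
# (proteins x steps); NA = missing cell.
make_intensities <- function(mats, steps = paste0("S", seq_len(ncol(mats[[1]])))) {
  purrr::imap(mats, function(m, rep_id) {
    tibble::tibble(
      accession = rep(rownames(m), each = ncol(m)),
      replicate = rep_id,
      step = factor(rep(steps, nrow(m)), levels = steps),
      intensity = as.vector(t(m))
    )
  }) |> purrr::list_rbind()
}

# Profiles object straight from a proteins x steps matrix of cumulative values
make_profiles <- function(m, steps = paste0("S", seq_len(ncol(m)))) {
  reps <- list(A = m) # single "replicate" already in profile units: feed
  # through elution_profiles by converting cumulative back to per-step mass
  masses <- t(apply(m, 1L, function(p) diff(c(0, p))))
  rownames(masses) <- rownames(m)
  elution_profiles(make_intensities(list(R1 = masses), steps))
}

# Random monotone cumulative profile ending at 1
random_profile <- function(n_steps = 5L) {
  w <- runif(n_steps)
  cumsum(w) / sum(w)
}

# EPD tibble built by hand
make_epd <- function(df) {
  structure(tibble::as_tibble(df), normalized = FALSE,
            class = c("epasis_epd", class(tibble::tibble())))
}

# Accuracy of the full assignment pipeline on one synthetic experiment
synth_accuracy <- function(seed, sigma = 0.2, dropout = 0.1, n_steps = 200L) {
  sim <- simulate_experiment(synth_config(seed = seed, sigma = sigma,
                                          dropout = dropout))
  profiles <- sim$intensities |> presence_filter() |> elution_profiles()
  consensus <- suppressWarnings(consensus_profiles(profiles, sim$modules))
  epd <- epd_table(profiles, consensus, modules = sim$modules)
  search <- threshold_search(epd, sim$modules, n_steps = n_steps)
  asn <- assign_modules(epd, sim$modules, search$threshold)
  assignment_accuracy(asn, sim$truth)
}
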