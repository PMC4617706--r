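# Consensus construction, EPD scoring, threshold calibration and module
# assignment.

test_that("consensus is the unweighted mean of member profiles", {
  m <- rbind(A = c(0, 1), B = c(1, 1), C = c(0.5, 1))
  prof <- make_profiles(m, steps = c("S1", "S2"))
  cons <- build_consensus(prof, c("A", "B"), "MOD")
  expect_equal(cons$cumulative, c(0.5, 1))
  expect_equal(build_consensus(prof, "C", "MOD")$cumulative, c(0.5, 1))
  expect_error(build_consensus(prof, character(0), "MOD"), "empty")
  expect_warning(build_consensus(prof, c("A", "ZZZ"), "MOD"), "ZZZ")
  expect_error(build_consensus(prof, "ZZZ", "MOD"), "No member")
})

test_that("compute_epd matches hand arithmetic and supports both dialects", {
  expect_equal(compute_epd(c(0, 1), c(0, 1)), 0)
  expect_equal(compute_epd(c(0, 1), c(1, 1)), 1)
  expect_equal(compute_epd(c(0, 1), c(1, 1), normalized = TRUE), 1 / sqrt(2))
  expect_error(compute_epd(c(0, 1), c(0, 0.5, 1)), "same step axis")
})

test_that("EPD satisfies the metric axioms on random profile triples", {
  set.seed(23)
  for (i in 1:100) {
    p <- random_profile()
    q <- random_profile()
    r <- random_profile()
    expect_gte(compute_epd(p, q), 0)
    expect_equal(compute_epd(p, p), 0)
    expect_equal(compute_epd(p, q), compute_epd(q, p))
    expect_lte(compute_epd(p, r),
               compute_epd(p, q) + compute_epd(q, r) + 1e-12)
  }
})

test_that("epd_table equals entry-wise compute_epd and breaks ties lexicographically", {
  m <- rbind(P1 = c(0, 0.5, 1), P2 = c(0.5, 1, 1), P3 = c(0.25, 0.75, 1))
  prof <- make_profiles(m, steps = c("S1", "S2", "S3"))
  modules <- tibble::tibble(module = c("A", "B"), accession = c("P1", "P2"))
  cons <- consensus_profiles(prof, modules)
  epd <- epd_table(prof, cons)
  # entry-wise oracle
  cons_m <- split(cons$cumulative, cons$module)
  for (i in seq_len(nrow(epd))) {
    expect_equal(epd$epd[i],
                 compute_epd(m[epd$accession[i], ],
                             cons_m[[epd$module[i]]]))
  }
  # P3 is exactly midway between the two consensus profiles
  expect_equal(epd$epd[epd$accession == "P3" & epd$module == "A"],
               epd$epd[epd$accession == "P3" & epd$module == "B"])
  expect_equal(epd_nearest(epd)$nearest_module[3], "A")
  # a protein equal to a consensus has EPD zero to it
  expect_equal(epd$epd[epd$accession == "P1" & epd$module == "A"], 0)
})

test_that("leave-one-out consensus excludes the scored member", {
  m <- rbind(P1 = c(0, 1), P2 = c(1, 1), Q1 = c(0.5, 1), Q2 = c(0.25, 1))
  prof <- make_profiles(m, steps = c("S1", "S2"))
  modules <- tibble::tibble(module = c("A", "A", "B", "B"),
                            accession = c("P1", "P2", "Q1", "Q2"))
  cons <- consensus_profiles(prof, modules)
  loo <- epd_table(prof, cons, leave_one_out = TRUE, modules = modules)
  # P1 scored against consensus of {P2} alone
  expect_equal(loo$epd[loo$accession == "P1" & loo$module == "A"],
               compute_epd(c(0, 1), c(1, 1)))
  # non-members still use the full consensus
  full <- epd_table(prof, cons)
  expect_equal(loo$epd[loo$accession == "Q1" & loo$module == "A"],
               full$epd[full$accession == "Q1" & full$module == "A"])
  expect_error(epd_table(prof, cons, leave_one_out = TRUE), "modules")
})

test_that("threshold search finds the separating interval on clean data", {
  # members within 0.01 of their own module, 0.5+ away from the other
  modules <- tibble::tibble(module = rep(c("A", "B"), each = 3),
                            accession = c("a1", "a2", "a3", "b1", "b2", "b3"))
  epd <- make_epd(tidyr::expand_grid(
    accession = modules$accession, module = c("A", "B"))) |>
    dplyr::mutate(epd = ifelse(
      substr(accession, 1, 1) == tolower(module),
      c(0.002, 0.005, 0.01)[as.integer(substr(accession, 2, 2))],
      0.5 + 0.1 * as.integer(substr(accession, 2, 2))))
  epd <- make_epd(epd)
  res <- threshold_search(epd, modules, n_steps = 500)
  grid <- tidy(res)
  inside <- grid$threshold > 0.01 & grid$threshold < 0.5
  expect_true(all(grid$sensitivity[inside] == 1))
  expect_true(all(grid$specificity[inside] == 1))
  # direct-counting oracle at a handful of grid points
  pos <- c(0.002, 0.005, 0.01)
  neg <- c(0.6, 0.7, 0.8)
  for (t in grid$threshold[c(1, 100, 250, 400, 500)]) {
    expect_equal(grid$sensitivity[grid$threshold == t],
                 sum(pos <= t) / 6 * 2) # each member scored once vs own module
    expect_equal(grid$specificity[grid$threshold == t],
                 sum(neg > t) / 6 * 2)
  }
  # selected threshold sits at the near edge of the separating interval
  expect_gte(res$threshold, 0.01)
  expect_lt(res$threshold, 0.5)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
})

test_that("sensitivity is non-decreasing and specificity non-increasing on the grid", {
  sim <- simulate_experiment(synth_config(seed = 31, sigma = 0.6))
  prof <- sim$intensities |> presence_filter() |> elution_profiles()
  cons <- suppressWarnings(consensus_profiles(prof, sim$modules))
  epd <- epd_table(prof, cons)
  grid <- tidy(threshold_search(epd, sim$modules, n_steps = 1000))
  expect_true(all(diff(grid$sensitivity) >= 0))
  expect_true(all(diff(grid$specificity) <= 0))
})

test_that("threshold search requires both positives and negatives", {
  modules_one <- tibble::tibble(module = "A", accession = c("a1", "a2"))
  epd <- make_epd(tibble::tibble(accession = c("a1", "a2"),
                                 module = "A", epd = c(0, 0.1)))
  expect_error(threshold_search(epd, modules_one, 100), "[Nn]egatives")
  epd_empty <- make_epd(tibble::tibble(accession = "x1", module = "A",
                                       epd = 0.2))
  expect_error(threshold_search(epd_empty, modules_one, 100), "[Pp]ositives")
})

test_that("assignment respects thresholds, membership and boundary cases", {
  modules <- tibble::tibble(module = c("A", "B"), accession = c("a1", "b1"))
  epd <- make_epd(tibble::tibble(
    accession = rep(c("a1", "b1", "x1", "x2"), each = 2),
    module = rep(c("A", "B"), 4),
    epd = c(0.01, 0.9,   # a1: good member of A
            0.8, 0.02,   # b1: good member of B
            0.03, 0.7,   # x1: near A
            0.4, 0.5)))  # x2: near nothing
  asn <- assign_modules(epd, modules, threshold = 0.05)
  expect_equal(asn$category[asn$accession == "a1"], "A")
  expect_equal(asn$category[asn$accession == "b1"], "B")
  expect_equal(asn$category[asn$accession == "x1"], "A_cand")
  expect_equal(asn$category[asn$accession == "x2"], "unknown")
  expect_equal(glance(asn)$n_reference, 2)
  expect_equal(glance(asn)$n_candidate, 1)
  # threshold 0: only exact-zero EPDs assigned
  asn0 <- assign_modules(epd, modules, threshold = 0)
  expect_true(all(asn0$category == "unknown"))
  # threshold = max EPD: nothing unknown
  asn_max <- assign_modules(epd, modules, threshold = max(epd$epd))
  expect_true(all(asn_max$category != "unknown"))
})

test_that("raising the threshold never moves a protein from assigned to unknown", {
  sim <- simulate_experiment(synth_config(seed = 41, sigma = 0.5))
  prof <- sim$intensities |> presence_filter() |> elution_profiles()
  cons <- suppressWarnings(consensus_profiles(prof, sim$modules))
  epd <- epd_table(prof, cons)
  thresholds <- seq(0, max(epd$epd), length.out = 12)
  prev_assigned <- character(0)
  for (t in thresholds) {
    asn <- assign_modules(epd, sim$modules, t)
    assigned <- asn$accession[asn$category != "unknown"]
    expect_true(all(prev_assigned %in% assigned))
    prev_assigned <- assigned
  }
})

test_that("curated label governs a member sitting on another module's consensus", {
  # member a2 of module A placed exactly on B's consensus
  m <- rbind(a1 = c(0, 0.2, 1), a2 = c(0.8, 1, 1),
             b1 = c(0.8, 1, 1), b2 = c(0.8, 1, 1))
  prof <- make_profiles(m, steps = c("S1", "S2", "S3"))
  modules <- tibble::tibble(module = c("A", "A", "B", "B"),
                            accession = c("a1", "a2", "b1", "b2"))
  cons <- consensus_profiles(prof, modules)
  epd <- epd_table(prof, cons)
  near <- epd_nearest(epd)
  expect_equal(near$nearest_module[near$accession == "a2"], "B")
  d_own <- epd$epd[epd$accession == "a2" & epd$module == "A"]
  # below threshold on its own module: stays an A reference member
  asn_hi <- assign_modules(epd, modules, threshold = d_own + 1e-6)
  expect_equal(asn_hi$category[asn_hi$accession == "a2"], "A")
  # above threshold on its own module: unknown, never a B candidate
  asn_lo <- assign_modules(epd, modules, threshold = d_own / 2)
  expect_equal(asn_lo$category[asn_lo$accession == "a2"], "unknown")
})

test_that("noise-free synthetic recovery is exact, degraded noise stays above chance", {
  sim <- simulate_experiment(synth_config(seed = 3, sigma = 0, dropout = 0))
  prof <- sim$intensities |> presence_filter() |> elution_profiles()
  cons <- consensus_profiles(prof, sim$modules)
  epd <- epd_table(prof, cons)
  own <- dplyr::inner_join(epd, dplyr::rename(sim$modules, own = "module"),
                           by = "accession")
  expect_equal(max(own$epd[own$module == own$own]), 0, tolerance = 1e-12)
  expect_equal(synth_accuracy(3, sigma = 0, dropout = 0), 1.0)
  acc_noisy <- synth_accuracy(3, sigma = 0.8)
  chance <- 20 / 40 # majority class (background) rate
  expect_gt(acc_noisy, chance)
})
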