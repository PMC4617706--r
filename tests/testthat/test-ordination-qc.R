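# NMDS ordination and replicate-reproducibility statistics.

test_that("profile distance matrix matches entry-wise EPD", {
  sim <- simulate_experiment(synth_config(seed = 13))
  prof <- sim$intensities |> presence_filter() |> elution_profiles()
  d <- profile_distance_matrix(prof)
  dm <- as.matrix(d)
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
  pm <- t(sapply(split(prof$cumulative[order(prof$accession, prof$step)],
                       sort(prof$accession)), identity))
  set.seed(1)
  idx <- sample(nrow(dm), 5)
  for (i in idx) for (j in idx) {
    expect_equal(dm[i, j],
                 compute_epd(pm[rownames(dm)[i], ], pm[rownames(dm)[j], ]))
  }
  one <- make_profiles(rbind(P1 = c(0.5, 1)), steps = c("S1", "S2"))
  expect_error(profile_distance_matrix(one), "two profiles")
})

test_that("identical profiles give zero distance", {
  m <- rbind(A = c(0.3, 0.6, 1), B = c(0.3, 0.6, 1), C = c(0, 0.5, 1))
  d <- as.matrix(profile_distance_matrix(
    make_profiles(m, steps = c("S1", "S2", "S3"))))
  expect_equal(d["A", "B"], 0)
  expect_gt(d["A", "C"], 0)
})

test_that("NMDS recovers perfectly embeddable configurations with near-zero stress", {
  set.seed(17)
  pts <- matrix(rnorm(30 * 2), 30, 2)
  rownames(pts) <- sprintf("P%02d", 1:30)
  d <- dist(pts)
  ord <- nmds_ordination(d, dims = 2, seed = 1, n_restarts = 4)
  expect_lt(ord$stress, 1e-3)
  # independent stress-1 oracle from the returned coordinates: monotone
  # (isotonic) regression of configuration distances on observed ranks
  dhat <- dist(as.matrix(ord$points[, c("axis1", "axis2")]))
  ord_d <- order(as.vector(d))
  fit <- stats::isoreg(as.vector(d)[ord_d], as.vector(dhat)[ord_d])
  stress1 <- sqrt(sum((fit$y - fit$yf)^2) / sum(fit$y^2))
  expect_lt(stress1, 1e-3)
})

test_that("collinear points embed in one dimension with near-zero stress", {
  pts <- cbind(c(0, 1, 3, 7))
  rownames(pts) <- paste0("P", 1:4)
  ord <- nmds_ordination(dist(pts), dims = 1, seed = 2, n_restarts = 4)
  expect_lt(ord$stress, 1e-3)
})

test_that("NMDS is deterministic for fixed seed and stress non-increasing in dims", {
  sim <- simulate_experiment(synth_config(seed = 19))
  prof <- sim$intensities |> presence_filter() |> elution_profiles()
  d <- profile_distance_matrix(prof)
  o1 <- nmds_ordination(d, dims = 2, seed = 3, n_restarts = 4)
  o2 <- nmds_ordination(d, dims = 2, seed = 3, n_restarts = 4)
  expect_identical(o1$points, o2$points)
  expect_identical(o1$stress, o2$stress)
  s <- sapply(1:3, function(k)
    nmds_ordination(d, dims = k, seed = 3, n_restarts = 4)$stress)
  expect_true(all(diff(s) <= 1e-8))
})

test_that("stress is invariant under relabeling of proteins", {
  set.seed(29)
  pts <- matrix(rnorm(15 * 3), 15, 3)
  rownames(pts) <- sprintf("P%02d", 1:15)
  d <- dist(pts)
  perm <- sample(15)
  d_perm <- dist(pts[perm, ])
  s1 <- nmds_ordination(d, dims = 2, seed = 4, n_restarts = 6)$stress
  s2 <- nmds_ordination(d_perm, dims = 2, seed = 4, n_restarts = 6)$stress
  expect_equal(s1, s2, tolerance = 1e-4)
})

test_that("degenerate distance matrices are rejected", {
  d0 <- dist(matrix(1, 4, 2))
  expect_error(nmds_ordination(d0), "[Dd]egenerate")
})

test_that("replicate QC recovers exact copy and scale relations", {
  set.seed(37)
  base <- matrix(rlnorm(20 * 5, 10, 1), 20, 5,
                 dimnames = list(sprintf("P%02d", 1:20), NULL))
  data <- make_intensities(list(R1 = base, R2 = base, R3 = base * 4))
  qc <- replicate_qc(data)
  pairs <- tidy(qc)
  copy <- pairs[pairs$replicate_a == "R1" & pairs$replicate_b == "R2", ]
  expect_equal(copy$pearson_r, 1, tolerance = 1e-12)
  expect_equal(copy$slope, 1, tolerance = 1e-9)
  expect_equal(copy$intercept, 0, tolerance = 1e-9)
  scaled <- pairs[pairs$replicate_a == "R1" & pairs$replicate_b == "R3", ]
  expect_equal(scaled$pearson_r, 1, tolerance = 1e-12)
  expect_equal(scaled$slope, 1, tolerance = 1e-9)
  expect_equal(scaled$intercept, 2, tolerance = 1e-9) # log2(4)
  expect_true(all(pairs$ci_lower <= pairs$pearson_r &
                    pairs$pearson_r <= pairs$ci_upper))
})

test_that("step-level Spearman correlation is 1 under monotone transforms", {
  set.seed(41)
  x <- rlnorm(25, 8, 1)
  base <- cbind(x, x^1.7, exp(log(x) + 2), sqrt(x), x * 3)
  rownames(base) <- sprintf("P%02d", 1:25)
  qc <- replicate_qc(make_intensities(list(R1 = base, R2 = base)))
  off <- qc$step_correlations[qc$step_correlations$step_a !=
                                qc$step_correlations$step_b, ]
  expect_true(all(abs(off$spearman_rho - 1) < 1e-12))
})

test_that("pairs with fewer than three shared proteins are undefined", {
  a <- matrix(c(5, 5, 5, 5, NA, NA, NA, NA), 4, 2,
              dimnames = list(paste0("P", 1:4), NULL))
  b <- matrix(c(NA, NA, 6, 6, NA, NA, 6, 6), 4, 2,
              dimnames = list(paste0("P", 1:4), NULL))
  qc <- replicate_qc(make_intensities(list(R1 = a, R2 = b)))
  row <- tidy(qc)
  expect_equal(row$n_shared, 2)
  expect_true(is.na(row$pearson_r) && is.na(row$slope))
})

test_that("orthogonal regression of (x, y) and (y, x) gives reciprocal slopes", {
  set.seed(43)
  for (i in 1:10) {
    x <- rnorm(50)
    y <- 0.6 * x + rnorm(50, sd = 0.3)
    f <- epasis:::orthogonal_regression(x, y)
    b <- epasis:::orthogonal_regression(y, x)
    expect_equal(f$slope, 1 / b$slope, tolerance = 1e-8)
  }
})
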