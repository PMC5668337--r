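test_that("the default fingerprint grid has 701 bins", {
  centers <- bin_centers(preprocess_config())
  expect_length(centers, 701L)
  expect_equal(centers[1], 600.0)
  expect_equal(centers[701], 950.0)
  expect_equal(unique(round(diff(centers), 10)), 0.5)
})

test_that("burn gating segments exactly the above-threshold scan intervals", {
  run <- toy_run(c(1e6, 2e8, 3e8, 1e6, 5e8, 1e6))
  seg <- detect_burns(run)
  expect_identical(seg$start, c(2L, 5L))
  expect_identical(seg$end, c(4L, 6L))
  expect_identical(seg$n_scans, c(2L, 1L))
  expect_equal(seg$duration, c(1.0, 0.5))

  expect_identical(nrow(detect_burns(toy_run(rep(1e6, 5)))), 0L)

  # a burn still open at end-of-stream is closed there
  seg2 <- detect_burns(toy_run(c(1e6, 2e8, 3e8)))
  expect_identical(seg2$start, 2L)
  expect_identical(seg2$end, 4L)
})

test_that("detected burns match the generator's ground truth", {
  run <- raw_run()
  seg <- detect_burns(run)
  expect_identical(seg$start, run$meta$burns$start)
  expect_identical(seg$end, run$meta$burns$end)
})

test_that("raising the gate never increases the number of burns", {
  run <- raw_run()
  cfgs <- lapply(c(1e8, 2e8, 3e8, 4e8, 6e8),
                 function(g) preprocess_config(burn_gate_tic = g))
  counts <- vapply(cfgs, function(cfg) nrow(detect_burns(run, cfg)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("scan averaging is the pointwise mean", {
  x <- c(1, 2, 4)
  m <- rbind(x, 3 * x)
  attr(m, "mz") <- c(700, 700.5, 701)
  avg <- average_scans(m)
  expect_equal(avg$intensity, 2 * x)

  one <- average_scans(m[1, , drop = FALSE], mz = c(700, 700.5, 701))
  expect_equal(one$intensity, x)

  set.seed(31)
  big <- matrix(runif(40 * 25), nrow = 40)
  attr(big, "mz") <- seq_len(25)
  brute <- colSums(big) / nrow(big)  # summation oracle
  expect_equal(average_scans(big)$intensity, brute, tolerance = 1e-9)

  s1 <- new_spectrum(c(1, 2), c(1, 1))
  s2 <- new_spectrum(c(1, 3), c(1, 1))
  expect_error(average_scans(list(s1, s2)), "grid")
  expect_error(average_scans(list()), "no scans")
})

test_that("lockmass correction rescales the mass axis by the centroid ratio", {
  cfg <- preprocess_config()
  # already calibrated: factor is exactly 1
  spec <- new_spectrum(c(554.2615, 788.6), c(1e6, 5e6))
  res <- lockmass_correct(spec, cfg)
  expect_equal(res$factor, 1.0)
  expect_equal(res$spectrum$mz, spec$mz)

  # +100 ppm drift: whole axis scaled back, 788.6 lands near 788.52
  drifted <- new_spectrum(c(554.3169, 788.6), c(1e6, 5e6))
  res <- lockmass_correct(drifted, cfg)
  expect_equal(res$factor, 554.2615 / 554.3169)
  expect_equal(res$spectrum$mz[1], 554.2615)
  expect_lt(abs(res$spectrum$mz[2] - 788.52), 0.01)

  # weighted centroid of several points in the window
  multi <- new_spectrum(c(554.20, 554.30, 700), c(1, 3, 10))
  cent <- (554.20 * 1 + 554.30 * 3) / 4
  expect_equal(lockmass_correct(multi, cfg)$factor, 554.2615 / cent)

  expect_error(lockmass_correct(new_spectrum(700, 1), cfg), "lockmass")
})

test_that("binning sums points per half-open bin and applies the 2e6 floor", {
  cfg <- preprocess_config()
  spec <- new_spectrum(c(788.51, 788.53, 788.55), c(2e6, 2e6, 1e6))
  v <- bin_spectrum(spec, cfg)
  expect_length(v, 701L)
  expect_equal(unname(v[["788.5"]]), 5e6)
  expect_equal(sum(v > 0), 1L)

  below <- bin_spectrum(new_spectrum(788.53, 1.9e6), cfg)
  expect_true(all(below == 0))

  # half-open membership: 788.75 belongs to the 789.0 bin, 788.25 to 788.5
  edges <- bin_spectrum(new_spectrum(c(788.25, 788.75), c(3e6, 4e6)), cfg)
  expect_equal(unname(edges[["788.5"]]), 3e6)
  expect_equal(unname(edges[["789.0"]]), 4e6)

  # points outside the modelled window are discarded
  outside <- bin_spectrum(new_spectrum(c(599.7, 950.3), c(5e6, 5e6)), cfg)
  expect_true(all(outside == 0))
})

test_that("binning never creates intensity (conservation)", {
  run <- raw_run()
  burns <- detect_burns(run)
  rows <- unlist(Map(seq.int, burns$start, burns$end - 1L))
  avg <- average_scans(run$scans[rows, , drop = FALSE], mz = run$mz)
  v <- bin_spectrum(avg, preprocess_config())
  window <- avg$mz >= 599.75 & avg$mz < 950.25
  expect_lte(sum(v), sum(avg$intensity[window]))
})

test_that("TIC normalisation scales to unit sum and rejects empty vectors", {
  v <- c(2e6, 3e6, 5e6)
  expect_equal(tic_normalize(v), c(0.2, 0.3, 0.5))
  expect_equal(tic_normalize(tic_normalize(v)), tic_normalize(v))
  expect_error(tic_normalize(rep(0, 3)), "no usable signal")
})

test_that("run_to_features equals the hand-stepped chain and sums to one", {
  run <- raw_run()
  cfg <- preprocess_config()
  v <- run_to_features(run, cfg, mode = "per_sample")
  expect_equal(sum(v), 1, tolerance = 1e-9)

  # stepwise oracle: average all burn scans -> lockmass -> bin -> normalise
  burns <- detect_burns(run, cfg)
  rows <- unlist(Map(seq.int, burns$start, burns$end - 1L))
  avg <- average_scans(run$scans[rows, , drop = FALSE], mz = run$mz)
  corr <- lockmass_correct(avg, cfg)
  manual <- tic_normalize(bin_spectrum(corr$spectrum, cfg))
  expect_identical(unname(as.numeric(v)), unname(as.numeric(manual)))
  expect_equal(attr(v, "lockmass_factor"), corr$factor)
  # correction factor undoes the simulated drift
  expect_equal(corr$factor * run$meta$drift, 1, tolerance = 1e-4)

  vb <- run_to_features(run, cfg, mode = "per_burn")
  expect_identical(nrow(vb), nrow(burns))
  expect_equal(unname(rowSums(vb)), rep(1, nrow(vb)), tolerance = 1e-9)

  expect_error(run_to_features(toy_run(rep(1e6, 4))), "no burns")
})

test_that("feature matrix CSV round trip is bit-exact", {
  dat <- fp5()
  x <- dat$x[1:6, , drop = FALSE]
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(x, dat$labels[1:6], path)
  back <- read_feature_matrix(path)
  bx <- back$x
  attr(bx, "mz") <- NULL
  expect_identical(unname(bx), unname(x))
  expect_identical(back$labels, dat$labels[1:6])
  expect_identical(back$ids, rownames(x))
})
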