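test_that("fraction sets enforce heavy-first ordering", {
  fs <- make_test_fs(c(1, 5, 2))
  expect_s3_class(fs, "fraction_set")
  expect_warning(
    fraction_set(1:3, c(1.69, 1.70, 1.71), c(1, 2, 3)),
    "re-sorting")
  expect_error(fraction_set(c(1, 1, 2), c(1.7, 1.71, 1.72), c(1, 1, 1)),
               "duplicate")
})

test_that("peak detection finds prominent local maxima with plateau rules", {
  fs <- make_test_fs(c(1, 2, 10, 3, 2, 2, 2, 9, 2, 1, 1, 1))
  pk <- detect_peaks(fs)
  expect_setequal(pk$peak_fraction_ids, c(3, 8))
  expect_equal(pk$peak_fraction_ids[1], 3)       # sorted by concentration
  expect_equal(sum(pk$relative_profile), 1, tolerance = 1e-9)

  # single Gaussian band -> one peak at its mode
  conc <- dnorm(1:12, mean = 6, sd = 1.5)
  expect_equal(detect_peaks(make_test_fs(conc))$peak_fraction_ids, 6)

  expect_length(detect_peaks(make_test_fs(rep(2, 12)))$peak_fraction_ids, 0)
  expect_error(detect_peaks(make_test_fs(c(1, 2))), "at least 3")

  # plateau above both flanks counts once, at its heaviest fraction
  pk2 <- detect_peaks(make_test_fs(c(1, 5, 5, 5, 1, 1, 1, 1, 1, 1, 1, 1)))
  expect_equal(pk2$peak_fraction_ids, 2)

  # low-prominence bumps are suppressed
  pk3 <- detect_peaks(make_test_fs(c(1, 10, 1, 1.05, 1, 1, 1, 1, 1, 1, 1, 1)),
                      min_prominence = 0.1)
  expect_equal(pk3$peak_fraction_ids, 2)
})

test_that("failed fractions are excluded unless explicitly included", {
  conc <- c(1, 2, 10, 3, 2, 2, 2, 9, 2, 1, 1, 1)
  failed <- rep(FALSE, 12); failed[3] <- TRUE
  fs <- make_test_fs(conc, failed = failed)
  expect_false(3 %in% detect_peaks(fs)$peak_fraction_ids)
  expect_true(3 %in% detect_peaks(fs, include_failed = TRUE)$peak_fraction_ids)
})

test_that("profile separation is null for identical sets and errors on grid mismatch", {
  fs <- make_test_fs(c(1, 2, 10, 3, 2, 2, 2, 9, 2, 1, 1, 1))
  sep <- peak_separation(fs, fs)
  expect_equal(sep$separation_score, 0)
  expect_false(sep$distinguishable)
  expect_error(peak_separation(fs, make_test_fs(c(1, 2, 3))), "grids")
})

test_that("blank-vs-blank replicates are rarely called distinguishable", {
  com <- make_community(60, 0, 0, seed = 21)
  cfg <- gradient_config(dna_noise_cv = 0.05)
  calls <- vapply(1:100, function(s) {
    a <- simulate_gradient(com, 1, "blank", cfg, seed = 2 * s)
    b <- simulate_gradient(com, 1, "blank", cfg, seed = 2 * s + 1)
    peak_separation(a$fractions, b$fractions)$distinguishable
  }, logical(1))
  expect_lte(sum(calls), 5)
})

test_that("heavy/light orientation follows mean density", {
  failed <- rep(FALSE, 12); failed[c(4, 6, 7)] <- TRUE
  fs <- make_test_fs(c(2, 3, 4, 3, 9, 4, 2, 3, 6, 10, 4, 1), failed = failed)
  hl <- assign_heavy_light(fs, list(c(1, 2, 3, 5), c(8, 9, 10, 11, 12)))
  expect_equal(hl$heavy, c(1, 2, 3, 5))
  expect_equal(hl$light, c(8, 9, 10, 11, 12))

  fs2 <- make_test_fs(rep(1, 12))
  hl2 <- assign_heavy_light(fs2, list(1:6, 7:12))
  expect_equal(hl2$heavy, 1:6)
  expect_error(
    assign_heavy_light(fs2, list(c(1, 4, 5, 8, 9, 12), c(2, 3, 6, 7, 10, 11))),
    "degenerate")
  expect_error(assign_heavy_light(fs2, list(1:4, 5:8)), "partition")
})

test_that("representative fraction selection follows peaks, groups and failures", {
  failed <- rep(FALSE, 12); failed[c(4, 6, 7)] <- TRUE
  fs <- make_test_fs(c(2, 3, 4, 3, 9, 4, 2, 3, 6, 10, 4, 1), failed = failed)
  sel <- select_representative_fractions(fs, NULL,
                                         heavy_group = c(1, 2, 3, 5),
                                         light_group = c(8, 9, 10, 11, 12))
  expect_equal(sel$h_fraction, 5)
  expect_equal(sel$l_fraction, 10)
  expect_gt(sel$h_density, sel$l_density)

  # peak on a failed fraction: nearest non-failed in-group, heavier on ties
  failed2 <- rep(FALSE, 12); failed2[4] <- TRUE
  fs2 <- make_test_fs(c(1, 2, 3, 10, 3, 1, 1, 2, 8, 2, 1, 1),
                      failed = failed2)
  sel2 <- select_representative_fractions(fs2, NULL,
                                          heavy_group = 1:5,
                                          light_group = 6:12)
  expect_equal(sel2$h_fraction, 3)

  # no peak in the heavy group is an error naming the candidates
  fs3 <- make_test_fs(c(1, 1, 1, 1, 1, 1, 1, 2, 8, 2, 1, 1))
  expect_error(select_representative_fractions(fs3, NULL, 1:6, 7:12),
               "no DNA peak inside the heavy group")
})

test_that("valley split delimits the two main bands", {
  fs <- make_test_fs(c(2, 3, 4, 3, 9, 4, 2, 3, 6, 10, 4, 1))
  hl <- valley_groups(fs)
  expect_equal(hl$heavy, 1:6)          # trough at fraction 7
  expect_equal(hl$light, 7:12)
  expect_error(valley_groups(make_test_fs(dnorm(1:12, 6, 1.5))), "two DNA peaks")
})

test_that("incubation-time choice maximises eligible H/L dissimilarity", {
  # worked example: estuary-like series, all timepoints eligible
  p1 <- data.frame(t = c(1, 3, 4),
                   hl_dissimilarity = c(0.7636, 0.6821, 0.5349),
                   peaks_distinguishable = TRUE,
                   anosim_p = c(0.01, 0.01, 0.01))
  expect_equal(select_timepoint(p1)$chosen_t, 1)

  # basin-like series: day 2 best, day 1 peaks not distinguishable
  b4 <- data.frame(t = c(1, 2, 4),
                   hl_dissimilarity = c(0.80, 0.70, 0.60),
                   peaks_distinguishable = c(FALSE, TRUE, TRUE),
                   anosim_p = NA_real_)
  expect_equal(select_timepoint(b4)$chosen_t, 2)

  none <- data.frame(t = c(1, 2), hl_dissimilarity = c(0.5, 0.6),
                     peaks_distinguishable = FALSE)
  dec <- select_timepoint(none)
  expect_true(is.na(dec$chosen_t))
  expect_match(dec$diagnostic, "no eligible")

  # ties resolve to the earliest time
  tie <- data.frame(t = c(2, 4), hl_dissimilarity = c(0.7, 0.7),
                    peaks_distinguishable = TRUE)
  expect_equal(select_timepoint(tie)$chosen_t, 2)
  expect_error(select_timepoint(data.frame()), "non-empty")
})
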