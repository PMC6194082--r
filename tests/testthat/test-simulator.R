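test_that("buoyant density follows the linear GC/label model", {
  expect_equal(buoyant_density(0.5, 0), 1.709)
  expect_equal(buoyant_density(0.5, 1), 1.745)
  expect_equal(buoyant_density(0, 0), 1.660)
  expect_error(buoyant_density(1.2, 0), "\\[0, 1\\]")
  expect_error(buoyant_density(0.5, -0.1), "\\[0, 1\\]")
})

test_that("community generation is seeded, normalised and typed", {
  a <- make_community(100, 5, 10, seed = 42)
  b <- make_community(100, 5, 10, seed = 42)
  expect_identical(a, b)
  expect_equal(sum(a$base_abundance), 1, tolerance = 1e-9)
  expect_equal(as.vector(table(a$true_type)), c(5, 10, 85))

  none <- make_community(10, 0, 0, seed = 1)
  expect_true(all(none$true_type == "none"))
  expect_error(make_community(5, 4, 4, seed = 1), "exceed")

  # planted rapid incorporators come from the rarer half of the community
  expect_true(max(a$base_abundance[a$true_type == "rapid"]) <=
                stats::median(a$base_abundance) * 1.0000001)
})

test_that("labelling trajectories separate rapid from slow incorporators", {
  com <- make_community(30, 10, 10, seed = 3)
  lf1 <- labeled_fraction(com, 1)
  lf4 <- labeled_fraction(com, 4)
  rapid <- com$true_type == "rapid"; slow <- com$true_type == "slow"
  none <- com$true_type == "none"
  expect_true(all(lf1[rapid] >= 0.5))         # labelled by the short timepoint
  expect_true(all(lf1[slow] < 0.5))
  expect_true(all(lf4[slow] >= 0.5))          # and by the long one
  expect_true(all(lf1[none] == 0) && all(lf4[none] == 0))
  # non-decreasing in time
  ts <- seq(0, 6, by = 0.5)
  traj <- sapply(ts, function(t) labeled_fraction(com, t))
  expect_true(all(apply(traj, 1, function(x) all(diff(x) >= 0))))
})

test_that("gradient geometry: 12 heavy-first fractions inside the density range", {
  com <- make_community(20, 2, 3, seed = 7)
  g <- simulate_gradient(com, 1, "labeled", gradient_config(), seed = 1)
  dens <- g$fractions$fractions$density
  expect_length(dens, 12L)
  expect_true(all(diff(dens) < 0))
  expect_true(all(dens > 1.687 & dens < 1.770))
})

test_that("blank gradients centre each taxon at its unlabelled density", {
  com <- make_community(15, 3, 3, seed = 5)
  cfg <- gradient_config(dna_noise_cv = 0)
  g <- simulate_gradient(com, 4, "blank", cfg)
  dens <- g$fractions$fractions$density
  wmean <- colSums(g$mass * dens) / colSums(g$mass)
  expect_true(all(abs(wmean - buoyant_density(com$gc, 0, cfg)) < 1e-3))
})

test_that("full labelling shifts a taxon's DNA by the substrate-weighted shift", {
  com <- make_community(1, 1, 0, seed = 2)
  cfg <- gradient_config(dna_noise_cv = 0)
  t_long <- 40                       # labelled fraction ~ 1
  glab <- simulate_gradient(com, t_long, "labeled", cfg)
  gblk <- simulate_gradient(com, t_long, "blank", cfg)
  dens <- glab$fractions$fractions$density
  wm <- function(g) sum(g$mass[, 1] * dens) / sum(g$mass[, 1])
  expect_equal(wm(glab) - wm(gblk), 0.99 * 0.036, tolerance = 2e-3)
})

test_that("gradient conserves DNA mass up to Gaussian edge truncation", {
  com <- make_community(50, 5, 5, seed = 9)
  cfg <- gradient_config(dna_noise_cv = 0)
  g <- simulate_gradient(com, 2, "labeled", cfg)
  total_in <- sum(com$base_abundance * growth_factor(com, 2))
  expect_equal(sum(g$mass), total_in, tolerance = 0.01)
  expect_equal(sum(g$fractions$fractions$dna_conc), total_in,
               tolerance = 0.01)
})

test_that("separation score grows monotonically with labelling time", {
  com <- make_community(40, 4, 6, seed = 13)
  cfg <- gradient_config(dna_noise_cv = 0)
  scores <- sapply(c(0.5, 1, 2, 3, 4, 6), function(t) {
    peak_separation(simulate_gradient(com, t, "labeled", cfg)$fractions,
                    simulate_gradient(com, t, "blank", cfg)$fractions)$separation_score
  })
  expect_true(all(diff(scores) > 0))
})

test_that("read simulation is multinomial, seeded and guards empty input", {
  m <- rbind(s1 = c(a = 1, b = 0), s2 = c(a = 2, b = 2))
  r1 <- simulate_reads(m, depth = 100, seed = 4)
  expect_equal(unname(r1$counts["s1", ]), c(100L, 0L))
  expect_equal(sum(r1$counts["s2", ]), 100L)
  r2 <- simulate_reads(m, depth = 100, seed = 4)
  expect_identical(r1$counts, r2$counts)

  big <- simulate_reads(rbind(s = c(a = 5, b = 5)), depth = 1e6, seed = 8)
  expect_equal(big$counts[1, "a"] / 1e6, 0.5, tolerance = 0.002)

  expect_error(simulate_reads(rbind(s = c(a = 0, b = 0)), 10),
               "nothing to sequence")
  expect_error(simulate_reads(m, depth = 0), "> 0")
})

test_that("POC time series honours its boundary conditions", {
  sc0 <- incubation_scenario(planted_rates = 0, natural_delta = -22)
  ts0 <- simulate_poc_timeseries(sc0)
  expect_true(all(abs(ts0$delta13c_poc_permil - (-22)) < 1e-9))

  sc <- incubation_scenario(planted_rates = 50, natural_delta = -22)
  ts <- simulate_poc_timeseries(sc)
  blank <- ts[ts$treatment == "blank", ]
  expect_true(all(abs(blank$delta13c_poc_permil - (-22)) < 1e-9))
  rep_ <- assimilation_report(ts)
  expect_true(all(abs(rep_$assimilation_rate_ug_l_d - 50) < 1e-4))
})
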