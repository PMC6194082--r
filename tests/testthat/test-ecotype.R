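test_that("abundance screen keeps OTUs above 1% in any library", {
  h <- c(a = 0.02, b = 0.005, c = 0.01)
  l <- c(a = 0.001, b = 0.005, c = 0.002)
  is_ <- c(a = 0.001, b = 0.005, c = 0.003)
  expect_equal(filter_abundant(h, l, is_), "a")   # c sits exactly at 1%
  expect_error(filter_abundant(h, l[c("a", "b")], is_), "aligned")
  expect_error(ecotype_config(abund_filter = 0.0005), "presence_min")
  expect_error(ecotype_config(fold_enrich = 1), "exceed 1")
})

test_that("classification rules fire in order and record their rationale", {
  calls <- classify_otu(h = c(0.40, 0.05, 0.001),
                        l = c(0.02, 0.05, 0.05),
                        is_ = c(0.01, 0.04, 0.06))
  expect_equal(as.character(calls$ecotype), c("I", "II", "III"))
  expect_match(calls$rationale[1], "enriched in H")
  expect_match(calls$rationale[3], "lowest")

  # H tied with L is never "lowest in H"
  tie <- classify_otu(0.03, 0.03, 0.05)
  expect_false(as.character(tie$ecotype) == "III")

  # below presence with no enrichment -> unclassified
  un <- classify_otu(0.0005, 0.0004, 0.0004)
  expect_equal(as.character(un$ecotype), "unclassified")
  expect_error(classify_otu(1.2, 0, 0), "\\[0, 1\\]")
})

test_that("the rule set is exclusive, exhaustive and monotone in h", {
  set.seed(55)
  h <- runif(500); l <- runif(500); is_ <- runif(500)
  calls <- classify_otu(h, l, is_)
  expect_true(all(!is.na(calls$ecotype)))
  expect_equal(nrow(calls), 500L)

  # raising h with l, is_ fixed never demotes a type I call
  for (k in 1:20) {
    l0 <- runif(1, 0, 0.2); i0 <- runif(1, 0, 0.2)
    hs <- seq(0, 1, length.out = 50)
    types <- as.character(classify_otu(hs, rep(l0, 50),
                                       rep(i0, 50))$ecotype)
    first_I <- match("I", types)
    if (!is.na(first_I)) {
      expect_true(all(types[first_I:length(types)] == "I"))
    }
  }
})

test_that("ecotype reports aggregate calls and validate roles", {
  set.seed(9)
  base <- rmultinom(1, 5000, prob = rep(1, 40))[, 1]
  h <- base; l <- base; is_ <- base
  h[1:3] <- h[1:3] + 3000L     # strong heavy enrichment for three OTUs
  tab <- make_role_table(h, l, is_)
  rep_ <- ecotype_report(tab, seed = 1)
  expect_s3_class(rep_, "ecotype_report")
  first3 <- rep_$calls[rep_$calls$otu %in% c("otu001", "otu002", "otu003"), ]
  expect_true(all(first3$ecotype == "I"))
  expect_true(all(c("n_I", "median_h") %in% names(rep_$summary)))

  # without the H sample the report refuses, naming the role
  tab2 <- tab
  tab2$meta$role[1] <- "fraction"
  expect_error(ecotype_report(tab2), "role 'H'")
})

test_that("no incorporators means no type I calls; swapping H and L flips them", {
  # without incorporators the gradient never shows a distinguishable heavy
  # band, so the chain selects no H fraction and makes no type I call
  res <- suppressWarnings(
    run_pipeline(withr::local_tempdir(), seed = 12, n_taxa = 60,
                 n_rapid = 0, n_slow = 0, fraction_depth = 2000,
                 library_depth = 5000, n_perm = 49, quiet = TRUE))
  n_I <- if (is.null(res$ecotype)) 0L else {
    sum(res$ecotype$calls$ecotype == "I")
  }
  expect_equal(n_I, 0L)

  # planted incorporators: swapping the H and L roles turns type I calls
  # into non-incorporator (III/unclassified) calls
  com2 <- make_community(60, 5, 5, seed = 14)
  g2 <- simulate_gradient(com2, 4, "labeled", seed = 6)
  hrow <- g2$labeled_peak_fraction
  m3 <- rbind(g2$mass[hrow, ], g2$mass[10, ],
              stats::setNames(com2$base_abundance, com2$taxon_id))
  rownames(m3) <- c("H_lib", "L_lib", "insitu_lib")
  fwd <- ecotype_report(simulate_reads(m3, 20000, seed = 7,
                                       role = c("H", "L", "in-situ")),
                        seed = 8)
  m3r <- m3[c(2, 1, 3), ]
  rownames(m3r) <- c("H_lib", "L_lib", "insitu_lib")
  rev_ <- ecotype_report(simulate_reads(m3r, 20000, seed = 7,
                                        role = c("H", "L", "in-situ")),
                         seed = 8)
  n_I_fwd <- sum(fwd$calls$ecotype == "I")
  expect_gt(n_I_fwd, 0)
  expect_lt(sum(rev_$calls$ecotype == "I"), n_I_fwd)
  was_I <- fwd$calls$otu[fwd$calls$ecotype == "I"]
  rev_types <- rev_$calls$ecotype[match(was_I, rev_$calls$otu)]
  expect_true(all(is.na(rev_types) |
                    as.character(rev_types) %in% c("III", "unclassified")))
})

test_that("long incubations flag type II calls for cross-feeding", {
  h <- c(400L, 300L, 300L); l <- c(380L, 320L, 300L)
  is_ <- c(350L, 350L, 300L)
  counts <- rbind(H_lib = h, L_lib = l, insitu_lib = is_)
  colnames(counts) <- paste0("otu", 1:3)
  tab <- otu_table(counts, data.frame(
    sample = rownames(counts), role = c("H", "L", "in-situ"),
    timepoint_days = 4))
  expect_warning(ecotype_report(tab, seed = 1), "cross-feeding")
})
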