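test_that("OTU table construction validates counts, ids and roles", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("o1", "o2")))
  tab <- otu_table(m)
  expect_s3_class(tab, "sip_otu")
  expect_error(otu_table(matrix(-1, 1, 1, dimnames = list("a", "o"))),
               "non-negative")
  expect_error(otu_table(matrix(1.5, 1, 1, dimnames = list("a", "o"))),
               "integer")
  meta <- data.frame(sample = c("a", "b"), role = c("heavy", "L"))
  expect_error(otu_table(m, meta), "did you mean H")
})

test_that("rarefaction hits the target depth without replacement", {
  m <- rbind(a = c(10L, 0L, 0L), b = c(50L, 30L, 20L))
  colnames(m) <- c("x", "y", "z")
  sub <- subsample_counts(otu_table(m), 5, seed = 1)
  expect_equal(unname(sub$counts["a", ]), c(5L, 0L, 0L))
  expect_true(all(rowSums(sub$counts) == 5))
  expect_true(all(sub$counts <= m))

  same <- subsample_counts(otu_table(m), 10, seed = 1)
  expect_equal(unname(same$counts["a", ]), c(10L, 0L, 0L))

  expect_warning(out <- subsample_counts(otu_table(m), 20, seed = 1),
                 "dropping")
  expect_equal(rownames(out$counts), "b")
  expect_error(subsample_counts(otu_table(m), 0), "> 0")

  # hypergeometric expectation: row [500, 500] at depth 100 -> mean ~ 50
  mm <- otu_table(rbind(s = c(u = 500L, v = 500L)))
  draws <- vapply(1:1000, function(s) {
    subsample_counts(mm, 100, seed = s)$counts[1, "u"]
  }, integer(1))
  expect_equal(mean(draws), 50, tolerance = 2 / 50)  # +- 2 counts
})

test_that("Bray-Curtis matches its definition and a brute-force oracle", {
  m <- rbind(a = c(6L, 2L), b = c(2L, 2L))
  colnames(m) <- c("x", "y")
  expect_equal(bray_curtis_matrix(m, use_relative = FALSE)["a", "b"], 1 / 3)

  ident <- rbind(a = c(3L, 1L), b = c(3L, 1L)); colnames(ident) <- c("x", "y")
  expect_equal(bray_curtis_matrix(ident)["a", "b"], 0)
  disj <- rbind(a = c(5L, 0L), b = c(0L, 7L)); colnames(disj) <- c("x", "y")
  expect_equal(bray_curtis_matrix(disj)["a", "b"], 1)

  set.seed(77)
  for (k in 1:100) {
    x <- matrix(rpois(2 * 30, 5), 2,
                dimnames = list(c("a", "b"), paste0("o", 1:30)))
    x[1, 1] <- x[1, 1] + 1L   # guard zero rows
    x[2, 2] <- x[2, 2] + 1L
    rel <- x / rowSums(x)
    expect_equal(bray_curtis_matrix(x)["a", "b"],
                 bc_brute(rel[1, ], rel[2, ]), tolerance = 1e-12)
  }
  zero <- rbind(a = c(0L, 0L), b = c(1L, 2L)); colnames(zero) <- c("x", "y")
  expect_error(bray_curtis_matrix(zero), "zero total")
})

test_that("Shannon diversity matches closed forms", {
  expect_equal(shannon_index(c(5, 5, 5, 5)), log(4))
  expect_equal(shannon_index(c(7, 0, 0)), 0)
  p <- c(1, 2, 3) / 6
  expect_equal(shannon_index(c(1, 2, 3)), -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(shannon_index(c(2, 2, 2, 2), base = 2), 2)
  expect_error(shannon_index(c(0, 0)), "zero total")
})

test_that("group-average clustering reproduces hand-computed merges", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["A", "C"] <- d["C", "A"] <- 0.8
  d["B", "C"] <- d["C", "B"] <- 0.8
  tr <- upgma_cluster(d)
  expect_equal(tr$merge_heights, c(0.1, 0.8))
  expect_equal(sort(names(which(tr$two_groups == tr$two_groups["A"]))),
               c("A", "B"))

  two <- matrix(c(0, 0.4, 0.4, 0), 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(upgma_cluster(two)$merge_heights, 0.4)

  asym <- d; asym["A", "B"] <- 0.5
  expect_error(upgma_cluster(asym), "symmetric")

  # ultrametric heights on random proper dissimilarities
  set.seed(5)
  for (k in 1:10) {
    x <- matrix(runif(60), 6)
    dd <- as.matrix(dist(x))
    expect_true(all(diff(upgma_cluster(dd)$merge_heights) >= -1e-12))
  }
})

test_that("NMDS embeds low-dimensional configurations at near-zero stress", {
  set.seed(31)
  pts <- matrix(rnorm(8), 4, 2,
                dimnames = list(paste0("s", 1:4), NULL))
  d <- as.matrix(dist(pts))
  fit <- suppressWarnings(nmds_embed(d, seed = 1))
  expect_lt(fit$stress, 0.01)
  expect_equal(dim(fit$points), c(4L, 2L))

  tri <- matrix(1, 3, 3,
                dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  diag(tri) <- 0
  expect_lt(suppressWarnings(nmds_embed(tri, seed = 1))$stress, 0.01)

  zero <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nmds_embed(zero), "degenerate")
})

test_that("ANOSIM attains R = 1 for perfect separation and enumerates exactly", {
  # two tight clusters far apart: all within < all between
  x <- c(0, 0.01, 0.02, 10, 10.01, 10.02)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("p", "q"), each = 3)
  res <- anosim_test(d, g, n_perm = 99, seed = 1)
  expect_equal(unname(res$statistic), 1)
  expect_true(res$p.value > 0 && res$p.value <= 1)

  # n = 4, 2+2: three distinct partitions; uniquely maximal R -> exact 1/3
  x4 <- c(0, 0.1, 5, 5.1)
  d4 <- as.matrix(dist(x4))
  dimnames(d4) <- list(paste0("s", 1:4), paste0("s", 1:4))
  ex <- anosim_test(d4, c("a", "a", "b", "b"), exact = TRUE)
  expect_equal(ex$p.value, 1 / 3)

  # exact enumeration agrees with an independent oracle (n = 6)
  set.seed(19)
  for (k in 1:3) {
    dd <- as.matrix(dist(runif(6)))
    dimnames(dd) <- list(paste0("s", 1:6), paste0("s", 1:6))
    gg <- rep(c("a", "b"), each = 3)
    mine <- anosim_test(dd, gg, exact = TRUE)
    orc <- anosim_enum_oracle(dd, gg)
    expect_equal(unname(mine$statistic), orc$R, tolerance = 1e-12)
    expect_equal(mine$p.value, orc$p, tolerance = 1e-12)
  }
  expect_error(anosim_test(d4, c("a", "a", "a", "b")), ">= 2")
})

test_that("ANOSIM R agrees with the reference implementation in vegan", {
  set.seed(23)
  x <- matrix(rpois(8 * 20, 8), 8,
              dimnames = list(paste0("s", 1:8), paste0("o", 1:20)))
  d <- bray_curtis_matrix(x)
  g <- rep(c("a", "b"), each = 4)
  mine <- anosim_test(d, g, n_perm = 99, seed = 1)
  ref <- vegan::anosim(stats::as.dist(d), grouping = factor(g),
                       permutations = 9)
  expect_equal(unname(mine$statistic), unname(ref$statistic),
               tolerance = 1e-12)
  expect_true(abs(unname(mine$statistic)) <= 1)
})
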