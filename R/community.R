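# Community comparison statistics: OTU table container, equal-depth
# subsampling, Bray-Curtis dissimilarity, Shannon diversity, group-average
# (UPGMA) clustering, NMDS ordination, and ANOSIM.
#
# The standard computations are delegated to vegan (vegdist, diversity,
# rrarefy, metaMDS) and stats::hclust/ape. ANOSIM is implemented here
# because the permutation p-value uses the +1/+1 convention and small
# designs are enumerated exactly, which vegan does not expose.

#' Construct an OTU count table with sample metadata
#'
#' @param counts samples x OTUs matrix of non-negative integer counts, with
#'   unique sample row names and OTU column names.
#' @param meta `data.frame` with columns `sample` (matching row names of
#'   `counts`), `role` (one of `H`, `L`, `in-situ`, `fraction`), and
#'   optionally `treatment`, `timepoint_days`, `fraction`.
#' @param otu_meta optional per-OTU annotation (e.g. taxonomy strings) named
#'   by OTU id.
#' @return an object of class `sip_otu`.
#' @export
otu_table <- function(counts, meta = NULL, otu_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop_domain("'counts' must have sample row names")
  }
  if (anyDuplicated(rownames(counts))) stop_domain("duplicate sample ids")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(!is_wholenumber(counts))) {
    stop_domain("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (is.null(meta)) {
    meta <- data.frame(sample = rownames(counts), role = "fraction",
                       stringsAsFactors = FALSE)
  }
  if (!all(c("sample", "role") %in% names(meta))) {
    stop_domain("meta must contain 'sample' and 'role' columns")
  }
  if (!setequal(meta$sample, rownames(counts)) ||
      anyDuplicated(meta$sample)) {
    stop_domain("meta must describe each sample exactly once")
  }
  ok_roles <- c("H", "L", "in-situ", "fraction")
  bad <- setdiff(unique(meta$role), ok_roles)
  if (length(bad)) {
    hint <- c(heavy = "H", light = "L", insitu = "in-situ",
              "in situ" = "in-situ")[tolower(bad)]
    stop_domain("unknown role(s): ", paste(bad, collapse = ", "),
                if (any(!is.na(hint))) {
                  paste0(" (did you mean ",
                         paste(stats::na.omit(hint), collapse = ", "), "?)")
                })
  }
  meta <- meta[match(rownames(counts), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta, otu_meta = otu_meta),
            class = "sip_otu")
}

#' @export
print.sip_otu <- function(x, ...) {
  cat(sprintf("<sip_otu> %d samples x %d OTUs; roles: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(names(table(x$meta$role)), table(x$meta$role),
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' Rarefy all samples to an equal sequencing depth
#'
#' Subsamples each sample's reads to exactly `depth` without replacement
#' (multivariate hypergeometric). Samples shallower than `depth` are dropped
#' with a warning.
#'
#' @param table a [otu_table()].
#' @param depth target depth, `> 0`.
#' @param seed RNG seed.
#' @return a rarefied [otu_table()].
#' @export
subsample_counts <- function(table, depth, seed = NULL) {
  stopifnot(inherits(table, "sip_otu"))
  if (depth <= 0) stop_domain("'depth' must be > 0")
  tot <- rowSums(table$counts)
  keep <- tot >= depth
  if (!any(keep)) stop_domain("no sample reaches depth ", depth)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " sample(s) shallower than depth ",
            depth, ": ", paste(rownames(table$counts)[!keep], collapse = ", "),
            call. = FALSE)
  }
  counts <- table$counts[keep, , drop = FALSE]
  # rrarefy speculates about non-count data when the smallest nonzero entry
  # exceeds 1; our inputs are validated integer counts, so silence that one
  sub <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(counts, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  storage.mode(sub) <- "integer"
  otu_table(sub, table$meta[keep, , drop = FALSE], table$otu_meta)
}

#' Relative abundances of an OTU table
#'
#' @param table a [otu_table()] or counts matrix.
#' @return samples x OTUs matrix of row-normalised relative abundances.
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "sip_otu")) table$counts else as.matrix(table)
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    stop_domain("sample(s) with zero total count: ",
                paste(rownames(counts)[tot == 0], collapse = ", "))
  }
  sweep(counts, 1, tot, "/")
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(a, b) = sum|a_i - b_i| / sum(a_i + b_i)`, computed on relative
#' abundances by default (set `use_relative = FALSE` for raw counts).
#' Similarity, where reported, is `1 - BC`.
#'
#' @param table a [otu_table()] or samples x OTUs matrix.
#' @param use_relative normalise rows to relative abundance first.
#' @return symmetric labelled matrix with zero diagonal, entries in `[0, 1]`.
#' @export
bray_curtis_matrix <- function(table, use_relative = TRUE) {
  x <- if (inherits(table, "sip_otu")) table$counts else as.matrix(table)
  if (nrow(x) < 2L) stop_domain("need at least 2 samples")
  tot <- rowSums(x)
  if (any(tot == 0)) {
    stop_domain("sample(s) with zero total count: ",
                paste(rownames(x)[tot == 0], collapse = ", "))
  }
  if (use_relative) x <- sweep(x, 1, tot, "/")
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Shannon diversity index of one sample
#'
#' `H' = -sum(p_i * log(p_i))` over OTUs with nonzero counts. Natural log by
#' default, following the mothur convention.
#'
#' @param counts count (or abundance) vector for one sample.
#' @param base logarithm base.
#' @return diversity in nats (or units of the chosen log base).
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (!is.numeric(counts) || any(counts < 0) || any(!is.finite(counts))) {
    stop_domain("counts must be finite and >= 0")
  }
  if (sum(counts) <= 0) stop_domain("sample has zero total count")
  unname(vegan::diversity(matrix(counts, nrow = 1), index = "shannon",
                          base = base)[1])
}

# validated dissimilarity input: symmetric, zero diagonal, labelled
check_dissim <- function(d, tol = 1e-12) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop_domain("dissimilarity matrix must be square")
  if (max(abs(d - t(d))) > tol) {
    stop_domain("dissimilarity matrix must be symmetric")
  }
  if (any(abs(diag(d)) > tol)) stop_domain("diagonal must be zero")
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("s", seq_len(nrow(d))),
                        paste0("s", seq_len(nrow(d))))
  }
  d
}

#' Group-average (UPGMA) dendrogram from a dissimilarity matrix
#'
#' Agglomerative clustering with arithmetic-mean linkage, the "group average
#' model" of classical community ecology. Labels are put in lexicographic
#' order first so that ties in merge distances resolve deterministically.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @return list of class `upgma_tree`: `hclust` (the [stats::hclust()]
#'   object), `phylo` (an [ape::as.phylo()] tree for newick export),
#'   `merge_heights`, and `two_groups` (the two-group cut at the root, named
#'   by label).
#' @export
upgma_cluster <- function(d) {
  d <- check_dissim(d)
  if (nrow(d) < 2L) stop_domain("need at least 2 labels")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(hclust = hc,
                 phylo = ape::as.phylo(hc),
                 merge_heights = hc$height,
                 two_groups = stats::cutree(hc, k = 2)),
            class = "upgma_tree")
}

#' Write a dendrogram as newick
#'
#' @param tree an `upgma_tree` (or `phylo`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- if (inherits(tree, "upgma_tree")) tree$phylo else tree
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Nonmetric multidimensional scaling (NMDS)
#'
#' Ordains samples in `ndim` dimensions to preserve the rank order of their
#' dissimilarities, minimising Kruskal stress-1 with monotone regression
#' (primary treatment of ties), taking the best of `restarts` random starts.
#' Backed by [vegan::metaMDS()]/monoMDS.
#'
#' @param d symmetric dissimilarity matrix.
#' @param ndim embedding dimension.
#' @param restarts number of random starts.
#' @param seed RNG seed.
#' @return list: `points` (samples x ndim coordinates), `stress` (Kruskal
#'   stress-1, 0-1 scale), `converged`.
#' @export
nmds_embed <- function(d, ndim = 2L, restarts = 20L, seed = NULL) {
  d <- check_dissim(d)
  if (nrow(d) < 3L) stop_domain("need at least 3 samples for NMDS")
  if (max(d) <= 0) stop_domain("degenerate matrix: all dissimilarities zero")
  fit <- with_seed(seed, vegan::metaMDS(
    stats::as.dist(d), k = ndim, try = restarts, trymax = max(restarts, 20L),
    trace = 0, autotransform = FALSE, wascores = FALSE))
  pts <- fit$points
  rownames(pts) <- rownames(d)
  list(points = pts, stress = fit$stress, converged = isTRUE(fit$converged > 0))
}

# ANOSIM R from pairwise ranks: mean between-group rank minus mean
# within-group rank, scaled by M/2
anosim_r_stat <- function(ranks, within) {
  M <- length(ranks)
  (mean(ranks[!within]) - mean(ranks[within])) / (M / 2)
}

# all permutations of 1..n (n small) as a list of integer vectors
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of the null hypothesis that within-group
#' community dissimilarities are no smaller than between-group ones. All
#' pairwise dissimilarities are ranked (mid-ranks on ties) and
#' `R = (mean rank between - mean rank within) / (M/2)` with
#' `M = n(n-1)/2`. The p-value counts label permutations whose R is at least
#' the observed one, including the observed labelling itself
#' (`p = (1 + #{R_perm >= R_obs}) / (1 + n_perm)`). With `exact = TRUE`
#' (only for small n) every permutation of the labels is enumerated and the
#' p-value is the exact tail probability.
#'
#' @param d symmetric dissimilarity matrix.
#' @param groups group labels, one per sample; at least two groups with at
#'   least two members each.
#' @param n_perm number of random permutations.
#' @param seed RNG seed.
#' @param exact enumerate all label permutations (requires `n <= 8`).
#' @return list of class `anosim_result`: `statistic` (R), `p.value`,
#'   `permutations`, `method`.
#' @export
anosim_test <- function(d, groups, n_perm = 999L, seed = NULL,
                        exact = FALSE) {
  d <- check_dissim(d)
  n <- nrow(d)
  groups <- as.factor(groups)
  if (length(groups) != n) stop_domain("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop_domain("need >= 2 groups with >= 2 members each")
  }
  pair <- which(upper.tri(d), arr.ind = TRUE)
  ii <- pair[, 1]; jj <- pair[, 2]
  ranks <- rank(d[upper.tri(d)])           # mid-ranks on ties
  g <- as.integer(groups)
  r_obs <- anosim_r_stat(ranks, g[ii] == g[jj])

  if (exact) {
    if (n > 8L) stop_domain("exact enumeration limited to n <= 8")
    perms <- all_perms(n)
    r_perm <- vapply(perms, function(p) {
      gp <- g[p]
      anosim_r_stat(ranks, gp[ii] == gp[jj])
    }, numeric(1))
    p <- mean(r_perm >= r_obs - 1e-12)
    n_used <- length(perms)
    method <- "exact enumeration"
  } else {
    r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      gp <- sample(g)
      anosim_r_stat(ranks, gp[ii] == gp[jj])
    }, numeric(1)))
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
    method <- "random permutations"
  }
  structure(list(statistic = c(R = r_obs), p.value = p,
                 permutations = n_used, method = method),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4f, p = %.4g (%s, %d permutations)\n",
              x$statistic, x$p.value, x$method, x$permutations))
  invisible(x)
}
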