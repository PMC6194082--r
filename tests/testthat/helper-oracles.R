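# Independent oracles used to cross-check package computations.
# Deliberately naive, formula-level implementations.

# Bray-Curtis from its definition
bc_brute <- function(a, b) sum(abs(a - b)) / sum(a + b)

# ANOSIM by exhaustive enumeration of every permutation of the labels,
# with the R statistic computed directly from the definition
anosim_enum_oracle <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  pr <- which(upper.tri(d), arr.ind = TRUE)
  rk <- rank(d[upper.tri(d)])
  M <- nrow(pr)
  rstat <- function(g) {
    w <- g[pr[, 1]] == g[pr[, 2]]
    (mean(rk[!w]) - mean(rk[w])) / (M / 2)
  }
  perm_rec <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  g <- as.integer(as.factor(groups))
  r_obs <- rstat(g)
  r_all <- vapply(perm_rec(seq_len(n)), function(p) rstat(g[p]), numeric(1))
  list(R = r_obs, p = mean(r_all >= r_obs - 1e-12))
}

# terminal restriction fragment by explicit position-by-position scan
trf_naive <- function(seq, enzymes = trf_enzymes()) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  chars <- strsplit(seq, "")[[1]]
  best <- Inf
  for (e in enzymes) {
    site <- strsplit(toupper(e$site), "")[[1]]
    L <- length(site)
    for (i in seq_len(max(0L, length(chars) - L + 1L))) {
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!(chars[i + j - 1L] %in% iupac[[site[j]]])) { ok <- FALSE; break }
      }
      if (ok) { best <- min(best, i + e$offset - 1L); break }
    }
  }
  if (is.finite(best)) as.integer(best) else NA_integer_
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# fraction set on the default 12-fraction grid from a concentration vector
make_test_fs <- function(conc, failed = FALSE, treatment = "labeled",
                         timepoint = 1) {
  cfg <- gradient_config()
  w <- (cfg$density_heavy - cfg$density_light) / cfg$n_fractions
  mids <- cfg$density_heavy - w * (seq_len(cfg$n_fractions) - 0.5)
  fraction_set(seq_along(conc), mids[seq_along(conc)], conc, failed,
               treatment = treatment, timepoint = timepoint)
}

# small OTU table with one sample per role, built from count rows
make_role_table <- function(h, l, insitu) {
  counts <- rbind(H_lib = h, L_lib = l, insitu_lib = insitu)
  colnames(counts) <- sprintf("otu%03d", seq_len(ncol(counts)))
  otu_table(counts, data.frame(
    sample = rownames(counts), role = c("H", "L", "in-situ"),
    treatment = "labeled", timepoint_days = 1, stringsAsFactors = FALSE))
}
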