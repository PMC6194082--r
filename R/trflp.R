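# In-silico terminal restriction fragment (T-RF) digestion.
#
# T-RFLP fingerprints a community by the length of the 5'-labelled fragment
# from the labelled primer base to the first restriction cut. The default
# double digest uses MspI (C^CGG) and RsaI (GT^AC) together; the shortest
# fragment over all enzymes wins.

#' Default T-RFLP restriction enzymes
#'
#' MspI (recognition `CCGG`, cut after position 1 of the site) and RsaI
#' (`GTAC`, cut after position 2), applied as a double digest.
#'
#' @return named list of `list(site, offset)` entries. IUPAC degeneracy codes
#'   are allowed in `site`.
#' @export
trf_enzymes <- function() {
  list(MspI = list(site = "CCGG", offset = 1L),
       RsaI = list(site = "GTAC", offset = 2L))
}

# IUPAC nucleotide code -> regex character class
iupac_regex <- function(site) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(site), "")[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad)) {
    stop_domain("invalid IUPAC code in recognition site: ",
                paste(bad, collapse = ", "))
  }
  paste(map[chars], collapse = "")
}

#' In-silico terminal restriction fragment length
#'
#' For each sequence (assumed to begin at the 5'-labelled primer base),
#' returns the length in nt from position 1 to the first cut site over all
#' enzymes of a double digest, or `NA` if no enzyme cuts ("uncut"). Lengths
#' are 1-based and include the labelled 5' base; the cut position for an
#' enzyme whose site starts at position `s` with cut offset `k` is
#' `s + k - 1`.
#'
#' @param seqs character vector of uppercase A/C/G/T sequences.
#' @param enzymes list of `list(site, offset)` entries; default
#'   [trf_enzymes()] (MspI + RsaI).
#' @return integer vector of T-RF lengths; `NA` marks uncut sequences.
#' @examples
#' insilico_trf("AAAACCGGTTTT")  # MspI cuts C^CGG -> 5
#' insilico_trf("AAAGTACAA")     # RsaI cuts GT^AC -> 5
#' insilico_trf("AAAA")          # uncut -> NA
#' @export
insilico_trf <- function(seqs, enzymes = trf_enzymes()) {
  if (!is.character(seqs)) stop_domain("'seqs' must be character")
  if (any(grepl("[^ACGT]", seqs))) {
    stop_domain("sequences must contain only A, C, G, T")
  }
  if (length(enzymes) == 0L) stop_domain("need at least one enzyme")
  pats <- vapply(enzymes, function(e) iupac_regex(e$site), character(1))
  offs <- vapply(enzymes, function(e) as.integer(e$offset), integer(1))
  vapply(seqs, function(s) {
    cuts <- integer(0)
    for (k in seq_along(pats)) {
      hit <- regexpr(pats[k], s)
      if (hit > 0L) cuts <- c(cuts, as.integer(hit) + offs[k] - 1L)
    }
    if (length(cuts)) min(cuts) else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Aggregate OTU counts into a T-RF profile
#'
#' Collapses an OTU count table into per-sample T-RF length bins using each
#' OTU's in-silico fragment length; uncut OTUs pool into an `"uncut"` bin.
#' This is the in-silico analogue of a per-fraction T-RFLP electropherogram.
#'
#' @param table an [otu_table()] whose OTU ids match `names(trf)`.
#' @param trf integer vector of T-RF lengths named by OTU id (from
#'   [insilico_trf()] on the OTU representative sequences); `NA` = uncut.
#' @return samples x T-RF-bin count matrix, bin columns sorted by length.
#' @export
trf_profile <- function(table, trf) {
  counts <- table$counts
  if (is.null(names(trf)) || !all(colnames(counts) %in% names(trf))) {
    stop_domain("'trf' must be named by OTU id and cover every OTU")
  }
  bins <- ifelse(is.na(trf[colnames(counts)]), "uncut",
                 as.character(trf[colnames(counts)]))
  agg <- t(rowsum(t(counts), group = bins))
  num <- suppressWarnings(as.numeric(colnames(agg)))
  agg[, order(is.na(num), num), drop = FALSE]
}
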