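# Classification of OTUs into ecological response types from their relative
# abundances in the representative heavy (H) and light (L) gradient
# fractions and the in-situ community:
#   type I   rapid, dominant substrate incorporation (enriched in heavy DNA)
#   type II  slow/minor incorporation (present in H at L-like abundance)
#   type III no incorporation (depleted in H relative to both L and in-situ)

#' Ecotype classification thresholds
#'
#' The abundance screen (`abund_filter`) keeps OTUs exceeding 1% in at least
#' one of the H, L or in-situ libraries, mirroring common practice of
#' analysing only abundant community members. The qualitative notions of
#' "enriched in heavy DNA" and "similar abundance in H and L" are made
#' operational by a fold threshold `fold_enrich` and a minimum H presence
#' `presence_min`; a pseudo-abundance `pseudo` guards ratios against zero
#' denominators.
#'
#' @param abund_filter strict lower bound on `max(h, l, insitu)`.
#' @param fold_enrich fold-change threshold F (`> 1`).
#' @param presence_min minimum H abundance for a type II call.
#' @param pseudo pseudo-abundance for ratio denominators.
#' @return an object of class `ecotype_config`.
#' @export
ecotype_config <- function(abund_filter = 0.01, fold_enrich = 3,
                           presence_min = 0.001, pseudo = 1e-6) {
  if (fold_enrich <= 1) stop_domain("'fold_enrich' must exceed 1")
  if (!(abund_filter > presence_min && presence_min > 0)) {
    stop_domain("need abund_filter > presence_min > 0")
  }
  check_scalar_num(pseudo, "pseudo", lower = 0, strict_lower = TRUE)
  structure(list(abund_filter = abund_filter, fold_enrich = fold_enrich,
                 presence_min = presence_min, pseudo = pseudo),
            class = "ecotype_config")
}

check_abund <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_domain("'", name, "' abundances must lie in [0, 1]")
  }
  x
}

align_otus <- function(h, l, is_) {
  if (is.null(names(h)) || is.null(names(l)) || is.null(names(is_))) {
    if (length(h) == length(l) && length(l) == length(is_)) {
      return(names(h) %||% paste0("otu", seq_along(h)))
    }
    stop_domain("unnamed abundance vectors must have equal length")
  }
  if (!setequal(names(h), names(l)) || !setequal(names(h), names(is_))) {
    stop_domain("h, l and in-situ vectors are not aligned on the same OTUs")
  }
  names(h)
}

#' Abundance screen for ecotype classification
#'
#' Keeps OTUs whose relative abundance strictly exceeds
#' `config$abund_filter` in at least one of the three libraries (H, L,
#' in-situ).
#'
#' @param h,l,is_ per-OTU relative abundance vectors, aligned by OTU name.
#' @param config an [ecotype_config()].
#' @return character vector of retained OTU ids.
#' @export
filter_abundant <- function(h, l, is_, config = ecotype_config()) {
  ids <- align_otus(h, l, is_)
  if (!is.null(names(h))) {
    l <- l[ids]; is_ <- is_[ids]; h <- h[ids]
  }
  check_abund(h, "h"); check_abund(l, "l"); check_abund(is_, "is_")
  ids[pmax(h, l, is_) > config$abund_filter]
}

#' Classify OTUs into ecological response types
#'
#' Rules applied in order, per OTU (F = `fold_enrich`, eps = `pseudo`):
#' type I when `h / max(l, is_, eps) >= F` (enriched in heavy DNA); type III
#' when `h < l` and `h < is_` (strictly lowest in the heavy fraction; ties
#' fall through, defaulting toward unclassified); type II when
#' `h >= presence_min` and `1/F < h / max(l, eps) < F` (present in H at an
#' abundance similar to L); otherwise unclassified. The rule order makes the
#' classes mutually exclusive and exhaustive.
#'
#' @param h,l,is_ per-OTU relative abundances in the heavy, light and
#'   in-situ libraries (vectors aligned by name, or equal-length).
#' @param config an [ecotype_config()].
#' @return `data.frame` with columns `otu`, `h`, `l`, `insitu`, `ecotype`
#'   (factor `I/II/III/unclassified`) and `rationale`.
#' @export
classify_otu <- function(h, l, is_, config = ecotype_config()) {
  ids <- align_otus(h, l, is_)
  if (!is.null(names(h))) {
    l <- l[ids]; is_ <- is_[ids]; h <- h[ids]
  }
  check_abund(h, "h"); check_abund(l, "l"); check_abund(is_, "is_")
  F_ <- config$fold_enrich
  eps <- config$pseudo
  ref_heavy <- pmax(l, is_, eps)
  ratio_hl <- h / pmax(l, eps)

  type <- rep("unclassified", length(h))
  why <- rep("no rule matched", length(h))

  i_call <- h / ref_heavy >= F_
  type[i_call] <- "I"
  why[i_call] <- sprintf(">=%g-fold enriched in H over max(L, in-situ)", F_)

  iii_call <- !i_call & h < l & h < is_
  type[iii_call] <- "III"
  why[iii_call] <- "strictly lowest abundance in H"

  ii_call <- !i_call & !iii_call & h >= config$presence_min &
    ratio_hl > 1 / F_ & ratio_hl < F_
  type[ii_call] <- "II"
  why[ii_call] <- "present in H at abundance similar to L"

  data.frame(otu = ids, h = unname(h), l = unname(l), insitu = unname(is_),
             ecotype = factor(type, levels = c("I", "II", "III",
                                               "unclassified")),
             rationale = why, stringsAsFactors = FALSE)
}

#' Full ecotype report from an OTU table with H/L/in-situ libraries
#'
#' Takes an OTU table containing exactly one sample for each of the roles
#' `H`, `L` and `in-situ`, rarefies the three libraries to a common depth,
#' applies the abundance screen and the type I/II/III classifier, and
#' aggregates calls by taxonomy group (clade-style summary with per-role
#' median abundances). OTUs failing the abundance screen are reported as
#' filtered.
#'
#' Type II calls made on incubations longer than `crossfeed_warn_days` are
#' flagged with a warning: in long incubations, taxa feeding on metabolites
#' or biomass of the primary incorporators (cross-feeding) can acquire label
#' and masquerade as slow incorporators.
#'
#' @param table a [otu_table()] with roles `H`, `L`, `in-situ`.
#' @param taxonomy optional per-OTU group strings named by OTU id (defaults
#'   to `table$otu_meta`, else one pooled group).
#' @param config an [ecotype_config()].
#' @param depth common rarefaction depth (default: the shallowest of the
#'   three libraries).
#' @param seed RNG seed for rarefaction.
#' @param crossfeed_warn_days incubation length, days, beyond which type II
#'   calls trigger the cross-feeding caveat.
#' @return list of class `ecotype_report`: `calls` (per-OTU, abundant OTUs
#'   only), `summary` (per taxonomy group), `n_filtered`, `depth`.
#' @export
ecotype_report <- function(table, taxonomy = NULL,
                           config = ecotype_config(), depth = NULL,
                           seed = NULL, crossfeed_warn_days = 2) {
  stopifnot(inherits(table, "sip_otu"))
  for (role in c("H", "L", "in-situ")) {
    k <- sum(table$meta$role == role)
    if (k != 1L) {
      stop_domain("need exactly one sample with role '", role,
                  "' (found ", k, ")")
    }
  }
  idx <- match(c("H", "L", "in-situ"), table$meta$role)
  sub3 <- otu_table(table$counts[idx, , drop = FALSE],
                    table$meta[idx, , drop = FALSE], table$otu_meta)
  depth <- depth %||% min(rowSums(sub3$counts))
  sub3 <- subsample_counts(sub3, depth, seed = seed)
  rel <- relative_abundance(sub3)
  h <- rel[sub3$meta$role == "H", ]
  l <- rel[sub3$meta$role == "L", ]
  is_ <- rel[sub3$meta$role == "in-situ", ]

  keep <- filter_abundant(h, l, is_, config)
  n_filtered <- length(h) - length(keep)
  if (!length(keep)) {
    stop_domain("no OTU passes the ", 100 * config$abund_filter,
                "% abundance screen")
  }
  calls <- classify_otu(h[keep], l[keep], is_[keep], config)

  t_inc <- table$meta$timepoint_days[idx[1]]
  if (!is.na(t_inc) && t_inc > crossfeed_warn_days &&
      any(calls$ecotype == "II")) {
    warning("type II calls after ", t_inc, " d of incubation may reflect ",
            "cross-feeding rather than direct substrate incorporation",
            call. = FALSE)
  }

  taxonomy <- taxonomy %||% table$otu_meta
  grp <- if (is.null(taxonomy)) rep("all", nrow(calls)) else {
    unname(taxonomy[calls$otu])
  }
  grp[is.na(grp)] <- "unassigned"
  calls$group <- grp
  summ <- do.call(rbind, lapply(split(calls, calls$group), function(g) {
    data.frame(group = g$group[1], n_otus = nrow(g),
               n_I = sum(g$ecotype == "I"), n_II = sum(g$ecotype == "II"),
               n_III = sum(g$ecotype == "III"),
               n_unclassified = sum(g$ecotype == "unclassified"),
               median_h = stats::median(g$h), median_l = stats::median(g$l),
               median_insitu = stats::median(g$insitu),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(calls = calls, summary = summ,
                 n_filtered = n_filtered, depth = depth),
            class = "ecotype_report")
}

#' @export
print.ecotype_report <- function(x, ...) {
  tab <- table(x$calls$ecotype)
  cat(sprintf("<ecotype_report> %d abundant OTUs at depth %d (%d filtered): I=%d II=%d III=%d unclassified=%d\n",
              nrow(x$calls), x$depth, x$n_filtered,
              tab["I"], tab["II"], tab["III"], tab["unclassified"]))
  invisible(x)
}

#' Write ecotype calls and summary as TSV
#'
#' @param report an [ecotype_report()].
#' @param calls_path,summary_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_ecotype_report <- function(report, calls_path = NULL,
                                 summary_path = NULL) {
  if (!is.null(calls_path)) {
    utils::write.table(report$calls, calls_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    utils::write.table(report$summary, summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(calls_path, summary_path))
}
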