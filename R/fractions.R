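# Analysis of DNA distributions across CsCl density-gradient fractions:
# peak detection, 13C-vs-12C profile separation, representative heavy/light
# fraction selection, and incubation-time selection.

#' Construct a gradient fraction set
#'
#' One ultracentrifuge tube's ordered fractions. Fractions are numbered
#' heavy-first (fraction 1 = highest density); inputs not sorted that way are
#' re-sorted with a warning.
#'
#' @param fraction integer fraction ids, unique.
#' @param density buoyant densities, g/mL.
#' @param dna_conc DNA concentrations, `>= 0` (arbitrary units).
#' @param failed logical: fingerprint/profile failed for this fraction (DNA
#'   concentration may still be measured).
#' @param treatment `"labeled"` or `"blank"`.
#' @param timepoint incubation time, days.
#' @param tube_id tube identifier.
#' @return an object of class `fraction_set`.
#' @export
fraction_set <- function(fraction, density, dna_conc, failed = FALSE,
                         treatment = c("labeled", "blank"),
                         timepoint = NA_real_, tube_id = "tube1") {
  treatment <- match.arg(treatment)
  n <- length(fraction)
  if (n < 1L) stop_domain("empty fraction set")
  if (anyDuplicated(fraction)) stop_domain("duplicate fraction ids")
  if (length(density) != n || length(dna_conc) != n) {
    stop_domain("'fraction', 'density', 'dna_conc' must have equal length")
  }
  if (any(!is.finite(density))) stop_domain("densities must be finite")
  if (any(!is.finite(dna_conc)) || any(dna_conc < 0)) {
    stop_domain("DNA concentrations must be finite and >= 0")
  }
  failed <- rep_len(as.logical(failed), n)
  df <- data.frame(fraction = as.integer(fraction), density = density,
                   dna_conc = dna_conc, failed = failed)
  if (is.unsorted(rev(df$density), strictly = TRUE)) {
    # enforce heavy-first ordering
    if (anyDuplicated(df$density)) stop_domain("densities must be distinct")
    warning("fractions not ordered heavy-first; re-sorting by density",
            call. = FALSE)
    df <- df[order(df$density, decreasing = TRUE), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(list(fractions = df, treatment = treatment,
                 timepoint = timepoint, tube_id = tube_id),
            class = "fraction_set")
}

#' @export
print.fraction_set <- function(x, ...) {
  cat(sprintf("<fraction_set> tube %s, %s, t = %s d: %d fractions (%d failed), %.4f-%.4f g/mL\n",
              x$tube_id, x$treatment, format(x$timepoint),
              nrow(x$fractions), sum(x$fractions$failed),
              min(x$fractions$density), max(x$fractions$density)))
  invisible(x)
}

# usable (profiled) fractions of a set
usable_fractions <- function(fs, include_failed = FALSE) {
  df <- fs$fractions
  if (!include_failed) df <- df[!df$failed, , drop = FALSE]
  df
}

weighted_mean_density <- function(fs, include_failed = FALSE) {
  df <- usable_fractions(fs, include_failed)
  sum(df$density * df$dna_conc) / sum(df$dna_conc)
}

#' Locate DNA concentration peaks across gradient fractions
#'
#' Normalises the concentration profile to relative shares and reports local
#' maxima: fractions whose concentration exceeds both neighbouring usable
#' fractions and whose topographic prominence reaches
#' `min_prominence * max(concentration)`. Plateaus (runs of equal values
#' above both flanks) count once, attributed to the heaviest (lowest-id)
#' fraction of the run; a flat profile has no peaks. Edge fractions, having
#' one neighbour, are never peaks.
#'
#' @param fs a [fraction_set()].
#' @param min_prominence prominence threshold as a fraction of the maximum
#'   concentration.
#' @param include_failed treat failed fractions as usable (their DNA
#'   concentration is typically still measured even when the community
#'   profile failed).
#' @return list of class `peak_report`: `peak_fraction_ids` (sorted by
#'   concentration, descending), `relative_profile` (named per-fraction DNA
#'   share, sums to 1), `weighted_mean_density` (g/mL).
#' @export
detect_peaks <- function(fs, min_prominence = 0.1, include_failed = FALSE) {
  df <- usable_fractions(fs, include_failed)
  if (nrow(df) < 3L) stop_domain("need at least 3 usable fractions")
  if (sum(df$dna_conc) <= 0) stop_domain("no DNA in any usable fraction")
  v <- df$dna_conc

  # collapse plateaus: runs of equal concentration
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  peaks <- integer(0)
  if (m >= 3L) {
    for (k in 2:(m - 1L)) {
      if (r$values[k] > r$values[k - 1L] && r$values[k] > r$values[k + 1L]) {
        # prominence: height above the key saddle on either side
        left <- min(r$values[seq_len(k - 1L)][
          rev(cumall_below(rev(r$values[seq_len(k - 1L)]), r$values[k]))])
        right <- min(r$values[(k + 1L):m][
          cumall_below(r$values[(k + 1L):m], r$values[k])])
        prom <- r$values[k] - max(left, right)
        if (prom >= min_prominence * max(v)) {
          peaks <- c(peaks, starts[k])   # heaviest fraction of the plateau
        }
      }
    }
  }
  ids <- df$fraction[peaks]
  ids <- ids[order(v[peaks], decreasing = TRUE)]
  structure(list(
    peak_fraction_ids = ids,
    relative_profile = stats::setNames(v / sum(v), df$fraction),
    weighted_mean_density = sum(df$density * v) / sum(v)
  ), class = "peak_report")
}

# TRUE for leading elements of x strictly below `lim` up to (excluding) the
# first element >= lim; used to bound the saddle search at the next
# higher-or-equal value
cumall_below <- function(x, lim) {
  out <- x < lim
  stop_at <- which(!out)
  if (length(stop_at)) out[stop_at[1]:length(out)] <- FALSE
  # an unbounded side (no higher value) searches to the edge
  if (!length(stop_at)) out[] <- TRUE
  out
}

#' Separation between 13C- and 12C-incubation DNA profiles
#'
#' Quantifies how far the labelled incubation's DNA has moved toward higher
#' buoyant density relative to the unlabelled (blank) incubation run on the
#' same fraction grid. The separation score is the difference in
#' DNA-weighted mean density; the profiles are called distinguishable when
#' the score reaches `min_shift` or when the share of DNA in the heavy half
#' of the gradient (densities at or above the grid median) grows by at least
#' `min_heavy_share_gain`.
#'
#' @param labeled,blank [fraction_set()] objects on the same fraction grid.
#' @param min_shift minimum weighted-mean density shift, g/mL.
#' @param min_heavy_share_gain minimum gain in heavy-half DNA share.
#' @return list: `separation_score` (g/mL), `heavy_share_gain`,
#'   `distinguishable` (logical).
#' @export
peak_separation <- function(labeled, blank, min_shift = 0.010,
                            min_heavy_share_gain = 0.15) {
  gl <- labeled$fractions; gb <- blank$fractions
  if (nrow(gl) != nrow(gb) ||
      any(gl$fraction != gb$fraction) ||
      any(abs(gl$density - gb$density) > 1e-9)) {
    stop_domain("labeled and blank sets are on different fraction grids")
  }
  score <- weighted_mean_density(labeled) - weighted_mean_density(blank)
  heavy_share <- function(fs) {
    df <- usable_fractions(fs)
    med <- stats::median(fs$fractions$density)
    sum(df$dna_conc[df$density >= med]) / sum(df$dna_conc)
  }
  gain <- heavy_share(labeled) - heavy_share(blank)
  list(separation_score = score,
       heavy_share_gain = gain,
       distinguishable = (score >= min_shift) || (gain >= min_heavy_share_gain))
}

#' Orient a two-group fraction clustering as heavy vs light
#'
#' Given a two-group labelling of the usable fractions (typically the
#' two-group cut of a community dendrogram), names the group with the larger
#' mean buoyant density the heavy group.
#'
#' @param fs a [fraction_set()].
#' @param groups either a list of two vectors of fraction ids, or a vector of
#'   group labels named by fraction id, covering all usable fractions.
#' @return list with sorted id vectors `heavy` and `light`.
#' @export
assign_heavy_light <- function(fs, groups) {
  if (!is.list(groups)) {
    if (is.null(names(groups))) {
      stop_domain("'groups' vector must be named by fraction id")
    }
    groups <- split(as.integer(names(groups)), groups)
  }
  if (length(groups) != 2L) stop_domain("need exactly 2 groups")
  usable <- usable_fractions(fs)$fraction
  cover <- sort(unlist(groups, use.names = FALSE))
  if (!setequal(cover, usable) || anyDuplicated(cover)) {
    stop_domain("groups must partition exactly the usable fractions")
  }
  dens <- stats::setNames(fs$fractions$density, fs$fractions$fraction)
  means <- vapply(groups, function(g) mean(dens[as.character(g)]), numeric(1))
  if (abs(diff(means)) < 1e-12) {
    stop_domain("degenerate clustering: groups have equal mean density")
  }
  hv <- which.max(means)
  list(heavy = sort(as.integer(groups[[hv]])),
       light = sort(as.integer(groups[[3L - hv]])))
}

# nearest non-failed fraction within a group; ties resolved heavier (lower id)
substitute_failed <- function(fs, id, group) {
  df <- fs$fractions
  if (!df$failed[df$fraction == id]) return(id)
  cand <- df$fraction[!df$failed & df$fraction %in% group]
  if (!length(cand)) {
    stop_domain("no non-failed fraction available in group {",
                paste(group, collapse = ","), "}")
  }
  dist <- abs(cand - id)
  cand <- cand[dist == min(dist)]
  min(cand)  # heavier fraction wins the tie
}

#' Select representative heavy and light fractions for sequencing
#'
#' The representative heavy (H) fraction is the highest-concentration DNA
#' peak of the labelled incubation lying in the heavy group; the light (L)
#' fraction is the labelled profile's peak in the light group, falling back
#' to the blank profile's peak there if the labelled profile has none.
#' Peaks are located on all fractions with measured DNA (including failed
#' ones); if a selected fraction is failed, the nearest non-failed fraction
#' within the same group substitutes (ties resolve to the heavier fraction).
#'
#' @param fs_labeled labelled-incubation [fraction_set()].
#' @param fs_blank optional blank [fraction_set()] (fallback for L).
#' @param heavy_group,light_group fraction id vectors from
#'   [assign_heavy_light()].
#' @param min_prominence passed to [detect_peaks()].
#' @return list: `h_fraction`, `l_fraction` (fraction ids), `h_density` and
#'   `l_density` (g/mL).
#' @export
select_representative_fractions <- function(fs_labeled, fs_blank = NULL,
                                            heavy_group, light_group,
                                            min_prominence = 0.1) {
  pk <- detect_peaks(fs_labeled, min_prominence, include_failed = TRUE)
  in_group <- function(ids, group) ids[ids %in% group]

  h_cand <- in_group(pk$peak_fraction_ids, heavy_group)
  if (!length(h_cand)) {
    stop_domain("no DNA peak inside the heavy group {",
                paste(heavy_group, collapse = ","), "}; peaks found at {",
                paste(pk$peak_fraction_ids, collapse = ","), "}")
  }
  l_cand <- in_group(pk$peak_fraction_ids, light_group)
  if (!length(l_cand) && !is.null(fs_blank)) {
    pkb <- detect_peaks(fs_blank, min_prominence, include_failed = TRUE)
    l_cand <- in_group(pkb$peak_fraction_ids, light_group)
  }
  if (!length(l_cand)) {
    stop_domain("no DNA peak inside the light group {",
                paste(light_group, collapse = ","), "}; peaks found at {",
                paste(pk$peak_fraction_ids, collapse = ","), "}")
  }
  h <- substitute_failed(fs_labeled, h_cand[1], heavy_group)
  l <- substitute_failed(fs_labeled, l_cand[1], light_group)
  dens <- stats::setNames(fs_labeled$fractions$density,
                          fs_labeled$fractions$fraction)
  list(h_fraction = h, l_fraction = l,
       h_density = unname(dens[as.character(h)]),
       l_density = unname(dens[as.character(l)]))
}

#' Split a gradient at the DNA trough between its two main bands
#'
#' Takes the two highest-concentration DNA peaks of the profile, finds the
#' minimum-concentration fraction strictly between them (the valley
#' separating the 13C and 12C DNA bands), and splits the fraction series
#' there: fractions heavier than the valley form one group, the valley and
#' everything lighter the other. Oriented by [assign_heavy_light()].
#'
#' @param fs a [fraction_set()].
#' @param min_prominence passed to [detect_peaks()].
#' @return list with id vectors `heavy` and `light`.
#' @export
valley_groups <- function(fs, min_prominence = 0.1) {
  pk <- detect_peaks(fs, min_prominence, include_failed = TRUE)
  if (length(pk$peak_fraction_ids) < 2L) {
    stop_domain("need two DNA peaks to delimit heavy and light bands")
  }
  top2 <- sort(pk$peak_fraction_ids[1:2])      # heavy-first ids: low = heavy
  df <- fs$fractions
  between <- df$fraction > top2[1] & df$fraction < top2[2]
  if (!any(between)) stop_domain("peaks are adjacent; no valley between them")
  valley <- df$fraction[between][which.min(df$dna_conc[between])]
  ok <- !df$failed     # groups must cover exactly the usable fractions
  groups <- list(df$fraction[ok & df$fraction < valley],
                 df$fraction[ok & df$fraction >= valley])
  assign_heavy_light(fs, groups)
}

#' Choose the incubation time that best resolves substrate incorporators
#'
#' A timepoint is eligible when its 13C/12C DNA peaks are distinguishable
#' and, where an ANOSIM p-value is available, the heavy-light community
#' difference is significant at `alpha`. Among eligible timepoints the one
#' with the greatest heavy-light community dissimilarity is chosen; ties go
#' to the earliest time, which minimises cross-feeding and bottle effects.
#'
#' @param records `data.frame` with columns `t` (days), `hl_dissimilarity`
#'   (Bray-Curtis, 0-1), `peaks_distinguishable` (logical), and optionally
#'   `anosim_r`, `anosim_p` (`NA` where the test could not be run).
#' @param alpha significance level for the ANOSIM eligibility screen.
#' @return list of class `timepoint_decision`: `records` (with an `eligible`
#'   column), `chosen_t` (`NA` if no timepoint qualifies), `diagnostic`.
#' @export
select_timepoint <- function(records, alpha = 0.05) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_domain("'records' must be a non-empty data.frame")
  }
  need <- c("t", "hl_dissimilarity", "peaks_distinguishable")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop_domain("records missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"anosim_p" %in% names(records)) records$anosim_p <- NA_real_
  records$eligible <- records$peaks_distinguishable &
    !is.na(records$hl_dissimilarity) &
    (is.na(records$anosim_p) | records$anosim_p < alpha)
  el <- records[records$eligible, , drop = FALSE]
  if (nrow(el) == 0L) {
    return(structure(list(records = records, chosen_t = NA_real_,
                          diagnostic = paste(
                            "no eligible timepoint:",
                            "13C/12C peaks never distinguishable",
                            "or community difference never significant")),
                     class = "timepoint_decision"))
  }
  best <- el[el$hl_dissimilarity == max(el$hl_dissimilarity), , drop = FALSE]
  chosen <- min(best$t)
  structure(list(records = records, chosen_t = chosen,
                 diagnostic = sprintf(
                   "chose t = %g d (H-L dissimilarity %.4f, %d of %d timepoints eligible)",
                   chosen, max(el$hl_dissimilarity), nrow(el), nrow(records))),
            class = "timepoint_decision")
}

#' @export
print.timepoint_decision <- function(x, ...) {
  cat("<timepoint_decision>", x$diagnostic, "\n")
  print(x$records, row.names = FALSE)
  invisible(x)
}
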