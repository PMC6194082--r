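# Carbon isotope mass balance for SIP incubations.
#
# delta-13C of particulate organic carbon (POC) measured against the VPDB
# standard is converted to the 13C/12C atom ratio, then to the mass of 13C in
# the POC pool, and finally (after blank correction against the parallel
# 12C-substrate incubation) to a microbial 13C assimilation rate and the
# percentage of 13C in the POC pool.

#' 13C/12C atom ratio of the VPDB reference standard
#'
#' Vienna Peedee Belemnite, the international carbon-isotope reference.
#' Although isotope reports often quote this quantity as an "atomic percent",
#' it enters the mass balance algebraically as the 13C/12C atom ratio, and
#' that is how it is used throughout this package.
#'
#' @format A length-one numeric, 0.0112372 (dimensionless atom ratio).
#' @export
vpdb_r13c <- 0.0112372

#' Convert delta-13C to a 13C/12C atom ratio
#'
#' `R_sample = (delta13c/1000 + 1) * r_ref`. The physical lower limit
#' `delta13c = -1000` permil corresponds to carbon containing no 13C at all.
#'
#' @param delta13c delta-13C in permil versus VPDB; numeric vector.
#' @param r_ref atom ratio of the reference standard (default VPDB).
#' @return 13C/12C atom ratio(s), always `>= 0`.
#' @seealso [ratio_to_delta()] for the inverse.
#' @examples
#' delta_to_ratio(0)        # the reference ratio itself
#' delta_to_ratio(-29.53)   # a typical organic-carbon value
#' @export
delta_to_ratio <- function(delta13c, r_ref = vpdb_r13c) {
  check_scalar_num(r_ref, "r_ref", lower = 0, strict_lower = TRUE)
  if (!is.numeric(delta13c) || any(!is.finite(delta13c))) {
    stop_domain("'delta13c' must be finite numeric")
  }
  if (any(delta13c < -1000)) {
    stop_domain("delta13c < -1000 permil implies a negative atom ratio")
  }
  (delta13c / 1000 + 1) * r_ref
}

#' Convert a 13C/12C atom ratio to delta-13C
#'
#' Algebraic inverse of [delta_to_ratio()]; used by the forward simulator to
#' emit delta-13C values whose mass-balance inversion is exact.
#'
#' @param r_sample sample atom ratio(s), `>= 0`.
#' @param r_ref reference atom ratio (default VPDB).
#' @return delta-13C in permil versus the reference.
#' @export
ratio_to_delta <- function(r_sample, r_ref = vpdb_r13c) {
  check_scalar_num(r_ref, "r_ref", lower = 0, strict_lower = TRUE)
  if (!is.numeric(r_sample) || any(!is.finite(r_sample)) || any(r_sample < 0)) {
    stop_domain("'r_sample' must be finite and >= 0")
  }
  (r_sample / r_ref - 1) * 1000
}

#' Mass of 13C in a carbon pool
#'
#' `m13 = 13 * m_poc * R / (13 * R + 12)`: the exact mass fraction of 13C in
#' carbon whose 13C/12C atom ratio is `R`, applied to the POC mass.
#'
#' @param m_poc POC mass (ug C per litre of incubated seawater); `>= 0`.
#' @param r_sample 13C/12C atom ratio; `>= 0`.
#' @return mass of 13C, ug per litre; strictly less than `m_poc` for finite
#'   ratios and monotonically increasing in `r_sample`.
#' @export
mass_13c <- function(m_poc, r_sample) {
  if (!is.numeric(m_poc) || any(!is.finite(m_poc)) || any(m_poc < 0)) {
    stop_domain("'m_poc' must be finite and >= 0")
  }
  if (!is.numeric(r_sample) || any(!is.finite(r_sample)) || any(r_sample < 0)) {
    stop_domain("'r_sample' must be finite and >= 0")
  }
  13 * m_poc * r_sample / (13 * r_sample + 12)
}

#' Microbial 13C assimilation rate
#'
#' Blank-corrected rate `(m13_sample - m13_blank) / t`, where the blank is the
#' parallel incubation with the unlabelled (12C) substrate. Negative values
#' can arise from measurement noise and are returned with a warning rather
#' than clamped, so noise behaviour stays inspectable.
#'
#' @param m13c_sample 13C mass in the labelled incubation (ug/L).
#' @param m13c_blank 13C mass in the 12C-substrate blank (ug/L).
#' @param t incubation time in days; must be `> 0`.
#' @return assimilation rate, ug 13C per litre per day.
#' @export
assimilation_rate <- function(m13c_sample, m13c_blank, t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0)) {
    stop_domain("incubation time 't' must be > 0")
  }
  rate <- (m13c_sample - m13c_blank) / t
  if (any(rate < 0)) {
    warning("negative blank-corrected assimilation rate; ",
            "blank exceeded labelled sample (measurement noise?)",
            call. = FALSE)
  }
  rate
}

#' Fraction of 13C in the POC pool
#'
#' `(m13_sample - m13_blank) / m_poc`, reported as a fraction (multiply by
#' 100 for percent). Shares its numerator with [assimilation_rate()], so
#' `percent * m_poc == rate * t` identically.
#'
#' @param m13c_sample 13C mass in the labelled incubation (ug/L).
#' @param m13c_blank 13C mass in the blank (ug/L).
#' @param m_poc total POC mass (ug/L); must be `> 0`.
#' @return fraction of 13C in the POC pool.
#' @export
percent_13c_in_poc <- function(m13c_sample, m13c_blank, m_poc) {
  if (!is.numeric(m_poc) || any(!is.finite(m_poc)) || any(m_poc <= 0)) {
    stop_domain("'m_poc' must be > 0")
  }
  (m13c_sample - m13c_blank) / m_poc
}

#' Read an isotope measurement table
#'
#' CSV with columns `sample,treatment,delta13c_poc_permil,m_poc_ug_per_l,
#' time_days` (an optional `substrate` column is carried through). Treatment
#' must be `labeled` or `blank`.
#'
#' @param path path to the CSV file.
#' @return a `data.frame` of validated measurements.
#' @export
read_isotope_table <- function(path) {
  if (!file.exists(path)) stop_domain("isotope table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "treatment", "delta13c_poc_permil",
            "m_poc_ug_per_l", "time_days")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_domain("isotope table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(df$treatment %in% c("labeled", "blank"))) {
    stop_domain("treatment must be 'labeled' or 'blank'")
  }
  if (any(!is.finite(df$delta13c_poc_permil)) ||
      any(df$delta13c_poc_permil < -1000)) {
    stop_domain("delta13c_poc_permil must be finite and >= -1000")
  }
  if (any(!is.finite(df$m_poc_ug_per_l)) || any(df$m_poc_ug_per_l < 0)) {
    stop_domain("m_poc_ug_per_l must be finite and >= 0")
  }
  df
}

#' Assimilation rates and 13C percentages from paired incubations
#'
#' Pairs each labelled measurement with the blank for the same `sample` and
#' `time_days`, runs the full mass-balance chain (delta-13C to atom ratio to
#' 13C mass to blank-corrected rate), and reports one row per pair in a
#' layout mirroring a rate table: `sample, substrate, time_days,
#' assimilation_rate_ug_l_d, percent_13c` (percent on the 0-100 scale).
#'
#' @param measurements `data.frame` as returned by [read_isotope_table()], or
#'   [simulate_poc_timeseries()].
#' @param r_ref reference atom ratio (default VPDB).
#' @return a `data.frame`, one row per (sample, time) pair.
#' @export
assimilation_report <- function(measurements, r_ref = vpdb_r13c) {
  df <- measurements
  need <- c("sample", "treatment", "delta13c_poc_permil",
            "m_poc_ug_per_l", "time_days")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_domain("measurements missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"substrate" %in% names(df)) df$substrate <- NA_character_
  lab <- df[df$treatment == "labeled", , drop = FALSE]
  blk <- df[df$treatment == "blank", , drop = FALSE]
  if (nrow(lab) == 0L || nrow(blk) == 0L) {
    stop_domain("need at least one labelled and one blank measurement")
  }
  m <- merge(lab, blk, by = c("sample", "time_days"),
             suffixes = c("_lab", "_blk"))
  if (nrow(m) == 0L) {
    stop_domain("no (sample, time_days) pair has both treatments")
  }
  m13_lab <- mass_13c(m$m_poc_ug_per_l_lab,
                      delta_to_ratio(m$delta13c_poc_permil_lab, r_ref))
  m13_blk <- mass_13c(m$m_poc_ug_per_l_blk,
                      delta_to_ratio(m$delta13c_poc_permil_blk, r_ref))
  out <- data.frame(
    sample = m$sample,
    substrate = m$substrate_lab,
    time_days = m$time_days,
    assimilation_rate_ug_l_d = assimilation_rate(m13_lab, m13_blk, m$time_days),
    percent_13c = 100 * percent_13c_in_poc(m13_lab, m13_blk,
                                           m$m_poc_ug_per_l_lab),
    stringsAsFactors = FALSE
  )
  out[order(out$sample, out$time_days), , drop = FALSE]
}

#' Write an assimilation report as TSV
#'
#' @param report `data.frame` from [assimilation_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assimilation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
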