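# Forward simulator of a DNA-SIP experiment.
#
# A synthetic bacterioplankton community is incubated with a 13C-labelled
# one-carbon substrate. Taxa that incorporate the substrate replicate their
# DNA with heavy carbon, shifting part of it to higher buoyant density in a
# CsCl gradient. The simulator produces the observables of the real
# experiment -- per-fraction DNA concentrations, per-fraction sequencing
# reads, a delta-13C POC time series -- together with the planted ground
# truth every downstream method is validated against.

#' CsCl gradient configuration
#'
#' Geometry and physics of the simulated density gradient. Defaults follow a
#' 12-fraction gradient spanning 1.687-1.770 g/mL (fraction 1 heaviest), the
#' standard linear GC/buoyant-density relation rho = 1.660 + 0.098 GC, a full
#' 13C-label density shift of 0.036 g/mL, and a 99 atom% 13C substrate.
#'
#' @param n_fractions number of equal fractions the gradient is divided into.
#' @param density_heavy,density_light gradient limits, g/mL.
#' @param band_sigma within-gradient spread of a single DNA band, g/mL.
#' @param full_label_shift density shift of fully 13C-substituted DNA, g/mL.
#' @param substrate_atom_fraction 13C atom fraction of the labelled substrate.
#' @param dna_noise_cv coefficient of variation of multiplicative lognormal
#'   noise on measured fraction DNA concentrations.
#' @param bd_intercept,bd_gc_slope coefficients of the GC/density relation.
#' @param seed default RNG seed for gradients simulated with this config.
#' @return an object of class `gradient_config`.
#' @export
gradient_config <- function(n_fractions = 12L,
                            density_heavy = 1.770,
                            density_light = 1.687,
                            band_sigma = 0.005,
                            full_label_shift = 0.036,
                            substrate_atom_fraction = 0.99,
                            dna_noise_cv = 0.05,
                            bd_intercept = 1.660,
                            bd_gc_slope = 0.098,
                            seed = NULL) {
  if (n_fractions < 2L) stop_domain("'n_fractions' must be >= 2")
  if (density_heavy <= density_light) {
    stop_domain("'density_heavy' must exceed 'density_light'")
  }
  check_scalar_num(band_sigma, "band_sigma", lower = 0, strict_lower = TRUE)
  check_scalar_num(full_label_shift, "full_label_shift",
                   lower = 0, strict_lower = TRUE)
  check_scalar_num(substrate_atom_fraction, "substrate_atom_fraction",
                   lower = 0, upper = 1)
  check_scalar_num(dna_noise_cv, "dna_noise_cv", lower = 0)
  structure(list(n_fractions = as.integer(n_fractions),
                 density_heavy = density_heavy,
                 density_light = density_light,
                 band_sigma = band_sigma,
                 full_label_shift = full_label_shift,
                 substrate_atom_fraction = substrate_atom_fraction,
                 dna_noise_cv = dna_noise_cv,
                 bd_intercept = bd_intercept,
                 bd_gc_slope = bd_gc_slope,
                 seed = seed),
            class = "gradient_config")
}

#' Buoyant density of DNA from GC content and 13C labelling
#'
#' Linear model `rho = bd_intercept + bd_gc_slope * gc +
#' labeled_atom_fraction * full_label_shift` (g/mL).
#'
#' @param gc_fraction molar GC fraction of the DNA, in `[0, 1]`.
#' @param labeled_atom_fraction 13C atom fraction of the DNA's carbon due to
#'   labelling, in `[0, 1]` (0 = natural, unlabelled DNA).
#' @param config a [gradient_config()].
#' @return buoyant density in g/mL.
#' @examples
#' buoyant_density(0.5)       # 1.709, unlabelled mid-GC DNA
#' buoyant_density(0.5, 1.0)  # + 0.036 full-label shift
#' @export
buoyant_density <- function(gc_fraction, labeled_atom_fraction = 0,
                            config = gradient_config()) {
  if (any(!is.finite(gc_fraction)) || any(gc_fraction < 0) ||
      any(gc_fraction > 1)) {
    stop_domain("'gc_fraction' must lie in [0, 1]")
  }
  if (any(!is.finite(labeled_atom_fraction)) ||
      any(labeled_atom_fraction < 0) || any(labeled_atom_fraction > 1)) {
    stop_domain("'labeled_atom_fraction' must lie in [0, 1]")
  }
  config$bd_intercept + config$bd_gc_slope * gc_fraction +
    labeled_atom_fraction * config$full_label_shift
}

#' Generate a synthetic bacterioplankton community
#'
#' Relative abundances are drawn from a long-tailed lognormal and normalised
#' to sum to one. `n_rapid` taxa are planted as rapid substrate incorporators
#' (ecological type I) and are drawn from the rarer half of the community,
#' reflecting that rapid C1-incorporators tend to be rare in situ; `n_slow`
#' taxa are slow/minor incorporators (type II); the rest do not incorporate
#' the substrate (type III). GC content is drawn from a truncated normal
#' typical of marine bacterioplankton. Incorporators label their DNA as
#' `1 - exp(-t/tau)` and grow exponentially; non-incorporators neither label
#' nor grow.
#'
#' @param n_taxa total number of taxa.
#' @param n_rapid,n_slow numbers of planted rapid and slow incorporators;
#'   `n_rapid + n_slow <= n_taxa`.
#' @param seed integer RNG seed; identical seeds give identical communities.
#' @param abund_sdlog lognormal shape of the rank-abundance curve.
#' @param gc_mean,gc_sd,gc_range GC-content distribution (truncated normal).
#' @param tau_rapid,tau_slow labelling time constants in days. Defaults put
#'   rapid taxa above 50% labelled DNA by day 1 and slow taxa above 50% only
#'   by day 4.
#' @param growth_rapid,growth_slow growth rates in doublings per day.
#' @param with_sequences also generate random 16S-like sequences (starting at
#'   the forward-primer position) for in-silico T-RF digestion.
#' @param seq_length length of generated sequences, nt.
#' @return a `data.frame` of class `sip_community` with columns `taxon_id`,
#'   `gc`, `base_abundance`, `true_type`, `tau`, `growth_rate` and optionally
#'   `seq`.
#' @export
make_community <- function(n_taxa, n_rapid = 0L, n_slow = 0L, seed = NULL,
                           abund_sdlog = 1.5,
                           gc_mean = 0.5, gc_sd = 0.05,
                           gc_range = c(0.35, 0.65),
                           tau_rapid = 0.5, tau_slow = 3,
                           growth_rapid = 1, growth_slow = 0.5,
                           with_sequences = FALSE, seq_length = 900L) {
  if (n_taxa < 1L || n_rapid < 0L || n_slow < 0L) {
    stop_domain("taxon counts must be non-negative (n_taxa >= 1)")
  }
  if (n_rapid + n_slow > n_taxa) {
    stop_domain("n_rapid + n_slow must not exceed n_taxa")
  }
  with_seed(seed, {
    ab <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = abund_sdlog)
    ab <- ab / sum(ab)
    # truncated normal GC via inverse-CDF so no mass piles at the bounds
    plo <- stats::pnorm(gc_range[1], gc_mean, gc_sd)
    phi <- stats::pnorm(gc_range[2], gc_mean, gc_sd)
    gc <- stats::qnorm(stats::runif(n_taxa, plo, phi), gc_mean, gc_sd)

    type <- rep("none", n_taxa)
    ord <- order(ab)                      # ascending abundance
    if (n_rapid > 0L) {
      # rare-but-detectable stratum: 20th-50th percentile of abundance
      lo <- max(1L, ceiling(0.2 * n_taxa))
      hi <- max(lo + n_rapid - 1L, floor(0.5 * n_taxa))
      pool <- ord[seq(lo, min(hi, n_taxa))]
      type[sample(pool, n_rapid)] <- "rapid"
    }
    if (n_slow > 0L) {
      pool <- which(type == "none")
      type[sample(pool, n_slow)] <- "slow"
    }

    com <- data.frame(
      taxon_id = sprintf("otu%03d", seq_len(n_taxa)),
      gc = gc,
      base_abundance = ab,
      true_type = factor(type, levels = c("rapid", "slow", "none")),
      tau = ifelse(type == "rapid", tau_rapid,
                   ifelse(type == "slow", tau_slow, NA_real_)),
      growth_rate = ifelse(type == "rapid", growth_rapid,
                           ifelse(type == "slow", growth_slow, 0)),
      stringsAsFactors = FALSE
    )
    if (with_sequences) {
      com$seq <- vapply(gc, random_16s, character(1), len = seq_length)
    }
    class(com) <- c("sip_community", "data.frame")
    com
  })
}

# random 16S-like sequence starting at the 27F forward-primer position
# (degenerate M resolved to A), tail base composition matching the taxon GC
random_16s <- function(gc, len = 900L) {
  primer <- "AGAGTTTGATCATGGCTCAG"
  ntail <- max(0L, len - nchar(primer))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  tail <- paste(sample(names(p), ntail, replace = TRUE, prob = p),
                collapse = "")
  paste0(primer, tail)
}

#' Fraction of a taxon's DNA that is isotopically labelled at time t
#'
#' `1 - exp(-t/tau)` for planted incorporators, 0 for non-incorporators.
#' Non-decreasing in `t`.
#'
#' @param community a `sip_community`.
#' @param t time in days, `>= 0`.
#' @return numeric vector, one value per taxon, in `[0, 1]`.
#' @export
labeled_fraction <- function(community, t) {
  check_scalar_num(t, "t", lower = 0)
  lf <- ifelse(is.na(community$tau), 0, 1 - exp(-t / community$tau))
  pmin(pmax(lf, 0), 1)
}

#' Multiplicative biomass change of each taxon by time t
#'
#' `2^(growth_rate * t)`; non-incorporators default to growth rate 0
#' (factor 1).
#'
#' @inheritParams labeled_fraction
#' @return numeric vector of growth factors.
#' @export
growth_factor <- function(community, t) {
  check_scalar_num(t, "t", lower = 0)
  2^(community$growth_rate * t)
}

#' Simulate one CsCl density-gradient run
#'
#' Fraction densities are the midpoints of `n_fractions` equal intervals
#' spanning the gradient, numbered heavy-first (fraction 1 = heaviest). Each
#' taxon's DNA (mass `base_abundance * growth_factor(t)`) splits into an
#' unlabelled band centred at `buoyant_density(gc, 0)` and a labelled band at
#' `buoyant_density(gc, substrate_atom_fraction)`, weighted by
#' `1 - labeled_fraction(t)` and `labeled_fraction(t)`. Band mass per
#' fraction is the Gaussian (sd `band_sigma`) integral over the fraction's
#' density interval. Measured fraction concentrations get multiplicative
#' lognormal noise (unit mean, cv `dna_noise_cv`). The `blank` treatment (12C
#' substrate) forces the labelled fraction to zero for every taxon but keeps
#' growth, since the unlabelled substrate is consumed all the same.
#'
#' @param community a `sip_community`.
#' @param t incubation time, days (`>= 0`).
#' @param treatment `"labeled"` or `"blank"`.
#' @param config a [gradient_config()].
#' @param seed RNG seed for the concentration noise (default: `config$seed`).
#' @param tube_id identifier for the simulated tube.
#' @return a list of class `sip_gradient` with elements `fractions` (a
#'   [fraction_set()]), `mass` (noise-free fractions x taxa DNA mass),
#'   `mass_labeled`, `mass_unlabeled` (same shape, per band), and
#'   `labeled_peak_fraction` (ground truth: fraction with the most labelled
#'   DNA, `NA` if no DNA is labelled).
#' @export
simulate_gradient <- function(community, t, treatment = c("labeled", "blank"),
                              config = gradient_config(), seed = NULL,
                              tube_id = NULL) {
  treatment <- match.arg(treatment)
  check_scalar_num(t, "t", lower = 0)
  n <- config$n_fractions
  w <- (config$density_heavy - config$density_light) / n
  upper <- config$density_heavy - w * (seq_len(n) - 1L)   # heavy-first
  lower <- upper - w
  mids <- (upper + lower) / 2

  lf <- if (treatment == "blank") rep(0, nrow(community)) else {
    labeled_fraction(community, t)
  }
  mass_tot <- community$base_abundance * growth_factor(community, t)
  centre_u <- buoyant_density(community$gc, 0, config)
  centre_l <- buoyant_density(community$gc, config$substrate_atom_fraction,
                              config)

  band_split <- function(centres, masses) {
    # fractions x taxa matrix of band mass integrated over each interval;
    # evaluated from both tails so far-off bands keep a nonzero (tiny)
    # weight instead of underflowing to 1 - 1 = 0
    vapply(seq_along(centres), function(k) {
      lo <- stats::pnorm(upper, centres[k], config$band_sigma) -
        stats::pnorm(lower, centres[k], config$band_sigma)
      hi <- stats::pnorm(lower, centres[k], config$band_sigma,
                         lower.tail = FALSE) -
        stats::pnorm(upper, centres[k], config$band_sigma,
                     lower.tail = FALSE)
      masses[k] * pmax(lo, hi, 0)
    }, numeric(n))
  }
  m_unlab <- band_split(centre_u, mass_tot * (1 - lf))
  m_lab <- band_split(centre_l, mass_tot * lf)
  mass <- m_unlab + m_lab
  dimnames(mass) <- dimnames(m_lab) <- dimnames(m_unlab) <-
    list(paste0("F", seq_len(n)), community$taxon_id)

  conc <- rowSums(mass)
  cv <- config$dna_noise_cv
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    noise <- with_seed(seed %||% config$seed,
                       stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog))
    conc <- conc * noise
  }

  lab_tot <- rowSums(m_lab)
  structure(list(
    fractions = fraction_set(
      fraction = seq_len(n), density = mids, dna_conc = conc,
      failed = FALSE, treatment = treatment, timepoint = t,
      tube_id = tube_id %||% sprintf("sim_%s_t%g", treatment, t)),
    mass = mass,
    mass_labeled = m_lab,
    mass_unlabeled = m_unlab,
    labeled_peak_fraction = if (sum(lab_tot) > 0) which.max(lab_tot)
                            else NA_integer_
  ), class = "sip_gradient")
}

#' Simulate sequencing reads from per-fraction DNA masses
#'
#' Each row (fraction sample) of the mass table is sequenced to `depth` reads
#' drawn multinomially with probabilities proportional to per-taxon DNA mass
#' in that fraction.
#'
#' @param mass fractions x taxa numeric matrix (e.g. `$mass` from
#'   [simulate_gradient()]), or a single named vector for one sample.
#' @param depth reads per sample, `> 0`.
#' @param seed RNG seed.
#' @param sample_ids sample identifiers (default: row names of `mass`).
#' @param role,treatment,timepoint,fraction metadata recycled across samples.
#' @return a [otu_table()] with one row per fraction sample.
#' @export
simulate_reads <- function(mass, depth, seed = NULL, sample_ids = NULL,
                           role = "fraction", treatment = NA_character_,
                           timepoint = NA_real_, fraction = NA_integer_) {
  if (is.null(dim(mass))) mass <- matrix(mass, nrow = 1,
                                         dimnames = list("s1", names(mass)))
  if (depth <= 0) stop_domain("'depth' must be > 0")
  if (any(mass < 0) || any(!is.finite(mass))) {
    stop_domain("DNA masses must be finite and >= 0")
  }
  zero <- rowSums(mass) == 0
  if (any(zero)) {
    stop_domain("nothing to sequence: all-zero DNA mass in sample(s) ",
                paste(rownames(mass)[zero], collapse = ", "))
  }
  counts <- with_seed(seed, t(apply(mass, 1, function(p) {
    stats::rmultinom(1, size = depth, prob = p)[, 1]
  })))
  dimnames(counts) <- dimnames(mass)
  ids <- sample_ids %||% rownames(mass)
  rownames(counts) <- ids
  meta <- data.frame(sample = ids, role = rep_len(role, length(ids)),
                     treatment = rep_len(treatment, length(ids)),
                     timepoint_days = rep_len(timepoint, length(ids)),
                     fraction = rep_len(fraction, length(ids)),
                     stringsAsFactors = FALSE)
  otu_table(counts, meta)
}

#' Incubation scenario for the delta-13C POC time series
#'
#' @param substrate substrate identity, `"MOH"` (methanol) or `"MMA"`
#'   (methylamine); informational.
#' @param substrate_conc substrate concentration, uM; informational.
#' @param timepoints sampling times in days, strictly increasing, all `> 0`.
#' @param m_poc0 initial POC standing stock, ug C/L.
#' @param planted_rates per-taxon blank-corrected 13C assimilation rates,
#'   ug 13C/L/day (named vector or single total).
#' @param natural_delta delta-13C of the unamended POC pool, permil.
#' @param substrate_atom_fraction 13C atom fraction of the labelled substrate.
#' @param label sample id stamped on emitted measurements.
#' @return an object of class `incubation_scenario`.
#' @export
incubation_scenario <- function(substrate = c("MOH", "MMA"),
                                substrate_conc = 100,
                                timepoints = c(1, 2, 4),
                                m_poc0 = 600,
                                planted_rates = 10,
                                natural_delta = -22,
                                substrate_atom_fraction = 0.99,
                                label = "site1_5m") {
  substrate <- match.arg(substrate)
  if (length(timepoints) < 1L || any(timepoints <= 0) ||
      any(diff(timepoints) <= 0)) {
    stop_domain("'timepoints' must be strictly increasing and > 0")
  }
  check_scalar_num(m_poc0, "m_poc0", lower = 0, strict_lower = TRUE)
  if (any(planted_rates < 0)) stop_domain("planted rates must be >= 0")
  structure(list(substrate = substrate, substrate_conc = substrate_conc,
                 timepoints = timepoints, m_poc0 = m_poc0,
                 planted_rates = planted_rates,
                 natural_delta = natural_delta,
                 substrate_atom_fraction = substrate_atom_fraction,
                 label = label),
            class = "incubation_scenario")
}

#' Simulate a delta-13C POC time series from planted assimilation rates
#'
#' Exact forward model of the isotope mass balance. Planted rates are
#' *blank-corrected excess* 13C assimilation rates: both treatments
#' assimilate the same total carbon `c(t) = rho_tot * t / (w_sub - w_nat)`
#' (where `w_sub`, `w_nat` are the 13C mass fractions of the substrate and of
#' natural-abundance carbon), the labelled treatment at the substrate's
#' isotopic composition and the blank at natural abundance. Consequently the
#' blank's delta-13C stays exactly at the natural background, POC mass is
#' identical across treatments, and the mass-balance chain
#' ([assimilation_report()]) recovers `sum(planted_rates)` exactly.
#' delta-13C is emitted through atom-count bookkeeping
#' (`n13 = m13/13`, `n12 = (m_poc - m13)/12`, `R = n13/n12`), the exact
#' algebraic inverse of the analysis equations.
#'
#' @param scenario an [incubation_scenario()].
#' @param r_ref reference atom ratio (default VPDB).
#' @param delta_sd optional measurement noise, permil (default 0 = noise
#'   free); applied to emitted delta-13C values.
#' @param seed RNG seed for measurement noise.
#' @return a `data.frame` of measurements (both treatments at every
#'   timepoint) in the layout accepted by [assimilation_report()], with the
#'   planted total rate attached as attribute `planted_total_rate`.
#' @export
simulate_poc_timeseries <- function(scenario, r_ref = vpdb_r13c,
                                    delta_sd = 0, seed = NULL) {
  stopifnot(inherits(scenario, "incubation_scenario"))
  rho <- sum(scenario$planted_rates)
  r_nat <- delta_to_ratio(scenario$natural_delta, r_ref)
  w_nat <- 13 * r_nat / (13 * r_nat + 12)
  x <- scenario$substrate_atom_fraction
  w_sub <- 13 * x / (13 * x + 12 * (1 - x))
  if (w_sub <= w_nat) {
    stop_domain("substrate 13C content must exceed natural abundance")
  }
  rows <- list()
  for (t in scenario$timepoints) {
    assimilated <- rho * t / (w_sub - w_nat)
    m_poc <- scenario$m_poc0 + assimilated
    for (trt in c("labeled", "blank")) {
      m13 <- w_nat * m_poc + if (trt == "labeled") rho * t else 0
      if (m13 > m_poc) {
        stop_domain("planted rates imply more 13C than total POC at t = ", t)
      }
      n13 <- m13 / 13
      n12 <- (m_poc - m13) / 12
      delta <- ratio_to_delta(n13 / n12, r_ref)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = scenario$label, substrate = scenario$substrate,
        treatment = trt, delta13c_poc_permil = delta,
        m_poc_ug_per_l = m_poc, time_days = t, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (delta_sd > 0) {
    out$delta13c_poc_permil <- with_seed(seed,
      out$delta13c_poc_permil + stats::rnorm(nrow(out), 0, delta_sd))
  }
  attr(out, "planted_total_rate") <- rho
  out
}
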