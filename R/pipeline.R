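# End-to-end orchestration: simulate a SIP experiment, analyse the density
# gradients, pick representative H/L fractions and the incubation time,
# compare communities, and classify ecotypes. Every stochastic stage draws
# its seed deterministically from the master seed, so a run is reproducible
# bit-for-bit from its manifest.

# fixed offsets for per-stage seed derivation (recorded in the manifest)
.seed_offsets <- c(community = 1L, gradient = 100L, reads = 200L,
                   libraries = 300L, subsample = 400L, nmds = 500L,
                   anosim = 600L)

#' Simulate a complete SIP experiment
#'
#' Builds a community with planted incorporators, runs labelled and blank
#' density gradients at every timepoint, sequences the labelled gradient's
#' fractions, and simulates the delta-13C POC time series.
#'
#' @param n_taxa,n_rapid,n_slow community composition (see
#'   [make_community()]).
#' @param timepoints incubation times, days.
#' @param config a [gradient_config()].
#' @param scenario an [incubation_scenario()] for the POC time series
#'   (defaults to one scaled to the community size).
#' @param fraction_depth reads per gradient fraction (fingerprinting depth).
#' @param seed master seed.
#' @return list of class `sip_experiment`: `community`, `runs` (per
#'   timepoint: `labeled`/`blank` [simulate_gradient()] results and
#'   `reads_labeled`), `isotope` (measurement table), `seed`.
#' @export
simulate_sip_experiment <- function(n_taxa = 100L, n_rapid = 5L,
                                    n_slow = 10L, timepoints = c(1, 2, 4),
                                    config = gradient_config(),
                                    scenario = NULL,
                                    fraction_depth = 5000L, seed = 1L) {
  community <- make_community(n_taxa, n_rapid, n_slow,
                              seed = derive_seed(seed, .seed_offsets["community"]))
  runs <- list()
  for (k in seq_along(timepoints)) {
    t <- timepoints[k]
    glab <- simulate_gradient(community, t, "labeled", config,
                              seed = derive_seed(seed, .seed_offsets["gradient"] + 2L * k))
    gblk <- simulate_gradient(community, t, "blank", config,
                              seed = derive_seed(seed, .seed_offsets["gradient"] + 2L * k + 1L))
    reads <- simulate_reads(glab$mass, fraction_depth,
                            seed = derive_seed(seed, .seed_offsets["reads"] + k),
                            sample_ids = sprintf("t%g_labeled_F%d", t,
                                                 seq_len(config$n_fractions)),
                            role = "fraction", treatment = "labeled",
                            timepoint = t,
                            fraction = seq_len(config$n_fractions))
    runs[[as.character(t)]] <- list(labeled = glab, blank = gblk,
                                    reads_labeled = reads)
  }
  scenario <- scenario %||% incubation_scenario(
    timepoints = timepoints,
    planted_rates = stats::setNames(
      ifelse(community$true_type == "rapid", 5,
             ifelse(community$true_type == "slow", 1, 0)),
      community$taxon_id))
  structure(list(community = community, runs = runs,
                 isotope = simulate_poc_timeseries(scenario),
                 scenario = scenario, config = config, seed = seed),
            class = "sip_experiment")
}

#' Analyse one timepoint of a SIP experiment
#'
#' The standard per-timepoint SIP workflow: test 13C-vs-12C profile
#' separation, cluster the labelled gradient's fraction communities
#' (Bray-Curtis + UPGMA two-group cut), orient the clusters as heavy/light,
#' select the representative H and L fractions, measure their community
#' dissimilarity, and (when both groups have at least two fractions) test
#' the heavy-light split by ANOSIM.
#'
#' @param glab,gblk labelled and blank [simulate_gradient()] results (or
#'   lists with `$fractions`).
#' @param reads fraction-level [otu_table()] for the labelled gradient.
#' @param n_perm,alpha ANOSIM permutations and significance level.
#' @param seed RNG seed for the ANOSIM permutations.
#' @return list: `record` (one row for [select_timepoint()]), `groups`,
#'   `selection`, `separation`, `anosim` (possibly `NULL`).
#' @export
analyze_sip_timepoint <- function(glab, gblk, reads, n_perm = 999L,
                                  alpha = 0.05, seed = NULL) {
  sep <- peak_separation(glab$fractions, gblk$fractions)
  d <- bray_curtis_matrix(reads)
  tree <- upgma_cluster(d)
  # map dendrogram labels back to fraction ids
  fr_of <- stats::setNames(reads$meta$fraction, reads$meta$sample)
  cut2 <- tree$two_groups
  groups <- split(unname(fr_of[names(cut2)]), cut2)
  hl <- assign_heavy_light(glab$fractions, groups)
  # a timepoint whose gradient has no selectable peak in one of the groups
  # (e.g. too little labelled DNA yet) is recorded as unusable, not fatal
  try_select <- function(hl) tryCatch(
    select_representative_fractions(glab$fractions, gblk$fractions,
                                    hl$heavy, hl$light),
    error = function(e) structure(list(note = conditionMessage(e)),
                                  class = "selection_failure"))
  selection <- try_select(hl)
  if (inherits(selection, "selection_failure")) {
    # the community two-group cut can strand the labelled peak when the
    # heavy-light transition is gradual; fall back to delimiting the groups
    # at the DNA-concentration trough between the two main bands
    hl2 <- tryCatch(valley_groups(glab$fractions), error = function(e) NULL)
    if (!is.null(hl2)) {
      sel2 <- try_select(hl2)
      if (!inherits(sel2, "selection_failure")) {
        hl <- hl2
        selection <- sel2
      }
    }
  }
  if (inherits(selection, "selection_failure")) {
    hl_diss <- NA_real_
  } else {
    s_of <- stats::setNames(reads$meta$sample, reads$meta$fraction)
    hs <- s_of[as.character(selection$h_fraction)]
    ls <- s_of[as.character(selection$l_fraction)]
    hl_diss <- d[hs, ls]
  }

  ano <- NULL
  if (length(hl$heavy) >= 2L && length(hl$light) >= 2L) {
    lab <- ifelse(unname(fr_of[rownames(d)]) %in% hl$heavy, "H", "L")
    ano <- anosim_test(d, lab, n_perm = n_perm, seed = seed)
  }
  t <- glab$fractions$timepoint
  list(record = data.frame(t = t, hl_dissimilarity = hl_diss,
                           peaks_distinguishable = sep$distinguishable,
                           anosim_r = if (is.null(ano)) NA_real_ else
                             unname(ano$statistic),
                           anosim_p = if (is.null(ano)) NA_real_ else
                             ano$p.value),
       groups = hl, selection = selection, separation = sep,
       dissimilarity = d, tree = tree, anosim = ano)
}

#' Run the full SIP analysis pipeline
#'
#' Stages, in the order of the underlying workflow: `simulate` (synthetic
#' experiment and its file artifacts), `isotope` (mass-balance rate table),
#' `fractions`/`select` (per-timepoint gradient analysis and incubation-time
#' choice), `compare` (NMDS, ANOSIM, Shannon, UPGMA dendrogram at the chosen
#' timepoint), `ecotype` (H/L/in-situ libraries and type I/II/III calls).
#' `stage = "all"` runs everything. Every artifact lands under `out_dir`
#' together with a JSON manifest (configuration echo, derived seeds, file
#' digests) sufficient to reproduce the run.
#'
#' @param out_dir output directory (created if absent).
#' @param stage one of `"all"`, `"simulate"`, `"isotope"`, `"fractions"`,
#'   `"select"`, `"compare"`, `"ecotype"`. Stages after `simulate` re-derive
#'   the experiment deterministically from `seed`.
#' @param seed master seed; all stage seeds derive from it.
#' @param n_taxa,n_rapid,n_slow,timepoints,fraction_depth passed to
#'   [simulate_sip_experiment()].
#' @param library_depth reads for the H, L and in-situ libraries.
#' @param n_perm,alpha ANOSIM parameters.
#' @param config a [gradient_config()].
#' @param eco_config an [ecotype_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the main in-memory results (`experiment`,
#'   `records`, `decision`, `ecotype`, `manifest`).
#' @export
run_pipeline <- function(out_dir, stage = "all", seed = 1L,
                         n_taxa = 100L, n_rapid = 5L, n_slow = 10L,
                         timepoints = c(1, 2, 4),
                         fraction_depth = 5000L, library_depth = 20000L,
                         n_perm = 999L, alpha = 0.05,
                         config = gradient_config(),
                         eco_config = ecotype_config(),
                         quiet = FALSE) {
  stage <- match.arg(stage, c("all", "simulate", "isotope", "fractions",
                              "select", "compare", "ecotype"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  path <- function(f) file.path(out_dir, f)

  # the experiment is a pure function of the seed, so later stages can
  # re-derive it instead of reading intermediate state
  exper <- simulate_sip_experiment(n_taxa, n_rapid, n_slow, timepoints,
                                   config = config,
                                   fraction_depth = fraction_depth,
                                   seed = seed)
  want <- function(s) stage %in% c("all", s)
  results <- list(experiment = exper)

  if (want("simulate")) {
    say("stage simulate: writing experiment artifacts")
    fsets <- unlist(lapply(exper$runs, function(r) {
      list(r$labeled$fractions, r$blank$fractions)
    }), recursive = FALSE)
    write_fraction_table(fsets, path("fractions.csv"))
    allreads <- lapply(exper$runs, `[[`, "reads_labeled")
    merged <- otu_table(do.call(rbind, lapply(allreads, `[[`, "counts")),
                        do.call(rbind, lapply(allreads, `[[`, "meta")))
    write_otu_table(merged, path("otu_fractions.tsv"))
    utils::write.csv(exper$isotope, path("isotope.csv"), row.names = FALSE)
    truth <- list(
      taxa = exper$community$taxon_id,
      true_type = as.character(exper$community$true_type),
      planted_rates = as.list(exper$scenario$planted_rates),
      labeled_peak_fraction = lapply(exper$runs, function(r) {
        r$labeled$labeled_peak_fraction
      }))
    jsonlite::write_json(truth, path("truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  if (want("isotope")) {
    say("stage isotope: mass-balance assimilation rates")
    rep_ <- assimilation_report(exper$isotope)
    write_assimilation_report(rep_, path("assimilation.tsv"))
    results$assimilation <- rep_
  }

  analyses <- NULL
  if (want("fractions") || want("select") || want("compare") ||
      want("ecotype")) {
    say("stage fractions/select: gradient analysis per timepoint")
    analyses <- lapply(seq_along(timepoints), function(k) {
      r <- exper$runs[[k]]
      analyze_sip_timepoint(r$labeled, r$blank, r$reads_labeled,
                            n_perm = n_perm, alpha = alpha,
                            seed = derive_seed(seed, .seed_offsets["anosim"] + k))
    })
    records <- do.call(rbind, lapply(analyses, `[[`, "record"))
    decision <- select_timepoint(records, alpha = alpha)
    results$analyses <- analyses
    results$records <- decision$records
    results$decision <- decision
    jsonlite::write_json(list(
      records = decision$records, chosen_t = decision$chosen_t,
      diagnostic = decision$diagnostic,
      selections = lapply(analyses, function(a) unclass(a$selection)),
      groups = lapply(analyses, `[[`, "groups")),
      path("selection.json"), auto_unbox = TRUE, digits = NA, na = "null")
  }

  chosen_k <- if (!is.null(analyses) && !is.na(results$decision$chosen_t)) {
    match(results$decision$chosen_t, timepoints)
  } else NA_integer_
  if (!is.na(chosen_k)) results$selection <- analyses[[chosen_k]]$selection

  if (want("compare")) {
    if (is.na(chosen_k)) {
      say("stage compare: skipped (no eligible timepoint)")
    } else {
      say("stage compare: ordination and diversity at t = ",
          timepoints[chosen_k], " d")
      an <- analyses[[chosen_k]]
      nm <- nmds_embed(an$dissimilarity,
                       seed = derive_seed(seed, .seed_offsets["nmds"]))
      utils::write.table(
        data.frame(sample = rownames(nm$points), nm$points,
                   stress = nm$stress),
        path("nmds.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      reads <- exper$runs[[chosen_k]]$reads_labeled
      sh <- apply(reads$counts, 1, shannon_index)
      utils::write.table(data.frame(sample = names(sh), shannon = sh),
                         path("shannon.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_newick(an$tree, path("dendrogram.nwk"))
      if (!is.null(an$anosim)) {
        jsonlite::write_json(list(R = unname(an$anosim$statistic),
                                  p = an$anosim$p.value,
                                  permutations = an$anosim$permutations),
                             path("anosim.json"), auto_unbox = TRUE,
                             digits = NA)
      }
      results$nmds <- nm
    }
  }

  if (want("ecotype")) {
    if (is.na(chosen_k)) {
      say("stage ecotype: skipped (no eligible timepoint)")
    } else {
      t <- timepoints[chosen_k]
      say("stage ecotype: H/L/in-situ libraries at t = ", t, " d")
      an <- analyses[[chosen_k]]
      glab <- exper$runs[[chosen_k]]$labeled
      mass_hl <- glab$mass[c(an$selection$h_fraction,
                             an$selection$l_fraction), , drop = FALSE]
      insitu_mass <- stats::setNames(exper$community$base_abundance,
                                     exper$community$taxon_id)
      mass3 <- rbind(mass_hl, insitu = insitu_mass)
      rownames(mass3) <- c("H_lib", "L_lib", "insitu_lib")
      libs <- simulate_reads(
        mass3, library_depth,
        seed = derive_seed(seed, .seed_offsets["libraries"]),
        role = c("H", "L", "in-situ"), treatment = "labeled", timepoint = t,
        fraction = c(an$selection$h_fraction, an$selection$l_fraction, NA))
      write_otu_table(libs, path("otu_libraries.tsv"))
      eco <- ecotype_report(libs, config = eco_config,
                            seed = derive_seed(seed, .seed_offsets["subsample"]))
      write_ecotype_report(eco, path("ecotype_calls.tsv"),
                           path("ecotype_summary.tsv"))
      results$ecotype <- eco
      results$recovery <- ecotype_recovery(eco$calls, exper$community)
    }
  }

  manifest <- list(
    package = "sipgrad",
    version = as.character(utils::packageVersion("sipgrad")),
    stage = stage, seed = seed,
    derived_seed_offsets = as.list(.seed_offsets),
    parameters = list(n_taxa = n_taxa, n_rapid = n_rapid, n_slow = n_slow,
                      timepoints = timepoints,
                      fraction_depth = fraction_depth,
                      library_depth = library_depth, n_perm = n_perm,
                      alpha = alpha,
                      gradient = unclass(config),
                      ecotype = unclass(eco_config)),
    artifacts = as.list(tools::md5sum(
      list.files(out_dir, full.names = TRUE, pattern = "\\.(csv|tsv|json|nwk)$")))
  )
  names(manifest$artifacts) <- basename(names(manifest$artifacts))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  results$manifest <- manifest
  invisible(results)
}

#' Compare ecotype calls with the simulator's planted truth
#'
#' Sensitivity for type I is the share of planted rapid incorporators called
#' type I; the incorporation false-positive rate is the share of planted
#' non-incorporators called type I or II. Taxa removed by the abundance
#' screen count as not called.
#'
#' @param calls `calls` data.frame from [ecotype_report()].
#' @param community the `sip_community` the experiment was simulated from.
#' @return list: `sensitivity_I`, `sensitivity_incorporation` (I or II call
#'   on any planted incorporator), `fpr_incorporation`, `n_rapid`, `n_slow`,
#'   `n_none`.
#' @export
ecotype_recovery <- function(calls, community) {
  called <- stats::setNames(as.character(calls$ecotype), calls$otu)
  type_of <- function(id) {
    v <- called[id]
    ifelse(is.na(v), "unclassified", v)
  }
  rapid <- community$taxon_id[community$true_type == "rapid"]
  slow <- community$taxon_id[community$true_type == "slow"]
  none <- community$taxon_id[community$true_type == "none"]
  incorp <- c(rapid, slow)
  list(
    sensitivity_I = if (length(rapid)) mean(type_of(rapid) == "I") else NA,
    sensitivity_incorporation = if (length(incorp)) {
      mean(type_of(incorp) %in% c("I", "II"))
    } else NA,
    fpr_incorporation = if (length(none)) {
      mean(type_of(none) %in% c("I", "II"))
    } else NA,
    n_rapid = length(rapid), n_slow = length(slow), n_none = length(none))
}
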