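# End-to-end orchestration: per-pair analysis (metrics -> environment ->
# rotamer categories -> deltas -> summary) and cohort-level statistics.

#' Pipeline configuration
#'
#' Collects the analysis thresholds: binding-site and distant-residue
#' distance cutoffs, the RASA exposure threshold, hydrogen-bond criteria,
#' the order-parameter normalization, ligand qualification rules and the
#' Bonferroni family size.
#'
#' @param binding_site_cutoff,distant_cutoff Angstrom.
#' @param exposure_threshold RASA fraction.
#' @param hbond_cutoff H-acceptor distance, Angstrom.
#' @param hbond_min_angle Minimum D-H-A angle, degrees.
#' @param normalization A [norm_config()].
#' @param min_ligand_heavy Minimum ligand heavy atoms.
#' @param min_ligand_occ Minimum ligand occupancy.
#' @param bonferroni_m Hypothesis count for the ligand quartile tests.
#' @param sasa_points Sphere points for solvent accessibility.
#' @param sasa_scope `"all"` residues, or `"distant"` to compute solvent
#'   exposure only where the buried/exposed split is consumed.
#' @param hbonds Compute hydrogen-bond summaries in [run_pair()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(binding_site_cutoff = 5.0, distant_cutoff = 10.0,
                            exposure_threshold = 0.20, hbond_cutoff = 3.2,
                            hbond_min_angle = 90,
                            normalization = norm_config(),
                            min_ligand_heavy = 10, min_ligand_occ = 0.15,
                            bonferroni_m = 10, sasa_points = 960,
                            sasa_scope = c("all", "distant"),
                            hbonds = TRUE) {
  sasa_scope <- match.arg(sasa_scope)
  stopifnot(binding_site_cutoff > 0, distant_cutoff > 0,
            exposure_threshold > 0, exposure_threshold < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Analyse one apo/holo pair
#'
#' Runs the per-pair pipeline: role checks, per-residue order-parameter
#' metrics for both structures, the spatial environment of the holo
#' structure, rotamer-change classification, holo-minus-apo deltas, the
#' occupancy-weighted binding-site hydrogen-bond difference and the pair
#' summary.
#'
#' @param apo,holo [structure_model()]s or PDB file paths.
#' @param ligand_id Ligand residue code; defaults to the first qualifying
#'   ligand of the holo structure.
#' @param config A [pipeline_config()].
#' @param pair_id Identifier for the output tables.
#' @param out_dir Optional directory: the result tables are written as CSV.
#' @return List with metrics_apo, metrics_holo, environment, rotamers,
#'   deltas, summary.
#' @export
run_pair <- function(apo, holo, ligand_id = NULL,
                     config = pipeline_config(), pair_id = NULL,
                     out_dir = NULL) {
  if (is.character(apo)) apo <- read_pdb(apo)
  if (is.character(holo)) holo <- read_pdb(holo)
  if (is.null(pair_id)) pair_id <- paste0(holo$id, "__", apo$id)

  if (classify_role(apo, min_heavy = config$min_ligand_heavy) != "apo")
    stop("role error: the apo structure contains a qualifying ligand")
  if (classify_role(holo, min_heavy = config$min_ligand_heavy) != "holo")
    stop("role error: the holo structure contains no qualifying ligand")
  ligs <- qualifying_ligands(holo, min_heavy = config$min_ligand_heavy)
  if (!is.null(ligand_id)) {
    ligs <- ligs[vapply(ligs, `[[`, "", "aa") == ligand_id]
    if (!length(ligs)) stop("ligand id not found in holo structure: ",
                            ligand_id)
  }
  ligand <- ligs[[1]]

  metrics_apo <- structure_metrics(apo, cfg = config$normalization)
  metrics_holo <- structure_metrics(holo, cfg = config$normalization)
  env <- environment_table(holo, ligand,
                           binding_cutoff = config$binding_site_cutoff,
                           distant_cutoff = config$distant_cutoff,
                           exposure_threshold = config$exposure_threshold,
                           sasa_scope = config$sasa_scope,
                           n_points = config$sasa_points)

  sets_apo <- residue_rotamer_sets(apo)
  sets_holo <- residue_rotamer_sets(holo)
  common <- intersect(names(sets_apo), names(sets_holo))
  categories <- vapply(common, function(k)
    classify_pair_rotamers(sets_apo[[k]], sets_holo[[k]]), "")

  deltas <- pair_residue_deltas(metrics_apo, metrics_holo, env,
                                rotamer_categories = categories,
                                pair_id = pair_id)

  hb_delta <- NA_real_
  if (isTRUE(config$hbonds)) {
    bs <- binding_site_residues(holo, ligand,
                                cutoff = config$binding_site_cutoff)
    hb_holo <- weighted_hbond_count(holo, bs,
                                    h_a_cutoff = config$hbond_cutoff,
                                    min_dha = config$hbond_min_angle)
    hb_apo <- weighted_hbond_count(apo, bs,
                                   h_a_cutoff = config$hbond_cutoff,
                                   min_dha = config$hbond_min_angle)
    hb_delta <- hb_holo - hb_apo
  }
  summary <- pair_summary(deltas, hbond_delta = hb_delta)

  out <- list(metrics_apo = metrics_apo, metrics_holo = metrics_holo,
              environment = env, rotamers = data.frame(
                residue = common, category = unname(categories),
                stringsAsFactors = FALSE),
              deltas = deltas, summary = summary)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(out))
      utils::write.csv(out[[nm]],
                       file.path(out_dir, paste0(pair_id, "_", nm, ".csv")),
                       row.names = FALSE)
  }
  out
}

#' Cohort-level statistics over analysed pairs
#'
#' Aggregates [run_pair()] results: the per-pair summary table, paired
#' Wilcoxon tests of the binding-site and all-residue deltas, the
#' matched-control comparison (Mann-Whitney U of per-pair binding-site
#' means against matched non-binding-site control means), the residual
#' regression of distant-buried changes on binding-site changes, category
#' summaries, and (when a control cohort of pair results is supplied) a
#' bootstrap comparison of the two residual-regression slopes.
#'
#' @param pair_results List of [run_pair()] results.
#' @param config A [pipeline_config()].
#' @param control_results Optional control cohort (e.g. apo/apo pairs).
#' @param n_boot Bootstrap replicates for the slope comparison.
#' @param control_draws Matched-control draws per pair (0 skips the
#'   matched-control comparison).
#' @return List with summaries, deltas, paired tests, matched-control test,
#'   regression, categories, and optionally bootstrap.
#' @export
run_cohort <- function(pair_results, config = pipeline_config(),
                       control_results = NULL, n_boot = 1000,
                       control_draws = 100) {
  if (!length(pair_results)) stop("no pair results supplied")
  summaries <- do.call(rbind, lapply(pair_results, `[[`, "summary"))
  deltas <- do.call(rbind, lapply(pair_results, `[[`, "deltas"))

  bs_means <- summaries$mean_delta_s2_bs
  control_means <- rep(NA_real_, length(pair_results))
  if (control_draws > 0)
    control_means <- vapply(pair_results, function(pr)
      as.numeric(matched_control_delta(pr$deltas, n_draws = control_draws)),
      0)

  out <- list(
    summaries = summaries,
    deltas = deltas,
    median_delta_s2_bs = stats::median(bs_means, na.rm = TRUE),
    median_delta_s2_control = stats::median(control_means, na.rm = TRUE),
    paired_bs = paired_test(bs_means),
    matched_control = if (control_draws > 0)
      group_test(bs_means[is.finite(bs_means)],
                 control_means[is.finite(control_means)]) else NULL,
    regression = residual_regression(summaries, subset = "distant_buried"),
    categories = summarize_categories(deltas),
    mean_hbond_delta = mean(summaries$hbond_delta, na.rm = TRUE))
  if (!is.null(control_results)) {
    ctrl <- do.call(rbind, lapply(control_results, `[[`, "summary"))
    out$bootstrap <- bootstrap_slope_compare(summaries, ctrl,
                                             n_boot = n_boot)
  }
  out
}
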