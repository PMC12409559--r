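## End-to-end workflow: align -> displacement profiles -> B aggregation
## and normalization -> thermal fits -> water/ligand fits ->
## cross-correlations -> ensemble comparison, with TSV outputs and a
## run log.

#' Pipeline configuration
#'
#' @param altloc_policy passed to [read_structure()].
#' @param fit_selection superposition selection, `"calpha"` or
#'   `"backbone"`.
#' @param water_cutoff conserved-water match cutoff, Angstrom.
#' @param conserved_frac fraction of structures a water must appear in
#'   to count as conserved.
#' @param min_coverage minimum residue coverage for per-residue fits.
#' @param residue_range optional residue numbers for the global
#'   displacement averages (default: all shared residues).
#' @param override_table optional named temperature overrides.
#' @param seed seed echoed into the run log (the analysis itself is
#'   deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(altloc_policy = "highest_occupancy",
                            fit_selection = "calpha", water_cutoff = 1.0,
                            conserved_frac = 1.0, min_coverage = 2 / 3,
                            residue_range = NULL, override_table = NULL,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

.pipe_tsv <- function(x, dir, name) {
  utils::write.table(as.data.frame(x), file.path(dir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

.fit_row <- function(fit, label) {
  if (is.null(fit)) return(NULL)
  data.frame(channel = label, amplitude = fit$amplitude, k = fit$k,
             pearson_r = fit$pearson_r, ci_low = fit$r_ci95[1],
             ci_high = fit$r_ci95[2], p = fit$p_two_tailed,
             n = fit$n_points, converged = fit$converged,
             stringsAsFactors = FALSE)
}

.cor_row <- function(cr, label) {
  data.frame(panel = label, pearson_r = cr$pearson_r, ci_low = cr$r_ci95[1],
             ci_high = cr$r_ci95[2], p = cr$p_two_tailed, n = cr$n,
             x_transform = cr$x_transform, stringsAsFactors = FALSE)
}

#' Run the full temperature-series analysis
#'
#' Executes the whole workflow on a manifest (or an in-memory series):
#' superposition onto the reference, per-residue displacement and
#' B-factor profiles, global and per-residue thermal fits (raw and
#' normalized B; linear displacement slopes), water census and
#' non-protein component fits, the four B-vs-plasticity correlations
#' and sequence trends, plus per-structure summary metadata. Results
#' are returned and, when `out_dir` is given, written as TSV tables
#' with a plain-text run log.
#'
#' @param manifest path to a series manifest TSV, or a
#'   [temperature_series()].
#' @param out_dir optional output directory for TSV tables and the log.
#' @param reference_id reference structure (default: the manifest's
#'   first entry).
#' @param config a [pipeline_config()].
#' @return invisible list with elements `series`, `summary`,
#'   `global_fits`, `profile_fits` (per selection/response),
#'   `displacement_fits`, `water_census`, `component_fits`,
#'   `correlations`, `sequence_trends`.
#' @export
run_pipeline <- function(manifest, out_dir = NULL, reference_id = NULL,
                         config = pipeline_config()) {
  t0 <- Sys.time()
  series <- if (inherits(manifest, "temperature_series")) manifest
            else read_series(manifest, reference_id = reference_id,
                             altloc_policy = config$altloc_policy,
                             override_table = config$override_table)
  log <- c(sprintf("run_pipeline started %s", format(t0)),
           sprintf("seed: %s", config$seed),
           sprintf("structures: %d, reference: %s", length(series$models),
                   series$reference_id),
           paste0("config: ", paste(names(config), vapply(config, function(v)
             paste(format(v), collapse = ","), character(1)),
             sep = "=", collapse = "; ")))
  aligned <- align_series(series, config$fit_selection)
  summary <- summary_stats(aligned$models)

  global <- global_b_fits(series)

  profile_fits <- list()
  for (sel in c("calpha", "side_chain"))
    for (resp in c("b_raw", "b_norm"))
      profile_fits[[paste(sel, resp, sep = "_")]] <-
        fit_profile_series(series, sel, resp, "exponential",
                           min_coverage = config$min_coverage)
  displacement_fits <- list(
    calpha = fit_profile_series(series, response = "d_calpha",
                                model_form = "linear",
                                min_coverage = config$min_coverage),
    side_chain = fit_profile_series(series, response = "d_side_chain",
                                    model_form = "linear",
                                    min_coverage = config$min_coverage))

  census <- water_census(series)
  component_fits <- list()
  for (comp in c("all_water", "conserved_water", "ion", "ligand")) {
    component_fits[[comp]] <- tryCatch(
      component_thermal_fit(aligned, comp, cutoff = config$water_cutoff,
                            conserved_frac = config$conserved_frac),
      error = function(e) {
        log <<- c(log, sprintf("component %s skipped: %s", comp,
                               conditionMessage(e)))
        NULL
      })
  }

  correlations <- b_vs_plasticity(
    displacement_fits,
    list(calpha = profile_fits$calpha_b_raw,
         side_chain = profile_fits$side_chain_b_raw))
  sequence_trends <- list(
    calpha_k = sequence_trend(profile_fits$calpha_b_raw, "k"),
    side_chain_k = sequence_trend(profile_fits$side_chain_b_raw, "k"),
    calpha_norm_k = sequence_trend(profile_fits$calpha_b_norm, "k"),
    side_chain_norm_k = sequence_trend(profile_fits$side_chain_b_norm, "k"))

  res <- list(series = series, summary = summary, global_fits = global,
              profile_fits = profile_fits,
              displacement_fits = displacement_fits,
              water_census = census, component_fits = component_fits,
              correlations = correlations, sequence_trends = sequence_trends)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    .pipe_tsv(summary, out_dir, "summary.tsv")
    glob <- do.call(rbind, Filter(Negate(is.null), list(
      .fit_row(global$wilson, "wilson"),
      .fit_row(global$side_chain, "side_chain_avg"),
      .fit_row(global$calpha, "calpha_avg"))))
    .pipe_tsv(glob, out_dir, "global_fits.tsv")
    for (nm in names(profile_fits))
      write_fits(profile_fits[[nm]], file.path(out_dir, paste0("fits_", nm, ".tsv")))
    for (nm in names(displacement_fits))
      write_fits(displacement_fits[[nm]],
                 file.path(out_dir, paste0("fits_displacement_", nm, ".tsv")))
    .pipe_tsv(census, out_dir, "water_census.tsv")
    comp <- do.call(rbind, Filter(Negate(is.null), Map(.fit_row,
      component_fits, names(component_fits))))
    if (!is.null(comp)) .pipe_tsv(comp, out_dir, "component_fits.tsv")
    cors <- do.call(rbind, c(Map(.cor_row, correlations, names(correlations)),
                             Map(.cor_row, sequence_trends,
                                 paste0("trend_", names(sequence_trends)))))
    .pipe_tsv(cors, out_dir, "correlations.tsv")
    log <- c(log, sprintf("finished %s (%.1f s)", format(Sys.time()),
                          as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  invisible(res)
}
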