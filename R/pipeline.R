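#' Pipeline configuration with study defaults
#'
#' Collects every tunable of the end-to-end analysis. Defaults are the
#' method's canonical parameters: small window 51 probes, broad window 641
#' reduced sites (~32 Mb on a ~1M-probe array, so events shorter than
#' ~16 Mb are focal), calling threshold 3 epsilon, peak scanning window 41
#' sites with height floor 8, 500 bootstrap resamples, alpha 0.05, CI width
#' cap 1 Mb, fewer than 4 normal-sample events, CNP screening at 5 epsilon.
#'
#' @param w,wb Decomposition windows (probes / reduced sites).
#' @param k Calling threshold multiplier.
#' @param peak_window Peak scanning window in reduced sites.
#' @param min_height Peak height floor in samples.
#' @param B Bootstrap resamples for peak-position CIs.
#' @param alpha Significance level of the asymmetry criterion.
#' @param max_ci_width CI width cap in base pairs.
#' @param max_normal_events Normal-event cap (strictly fewer required).
#' @param cnp_k Threshold multiplier for normal-tissue CNP screening.
#' @param cnp_fence Tukey fence multiplier for CNP outlier removal.
#' @param sided Sidedness of the asymmetry criterion.
#' @param seed Seed governing the bootstrap stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(w = 51L, wb = 641L, k = 3, peak_window = 41L,
                            min_height = 8L, B = 500L, alpha = 0.05,
                            max_ci_width = 1e6, max_normal_events = 4,
                            cnp_k = 5, cnp_fence = 3, sided = "two",
                            seed = 1L) {
  structure(list(w = as.integer(w), wb = as.integer(wb), k = k,
                 peak_window = as.integer(peak_window),
                 min_height = min_height, B = as.integer(B), alpha = alpha,
                 max_ci_width = max_ci_width,
                 max_normal_events = max_normal_events, cnp_k = cnp_k,
                 cnp_fence = cnp_fence, sided = sided,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full focal-region discovery pipeline
#'
#' Decompose every tumor profile, call three-state focal events, aggregate
#' the cohort frequency track, locate gain and loss peaks, attach bootstrap
#' confidence intervals, screen normal tissue for copy-number polymorphisms
#' (when normals are supplied), apply the four region-selection criteria,
#' and — when a gene annotation is supplied — map genes into the selected
#' regions and test the oncogene/TSG association.
#'
#' @param tumors List of tumor [probe_profile] objects.
#' @param normals Optional list of normal [probe_profile] objects.
#' @param genes Optional gene annotation data frame.
#' @param config A [pipeline_config].
#' @param out_dir Optional directory; when given, intermediate artifacts are
#'   written there (calls.seg, track.tsv, regions.bed, regions.tsv).
#' @return List with `decomposed`, `calls`, `track`, `peaks`, `regions`,
#'   `cnp_summary`, `normal_calls`, `enrichment` and the `config`.
#' @export
run_end_to_end <- function(tumors, normals = NULL, genes = NULL,
                           config = pipeline_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  decomposed <- stage("decompose",
                      decompose_cohort(tumors, w = config$w, wb = config$wb))
  calls <- stage("call", call_cohort(decomposed, k = config$k))
  track <- stage("aggregate", aggregate_frequency_track(calls))
  peaks <- stage("peaks",
                 find_peaks(track, "both", window = config$peak_window,
                            min_height = config$min_height))
  peaks <- stage("bootstrap",
                 bootstrap_peak_ci(calls, peaks, B = config$B,
                                   seed = config$seed))
  cnp_summary <- NULL
  normal_calls <- NULL
  if (!is.null(normals) && length(normals) > 0) {
    dn <- stage("decompose_normals",
                decompose_cohort(normals, w = config$w, wb = config$wb))
    cnp_summary <- stage("cnp", {
      s <- count_cnp_per_normal_sample(dn, k = config$cnp_k)
      if (nrow(s) >= 5L) flag_cnp_outliers(s, rule = config$cnp_fence)
      else { s$outlier <- FALSE; s }
    })
    keep <- cnp_summary$sample_id[!cnp_summary$outlier]
    normal_calls <- stage("call_normals",
                          call_cohort(dn[keep], k = config$k))
  }
  regions <- stage("regions",
                   select_focal_regions(peaks, track, normal_calls,
                                        alpha = config$alpha,
                                        max_ci_width = config$max_ci_width,
                                        max_normal_events = config$max_normal_events,
                                        min_height = config$min_height,
                                        sided = config$sided))
  enrichment <- NULL
  if (!is.null(genes) && any(regions$selected)) {
    sel <- regions[regions$selected, , drop = FALSE]
    enrichment <- stage("enrich", {
      mapping <- map_genes_to_regions(sel, genes)
      tab <- driver_contingency(mapping)
      test <- if (sum(tab) > 0) driver_contingency_test(tab) else NULL
      list(mapping = mapping, table = tab, test = test)
    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_calls_seg(calls, file.path(out_dir, "calls.seg"))
    utils::write.table(track, file.path(out_dir, "track.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(regions),
                       file.path(out_dir, "regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (any(regions$selected))
      write_regions_bed(regions[regions$selected, , drop = FALSE],
                        file.path(out_dir, "regions.bed"))
  }
  list(decomposed = decomposed, calls = calls, track = track, peaks = peaks,
       regions = regions, cnp_summary = cnp_summary,
       normal_calls = normal_calls, enrichment = enrichment, config = config)
}
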