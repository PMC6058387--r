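#' @title Full-pipeline orchestration and power comparison
#' @description Runs the complete analysis on a synthetic cohort —
#'   simulate, normalize, PCA, cell-type marker calling, aging and Braak
#'   association scans per cell fraction, cross-cell-type meta-analysis,
#'   overlap summaries and bulk deconvolution — writing tab-separated result
#'   tables plus a JSON run manifest. Also provides the sorted-versus-bulk
#'   detection-power comparison for planted Braak effects under
#'   age/disease-correlated cell-composition drift.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Bundles all thresholds and cohort sizes with validation. Defaults follow
#' the conventional analysis choices: detection-p 0.01, cell-type difference
#' threshold 0.20 beta at Bonferroni 0.05, 600 reference markers, top-1000
#' overlap lists.
#'
#' @param seed Integer seed (mandatory; drives every random draw).
#' @param n_probes Probes in the synthetic design.
#' @param n_sorted Donors in the sorted cohort (samples per fraction).
#' @param n_bulk Bulk samples.
#' @param delta_min Cell-type difference threshold (default 0.20).
#' @param alpha Bonferroni level for marker calling (default 0.05).
#' @param k_markers Reference-panel size (default 600).
#' @param top_k Overlap list length (default 1000).
#' @param n_components Principal components to keep (default 10).
#' @param design_args Named list of overrides passed to
#'   [make_default_design()].
#' @return A `ctewas_pipeline_config` list.
#' @export
pipeline_config <- function(seed, n_probes = 10000L, n_sorted = 40L,
                            n_bulk = 60L, delta_min = 0.20, alpha = 0.05,
                            k_markers = 600L, top_k = 1000L,
                            n_components = 10L, design_args = list()) {
  if (missing(seed)) abort_config("seed is mandatory")
  if (delta_min < 0 || delta_min > 1) abort_config("delta_min must be in [0,1]")
  if (alpha <= 0 || alpha >= 1) abort_config("alpha must be in (0,1)")
  if (k_markers < 2L) abort_config("k_markers must be >= 2")
  if (top_k < 1L) abort_config("top_k must be >= 1")
  structure(list(seed = as.integer(seed), n_probes = as.integer(n_probes),
                 n_sorted = as.integer(n_sorted), n_bulk = as.integer(n_bulk),
                 delta_min = delta_min, alpha = alpha,
                 k_markers = as.integer(k_markers), top_k = as.integer(top_k),
                 n_components = as.integer(n_components),
                 design_args = design_args),
            class = "ctewas_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Deterministic given the config seed. Emits, under `out_dir`: the
#' simulated matrices and sheets, the ct-DMCG table, aging and Braak
#' association tables per cell fraction, the Braak meta-analysis table,
#' overlap summaries, proportion estimates for the bulk cohort, the design
#' ground truth, and `manifest.json` recording versions, seed, thresholds
#' and per-stage probe/sample counts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "ctewas_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  design <- do.call(make_default_design,
                    c(list(n_probes = config$n_probes, seed = config$seed),
                      config$design_args))
  sorted <- generate_sorted_cohort(design, config$n_sorted,
                                   seed = config$seed + 1L)
  bulk <- generate_bulk_cohort(design, config$n_bulk,
                               seed = config$seed + 2L)
  say("simulated %d probes; %d sorted samples; %d bulk samples",
      config$n_probes, ncol(sorted$beta), ncol(bulk$beta))

  write_beta_matrix(sorted$beta, pth("sorted_beta.tsv"))
  write_sample_sheet(sorted$sheet, pth("sorted_sheet.tsv"))
  write_beta_matrix(bulk$beta, pth("bulk_beta.tsv"))
  write_sample_sheet(bulk$sheet, pth("bulk_sheet.tsv"))
  write_probe_annotation(design$annotation, pth("annotation.tsv"))
  utils::write.table(design$probes, pth("ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  norm <- quantile_normalize(sorted$beta)
  say("quantile normalization: %d probes in, %d out", nrow(sorted$beta),
      nrow(norm))
  pcs <- compute_principal_components(norm, config$n_components)
  pc_assoc <- suppressWarnings(correlate_pcs_with_covariates(pcs, sorted$sheet))
  pcs <- pick_batch_component(pcs, sorted$sheet)
  utils::write.table(pc_assoc, pth("pc_associations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ct <- celltype_ttest(norm, sorted$sheet)
  ct_dmcgs <- call_ct_dmcgs(ct, design$annotation,
                            delta_min = config$delta_min,
                            alpha = config$alpha)
  say("ct-DMCGs: %d of %d probes pass Bonferroni %.2g and |delta| >= %.2f",
      nrow(ct_dmcgs), nrow(ct), config$alpha, config$delta_min)
  write_results_table(ct, pth("celltype_ttest.tsv"), design$annotation)
  write_results_table(ct_dmcgs, pth("ct_dmcgs.tsv"), design$annotation)

  ewas <- list()
  for (fraction in c("neuron", "glia")) {
    for (predictor in c("age", "braak")) {
      spec <- regression_spec(predictor = predictor, fraction = fraction)
      tab <- run_ewas(norm, sorted$sheet, pcs, spec)
      ewas[[paste(predictor, fraction, sep = "_")]] <- tab
      write_results_table(tab, pth(sprintf("ewas_%s_%s.tsv", predictor,
                                           fraction)), design$annotation)
      say("EWAS %s/%s: %d probes, min p = %.3g", predictor, fraction,
          nrow(tab), min(tab$p))
    }
  }

  meta <- combine_cell_types(ewas$braak_neuron, ewas$braak_glia)
  write_results_table(meta, pth("meta_braak.tsv"), design$annotation)
  say("Braak meta-analysis: %d probes combined", nrow(meta))

  k_ov <- min(config$top_k, config$n_probes)
  overlaps <- data.frame(
    comparison = c("aging_neuron_vs_glia", "braak_neuron_vs_glia"),
    k = k_ov,
    n_overlap = c(top_k_overlap(ewas$age_neuron, ewas$age_glia, k_ov)$n_overlap,
                  top_k_overlap(ewas$braak_neuron, ewas$braak_glia, k_ov)$n_overlap))
  utils::write.table(overlaps, pth("top_k_overlaps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  panel <- select_reference_markers(norm, sorted$sheet,
                                    k = min(config$k_markers, nrow(norm)))
  props <- estimate_proportions(bulk$beta, panel)
  utils::write.table(props, pth("bulk_proportions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rmse <- sqrt(mean((props$w_neuron - bulk$sheet$true_neuron_prop)^2))
  say("deconvolution: %d markers, RMSE vs truth = %.4f",
      length(panel$markers), rmse)

  manifest <- list(
    package = "ctewas",
    version = as.character(utils::packageVersion("ctewas")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = config[c("delta_min", "alpha", "k_markers", "top_k")],
    sizes = list(n_probes = config$n_probes, n_sorted = config$n_sorted,
                 n_bulk = config$n_bulk),
    counts = list(ct_dmcgs = nrow(ct_dmcgs), meta_probes = nrow(meta)),
    deconvolution_rmse = rmse,
    log = log_lines
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(design = design, sorted = sorted, bulk = bulk,
                 pcs = pcs, pc_associations = pc_assoc,
                 celltype = ct, ct_dmcgs = ct_dmcgs, ewas = ewas,
                 meta = meta, overlaps = overlaps, panel = panel,
                 proportions = props, manifest = manifest))
}

#' Sorted-versus-bulk detection power for planted Braak effects
#'
#' Generates one sorted and one bulk cohort of matched donor count from the
#' same design, runs the Braak association scan in each cell fraction and in
#' bulk, and reports the fraction of planted Braak-effect probes reaching
#' Bonferroni significance in each arm. A planted probe counts as detected
#' in the sorted arm when it is significant in a cell fraction where its
#' effect was planted.
#'
#' @param design A `ctewas_design` with nonzero Braak effects.
#' @param n_donors Donors per arm (default 60, comparable to a combined
#'   sorted cohort of about sixty individuals).
#' @param seed Seed for the cohort draws (default: design seed).
#' @param alpha Bonferroni level (default 0.05).
#' @return A one-row `data.frame`: n_planted, power_sorted, power_bulk,
#'   power_diff.
#' @export
power_comparison <- function(design, n_donors = 60L, seed = design$seed,
                             alpha = 0.05) {
  stopifnot(inherits(design, "ctewas_design"))
  truth <- design$probes
  planted_n <- truth$braak_effect_neuron != 0
  planted_g <- truth$braak_effect_glia != 0
  planted <- which(planted_n | planted_g)
  if (length(planted) == 0L)
    abort_config("design has no planted Braak effects")

  sorted <- generate_sorted_cohort(design, n_donors, seed = seed)
  bulk <- generate_bulk_cohort(design, n_donors, seed = seed + 5000L)
  pcs_sorted <- pick_batch_component(
    compute_principal_components(sorted$beta, min(10L, ncol(sorted$beta) - 1L)),
    sorted$sheet)
  pcs_bulk <- pick_batch_component(
    compute_principal_components(bulk$beta, min(10L, ncol(bulk$beta) - 1L)),
    bulk$sheet)
  sig <- function(tab) {
    hit <- tab$bonferroni_p < alpha
    stats::setNames(hit, tab$probe_id)[truth$probe_id]
  }
  hit_n <- sig(run_ewas(sorted$beta, sorted$sheet, pcs_sorted,
                        regression_spec("braak", fraction = "neuron")))
  hit_g <- sig(run_ewas(sorted$beta, sorted$sheet, pcs_sorted,
                        regression_spec("braak", fraction = "glia")))
  hit_b <- sig(run_ewas(bulk$beta, bulk$sheet, pcs_bulk,
                        regression_spec("braak", fraction = "bulk")))
  detected_sorted <- (planted_n & hit_n) | (planted_g & hit_g)
  power_sorted <- mean(detected_sorted[planted])
  power_bulk <- mean(hit_b[planted])
  data.frame(n_planted = length(planted), power_sorted = power_sorted,
             power_bulk = power_bulk,
             power_diff = power_sorted - power_bulk)
}
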