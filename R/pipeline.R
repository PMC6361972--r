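# End-to-end orchestration: simulate -> qc -> call-hits -> fit-dr ->
# classify -> gsea, with a run manifest (package version, seed, config
# hash) written next to every stage's output table.

# Polynomial rolling hash (mod 2^31 - 1) over the config's JSON
# serialization; cheap, dependency free, stable across sessions.
config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' A self-contained demo configuration: a 2,640-compound single-dose
#' screen with 5 planted EMT-selective and 6 planted
#' epithelial-selective compounds, dose-response truths for the three
#' ionophores at their published IC50 pairs (nigericin 194 vs 7 nM,
#' monensin 186 vs 9 nM, salinomycin 1564 vs 276 nM) with the published
#' replicate counts, and a 13-vs-11 expression panel with one planted
#' up-shifted gene set.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  n_inactive <- 2629L
  planted_emt <- data.frame(
    compound_id = sprintf("EMT_HIT_%02d", 1:5), g = 0.9, r = 0.2)
  planted_epi <- data.frame(
    compound_id = sprintf("EPI_HIT_%02d", 1:6), g = 0.25, r = 0.95)
  inactive <- data.frame(
    compound_id = sprintf("CPD_%04d", seq_len(n_inactive)), g = 1, r = 1)
  dr_truth <- data.frame(
    compound_id = rep(c("nigericin", "monensin", "salinomycin"), each = 2L),
    cell_line = rep(c("PC-3E", "TEM4-18"), 3L),
    bottom = 0, top = 1, hill = 1,
    ec50_nM = c(194, 7, 186, 9, 1564, 276),
    replicates = c(5L, 5L, 24L, 24L, 5L, 5L),
    stringsAsFactors = FALSE)
  list(
    seed = seed,
    thresholds = c(hit_thresholds(),
                   list(ic50_cutoff_nM = 100, z_prime_min = 0.5)),
    screen_sim = list(effects = rbind(planted_emt, planted_epi, inactive),
                      baseline = 60, noise = "nb", dispersion = 20,
                      pos_kill_red = 1 / 6),
    dr_sim = list(truth = dr_truth, top_dose_nM = 10000,
                  dilution_factor = 3, n_points = 9L, noise_sd = 0.05),
    panel_sim = list(n_sensitive = 13L, n_resistant = 11L, n_genes = 1000L,
                     set_size = 50L, effect_size = 2, n_decoys = 10L,
                     decoy_size = 50L),
    gsea = list(n_perm = 1000L, min_size = 15L, max_size = 500L,
                fdr_cutoff = 0.25))
}

#' Read a pipeline configuration from JSON
#' @param path JSON config file.
#' @return configuration list (data.frame sections restored).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cfg
}

write_manifest <- function(outdir, stage, seed, hash) {
  manifest <- list(package = "emtscreen",
                   version = as.character(utils::packageVersion("emtscreen")),
                   stage = stage, seed = seed, config_hash = hash,
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest,
                       file.path(outdir, sprintf("%s_manifest.json", stage)),
                       auto_unbox = TRUE)
}

#' Run the full screen-to-enrichment pipeline
#'
#' Executes simulate -> qc -> call-hits -> fit-dr -> classify -> gsea on
#' a configuration (default: [default_config()]), writing each stage's
#' table plus a manifest into `outdir` when given. Plates failing the
#' Z'-factor gate are excluded from hit calling, with the excluded list
#' reported.
#'
#' @param config configuration list.
#' @param outdir output directory (NULL = no files written).
#' @param quiet suppress stage messages.
#' @return list with `qc`, `hit_calls`, `hit_lists`, `failed_plates`,
#'   `dr_fits`, `selectivity`, `panel`, `gsea`, `truth`, `config_hash`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         quiet = FALSE) {
  hash <- config_hash(config)
  seed <- as.integer(config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  emit <- function(df, stage, file) {
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_delim_file(df, file.path(outdir, file))
      write_manifest(outdir, stage, seed, hash)
    }
  }
  th <- do.call(hit_thresholds,
                config$thresholds[names(config$thresholds) %in%
                                    names(formals(hit_thresholds))])

  say("[simulate] screen: %d compounds", nrow(config$screen_sim$effects))
  scr_cfg <- screen_sim_config(
    compound_effects = config$screen_sim$effects,
    baseline = config$screen_sim$baseline,
    noise = config$screen_sim$noise,
    dispersion = config$screen_sim$dispersion,
    pos_kill_red = config$screen_sim$pos_kill_red,
    seed = seed)
  screen <- gen_screen_plates(scr_cfg, thresholds = th)
  normalized <- normalize_screen(screen$records, screen$layouts)

  say("[qc] %d plates", length(screen$layouts))
  qc <- compute_qc(normalized, channel = "red")
  emit(qc, "qc", "qc_table.tsv")
  per_plate <- qc[qc$plate_id != "screen-average", ]
  failed <- per_plate$plate_id[per_plate$z_prime <
                                 config$thresholds$z_prime_min]
  if (length(failed)) {
    say("[qc] %d plate(s) fail the Z' >= %.2f gate: %s", length(failed),
        config$thresholds$z_prime_min, paste(failed, collapse = ", "))
  }

  say("[call-hits] classifying compounds")
  keep <- !(normalized$plate_id %in% failed)
  calls <- call_hits(normalized[keep, ], thresholds = th)
  emit(calls[!vapply(calls, is.list, TRUE)], "call_hits", "hit_calls.tsv")

  say("[fit-dr] %d dose-response series", nrow(config$dr_sim$truth))
  tr <- config$dr_sim$truth
  reps <- tr$replicates %||% rep(3L, nrow(tr))
  dr_parts <- lapply(seq_len(nrow(tr)), function(i) {
    gen_dose_response(dr_sim_config(
      tr[i, c("compound_id", "cell_line", "bottom", "top", "hill",
              "ec50_nM")],
      top_dose_nM = config$dr_sim$top_dose_nM,
      dilution_factor = config$dr_sim$dilution_factor,
      n_points = config$dr_sim$n_points,
      replicates = reps[i],
      noise_sd = config$dr_sim$noise_sd,
      seed = seed + i))$data
  })
  dr_data <- do.call(rbind, dr_parts)
  fits <- fit_dr_table(dr_data)
  emit(fits, "fit_dr", "dr_fits.tsv")

  sel <- do.call(rbind, lapply(split(fits, fits$compound_id), function(d) {
    if (nrow(d) != 2L || anyNA(d$ic50_abs_nM)) return(NULL)
    hi <- which.max(d$ic50_abs_nM); lo <- which.min(d$ic50_abs_nM)
    fs <- fold_selectivity(d$ic50_abs_nM[hi], d$ic50_abs_nM[lo])
    data.frame(compound_id = d$compound_id[1L],
               resistant_line = d$cell_line[hi],
               sensitive_line = d$cell_line[lo],
               ic50_resistant_nM = d$ic50_abs_nM[hi],
               ic50_sensitive_nM = d$ic50_abs_nM[lo],
               fold = fs$fold, reported_fold = fs$reported_fold,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(sel)) rownames(sel) <- NULL
  emit(sel, "selectivity", "selectivity.tsv")

  say("[classify] + [gsea] expression panel")
  pan_cfg <- panel_sim_config(
    n_sensitive = config$panel_sim$n_sensitive,
    n_resistant = config$panel_sim$n_resistant,
    n_genes = config$panel_sim$n_genes,
    set_size = config$panel_sim$set_size,
    effect_size = config$panel_sim$effect_size,
    n_decoys = config$panel_sim$n_decoys,
    decoy_size = config$panel_sim$decoy_size,
    seed = seed + 1000L)
  panel_sim <- gen_panel_expression(pan_cfg)
  gs <- gsea(panel_sim$expr, panel_sim$gene_sets,
             n_perm = config$gsea$n_perm, seed = seed + 2000L,
             min_size = config$gsea$min_size,
             max_size = config$gsea$max_size,
             fdr_cutoff = config$gsea$fdr_cutoff)
  emit(gs$table, "gsea", "gsea_table.tsv")

  list(qc = qc, hit_calls = calls, hit_lists = hit_lists(calls),
       failed_plates = failed, dr_fits = fits, selectivity = sel,
       panel = panel_sim, gsea = gs, truth = screen$truth,
       config_hash = hash)
}
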