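# Seeded generators for every input the pipeline consumes: two-channel
# per-field plate counts with vehicle and hygromycin-style positive
# controls, 4PL dose-response tables, exponential growth curves, and an
# expression matrix with one truly shifted gene set among decoys.
# All generators are pure functions of (config, seed): the global RNG
# stream is saved and restored around each call.

#' Screen simulation configuration
#'
#' Describes a single-dose two-channel co-culture screen. Each library
#' compound has a true green-channel (epithelial line) and red-channel
#' (EMT-like line) viability fraction; vehicle wells have fraction 1 in
#' both channels; the positive control emulates hygromycin, which kills
#' only the hygromycin-sensitive red line.
#'
#' @param compound_effects data.frame with columns `compound_id`, `g`,
#'   `r`: true viability fractions in `[0, 1]` per channel.
#' @param n_vehicle,n_positive control wells per 96-well plate
#'   (vehicle in column 1, positive control in column 12 by default
#'   template; compounds fill the remaining 80 wells).
#' @param fields_per_well imaged fields per well (default 13).
#' @param baseline expected cells per field per channel in an untreated
#'   well (default 60, i.e. ~780 cells/well over 13 fields).
#' @param noise count noise model: `"nb"` (negative binomial; imaging
#'   counts are typically overdispersed) or `"poisson"`.
#' @param dispersion negative-binomial size parameter (ignored for
#'   Poisson); smaller = more overdispersion.
#' @param pos_kill_red surviving red fraction in positive-control wells
#'   (default 1/6).
#' @param screen_dose_nM nominal screen dose recorded in layouts
#'   (default 1000 nM = 1 uM).
#' @param seed integer seed.
#' @return object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(compound_effects,
                              n_vehicle = 8L, n_positive = 8L,
                              fields_per_well = 13L,
                              baseline = 60,
                              noise = c("nb", "poisson"),
                              dispersion = 20,
                              pos_kill_red = 1 / 6,
                              screen_dose_nM = 1000,
                              seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(is.data.frame(compound_effects),
            all(c("compound_id", "g", "r") %in% names(compound_effects)))
  if (any(compound_effects$g < 0 | compound_effects$g > 1 |
          compound_effects$r < 0 | compound_effects$r > 1)) {
    stopf("planted viability fractions must lie in [0, 1]")
  }
  if (baseline <= 0) stopf("baseline expected count must be > 0")
  if (pos_kill_red < 0 || pos_kill_red > 1) {
    stopf("positive-control surviving fraction must lie in [0, 1]")
  }
  structure(list(compound_effects = compound_effects,
                 n_vehicle = as.integer(n_vehicle),
                 n_positive = as.integer(n_positive),
                 fields_per_well = as.integer(fields_per_well),
                 baseline = baseline, noise = noise,
                 dispersion = dispersion, pos_kill_red = pos_kill_red,
                 screen_dose_nM = screen_dose_nM,
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

draw_counts <- function(n, mu, noise, dispersion) {
  if (noise == "poisson") stats::rpois(n, mu)
  else stats::rnbinom(n, size = dispersion, mu = mu)
}

#' Simulate a single-dose co-culture screen
#'
#' Lays compounds out on as many 96-well plates as needed (80 compound
#' wells per plate with the default template), draws per-field counts
#' for both channels with expectation `baseline * true fraction`, and
#' returns the records, layouts, and a truth table. Truth labels are the
#' hit-calling rules applied to the noiseless planted fractions, so
#' recovery by the caller is well-defined.
#'
#' @param cfg a `screen_sim_config`.
#' @param thresholds hit-calling thresholds used to derive truth labels
#'   (default [hit_thresholds()]).
#' @return list with `records` (well-record data.frame), `layouts`
#'   (named list of `plate_layout`), `truth` (data.frame: compound_id,
#'   g, r, true_class), and `seed`.
#' @export
gen_screen_plates <- function(cfg, thresholds = hit_thresholds()) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  eff <- cfg$compound_effects
  n_cpd_per_plate <- 96L - cfg$n_vehicle - cfg$n_positive
  n_plates <- ceiling(nrow(eff) / n_cpd_per_plate)

  geom <- plate_geometry(96L)
  all_wells <- as.vector(t(outer(geom$rows, seq_len(geom$n_col),
                                 function(r, c) sprintf("%s%02d", r, c))))
  veh_wells <- sprintf("%s01", geom$rows)[seq_len(cfg$n_vehicle)]
  pos_wells <- sprintf("%s12", geom$rows)[seq_len(cfg$n_positive)]
  cpd_wells <- setdiff(all_wells, c(veh_wells, pos_wells))

  layouts <- list()
  rec <- vector("list", n_plates)
  with_seed(cfg$seed, {
    for (p in seq_len(n_plates)) {
      pid <- sprintf("P%03d", p)
      idx <- ((p - 1L) * n_cpd_per_plate + 1L):min(p * n_cpd_per_plate, nrow(eff))
      plate_eff <- eff[idx, , drop = FALSE]
      used_cpd <- cpd_wells[seq_len(nrow(plate_eff))]
      wells <- data.frame(
        well = c(veh_wells, pos_wells, used_cpd),
        kind = c(rep("vehicle", length(veh_wells)),
                 rep("positive_control", length(pos_wells)),
                 rep("compound", length(used_cpd))),
        compound_id = c(rep(NA_character_, length(veh_wells)),
                        rep(NA_character_, length(pos_wells)),
                        plate_eff$compound_id),
        concentration = c(rep(NA_real_, length(veh_wells)),
                          rep(350, length(pos_wells)),  # hygromycin, ug/ml
                          rep(cfg$screen_dose_nM, length(used_cpd))),
        stringsAsFactors = FALSE)
      layouts[[pid]] <- plate_layout(pid, wells)

      well_v <- c(veh_wells, pos_wells, used_cpd)
      g_frac <- c(rep(1, length(veh_wells)), rep(1, length(pos_wells)),
                  plate_eff$g)
      r_frac <- c(rep(1, length(veh_wells)),
                  rep(cfg$pos_kill_red, length(pos_wells)), plate_eff$r)
      nf <- cfg$fields_per_well
      nw <- length(well_v)
      rec[[p]] <- data.frame(
        plate_id = pid,
        well = rep(rep(well_v, each = nf), 2L),
        channel = rep(c("green", "red"), each = nw * nf),
        field = rep(seq_len(nf), nw * 2L),
        count = c(draw_counts(nw * nf, rep(cfg$baseline * g_frac, each = nf),
                              cfg$noise, cfg$dispersion),
                  draw_counts(nw * nf, rep(cfg$baseline * r_frac, each = nf),
                              cfg$noise, cfg$dispersion)),
        stringsAsFactors = FALSE)
    }
  })
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  truth <- eff
  truth$true_class <- classify_viability(eff$g, eff$r, thresholds)$class
  list(records = records, layouts = layouts, truth = truth, seed = cfg$seed)
}

#' Dose-response simulation configuration
#'
#' @param truth data.frame with one row per (compound, cell line):
#'   columns `compound_id, cell_line, bottom, top, hill, ec50_nM`.
#' @param top_dose_nM highest tested concentration (nM).
#' @param dilution_factor serial dilution factor (> 1).
#' @param n_points concentrations in the series.
#' @param replicates replicate wells per concentration.
#' @param noise_sd additive Gaussian noise SD on viability.
#' @param seed integer seed.
#' @return object of class `dr_sim_config`.
#' @export
dr_sim_config <- function(truth, top_dose_nM = 10000, dilution_factor = 3,
                          n_points = 9L, replicates = 3L, noise_sd = 0.05,
                          seed = 1L) {
  stopifnot(is.data.frame(truth),
            all(c("compound_id", "cell_line", "bottom", "top", "hill",
                  "ec50_nM") %in% names(truth)))
  if (any(truth$bottom < 0 | truth$bottom >= truth$top)) {
    stopf("need 0 <= bottom < top for every truth row")
  }
  if (any(truth$hill <= 0) || any(truth$ec50_nM <= 0)) {
    stopf("hill and ec50 must be > 0")
  }
  if (dilution_factor <= 0) stopf("dilution factor must be positive")
  if (noise_sd < 0) stopf("noise SD must be >= 0")
  structure(list(truth = truth, top_dose_nM = top_dose_nM,
                 dilution_factor = dilution_factor,
                 n_points = as.integer(n_points),
                 replicates = as.integer(replicates),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dr_sim_config")
}

four_pl <- function(conc, bottom, top, hill, ec50) {
  bottom + (top - bottom) / (1 + (conc / ec50)^hill)
}

#' Simulate dose-response viability tables
#'
#' Viability is the 4PL curve evaluated at a serial-dilution
#' concentration series (emitted in nM) plus additive Gaussian noise,
#' truncated at zero.
#'
#' @param cfg a `dr_sim_config`.
#' @return list with `data` (long viability table) and `truth`.
#' @export
gen_dose_response <- function(cfg) {
  stopifnot(inherits(cfg, "dr_sim_config"))
  conc <- cfg$top_dose_nM / cfg$dilution_factor^(seq_len(cfg$n_points) - 1L)
  out <- with_seed(cfg$seed, {
    do.call(rbind, lapply(seq_len(nrow(cfg$truth)), function(i) {
      tr <- cfg$truth[i, ]
      mu <- four_pl(conc, tr$bottom, tr$top, tr$hill, tr$ec50_nM)
      df <- expand.grid(replicate = seq_len(cfg$replicates),
                        concentration_nM = conc)
      df$viability <- pmax(0, rep(mu, each = cfg$replicates) +
                             stats::rnorm(nrow(df), 0, cfg$noise_sd))
      cbind(compound_id = tr$compound_id, cell_line = tr$cell_line,
            df[c("concentration_nM", "replicate", "viability")])
    }))
  })
  rownames(out) <- NULL
  list(data = out, truth = cfg$truth, seed = cfg$seed)
}

#' Simulate exponential growth curves
#'
#' Cell counts grow exponentially from a fixed inoculum with optional
#' multiplicative lognormal noise; a treatment effect scales the growth
#' rate (effect 0.5 halves the rate).
#'
#' @param doubling_times_h named numeric vector of per-line control
#'   doubling times (hours).
#' @param treatment_effect multiplier on growth rate under treatment
#'   (1 = no effect); a `treated` condition is emitted when < 1.
#' @param timepoints_h sampling times (hours), all >= 0.
#' @param x0 inoculum cells/well (default 50,000).
#' @param noise_sd SD of lognormal multiplicative noise (log scale).
#' @param seed integer seed.
#' @return data.frame `cell_line, condition, time_h, count, x0`.
#' @export
gen_growth_curves <- function(doubling_times_h, treatment_effect = 1,
                              timepoints_h = c(0, 24, 48, 72),
                              x0 = 50000, noise_sd = 0, seed = 1L) {
  if (any(doubling_times_h <= 0)) stopf("doubling times must be > 0")
  if (any(timepoints_h < 0)) stopf("timepoints must be >= 0")
  if (is.null(names(doubling_times_h))) {
    names(doubling_times_h) <- sprintf("line%02d", seq_along(doubling_times_h))
  }
  conditions <- if (treatment_effect < 1) c("control", "treated") else "control"
  grid <- expand.grid(cell_line = names(doubling_times_h),
                      condition = conditions, time_h = timepoints_h,
                      stringsAsFactors = FALSE)
  rate <- log(2) / doubling_times_h[grid$cell_line]
  rate[grid$condition == "treated"] <-
    rate[grid$condition == "treated"] * treatment_effect
  mu <- x0 * exp(rate * grid$time_h)
  grid$count <- with_seed(seed, {
    if (noise_sd > 0) mu * stats::rlnorm(nrow(grid), 0, noise_sd) else mu
  })
  grid$x0 <- x0
  grid[order(grid$cell_line, grid$condition, grid$time_h), ]
}

#' Panel expression simulation configuration
#'
#' @param n_sensitive,n_resistant samples per phenotype class
#'   (defaults 13 and 11, the usual panel split for this assay).
#' @param n_genes gene universe size.
#' @param set_size genes in the planted ("EMT hallmark"-like) set.
#' @param effect_size mean up-shift of planted-set genes in sensitive
#'   samples, in units of within-group SD.
#' @param noise_sd within-group SD of expression values.
#' @param n_decoys number of decoy gene sets drawn from background genes.
#' @param decoy_size genes per decoy set.
#' @param seed integer seed.
#' @return object of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_sensitive = 13L, n_resistant = 11L,
                             n_genes = 1000L, set_size = 50L,
                             effect_size = 2, noise_sd = 1,
                             n_decoys = 10L, decoy_size = 50L, seed = 1L) {
  if (set_size > n_genes) stopf("planted set larger than gene universe")
  if (effect_size < 0) stopf("effect size must be >= 0")
  structure(list(n_sensitive = as.integer(n_sensitive),
                 n_resistant = as.integer(n_resistant),
                 n_genes = as.integer(n_genes),
                 set_size = as.integer(set_size),
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_decoys = as.integer(n_decoys),
                 decoy_size = as.integer(decoy_size),
                 seed = as.integer(seed)),
            class = "panel_sim_config")
}

#' Simulate a panel expression matrix with a planted enriched set
#'
#' Background genes are N(0, noise_sd) in every sample; genes of the
#' planted set get `effect_size * noise_sd` added in sensitive samples.
#' Decoy sets are sampled from background genes only.
#'
#' @param cfg a `panel_sim_config`.
#' @return list with `expr` (`expression_matrix`), `gene_sets`
#'   (`gene_set_collection`; planted set named `EMT_UP_SYNTHETIC`), and
#'   `planted_set` (its name).
#' @export
gen_panel_expression <- function(cfg) {
  stopifnot(inherits(cfg, "panel_sim_config"))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  samples <- c(sprintf("S%02d", seq_len(cfg$n_sensitive)),
               sprintf("R%02d", seq_len(cfg$n_resistant)))
  phenotype <- stats::setNames(
    rep(c("sensitive", "resistant"), c(cfg$n_sensitive, cfg$n_resistant)),
    samples)
  with_seed(cfg$seed, {
    values <- matrix(stats::rnorm(cfg$n_genes * length(samples),
                                  0, cfg$noise_sd),
                     cfg$n_genes, length(samples),
                     dimnames = list(genes, samples))
    planted <- sample(genes, cfg$set_size)
    values[planted, phenotype == "sensitive"] <-
      values[planted, phenotype == "sensitive"] +
      cfg$effect_size * cfg$noise_sd
    background <- setdiff(genes, planted)
    decoys <- lapply(seq_len(cfg$n_decoys), function(i) {
      sample(background, cfg$decoy_size)
    })
    names(decoys) <- sprintf("DECOY_%02d", seq_len(cfg$n_decoys))
    sets <- c(stats::setNames(list(planted), "EMT_UP_SYNTHETIC"), decoys)
    list(expr = expression_matrix(values, phenotype),
         gene_sets = gene_set_collection(sets, "synthetic"),
         planted_set = "EMT_UP_SYNTHETIC", seed = cfg$seed)
  })
}
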