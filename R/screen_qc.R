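# Per-plate normalization to untreated controls, assay-quality
# statistics (Z'-factor, S/N, S/B), and the three-criterion selectivity
# hit classifier.

#' Hit-calling thresholds
#'
#' Default values are the published screen criteria. EMT-selective:
#' green_norm >= `g_min`, red_norm <= `r_max`, R/G ratio <= `ratio_max`.
#' Epithelial-selective: green_norm <= `g_max`, red_norm >= `r_min`,
#' ratio >= `ratio_min`. Pan-cytotoxic: both channels <= `pan_max`
#' (the kill threshold reused symmetrically; the original report only
#' describes this cluster qualitatively).
#'
#' @param g_min,r_max,ratio_max EMT-selective rule thresholds.
#' @param g_max,r_min,ratio_min epithelial-selective rule thresholds.
#' @param pan_max pan-cytotoxic threshold applied to both channels.
#' @return named list of thresholds.
#' @export
hit_thresholds <- function(g_min = 0.55, r_max = 0.41, ratio_max = 0.65,
                           g_max = 0.41, r_min = 0.46, ratio_min = 1.80,
                           pan_max = 0.41) {
  list(g_min = g_min, r_max = r_max, ratio_max = ratio_max,
       g_max = g_max, r_min = r_min, ratio_min = ratio_min,
       pan_max = pan_max)
}

#' Classify normalized viability pairs
#'
#' Applies the three-criterion rules to normalized green/red viability.
#' The R/G ratio is red_norm / green_norm, undefined when green_norm is
#' zero, in which case the compound can only reach the pan-cytotoxic or
#' inactive class (never a selective one).
#'
#' @param g,r numeric vectors of normalized green / red viability.
#' @param thresholds a [hit_thresholds()] list.
#' @return data.frame with `ratio_rg`, `class` (one of `emt_selective`,
#'   `epithelial_selective`, `pan_cytotoxic`, `inactive`) and the six
#'   per-criterion flags `emt_a, emt_b, emt_c, epi_a, epi_b, epi_c`.
#' @export
classify_viability <- function(g, r, thresholds = hit_thresholds()) {
  stopifnot(length(g) == length(r), all(g >= 0), all(r >= 0))
  th <- thresholds
  ratio <- ifelse(g > 0, r / g, NA_real_)
  emt_a <- g >= th$g_min
  emt_b <- r <= th$r_max
  emt_c <- !is.na(ratio) & ratio <= th$ratio_max
  epi_a <- g <= th$g_max
  epi_b <- r >= th$r_min
  epi_c <- !is.na(ratio) & ratio >= th$ratio_min
  cls <- rep("inactive", length(g))
  cls[g <= th$pan_max & r <= th$pan_max] <- "pan_cytotoxic"
  cls[emt_a & emt_b & emt_c] <- "emt_selective"
  cls[epi_a & epi_b & epi_c] <- "epithelial_selective"
  data.frame(ratio_rg = ratio, class = cls,
             emt_a = emt_a, emt_b = emt_b, emt_c = emt_c,
             epi_a = epi_a, epi_b = epi_b, epi_c = epi_c,
             stringsAsFactors = FALSE)
}

well_totals <- function(records) {
  agg <- stats::aggregate(count ~ plate_id + well + channel, records, sum)
  agg
}

#' Normalize a plate to its untreated controls
#'
#' Per-well totals (sum over fields) are divided, channel by channel, by
#' the mean vehicle-well total of the same plate, yielding relative
#' viability; vehicle wells therefore average exactly 1 per channel.
#'
#' @param records well-record data.frame for one plate.
#' @param layout the matching `plate_layout`.
#' @return data.frame with `plate_id, well, kind, compound_id,
#'   green_norm, red_norm, ratio_rg`.
#' @export
normalize_plate <- function(records, layout) {
  stopifnot(inherits(layout, "plate_layout"))
  records <- records[records$plate_id == layout$plate_id, , drop = FALSE]
  if (!nrow(records)) stopf("no records for plate %s", layout$plate_id)
  totals <- well_totals(records)
  roles <- layout_roles(layout)
  veh <- names(roles)[roles == "vehicle"]
  wide <- data.frame(well = unique(totals$well), stringsAsFactors = FALSE)
  for (ch in c("green", "red")) {
    t_ch <- totals[totals$channel == ch, ]
    denom <- mean(t_ch$count[t_ch$well %in% veh])
    if (!is.finite(denom) || denom == 0) {
      stopf("vehicle mean is zero for plate %s channel %s",
            layout$plate_id, ch)
    }
    wide[[paste0(ch, "_norm")]] <-
      t_ch$count[match(wide$well, t_ch$well)] / denom
  }
  wide$ratio_rg <- ifelse(wide$green_norm > 0,
                          wide$red_norm / wide$green_norm, NA_real_)
  info <- layout$wells[match(wide$well, layout$wells$well), ]
  out <- data.frame(plate_id = layout$plate_id, well = wide$well,
                    kind = info$kind, compound_id = info$compound_id,
                    green_norm = wide$green_norm, red_norm = wide$red_norm,
                    ratio_rg = wide$ratio_rg, stringsAsFactors = FALSE)
  out[order(out$well), ]
}

#' Normalize many plates
#'
#' @param records multi-plate well-record data.frame.
#' @param layouts named list of `plate_layout` objects.
#' @return row-bound [normalize_plate()] results.
#' @export
normalize_screen <- function(records, layouts) {
  out <- do.call(rbind, lapply(layouts, function(l) normalize_plate(records, l)))
  rownames(out) <- NULL
  out
}

#' Closed-form assay quality statistics
#'
#' Z' = 1 - 3 (SD_p + SD_n) / (mu_n - mu_p); S/N = (mu_n - mu_p) / SD_n;
#' S/B = mu_n / mu_p. Undefined cases (mu_n = mu_p, or mu_p = 0 for S/B)
#' are reported as NA. With both SDs zero and distinct means, Z' is
#' exactly 1.
#'
#' @param mu_n,sd_n mean and SD of negative (vehicle) controls.
#' @param mu_p,sd_p mean and SD of positive controls.
#' @return list `mu_n, sd_n, mu_p, sd_p, z_prime, s_over_n, s_over_b`.
#' @export
qc_stats <- function(mu_n, sd_n, mu_p, sd_p) {
  sep <- mu_n - mu_p
  z <- if (sep == 0) NA_real_ else 1 - 3 * (sd_p + sd_n) / sep
  sn <- if (sd_n == 0) NA_real_ else sep / sd_n
  if (sd_n == 0 && sd_p == 0 && sep != 0) z <- 1
  sb <- if (mu_p == 0) NA_real_ else mu_n / mu_p
  list(mu_n = mu_n, sd_n = sd_n, mu_p = mu_p, sd_p = sd_p,
       z_prime = z, s_over_n = sn, s_over_b = sb)
}

#' Plate and screen QC from normalized wells
#'
#' Computes [qc_stats()] per plate from the vehicle (negative) and
#' positive-control wells of the chosen channel, using the sample
#' (n - 1) standard deviation, and appends a `screen-average` row
#' averaging the per-plate statistics. The red channel is the default
#' because the positive control (hygromycin) acts on the
#' hygromycin-sensitive red line only; asking for green-channel QC
#' warns accordingly.
#'
#' @param normalized output of [normalize_screen()] / [normalize_plate()].
#' @param channel `"red"` (default) or `"green"`.
#' @return data.frame, one row per plate plus `screen-average`, columns
#'   `plate_id, channel, n_neg, n_pos, mu_n, sd_n, mu_p, sd_p, z_prime,
#'   s_over_n, s_over_b`.
#' @export
compute_qc <- function(normalized, channel = c("red", "green")) {
  channel <- match.arg(channel)
  if (channel == "green") {
    warning("green-channel QC requested but the assay's positive control only acts on the red channel",
            call. = FALSE)
  }
  col <- paste0(channel, "_norm")
  rows <- lapply(split(normalized, normalized$plate_id), function(d) {
    neg <- d[[col]][d$kind == "vehicle"]
    pos <- d[[col]][d$kind == "positive_control"]
    if (length(neg) < 2L || length(pos) < 2L) {
      stopf("plate %s: need >= 2 negative and >= 2 positive control wells",
            d$plate_id[1L])
    }
    s <- qc_stats(mean(neg), stats::sd(neg), mean(pos), stats::sd(pos))
    data.frame(plate_id = d$plate_id[1L], channel = channel,
               n_neg = length(neg), n_pos = length(pos),
               as.data.frame(s), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (nrow(out) > 1L) {
    avg <- out[1L, ]
    avg$plate_id <- "screen-average"
    avg$n_neg <- sum(out$n_neg); avg$n_pos <- sum(out$n_pos)
    for (cn in c("mu_n", "sd_n", "mu_p", "sd_p", "z_prime", "s_over_n",
                 "s_over_b")) {
      avg[[cn]] <- mean(out[[cn]])
    }
    out <- rbind(out, avg)
  }
  out
}

#' Call selectivity hits from normalized compound wells
#'
#' Aggregates normalized values per compound (mean across wells if a
#' compound appears more than once), applies the three-criterion rules,
#' and annotates exclusions. Excluded compounds keep their data-driven
#' class but are dropped from reported hit lists (see [hit_lists()]).
#'
#' @param normalized output of [normalize_screen()].
#' @param thresholds a [hit_thresholds()] list.
#' @param exclusions named character vector: names are compound ids,
#'   values the exclusion reason (e.g. `"auto-fluorescent"`).
#' @return data.frame: `compound_id, green_norm, red_norm, ratio_rg,
#'   class`, six criteria flags, `excluded, exclusion_reason`.
#' @export
call_hits <- function(normalized, thresholds = hit_thresholds(),
                      exclusions = character()) {
  cpd <- normalized[normalized$kind == "compound", , drop = FALSE]
  if (!nrow(cpd)) stopf("no compound wells to classify")
  g <- tapply(cpd$green_norm, cpd$compound_id, mean)
  r <- tapply(cpd$red_norm, cpd$compound_id, mean)
  ids <- names(g)
  cls <- classify_viability(as.numeric(g), as.numeric(r), thresholds)
  out <- cbind(data.frame(compound_id = ids, green_norm = as.numeric(g),
                          red_norm = as.numeric(r),
                          stringsAsFactors = FALSE),
               cls)
  out$excluded <- out$compound_id %in% names(exclusions)
  out$exclusion_reason <- ifelse(out$excluded,
                                 exclusions[out$compound_id], NA_character_)
  rownames(out) <- NULL
  out[order(out$compound_id), ]
}

#' Reported hit lists
#'
#' @param calls output of [call_hits()].
#' @return list with character vectors `emt_selective`,
#'   `epithelial_selective`, `pan_cytotoxic` (excluded compounds removed).
#' @export
hit_lists <- function(calls) {
  keep <- calls[!calls$excluded, ]
  list(emt_selective = keep$compound_id[keep$class == "emt_selective"],
       epithelial_selective =
         keep$compound_id[keep$class == "epithelial_selective"],
       pan_cytotoxic = keep$compound_id[keep$class == "pan_cytotoxic"])
}
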