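# Shared fixtures and independent oracles used across test files.

# A small single-plate layout: n_cpd compound wells in column 2, vehicle
# in column 1, positive controls in column 12.
tiny_layout <- function(plate_id = "P1", n_cpd = 4L, n_veh = 3L,
                        n_pos = 3L) {
  rows <- LETTERS[1:8]
  wells <- data.frame(
    well = c(sprintf("%s01", rows[seq_len(n_veh)]),
             sprintf("%s12", rows[seq_len(n_pos)]),
             sprintf("%s02", rows[seq_len(n_cpd)])),
    kind = c(rep("vehicle", n_veh), rep("positive_control", n_pos),
             rep("compound", n_cpd)),
    compound_id = c(rep(NA, n_veh + n_pos), sprintf("C%02d", seq_len(n_cpd))),
    concentration = c(rep(NA, n_veh), rep(350, n_pos), rep(1000, n_cpd)),
    stringsAsFactors = FALSE)
  plate_layout(plate_id, wells)
}

# Per-well records with a single field so well totals equal the given
# counts; `counts` is a named list well -> c(green, red).
records_from_totals <- function(counts, plate_id = "P1") {
  do.call(rbind, lapply(names(counts), function(w) {
    data.frame(plate_id = plate_id, well = w,
               channel = c("green", "red"), field = 1L,
               count = as.integer(counts[[w]]), stringsAsFactors = FALSE)
  }))
}

# Brute-force classical KS enrichment statistic (weight p = 0):
# explicitly evaluates the hit/miss step function at every prefix and
# returns the signed maximum deviation. Independent of the package's
# cumsum-based running sum.
ks_es_bruteforce <- function(ranked_genes, gene_set) {
  n <- length(ranked_genes)
  k <- sum(ranked_genes %in% gene_set)
  best <- 0
  for (i in seq_len(n)) {
    prefix <- ranked_genes[seq_len(i)]
    hits <- sum(prefix %in% gene_set)
    dev <- hits / k - (i - hits) / (n - k)
    if (abs(dev) > abs(best)) best <- dev
  }
  best
}

# Direct signal-to-noise formula, evaluated gene by gene with explicit
# mean/sd calls (oracle for the vectorized implementation).
s2n_direct <- function(values, phenotype) {
  sens <- phenotype == "sensitive"
  apply(values, 1L, function(v) {
    m1 <- mean(v[sens]); m2 <- mean(v[!sens])
    s1 <- max(sd(v[sens]), 0.2 * abs(m1), 0.2)
    s2 <- max(sd(v[!sens]), 0.2 * abs(m2), 0.2)
    (m1 - m2) / (s1 + s2)
  })
}

default_screen_effects <- function(n_inactive = 2629L) {
  rbind(data.frame(compound_id = sprintf("EMT_HIT_%02d", 1:5),
                   g = 0.9, r = 0.2),
        data.frame(compound_id = sprintf("EPI_HIT_%02d", 1:6),
                   g = 0.25, r = 0.95),
        data.frame(compound_id = sprintf("CPD_%04d", seq_len(n_inactive)),
                   g = 1, r = 1))
}
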