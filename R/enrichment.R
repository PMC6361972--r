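# Sensitive/resistant panel classification by absolute-IC50 cutoff and
# a from-scratch gene set enrichment analysis (signal-to-noise ranking,
# weighted running-sum enrichment score, phenotype-permutation null,
# NES and positive/negative-side FDR q-values).

parse_ic50_label <- function(x) {
  # numbers, ">x" (censored above) or "<x" (censored below)
  x <- trimws(as.character(x))
  num <- suppressWarnings(as.numeric(x))
  cens <- rep("none", length(x))
  cens[grepl("^>", x)] <- "above"
  cens[grepl("^<", x)] <- "below"
  num[cens != "none"] <-
    suppressWarnings(as.numeric(sub("^[<>]", "", x[cens != "none"])))
  if (anyNA(num)) stopf("unparseable IC50 value: %s", x[is.na(num)][1L])
  data.frame(value = num, censored = cens, stringsAsFactors = FALSE)
}

#' Classify a cell-line panel as sensitive or resistant
#'
#' Strict-inequality cutoff as published: finite IC50 < cutoff is
#' sensitive, > cutoff resistant; an IC50 exactly at the cutoff is
#' assigned resistant (documented tie rule; the strict inequalities
#' leave the point unassigned). A censored ">x" with x >= cutoff is
#' resistant; a censored "<x" with x >= cutoff cannot be resolved and
#' is flagged `ambiguous`.
#'
#' @param panel data.frame with columns `cell_line` and `ic50_nM`
#'   (numeric, or character labels allowing `">x"`/`"<x"`).
#' @param cutoff_nM classification cutoff, default 100 nM.
#' @return list with `entries` (cell_line, ic50_nM, censored, class)
#'   and group sizes `n_sensitive, n_resistant, n_ambiguous`.
#' @export
classify_panel <- function(panel, cutoff_nM = 100) {
  stopifnot(all(c("cell_line", "ic50_nM") %in% names(panel)))
  if (anyDuplicated(panel$cell_line)) stopf("one IC50 per cell line required")
  p <- parse_ic50_label(panel$ic50_nM)
  class <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    class[i] <- switch(p$censored[i],
      none = if (p$value[i] < cutoff_nM) "sensitive" else "resistant",
      above = if (p$value[i] >= cutoff_nM) "resistant" else "ambiguous",
      below = if (p$value[i] <= cutoff_nM) "sensitive" else "ambiguous")
  }
  entries <- data.frame(cell_line = panel$cell_line, ic50_nM = p$value,
                        censored = p$censored, class = class,
                        stringsAsFactors = FALSE)
  list(entries = entries,
       n_sensitive = sum(class == "sensitive"),
       n_resistant = sum(class == "resistant"),
       n_ambiguous = sum(class == "ambiguous"))
}

s2n_scores <- function(values, is_sensitive, sd_floor = TRUE) {
  n1 <- sum(is_sensitive); n2 <- sum(!is_sensitive)
  x1 <- values[, is_sensitive, drop = FALSE]
  x2 <- values[, !is_sensitive, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  s1 <- sqrt((rowSums(x1^2) - n1 * m1^2) / (n1 - 1))
  s2 <- sqrt((rowSums(x2^2) - n2 * m2^2) / (n2 - 1))
  if (sd_floor) {
    s1 <- pmax(s1, 0.2 * abs(m1), 0.2)
    s2 <- pmax(s2, 0.2 * abs(m2), 0.2)
  }
  (m1 - m2) / (s1 + s2)
}

#' Signal-to-noise gene ranking
#'
#' Scores each gene by `(mean_sensitive - mean_resistant) /
#' (sd_sensitive + sd_resistant)` with each class SD floored at
#' `max(0.2 |class mean|, 0.2)` (the canonical GSEA adjustment), and
#' returns genes in descending score order with a deterministic
#' tie-break by gene identifier.
#'
#' @param expr an `expression_matrix` (>= 2 samples per class).
#' @return data.frame `gene, score`, sorted.
#' @export
rank_genes_s2n <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  sc <- s2n_scores(expr$values, expr$phenotype == "sensitive")
  ord <- order(-sc, rownames(expr$values))
  data.frame(gene = rownames(expr$values)[ord], score = sc[ord],
             stringsAsFactors = FALSE)
}

es_from_ranked <- function(genes, scores, gene_set, p = 1) {
  hit <- genes %in% gene_set
  n <- length(genes); nh <- sum(hit)
  if (nh == 0L) stopf("gene set has empty intersection with ranked list")
  if (nh == n) stopf("gene set equals the whole ranked list")
  w <- abs(scores)^p * hit
  denom <- sum(w)
  if (denom == 0) {          # all in-set scores zero: fall back to equal steps
    w <- as.numeric(hit)
    denom <- nh
  }
  run <- cumsum(w / denom - (!hit) / (n - nh))
  i <- which.max(abs(run))
  list(es = run[i], running_sum = run, peak = i, hit = hit)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list; hits increment the running sum by
#' `|score|^p / sum_set |score|^p`, misses decrement by `1/(N - N_set)`.
#' The enrichment score is the signed maximum deviation from zero. With
#' `p = 0` this is the classical Kolmogorov-Smirnov statistic.
#'
#' @param ranked data.frame `gene, score` from [rank_genes_s2n()].
#' @param gene_set character vector of gene identifiers.
#' @param p weighting exponent (default 1).
#' @return list `es`, `running_sum`, `peak` (index of the extremum),
#'   `leading_edge` (set genes up to / after the extremum).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  r <- es_from_ranked(ranked$gene, ranked$score, gene_set, p)
  le <- if (r$es >= 0) {
    ranked$gene[seq_len(r$peak)][r$hit[seq_len(r$peak)]]
  } else {
    idx <- r$peak:length(ranked$gene)
    ranked$gene[idx][r$hit[idx]]
  }
  list(es = r$es, running_sum = r$running_sum, peak = r$peak,
       leading_edge = le)
}

perm_label_matrix <- function(n, n_sens, n_perm, seed) {
  n_distinct <- choose(n, n_sens)
  if (n_distinct <= n_perm) {
    sel <- utils::combn(n, n_sens)   # exact enumeration for tiny designs
    m <- matrix(FALSE, n, ncol(sel))
    for (j in seq_len(ncol(sel))) m[sel[, j], j] <- TRUE
    return(m)
  }
  with_seed(seed, {
    m <- matrix(FALSE, n, n_perm)
    for (j in seq_len(n_perm)) m[sample.int(n, n_sens), j] <- TRUE
    m
  })
}

#' Gene set enrichment analysis with a phenotype-permutation null
#'
#' Ranks genes by signal-to-noise between the sensitive and resistant
#' groups, computes weighted enrichment scores, and builds the null by
#' permuting phenotype labels at fixed group sizes (re-ranking the
#' genes each time). NES is the ES divided by the mean of same-sign
#' permutation ES for that set; the nominal p is the same-sign
#' permutation tail; FDR q follows the standard positive/negative NES
#' procedure. Designs with fewer distinct label assignments than
#' `n_perm` are enumerated exactly.
#'
#' @param expr an `expression_matrix`.
#' @param gene_sets a `gene_set_collection`.
#' @param n_perm permutations (default 1000; < 100 warns).
#' @param seed integer seed for the permutation draw.
#' @param min_size,max_size gene-set size filter applied after
#'   intersection with the measured genes (defaults 15 and 500).
#' @param p weighting exponent for the running sum (default 1).
#' @param fdr_cutoff flag threshold on the q-value (default 0.25).
#' @return object of class `gsea_result`: `table` (set_name, size, es,
#'   nes, p_nominal, fdr_q, enriched_in, flagged), `leading_edge`
#'   (named list), `n_perm_used`, `exact`, `seed`.
#' @export
gsea <- function(expr, gene_sets, n_perm = 1000L, seed = 1L,
                 min_size = 15L, max_size = 500L, p = 1,
                 fdr_cutoff = 0.25) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(gene_sets, "gene_set_collection"))
  if (n_perm < 100L) warning("n_perm < 100: p-values and FDR will be coarse",
                             call. = FALSE)
  # canonical order: genes by name, samples by (class, name), so results
  # are invariant to input row/column order
  values <- expr$values[order(rownames(expr$values)), , drop = FALSE]
  samp_ord <- order(expr$phenotype, colnames(values))
  values <- values[, samp_ord, drop = FALSE]
  phen <- expr$phenotype[colnames(values)]
  genes <- rownames(values)

  sets <- lapply(gene_sets$sets, function(g) intersect(g, genes))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]
  if (!length(sets)) stopf("no gene set within [%d, %d] after filtering",
                           min_size, max_size)

  obs_sens <- phen == "sensitive"
  obs_scores <- s2n_scores(values, obs_sens)
  ord <- order(-obs_scores, genes)
  ranked <- data.frame(gene = genes[ord], score = obs_scores[ord],
                       stringsAsFactors = FALSE)
  obs <- lapply(sets, function(g) enrichment_score(ranked, g, p))
  es_obs <- vapply(obs, `[[`, 1, "es")

  labels <- perm_label_matrix(ncol(values), sum(obs_sens), n_perm, seed)
  n_used <- ncol(labels)
  exact <- n_used < n_perm || choose(ncol(values), sum(obs_sens)) <= n_perm
  es_perm <- matrix(NA_real_, length(sets), n_used,
                    dimnames = list(names(sets), NULL))
  set_idx <- lapply(sets, function(g) genes %in% g)
  for (j in seq_len(n_used)) {
    sc <- s2n_scores(values, labels[, j])
    oj <- order(-sc, genes)
    sc_o <- sc[oj]
    for (k in seq_along(sets)) {
      hit <- set_idx[[k]][oj]
      n <- length(genes); nh <- sum(hit)
      w <- abs(sc_o)^p * hit
      denom <- sum(w)
      if (denom == 0) { w <- as.numeric(hit); denom <- nh }
      run <- cumsum(w / denom - (!hit) / (n - nh))
      es_perm[k, j] <- run[which.max(abs(run))]
    }
  }

  norm_pos <- apply(es_perm, 1L, function(e) mean(e[e >= 0]))
  norm_neg <- apply(es_perm, 1L, function(e) mean(abs(e[e < 0])))
  # a set may lack same-sign permutation scores in tiny designs; fall
  # back to the unsigned mean so NES stays finite
  fallback <- apply(abs(es_perm), 1L, mean)
  norm_pos[!is.finite(norm_pos) | norm_pos == 0] <-
    fallback[!is.finite(norm_pos) | norm_pos == 0]
  norm_neg[!is.finite(norm_neg) | norm_neg == 0] <-
    fallback[!is.finite(norm_neg) | norm_neg == 0]
  nes_of <- function(es, k) {
    if (es >= 0) es / norm_pos[k] else es / norm_neg[k]
  }
  nes_obs <- vapply(seq_along(sets), function(k) nes_of(es_obs[k], k), 1)
  nes_perm <- es_perm
  for (k in seq_along(sets)) {
    pos <- es_perm[k, ] >= 0
    nes_perm[k, pos] <- es_perm[k, pos] / norm_pos[k]
    nes_perm[k, !pos] <- es_perm[k, !pos] / norm_neg[k]
  }

  p_nom <- vapply(seq_along(sets), function(k) {
    e <- es_perm[k, ]
    if (es_obs[k] >= 0) {
      tail_set <- e[e >= 0]
      mean(tail_set >= es_obs[k])
    } else {
      tail_set <- e[e < 0]
      if (!length(tail_set)) 0 else mean(tail_set <= es_obs[k])
    }
  }, 1)

  all_nes_perm <- as.vector(nes_perm)
  fdr_q <- vapply(seq_along(sets), function(k) {
    ns <- nes_obs[k]
    if (ns >= 0) {
      num_pool <- all_nes_perm[all_nes_perm >= 0]
      num <- if (length(num_pool)) mean(num_pool >= ns) else 0
      obs_pool <- nes_obs[nes_obs >= 0]
      den <- mean(obs_pool >= ns)
    } else {
      num_pool <- all_nes_perm[all_nes_perm < 0]
      num <- if (length(num_pool)) mean(num_pool <= ns) else 0
      obs_pool <- nes_obs[nes_obs < 0]
      den <- mean(obs_pool <= ns)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, 1)

  tab <- data.frame(set_name = names(sets), size = lengths(sets),
                    es = es_obs, nes = nes_obs, p_nominal = p_nom,
                    fdr_q = fdr_q,
                    enriched_in = ifelse(es_obs >= 0, "sensitive",
                                         "resistant"),
                    flagged = fdr_q <= fdr_cutoff,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$nes), ]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 leading_edge = lapply(obs, `[[`, "leading_edge"),
                 n_perm_used = n_used, exact = exact, seed = seed),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> %d sets, %d permutations%s\n",
              nrow(x$table), x$n_perm_used,
              if (x$exact) " (exact enumeration)" else ""))
  print(utils::head(x$table, 10L))
  invisible(x)
}
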