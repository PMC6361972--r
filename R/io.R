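# Readers/writers for the plain-text formats the pipeline owns:
# plate maps, per-field count tables, dose-response tables, growth
# tables, GMT gene sets, and expression matrices with a phenotype
# sidecar. Delimiter is auto-detected from the extension (.csv comma,
# otherwise tab).

CHANNEL_SYNONYMS <- c(green = "green", gfp = "green",
                      red = "red", mcherry = "red")

normalize_channel <- function(channel) {
  key <- tolower(trimws(as.character(channel)))
  out <- CHANNEL_SYNONYMS[key]
  if (anyNA(out)) {
    stopf("unknown channel label: %s",
          paste(unique(channel[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Read per-field well counts
#'
#' Reads a delimited text file of per-field, per-channel cell counts and
#' validates every record against a plate layout: addresses must exist in
#' the layout, counts must be non-negative integers, and
#' (plate, well, channel, field) keys must be unique. Channel labels are
#' normalized (`GFP` -> `green`, `mCherry` -> `red`).
#'
#' @param path file with header columns `plate_id, well, channel, field, count`.
#' @param layout a `plate_layout` or a list of them covering all plates
#'   present in the file.
#' @return data.frame of validated well records.
#' @export
read_plate_counts <- function(path, layout) {
  df <- read_delim_file(path, colClasses = "character")
  need <- c("plate_id", "well", "channel", "field", "count")
  if (!all(need %in% names(df))) {
    stopf("count file %s lacks columns: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  count_num <- suppressWarnings(as.numeric(df$count))
  bad <- is.na(count_num) | count_num < 0 | count_num != round(count_num)
  if (any(bad)) {
    stopf("non-integer or negative count at data line %d of %s (count='%s')",
          which(bad)[1L], path, df$count[which(bad)[1L]])
  }
  field_num <- suppressWarnings(as.integer(df$field))
  if (anyNA(field_num) || any(field_num < 1L)) {
    stopf("invalid field index at data line %d of %s",
          which(is.na(field_num) | field_num < 1L)[1L], path)
  }
  records <- data.frame(plate_id = df$plate_id,
                        well = df$well,
                        channel = normalize_channel(df$channel),
                        field = field_num,
                        count = as.integer(count_num),
                        stringsAsFactors = FALSE)
  validate_plate_records(records, layout)
}

validate_plate_records <- function(records, layout) {
  layouts <- if (inherits(layout, "plate_layout")) list(layout) else layout
  names(layouts) <- vapply(layouts, `[[`, "", "plate_id")
  unknown <- setdiff(unique(records$plate_id), names(layouts))
  if (length(unknown)) {
    stopf("records reference plates with no layout: %s",
          paste(unknown, collapse = ", "))
  }
  for (pid in unique(records$plate_id)) {
    lay <- layouts[[pid]]
    idx <- records$plate_id == pid
    w <- normalize_well(records$well[idx], lay$plate_format)
    records$well[idx] <- w
    off <- setdiff(unique(w), lay$wells$well)
    if (length(off)) {
      stopf("plate %s: well address not in layout: %s", pid, off[1L])
    }
  }
  key <- paste(records$plate_id, records$well, records$channel, records$field)
  if (anyDuplicated(key)) {
    stopf("duplicate (plate, well, channel, field) record: %s",
          key[duplicated(key)][1L])
  }
  records
}

#' Write per-field well counts
#' @param records well-record data.frame.
#' @param path output path (`.csv` comma, otherwise tab).
#' @export
write_plate_counts <- function(records, path) {
  write_delim_file(records[c("plate_id", "well", "channel", "field", "count")],
                   path)
  invisible(path)
}

#' Read a plate layout file
#'
#' Expects columns `plate_id, well, kind, compound_id, concentration`;
#' an optional comment line `# plate_format: N` declares geometry
#' (default 96). Files holding several plates yield a named list of
#' layouts.
#'
#' @param path layout file.
#' @return a `plate_layout`, or a named list of them.
#' @export
read_plate_layout <- function(path) {
  first <- readLines(path, n = 1L)
  fmt <- 96L
  if (grepl("^#\\s*plate_format:", first)) {
    fmt <- as.integer(sub("^#\\s*plate_format:\\s*", "", first))
  }
  df <- read_delim_file(path)
  for (col in c("compound_id", "concentration")) {
    if (is.null(df[[col]])) df[[col]] <- NA
    df[[col]][df[[col]] %in% c("", "NA")] <- NA
  }
  df$concentration <- as.numeric(df$concentration)
  out <- lapply(split(df, df$plate_id), function(d) {
    plate_layout(d$plate_id[1L],
                 d[c("well", "kind", "compound_id", "concentration")],
                 plate_format = fmt)
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Write plate layout(s)
#' @param layout a `plate_layout` or list of them.
#' @param path output path.
#' @export
write_plate_layout <- function(layout, path) {
  layouts <- if (inherits(layout, "plate_layout")) list(layout) else layout
  fmt <- unique(vapply(layouts, `[[`, 1L, "plate_format"))
  if (length(fmt) != 1L) stopf("all plates in one file must share a format")
  df <- do.call(rbind, lapply(layouts, function(l) {
    cbind(plate_id = l$plate_id, l$wells)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# plate_format: %d", fmt), con)
  utils::write.table(df, con, sep = delim_for_path(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene set file
#'
#' Each tab-separated line is `set_name<TAB>description<TAB>gene1<TAB>...`.
#' Duplicate genes within a set are collapsed with a warning; an empty
#' file yields an empty collection.
#'
#' @param path GMT file.
#' @param provenance provenance label stored on the collection.
#' @return a `gene_set_collection`.
#' @export
read_gene_sets <- function(path, provenance = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(gene_set_collection(list(), provenance))
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stopf("GMT line %d has %d field(s); need name, description, >=1 gene",
            i, length(f))
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("gene set '%s': duplicate genes collapsed", f[1L]),
              call. = FALSE)
      genes <- unique(genes)
    }
    sets[[f[1L]]] <- genes
  }
  gene_set_collection(sets, provenance)
}

#' Write a gene set collection in GMT dialect
#' @param gsc a `gene_set_collection`.
#' @param path output path.
#' @export
write_gene_sets <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$provenance, gsc$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix with its phenotype sidecar
#'
#' The matrix file is genes-by-samples delimited text with a `gene`
#' first column; the sidecar maps each sample to a class with columns
#' `sample, class`.
#'
#' @param path matrix file.
#' @param phenotype_path sidecar file.
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(path, phenotype_path) {
  df <- read_delim_file(path)
  genes <- as.character(df[[1L]])
  values <- as.matrix(df[-1L])
  rownames(values) <- genes
  ph <- read_delim_file(phenotype_path)
  phenotype <- stats::setNames(as.character(ph$class), as.character(ph$sample))
  expression_matrix(values, phenotype)
}

#' Write an expression matrix and its phenotype sidecar
#' @param em an `expression_matrix`.
#' @param path matrix output path.
#' @param phenotype_path sidecar output path.
#' @export
write_expression_matrix <- function(em, path, phenotype_path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_delim_file(df, path)
  write_delim_file(data.frame(sample = names(em$phenotype),
                              class = unname(em$phenotype)),
                   phenotype_path)
  invisible(path)
}

#' Read a dose-response viability table
#'
#' @param path file with columns
#'   `compound_id, cell_line, concentration_nM, replicate, viability`.
#' @return data.frame.
#' @export
read_dose_response <- function(path) {
  df <- read_delim_file(path)
  need <- c("compound_id", "cell_line", "concentration_nM", "replicate",
            "viability")
  if (!all(need %in% names(df))) {
    stopf("dose-response file %s lacks columns: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}

#' Write a dose-response viability table
#' @param df dose-response data.frame.
#' @param path output path.
#' @export
write_dose_response <- function(df, path) {
  write_delim_file(df, path)
  invisible(path)
}
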