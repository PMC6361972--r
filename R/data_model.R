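# Core domain types: plate layouts, well records, gene set collections,
# expression matrices. All tabular objects are plain data.frames; richer
# objects are light S3 classes, in the style of phyloseq/limma containers.

plate_geometry <- function(plate_format = 96L) {
  switch(as.character(plate_format),
         "96"  = list(rows = LETTERS[1:8],  n_col = 12L),
         "384" = list(rows = LETTERS[1:16], n_col = 24L),
         stopf("unsupported plate format: %s", plate_format))
}

#' Normalize a well address
#'
#' Accepts addresses like `"B7"` or `"b07"` and returns the canonical
#' row-letter + zero-padded column form (`"B07"`), validating against the
#' plate geometry.
#'
#' @param well character vector of well addresses.
#' @param plate_format plate size (96 or 384).
#' @return canonical character vector.
#' @export
normalize_well <- function(well, plate_format = 96L) {
  geom <- plate_geometry(plate_format)
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-Z])([0-9]{1,2})$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stopf("malformed well address: %s", paste(well[bad], collapse = ", "))
  row <- vapply(m, `[`, "", 2L)
  col <- as.integer(vapply(m, `[`, "", 3L))
  off <- !(row %in% geom$rows) | col < 1L | col > geom$n_col
  if (any(off)) {
    stopf("well address outside %d-well geometry: %s",
          plate_format, paste(well[off], collapse = ", "))
  }
  sprintf("%s%02d", row, col)
}

#' Construct a plate layout
#'
#' A plate layout maps well addresses to their role on the plate:
#' a library compound at some concentration, a vehicle (untreated
#' negative control), a positive control, or an empty well.
#'
#' @param plate_id plate identifier.
#' @param wells data.frame with columns `well`, `kind` (one of
#'   `"compound"`, `"vehicle"`, `"positive_control"`, `"empty"`),
#'   `compound_id` (NA unless kind is compound) and `concentration`
#'   (treatment dose; NA unless kind is compound or positive_control).
#' @param plate_format plate size, default 96.
#' @return an object of class `plate_layout`.
#' @export
plate_layout <- function(plate_id, wells, plate_format = 96L) {
  stopifnot(is.data.frame(wells),
            all(c("well", "kind") %in% names(wells)))
  if (is.null(wells$compound_id)) wells$compound_id <- NA_character_
  if (is.null(wells$concentration)) wells$concentration <- NA_real_
  wells$well <- normalize_well(wells$well, plate_format)
  if (anyDuplicated(wells$well)) {
    stopf("duplicate well address in layout %s: %s", plate_id,
          wells$well[duplicated(wells$well)][1L])
  }
  ok_kind <- c("compound", "vehicle", "positive_control", "empty")
  if (!all(wells$kind %in% ok_kind)) {
    stopf("unknown well kind: %s",
          paste(setdiff(unique(wells$kind), ok_kind), collapse = ", "))
  }
  cmp <- wells$kind == "compound"
  if (any(cmp & (is.na(wells$compound_id) | is.na(wells$concentration)))) {
    stopf("compound wells must carry compound_id and concentration (plate %s)",
          plate_id)
  }
  veh <- wells$kind == "vehicle"
  if (any(veh & (!is.na(wells$compound_id) | !is.na(wells$concentration)))) {
    stopf("vehicle wells must not carry compound_id or concentration (plate %s)",
          plate_id)
  }
  if (!any(veh)) stopf("layout %s has no vehicle (untreated) well", plate_id)
  structure(list(plate_id = as.character(plate_id),
                 plate_format = as.integer(plate_format),
                 wells = wells[c("well", "kind", "compound_id", "concentration")]),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %s (%d-well): %d mapped wells (%d compound, %d vehicle, %d positive control)\n",
              x$plate_id, x$plate_format, nrow(x$wells),
              sum(x$wells$kind == "compound"), sum(x$wells$kind == "vehicle"),
              sum(x$wells$kind == "positive_control")))
  invisible(x)
}

layout_roles <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  stats::setNames(layout$wells$kind, layout$wells$well)
}

#' Construct a gene set collection
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param provenance free-text provenance label (e.g. a collection name).
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, provenance = "unspecified") {
  stopifnot(is.list(sets))
  if (length(sets) > 0 && (is.null(names(sets)) || any(names(sets) == ""))) {
    stopf("all gene sets must be named")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) < 1L)) stopf("gene sets must have size >= 1")
  structure(list(sets = sets, provenance = provenance),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (provenance: %s); sizes %s\n",
              length(x$sets), x$provenance,
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-") else "-"))
  invisible(x)
}

#' Construct an expression matrix with a binary phenotype
#'
#' @param values numeric genes-by-samples matrix with row and column names.
#' @param phenotype named character vector mapping every sample to
#'   `"sensitive"` or `"resistant"`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, phenotype) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("expression matrix needs gene rownames and sample colnames")
  }
  if (anyNA(values)) stopf("expression matrix contains missing values")
  phenotype <- phenotype[colnames(values)]
  if (anyNA(phenotype)) stopf("phenotype missing for some samples")
  if (!all(phenotype %in% c("sensitive", "resistant"))) {
    stopf("phenotype labels must be 'sensitive' or 'resistant'")
  }
  if (any(table(factor(phenotype, c("sensitive", "resistant"))) < 2L)) {
    stopf("each phenotype class needs >= 2 samples")
  }
  structure(list(values = values, phenotype = phenotype),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$phenotype)
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
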