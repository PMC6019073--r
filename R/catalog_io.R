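#' Read a DN catalog from CSV or JSON
#'
#' The CSV schema has one row per DN type with mandatory columns
#' `type_id, soma_group, kind, n_pairs, laterality, tract` followed by one
#' polarity-code column per atlas compartment (brain first, then VNC).
#' Columns that match no compartment of either atlas are an error. The
#' JSON schema is a list of record objects, each carrying the same scalar
#' fields plus `brain_innervation` / `vnc_innervation` maps from
#' compartment abbreviation to polarity code; absent keys mean no
#' innervation.
#'
#' @param path file to read; format inferred from the extension
#'   (`.csv` / `.json`) unless `format` is given.
#' @param brain_atlas,vnc_atlas [neuropil_atlas()] objects; defaults from
#'   [load_default_atlases()].
#' @param format `"csv"`, `"json"`, or `"auto"`.
#' @return a [dn_catalog()].
#' @seealso [write_catalog()]
#' @export
parse_catalog <- function(path, brain_atlas = NULL, vnc_atlas = NULL,
                          format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  atl <- load_default_atlases()
  if (is.null(brain_atlas)) brain_atlas <- atl$brain
  if (is.null(vnc_atlas)) vnc_atlas <- atl$vnc

  if (format == "csv") {
    .parse_catalog_csv(path, brain_atlas, vnc_atlas)
  } else {
    .parse_catalog_json(path, brain_atlas, vnc_atlas)
  }
}

.meta_columns <- c("type_id", "soma_group", "kind", "n_pairs", "laterality",
                   "tract")

.parse_catalog_csv <- function(path, brain_atlas, vnc_atlas) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(.meta_columns, names(tab))
  if (length(missing) > 0) {
    stop("catalog CSV lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  b_ab <- atlas_abbrevs(brain_atlas)
  v_ab <- atlas_abbrevs(vnc_atlas)
  neuropil_cols <- setdiff(names(tab), .meta_columns)
  unknown <- setdiff(neuropil_cols, c(b_ab, v_ab))
  if (length(unknown) > 0) {
    stop("catalog columns match no atlas compartment: ",
         paste(unknown, collapse = ", "))
  }
  ids <- tab$type_id
  codes <- function(abbrevs) {
    cols <- intersect(abbrevs, neuropil_cols)
    m <- matrix("N", nrow(tab), length(cols), dimnames = list(ids, cols))
    for (cl in cols) m[, cl] <- tab[[cl]]
    m
  }
  dn_catalog(records = tab[, .meta_columns],
             brain = if (nrow(tab) > 0) codes(b_ab) else NULL,
             vnc = if (nrow(tab) > 0) codes(v_ab) else NULL,
             brain_atlas = brain_atlas, vnc_atlas = vnc_atlas,
             provenance = paste0("parsed from ", basename(path)))
}

.parse_catalog_json <- function(path, brain_atlas, vnc_atlas) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  recs <- if (!is.null(doc$records)) doc$records else doc
  n <- length(recs)
  records <- data.frame(
    type_id = vapply(recs, function(r) as.character(r$type_id), ""),
    soma_group = vapply(recs, function(r) as.character(r$soma_group), ""),
    kind = vapply(recs, function(r) as.character(r$kind), ""),
    n_pairs = vapply(recs, function(r) as.integer(r$n_pairs), 1L),
    laterality = vapply(recs, function(r) as.character(r$laterality), ""),
    tract = vapply(recs, function(r) as.character(r$tract), ""))
  fill <- function(field, abbrevs) {
    m <- matrix("N", n, length(abbrevs),
                dimnames = list(records$type_id, abbrevs))
    for (i in seq_len(n)) {
      ann <- recs[[i]][[field]]
      if (is.null(ann)) next
      unknown <- setdiff(names(ann), abbrevs)
      if (length(unknown) > 0) {
        stop(field, " of ", records$type_id[i],
             " names compartment(s) absent from the atlas: ",
             paste(unknown, collapse = ", "))
      }
      for (np in names(ann)) m[i, np] <- as.character(ann[[np]])
    }
    m
  }
  dn_catalog(records = records,
             brain = if (n > 0) fill("brain_innervation",
                                     atlas_abbrevs(brain_atlas)) else NULL,
             vnc = if (n > 0) fill("vnc_innervation",
                                   atlas_abbrevs(vnc_atlas)) else NULL,
             brain_atlas = brain_atlas, vnc_atlas = vnc_atlas,
             provenance = paste0("parsed from ", basename(path)))
}

#' Write a DN catalog to CSV or JSON
#'
#' Emits a canonical, lossless serialization: records sorted by `type_id`,
#' neuropil columns in atlas order, polarity codes normalized (dense
#' annotations as bare letters). `parse_catalog(write_catalog(x))`
#' reproduces `x` up to canonical ordering.
#'
#' @param catalog a [dn_catalog()].
#' @param path output file.
#' @param format `"csv"`, `"json"`, or `"auto"` (from the extension).
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(catalog, "dn_catalog"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  catalog <- .canonicalize_catalog(catalog)
  if (format == "csv") {
    tab <- cbind(catalog$records,
                 as.data.frame(catalog$brain, optional = TRUE),
                 as.data.frame(catalog$vnc, optional = TRUE))
    names(tab) <- c(.meta_columns, colnames(catalog$brain),
                    colnames(catalog$vnc))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    recs <- lapply(seq_len(nrow(catalog$records)), function(i) {
      r <- as.list(catalog$records[i, ])
      brow <- catalog$brain[i, ]
      vrow <- catalog$vnc[i, ]
      r$brain_innervation <- as.list(brow[brow != "N"])
      r$vnc_innervation <- as.list(vrow[vrow != "N"])
      r
    })
    jsonlite::write_json(list(records = recs), path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}
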