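#' Descending-neuron nomenclature
#'
#' DN type names follow the grammar `DN` + soma-group letter + two-digit
#' index. The letter records cell-body position: `a` anterior dorsal,
#' `b` anterior ventral, `c` pars intercerebralis, `d` outside the anterior
#' cluster, `g` gnathal ganglia, `p` posterior surface, `x` outside the
#' brain.
#'
#' @param name character scalar to validate, e.g. `"DNp01"`.
#' @return a list with `valid` (logical), and for valid names `soma_group`
#'   (letter) and `index` (two-digit string); for invalid names a `reason`
#'   string describing the violation.
#' @examples
#' validate_dn_name("DNp01")
#' validate_dn_name("DNg100")$reason
#' @export
validate_dn_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!startsWith(name, "DN")) {
    return(list(valid = FALSE, reason = "name must start with prefix 'DN'"))
  }
  body <- substr(name, 3, nchar(name))
  letter <- substr(body, 1, 1)
  if (!letter %in% .soma_groups) {
    return(list(valid = FALSE,
                reason = paste0("illegal soma-group letter '", letter,
                                "' (expected one of ",
                                paste(.soma_groups, collapse = ""), ")")))
  }
  index <- substr(body, 2, nchar(body))
  if (!grepl("^[0-9]{2}$", index)) {
    return(list(valid = FALSE,
                reason = paste0("index '", index,
                                "' must be exactly two digits")))
  }
  list(valid = TRUE, soma_group = letter, index = index)
}

.soma_groups <- c("a", "b", "c", "d", "g", "p", "x")
.lateralities <- c("ipsilateral", "contralateral", "unknown")
.tracts <- c("DLT", "MDA", "MTD", "ITD", "VLT", "DLV", "VTV", "unknown")

#' Assemble a DN catalog
#'
#' A catalog couples a table of per-type metadata with two polarity-code
#' matrices recording innervation of brain and VNC compartments, each tied
#' to a [neuropil_atlas()].
#'
#' @param records data.frame with columns `type_id`, `soma_group`, `kind`
#'   (`unique` or `population`), `n_pairs` (positive integer count of
#'   bilateral pairs), `laterality` (`ipsilateral`, `contralateral`,
#'   `unknown`), `tract` (a named descending tract or `unknown`).
#' @param brain,vnc character matrices of polarity codes (see
#'   [decode_polarity()]), rows = `type_id`s, columns = atlas abbreviations.
#'   Missing rows/columns are filled with `"N"`.
#' @param brain_atlas,vnc_atlas [neuropil_atlas()] objects; default atlases
#'   are used when omitted.
#' @param provenance free-text metadata string.
#' @return an object of class `dn_catalog`.
#' @examples
#' rec <- data.frame(type_id = "DNp01", soma_group = "p", kind = "unique",
#'                   n_pairs = 1, laterality = "ipsilateral", tract = "MTD")
#' b <- matrix("S", 1, 1, dimnames = list("DNp01", "PVLP"))
#' v <- matrix("V", 1, 1, dimnames = list("DNp01", "LTct"))
#' cat1 <- dn_catalog(rec, brain = b, vnc = v)
#' @export
dn_catalog <- function(records, brain = NULL, vnc = NULL,
                       brain_atlas = NULL, vnc_atlas = NULL,
                       provenance = "") {
  atl <- load_default_atlases()
  if (is.null(brain_atlas)) brain_atlas <- atl$brain
  if (is.null(vnc_atlas)) vnc_atlas <- atl$vnc
  stopifnot(inherits(brain_atlas, "neuropil_atlas"),
            inherits(vnc_atlas, "neuropil_atlas"))

  required <- c("type_id", "soma_group", "kind", "n_pairs", "laterality",
                "tract")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("records lack mandatory column(s): ", paste(missing, collapse = ", "))
  }
  records <- as.data.frame(records)[, required]
  for (col in setdiff(required, "n_pairs")) {
    records[[col]] <- as.character(records[[col]])
  }
  records$n_pairs <- as.integer(records$n_pairs)

  if (anyDuplicated(records$type_id)) {
    dup <- unique(records$type_id[duplicated(records$type_id)])
    stop("duplicated type_id(s): ", paste(dup, collapse = ", "))
  }
  for (id in records$type_id) {
    v <- validate_dn_name(id)
    if (!v$valid) stop("invalid type_id '", id, "': ", v$reason)
  }
  bad <- records$soma_group != substr(records$type_id, 3, 3)
  if (any(bad)) {
    stop("soma_group disagrees with type_id for: ",
         paste(records$type_id[bad], collapse = ", "))
  }
  if (!all(records$kind %in% c("unique", "population"))) {
    stop("kind must be 'unique' or 'population'")
  }
  if (any(is.na(records$n_pairs)) || any(records$n_pairs < 1L)) {
    stop("n_pairs must be a positive integer")
  }
  bad <- records$kind == "unique" & records$n_pairs != 1L
  if (any(bad)) {
    stop("unique types must have n_pairs = 1: ",
         paste(records$type_id[bad], collapse = ", "))
  }
  if (!all(records$laterality %in% .lateralities)) {
    stop("laterality must be one of: ", paste(.lateralities, collapse = ", "))
  }
  if (!all(records$tract %in% .tracts)) {
    stop("tract must be one of: ", paste(.tracts, collapse = ", "))
  }
  rownames(records) <- NULL

  brain <- .conform_codes(brain, records$type_id, atlas_abbrevs(brain_atlas),
                          "brain")
  vnc <- .conform_codes(vnc, records$type_id, atlas_abbrevs(vnc_atlas), "vnc")

  smooth_vnc <- decode_polarity(vnc)$polarity %in% c("smooth", "both")
  if (any(smooth_vnc)) {
    # VNC terminals are expected to be varicose (output) endings; smooth
    # annotations there are legal but worth surfacing.
    message("note: ", sum(smooth_vnc),
            " VNC annotation(s) include smooth (input-like) processes")
  }

  structure(list(records = records, brain = brain, vnc = vnc,
                 brain_atlas = brain_atlas, vnc_atlas = vnc_atlas,
                 provenance = as.character(provenance)),
            class = "dn_catalog")
}

# Expand/validate a polarity-code matrix against row and column universes.
.conform_codes <- function(codes, type_ids, abbrevs, what) {
  full <- matrix("N", nrow = length(type_ids), ncol = length(abbrevs),
                 dimnames = list(type_ids, abbrevs))
  if (is.null(codes)) return(full)
  stopifnot(is.matrix(codes))
  if (is.null(rownames(codes)) || is.null(colnames(codes))) {
    stop(what, " code matrix needs row and column names")
  }
  unknown_rows <- setdiff(rownames(codes), type_ids)
  if (length(unknown_rows) > 0) {
    stop(what, " codes reference unknown type_id(s): ",
         paste(unknown_rows, collapse = ", "))
  }
  unknown_cols <- setdiff(colnames(codes), abbrevs)
  if (length(unknown_cols) > 0) {
    stop(what, " codes reference neuropil(s) absent from the atlas: ",
         paste(unknown_cols, collapse = ", "))
  }
  codes <- .normalize_codes(codes)
  full[rownames(codes), colnames(codes)] <- codes
  full
}

#' @export
print.dn_catalog <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "<dn_catalog> %d types (%d unique, %d population), %d bilateral pairs\n",
    nrow(r), sum(r$kind == "unique"), sum(r$kind == "population"),
    sum(r$n_pairs)))
  cat(sprintf("  brain atlas: %d compartments; vnc atlas: %d compartments\n",
              nrow(x$brain_atlas), nrow(x$vnc_atlas)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of DN types in a catalog
#' @param catalog a [dn_catalog()]
#' @return integer count of types (rows).
#' @export
n_types <- function(catalog) {
  stopifnot(inherits(catalog, "dn_catalog"))
  nrow(catalog$records)
}

# Canonical form: records sorted by type_id, codes in atlas order.
.canonicalize_catalog <- function(catalog) {
  ord <- order(catalog$records$type_id)
  ids <- catalog$records$type_id[ord]
  catalog$records <- catalog$records[ord, , drop = FALSE]
  rownames(catalog$records) <- NULL
  catalog$brain <- catalog$brain[ids, atlas_abbrevs(catalog$brain_atlas),
                                 drop = FALSE]
  catalog$vnc <- catalog$vnc[ids, atlas_abbrevs(catalog$vnc_atlas),
                             drop = FALSE]
  catalog
}
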