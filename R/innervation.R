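#' Build a binary innervation matrix
#'
#' Converts the polarity annotations of a catalog into a 0/1 DN-type by
#' neuropil matrix under a polarity filter. Following the scoring
#' convention used throughout the analyses, `smooth` matches annotations
#' `smooth` or `both` (a compartment receiving both kinds of processes is
#' an input site too), `varicose` matches `varicose` or `both`, and `any`
#' matches any innervation. Ordinal annotations are thresholded:
#' an entry scores 1 only when its intensity is at least
#' `intensity_threshold` (1 counts sparse innervation, 2 restricts to
#' dense).
#'
#' @param catalog a [dn_catalog()].
#' @param side `"brain"` or `"vnc"` (which annotation block and atlas).
#' @param polarity_filter `"smooth"`, `"varicose"`, or `"any"`.
#' @param intensity_threshold minimum ordinal intensity scored as
#'   innervation (default 1 = sparse counts).
#' @param atlas optional [neuropil_atlas()] restricting/ordering the
#'   columns; defaults to the catalog's atlas for `side`.
#' @return an `innervation_matrix`: an integer 0/1 matrix with type_id
#'   rows, neuropil columns, and attributes `polarity_filter`, `side`,
#'   `intensity_threshold`.
#' @examples
#' cat1 <- generate_catalog(seed = 1)$catalog
#' m <- build_matrix(cat1, side = "vnc", polarity_filter = "varicose")
#' colSums(m)
#' @export
build_matrix <- function(catalog, side = c("brain", "vnc"),
                         polarity_filter = c("smooth", "varicose", "any"),
                         intensity_threshold = 1L, atlas = NULL) {
  stopifnot(inherits(catalog, "dn_catalog"))
  side <- match.arg(side)
  polarity_filter <- match.arg(polarity_filter)
  stopifnot(intensity_threshold >= 0)
  codes <- if (side == "brain") catalog$brain else catalog$vnc
  if (is.null(atlas)) {
    atlas <- if (side == "brain") catalog$brain_atlas else catalog$vnc_atlas
  }
  abbrevs <- atlas_abbrevs(atlas)
  if (length(abbrevs) == 0) stop("empty atlas")
  unknown <- setdiff(abbrevs, colnames(codes))
  if (length(unknown) > 0) {
    stop("atlas compartment(s) absent from catalog annotations: ",
         paste(unknown, collapse = ", "))
  }
  codes <- codes[, abbrevs, drop = FALSE]
  dec <- decode_polarity(codes)
  hit <- .polarity_matches(dec$polarity, polarity_filter) &
    dec$intensity >= intensity_threshold
  m <- matrix(as.integer(hit), nrow = nrow(codes), ncol = ncol(codes),
              dimnames = dimnames(codes))
  structure(m, polarity_filter = polarity_filter, side = side,
            intensity_threshold = as.integer(intensity_threshold),
            class = c("innervation_matrix", class(m)))
}

#' @export
print.innervation_matrix <- function(x, ...) {
  cat(sprintf("<innervation_matrix> %d types x %d neuropils (side=%s, polarity=%s, intensity>=%d)\n",
              nrow(x), ncol(x), attr(x, "side"), attr(x, "polarity_filter"),
              attr(x, "intensity_threshold")))
  print(unclass(x), ...)
  invisible(x)
}

#' Per-neuropil innervation counts
#'
#' Column totals of an innervation matrix under two weightings:
#' `types` counts DN types (one per matrix row), `cells` weights each row
#' by its number of bilateral pairs, counting neurons individually the
#' way population types are tallied in the census figures.
#'
#' @param matrix an [build_matrix()] result (or any 0/1 matrix with
#'   type_id rownames).
#' @param catalog the source [dn_catalog()]; required for
#'   `weighting = "cells"`.
#' @param weighting `"types"` or `"cells"`.
#' @return named numeric vector of per-neuropil counts.
#' @export
neuropil_counts <- function(matrix, catalog = NULL,
                            weighting = c("types", "cells")) {
  weighting <- match.arg(weighting)
  if (weighting == "types") {
    return(colSums(matrix))
  }
  stopifnot(inherits(catalog, "dn_catalog"))
  idx <- match(rownames(matrix), catalog$records$type_id)
  if (anyNA(idx)) {
    stop("matrix rows absent from catalog: ",
         paste(rownames(matrix)[is.na(idx)], collapse = ", "))
  }
  w <- catalog$records$n_pairs[idx]
  colSums(matrix * w)
}

#' Innervation breadth per DN type
#'
#' Row sums of an innervation matrix (how many compartments each type
#' reaches), with their mean, population standard deviation, and a
#' histogram table of breadth values.
#'
#' @param matrix an innervation matrix with at least one row.
#' @return a list with `breadth` (named integer vector), `mean`, `sd`
#'   (population SD, divisor n), and `histogram` (a table over observed
#'   breadths 0..max).
#' @export
innervation_breadth <- function(matrix) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0) stop("empty matrix")
  b <- rowSums(matrix)
  m <- mean(b)
  sdev <- sqrt(mean((b - m)^2))
  hist <- table(factor(b, levels = 0:max(b)))
  list(breadth = b, mean = m, sd = sdev, histogram = hist)
}

#' Select DN types by required innervation
#'
#' Returns the types whose row has a 1 in at least one member of every
#' requirement set — e.g. `list("Wing", c("LegT1","LegT2","LegT3"))`
#' selects the rare types with projections to both wing and leg neuropil.
#'
#' @param matrix an innervation matrix.
#' @param must_include list of character vectors of neuropil abbreviations;
#'   an empty list selects every type.
#' @return character vector of type_ids, in matrix row order.
#' @export
select_types <- function(matrix, must_include = list()) {
  stopifnot(is.list(must_include))
  unknown <- setdiff(unlist(must_include), colnames(matrix))
  if (length(unknown) > 0) {
    stop("unknown neuropil(s): ", paste(unknown, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(matrix))
  for (set in must_include) {
    keep <- keep & rowSums(matrix[, set, drop = FALSE]) > 0
  }
  rownames(matrix)[keep]
}

#' Export / import an innervation matrix as CSV with a JSON sidecar
#'
#' The CSV carries the 0/1 values with row and column headers; the sidecar
#' (`<path>.json`) records the polarity filter, side and intensity
#' threshold so the matrix provenance survives a round trip.
#'
#' @param matrix an innervation matrix.
#' @param path CSV output path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns
#'   an `innervation_matrix`.
#' @export
write_matrix <- function(matrix, path) {
  utils::write.csv(as.data.frame(unclass(matrix)), path, quote = FALSE)
  meta <- list(polarity_filter = attr(matrix, "polarity_filter"),
               side = attr(matrix, "side"),
               intensity_threshold = attr(matrix, "intensity_threshold"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(tab)
  storage.mode(m) <- "integer"
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list(polarity_filter = NA_character_, side = NA_character_,
         intensity_threshold = NA_integer_)
  }
  structure(m, polarity_filter = meta$polarity_filter, side = meta$side,
            intensity_threshold = meta$intensity_threshold,
            class = c("innervation_matrix", class(m)))
}
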