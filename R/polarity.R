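# Polarity codes --------------------------------------------------------
#
# Each (neuron, neuropil) annotation carries a polarity and an ordinal
# intensity. Polarity distinguishes smooth (putatively postsynaptic,
# dendritic) from varicose (putatively presynaptic, output) neurites, with
# "both" for compartments receiving the two kinds and "none" for no
# innervation. Intensity is a 0/1/2 ordinal (absent/sparse/dense) used for
# fine-grained annotations such as optic-glomerulus tables; plain catalogs
# leave it at dense for any innervated compartment.
#
# File codes (single cell of a catalog table):
#   "N"              none (intensity 0)
#   "S", "V", "B"    smooth / varicose / both, dense (intensity 2)
#   "S1","V1","B1"   same polarities at sparse intensity
#   "S2","V2","B2"   explicit dense
#   "0","1","2"      ordinal shorthand: absent / sparse / dense smooth
#   ""               treated as "N"

.polarity_levels <- c("none", "smooth", "varicose", "both")

#' Decode polarity annotation codes
#'
#' @param code character vector of annotation codes (see Details).
#' @return a list with character vector `polarity` (one of `none`, `smooth`,
#'   `varicose`, `both`) and integer vector `intensity` (0 = absent,
#'   1 = sparse, 2 = dense).
#' @details Valid codes are `N`, `S`, `V`, `B` optionally suffixed with an
#'   intensity digit (`S1` = sparse smooth), the bare ordinal digits
#'   `0`/`1`/`2` (absent / sparse smooth / dense smooth), and the empty
#'   string (none). `none` always has intensity 0 and vice versa.
#' @examples
#' decode_polarity(c("S", "B1", "0", "2"))
#' @export
decode_polarity <- function(code) {
  code <- as.character(code)
  code[is.na(code) | code == ""] <- "N"
  polarity <- character(length(code))
  intensity <- integer(length(code))
  letter_map <- c(N = "none", S = "smooth", V = "varicose", B = "both")
  for (i in seq_along(code)) {
    x <- code[i]
    if (x %in% c("0", "1", "2")) {
      lvl <- as.integer(x)
      polarity[i] <- if (lvl == 0L) "none" else "smooth"
      intensity[i] <- lvl
    } else if (grepl("^[NSVB][12]?$", x)) {
      polarity[i] <- letter_map[[substr(x, 1, 1)]]
      if (polarity[i] == "none") {
        if (nchar(x) > 1) stop("polarity 'N' cannot carry an intensity: ", x)
        intensity[i] <- 0L
      } else {
        intensity[i] <- if (nchar(x) == 2) as.integer(substr(x, 2, 2)) else 2L
      }
    } else {
      stop("unknown polarity code: '", x, "'")
    }
  }
  list(polarity = polarity, intensity = intensity)
}

#' Encode polarity/intensity pairs as file codes
#'
#' Canonical inverse of [decode_polarity()]: dense annotations are written
#' as the bare polarity letter, sparse ones with a `1` suffix.
#'
#' @param polarity character vector in `none`/`smooth`/`varicose`/`both`.
#' @param intensity integer vector in 0..2 (defaults to dense where
#'   innervated).
#' @return character vector of codes.
#' @export
encode_polarity <- function(polarity, intensity = NULL) {
  stopifnot(all(polarity %in% .polarity_levels))
  if (is.null(intensity)) intensity <- ifelse(polarity == "none", 0L, 2L)
  stopifnot(length(polarity) == length(intensity), all(intensity %in% 0:2))
  if (any(xor(polarity == "none", intensity == 0L))) {
    stop("polarity 'none' must pair with intensity 0, and only with it")
  }
  letter <- c(none = "N", smooth = "S", varicose = "V", both = "B")[polarity]
  ifelse(intensity == 1L, paste0(letter, "1"), letter)
}

# Normalize a code matrix to canonical encoding; validates as a side effect.
.normalize_codes <- function(codes) {
  dec <- decode_polarity(codes)
  out <- encode_polarity(dec$polarity, dec$intensity)
  dim(out) <- dim(codes)
  dimnames(out) <- dimnames(codes)
  out
}

# Does a decoded polarity match a filter?
.polarity_matches <- function(polarity, filter) {
  switch(filter,
         smooth   = polarity %in% c("smooth", "both"),
         varicose = polarity %in% c("varicose", "both"),
         any      = polarity != "none",
         stop("unknown polarity filter: ", filter))
}
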