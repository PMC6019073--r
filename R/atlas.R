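#' Construct a neuropil atlas
#'
#' An atlas is an ordered list of CNS compartments, each identified by a
#' unique abbreviation and assigned to exactly one analysis group. Atlases
#' fix the column order of innervation matrices and supply the group labels
#' used by the pathway-level summaries.
#'
#' @param compartments a data.frame with character columns `abbrev`, `name`
#'   and `group`, one row per compartment, in display order.
#' @param side one of `"brain"`, `"vnc"`, `"custom"`.
#' @return an object of class `neuropil_atlas` (a data.frame with a `side`
#'   attribute).
#' @examples
#' optic <- neuropil_atlas(
#'   data.frame(abbrev = c("LC4", "LC22"),
#'              name   = c("LC4 glomerulus", "LC22 glomerulus"),
#'              group  = "glomerulus"),
#'   side = "custom")
#' @export
neuropil_atlas <- function(compartments, side = c("brain", "vnc", "custom")) {
  side <- match.arg(side)
  stopifnot(is.data.frame(compartments))
  required <- c("abbrev", "name", "group")
  missing <- setdiff(required, names(compartments))
  if (length(missing) > 0) {
    stop("atlas table lacks column(s): ", paste(missing, collapse = ", "))
  }
  compartments <- compartments[, required]
  for (col in required) {
    compartments[[col]] <- as.character(compartments[[col]])
  }
  if (anyDuplicated(compartments$abbrev)) {
    dup <- unique(compartments$abbrev[duplicated(compartments$abbrev)])
    stop("duplicated compartment abbreviation(s): ", paste(dup, collapse = ", "))
  }
  if (any(is.na(compartments$group)) || any(compartments$group == "")) {
    stop("every compartment needs exactly one group label")
  }
  rownames(compartments) <- NULL
  structure(compartments, side = side,
            class = c("neuropil_atlas", "data.frame"))
}

#' @export
print.neuropil_atlas <- function(x, ...) {
  cat(sprintf("<neuropil_atlas> side=%s, %d compartments, %d groups\n",
              attr(x, "side"), nrow(x), length(unique(x$group))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Abbreviations of an atlas, in atlas order
#' @param atlas a [neuropil_atlas()]
#' @return character vector of compartment abbreviations.
#' @export
atlas_abbrevs <- function(atlas) {
  stopifnot(inherits(atlas, "neuropil_atlas"))
  atlas$abbrev
}

#' Group label of one or more compartments
#' @param atlas a [neuropil_atlas()]
#' @param abbrev character vector of compartment abbreviations.
#' @return character vector of group labels, named by `abbrev`.
#' @export
atlas_group <- function(atlas, abbrev) {
  stopifnot(inherits(atlas, "neuropil_atlas"))
  idx <- match(abbrev, atlas$abbrev)
  if (anyNA(idx)) {
    stop("unknown compartment(s): ", paste(abbrev[is.na(idx)], collapse = ", "))
  }
  stats::setNames(atlas$group[idx], abbrev)
}

# Canonical compartment tables -------------------------------------------

.brain_atlas_table <- function() {
  # Standard insect-brain nomenclature; mushroom body split into its four
  # lobes so the list covers 41 named compartments plus the gnathal ganglia.
  tab <- rbind(
    c("LA",   "lamina",                                   "optic_lobe"),
    c("ME",   "medulla",                                  "optic_lobe"),
    c("AME",  "accessory medulla",                        "optic_lobe"),
    c("LO",   "lobula",                                   "optic_lobe"),
    c("LOP",  "lobula plate",                             "optic_lobe"),
    c("AL",   "antennal lobe",                            "antennal"),
    c("AOTU", "anterior optic tubercle",                  "optic_tubercle"),
    c("AVLP", "anterior ventrolateral protocerebrum",     "ventrolateral"),
    c("PVLP", "posterior ventrolateral protocerebrum",    "ventrolateral"),
    c("PLP",  "posterior lateral protocerebrum",          "ventrolateral"),
    c("WED",  "wedge",                                    "ventrolateral"),
    c("LH",   "lateral horn",                             "lateral"),
    c("SLP",  "superior lateral protocerebrum",           "superior"),
    c("SIP",  "superior intermediate protocerebrum",      "superior"),
    c("SMP",  "superior medial protocerebrum",            "superior"),
    c("CRE",  "crepine",                                  "inferior"),
    c("SCL",  "superior clamp",                           "inferior"),
    c("ICL",  "inferior clamp",                           "inferior"),
    c("IB",   "inferior bridge",                          "inferior"),
    c("ATL",  "antler",                                   "inferior"),
    c("CA",   "mushroom body calyx",                      "mushroom_body"),
    c("PED",  "mushroom body pedunculus",                 "mushroom_body"),
    c("VL",   "mushroom body vertical lobe",              "mushroom_body"),
    c("ML",   "mushroom body medial lobe",                "mushroom_body"),
    c("FB",   "fan-shaped body",                          "central_complex"),
    c("EB",   "ellipsoid body",                           "central_complex"),
    c("PB",   "protocerebral bridge",                     "central_complex"),
    c("NO",   "noduli",                                   "central_complex"),
    c("BU",   "bulb",                                     "lateral"),
    c("GA",   "gall",                                     "lateral"),
    c("LAL",  "lateral accessory lobe",                   "lateral"),
    c("VES",  "vest",                                     "ventromedial"),
    c("EPA",  "epaulette",                                "ventromedial"),
    c("GOR",  "gorget",                                   "ventromedial"),
    c("SPS",  "superior posterior slope",                 "posterior_slope"),
    c("IPS",  "inferior posterior slope",                 "posterior_slope"),
    c("AMMC", "antennal mechanosensory and motor center", "periesophageal"),
    c("FLA",  "flange",                                   "periesophageal"),
    c("CAN",  "cantle",                                   "periesophageal"),
    c("PRW",  "prow",                                     "periesophageal"),
    c("SAD",  "saddle",                                   "periesophageal"),
    c("GNG",  "gnathal ganglia",                          "gnathal")
  )
  data.frame(abbrev = tab[, 1], name = tab[, 2], group = tab[, 3])
}

.vnc_atlas_table <- function() {
  tab <- rbind(
    c("Neck",    "neck neuropil",                       "dorsal"),
    c("Wing",    "wing neuropil",                       "dorsal"),
    c("Haltere", "haltere neuropil",                    "dorsal"),
    c("Tct",     "tectulum",                            "tectulum"),
    c("LTct",    "lower tectulum",                      "lower_tectulum"),
    c("LegT1",   "prothoracic (foreleg) neuropil",      "leg"),
    c("LegT2",   "mesothoracic (middle-leg) neuropil",  "leg"),
    c("LegT3",   "metathoracic (hindleg) neuropil",     "leg"),
    c("AMN",     "accessory mesothoracic neuropil",     "other"),
    c("VAC",     "ventral association center",          "other"),
    c("mVAC",    "medial ventral association center",   "other"),
    c("AS",      "abdominal segments",                  "other")
  )
  data.frame(abbrev = tab[, 1], name = tab[, 2], group = tab[, 3])
}

#' Default brain and VNC atlases
#'
#' The brain atlas lists the standard named neuropils of the fly brain
#' (optic lobes included, mushroom body split into calyx, pedunculus and
#' the two lobes) together with the gnathal ganglia (GNG). The VNC atlas
#' lists the twelve nerve-cord compartments used throughout the analyses,
#' grouped as dorsal (neck, wing, haltere), tectulum, lower tectulum, the
#' three bilateral leg neuromeres, and the smaller association centers
#' (AMN, VAC, mVAC, AS) as "other". Both atlases are user-extensible via
#' [neuropil_atlas()].
#'
#' @return a list with elements `brain` and `vnc`, each a [neuropil_atlas()].
#' @examples
#' atl <- load_default_atlases()
#' atlas_group(atl$vnc, c("Wing", "mVAC"))
#' @export
load_default_atlases <- function() {
  list(brain = neuropil_atlas(.brain_atlas_table(), side = "brain"),
       vnc   = neuropil_atlas(.vnc_atlas_table(), side = "vnc"))
}

#' Read or write an atlas as YAML
#'
#' The YAML layout is a top-level `side` scalar plus a `compartments`
#' sequence of `{abbrev, name, group}` mappings, in atlas order.
#'
#' @param path file path.
#' @param atlas a [neuropil_atlas()] (for writing).
#' @return `read_atlas` returns a [neuropil_atlas()]; `write_atlas` returns
#'   `path` invisibly.
#' @export
read_atlas <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$compartments)) stop("atlas YAML lacks a 'compartments' list")
  comp <- do.call(rbind, lapply(doc$compartments, function(x) {
    data.frame(abbrev = x$abbrev, name = x$name, group = x$group)
  }))
  neuropil_atlas(comp, side = if (is.null(doc$side)) "custom" else doc$side)
}

#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "neuropil_atlas"))
  doc <- list(
    side = attr(atlas, "side"),
    compartments = lapply(seq_len(nrow(atlas)), function(i) {
      list(abbrev = atlas$abbrev[i], name = atlas$name[i],
           group = atlas$group[i])
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}
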