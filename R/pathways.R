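#' Bipartite brain-to-VNC connectivity matrix
#'
#' Entry (v, b) counts the DN types (or pair-weighted cells) that both
#' receive `brain_filter`-matching processes in brain neuropil `b` and
#' place `vnc_filter`-matching processes in VNC neuropil `v`. The default
#' filters follow the scoring convention for descending information flow:
#' smooth (input) processes on the brain side, varicose (output)
#' processes on the nerve-cord side.
#'
#' @param catalog a [dn_catalog()].
#' @param brain_filter,vnc_filter polarity filters (see [build_matrix()]).
#' @param weighting `"types"` (default, counts DN types) or `"cells"`
#'   (weights by `n_pairs`).
#' @return a `connectivity_matrix`: numeric matrix, rows = VNC neuropils,
#'   columns = brain neuropils, with attributes `weighting`,
#'   `brain_filter`, `vnc_filter`.
#' @examples
#' cat1 <- generate_catalog(seed = 1)$catalog
#' C <- connectivity_matrix(cat1)
#' rank_pathways(C, top_n = 3)
#' @export
connectivity_matrix <- function(catalog, brain_filter = "smooth",
                                vnc_filter = "varicose",
                                weighting = c("types", "cells")) {
  weighting <- match.arg(weighting)
  Mb <- build_matrix(catalog, side = "brain", polarity_filter = brain_filter)
  Mv <- build_matrix(catalog, side = "vnc", polarity_filter = vnc_filter)
  w <- if (weighting == "cells") catalog$records$n_pairs else
    rep(1L, n_types(catalog))
  C <- t(unclass(Mv)) %*% (unclass(Mb) * w)
  structure(C, weighting = weighting, brain_filter = brain_filter,
            vnc_filter = vnc_filter,
            class = c("connectivity_matrix", class(C)))
}

#' Brain-input counts for DNs targeting one VNC neuropil
#'
#' Restricts the catalog to DN types with a `vnc_filter`-matching process
#' in `vnc_neuropil` (the "grouped by output" view) and counts their
#' brain innervation per neuropil. Equals the corresponding row of
#' [connectivity_matrix()].
#'
#' @param catalog a [dn_catalog()].
#' @param vnc_neuropil a VNC compartment abbreviation.
#' @inheritParams connectivity_matrix
#' @return named numeric vector over brain neuropils.
#' @export
group_counts_by_target <- function(catalog, vnc_neuropil,
                                   brain_filter = "smooth",
                                   vnc_filter = "varicose",
                                   weighting = c("types", "cells")) {
  weighting <- match.arg(weighting)
  Mv <- build_matrix(catalog, side = "vnc", polarity_filter = vnc_filter)
  if (!vnc_neuropil %in% colnames(Mv)) {
    stop("unknown VNC neuropil: ", vnc_neuropil)
  }
  sel <- rownames(Mv)[Mv[, vnc_neuropil] == 1L]
  Mb <- build_matrix(catalog, side = "brain", polarity_filter = brain_filter)
  sub <- Mb[sel, , drop = FALSE]
  if (weighting == "types") return(colSums(sub))
  w <- catalog$records$n_pairs[match(sel, catalog$records$type_id)]
  colSums(sub * w)
}

#' VNC-output counts for DNs originating in one brain neuropil
#'
#' Mirror of [group_counts_by_target()]: restricts to DN types with a
#' `brain_filter`-matching process in `brain_neuropil` (the "grouped by
#' input" view) and counts their VNC innervation. Equals the
#' corresponding column of [connectivity_matrix()].
#'
#' @param catalog a [dn_catalog()].
#' @param brain_neuropil a brain compartment abbreviation.
#' @inheritParams connectivity_matrix
#' @return named numeric vector over VNC neuropils.
#' @export
group_counts_by_source <- function(catalog, brain_neuropil,
                                   brain_filter = "smooth",
                                   vnc_filter = "varicose",
                                   weighting = c("types", "cells")) {
  weighting <- match.arg(weighting)
  Mb <- build_matrix(catalog, side = "brain", polarity_filter = brain_filter)
  if (!brain_neuropil %in% colnames(Mb)) {
    stop("unknown brain neuropil: ", brain_neuropil)
  }
  sel <- rownames(Mb)[Mb[, brain_neuropil] == 1L]
  Mv <- build_matrix(catalog, side = "vnc", polarity_filter = vnc_filter)
  sub <- Mv[sel, , drop = FALSE]
  if (weighting == "types") return(colSums(sub))
  w <- catalog$records$n_pairs[match(sel, catalog$records$type_id)]
  colSums(sub * w)
}

#' Rank brain-to-VNC pathways by DN count
#'
#' Flattens a connectivity matrix into (brain, vnc, count) triples sorted
#' by count, ties broken by brain then VNC label order (matrix order).
#' Zero-count pairs are dropped, so a zero matrix yields an empty ranking.
#'
#' @param C a [connectivity_matrix()].
#' @param top_n maximum number of triples to return (>= 1).
#' @return data.frame with columns `brain`, `vnc`, `count`.
#' @export
rank_pathways <- function(C, top_n = Inf) {
  if (top_n < 1) stop("top_n must be at least 1")
  brain_lab <- colnames(C)
  vnc_lab <- rownames(C)
  df <- data.frame(
    brain = rep(brain_lab, each = length(vnc_lab)),
    vnc = rep(vnc_lab, times = length(brain_lab)),
    count = as.vector(unclass(C)))
  df <- df[df$count > 0, , drop = FALSE]
  ord <- order(-df$count, match(df$brain, brain_lab), match(df$vnc, vnc_lab))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, n = if (is.finite(top_n)) top_n else nrow(df))
}

#' Aggregate connectivity by atlas group
#'
#' Sums a connectivity matrix over (brain group, VNC group) blocks — the
#' resolution at which the dominant descending pathways (posterior slope
#' to dorsal neuropils; GNG to leg neuromeres) stand out.
#'
#' @param C a [connectivity_matrix()].
#' @param brain_atlas,vnc_atlas the atlases supplying group labels.
#' @return numeric matrix, rows = VNC groups, columns = brain groups.
#' @export
aggregate_by_group <- function(C, brain_atlas, vnc_atlas) {
  bg <- atlas_group(brain_atlas, colnames(C))
  vg <- atlas_group(vnc_atlas, rownames(C))
  out <- rowsum(t(rowsum(unclass(C), vg)), bg)
  t(out)
}

#' Normalized convergence index of a VNC target
#'
#' Shannon entropy (natural log, with 0*log 0 = 0) of the brain-source
#' distribution feeding one VNC neuropil, normalized by the log count of
#' brain compartments with any nonzero count in the whole matrix: 0 for a
#' single-source (direct) target, 1 for a uniformly convergent one.
#'
#' @param C a [connectivity_matrix()].
#' @param vnc_neuropil row label of the target.
#' @return a number in \[0, 1\].
#' @export
convergence_index <- function(C, vnc_neuropil) {
  if (!vnc_neuropil %in% rownames(C)) {
    stop("unknown VNC neuropil: ", vnc_neuropil)
  }
  row <- unclass(C)[vnc_neuropil, ]
  if (sum(row) <= 0) stop("target row has zero total")
  p <- row[row > 0] / sum(row)
  H <- -sum(p * log(p))
  active <- sum(colSums(unclass(C)) > 0)
  if (active <= 1) return(0)
  H / log(active)
}

#' Distribution of DNs over descending tracts
#'
#' Pair-weighted counts of DNs per descending tract. With
#' `group_by = "vnc_group"` the counts are cross-tabulated against the
#' VNC compartment groups each DN targets with `vnc_filter`-matching
#' processes; a DN targeting several groups contributes to each of their
#' rows, so grouped totals can exceed the catalog total. Records with
#' tract `"unknown"` are excluded from the main table and reported in the
#' `unknown` attribute.
#'
#' @param catalog a [dn_catalog()].
#' @param group_by `"none"` or `"vnc_group"`.
#' @param vnc_filter polarity filter for the grouped variant.
#' @return for `"none"` a named numeric vector over tracts; for
#'   `"vnc_group"` a matrix (rows = VNC groups, columns = tracts). Both
#'   carry attribute `unknown` = pair-weighted count of unknown-tract DNs.
#' @export
tract_distribution <- function(catalog, group_by = c("none", "vnc_group"),
                               vnc_filter = "varicose") {
  group_by <- match.arg(group_by)
  r <- catalog$records
  known <- r$tract != "unknown"
  n_unknown <- sum(r$n_pairs[!known])
  tracts <- setdiff(.tracts, "unknown")
  if (group_by == "none") {
    counts <- vapply(tracts, function(tr) {
      sum(r$n_pairs[known & r$tract == tr])
    }, numeric(1))
    return(structure(counts, unknown = n_unknown))
  }
  Mv <- build_matrix(catalog, side = "vnc", polarity_filter = vnc_filter)
  groups <- atlas_group(catalog$vnc_atlas, colnames(Mv))
  glevels <- unique(catalog$vnc_atlas$group)
  out <- matrix(0, length(glevels), length(tracts),
                dimnames = list(glevels, tracts))
  for (i in seq_len(nrow(r))) {
    if (!known[i]) next
    hit_groups <- unique(groups[Mv[i, ] == 1L])
    out[hit_groups, r$tract[i]] <- out[hit_groups, r$tract[i]] + r$n_pairs[i]
  }
  structure(out, unknown = n_unknown)
}
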