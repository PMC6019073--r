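#' Half-up rounded percentage
#'
#' `100 * n / d` rounded half-up (0.5 always rounds away from zero, not
#' banker's rounding) to the requested number of decimals. Half-up is the
#' convention that reproduces the census arithmetic of printed reports
#' (e.g. 46/131 -> 35, 121/190 -> 64).
#'
#' @param numerator integer(ish) numerator.
#' @param denominator positive denominator.
#' @param decimals decimal places to keep (default 0).
#' @return the rounded percentage as a plain number.
#' @examples
#' percent_round(121, 180)      # 67
#' percent_round(19, 132, 1)    # 14.4
#' @export
percent_round <- function(numerator, denominator, decimals = 0) {
  if (length(denominator) != 1 || denominator <= 0) {
    stop("denominator must be a single positive number")
  }
  x <- 100 * numerator / denominator
  f <- 10^decimals
  # epsilon guards against values like 0.4999999... that are exactly .5
  # in rational arithmetic but fall just below it in binary floating point
  floor(x * f + 0.5 + 1e-9) / f
}

#' Laterality tallies of a catalog
#'
#' Counts ipsilateral vs contralateral DNs at the type level or the cell
#' level (weighting by bilateral-pair counts), plus the half-up rounded
#' ipsilateral percentage. Records with unknown laterality are excluded
#' and reported.
#'
#' @param catalog a nonempty [dn_catalog()].
#' @param level `"types"` or `"cells"`.
#' @return list with `ipsilateral`, `contralateral`, `unknown` counts and
#'   `percent_ipsilateral`.
#' @export
laterality_summary <- function(catalog, level = c("cells", "types")) {
  stopifnot(inherits(catalog, "dn_catalog"), n_types(catalog) > 0)
  level <- match.arg(level)
  r <- catalog$records
  w <- if (level == "cells") r$n_pairs else rep(1L, nrow(r))
  ipsi <- sum(w[r$laterality == "ipsilateral"])
  contra <- sum(w[r$laterality == "contralateral"])
  unk <- sum(w[r$laterality == "unknown"])
  if (unk > 0) {
    message("note: ", unk, " DN(s) with unknown laterality excluded")
  }
  pct <- if (ipsi + contra > 0) percent_round(ipsi, ipsi + contra, 0) else NA
  list(ipsilateral = ipsi, contralateral = contra, unknown = unk,
       percent_ipsilateral = pct)
}

#' Census table of estimated DN totals per soma cluster
#'
#' Records, per soma cluster, the whole-population DN count estimated by
#' the photoactivation census against which identified catalog coverage
#' is measured. Clusters map onto soma groups as anterior = {a, b, c, d},
#' posterior = {p}, gng = {g}; group x (soma outside the brain) is not
#' part of any census cluster.
#'
#' @param anterior,posterior,gng nonnegative integer census counts.
#' @return a `census_table` (named integer vector).
#' @export
census_table <- function(anterior, posterior, gng) {
  counts <- c(anterior = as.integer(anterior),
              posterior = as.integer(posterior), gng = as.integer(gng))
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("census counts must be nonnegative integers")
  }
  structure(counts, class = "census_table")
}

.census_clusters <- list(anterior = c("a", "b", "c", "d"), posterior = "p",
                         gng = "g")

#' Coverage of the identified catalog against a census
#'
#' Pair-weighted identified DN counts per soma cluster divided by the
#' census estimate, as half-up rounded percentages. Soma group `x` is
#' excluded (the census cannot see somata outside the brain).
#'
#' @param catalog a [dn_catalog()].
#' @param census a [census_table()].
#' @return data.frame with columns `cluster`, `identified`, `census`,
#'   `coverage_pct`. Rows where identified exceeds census are flagged in
#'   a `flagged` attribute (not an error).
#' @export
coverage_vs_census <- function(catalog, census) {
  stopifnot(inherits(catalog, "dn_catalog"), inherits(census, "census_table"))
  r <- catalog$records
  identified <- vapply(.census_clusters, function(groups) {
    sum(r$n_pairs[r$soma_group %in% groups])
  }, numeric(1))
  out <- data.frame(cluster = names(.census_clusters),
                    identified = unname(identified),
                    census = as.integer(census[names(.census_clusters)]))
  out$coverage_pct <- mapply(percent_round, out$identified, out$census)
  flagged <- out$cluster[out$identified > out$census]
  if (length(flagged) > 0) {
    message("note: identified exceeds census for cluster(s): ",
            paste(flagged, collapse = ", "))
  }
  structure(out, flagged = flagged)
}

#' Census summary of a DN catalog
#'
#' Totals of types and bilateral pairs, the unique/population breakdown,
#' per-soma-group tallies, and the laterality split at both levels.
#'
#' @param catalog a [dn_catalog()].
#' @return a `dn_summary` list with elements `n_types`, `n_pairs`,
#'   `n_unique_types`, `n_population_types`, `n_population_cells`,
#'   `per_soma_group` (data.frame of types and pairs per group), and
#'   `laterality` (cell-level [laterality_summary()], `NULL` for an empty
#'   catalog).
#' @export
population_summary <- function(catalog) {
  stopifnot(inherits(catalog, "dn_catalog"))
  r <- catalog$records
  per_group <- data.frame(
    soma_group = .soma_groups,
    types = vapply(.soma_groups, function(g) sum(r$soma_group == g),
                   numeric(1)),
    pairs = vapply(.soma_groups, function(g) {
      sum(r$n_pairs[r$soma_group == g])
    }, numeric(1)))
  rownames(per_group) <- NULL
  out <- list(
    n_types = nrow(r),
    n_pairs = sum(r$n_pairs),
    n_unique_types = sum(r$kind == "unique"),
    n_population_types = sum(r$kind == "population"),
    n_population_cells = sum(r$n_pairs[r$kind == "population"]),
    per_soma_group = per_group,
    laterality = if (nrow(r) > 0) {
      suppressMessages(laterality_summary(catalog, level = "cells"))
    })
  class(out) <- "dn_summary"
  out
}

#' @export
print.dn_summary <- function(x, ...) {
  cat(sprintf("<dn_summary> %d types / %d bilateral pairs\n",
              x$n_types, x$n_pairs))
  cat(sprintf("  unique: %d types; population: %d types (%d cells)\n",
              x$n_unique_types, x$n_population_types, x$n_population_cells))
  if (!is.null(x$laterality)) {
    cat(sprintf("  laterality (cells): %d ipsi / %d contra (%s%% ipsi)\n",
                x$laterality$ipsilateral, x$laterality$contralateral,
                format(x$laterality$percent_ipsilateral)))
  }
  invisible(x)
}
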