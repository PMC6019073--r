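#' Configuration for the synthetic-connectome generator
#'
#' Describes a planted three-pathway descending architecture: two direct
#' pathways (posterior slope to the dorsal flight neuropils; GNG to the
#' leg neuromeres), a convergent pathway drawing sources from across the
#' brain onto the tectulum, and a diffuse remainder class. Defaults
#' mirror the coarse census of a real DN catalog — about 98 types, about
#' one fifth of them population types carrying several bilateral pairs
#' each, a 64% ipsilateral majority, and MTD-dominant tract usage for the
#' dorsal pathway — without claiming to reproduce any real matrix.
#'
#' @param pathways named list of pathway specs. Each spec is a list with
#'   `n_types`, `sources` (brain abbreviations; for the convergent class
#'   `NULL` plus `breadth` = number of sources drawn per type), `targets`
#'   (VNC abbreviations), `p_in`, `p_bg` (in-block and background
#'   innervation probabilities), `soma_probs` (named sampling weights over
#'   soma groups), `tract_probs` (named weights over tracts), and
#'   `population_fraction`.
#' @param ipsilateral_prob probability a type is ipsilateral (default
#'   0.64).
#' @param pair_lambda Poisson rate for extra pairs of population types
#'   (`n_pairs = 1 + rpois(lambda)`; default 4.6 gives a mean near 5.6
#'   pairs so ~20 population types carry ~112 cells).
#' @return a `generator_config` list.
#' @export
generator_config <- function(pathways = NULL, ipsilateral_prob = 0.64,
                             pair_lambda = 4.6) {
  if (is.null(pathways)) pathways <- .default_pathways()
  stopifnot(ipsilateral_prob >= 0, ipsilateral_prob <= 1, pair_lambda >= 0)
  for (nm in names(pathways)) {
    pw <- pathways[[nm]]
    if (pw$n_types < 0) stop("negative n_types for pathway ", nm)
    if (pw$n_types > 0 && length(pw$targets) == 0) {
      stop("pathway ", nm, " has types but no targets")
    }
    if (pw$n_types > 0 && length(pw$sources) == 0 &&
        is.null(pw$breadth)) {
      stop("pathway ", nm, " has types but no sources and no breadth")
    }
    for (p in c(pw$p_in, pw$p_bg, pw$population_fraction)) {
      if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
    }
  }
  structure(list(pathways = pathways, ipsilateral_prob = ipsilateral_prob,
                 pair_lambda = pair_lambda),
            class = "generator_config")
}

.default_pathways <- function() {
  list(
    dorsal_direct = list(
      n_types = 30, sources = c("IPS", "SPS"),
      targets = c("Neck", "Wing", "Haltere"),
      p_in = 0.9, p_bg = 0.05,
      soma_probs = c(p = 0.7, g = 0.06, a = 0.08, b = 0.06, c = 0.06,
                     d = 0.04),
      tract_probs = c(MTD = 0.7, ITD = 0.1, DLT = 0.05, MDA = 0.05,
                      VLT = 0.1),
      population_fraction = 0.4),
    leg_direct = list(
      n_types = 30, sources = "GNG",
      targets = c("LegT1", "LegT2", "LegT3"),
      p_in = 0.9, p_bg = 0.05,
      soma_probs = c(g = 0.8, p = 0.1, a = 0.05, b = 0.05),
      tract_probs = c(DLT = 1, MTD = 1, ITD = 1, VLT = 1, DLV = 1, VTV = 1),
      population_fraction = 0.05),
    convergent = list(
      n_types = 25, sources = NULL, breadth = 6,
      targets = c("Tct", "LTct"),
      p_in = 0.9, p_bg = 0.05,
      soma_probs = c(p = 0.5, g = 0.2, a = 0.1, b = 0.1, c = 0.1),
      tract_probs = c(MTD = 0.6, ITD = 0.15, VLT = 0.1, DLV = 0.1,
                      VTV = 0.05),
      population_fraction = 0.3),
    other = list(
      n_types = 13, sources = NULL, breadth = 2,
      targets = c("AMN", "VAC", "mVAC", "AS"),
      p_in = 0.8, p_bg = 0.05,
      soma_probs = c(p = 0.3, g = 0.4, a = 0.1, b = 0.1, c = 0.05,
                     d = 0.05),
      tract_probs = c(MTD = 0.3, ITD = 0.2, VLT = 0.2, DLV = 0.15,
                      VTV = 0.15),
      population_fraction = 0.1))
}

# Deterministic per-class substream seed, kept under 2^31 so later pathway
# classes never perturb the draws of earlier ones when a class is added.
.substream_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1009L + 7919L * k
}

#' Generate a synthetic DN catalog with planted pathway structure
#'
#' Draws, for every DN type of every configured pathway class: a soma
#' group (biased per class — posterior for the dorsal-direct pathway,
#' gnathal for the leg-direct one), unique/population kind and pair
#' count, laterality, a tract from the class distribution, smooth brain
#' innervation as Bernoulli(`p_in`) on the class's source compartments
#' and Bernoulli(`p_bg`) elsewhere, and varicose VNC innervation likewise
#' on its targets. Each pathway class consumes its own seeded substream,
#' so outputs are reproducible and per-class stable.
#'
#' @param config a [generator_config()].
#' @param seed integer seed (mandatory for reproducibility).
#' @return list with `catalog` (a [dn_catalog()]) and `truth` (data.frame
#'   `type_id`, `pathway` — the planted labels).
#' @examples
#' sim <- generate_catalog(seed = 42)
#' table(sim$truth$pathway)
#' @export
generate_catalog <- function(config = generator_config(), seed) {
  stopifnot(inherits(config, "generator_config"))
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  atl <- load_default_atlases()
  b_ab <- atlas_abbrevs(atl$brain)
  v_ab <- atlas_abbrevs(atl$vnc)

  all_records <- list()
  all_brain <- list()
  all_vnc <- list()
  truth <- list()
  soma_counter <- stats::setNames(integer(length(.soma_groups)),
                                  .soma_groups)

  for (k in seq_along(config$pathways)) {
    pname <- names(config$pathways)[k]
    pw <- config$pathways[[k]]
    if (pw$n_types == 0) next
    set.seed(.substream_seed(seed, k))

    soma <- sample(names(pw$soma_probs), pw$n_types, replace = TRUE,
                   prob = pw$soma_probs)
    is_pop <- stats::runif(pw$n_types) < pw$population_fraction
    n_pairs <- ifelse(is_pop, 1L + stats::rpois(pw$n_types,
                                                config$pair_lambda), 1L)
    lat <- ifelse(stats::runif(pw$n_types) < config$ipsilateral_prob,
                  "ipsilateral", "contralateral")
    tract <- sample(names(pw$tract_probs), pw$n_types, replace = TRUE,
                    prob = pw$tract_probs)

    brain <- matrix("N", pw$n_types, length(b_ab),
                    dimnames = list(NULL, b_ab))
    vnc <- matrix("N", pw$n_types, length(v_ab),
                  dimnames = list(NULL, v_ab))
    for (i in seq_len(pw$n_types)) {
      sources <- if (!is.null(pw$sources)) pw$sources else
        sample(b_ab, pw$breadth)
      p_brain <- ifelse(b_ab %in% sources, pw$p_in, pw$p_bg)
      brain[i, stats::runif(length(b_ab)) < p_brain] <- "S"
      p_vnc <- ifelse(v_ab %in% pw$targets, pw$p_in, pw$p_bg)
      vnc[i, stats::runif(length(v_ab)) < p_vnc] <- "V"
    }

    ids <- character(pw$n_types)
    for (i in seq_len(pw$n_types)) {
      soma_counter[soma[i]] <- soma_counter[soma[i]] + 1L
      if (soma_counter[soma[i]] > 99L) {
        stop("more than 99 types in soma group ", soma[i],
             ": two-digit indices exhausted")
      }
      ids[i] <- sprintf("DN%s%02d", soma[i], soma_counter[soma[i]])
    }
    rownames(brain) <- ids
    rownames(vnc) <- ids

    all_records[[pname]] <- data.frame(
      type_id = ids, soma_group = soma,
      kind = ifelse(is_pop, "population", "unique"),
      n_pairs = n_pairs, laterality = lat, tract = tract)
    all_brain[[pname]] <- brain
    all_vnc[[pname]] <- vnc
    truth[[pname]] <- data.frame(type_id = ids, pathway = pname)
  }

  records <- do.call(rbind, all_records)
  rownames(records) <- NULL
  catalog <- suppressMessages(dn_catalog(
    records,
    brain = do.call(rbind, all_brain),
    vnc = do.call(rbind, all_vnc),
    brain_atlas = atl$brain, vnc_atlas = atl$vnc,
    provenance = sprintf("synthetic planted-pathway catalog (seed %d)",
                         as.integer(seed))))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(catalog = catalog, truth = truth)
}

#' Generate a synthetic voxel mask with a known neurite centroid
#'
#' Places neurite voxels whose positions along the profiled axis are
#' drawn from a normal distribution truncated to the volume (the other
#' two coordinates are uniform), plus optional soma and axon blobs at
#' stated axis positions. Voxel collisions merge, so the realized voxel
#' count can fall slightly below `n`.
#'
#' @param centroid planted mean position along the axis, µm.
#' @param spread standard deviation, µm (>= 0).
#' @param n number of neurite voxel draws.
#' @param dim integer length-3 volume dimensions (axis = third dimension).
#' @param voxel_size µm per voxel (scalar or length 3).
#' @param soma_at,axon_at optional axis positions (µm) at which to place a
#'   small labeled soma/axon blob.
#' @param seed integer seed.
#' @return a [voxel_mask()] with axes `c("ML", "DV", "AP")`.
#' @export
generate_voxel_mask <- function(centroid, spread, n = 5000,
                                dim = c(32, 32, 100), voxel_size = 1,
                                soma_at = NULL, axon_at = NULL, seed) {
  stopifnot(spread >= 0, n >= 0, length(dim) == 3)
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (prod(dim) < n) stop("volume too small for requested voxel count")
  set.seed(as.integer(seed))
  arr <- array(0L, dim = dim)
  extent <- dim[3] * voxel_size[3]
  pos <- stats::rnorm(n, mean = centroid, sd = spread)
  # truncate by resampling out-of-volume draws
  bad <- pos < 0 | pos >= extent
  while (any(bad)) {
    pos[bad] <- stats::rnorm(sum(bad), mean = centroid, sd = spread)
    bad <- pos < 0 | pos >= extent
  }
  k <- floor(pos / voxel_size[3]) + 1
  i <- sample.int(dim[1], n, replace = TRUE)
  j <- sample.int(dim[2], n, replace = TRUE)
  arr[cbind(i, j, k)] <- 1L
  blob <- function(at, label) {
    slice <- min(max(floor(at / voxel_size[3]) + 1, 1), dim[3])
    arr[1:2, 1:2, slice] <<- label
  }
  if (!is.null(soma_at)) blob(soma_at, 2L)
  if (!is.null(axon_at)) blob(axon_at, 3L)
  voxel_mask(arr, voxel_size = voxel_size, axes = c("ML", "DV", "AP"))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency-table
#' definition: `ARI = (sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`. Equals 1 iff the
#' partitions are identical up to renaming; 0 in expectation for random
#' labelings.
#'
#' @param predicted,truth vectors of cluster labels over the same items;
#'   when both are named, items are matched by name.
#' @return the ARI, a number in \[-1, 1\].
#' @export
recovery_score <- function(predicted, truth) {
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    if (!setequal(names(predicted), names(truth))) {
      stop("predicted and truth label different item sets")
    }
    truth <- truth[names(predicted)]
  }
  if (length(predicted) != length(truth)) {
    stop("partitions must cover the same number of items")
  }
  n <- length(predicted)
  tab <- table(predicted, truth)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  a <- sum(comb2(rowSums(tab)))
  b <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  expected <- a * b / total
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
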