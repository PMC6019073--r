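# Shared fixtures and independent oracles for the test suite.

# A random catalog built directly (independently of generate_catalog) for
# round-trip and brute-force-oracle properties.
random_catalog <- function(seed, n = 12, p_innervate = 0.25) {
  set.seed(seed)
  atl <- load_default_atlases()
  b_ab <- atlas_abbrevs(atl$brain)
  v_ab <- atlas_abbrevs(atl$vnc)
  soma <- sample(c("a", "b", "c", "d", "g", "p", "x"), n, replace = TRUE)
  ids <- character(n)
  counter <- integer(0)
  for (i in seq_len(n)) {
    counter[soma[i]] <- if (is.na(counter[soma[i]])) 1L else
      counter[soma[i]] + 1L
    ids[i] <- sprintf("DN%s%02d", soma[i], counter[soma[i]])
  }
  kind <- sample(c("unique", "population"), n, replace = TRUE,
                 prob = c(0.8, 0.2))
  records <- data.frame(
    type_id = ids, soma_group = soma, kind = kind,
    n_pairs = ifelse(kind == "population", sample(2:8, n, replace = TRUE),
                     1L),
    laterality = sample(c("ipsilateral", "contralateral", "unknown"), n,
                        replace = TRUE, prob = c(0.6, 0.35, 0.05)),
    tract = sample(c("DLT", "MDA", "MTD", "ITD", "VLT", "DLV", "VTV",
                     "unknown"), n, replace = TRUE))
  rand_codes <- function(abbrevs, pool) {
    m <- matrix(sample(pool, n * length(abbrevs), replace = TRUE,
                       prob = c(1 - p_innervate,
                                rep(p_innervate / (length(pool) - 1),
                                    length(pool) - 1))),
                n, length(abbrevs), dimnames = list(ids, abbrevs))
    m
  }
  suppressMessages(dn_catalog(
    records,
    brain = rand_codes(b_ab, c("N", "S", "V", "B", "S1")),
    vnc = rand_codes(v_ab, c("N", "V", "B", "V1")),
    brain_atlas = atl$brain, vnc_atlas = atl$vnc))
}

# Definition-based O(n^3) average-linkage oracle: at every step recompute
# every inter-cluster mean dissimilarity from the ORIGINAL matrix (no
# Lance-Williams update), merge the minimum with the same lexicographic
# smallest-leaf tie-break, and record the height.
naive_average_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  partitions <- list()
  for (step in seq_len(n - 1)) {
    best_val <- Inf
    best <- NULL
    best_key <- c(Inf, Inf)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        val <- mean(d[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        better <- val < best_val ||
          (val == best_val && (key[1] < best_key[1] ||
             (key[1] == best_key[1] && key[2] < best_key[2])))
        if (better) {
          best_val <- val
          best <- c(i, j)
          best_key <- key
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    heights[step] <- best_val
    partitions[[step]] <- lapply(clusters, identity)
  }
  list(height = heights, partitions = partitions)
}

# Brute-force ARI from the pair-counting definition: classify every item
# pair as together/apart in each partition.
pair_counting_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) return(1)
  (n11 - expected) / (max_index - expected)
}

# Two-type toy catalog used across the pathway examples:
# DN1 smooth {IPS} -> varicose {Wing}; DN2 smooth {GNG} -> varicose
# {Wing, LegT1}.
toy_pathway_catalog <- function() {
  records <- data.frame(
    type_id = c("DNp01", "DNg01"), soma_group = c("p", "g"),
    kind = "unique", n_pairs = 1L, laterality = "ipsilateral",
    tract = c("MTD", "ITD"))
  brain <- matrix("N", 2, 2, dimnames = list(records$type_id,
                                             c("IPS", "GNG")))
  brain["DNp01", "IPS"] <- "S"
  brain["DNg01", "GNG"] <- "S"
  vnc <- matrix("N", 2, 2, dimnames = list(records$type_id,
                                           c("Wing", "LegT1")))
  vnc["DNp01", "Wing"] <- "V"
  vnc["DNg01", c("Wing", "LegT1")] <- "V"
  dn_catalog(records, brain = brain, vnc = vnc)
}

# Config with only the two direct pathways planted (the recovery setting).
two_pathway_config <- function(n_per = 30, p_in = 0.9, p_bg = 0.05) {
  pw <- generator_config()$pathways[c("dorsal_direct", "leg_direct")]
  for (nm in names(pw)) {
    pw[[nm]]$n_types <- n_per
    pw[[nm]]$p_in <- p_in
    pw[[nm]]$p_bg <- p_bg
  }
  generator_config(pathways = pw)
}
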