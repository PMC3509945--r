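# Independent oracles and fixture builders. Everything here deliberately
# avoids the package's optimized code paths: string-level Hamming distances,
# double-loop peak finding, naive O(n^2 |p|^2) divergence recomputation, and
# igraph-based path enumeration on an adjacency built straight from the
# genotype table.

ham_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# the spec's L=2 worked micro-example
additive_l2 <- function() {
  fitness_landscape(c("00", "01", "10", "11"), c(0.6, 0.7, 0.9, 1.0))
}

# two-peak L=2 fixture: global peak 00, local peak 11
two_peak_l2 <- function() {
  fitness_landscape(c("00", "01", "10", "11"), c(1.0, 0.2, 0.2, 0.9))
}

# exactly additive full landscape from per-locus effects (peak = all-ones)
additive_from_effects <- function(effects, peak_fitness = 1) {
  L <- length(effects)
  gts <- vapply(0:(2^L - 1), function(cd)
    paste(rev(as.integer(intToBits(cd))[1:L]), collapse = ""), character(1))
  fit <- vapply(gts, function(g) {
    zero <- strsplit(g, "")[[1]] == "0"
    peak_fitness - sum(effects[zero])
  }, numeric(1))
  fitness_landscape(gts, fit)
}

# random partial landscape: subset of the hypercube, i.i.d. fitness
random_landscape <- function(L, seed, hole_frac = 0) {
  set.seed(seed)
  gts <- vapply(0:(2^L - 1), function(cd)
    paste(rev(as.integer(intToBits(cd))[1:L]), collapse = ""), character(1))
  if (hole_frac > 0) {
    keep <- runif(length(gts)) >= hole_frac
    if (!any(keep)) keep[sample.int(length(gts), 1)] <- TRUE
    gts <- gts[keep]
  }
  fitness_landscape(gts, runif(length(gts), 0.01, 1))
}

# brute-force peak finder: double loop over all genotype pairs
brute_peaks <- function(ls) {
  gts <- ls$genotypes
  f <- ls$fitness
  peaks <- character(0)
  for (i in seq_along(gts)) {
    is_peak <- TRUE
    for (j in seq_along(gts)) {
      if (i != j && ham_str(gts[i], gts[j]) == 1 && f[j] > f[i]) {
        is_peak <- FALSE
        break
      }
    }
    if (is_peak) peaks <- c(peaks, gts[i])
  }
  sort(peaks)
}

# naive inter-path distance: string Hamming, explicit loops
naive_inter_path <- function(p1, p2) {
  s <- 0
  for (x in p1) s <- s + min(vapply(p2, function(y) ham_str(x, y), numeric(1)))
  for (y in p2) s <- s + min(vapply(p1, function(x) ham_str(x, y), numeric(1)))
  s / (length(p1) + length(p2))
}

# naive ensemble divergence from explicit pair loops
naive_ensemble_div <- function(paths, probs, mode = "normalized") {
  m <- length(paths)
  if (m <= 1) return(0)
  raw <- 0; w <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    d <- naive_inter_path(paths[[i]], paths[[j]])
    raw <- raw + probs[i] * probs[j] * d
    w <- w + probs[i] * probs[j]
  }
  if (mode == "raw") raw else if (w > 0) raw / w else 0
}

# igraph oracle: all maximal monotone paths from `start`, built from the
# genotype table alone (edges g -> h iff Hamming 1 and fitness(h) > fitness(g))
igraph_monotone_paths <- function(ls, start) {
  gts <- ls$genotypes
  f <- ls$fitness
  edges <- character(0)
  for (i in seq_along(gts)) for (j in seq_along(gts)) {
    if (ham_str(gts[i], gts[j]) == 1 && f[j] > f[i])
      edges <- c(edges, gts[i], gts[j])
  }
  g <- igraph::make_graph(edges, directed = TRUE)
  outdeg <- igraph::degree(g, mode = "out")
  sinks <- names(outdeg)[outdeg == 0]
  peaks_not_in_graph <- setdiff(brute_peaks(ls), names(outdeg))
  if (start %in% c(sinks, peaks_not_in_graph)) return(list(start))
  paths <- igraph::all_simple_paths(g, from = start, to = sinks, mode = "out")
  lapply(paths, function(p) names(p))
}

# independent SSWM walk simulator on the raw table
simulate_walks <- function(ls, start, n, seed) {
  set.seed(seed)
  gts <- ls$genotypes
  f <- ls$fitness
  ends <- character(n)
  paths <- character(n)
  for (w in seq_len(n)) {
    cur <- start
    path <- cur
    repeat {
      i <- match(cur, gts)
      up <- gts[vapply(gts, function(h) ham_str(cur, h) == 1, logical(1)) & f > f[i]]
      if (length(up) == 0) break
      cur <- if (length(up) == 1) up else sample(up, 1)
      path <- c(path, cur)
    }
    ends[w] <- cur
    paths[w] <- paste(path, collapse = ",")
  }
  list(ends = ends, paths = paths)
}
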