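## Monotone-path machinery on the fitter-neighbor DAG.
##
## Under strong selection and weak mutation (SSWM) evolution is a sequence of
## selective sweeps: at each genotype one of its b strictly fitter neighbors
## is fixed, each with probability 1/b, until a peak (b = 0) is reached. A
## realized trajectory is therefore a fitness-monotonic path on the hypercube,
## and its occurrence probability is the product of 1/b over every genotype on
## the path except the terminal peak. Strictly-fitter edges guarantee the
## mutational graph is a DAG, so exhaustive enumeration terminates.

## ---- exact big-integer addition (base 1e15 limbs) --------------------------
## Monotone-path counts exceed 2^53 well below the L = 20 cap (20! ~ 2.4e18),
## and no arbitrary-precision package is assumed, so the counting DP carries
## exact little-endian base-1e15 limb vectors; the DP only ever adds.

.BIGBASE <- 1e15

.big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  r <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    r[i] <- r[i] + carry
    carry <- if (r[i] >= .BIGBASE) 1 else 0
    if (carry) r[i] <- r[i] - .BIGBASE
  }
  if (carry) r <- c(r, 1)
  r
}

.big_to_num <- function(a) sum(a * .BIGBASE^(seq_along(a) - 1))

.big_to_chr <- function(a) {
  a <- rev(a)
  paste0(format(a[1], scientific = FALSE),
         paste(vapply(a[-1], function(l) formatC(l, width = 15, flag = "0",
                                                 format = "f", digits = 0),
                      character(1)), collapse = ""))
}

## ---- enumeration -----------------------------------------------------------

# Index-level DFS over the fitter-neighbor DAG: every maximal monotone path
# from start index s, with SSWM probabilities accumulated along the way.
# Returns list(paths = list of integer index vectors, probs, term = terminal
# index per path). Children are visited in index order, which equals
# lexicographic genotype order.
.enum_paths <- function(landscape, s, max_paths) {
  fitter <- landscape$fitter
  acc <- new.env(parent = emptyenv())
  acc$paths <- vector("list", 256L)
  acc$probs <- numeric(256L)
  acc$n <- 0L
  dfs <- function(i, path, prob) {
    fi <- fitter[[i]]
    if (length(fi) == 0L) {               # peak: path is maximal
      if (acc$n >= max_paths)
        stop("monotone-path enumeration exceeded the cap of ", max_paths,
             " paths from start '", landscape$genotypes[s],
             "'; raise max_paths or use sample_sswm_walk()")
      acc$n <- acc$n + 1L
      if (acc$n > length(acc$paths)) {    # grow geometrically
        length(acc$paths) <- 2L * length(acc$paths)
        length(acc$probs) <- 2L * length(acc$probs)
      }
      acc$paths[[acc$n]] <- c(path, i)
      acc$probs[acc$n] <- prob
      return(invisible())
    }
    p <- prob / length(fi)
    for (j in fi) dfs(j, c(path, i), p)
    invisible()
  }
  dfs(s, integer(0), 1)
  paths <- acc$paths[seq_len(acc$n)]
  list(paths = paths,
       probs = acc$probs[seq_len(acc$n)],
       term = vapply(paths, function(p) p[length(p)], integer(1)))
}

#' Enumerate all maximal monotone paths from a starting genotype
#'
#' Depth-first traversal of the strictly-fitter-neighbor DAG producing every
#' maximal monotone path from `start` (fitness strictly increases at each
#' single-locus step; maximal means the path ends at a peak). Paths are
#' grouped into ensembles by terminal peak, and each path carries its SSWM
#' occurrence probability. Children are visited in lexicographic genotype
#' order, so output ordering is deterministic across runs and platforms.
#'
#' For every non-peak start the probabilities over *all* maximal monotone
#' paths (all terminal peaks pooled) sum to 1: SSWM walks terminate somewhere.
#'
#' @param landscape a [fitness_landscape].
#' @param start genotype string present in the landscape.
#' @param end optional genotype string: keep only ensembles terminating at
#'   `end`. Default `NULL` keeps ensembles to all reachable peaks.
#' @param max_paths enumeration cap (default 1e6 paths). Exceeding it raises
#'   an error naming the cap rather than silently truncating; callers may fall
#'   back to [sample_sswm_walk()].
#' @return list of `path_ensemble` objects, each a list with elements `start`,
#'   `peak`, `paths` (list of character vectors of genotypes) and
#'   `probabilities` (aligned numeric vector), ordered by peak genotype.
#' @examples
#' ls2 <- fitness_landscape(c("00", "01", "10", "11"), c(0.6, 0.7, 0.9, 1.0))
#' ens <- enumerate_monotone_paths(ls2, "00")
#' ens[[1]]$paths          # two paths around the square
#' ens[[1]]$probabilities  # 1/2 each
#' @export
enumerate_monotone_paths <- function(landscape, start, end = NULL,
                                     max_paths = 1e6) {
  s <- .ls_index(landscape, start)
  res <- .enum_paths(landscape, s, max_paths)
  paths <- res$paths
  probs <- res$probs
  term <- res$term
  keep_peaks <- sort(unique(term))
  if (!is.null(end)) {
    e <- .ls_index(landscape, end)
    keep_peaks <- keep_peaks[keep_peaks == e]
  }
  lapply(keep_peaks, function(pk) {
    sel <- which(term == pk)
    structure(list(
      start = start,
      peak = landscape$genotypes[pk],
      paths = lapply(paths[sel], function(p) landscape$genotypes[p]),
      probabilities = probs[sel]),
      class = "path_ensemble")
  })
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf("path_ensemble: %s -> %s, %d path(s), total probability %.6g\n",
              x$start, x$peak, length(x$paths), sum(x$probabilities)))
  invisible(x)
}

#' SSWM occurrence probability of a monotone path
#'
#' The probability that a strong-selection/weak-mutation walk realizes exactly
#' this path: the product, over every genotype on the path except the terminal
#' one, of 1 over its number of strictly fitter neighbors ("the number of
#' available beneficial mutations at that point"). A length-1 path has
#' probability 1.
#'
#' @param landscape a [fitness_landscape].
#' @param path character vector of genotypes forming a monotone path
#'   (consecutive genotypes at Hamming distance 1, fitness strictly
#'   increasing).
#' @return probability in (0, 1].
#' @export
sswm_path_probability <- function(landscape, path) {
  idx <- vapply(path, function(g) .ls_index(landscape, g), integer(1))
  if (length(idx) > 1L) {
    f <- landscape$fitness[idx]
    h <- .hamming_codes(landscape$codes[idx[-length(idx)]],
                        landscape$codes[idx[-1]])
    if (any(h != 1L) || any(diff(f) <= 0))
      stop("path is not monotone: steps must be single-locus and strictly fitness-increasing")
  }
  b <- lengths(landscape$fitter[idx])
  if (length(idx) > 1L && any(b[-length(b)] == 0L))
    stop("path continues past a peak")
  prod(1 / b[-length(b)])
}

## ---- dynamic programming ---------------------------------------------------

.check_peak <- function(landscape, end) {
  e <- .ls_index(landscape, end)
  if (length(landscape$fitter[[e]]) != 0L)
    stop("'", end, "' is not a peak (it has fitter neighbors)")
  e
}

# genotype indices in decreasing-fitness order (DP processes fitter first)
.desc_fitness_order <- function(landscape) order(-landscape$fitness)

#' Count monotone paths from every genotype to a peak
#'
#' Exact number of monotone paths from each genotype g to the peak `end`,
#' by dynamic programming over genotypes in decreasing-fitness order:
#' `N(end) = 1`, `N(g) = sum over fitter neighbors h of N(h)`, and any other
#' peak has `N = 0`. No enumeration is performed, so this scales to the full
#' `L <= 20` landscape cap. Counts are accumulated in exact arbitrary-size
#' integer arithmetic (they exceed the 2^53 double-precision integer range
#' near L = 20); the returned numeric vector may round above 2^53, and the
#' `"exact"` attribute carries the exact decimal strings.
#'
#' @param landscape a [fitness_landscape].
#' @param end a peak genotype (error otherwise).
#' @return named numeric vector over all viable genotypes, with attribute
#'   `exact` (character vector of exact decimal counts).
#' @export
count_monotone_paths <- function(landscape, end) {
  e <- .check_peak(landscape, end)
  n <- length(landscape$genotypes)
  big <- vector("list", n)
  zero <- 0; one <- 1
  for (i in seq_len(n)) big[[i]] <- zero
  big[[e]] <- one
  ord <- .desc_fitness_order(landscape)
  for (i in ord) {
    if (i == e) next
    fi <- landscape$fitter[[i]]
    if (length(fi) == 0L) next          # other peak: stays 0
    acc <- zero
    for (j in fi) acc <- .big_add(acc, big[[j]])
    big[[i]] <- acc
  }
  counts <- vapply(big, .big_to_num, numeric(1))
  names(counts) <- landscape$genotypes
  attr(counts, "exact") <- setNames(vapply(big, .big_to_chr, character(1)),
                                    landscape$genotypes)
  counts
}

#' SSWM probability of reaching a peak from every genotype
#'
#' The probability that a strong-selection/weak-mutation walk started at g
#' terminates at the peak `end`: `rho(end) = 1`, `rho = 0` at any other peak,
#' and otherwise `rho(g) = (1/b(g)) * sum over fitter neighbors h of rho(h)`
#' where `b(g)` is the number of fitter neighbors. Computed by dynamic
#' programming in decreasing-fitness order. For every genotype the reach
#' probabilities over all peaks sum to 1 (walks terminate somewhere).
#'
#' @inheritParams count_monotone_paths
#' @return named numeric vector of probabilities over all viable genotypes.
#' @export
reach_probability <- function(landscape, end) {
  e <- .check_peak(landscape, end)
  n <- length(landscape$genotypes)
  rho <- numeric(n)
  rho[e] <- 1
  for (i in .desc_fitness_order(landscape)) {
    if (i == e) next
    fi <- landscape$fitter[[i]]
    if (length(fi) > 0L) rho[i] <- sum(rho[fi]) / length(fi)
  }
  setNames(rho, landscape$genotypes)
}

#' Peak accessibility of the global optimum
#'
#' Two landscape-level summaries of how reachable the global peak is:
#' (a) existence accessibility -- the fraction of viable genotypes from which
#' at least one monotone path to the global peak exists; and (b) the mean
#' SSWM reach probability of the global peak over all viable genotypes.
#' Averages include the peak itself (which trivially reaches itself).
#'
#' If several genotypes tie for the global fitness maximum the summaries are
#' reported per global peak (with a warning) instead of being merged.
#'
#' @param landscape a [fitness_landscape].
#' @return list with `existence_accessibility`, `mean_reach_probability`,
#'   `n_peaks` and `global_peak`; with tied global peaks, a list of such lists.
#' @export
peak_accessibility <- function(landscape) {
  peaks <- find_peaks(landscape)
  globals <- peaks$genotype[peaks$is_global]
  one <- function(gp) {
    cnt <- count_monotone_paths(landscape, gp)
    rho <- reach_probability(landscape, gp)
    list(global_peak = gp,
         existence_accessibility = mean(cnt > 0),
         mean_reach_probability = mean(rho),
         n_peaks = nrow(peaks))
  }
  if (length(globals) > 1L) {
    warning("multiple genotypes tie for the global fitness maximum; ",
            "reporting accessibility per peak")
    return(lapply(globals, one))
  }
  one(globals)
}

#' Sample one SSWM adaptive walk
#'
#' Simulates a strong-selection/weak-mutation trajectory: starting from
#' `start`, repeatedly fix one of the strictly fitter neighbors chosen
#' uniformly at random, until a peak is reached. This is the simulation
#' oracle for the analytic path and reach probabilities, and the sampling
#' fallback when enumeration overflows its cap.
#'
#' @param landscape a [fitness_landscape].
#' @param start genotype string present in the landscape.
#' @param seed optional integer seed giving a reproducible walk; `NULL`
#'   (default) draws from the current RNG stream, convenient when sampling
#'   many walks under one outer seed.
#' @return character vector of genotypes: a maximal monotone path.
#' @export
sample_sswm_walk <- function(landscape, start, seed = NULL) {
  walk <- function() {
    i <- .ls_index(landscape, start)
    path <- i
    repeat {
      fi <- landscape$fitter[[i]]
      if (length(fi) == 0L) break
      i <- if (length(fi) == 1L) fi else fi[sample.int(length(fi), 1L)]
      path <- c(path, i)
    }
    landscape$genotypes[path]
  }
  if (is.null(seed)) walk() else .with_seed(seed, walk())
}
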