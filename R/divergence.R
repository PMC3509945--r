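## Path divergence: the core predictability statistic.
##
## An ensemble of monotone paths sharing a start and a terminal peak is
## summarized by how far its paths stray from one another, weighted by how
## likely SSWM dynamics are to realize each path. Low divergence = evolution
## repeatedly takes (nearly) the same route = high predictability.

.path_codes <- function(path) {
  if (any(!grepl("^[01]+$", path)))
    stop("paths must consist of {0,1} genotype strings")
  if (length(unique(nchar(path))) != 1L)
    stop("all genotypes on a path must have the same length")
  .gt_code(path)
}

#' Minimum Hamming distance from a genotype to a path
#'
#' @param x genotype string.
#' @param path character vector of genotypes (same length strings as `x`).
#' @return `min` over points y of `path` of the Hamming distance between `x`
#'   and y; 0 iff `x` lies on the path.
#' @export
point_to_path_distance <- function(x, path) {
  cx <- .path_codes(x)
  cp <- .path_codes(path)
  if (nchar(x) != nchar(path[1]))
    stop("genotype length mismatch between point and path")
  min(.hamming_codes(cp, cx))
}

#' Inter-path distance between two mutational paths
#'
#' The symmetrized mean of per-point minimum Hamming distances: for every
#' point on each path, find the Hamming distance to the closest point of the
#' other path; the inter-path distance is the sum of all these minima divided
#' by the combined number of points of the two paths,
#' `d(p1,p2) = (sum_{x in p1} d(x,p2) + sum_{y in p2} d(y,p1)) / (|p1|+|p2|)`.
#' The denominator counts POINTS (not steps), so `d` is the mean of the summed
#' per-point minima. The measure is symmetric, zero iff the two paths visit
#' identical point sets (it is order-insensitive), and expressed in raw
#' Hamming units (not divided by L).
#'
#' @param p1,p2 character vectors of genotypes over the same loci.
#' @return non-negative inter-path distance.
#' @examples
#' inter_path_distance(c("00", "10", "11"), c("00", "01", "11"))  # 1/3
#' @export
inter_path_distance <- function(p1, p2) {
  c1 <- .path_codes(p1); c2 <- .path_codes(p2)
  if (nchar(p1[1]) != nchar(p2[1]))
    stop("genotype length mismatch between the two paths")
  cpp_inter_path_distance(c1, c2)
}

#' Ensemble path divergence
#'
#' Divergence of a monotone-path ensemble (paths sharing a start genotype and
#' a terminal peak, each with its SSWM occurrence probability). In `raw` mode
#' it is the sum over unordered pairs of distinct paths of
#' `P_i * P_j * d(p_i, p_j)`; for an ensemble of exactly two paths this is the
#' product of their probabilities and their inter-path distance. In
#' `normalized` mode the raw sum is divided by the summed pair weights
#' `sum P_i * P_j`, giving the probability-weighted MEAN pairwise distance --
#' the scale-free choice when ensemble probabilities do not sum to 1 (e.g.
#' ensembles conditioned on one peak), hence the default. Single-path
#' ensembles have divergence 0 in both modes.
#'
#' @param ensemble a `path_ensemble` as returned by
#'   [enumerate_monotone_paths()] (or any list with `paths` and
#'   `probabilities`).
#' @param mode `"normalized"` (default) or `"raw"`; always recorded in output
#'   downstream.
#' @return non-negative divergence in Hamming units.
#' @export
ensemble_divergence <- function(ensemble, mode = c("normalized", "raw")) {
  mode <- match.arg(mode)
  if (is.null(ensemble$paths) || length(ensemble$paths) == 0L)
    stop("empty ensemble")
  if (length(ensemble$paths) == 1L) return(0)
  codes <- lapply(ensemble$paths, .path_codes)
  v <- cpp_ensemble_divergence(codes, as.numeric(ensemble$probabilities))
  if (mode == "raw") v[1] else if (v[2] > 0) v[1] / v[2] else 0
}

#' Mean path divergence of a landscape
#'
#' The landscape-level predictability statistic: for every viable genotype
#' taken as a start, enumerate the ensembles of monotone paths to the target
#' peak(s), compute each ensemble's divergence, and average. The mean is
#' UNWEIGHTED over contributing ensembles; starts with no monotone path to
#' the target are skipped, not counted as zero (inaccessibility is an
#' accessibility statistic, not a divergence of paths that do not exist).
#' Peaks themselves contribute single-path (zero-divergence) ensembles.
#'
#' @param landscape a [fitness_landscape].
#' @param mode `"normalized"` (default) or `"raw"`, see
#'   [ensemble_divergence()].
#' @param target `"global-peak"` (default): only ensembles terminating at the
#'   unique global optimum; `"all-peaks"`: one ensemble per (start, reachable
#'   peak) pair.
#' @param max_paths per-start enumeration cap; overflow raises an error
#'   identifying the offending start.
#' @return object of class `divergence_result`: list with `per_ensemble`
#'   (data.frame: start, peak, n_paths, divergence), `mean_divergence`,
#'   `normalization_mode`, `n_ensembles`.
#' @examples
#' ls2 <- fitness_landscape(c("00", "01", "10", "11"), c(0.6, 0.7, 0.9, 1.0))
#' mean_path_divergence(ls2)$mean_divergence  # 1/12
#' @export
mean_path_divergence <- function(landscape, mode = c("normalized", "raw"),
                                 target = c("global-peak", "all-peaks"),
                                 max_paths = 1e6) {
  mode <- match.arg(mode)
  target <- match.arg(target)
  peaks <- find_peaks(landscape)
  if (target == "global-peak") {
    globals <- peaks$genotype[peaks$is_global]
    if (length(globals) > 1L)
      warning("multiple global-fitness ties; ensembles computed to each tied peak")
    target_idx <- match(globals, landscape$genotypes)
  } else {
    target_idx <- match(peaks$genotype, landscape$genotypes)
  }
  starts <- character(0); pks <- character(0)
  npaths <- integer(0); div <- numeric(0)
  n <- length(landscape$genotypes)
  for (s in seq_len(n)) {
    res <- .enum_paths(landscape, s, max_paths)
    for (e in target_idx) {
      sel <- which(res$term == e)
      if (length(sel) == 0L) next       # start cannot reach this target
      d <- if (length(sel) == 1L) 0 else {
        v <- cpp_ensemble_divergence(lapply(res$paths[sel],
                                            function(p) landscape$codes[p]),
                                     res$probs[sel])
        if (mode == "raw") v[1] else if (v[2] > 0) v[1] / v[2] else 0
      }
      starts <- c(starts, landscape$genotypes[s])
      pks <- c(pks, landscape$genotypes[e])
      npaths <- c(npaths, length(sel))
      div <- c(div, d)
    }
  }
  per <- data.frame(start = starts, peak = pks, n_paths = npaths,
                    divergence = div, stringsAsFactors = FALSE)
  structure(list(per_ensemble = per,
                 mean_divergence = if (nrow(per)) mean(per$divergence) else NaN,
                 normalization_mode = mode,
                 n_ensembles = nrow(per)),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("mean path divergence (%s): %.6g over %d ensemble(s)\n",
              x$normalization_mode, x$mean_divergence, x$n_ensembles))
  invisible(x)
}
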