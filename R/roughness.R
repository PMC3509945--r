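## Four landscape-roughness measures and the fitness-permutation null
## comparison. No single parameter captures multidimensional ruggedness, so
## the four measures probe complementary aspects: departure from the best
## additive model, local fitness relief, local-optima density, and how far
## typical genotypes sit from the region where adaptation is deterministic.

.design_bits <- function(landscape) {
  L <- landscape$L
  codes <- landscape$codes
  vapply(seq_len(L), function(i) (codes %/% 2L^(L - i)) %% 2L,
         numeric(length(codes)))
}

#' Deviation from additivity (roughness-to-slope ratio)
#'
#' Least-squares fit of the additive model
#' `F(g) = a_0 + sum_i a_i g_i` over the viable genotypes, summarized as the
#' roughness-to-slope ratio `r/s` with `r` the root-mean-square residual and
#' `s` the mean absolute additive coefficient `mean(|a_i|)`. Exactly additive
#' landscapes give 0. The fit is on raw fitness by default; set
#' `log_fitness = TRUE` for multiplicative data.
#'
#' @param landscape a [fitness_landscape] with at least `L + 2` viable
#'   genotypes (the fit is saturated/underdetermined otherwise).
#' @param log_fitness fit `log(F)` instead of `F`.
#' @return non-negative ratio; `Inf` (with a warning) on a flat landscape
#'   where `s = 0`.
#' @export
additive_deviation <- function(landscape, log_fitness = FALSE) {
  n <- length(landscape$fitness)
  L <- landscape$L
  if (n < L + 2L)
    stop("additive fit underdetermined: need at least L + 2 = ", L + 2L,
         " viable genotypes, have ", n)
  X <- cbind(1, .design_bits(landscape))
  y <- if (log_fitness) log(landscape$fitness) else landscape$fitness
  fit <- lm.fit(X, y)
  if (any(is.na(fit$coefficients)))
    stop("additive fit underdetermined: design matrix is rank-deficient ",
         "(holes leave some loci unidentifiable)")
  r <- sqrt(mean(fit$residuals^2))
  s <- mean(abs(fit$coefficients[-1]))
  if (s == 0) {
    warning("flat additive fit (all slopes zero); roughness-to-slope ratio is Inf")
    return(Inf)
  }
  r / s
}

#' Root-mean-square fitness difference between neighbors
#'
#' The square root of the mean of `(F(g) - F(h))^2` over all viable
#' Hamming-distance-1 pairs, each unordered pair counted once (squaring makes
#' the ordered and unordered averages identical). Isolated genotypes
#' contribute nothing. Expressed in fitness units; rescaling fitness by c
#' rescales the measure by c.
#'
#' @param landscape a [fitness_landscape] with at least one viable neighbor
#'   pair.
#' @return non-negative RMS local fitness relief.
#' @export
rms_neighbor_difference <- function(landscape) {
  f <- landscape$fitness
  d2 <- unlist(lapply(seq_along(f), function(i) {
    j <- landscape$nbr[[i]]
    j <- j[j > i]                       # each unordered pair once
    (f[i] - f[j])^2
  }))
  if (length(d2) == 0L)
    stop("undefined measure: the landscape has no viable neighbor pairs")
  sqrt(mean(d2))
}

#' Peak fraction
#'
#' The number of local optima (genotypes with no strictly fitter viable
#' neighbor) divided by the number of viable genotypes. 1/2^L for a full
#' exactly additive landscape; approaches the uncorrelated expectation
#' 1/(L+1) on a full hypercube as ruggedness saturates.
#'
#' @param landscape a [fitness_landscape].
#' @return fraction in (0, 1].
#' @export
peak_fraction <- function(landscape) {
  sum(lengths(landscape$fitter) == 0L) / length(landscape$genotypes)
}

#' Mean Hamming distance to the tree component
#'
#' The tree component T is the set of genotypes with at most one strictly
#' fitter neighbor -- on T, SSWM dynamics are deterministic (every peak is in
#' T). The measure is the mean, over ALL viable genotypes, of the minimum
#' Hamming distance to T; members of T contribute 0. Distance is plain
#' Hamming distance through possibly nonviable space (the graph-restricted
#' variant coincides on full landscapes).
#'
#' @param landscape a [fitness_landscape].
#' @return non-negative mean distance in Hamming units.
#' @export
mean_tree_distance <- function(landscape) {
  tree <- which(lengths(landscape$fitter) <= 1L)
  tc <- landscape$codes[tree]
  mean(vapply(landscape$codes,
              function(cd) min(.hamming_codes(tc, cd)), numeric(1)))
}

.roughness_measures <- function(landscape, log_fitness = FALSE) {
  ad <- tryCatch(additive_deviation(landscape, log_fitness = log_fitness),
                 error = function(e) NA_real_)
  rms <- tryCatch(rms_neighbor_difference(landscape),
                  error = function(e) NA_real_)
  c(additive_deviation = ad, rms_neighbor_diff = rms,
    peak_fraction = peak_fraction(landscape),
    mean_tree_distance = mean_tree_distance(landscape))
}

#' Roughness report with a fitness-permutation null
#'
#' Computes the four roughness measures on the input landscape and, when
#' `n_permutations > 0`, their empirical null distributions over
#' fitness-permuted replicates (same genotype set, fitness values shuffled).
#' For each measure the report gives the null mean and SD and a one-sided
#' empirical quantile: the fraction of permuted replicates whose measure is
#' less than or equal to the observed value. Structured (smooth) landscapes
#' have quantiles near 0. Quantiles are descriptive; no multiple-testing
#' correction is applied across the four measures.
#'
#' @param landscape a [fitness_landscape].
#' @param n_permutations number of permuted replicates (default 0: no null
#'   block).
#' @param seed integer seed for the permutation stream.
#' @param log_fitness passed to [additive_deviation()].
#' @return object of class `roughness_report`: list with `observed` (named
#'   vector of the four measures), `n_genotypes`, `n_peaks`, and -- if
#'   permutations were run -- `null` (matrix of replicate measures),
#'   `null_mean`, `null_sd`, `empirical_quantile`.
#' @export
roughness_report <- function(landscape, n_permutations = 0L, seed = 1L,
                             log_fitness = FALSE) {
  if (n_permutations < 0L) stop("n_permutations must be >= 0")
  obs <- .roughness_measures(landscape, log_fitness)
  out <- list(observed = obs,
              n_genotypes = length(landscape$genotypes),
              n_peaks = sum(lengths(landscape$fitter) == 0L),
              n_permutations = as.integer(n_permutations))
  if (n_permutations > 0L) {
    seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                         n_permutations))
    nul <- t(vapply(seeds, function(sd_i)
      .roughness_measures(permute_fitness(landscape, sd_i), log_fitness),
      numeric(4)))
    out$null <- nul
    out$null_mean <- colMeans(nul, na.rm = TRUE)
    out$null_sd <- apply(nul, 2, sd, na.rm = TRUE)
    out$empirical_quantile <- vapply(seq_along(obs), function(k) {
      v <- nul[, k]
      if (is.na(obs[k])) NA_real_ else mean(v[!is.na(v)] <= obs[k])
    }, numeric(1))
    names(out$empirical_quantile) <- names(obs)
  }
  structure(out, class = "roughness_report")
}

#' @export
print.roughness_report <- function(x, ...) {
  cat(sprintf("roughness_report: %d genotypes, %d peak(s)\n",
              x$n_genotypes, x$n_peaks))
  for (m in names(x$observed)) {
    line <- sprintf("  %-20s %.6g", m, x$observed[m])
    if (!is.null(x$empirical_quantile))
      line <- paste0(line, sprintf("  [null %.4g +/- %.4g, quantile %.3f]",
                                   x$null_mean[m], x$null_sd[m],
                                   x$empirical_quantile[m]))
    cat(line, "\n")
  }
  invisible(x)
}
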