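## Seeded model-landscape generators: the noisy-additive family, the
## uncorrelated (house-of-cards) null, and the fitness-permutation null.

# Run expr with a seeded, self-contained RNG stream; the caller's RNG state is
# untouched. Mersenne-Twister is pinned so metadata can name the generator.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# 0/1 locus matrix for all 2^L genotypes in lexicographic (= code) order;
# column 1 is the first (most significant) string position.
.all_bits <- function(L) {
  codes <- 0:(2L^L - 1L)
  vapply(seq_len(L), function(i) (codes %/% 2L^(L - i)) %% 2L, numeric(2L^L))
}

#' Generate a noisy additive fitness landscape
#'
#' Constructs one instance of the noisy-additive family on the full
#' L-dimensional hypercube. Each locus i receives a fitness effect
#' `s_i ~ Exponential(mean = effect_mean)` (the cost of carrying the
#' non-reference allele `0` at that locus). The pre-noise fitness of a
#' genotype g is the peak fitness minus the summed effects of its `0` loci:
#' `F(g) = peak_fitness - sum_{i: g_i = 0} s_i`, so the all-ones genotype is
#' the additive peak. Every genotype's fitness is then perturbed
#' multiplicatively by `u^k` with `u ~ Uniform(0,1)` drawn independently per
#' genotype, and only genotypes with perturbed fitness > 0 are included
#' (viability filter). The noise power k tunes ruggedness continuously: k = 0
#' gives the exactly additive landscape (u^0 = 1, single peak at the all-ones
#' genotype); large k approaches an uncorrelated landscape.
#'
#' Random-stream discipline (fixed so seeds are portable): the L effects are
#' drawn first, then one noise uniform per genotype in lexicographic genotype
#' order -- including the all-ones peak, which is perturbed like every other
#' genotype. Consequently for k > 0 the all-ones genotype need not be the
#' global peak; use k = 0 when a known peak is required.
#'
#' @param L locus count, 1 <= L <= 20 (the full hypercube is enumerated).
#' @param noise_power k >= 0, exponent applied to the uniform noise draws.
#' @param seed integer seed; same seed and parameters give an identical
#'   landscape.
#' @param peak_fitness fitness of the unperturbed peak (default 1).
#' @param effect_mean mean of the exponential fitness-effect distribution
#'   (parameterized by its MEAN, not its rate). Default `0.5/L`, so the
#'   expected pre-noise fitness of the all-zeros genotype is
#'   `peak_fitness/2 > 0` and most genotypes pass the viability filter.
#' @param effects optional numeric vector of length L overriding the drawn
#'   effects (for reproducing hand-computed examples); the uniform draws are
#'   still consumed in the standard order.
#' @return a [fitness_landscape]; `metadata` records all parameters and the
#'   drawn effects.
#' @examples
#' ls <- generate_noisy_additive(L = 3, noise_power = 0, seed = 1)
#' find_peaks(ls)  # single peak at "111"
#' @export
generate_noisy_additive <- function(L, noise_power, seed, peak_fitness = 1,
                                    effect_mean = 0.5 / L, effects = NULL) {
  if (L < 1L || L > 20L) stop("L must satisfy 1 <= L <= 20")
  if (peak_fitness <= 0) stop("peak_fitness must be > 0")
  if (effect_mean <= 0) stop("effect_mean must be > 0")
  if (noise_power < 0) stop("noise_power must be >= 0")
  if (!is.null(effects) && length(effects) != L)
    stop("effects must have length L")
  res <- .with_seed(seed, {
    s <- rexp(L, rate = 1 / effect_mean)
    u <- runif(2L^L)
    list(s = s, u = u)
  })
  s <- if (is.null(effects)) res$s else as.numeric(effects)
  bits <- .all_bits(L)
  pre <- peak_fitness - as.vector((1 - bits) %*% s)
  fit <- pre * res$u^noise_power   # u^0 == 1 exactly
  keep <- fit > 0
  if (!any(keep)) stop("degenerate output: no genotype has positive perturbed fitness")
  gts <- .code_to_gt((0:(2L^L - 1L))[keep], L)
  fitness_landscape(gts, fit[keep],
                    metadata = list(model = "noisy-additive", L = L,
                                    peak_fitness = peak_fitness,
                                    effect_mean = effect_mean,
                                    noise_power = noise_power, seed = seed,
                                    effects = s, rng = "Mersenne-Twister"))
}

#' Generate an uncorrelated (house-of-cards) landscape
#'
#' Full hypercube with i.i.d. Uniform(0,1) fitness values: the
#' maximal-ruggedness null model. Any atomless fitness distribution yields
#' identical rank-based statistics (peaks, monotone paths, accessibility),
#' so the uniform choice is without loss of generality for those.
#'
#' @param L locus count, 1 <= L <= 12.
#' @param seed integer seed.
#' @return a [fitness_landscape] with all `2^L` genotypes viable.
#' @export
generate_uncorrelated <- function(L, seed) {
  if (L < 1L || L > 12L) stop("L must satisfy 1 <= L <= 12")
  fit <- .with_seed(seed, runif(2L^L))
  fitness_landscape(.code_to_gt(0:(2L^L - 1L), L), fit,
                    metadata = list(model = "uncorrelated", L = L, seed = seed,
                                    rng = "Mersenne-Twister"))
}

#' Randomly permute the fitness values of a landscape
#'
#' Returns a landscape on the same viable genotype set whose fitness values
#' are a uniformly random permutation of the original multiset. This is the
#' ruggedness null model against which real landscapes are compared:
#' structured landscapes are expected to be smoother (fewer peaks, lower
#' additive deviation, lower path divergence) than their permuted
#' counterparts.
#'
#' @param landscape a [fitness_landscape].
#' @param seed integer seed.
#' @return a [fitness_landscape] with permuted fitness; metadata records the
#'   permutation seed and the parent's metadata.
#' @export
permute_fitness <- function(landscape, seed) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  n <- length(landscape$fitness)
  perm <- .with_seed(seed, sample.int(n))
  fitness_landscape(landscape$genotypes, landscape$fitness[perm],
                    metadata = list(model = "permutation-null",
                                    permutation_seed = seed,
                                    parent = landscape$metadata))
}
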