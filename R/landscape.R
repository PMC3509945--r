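#' @useDynLib fitpaths, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm.fit rexp runif setNames sd quantile cor
#' @importFrom utils write.table packageVersion
NULL

# Hard cap on locus count at load/construction time; exhaustive operations
# (enumeration, full-hypercube generators) enforce tighter caps of their own.
.FP_MAX_L <- 25L

## ---- genotype <-> integer code helpers -------------------------------------
## A genotype is a fixed-length string over {0,1}; internally each genotype is
## the integer whose binary expansion (first character = most significant bit)
## equals the string, so lexicographic string order == numeric code order.

.gt_code <- function(genotypes) strtoi(genotypes, base = 2L)

.code_to_gt <- function(codes, L) {
  vapply(codes, function(cd) {
    bits <- integer(L)
    for (i in seq_len(L)) {
      bits[L - i + 1L] <- cd %% 2L
      cd <- cd %/% 2L
    }
    paste(bits, collapse = "")
  }, character(1))
}

.popcount <- function(x) {
  # x: integer vector, values < 2^25
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}

.hamming_codes <- function(a, b) .popcount(bitwXor(a, b))

## ---- constructor -----------------------------------------------------------

#' Construct a fitness landscape over binary loci
#'
#' A fitness landscape is a (possibly partial) map from genotypes -- fixed
#' length strings over `{0,1}`, i.e. vertices of the L-dimensional hypercube --
#' to strictly positive fitness values. Genotypes absent from the map are
#' treated as nonviable: they are removed from the mutational graph entirely
#' and adaptive paths may not traverse them.
#'
#' Neighborhood structure (Hamming-distance-1 adjacency) and the
#' strictly-fitter neighbor lists used by every downstream operation are
#' precomputed here. "Fitter" always means *strictly* greater fitness: under
#' strong-selection/weak-mutation dynamics neutral and deleterious mutations
#' never fix, so a fitness tie is not a beneficial step. Comparisons are exact
#' (no epsilon): generated landscapes have measure-zero tie probability, and
#' intended ties in loaded data are treated as neutral by design.
#'
#' @param genotypes character vector of equal-length `{0,1}` strings, no
#'   duplicates.
#' @param fitness numeric vector of finite, strictly positive values, aligned
#'   with `genotypes`.
#' @param metadata optional list recording provenance (source file or
#'   generator parameters).
#' @return An object of class `fitness_landscape`: a list with elements `L`
#'   (locus count), `genotypes` (lexicographically sorted), `fitness`,
#'   `metadata`, plus precomputed adjacency used internally.
#' @examples
#' ls2 <- fitness_landscape(c("00", "01", "10", "11"), c(0.6, 0.7, 0.9, 1.0))
#' find_peaks(ls2)
#' @export
fitness_landscape <- function(genotypes, fitness, metadata = list()) {
  if (length(genotypes) == 0L) stop("empty landscape: at least one genotype is required")
  if (length(genotypes) != length(fitness))
    stop("genotypes and fitness must have equal length")
  genotypes <- as.character(genotypes)
  L <- nchar(genotypes[1])
  if (any(nchar(genotypes) != L))
    stop("inconsistent genotype lengths: all genotypes must have the same number of loci")
  if (L < 1L || L > .FP_MAX_L)
    stop("locus count L must satisfy 1 <= L <= ", .FP_MAX_L)
  if (any(!grepl("^[01]+$", genotypes)))
    stop("genotypes must be strings over the alphabet {0,1}")
  if (anyDuplicated(genotypes))
    stop("duplicate genotypes are not allowed")
  fitness <- as.numeric(fitness)
  if (any(!is.finite(fitness)) || any(fitness <= 0))
    stop("every fitness must be finite and > 0 (nonviable genotypes are omitted, not stored)")

  ord <- order(genotypes)  # lexicographic
  genotypes <- genotypes[ord]
  fitness <- fitness[ord]
  codes <- .gt_code(genotypes)

  # Hamming-1 adjacency restricted to the viable set. match() hashes, so this
  # is O(n L) overall.
  n <- length(codes)
  flip <- vapply(seq_len(L) - 1L, function(b) match(bitwXor(codes, 2L^b), codes),
                 integer(n))
  flip <- matrix(flip, nrow = n)
  nbr <- lapply(seq_len(n), function(i) {
    v <- flip[i, ]
    sort(v[!is.na(v)])
  })
  fitter <- lapply(seq_len(n), function(i) {
    v <- nbr[[i]]
    v[fitness[v] > fitness[i]]
  })

  structure(
    list(L = L, genotypes = genotypes, fitness = fitness, codes = codes,
         nbr = nbr, fitter = fitter, metadata = metadata),
    class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("fitness_landscape: L = %d, %d viable genotypes (of %s possible)\n",
              x$L, length(x$genotypes), format(2^x$L, big.mark = ",")))
  cat(sprintf("  fitness range: [%g, %g]\n", min(x$fitness), max(x$fitness)))
  if (!is.null(x$metadata$source)) cat("  source:", x$metadata$source, "\n")
  if (!is.null(x$metadata$model)) cat("  model:", x$metadata$model, "\n")
  invisible(x)
}

.ls_index <- function(landscape, g) {
  i <- match(g, landscape$genotypes)
  if (is.na(i)) stop("genotype '", g, "' is not present (viable) in the landscape")
  i
}

#' Landscape fitness lookup
#'
#' @param landscape a [fitness_landscape].
#' @param g genotype string.
#' @return the fitness of `g`; error if `g` is not viable.
#' @export
fitness_of <- function(landscape, g) landscape$fitness[.ls_index(landscape, g)]

## ---- file I/O --------------------------------------------------------------

#' Read a genotype-fitness table
#'
#' Reads a plain-text table with a `genotype<TAB>fitness` header, one viable
#' genotype per row; lines starting with `#` are comments. Rows whose fitness
#' is non-numeric or not strictly positive are dropped (with a message giving
#' the count): only positive-fitness genotypes are included in the landscape,
#' mirroring the viability filter of the noisy-additive generator. The format
#' can hold published combinatorially-complete empirical landscapes (e.g. a
#' 2^5 antibiotic-resistance table) unchanged.
#'
#' @param path file to read.
#' @param sep field delimiter; `"\t"` (default) or `","` for CSV.
#' @return a [fitness_landscape]; `metadata$source` records `path`.
#' @seealso [save_landscape()]
#' @export
load_landscape <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty input: ", path, " contains no data rows")
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) stop("format error: every row needs genotype and fitness columns")
  gt <- vapply(fields, function(f) trimws(f[1]), character(1))
  fitraw <- vapply(fields, function(f) trimws(f[2]), character(1))
  # drop a header row if present
  if (tolower(gt[1]) == "genotype") {
    gt <- gt[-1]; fitraw <- fitraw[-1]
  }
  if (length(gt) == 0L) stop("empty input: ", path, " contains a header but no data rows")
  if (any(!grepl("^[01]+$", gt)))
    stop("format error: genotypes must be {0,1} strings (offending row: '",
         gt[which(!grepl("^[01]+$", gt))[1]], "')")
  if (length(unique(nchar(gt))) != 1L)
    stop("format error: inconsistent genotype lengths in ", path)
  fit <- suppressWarnings(as.numeric(fitraw))
  viable <- !is.na(fit) & fit > 0
  dropped <- sum(!viable)
  if (dropped > 0)
    message(dropped, " row(s) with non-numeric or non-positive fitness dropped (nonviable)")
  gt <- gt[viable]; fit <- fit[viable]
  if (length(gt) == 0L) stop("no viable genotypes: all rows failed the positivity filter")
  dup <- duplicated(gt) | duplicated(gt, fromLast = TRUE)
  if (any(dup)) {
    for (g in unique(gt[dup])) {
      if (length(unique(fit[gt == g])) > 1L)
        stop("duplicate genotype '", g, "' with conflicting fitness values")
    }
    keep <- !duplicated(gt)
    gt <- gt[keep]; fit <- fit[keep]
  }
  fitness_landscape(gt, fit,
                    metadata = list(source = path, dropped_nonviable = dropped))
}

#' Write a genotype-fitness table
#'
#' Writes the canonical TSV: a `genotype<TAB>fitness` header followed by one
#' row per viable genotype in lexicographic order, fitness at full precision
#' (17 significant digits, so save/load round-trips are exact and
#' save-load-save is byte-identical).
#'
#' @param landscape a [fitness_landscape].
#' @param path destination file.
#' @param header_comments optional character vector written as leading
#'   `#`-prefixed provenance lines.
#' @export
save_landscape <- function(landscape, path, header_comments = NULL) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comments))
    writeLines(paste0("# ", header_comments), con)
  writeLines("genotype\tfitness", con)
  writeLines(paste(landscape$genotypes,
                   formatC(landscape$fitness, digits = 17, format = "g"),
                   sep = "\t"), con)
  invisible(NULL)
}

## ---- neighborhoods and peaks ----------------------------------------------

#' Viable single-mutation neighbors of a genotype
#'
#' @param landscape a [fitness_landscape].
#' @param g genotype string present in the landscape.
#' @return character vector of all genotypes at Hamming distance exactly 1
#'   from `g` that are viable, in lexicographic order.
#' @export
viable_neighbors <- function(landscape, g) {
  i <- .ls_index(landscape, g)
  landscape$genotypes[landscape$nbr[[i]]]
}

#' Strictly fitter viable neighbors of a genotype
#'
#' The mutations available to an adapting population under
#' strong-selection/weak-mutation dynamics: viable single-mutation neighbors
#' with fitness strictly greater than that of `g`. Ties are neutral, hence
#' not fitter.
#'
#' @inheritParams viable_neighbors
#' @return character vector (possibly empty), lexicographic order.
#' @export
fitter_neighbors <- function(landscape, g) {
  i <- .ls_index(landscape, g)
  landscape$genotypes[landscape$fitter[[i]]]
}

#' Find all peaks (local fitness optima)
#'
#' A peak is a viable genotype with no strictly fitter viable neighbor. Peaks
#' whose fitness attains the landscape maximum are flagged global.
#'
#' @param landscape a [fitness_landscape].
#' @return data.frame with columns `genotype`, `fitness`, `is_global`, sorted
#'   by descending fitness with lexicographic tie-break.
#' @export
find_peaks <- function(landscape) {
  is_peak <- lengths(landscape$fitter) == 0L
  idx <- which(is_peak)
  fmax <- max(landscape$fitness)
  out <- data.frame(genotype = landscape$genotypes[idx],
                    fitness = landscape$fitness[idx],
                    is_global = landscape$fitness[idx] == fmax,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fitness, out$genotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}
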