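# Phased haplotype panels and genotype coding.
#
# Alleles are stored haplotype-major as 0/1 indicators; the -1/0/1 genotype
# code used by the relationship matrices is always derived from the phased
# alleles, never stored alongside them, so phase and code cannot disagree.

#' Construct a phased haplotype panel
#'
#' A panel holds the phased biallelic SNP alleles of one (non-overlapping)
#' generation: a `2N x L` matrix of 0/1 allele indicators in which rows
#' `2k - 1` and `2k` are the two haplotypes of individual `k`.
#'
#' @param alleles Numeric or integer matrix with entries in `{0, 1}`,
#'   `2N` rows (haplotypes) and `L` columns (loci).  Column names, if
#'   present, are taken as locus ids.
#' @param ids Character vector of `N` individual labels (default
#'   `"I1" ... "IN"`).
#' @param generation Non-negative integer generation index (founders are 0).
#' @return An object of class `haplotype_panel` with elements `alleles`,
#'   `ids` and `generation`.
#' @export
#' @examples
#' h <- matrix(c(1, 1, 0, 1, 0, 0, 1, 0), nrow = 4)
#' haplotype_panel(h, ids = c("A", "B"))
haplotype_panel <- function(alleles, ids = NULL, generation = 0L) {
  if (!is.matrix(alleles)) stop("'alleles' must be a matrix")
  if (nrow(alleles) == 0L || nrow(alleles) %% 2L != 0L) {
    stop("'alleles' must have a positive, even number of rows (2 per individual)")
  }
  if (!all(alleles %in% c(0, 1))) {
    stop("allele indicators must all be 0 or 1")
  }
  n <- nrow(alleles) %/% 2L
  if (is.null(ids)) ids <- paste0("I", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("'ids' must have one label per individual")
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  generation <- as.integer(generation)
  if (length(generation) != 1L || is.na(generation) || generation < 0L) {
    stop("'generation' must be a single non-negative integer")
  }
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) > 0L && is.null(colnames(alleles))) {
    colnames(alleles) <- paste0("L", seq_len(ncol(alleles)))
  }
  if (ncol(alleles) > 0L) {
    rownames(alleles) <- paste0(rep(ids, each = 2L), c("_h1", "_h2"))
  }
  structure(list(alleles = alleles, ids = ids, generation = generation),
            class = "haplotype_panel")
}

#' Number of individuals / loci in a panel
#' @param panel A `haplotype_panel`.
#' @return An integer.
#' @export
n_individuals <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  nrow(panel$alleles) %/% 2L
}

#' @rdname n_individuals
#' @export
n_loci <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  ncol(panel$alleles)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Haplotype panel: ", n_individuals(x), " individuals, ",
      n_loci(x), " loci, generation ", x$generation, "\n", sep = "")
  invisible(x)
}

#' Encode phased haplotypes as -1/0/1 genotypes
#'
#' The two homozygous states are coded -1 and 1 and the heterozygote 0:
#' `X[l, i] = h1 + h2 - 1` for the two allele indicators of individual `i`
#' at locus `l`.  This unscaled, frequency-uncorrected code is the basis of
#' the relationship matrices in [compute_G()] and [compute_Q()].
#'
#' @param panel A `haplotype_panel`.
#' @return An `L x N` integer matrix with entries in `{-1, 0, 1}`; rows are
#'   loci, columns individuals.
#' @export
#' @examples
#' p <- micro_panel()
#' encode_genotypes(p)
encode_genotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  a <- panel$alleles
  n2 <- nrow(a)
  h1 <- a[seq(1L, n2, by = 2L), , drop = FALSE]
  h2 <- a[seq(2L, n2, by = 2L), , drop = FALSE]
  x <- t(h1 + h2) - 1L
  storage.mode(x) <- "integer"
  dimnames(x) <- list(colnames(a), panel$ids)
  x
}

#' Per-locus allele frequencies
#'
#' Frequency of the "1" allele at each locus, i.e. the mean of the `2N`
#' allele indicators.
#'
#' @param panel A `haplotype_panel`.
#' @return Numeric vector of length `L` with values in `[0, 1]`.
#' @export
allele_frequency <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (nrow(panel$alleles) == 0L || ncol(panel$alleles) == 0L) {
    stop("empty panel")
  }
  colMeans(panel$alleles)
}

#' Restrict a panel to a subset of loci
#'
#' @param panel A `haplotype_panel`.
#' @param keep Integer indices (or locus names) of the loci to keep, in
#'   panel order.  The genetic map and effect vector must be subset with the
#'   same indices by the caller.
#' @return A `haplotype_panel` with the selected loci.
#' @export
subset_loci <- function(panel, keep) {
  stopifnot(inherits(panel, "haplotype_panel"))
  haplotype_panel(panel$alleles[, keep, drop = FALSE],
                  ids = panel$ids, generation = panel$generation)
}

#' Filter loci on minor allele frequency
#'
#' Keeps loci whose minor allele frequency strictly exceeds `threshold`
#' (the convention "minor allele frequency higher than the cutoff").  The
#' index set of retained loci is returned explicitly so that the genetic
#' map and the allelic-effect vector can be subset consistently; silent
#' reindexing is deliberately not offered.
#'
#' @param panel A `haplotype_panel`.
#' @param threshold MAF cutoff in `[0, 0.5)`; default 0.05.
#' @return A list with elements `panel` (the filtered `haplotype_panel`) and
#'   `keep` (integer indices of retained loci in the input panel).
#' @export
#' @examples
#' f <- maf_filter(micro_panel(), threshold = 0.3)
#' f$keep
maf_filter <- function(panel, threshold = 0.05) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 0.5) {
    stop("'threshold' must be a single value in [0, 0.5)")
  }
  p <- allele_frequency(panel)
  keep <- unname(which(pmin(p, 1 - p) > threshold))
  list(panel = subset_loci(panel, keep), keep = keep)
}

#' Shuffle alleles within each locus
#'
#' Independently permutes, at every locus, the `2N` allele indicators
#' across haplotypes.  Allele counts (and hence frequencies) are preserved
#' exactly, while linkage disequilibrium between loci is broken.  Used to
#' build a "shuffled" panel contrasting LD-rich and LD-free versions of the
#' same data.
#'
#' @param panel A `haplotype_panel`.
#' @param seed Integer seed; the permutations are deterministic given it.
#' @return A `haplotype_panel` of the same dimensions.
#' @export
shuffle_alleles <- function(panel, seed) {
  stopifnot(inherits(panel, "haplotype_panel"))
  a <- panel$alleles
  n2 <- nrow(a)
  with_seed(seed, {
    for (l in seq_len(ncol(a))) {
      a[, l] <- a[sample.int(n2), l]
    }
  })
  haplotype_panel(a, ids = panel$ids, generation = panel$generation)
}

#' Three-individual, four-locus example panel
#'
#' A tiny phased panel whose -1/0/1 coding is
#' `A = (1, 1, 0, -1)`, `B = (1, -1, 0, 0)`, `C = (0, 1, 1, 1)`.
#' Used throughout the documentation and tests because its relationship
#' matrices can be computed by hand.
#'
#' @return A `haplotype_panel` with 3 individuals and 4 loci.
#' @export
micro_panel <- function() {
  a <- rbind(
    c(1L, 1L, 0L, 0L),  # A h1
    c(1L, 1L, 1L, 0L),  # A h2
    c(1L, 0L, 0L, 0L),  # B h1
    c(1L, 0L, 1L, 1L),  # B h2
    c(0L, 1L, 1L, 1L),  # C h1
    c(1L, 1L, 1L, 1L)   # C h2
  )
  colnames(a) <- paste0("L", 1:4)
  haplotype_panel(a, ids = c("A", "B", "C"))
}
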