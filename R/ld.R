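# Small population-genetic summaries used to characterize panels.

#' Squared correlation between adjacent loci
#'
#' Haplotype-level LD: for each pair of adjacent loci (within a chromosome
#' when a map is supplied) the squared Pearson correlation of the 0/1
#' allele indicators across the `2N` haplotypes.  Monomorphic pairs are
#' skipped.
#'
#' @param panel A `haplotype_panel`.
#' @param map Optional `genetic_map`; adjacency then respects chromosome
#'   boundaries.
#' @return Numeric vector of r-squared values (one per adjacent pair).
#' @export
adjacent_r2 <- function(panel, map = NULL) {
  a <- panel$alleles
  L <- ncol(a)
  if (L < 2L) return(numeric(0))
  chrom <- if (is.null(map)) rep(1L, L) else map$chrom
  out <- numeric(0)
  for (l in seq_len(L - 1L)) {
    if (chrom[l] != chrom[l + 1L]) next
    x <- a[, l]; y <- a[, l + 1L]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    out <- c(out, stats::cor(x, y)^2)
  }
  out
}

#' Hudson's FST between two groups of individuals
#'
#' The ratio-of-averages Hudson estimator from haplotype allele
#' frequencies: per locus, numerator
#' `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and denominator
#' `p1(1-p2) + p2(1-p1)`, with `n` counted in haplotypes; FST is the sum of
#' numerators over the sum of denominators.
#'
#' @param panel A `haplotype_panel`.
#' @param groups Vector of length `N` with exactly two distinct values.
#' @return A scalar FST estimate.
#' @export
hudson_fst <- function(panel, groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("'groups' must define exactly two groups")
  if (length(g) != n_individuals(panel)) stop("'groups' must label every individual")
  hap_group <- rep(g, each = 2L)
  a <- panel$alleles
  p1 <- colMeans(a[hap_group == levels(g)[1L], , drop = FALSE])
  p2 <- colMeans(a[hap_group == levels(g)[2L], , drop = FALSE])
  n1 <- 2 * sum(g == levels(g)[1L])
  n2 <- 2 * sum(g == levels(g)[2L])
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- den > 0
  sum(num[ok]) / sum(den[ok])
}
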