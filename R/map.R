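# Genetic map: locus order, chromosome assignment and cM positions.

#' Construct a genetic map
#'
#' One row per locus of the companion panel, in the same order: chromosome
#' id and position in centimorgans.  Positions must be nondecreasing within
#' a chromosome.
#'
#' @param locus Character vector of locus ids.
#' @param chrom Chromosome ids (character or integer).
#' @param pos_cM Numeric positions in centimorgans.
#' @return A `data.frame` of class `genetic_map` with columns `locus`,
#'   `chrom`, `pos_cM`.
#' @export
genetic_map <- function(locus, chrom, pos_cM) {
  if (length(locus) != length(chrom) || length(locus) != length(pos_cM)) {
    stop("'locus', 'chrom' and 'pos_cM' must have equal length")
  }
  if (any(!is.finite(pos_cM)) || any(pos_cM < 0)) {
    stop("'pos_cM' must be finite and non-negative")
  }
  m <- data.frame(locus = as.character(locus), chrom = as.character(chrom),
                  pos_cM = as.numeric(pos_cM), stringsAsFactors = FALSE)
  for (ch in unique(m$chrom)) {
    p <- m$pos_cM[m$chrom == ch]
    if (is.unsorted(p)) {
      stop("positions on chromosome ", ch, " are not nondecreasing")
    }
  }
  class(m) <- c("genetic_map", "data.frame")
  m
}

# Check that a map and a panel describe the same loci in the same order.
check_map_panel <- function(map, panel) {
  if (nrow(map) != n_loci(panel)) {
    stop("map has ", nrow(map), " loci but panel has ", n_loci(panel))
  }
  invisible(TRUE)
}

#' Restrict a genetic map to a subset of loci
#'
#' @param map A `genetic_map`.
#' @param keep Integer indices as returned by [maf_filter()].
#' @return A `genetic_map`.
#' @export
subset_map <- function(map, keep) {
  stopifnot(inherits(map, "genetic_map"))
  m <- map[keep, , drop = FALSE]
  rownames(m) <- NULL
  genetic_map(m$locus, m$chrom, m$pos_cM)
}
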