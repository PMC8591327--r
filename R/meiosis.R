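# Gamete simulation: Poisson crossovers along the genetic map (Haldane
# model, no interference, no mutation).

#' Simulate one gamete from a parent
#'
#' Per chromosome, the crossover count is Poisson with mean equal to the
#' map length in Morgans and crossover positions are uniform in genetic
#' distance; the starting haplotype is a fair coin and strands switch at
#' every crossover.  This is the no-interference (Haldane) model: the
#' recombination fraction between two loci `d` Morgans apart is
#' `(1 - exp(-2d)) / 2`.  No mutation is introduced, so every gamete
#' allele exists in the parent.
#'
#' Uses the current RNG state; seed control belongs to the callers
#' ([make_offspring()] and the pipeline), which derive one stream per
#' meiosis batch.
#'
#' @param parent_haplotypes `2 x L` matrix of 0/1 allele indicators (the
#'   parent's two phased haplotypes).
#' @param map A `genetic_map` with one row per locus, aligned with the
#'   haplotype columns.
#' @return Integer vector of length `L`: the gamete haplotype.
#' @export
make_gamete <- function(parent_haplotypes, map) {
  if (!is.matrix(parent_haplotypes) || nrow(parent_haplotypes) != 2L) {
    stop("'parent_haplotypes' must be a 2 x L matrix")
  }
  if (ncol(parent_haplotypes) != nrow(map)) {
    stop("map and haplotypes disagree on the number of loci")
  }
  pick <- gamete_strands(map)
  out <- parent_haplotypes[1L, ]
  sel2 <- pick == 1L
  out[sel2] <- parent_haplotypes[2L, sel2]
  out
}

# Strand indicator (0/1) per locus for one meiosis, shared by make_gamete
# and the batched offspring builder.  Crossovers beyond the last locus of a
# chromosome have no effect; a zero-length chromosome yields a whole
# parental haplotype chosen by a fair coin.
gamete_strands <- function(map) {
  chroms <- map$chrom
  pos <- map$pos_cM
  pick <- integer(length(pos))
  for (ch in unique(chroms)) {
    sel <- which(chroms == ch)
    p <- pos[sel]
    len_m <- (max(p) - min(p)) / 100   # Morgans
    k <- stats::rpois(1L, len_m)
    start <- sample.int(2L, 1L) - 1L
    if (k == 0L) {
      pick[sel] <- start
    } else {
      xo <- sort(stats::runif(k, min = min(p), max = max(p)))
      nbelow <- findInterval(p, xo)
      pick[sel] <- (start + nbelow) %% 2L
    }
  }
  pick
}

#' Produce the next generation from a mate plan
#'
#' Each unit of the pair-count matrix yields exactly one offspring, built
#' from one independent meiosis of each parent.  The output generation
#' index is the input's plus one, and the number of offspring equals the
#' plan's mating count.
#'
#' @param panel Parental `haplotype_panel`.
#' @param plan A `mate_plan` over the panel's individuals.
#' @param map A `genetic_map` aligned with the panel.
#' @param seed Integer seed; the whole generation is deterministic given it.
#' @return A `haplotype_panel` of the offspring, with a `data.frame`
#'   attribute `"pedigree"` (columns `id`, `parent1`, `parent2`,
#'   `generation`).
#' @export
make_offspring <- function(panel, plan, map, seed) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(plan, "mate_plan"))
  check_map_panel(map, panel)
  N <- n_individuals(panel)
  if (nrow(plan$pair_counts) != N) {
    stop("plan references a different number of individuals than the panel")
  }
  L <- n_loci(panel)
  pc <- plan$pair_counts
  ut <- which(upper.tri(pc) & pc > 0L, arr.ind = TRUE)
  pairs <- ut[rep(seq_len(nrow(ut)), times = pc[ut]), , drop = FALSE]
  n_off <- nrow(pairs)
  stopifnot(n_off == plan$n_offspring)

  a <- panel$alleles
  out <- matrix(0L, nrow = 2L * n_off, ncol = L)
  colnames(out) <- colnames(a)
  gen <- panel$generation + 1L
  with_seed(seed, {
    for (o in seq_len(n_off)) {
      i <- pairs[o, 1L]; j <- pairs[o, 2L]
      hi <- a[c(2L * i - 1L, 2L * i), , drop = FALSE]
      hj <- a[c(2L * j - 1L, 2L * j), , drop = FALSE]
      out[2L * o - 1L, ] <- make_gamete(hi, map)
      out[2L * o, ] <- make_gamete(hj, map)
    }
  })
  ids <- sprintf("G%d_%04d", gen, seq_len(n_off))
  off <- haplotype_panel(out, ids = ids, generation = gen)
  attr(off, "pedigree") <- data.frame(
    id = ids,
    parent1 = panel$ids[pairs[, 1L]],
    parent2 = panel$ids[pairs[, 2L]],
    generation = gen,
    stringsAsFactors = FALSE)
  off
}
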