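# Synthetic founder populations.
#
# The generator emulates the statistical features of a dense-SNP perennial
# breeding population that matter for contribution optimization: minor
# allele frequencies above a filtering threshold, strong linkage
# disequilibrium decaying with map distance, and population structure.
# Each founder haplotype is a mosaic of a small pool of ancestral
# haplotypes, with exponentially distributed switch distances along the
# genetic map; this gives direct, testable control over LD (via the switch
# rate) and structure (via divergent ancestral pools per subpopulation) at
# negligible runtime, which a coalescent simulator would not.

#' Specify a synthetic founder population
#'
#' Defaults describe the desk-scale population used throughout the
#' package's own simulations: 100 individuals, 500 loci on 5 chromosomes
#' of 100 cM, two subpopulations drawing from 10 ancestral haplotypes
#' each, a mosaic switch rate of 0.05 per cM (expected ancestral segment
#' of 20 cM, hence LD-rich), and a MAF filter at 0.05.
#'
#' @param n_individuals Number of founders.
#' @param n_loci Number of loci requested before MAF filtering.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length_cM Length of each chromosome in centimorgans.
#' @param n_ancestral_haplotypes Ancestral haplotypes per subpopulation.
#' @param mosaic_switch_rate Ancestral-switch rate per cM (>= 0); lower
#'   values give longer shared segments and higher LD.
#' @param n_subpopulations Number of diverged subpopulations.
#' @param admixture_weights `NULL` for discrete structure (each individual
#'   drawn wholly from one subpopulation, in equal shares), or a
#'   probability vector of length `n_subpopulations`: each ancestral
#'   segment of every haplotype then draws its source subpopulation with
#'   these weights (admixed population).
#' @param maf_min MAF threshold in `[0, 0.5)`; loci at or below it are
#'   dropped.  0 disables filtering entirely (monomorphic loci are kept).
#' @param seed Integer seed.
#' @return An object of class `founder_spec`.
#' @export
founder_spec <- function(n_individuals = 100, n_loci = 500,
                         n_chromosomes = 5, chromosome_length_cM = 100,
                         n_ancestral_haplotypes = 10,
                         mosaic_switch_rate = 0.05,
                         n_subpopulations = 2,
                         admixture_weights = NULL,
                         maf_min = 0.05, seed = 1L) {
  stopifnot(n_individuals >= 1, n_loci >= 1, n_chromosomes >= 1,
            chromosome_length_cM > 0, n_ancestral_haplotypes >= 1,
            mosaic_switch_rate >= 0, n_subpopulations >= 1,
            maf_min >= 0, maf_min < 0.5)
  if (!is.null(admixture_weights)) {
    if (length(admixture_weights) != n_subpopulations ||
        any(admixture_weights < 0) || sum(admixture_weights) <= 0) {
      stop("'admixture_weights' must be non-negative with one weight per subpopulation")
    }
    admixture_weights <- admixture_weights / sum(admixture_weights)
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_loci = as.integer(n_loci),
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_cM = chromosome_length_cM,
                 n_ancestral_haplotypes = as.integer(n_ancestral_haplotypes),
                 mosaic_switch_rate = mosaic_switch_rate,
                 n_subpopulations = as.integer(n_subpopulations),
                 admixture_weights = admixture_weights,
                 maf_min = maf_min, seed = as.integer(seed)),
            class = "founder_spec")
}

#' Simulate a founder panel and its genetic map
#'
#' Per subpopulation, ancestral haplotypes are Bernoulli draws with
#' per-locus frequencies uniform on `(0.1, 0.9)`; subpopulations diverge
#' because their frequency vectors are drawn independently.  Each founder
#' haplotype copies a mosaic of ancestral haplotypes with exponential
#' switch distances at `mosaic_switch_rate` per cM.  Loci whose realized
#' MAF is not above `maf_min` are dropped and the map subset accordingly.
#'
#' @param spec A [founder_spec()].
#' @return A list with `panel` (a `haplotype_panel`, generation 0),
#'   `map` (a `genetic_map` of the retained loci), `subpopulation`
#'   (integer vector of each founder's subpopulation; `NA` under
#'   admixture) and `keep` (indices of retained loci in the pre-filter
#'   layout).
#' @export
#' @examples
#' f <- simulate_founders(founder_spec(n_individuals = 20, n_loci = 50,
#'                                     n_chromosomes = 2, seed = 7))
#' f$panel
simulate_founders <- function(spec) {
  stopifnot(inherits(spec, "founder_spec"))
  with_seed(spec$seed, {
    L <- spec$n_loci
    # Loci spread over chromosomes; sorted uniform positions.
    chrom_of <- sort(rep_len(seq_len(spec$n_chromosomes), L))
    pos <- numeric(L)
    for (ch in seq_len(spec$n_chromosomes)) {
      sel <- chrom_of == ch
      pos[sel] <- sort(stats::runif(sum(sel), 0, spec$chromosome_length_cM))
    }
    # Ancestral pools.
    K <- spec$n_subpopulations
    nanc <- spec$n_ancestral_haplotypes
    anc <- vector("list", K)
    for (s in seq_len(K)) {
      p <- stats::runif(L, 0.1, 0.9)
      anc[[s]] <- matrix(stats::rbinom(nanc * L, 1L, rep(p, each = nanc)),
                         nrow = nanc, ncol = L)
    }
    # Founders as mosaics.
    N <- spec$n_individuals
    subpop <- if (is.null(spec$admixture_weights)) {
      rep_len(seq_len(K), N)
    } else {
      rep(NA_integer_, N)
    }
    H <- matrix(0L, nrow = 2L * N, ncol = L)
    for (r in seq_len(2L * N)) {
      ind <- (r + 1L) %/% 2L
      H[r, ] <- mosaic_haplotype(anc, subpop[ind], spec, chrom_of, pos)
    }
    colnames(H) <- paste0("L", seq_len(L))
    panel0 <- haplotype_panel(H, generation = 0L)
    map0 <- genetic_map(colnames(H), chrom_of, pos)
    p <- allele_frequency(panel0)
    # maf_min = 0 disables filtering (monomorphic loci kept); a positive
    # threshold keeps loci with MAF strictly above it.
    keep <- if (spec$maf_min > 0) {
      unname(which(pmin(p, 1 - p) > spec$maf_min))
    } else {
      seq_len(L)
    }
    if (length(keep) < 0.1 * L) {
      stop("fewer than 10% of the requested loci survive the MAF filter; ",
           "widen the ancestral frequency bounds or lower 'maf_min'")
    }
    list(panel = subset_loci(panel0, keep),
         map = subset_map(map0, keep),
         subpopulation = subpop,
         keep = keep)
  })
}

# One mosaic haplotype; `subpop` NA means segment-wise admixture draws.
mosaic_haplotype <- function(anc, subpop, spec, chrom_of, pos) {
  L <- length(pos)
  out <- integer(L)
  rate <- spec$mosaic_switch_rate
  for (ch in unique(chrom_of)) {
    sel <- which(chrom_of == ch)
    p <- pos[sel]
    lo <- min(p); hi <- max(p)
    # Segment breakpoints: exponential gaps along the chromosome.
    brk <- numeric(0)
    if (rate > 0) {
      at <- lo + stats::rexp(1L, rate)
      while (at < hi) {
        brk <- c(brk, at)
        at <- at + stats::rexp(1L, rate)
      }
    }
    nseg <- length(brk) + 1L
    seg_of <- findInterval(p, brk) + 1L
    for (s in seq_len(nseg)) {
      take <- sel[seg_of == s]
      if (length(take) == 0L) next
      sp <- if (is.na(subpop)) {
        sample.int(length(anc), 1L, prob = spec$admixture_weights)
      } else subpop
      src <- sample.int(nrow(anc[[sp]]), 1L)
      out[take] <- anc[[sp]][src, take]
    }
  }
  out
}

#' Draw sparse Gaussian allelic effects
#'
#' A fraction `sparsity` of loci receive independent
#' `Normal(0, effect_sd^2)` effects (the count is deterministic:
#' `round(sparsity * n_loci)`), the rest are exactly zero.  If a founder
#' panel and a target TBV standard deviation are supplied, the whole
#' vector is rescaled so that the founder TBV standard deviation equals
#' the target exactly, mimicking a trait calibrated to a real evaluation.
#'
#' @param n_loci Number of loci.
#' @param effect_sd Standard deviation of the non-zero effects (>= 0).
#' @param sparsity Fraction of loci with non-zero effects, in `(0, 1]`.
#' @param seed Integer seed.
#' @param panel Optional founder `haplotype_panel` used for rescaling.
#' @param target_tbv_sd Optional positive target for the founder TBV
#'   standard deviation (requires `panel`).
#' @return Numeric effect vector of length `n_loci`.
#' @export
draw_effects <- function(n_loci, effect_sd = 1, sparsity = 1, seed = 1L,
                         panel = NULL, target_tbv_sd = NULL) {
  stopifnot(effect_sd >= 0, sparsity > 0, sparsity <= 1)
  a <- with_seed(seed, {
    k <- max(1L, as.integer(round(sparsity * n_loci)))
    nz <- sample.int(n_loci, k)
    v <- numeric(n_loci)
    v[nz] <- stats::rnorm(k, 0, effect_sd)
    v
  })
  if (!is.null(target_tbv_sd)) {
    if (is.null(panel)) stop("'panel' is required to rescale to a target TBV sd")
    tbv <- true_breeding_value(encode_genotypes(panel), a)
    s <- stats::sd(tbv)
    if (s == 0) {
      if (target_tbv_sd > 0) stop("founder TBVs are constant; cannot rescale")
    } else {
      a <- a * (target_tbv_sd / s)
    }
  }
  a
}
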