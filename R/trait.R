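# Additive trait model: true breeding values and phenotypes.

#' Define an additive trait architecture
#'
#' Per-locus additive allelic effects on the -1/0/1 genotype code, plus a
#' narrow-sense heritability.  Effects are treated as true and constant
#' across generations of a simulated program.
#'
#' @param effects Numeric vector of length `L` (trait units per unit of the
#'   -1/0/1 code).
#' @param h2 Heritability in `(0, 1]`.
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(effects, h2) {
  if (!is.numeric(effects) || any(!is.finite(effects))) {
    stop("'effects' must be a finite numeric vector")
  }
  if (!is.numeric(h2) || length(h2) != 1L || is.na(h2) || h2 <= 0 || h2 > 1) {
    stop("'h2' must be a single value in (0, 1]")
  }
  structure(list(effects = as.numeric(effects), h2 = as.numeric(h2)),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat("Additive trait model: ", length(x$effects), " loci (",
      sum(x$effects != 0), " non-zero effects), h2 = ", x$h2, "\n", sep = "")
  invisible(x)
}

#' True breeding values
#'
#' `TBV_i = sum_l a_l * X[l, i]` for the additive effect vector `a`.
#'
#' @param X `L x N` genotype matrix in the -1/0/1 code
#'   (see [encode_genotypes()]).
#' @param trait A `trait_model`, or a bare numeric effect vector.
#' @return Numeric vector of length `N`, named by individual.
#' @export
#' @examples
#' X <- encode_genotypes(micro_panel())
#' true_breeding_value(X, c(1, 2, -1, 0.5))
true_breeding_value <- function(X, trait) {
  a <- if (inherits(trait, "trait_model")) trait$effects else as.numeric(trait)
  if (length(a) != nrow(X)) {
    stop("effect vector length (", length(a),
         ") does not match the number of loci (", nrow(X), ")")
  }
  drop(crossprod(X, a))
}

#' Simulate phenotypes from true breeding values
#'
#' Adds an independent environmental deviation
#' `e_i ~ Normal(0, (1 - h2) * sigma_g2)` to each TBV, where `sigma_g2` is
#' the genetic (TBV) variance supplied by the caller.  With `h2 = 1` or
#' `sigma_g2 = 0` the phenotypes equal the TBVs exactly.
#'
#' @param tbv Numeric vector of true breeding values.
#' @param h2 Heritability in `(0, 1]`; `h2 = 0` is rejected because the
#'   environmental variance is scaled relative to `sigma_g2`.
#' @param sigma_g2 Genetic variance (>= 0) used to scale the noise.
#' @param seed Integer seed.
#' @return Numeric phenotype vector of the same length as `tbv`.
#' @export
simulate_phenotypes <- function(tbv, h2, sigma_g2, seed) {
  if (!is.numeric(h2) || length(h2) != 1L || h2 <= 0 || h2 > 1) {
    stop("'h2' must lie in (0, 1]; h2 = 0 leaves the environmental variance undefined")
  }
  if (!is.numeric(sigma_g2) || length(sigma_g2) != 1L || sigma_g2 < 0) {
    stop("'sigma_g2' must be a single non-negative value")
  }
  ve <- (1 - h2) * sigma_g2
  e <- with_seed(seed, stats::rnorm(length(tbv), mean = 0, sd = sqrt(ve)))
  tbv + e
}
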