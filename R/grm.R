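# Relationship matrices on the -1/0/1 code.
#
# G = X'X counts shared homozygous states: per pair and locus, identical
# homozygotes contribute +1, opposite homozygotes -1, and any pair
# involving a heterozygote 0.  Q counts the heterozygote-by-homozygote
# (He x Ho) loci of each pair, so G* = G + beta * Q assigns the He x Ho
# state the value beta instead of 0.  Negative beta therefore favours, in
# optimal contribution selection, individuals carrying many loci in He x Ho
# relationship with the rest of the population.
#
# Q scaling convention: Q_ij is the raw He x Ho locus count, which makes
# every per-pair, per-locus He x Ho value exactly beta in G*.  Under this
# convention the contribution quadratic form satisfies c'Qc = 2 He'Ho
# (each unordered pair is counted once in He'Ho but twice in the symmetric
# quadratic form); the factor 2 is absorbable into beta and changes no
# qualitative behaviour.

#' Realized genomic relationship matrix G = X'X
#'
#' No allele-frequency centering and no heterozygosity scaling are applied:
#' the diagonal of `G` is the number of homozygous loci per individual, and
#' off-diagonals count shared minus opposite homozygous states.
#'
#' @param X `L x N` genotype matrix in the -1/0/1 code.
#' @return An `N x N` symmetric matrix.
#' @export
#' @examples
#' compute_G(encode_genotypes(micro_panel()))
compute_G <- function(X) {
  check_coding(X)
  crossprod(X)
}

#' Heterozygote-by-homozygote count matrix Q
#'
#' `Q_ij` is the number of loci at which exactly one of individuals `i` and
#' `j` is heterozygous.  `Q` is symmetric with a zero diagonal.
#'
#' @inheritParams compute_G
#' @return An `N x N` symmetric matrix of non-negative integers.
#' @export
compute_Q <- function(X) {
  check_coding(X)
  het <- (X == 0) * 1L
  hom <- 1L - het
  q <- crossprod(het, hom)
  q + t(q)
}

#' Transformed relationship matrix G* = G + beta Q
#'
#' Sets the per-pair, per-locus value of every He x Ho state to `beta`
#' (in `[-1, 1]`), leaving homozygote pairs and He x He pairs as in `G`.
#'
#' @param G Matrix from [compute_G()].
#' @param Q Matrix from [compute_Q()].
#' @param beta Scalar in `[-1, 1]`.
#' @return An `N x N` symmetric matrix.
#' @export
compute_Gstar <- function(G, Q, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < -1 || beta > 1) {
    stop("'beta' must be a single value in [-1, 1]")
  }
  if (!identical(dim(G), dim(Q))) stop("'G' and 'Q' dimensions differ")
  G + beta * Q
}

#' Spectral projection onto positive definite matrices
#'
#' Eigendecomposes the (symmetrized) input and raises every eigenvalue
#' below `eig_floor` to `eig_floor`.  This is the closest positive definite
#' matrix in spectral norm with smallest eigenvalue at least `eig_floor`;
#' the distance to the input is `max(0, eig_floor - lambda_min)`.  A
#' strictly positive floor keeps the contribution quadratic program
#' strictly convex, hence uniquely solvable.
#'
#' @param M Symmetric matrix; `(M + t(M))/2` is used.
#' @param eig_floor Positive scalar; default `1e-8 * max(lambda_max(M), 1)`.
#' @return The projected matrix, with attributes `eig_floor` and
#'   `lambda_min` (smallest eigenvalue of the input).
#' @export
project_pd <- function(M, eig_floor = NULL) {
  if (any(!is.finite(M))) stop("'M' contains non-finite entries")
  S <- (M + t(M)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (is.null(eig_floor)) {
    eig_floor <- 1e-8 * max(e$values[1L], 1.0)
  }
  if (eig_floor <= 0) stop("'eig_floor' must be positive")
  vals <- pmax(e$values, eig_floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(M)
  attr(out, "eig_floor") <- eig_floor
  attr(out, "lambda_min") <- e$values[length(e$values)]
  out
}

#' Contribution-weighted heterozygote and homozygote proportions
#'
#' For a contribution vector `c` (non-negative, summing to 1),
#' `He_l = sum_i c_i 1{X[l,i] = 0}` is the contribution-weighted proportion
#' of heterozygous parents at locus `l`, and `Ho_l = 1 - He_l` the
#' homozygous complement.  Under the raw-count `Q`, `c'Qc = 2 * He'Ho`.
#'
#' @inheritParams compute_G
#' @param contrib Contribution vector of length `N`.
#' @return A list with numeric vectors `He` and `Ho` of length `L`.
#' @export
het_hom_vectors <- function(X, contrib) {
  check_coding(X)
  check_contrib(contrib, ncol(X))
  he <- drop((X == 0) %*% contrib)
  list(He = he, Ho = 1 - he)
}

#' Expected coancestry of a contribution-weighted parental pool
#'
#' The quadratic form `c'Mc`, optionally divided by the number of loci so
#' that values land on a `[-1, 1]`-like per-locus scale.  The "true"
#' coancestry of a scenario is this quantity evaluated with the unmodified
#' `G`, whatever `beta` drove selection and mating.
#'
#' @param contrib Contribution vector (non-negative, sums to 1).
#' @param M An `N x N` relationship matrix (`G` or `G*`).
#' @param n_loci Number of loci, required when `normalized = TRUE`.
#' @param normalized Divide by `n_loci` (default `TRUE`).
#' @return A scalar.
#' @export
#' @examples
#' X <- encode_genotypes(micro_panel())
#' coancestry(rep(1/3, 3), compute_G(X), n_loci = 4)
coancestry <- function(contrib, M, n_loci = NULL, normalized = TRUE) {
  if (length(contrib) != nrow(M)) stop("contribution/matrix dimension mismatch")
  check_contrib(contrib, nrow(M))
  v <- drop(crossprod(contrib, M %*% contrib))
  if (normalized) {
    if (is.null(n_loci)) stop("'n_loci' is required when normalized = TRUE")
    v <- v / n_loci
  }
  v
}

#' Bundle the relationship matrices of one candidate set
#'
#' Convenience constructor computing `G`, `Q`, `G* = G + beta Q` and the
#' positive-definite projection of `G*` in one call.
#'
#' @inheritParams compute_G
#' @param beta He x Ho value in `[-1, 1]`.
#' @param eig_floor Optional positive floor passed to [project_pd()].
#' @return An object of class `relationship_set` with elements `G`, `Q`,
#'   `beta`, `Gstar`, `Gstar_pd`, `eig_floor`, `n_loci`.
#' @export
relationship_set <- function(X, beta = 0, eig_floor = NULL) {
  G <- compute_G(X)
  Q <- compute_Q(X)
  Gstar <- compute_Gstar(G, Q, beta)
  Gpd <- project_pd(Gstar, eig_floor)
  structure(list(G = G, Q = Q, beta = beta, Gstar = Gstar,
                 Gstar_pd = Gpd, eig_floor = attr(Gpd, "eig_floor"),
                 n_loci = nrow(X)),
            class = "relationship_set")
}

#' @export
print.relationship_set <- function(x, ...) {
  cat("Relationship set: N = ", nrow(x$G), ", L = ", x$n_loci,
      ", beta = ", x$beta, "\n", sep = "")
  cat("  lambda_min(G*) = ", format(attr(x$Gstar_pd, "lambda_min")),
      ", eig_floor = ", format(x$eig_floor), "\n", sep = "")
  invisible(x)
}

check_coding <- function(X) {
  if (!is.matrix(X)) stop("'X' must be a matrix")
  if (!all(X %in% c(-1L, 0L, 1L))) {
    stop("'X' must be coded in {-1, 0, 1}")
  }
  invisible(TRUE)
}

check_contrib <- function(contrib, n) {
  if (length(contrib) != n) stop("contribution vector has wrong length")
  if (any(contrib < -1e-9)) stop("contributions must be non-negative")
  if (abs(sum(contrib) - 1) > 1e-6) {
    stop("contributions must sum to 1 (got ", format(sum(contrib)), ")")
  }
  invisible(TRUE)
}
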