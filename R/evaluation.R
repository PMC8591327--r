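# Ridge-regression genomic evaluation (RR-BLUP style) on the -1/0/1 code.
#
# Marker effects are shrunk towards zero with a fixed penalty lambda; with
# the variance-ratio plug-in of default_lambda() this is the classical
# RR-BLUP with known heritability.  Evaluation always uses the raw G-coding
# genotypes: the transformed matrix G* never enters prediction.

#' Fit a ridge-regression evaluation model
#'
#' Centers the phenotypes and estimates marker effects
#' `a_hat = argmin ||y_c - X'a||^2 + lambda ||a||^2`, through either the
#' primal `L x L` normal equations `(XX' + lambda I) a = X y_c` or the
#' equivalent dual `n x n` form `a = X (X'X + lambda I)^{-1} y_c`; the two
#' agree to numerical precision and the cheaper system is chosen by
#' default.
#'
#' @param X_ref `L x n` genotype matrix of the reference individuals
#'   (-1/0/1 code).
#' @param y Numeric phenotype vector of length `n`.
#' @param lambda Ridge penalty (> 0); see [default_lambda()].
#' @param method `"auto"` (default: smaller of the two systems),
#'   `"primal"` or `"dual"`.
#' @return An object of class `ridge_evaluation`: list with
#'   `marker_effects_hat`, `intercept`, `lambda`, `reference_size`.
#' @export
fit_ridge <- function(X_ref, y, lambda, method = c("auto", "primal", "dual")) {
  method <- match.arg(method)
  if (!is.matrix(X_ref)) stop("'X_ref' must be a matrix")
  n <- ncol(X_ref)
  L <- nrow(X_ref)
  if (length(y) != n) stop("phenotype/genotype dimension mismatch")
  if (n < 2L) stop("at least two reference individuals are required")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("'lambda' must be a single positive value")
  }
  mu <- mean(y)
  yc <- y - mu
  if (stats::sd(y) == 0) {
    warning("all phenotypes are identical; returning zero marker effects")
    a <- rep(0, L)
  } else {
    if (method == "auto") method <- if (L <= n) "primal" else "dual"
    a <- if (method == "primal") {
      K <- tcrossprod(X_ref)            # L x L
      diag(K) <- diag(K) + lambda
      drop(solve(K, X_ref %*% yc))
    } else {
      K <- crossprod(X_ref)             # n x n
      diag(K) <- diag(K) + lambda
      drop(X_ref %*% solve(K, yc))
    }
  }
  structure(list(marker_effects_hat = a, intercept = mu, lambda = lambda,
                 reference_size = n),
            class = "ridge_evaluation")
}

#' @export
print.ridge_evaluation <- function(x, ...) {
  cat("Ridge evaluation model: ", length(x$marker_effects_hat), " markers, ",
      x$reference_size, " reference individuals, lambda = ",
      format(x$lambda), "\n", sep = "")
  invisible(x)
}

#' @export
coef.ridge_evaluation <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$marker_effects_hat)
}

#' Predict genomic estimated breeding values
#'
#' `GEBV_i = intercept + sum_l a_hat_l X[l, i]`.
#'
#' @param model A `ridge_evaluation` from [fit_ridge()].
#' @param X_target `L x N` genotype matrix on the same loci as the
#'   reference.
#' @return Numeric vector of GEBVs, named by the target columns.
#' @export
predict_gebv <- function(model, X_target) {
  stopifnot(inherits(model, "ridge_evaluation"))
  if (nrow(X_target) != length(model$marker_effects_hat)) {
    stop("target loci do not match the fitted model")
  }
  model$intercept + drop(crossprod(X_target, model$marker_effects_hat))
}

#' Variance-ratio plug-in ridge penalty
#'
#' The classical RR-BLUP penalty for a known heritability:
#' `lambda = ((1 - h2) / h2) * sum_l 2 p_l (1 - p_l)`, with allele
#' frequencies taken from the reference panel.  As `h2` approaches 1 the
#' penalty vanishes; a small positive floor (1e-6) is returned instead of
#' zero so the system stays well posed.
#'
#' @param panel Reference `haplotype_panel`.
#' @param h2 Heritability in `(0, 1]`.
#' @return A positive scalar.
#' @export
default_lambda <- function(panel, h2) {
  if (!is.numeric(h2) || length(h2) != 1L || h2 <= 0 || h2 > 1) {
    stop("'h2' must lie in (0, 1]")
  }
  p <- allele_frequency(panel)
  het <- sum(2 * p * (1 - p))
  max(((1 - h2) / h2) * het, 1e-6)
}
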