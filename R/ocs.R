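# Optimal contribution selection as a scalarized quadratic program.
#
# min_c  alpha * c'Mc - (1 - alpha) * c'Y
# s.t.   sum(c) = 1,  0 <= c <= upper_bound  (, d'c = 0.5 for dioecy)
#
# M is the PD-projected transformed relationship matrix G*, Y the vector of
# (estimated) breeding values.  For alpha > 0 and M positive definite the
# objective is strictly convex and the solution unique.  The QP is solved
# with the Goldfarb-Idnani dual active-set method (quadprog), which is
# deterministic and achieves the KKT tolerances required here; the solver
# contract (KKT residual below tolerance), not the solver identity, is
# what the rest of the package relies on.

#' Solve the optimal-contribution quadratic program
#'
#' Minimizes `alpha * c'Mc - (1 - alpha) * c'Y` over the constrained
#' simplex `{0 <= c <= upper_bound, sum(c) = 1}`, optionally with the
#' dioecious constraint `d'c = 0.5`.
#'
#' `alpha = 0` is a degenerate linear program with possibly non-unique
#' optima; it is regularized with an effective `alpha` of `1e-9`, which
#' restores strict convexity and breaks ties deterministically.
#'
#' @param M Symmetric positive definite `N x N` matrix (use the
#'   `Gstar_pd` element of [relationship_set()]).
#' @param Y Numeric breeding-value vector of length `N` (GEBVs in a
#'   breeding program; the objective never sees TBVs).
#' @param alpha Trade-off weight in `[0, 1]`: the weight of coancestry
#'   relative to genetic gain.
#' @param upper_bound Per-individual contribution cap (default 0.5, which
#'   forbids selfing).
#' @param sex_design Optional 0/1 vector `d` of length `N`; adds the
#'   equality `d'c = 0.5` for dioecious populations.
#' @return An object of class `ocs_solution`: list with `c` (named
#'   contribution vector), `objective`, `cY`, `cMc`, `kkt_residual`,
#'   `status`, `alpha`, `upper_bound`.
#' @export
#' @examples
#' X <- encode_genotypes(micro_panel())
#' rs <- relationship_set(X, beta = 0)
#' solve_ocs(rs$Gstar_pd, c(2.5, 0.5, 2.0), alpha = 0.5)
solve_ocs <- function(M, Y, alpha, upper_bound = 0.5, sex_design = NULL) {
  n <- length(Y)
  if (!is.matrix(M) || nrow(M) != n || ncol(M) != n) {
    stop("'M' must be an N x N matrix matching length(Y)")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("'alpha' must lie in [0, 1]")
  }
  if (upper_bound <= 0 || upper_bound > 1) stop("'upper_bound' must be in (0, 1]")
  if (n * upper_bound < 1 - 1e-12) {
    stop("infeasible: N * upper_bound < 1, the contributions cannot sum to 1")
  }
  if (!is.null(sex_design)) {
    if (length(sex_design) != n || !all(sex_design %in% c(0, 1))) {
      stop("'sex_design' must be a 0/1 vector of length N")
    }
    if (sum(sex_design) * upper_bound < 0.5 - 1e-12 ||
        sum(1 - sex_design) * upper_bound < 0.5 - 1e-12) {
      stop("infeasible: a sex class cannot carry half of the contributions ",
           "under the given upper bound")
    }
  }

  alpha_eff <- if (alpha == 0) 1e-9 else alpha
  # Objective rescaled by 1/alpha_eff (same argmin, better conditioning when
  # alpha_eff is tiny): min 0.5 c' (2M) c - ((1-alpha)/alpha_eff) Y'c.
  Dmat <- 2 * (M + t(M)) / 2
  dvec <- ((1 - alpha) / alpha_eff) * Y

  Aeq <- matrix(1, n, 1)
  beq <- 1
  if (!is.null(sex_design)) {
    Aeq <- cbind(Aeq, sex_design)
    beq <- c(beq, 0.5)
  }
  Amat <- cbind(Aeq, diag(n), -diag(n))
  bvec <- c(beq, rep(0, n), rep(-upper_bound, n))

  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = ncol(Aeq)),
    error = function(e) {
      stop("OCS quadratic program failed (N = ", n, ", alpha = ", alpha,
           "): ", conditionMessage(e), call. = FALSE)
    })
  cc <- sol$solution
  cc[cc < 0] <- 0
  cc[cc > upper_bound] <- upper_bound
  # Repair the (tiny) simplex defect on interior coordinates only, so the
  # box constraints stay exactly satisfied.
  defect <- 1 - sum(cc)
  if (abs(defect) > 0) {
    interior <- which(cc > 1e-9 & cc < upper_bound - 1e-9)
    if (length(interior) > 0L) {
      cc[interior] <- cc[interior] + defect / length(interior)
    } else {
      cc <- cc / sum(cc)
    }
  }
  names(cc) <- if (!is.null(colnames(M))) colnames(M) else names(Y)

  cY <- sum(cc * Y)
  cMc <- drop(crossprod(cc, M %*% cc))
  kkt <- ocs_kkt_residual(M, Y, alpha, alpha_eff, cc, upper_bound, sex_design)

  structure(list(c = cc, objective = alpha * cMc - (1 - alpha) * cY,
                 cY = cY, cMc = cMc, kkt_residual = kkt,
                 status = "optimal", alpha = alpha,
                 upper_bound = upper_bound),
            class = "ocs_solution")
}

# Max KKT violation of the scaled problem min c'Mc - ((1-a)/a_eff) c'Y:
# stationarity on free coordinates, multiplier signs at the bounds, and
# complementarity, measured relative to the gradient scale.
ocs_kkt_residual <- function(M, Y, alpha, alpha_eff, cc, ub, sex_design) {
  n <- length(cc)
  g <- drop(2 * M %*% cc) - ((1 - alpha) / alpha_eff) * Y
  scale <- max(1, max(abs(g)))
  at_lo <- cc <= 1e-8
  at_up <- cc >= ub - 1e-8
  free <- !(at_lo | at_up)
  E <- matrix(1, n, 1)
  if (!is.null(sex_design)) E <- cbind(E, sex_design)
  if (any(free)) {
    # Equality multipliers by least squares on the free coordinates.
    mu <- tryCatch(qr.solve(E[free, , drop = FALSE], g[free]),
                   error = function(e) rep(0, ncol(E)))
    r <- g - drop(E %*% mu)
    resid <- max(abs(r[free]))
    if (any(at_lo)) resid <- max(resid, max(pmax(-r[at_lo], 0)))
    if (any(at_up)) resid <- max(resid, max(pmax(r[at_up], 0)))
  } else if (is.null(sex_design)) {
    # All coordinates at a bound: the simplex multiplier mu only needs to
    # lie in [max g at upper bounds, min g at lower bounds].
    mu_lo <- if (any(at_up)) max(g[at_up]) else -Inf
    mu_hi <- if (any(at_lo)) min(g[at_lo]) else Inf
    resid <- max(0, mu_lo - mu_hi)
  } else {
    # Vertex of the sex-constrained polytope: multipliers (mu1, mu2) must
    # satisfy one interval per sex class.
    resid <- 0
    for (s in c(0, 1)) {
      sel <- sex_design == s
      up <- at_up & sel; lo <- at_lo & sel
      m_lo <- if (any(up)) max(g[up]) else -Inf
      m_hi <- if (any(lo)) min(g[lo]) else Inf
      resid <- max(resid, m_lo - m_hi, 0)
    }
  }
  resid / scale
}

#' @export
print.ocs_solution <- function(x, ...) {
  cat("OCS solution (alpha = ", x$alpha, ")\n", sep = "")
  cat("  c'Y  = ", format(x$cY), "   c'Mc = ", format(x$cMc),
      "   KKT residual = ", format(x$kkt_residual), "\n", sep = "")
  nz <- sum(x$c > 1e-8)
  cat("  ", nz, " of ", length(x$c), " candidates contribute\n", sep = "")
  invisible(x)
}

#' @export
coef.ocs_solution <- function(object, ...) object$c

#' Trace the Pareto front by sweeping the trade-off weight
#'
#' Solves [solve_ocs()] for each `alpha` in `alphas`.  As `alpha` grows the
#' solutions move along the Pareto front: `c'Y` and `c'Mc` are both
#' nonincreasing, and the `(c'Mc, c'Y)` points are mutually non-dominated.
#'
#' @inheritParams solve_ocs
#' @param alphas Numeric vector of trade-off weights in `[0, 1]`.
#' @return An object of class `pareto_sweep`: list with `summary` (a
#'   data.frame with columns `alpha`, `cY`, `cMc`, `objective`,
#'   `kkt_residual`, `status`) and `solutions` (list of `ocs_solution` or
#'   `NULL` for failed alphas).
#' @export
pareto_sweep <- function(M, Y, alphas, upper_bound = 0.5, sex_design = NULL) {
  sols <- vector("list", length(alphas))
  rows <- vector("list", length(alphas))
  for (k in seq_along(alphas)) {
    s <- tryCatch(solve_ocs(M, Y, alphas[k], upper_bound, sex_design),
                  error = function(e) e)
    if (inherits(s, "error")) {
      rows[[k]] <- data.frame(alpha = alphas[k], cY = NA_real_,
                              cMc = NA_real_, objective = NA_real_,
                              kkt_residual = NA_real_,
                              status = conditionMessage(s))
    } else {
      sols[[k]] <- s
      rows[[k]] <- data.frame(alpha = alphas[k], cY = s$cY, cMc = s$cMc,
                              objective = s$objective,
                              kkt_residual = s$kkt_residual,
                              status = s$status)
    }
  }
  structure(list(summary = do.call(rbind, rows), solutions = sols),
            class = "pareto_sweep")
}

#' @export
print.pareto_sweep <- function(x, ...) {
  cat("Pareto sweep over", nrow(x$summary), "trade-off weights\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pareto_sweep <- function(x, ...) {
  s <- x$summary[!is.na(x$summary$cY), ]
  graphics::plot(s$cMc, s$cY, type = "b", pch = 19,
                 xlab = "coancestry  c'Mc", ylab = "expected gain  c'Y", ...)
  graphics::text(s$cMc, s$cY, labels = format(s$alpha), pos = 3, cex = 0.7)
  invisible(x)
}
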