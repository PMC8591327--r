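# Mate allocation: turn optimal contributions into an integer mating plan.
#
# Once the contributions are fixed, the mating plan cannot change the mean
# breeding value or the mean coancestry of the selected parents, but it
# does change progeny homozygosity: the expected number of homozygous loci
# of an offspring of parents i and j is (L + G_ij) / 2, so minimizing the
# plan total of G*_ij over matings minimizes the expected trace of G at
# the next generation.  The plan is found by a degree-constrained linear
# program over pair counts, with a rounding repair for the (half-integral)
# fractional vertices the relaxation can produce; a random-mating control
# realizes the same gamete counts without cost minimization.

#' Discretize contributions into integer gamete counts
#'
#' Largest-remainder rounding of `2 * n_offspring * c`: each unit is one
#' gamete, so `sum(g) = 2 * n_offspring`.  Ties on remainders are broken by
#' larger contribution, then lower index.  Because `c <= 0.5`, no parent
#' receives more than `n_offspring` gametes, which keeps a self-free plan
#' feasible.
#'
#' @param contrib Contribution vector (non-negative, sums to 1, entries
#'   at most 0.5).
#' @param n_offspring Number of offspring to produce (>= 1).
#' @return An object of class `gamete_allocation`: list with integer
#'   vector `g` and `n_offspring`.
#' @export
#' @examples
#' contributions_to_gametes(c(0.5, 0.25, 0.25), 2)
contributions_to_gametes <- function(contrib, n_offspring) {
  if (n_offspring < 1) stop("'n_offspring' must be at least 1")
  n_offspring <- as.integer(n_offspring)
  check_contrib(contrib, length(contrib))
  if (any(contrib > 0.5 + 1e-9)) stop("contributions must not exceed 0.5")
  target <- 2 * n_offspring * contrib / sum(contrib)
  g <- floor(target + 1e-12)
  rem <- target - g
  short <- 2L * n_offspring - as.integer(round(sum(g)))
  if (short > 0L) {
    ord <- order(-rem, -contrib, seq_along(contrib))
    add <- ord[seq_len(short)]
    g[add] <- g[add] + 1
  }
  g <- as.integer(round(g))
  # c <= 0.5 guarantees g_i <= n_offspring already; redistribute defensively
  # if numerical ties ever pushed a parent over the cap.
  while (any(over <- g > n_offspring)) {
    i <- which(over)[1L]
    excess <- g[i] - n_offspring
    g[i] <- n_offspring
    room <- which(g < n_offspring & seq_along(g) != i)
    ord <- room[order(-rem[room], -contrib[room], room)]
    for (j in ord) {
      if (excess == 0L) break
      g[j] <- g[j] + 1L
      excess <- excess - 1L
    }
    if (excess > 0L) stop("cannot redistribute gametes under the cap")
  }
  names(g) <- names(contrib)
  structure(list(g = g, n_offspring = n_offspring),
            class = "gamete_allocation")
}

#' @export
print.gamete_allocation <- function(x, ...) {
  cat("Gamete allocation: ", sum(x$g > 0), " parents, ",
      x$n_offspring, " offspring\n", sep = "")
  invisible(x)
}

as_gamete_allocation <- function(g, n_offspring = NULL) {
  if (inherits(g, "gamete_allocation")) return(g)
  g <- as.integer(round(g))
  if (any(g < 0)) stop("gamete counts must be non-negative")
  tot <- sum(g)
  if (tot %% 2L != 0L) stop("total gamete count must be even")
  if (is.null(n_offspring)) n_offspring <- tot %/% 2L
  if (tot != 2L * n_offspring) stop("sum(g) must equal 2 * n_offspring")
  if (max(g) > n_offspring) {
    stop("infeasible gamete counts: one parent holds more than half the gametes")
  }
  structure(list(g = g, n_offspring = as.integer(n_offspring)),
            class = "gamete_allocation")
}

new_mate_plan <- function(pair_counts, n_offspring, ids = NULL) {
  pair_counts <- as.matrix(pair_counts)
  storage.mode(pair_counts) <- "integer"
  if (!is.null(ids)) dimnames(pair_counts) <- list(ids, ids)
  if (any(diag(pair_counts) != 0L)) stop("selfing is not allowed in a mate plan")
  if (!identical(pair_counts, t(pair_counts))) stop("pair counts must be symmetric")
  if (sum(pair_counts[upper.tri(pair_counts)]) != n_offspring) {
    stop("pair counts do not realize n_offspring matings")
  }
  structure(list(pair_counts = pair_counts,
                 n_offspring = as.integer(n_offspring)),
            class = "mate_plan")
}

#' @export
print.mate_plan <- function(x, ...) {
  np <- sum(x$pair_counts[upper.tri(x$pair_counts)] > 0)
  cat("Mate plan: ", x$n_offspring, " matings over ", np, " distinct pairs\n",
      sep = "")
  invisible(x)
}

plan_degrees <- function(plan) {
  rowSums(plan$pair_counts)
}

#' Minimum-cost mate allocation by linear programming
#'
#' Finds non-negative integer pair counts `n_ij` (no selfing) with
#' prescribed parental degrees `sum_j n_ij = g_i`, minimizing
#' `sum_{i<j} n_ij * cost_ij`.  With `cost` set to the off-diagonal of the
#' transformed relationship matrix `G*`, this minimizes the expected
#' average progeny homozygosity of the plan.
#'
#' The degree-constrained (b-matching) LP relaxation is solved first; its
#' basic solutions are half-integral, and fractional edges are repaired
#' along alternating cycles, choosing for each cycle (or pair of odd
#' cycles) the candidate rounding of least cost that preserves all degrees
#' exactly.
#'
#' @param g A `gamete_allocation`, or a non-negative integer vector of
#'   gamete counts with an even, positive sum.
#' @param cost Symmetric `N x N` matrix of mating costs (typically `G*`,
#'   not PD-projected: the projection is needed only by the QP).
#' @param ids Optional individual labels for the plan dimnames.
#' @return An object of class `mate_plan`: list with the symmetric integer
#'   matrix `pair_counts` and `n_offspring`.
#' @export
#' @examples
#' g <- contributions_to_gametes(c(0.5, 0.25, 0.25), 2)
#' solve_mating(g, matrix(0, 3, 3))
solve_mating <- function(g, cost, ids = NULL) {
  ga <- as_gamete_allocation(g)
  gv <- ga$g
  N <- length(gv)
  if (!is.matrix(cost) || nrow(cost) != N || ncol(cost) != N) {
    stop("'cost' must be an N x N matrix")
  }
  if (any(!is.finite(cost))) stop("'cost' must be finite")
  if (is.null(ids) && !is.null(names(gv))) ids <- names(gv)
  if (is.null(ids) && !is.null(rownames(cost))) ids <- rownames(cost)
  active <- which(gv > 0L)
  if (sum(gv) == 0L) stop("no gametes to allocate")
  if (max(gv) > sum(gv[-which.max(gv)])) {
    stop("infeasible degrees: one parent needs more matings than the others can supply")
  }
  if (length(active) < 2L) stop("at least two parents must contribute")

  pc <- matrix(0L, N, N)
  if (length(active) == 2L) {
    i <- active[1L]; j <- active[2L]
    pc[i, j] <- pc[j, i] <- gv[i]
    return(new_mate_plan(pc, ga$n_offspring, ids))
  }

  edges <- t(utils::combn(active, 2L))
  m <- nrow(edges)
  cvec <- cost[edges]
  A <- matrix(0, length(active), m)
  rowof <- match(edges, active)
  dim(rowof) <- dim(edges)
  for (e in seq_len(m)) {
    A[rowof[e, 1L], e] <- 1
    A[rowof[e, 2L], e] <- 1
  }
  lp <- lp_simplex(cvec - min(cvec) + 1, A, gv[active])
  if (lp$status != "optimal") {
    stop("mate-allocation LP failed: ", lp$status)
  }
  x <- round(2 * lp$x) / 2        # vertices are half-integral
  if (max(abs(x - lp$x)) > 1e-5) {
    stop("LP vertex is not half-integral within tolerance")
  }
  x <- repair_half_integral(x, edges, cost)
  for (e in seq_len(m)) {
    if (x[e] > 0) {
      i <- edges[e, 1L]; j <- edges[e, 2L]
      pc[i, j] <- pc[j, i] <- as.integer(round(x[e]))
    }
  }
  new_mate_plan(pc, ga$n_offspring, ids)
}

# Round a half-integral b-matching vector to integers, preserving degrees.
# Fractional edges form an even-degree subgraph, decomposed into simple
# cycles.  Even cycles are rounded by the cheaper of the two alternating
# +/-1/2 assignments.  Odd cycles come in pairs (total weight is integral);
# each pair is closed through one extra edge (u, v), enumerating anchors
# u, v and both sign choices and keeping the cheapest feasible repair.
repair_half_integral <- function(x, edges, cost) {
  frac <- which(abs(x - round(x)) > 1e-9)
  if (length(frac) == 0L) return(round(x))
  # Edge lookup by vertex pair.
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  idx <- new.env(hash = TRUE)
  for (e in seq_len(nrow(edges))) assign(key(edges[e, 1], edges[e, 2]), e, idx)
  edge_id <- function(i, j) get(key(i, j), idx)

  # Decompose fractional edges into simple cycles by walking.
  adj <- list()
  for (e in frac) {
    for (v in edges[e, ]) {
      v <- as.character(v)
      adj[[v]] <- c(adj[[v]], e)
    }
  }
  used <- rep(FALSE, length(x))
  cycles <- list()   # each: list(edges = edge ids in walk order,
                     #            verts = vertex at the tail of each edge)
  for (e0 in frac) {
    if (used[e0]) next
    # Closed walk from e0's tail; in an even-degree subgraph the walk can
    # only terminate back at its start.
    start <- edges[e0, 1L]
    cyc_e <- integer(0)
    cyc_v <- integer(0)
    v <- start
    repeat {
      avail <- adj[[as.character(v)]]
      avail <- avail[!used[avail]]
      if (length(avail) == 0L) break
      e <- avail[1L]
      used[e] <- TRUE
      cyc_e <- c(cyc_e, e)
      cyc_v <- c(cyc_v, v)
      pair <- edges[e, ]
      v <- if (pair[1L] == v) pair[2L] else pair[1L]
      if (v == start) break
    }
    if (length(cyc_e) > 0L) {
      cycles[[length(cycles) + 1L]] <- list(edges = cyc_e, verts = cyc_v)
    }
  }

  apply_alternating <- function(x, cyc, sign0) {
    s <- sign0
    for (e in cyc) {
      x[e] <- x[e] + s * 0.5
      s <- -s
    }
    x
  }
  alt_cost <- function(cyc, sign0) {
    s <- sign0
    tot <- 0
    for (e in cyc) {
      tot <- tot + s * 0.5 * cost[edges[e, 1L], edges[e, 2L]]
      s <- -s
    }
    tot
  }
  # Rotate a closed walk so that it starts (and therefore ends) at `anchor`;
  # the alternation starting with sign s then changes only the anchor's
  # degree, by s * 1 for odd walks and 0 for even walks.
  rotate_to_anchor <- function(cyc, anchor) {
    r <- which(cyc$verts == anchor)[1L]
    k <- length(cyc$edges)
    cyc$edges[c(seq(r, k), if (r > 1L) seq(1L, r - 1L))]
  }

  odd <- list()
  for (cyc in cycles) {
    if (length(cyc$edges) %% 2L == 0L) {
      pick <- if (alt_cost(cyc$edges, 1) <= alt_cost(cyc$edges, -1)) 1 else -1
      x <- apply_alternating(x, cyc$edges, pick)
    } else {
      odd[[length(odd) + 1L]] <- cyc
    }
  }
  if (length(odd) %% 2L != 0L) stop("internal error: unpaired odd cycle")
  while (length(odd) >= 2L) {
    c1 <- odd[[1L]]; c2 <- odd[[2L]]
    odd <- odd[-(1:2)]
    best <- NULL
    for (u in unique(c1$verts)) for (v in unique(c2$verts)) {
      if (u == v) next
      e_uv <- edge_id(u, v)
      for (s in c(1, -1)) {
        # s = +1: both anchors gain 1; compensate with x_uv - 1 (needs >= 1).
        # s = -1: both anchors lose 1; compensate with x_uv + 1.
        if (s == 1 && x[e_uv] < 1 - 1e-9) next
        dc <- alt_cost(rotate_to_anchor(c1, u), s) +
              alt_cost(rotate_to_anchor(c2, v), s) -
              s * cost[edges[e_uv, 1L], edges[e_uv, 2L]]
        if (is.null(best) || dc < best$dc) {
          best <- list(u = u, v = v, s = s, dc = dc, e_uv = e_uv)
        }
      }
    }
    if (is.null(best)) stop("internal error: no feasible odd-cycle repair")
    x <- apply_alternating(x, rotate_to_anchor(c1, best$u), best$s)
    x <- apply_alternating(x, rotate_to_anchor(c2, best$v), best$s)
    x[best$e_uv] <- x[best$e_uv] - best$s
  }
  x <- round(x * 2) / 2
  if (any(abs(x - round(x)) > 1e-9) || any(x < -1e-9)) {
    stop("internal error: rounding repair failed")
  }
  round(x)
}

#' Random mating realizing given gamete counts
#'
#' Draws matings sequentially: each mating picks two distinct parents with
#' probability proportional to their remaining gamete counts.  If the draw
#' dead-ends with gametes left in a single parent, existing matings are
#' repaired by re-pairing, so the returned plan always satisfies the
#' degrees exactly.
#'
#' @inheritParams solve_mating
#' @param seed Integer seed; the plan is deterministic given it.
#' @return A `mate_plan`.
#' @export
random_mating <- function(g, seed, ids = NULL) {
  ga <- as_gamete_allocation(g)
  gv <- ga$g
  N <- length(gv)
  if (is.null(ids) && !is.null(names(gv))) ids <- names(gv)
  if (max(gv) > sum(gv[-which.max(gv)])) {
    stop("infeasible degrees: one parent needs more matings than the others can supply")
  }
  pc <- matrix(0L, N, N)
  with_seed(seed, {
    rem <- gv
    while (sum(rem) > 0L) {
      hot <- which(rem > 0L)
      if (length(hot) >= 2L) {
        i <- if (length(hot) == 1L) hot else
          sample(hot, 1L, prob = rem[hot])
        others <- hot[hot != i]
        j <- if (length(others) == 1L) others else
          sample(others, 1L, prob = rem[others])
        pc[i, j] <- pc[i, j] + 1L
        pc[j, i] <- pc[i, j]
        rem[i] <- rem[i] - 1L
        rem[j] <- rem[j] - 1L
      } else {
        # Dead end: all remaining gametes belong to one parent i.  Take an
        # existing mating (j, k) avoiding i, release it, and mate i with
        # both j and k: degrees of j and k are unchanged, i gains 2.
        i <- hot
        cand <- which(pc > 0L, arr.ind = TRUE)
        cand <- cand[cand[, 1] < cand[, 2] &
                     cand[, 1] != i & cand[, 2] != i, , drop = FALSE]
        if (nrow(cand) == 0L) stop("random mating cannot satisfy the degrees")
        r <- cand[sample.int(nrow(cand), 1L), ]
        j <- r[[1]]; k <- r[[2]]
        pc[j, k] <- pc[k, j] <- pc[j, k] - 1L
        pc[i, j] <- pc[j, i] <- pc[i, j] + 1L
        pc[i, k] <- pc[k, i] <- pc[i, k] + 1L
        rem[i] <- rem[i] - 2L
      }
    }
  })
  new_mate_plan(pc, ga$n_offspring, ids)
}

#' Expected mean progeny homozygosity of a plan
#'
#' Under Mendelian segregation the expected number of homozygous loci of an
#' offspring of parents `i` and `j` equals `(L + G_ij) / 2` -- the parents'
#' genomic relatedness up to a constant.  This returns the plan average
#' `(1 / n_offspring) * sum_{i<j} n_ij * (L + G_ij) / 2`.
#'
#' @param G Relationship matrix from [compute_G()] (or `G*` when scoring
#'   the transformed objective actually minimized by [solve_mating()]).
#' @param plan A `mate_plan`.
#' @param n_loci Number of loci `L`.
#' @return A scalar: expected homozygous-locus count per offspring.
#' @export
expected_progeny_homozygosity <- function(G, plan, n_loci) {
  stopifnot(inherits(plan, "mate_plan"))
  pc <- plan$pair_counts
  if (!identical(dim(pc), dim(G))) stop("plan/matrix dimension mismatch")
  ut <- upper.tri(pc)
  sum(pc[ut] * (n_loci + G[ut]) / 2) / plan$n_offspring
}
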