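# Dense two-phase revised simplex for equality-form linear programs:
#
#   min c'x   s.t.  A x = b,  x >= 0,   with b >= 0.
#
# Written for the degree-constrained mate-allocation LP (a few thousand
# edge variables, at most a few hundred degree constraints), where no
# suitable LP backend is available.  Pricing is fully vectorized
# (crossprod over the column matrix), the basis inverse is kept explicitly
# and updated by rank-one eta operations.  Dantzig pricing with
# lowest-index tie-breaks is used by default; after an iteration cap the
# rule switches to Bland's, which guarantees termination.

lp_simplex <- function(cost, A, b, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(cost) == n, length(b) == m)
  if (any(b < -tol)) stop("lp_simplex requires b >= 0")
  b <- pmax(b, 0)
  if (is.null(max_iter)) max_iter <- 50L * (n + m) + 1000L

  # Phase 1: artificial basis.
  Aext <- cbind(A, diag(m))
  cext <- c(rep(0, n), rep(1, m))
  basis <- n + seq_len(m)
  Binv <- diag(m)
  xB <- b

  run_phase <- function(cvec, basis, Binv, xB, allow, art_guard = FALSE) {
    it <- 0L
    bland_after <- 20L * (n + m)
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit", basis = basis,
                                     Binv = Binv, xB = xB))
      cB <- cvec[basis]
      y <- drop(crossprod(Binv, cB))          # simplex multipliers
      red <- cvec - drop(crossprod(Aext, y))  # reduced costs
      red[basis] <- 0
      red[!allow] <- Inf
      if (it <= bland_after) {
        j <- which.min(red)                   # Dantzig; lowest index on ties
        if (red[j] >= -tol) return(list(status = "optimal", basis = basis,
                                        Binv = Binv, xB = xB))
      } else {
        neg <- which(red < -tol)              # Bland's rule
        if (length(neg) == 0L) return(list(status = "optimal", basis = basis,
                                           Binv = Binv, xB = xB))
        j <- neg[1L]
      }
      d <- drop(Binv %*% Aext[, j])
      # A zero-level basic artificial must never regrow: if the step would
      # increase one (d < 0 on its row), pivot it out at step zero instead.
      if (art_guard) {
        art_rows <- which(basis > n & d < -tol)
        if (length(art_rows) > 0L) {
          r <- art_rows[1L]
          piv <- d[r]
          xB <- xB - 0 * d
          Er <- Binv[r, ] / piv
          Binv <- Binv - outer(d, Er)
          Binv[r, ] <- Er
          basis[r] <- j
          next
        }
      }
      pos <- which(d > tol)
      if (length(pos) == 0L) return(list(status = "unbounded", basis = basis,
                                         Binv = Binv, xB = xB))
      ratio <- xB[pos] / d[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      r <- cand[which.min(basis[cand])]       # leaving row: smallest basis index
      # Pivot: basis[r] leaves, j enters.
      piv <- d[r]
      xB <- xB - (rmin * d)
      xB[r] <- rmin
      xB[xB < 0] <- 0
      Er <- Binv[r, ] / piv
      Binv <- Binv - outer(d, Er)
      Binv[r, ] <- Er
      basis[r] <- j
    }
  }

  allow1 <- rep(TRUE, n + m)
  ph1 <- run_phase(cext, basis, Binv, xB, allow1)
  if (ph1$status != "optimal") {
    return(list(status = paste0("phase1_", ph1$status), x = NULL))
  }
  art_level <- sum(ph1$xB[ph1$basis > n])
  if (art_level > 1e-7 * max(1, max(b))) {
    return(list(status = "infeasible", x = NULL))
  }

  # Phase 2: original costs; artificials may stay basic at zero level but
  # must not re-enter.
  allow2 <- c(rep(TRUE, n), rep(FALSE, m))
  c2 <- c(cost, rep(0, m))
  ph2 <- run_phase(c2, ph1$basis, ph1$Binv, ph1$xB, allow2, art_guard = TRUE)
  if (ph2$status != "optimal") {
    return(list(status = paste0("phase2_", ph2$status), x = NULL))
  }
  x <- numeric(n)
  keep <- ph2$basis <= n
  x[ph2$basis[keep]] <- ph2$xB[keep]
  if (max(abs(A %*% x - b)) > 1e-6 * max(1, max(b))) {
    return(list(status = "numerical_failure", x = NULL))
  }
  list(status = "optimal", x = x, value = sum(cost * x))
}
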