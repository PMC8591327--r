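# Relationship matrices G, Q, G*, the PD projection, and coancestry.

test_that("micro-fixture relationship matrices match hand computation exactly", {
  X <- encode_genotypes(micro_panel())
  G <- compute_G(X)
  Q <- compute_Q(X)
  expect_identical(unname(diag(G)), c(3, 2, 3))
  expect_identical(G["A", "B"], 0)
  expect_identical(G["A", "C"], 0)
  expect_identical(G["B", "C"], -1)
  expect_identical(unname(diag(Q)), c(0, 0, 0))
  expect_identical(Q["A", "B"], 1)
  expect_identical(Q["A", "C"], 2)
  expect_identical(Q["B", "C"], 3)
  Gs <- compute_Gstar(G, Q, 0.5)
  expect_identical(Gs["A", "B"], 0.5)
  expect_identical(Gs["A", "C"], 1)
  expect_identical(Gs["B", "C"], 0.5)
  expect_identical(compute_Gstar(G, Q, -0.5)["B", "C"], -2.5)
  expect_identical(compute_Gstar(G, Q, 0), G)
  expect_error(compute_Gstar(G, Q, 1.5), "beta")
})

test_that("per-pair locus values and boundary cases behave as defined", {
  # identical fully homozygous individuals: G_ij = L
  a <- rbind(c(1, 1, 0), c(1, 1, 0), c(1, 1, 0), c(1, 1, 0))
  X <- encode_genotypes(haplotype_panel(a))
  expect_equal(compute_G(X)[1, 2], 3)
  expect_equal(compute_Q(X)[1, 2], 0)
  # fully het vs fully hom: Q_ij = L, G_ij = 0
  b <- rbind(c(0, 0, 0), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  Xb <- encode_genotypes(haplotype_panel(b))
  expect_equal(compute_Q(Xb)[1, 2], 3)
  expect_equal(compute_G(Xb)[1, 2], 0)
})

test_that("G and Q agree with the naive double-loop oracle on random panels", {
  for (s in 1:5) {
    p <- random_panel(sample(3:10, 1), sample(10:50, 1), seed = 100 + s)
    X <- encode_genotypes(p)
    expect_equal(unname(compute_G(X)), naive_G(X))
    expect_equal(unname(compute_Q(X)), naive_Q(X))
    expect_equal(unname(diag(compute_G(X))), unname(colSums(X^2)))
  }
})

test_that("the transformed quadratic form identity holds to 1e-10", {
  set.seed(9)
  for (s in 1:5) {
    p <- random_panel(12, 40, seed = 200 + s)
    X <- encode_genotypes(p)
    G <- compute_G(X); Q <- compute_Q(X)
    beta <- runif(1, -1, 1)
    Gs <- compute_Gstar(G, Q, beta)
    cc <- random_contrib(12)
    lhs <- drop(crossprod(cc, Gs %*% cc))
    rhs <- drop(crossprod(cc, G %*% cc)) + beta * drop(crossprod(cc, Q %*% cc))
    expect_lt(abs(lhs - rhs), 1e-10)
    hh <- het_hom_vectors(X, cc)
    expect_equal(unname(hh$He + hh$Ho), rep(1, 40))
    expect_lt(abs(drop(crossprod(cc, Q %*% cc)) - 2 * sum(hh$He * hh$Ho)),
              1e-10)
  }
})

test_that("micro-fixture He/Ho values and coancestry match hand counts", {
  X <- encode_genotypes(micro_panel())
  cc <- rep(1 / 3, 3)
  hh <- het_hom_vectors(X, cc)
  expect_equal(unname(hh$He * hh$Ho), c(2, 0, 2, 2) / 9)
  expect_equal(sum(hh$He * hh$Ho), 2 / 3)
  Q <- compute_Q(X)
  expect_equal(drop(crossprod(cc, Q %*% cc)), 4 / 3)
  G <- compute_G(X)
  expect_equal(coancestry(cc, G, n_loci = 4), 1 / 6)
  expect_equal(coancestry(cc, G, normalized = FALSE), 2 / 3)
  expect_error(het_hom_vectors(X, c(1, 1, 1)), "sum to 1")
  # N identical fully homozygous individuals -> normalized coancestry 1
  a <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  Xh <- encode_genotypes(haplotype_panel(a))
  expect_equal(coancestry(c(0.4, 0.6), compute_G(Xh), n_loci = 2), 1)
  # uniform normalized coancestry is bounded by per-locus values
  p <- random_panel(6, 25, seed = 31)
  Xp <- encode_genotypes(p)
  v <- coancestry(rep(1 / 6, 6), compute_G(Xp), n_loci = 25)
  expect_gte(v, -1); expect_lte(v, 1)
})

test_that("PD projection clips eigenvalues, is idempotent, and measures its distance", {
  M <- matrix(c(1, 2, 2, 1), 2)   # eigenvalues 3 and -1
  P <- project_pd(M, eig_floor = 1e-10)
  expect_lt(max(abs(P - matrix(1.5, 2, 2))), 1e-6)
  expect_equal(attr(P, "lambda_min"), -1)
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-10 * (1 - 1e-9))
  # spectral distance equals max(0, floor - lambda_min)
  expect_lt(abs(max(abs(eigen(P - M)$values)) - (1e-10 + 1)), 1e-8)
  # idempotence and identity on PD inputs
  P2 <- project_pd(P, eig_floor = 1e-10)
  expect_lt(max(abs(P2 - P)), 1e-10)
  D <- diag(c(2, 3, 4))
  expect_lt(max(abs(project_pd(D, 1e-8) - D)), 1e-12)
  # eigenvalues already above the floor are not decreased
  set.seed(4)
  A <- matrix(rnorm(25), 5); S <- (A + t(A)) / 2
  fl <- 0.5
  Pr <- project_pd(S, fl)
  e_in <- sort(eigen(S, TRUE, TRUE)$values)
  e_out <- sort(eigen(Pr, TRUE, TRUE)$values)
  expect_true(all(e_out >= pmin(pmax(e_in, fl), e_in) - 1e-10))
  expect_equal(e_out[e_in >= fl], e_in[e_in >= fl], tolerance = 1e-10)
  expect_error(project_pd(matrix(c(1, NA, NA, 1), 2)), "finite")
})

test_that("relabeling individuals permutes G, Q and G* consistently", {
  p <- random_panel(7, 20, seed = 77)
  X <- encode_genotypes(p)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  Xp <- X[, perm]
  expect_equal(unname(compute_G(Xp)), unname(compute_G(X)[perm, perm]))
  expect_equal(unname(compute_Q(Xp)), unname(compute_Q(X)[perm, perm]))
  Gs <- compute_Gstar(compute_G(X), compute_Q(X), 0.3)
  Gsp <- compute_Gstar(compute_G(Xp), compute_Q(Xp), 0.3)
  expect_equal(unname(Gsp), unname(Gs[perm, perm]))
})
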