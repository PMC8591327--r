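# Gamete discretization, LP mate allocation, random-mating control,
# expected progeny homozygosity.

test_that("largest-remainder gamete counts are exact and capped", {
  g1 <- contributions_to_gametes(c(0.5, 0.5), 10)
  expect_identical(unname(g1$g), c(10L, 10L))
  g2 <- contributions_to_gametes(c(0.5, 0.25, 0.25), 2)
  expect_identical(unname(g2$g), c(2L, 1L, 1L))
  g3 <- contributions_to_gametes(c(0.4, 0.35, 0.25), 5)
  expect_identical(sum(g3$g), 10L)
  expect_true(all(abs(g3$g - 10 * c(0.4, 0.35, 0.25)) < 1))
  expect_error(contributions_to_gametes(c(0.5, 0.5), 0), "at least 1")
  expect_error(contributions_to_gametes(c(0.7, 0.3), 4), "0.5")
  # property over random contributions
  set.seed(10)
  for (k in 1:20) {
    n <- sample(3:12, 1)
    cc <- random_contrib(n)
    noff <- sample(1:50, 1)
    g <- contributions_to_gametes(cc, noff)
    expect_identical(sum(g$g), 2L * as.integer(noff))
    expect_true(all(g$g <= noff))
    expect_true(all(abs(g$g - 2 * noff * cc) < 1 + 1e-9))
  }
})

test_that("forced mate plans are found regardless of cost", {
  cost <- matrix(c(0, 9, 1, 9, 0, 9, 1, 9, 0), 3)
  plan <- solve_mating(c(2L, 1L, 1L), cost)
  expect_identical(plan$pair_counts[1, 2], 1L)
  expect_identical(plan$pair_counts[1, 3], 1L)
  # two parents
  p2 <- solve_mating(c(4L, 4L), matrix(0, 2, 2))
  expect_identical(p2$pair_counts[1, 2], 4L)
  # four singles: the cheapest perfect matching wins
  cost4 <- matrix(5, 4, 4); diag(cost4) <- 0
  cost4[1, 2] <- cost4[2, 1] <- -2
  cost4[3, 4] <- cost4[4, 3] <- -1
  p4 <- solve_mating(rep(1L, 4), cost4)
  expect_identical(p4$pair_counts[1, 2], 1L)
  expect_identical(p4$pair_counts[3, 4], 1L)
  expect_error(solve_mating(c(5L, 1L, 2L), matrix(0, 3, 3)), "infeasible")
})

test_that("LP plus repair reaches the enumerated integer optimum", {
  set.seed(20)
  for (k in 1:40) {
    n <- sample(3:5, 1)
    noff <- sample(2:4, 1)
    cc <- random_contrib(n)
    g <- contributions_to_gametes(cc, noff)$g
    if (sum(g > 0) < 2) next
    A <- matrix(rnorm(n * n), n)
    cost <- A + t(A); diag(cost) <- 0
    plan <- solve_mating(g, cost)
    got <- sum(plan$pair_counts[upper.tri(cost)] * cost[upper.tri(cost)])
    best <- enumerate_min_plan_cost(g, cost)
    expect_equal(got, best, tolerance = 1e-9)
    expect_equal(unname(rowSums(plan$pair_counts)), as.numeric(g))
  }
})

test_that("plan degrees are conserved exactly on random instances", {
  set.seed(21)
  for (k in 1:100) {
    n <- sample(4:20, 1)
    noff <- sample(2:30, 1)
    cc <- random_contrib(n)
    g <- contributions_to_gametes(cc, noff)$g
    if (sum(g > 0) < 2) next
    A <- matrix(rnorm(n * n), n)
    cost <- A + t(A); diag(cost) <- 0
    plan <- solve_mating(g, cost)
    expect_equal(unname(rowSums(plan$pair_counts)), as.numeric(g))
    expect_identical(sum(plan$pair_counts[upper.tri(cost)]),
                     as.integer(noff))
    expect_true(all(diag(plan$pair_counts) == 0L))
  }
})

test_that("random mating satisfies degrees and never beats the LP on average", {
  # forced plans
  pr <- random_mating(c(3L, 3L), seed = 1)
  expect_identical(pr$pair_counts[1, 2], 3L)
  hits <- vapply(1:200, function(s) {
    p <- random_mating(c(2L, 1L, 1L), seed = s)
    p$pair_counts[1, 2] == 1L && p$pair_counts[1, 3] == 1L
  }, logical(1))
  expect_true(all(hits))    # only one degree-feasible plan exists
  # degree conservation across random instances (includes dead-end repair)
  set.seed(22)
  for (k in 1:60) {
    n <- sample(3:15, 1)
    g <- contributions_to_gametes(random_contrib(n), sample(2:20, 1))$g
    if (sum(g > 0) < 2) next
    p <- random_mating(g, seed = k)
    expect_equal(unname(rowSums(p$pair_counts)), as.numeric(g))
  }
  # expected cost: LP <= random, averaged over seeds
  set.seed(23)
  diffs <- numeric(50)
  for (k in 1:50) {
    n <- 8
    g <- contributions_to_gametes(random_contrib(n), 10)$g
    A <- matrix(rnorm(n * n), n)
    cost <- A + t(A); diag(cost) <- 0
    ut <- upper.tri(cost)
    lpc <- sum(solve_mating(g, cost)$pair_counts[ut] * cost[ut])
    rmc <- sum(random_mating(g, seed = 1000 + k)$pair_counts[ut] * cost[ut])
    diffs[k] <- rmc - lpc
  }
  expect_gte(mean(diffs), 0)
  expect_true(all(diffs > -1e-9))   # LP is optimal, so never worse
})

test_that("expected progeny homozygosity follows (L + G_ij) / 2", {
  X <- encode_genotypes(micro_panel())
  G <- compute_G(X)
  pc <- matrix(0L, 3, 3); pc[1, 2] <- pc[2, 1] <- 1L
  plan <- structure(list(pair_counts = pc, n_offspring = 1L),
                    class = "mate_plan")
  expect_equal(expected_progeny_homozygosity(G, plan, 4), 2)
  # identical fully homozygous parents -> L; opposite homozygotes -> 0
  a <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(0, 0), c(0, 0))
  Xh <- encode_genotypes(haplotype_panel(a))
  Gh <- compute_G(Xh)
  p12 <- matrix(0L, 3, 3); p12[1, 2] <- p12[2, 1] <- 1L
  plan12 <- structure(list(pair_counts = p12, n_offspring = 1L),
                      class = "mate_plan")
  expect_equal(expected_progeny_homozygosity(Gh, plan12, 2), 2)
  p13 <- matrix(0L, 3, 3); p13[1, 3] <- p13[3, 1] <- 1L
  plan13 <- structure(list(pair_counts = p13, n_offspring = 1L),
                      class = "mate_plan")
  expect_equal(expected_progeny_homozygosity(Gh, plan13, 2), 0)
})
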