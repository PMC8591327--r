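# Meiosis: Poisson crossovers on the map, Haldane recombination, Mendelian
# bookkeeping of offspring panels.

test_that("degenerate parents and maps give deterministic gametes", {
  mapz <- genetic_map(paste0("L", 1:3), rep(1, 3), rep(0, 3))  # zero length
  par <- rbind(c(1L, 0L, 1L), c(0L, 1L, 0L))
  set.seed(1)
  picks <- replicate(200, {
    g <- make_gamete(par, mapz)
    if (all(g == par[1, ])) 1L else if (all(g == par[2, ])) 2L else NA_integer_
  })
  expect_false(anyNA(picks))            # always a whole parental haplotype
  expect_gt(sum(picks == 1L), 50)       # fair coin between the two
  expect_gt(sum(picks == 2L), 50)
  # fully homozygous parent: gamete deterministic under any map
  m <- flat_map(5)
  hom <- rbind(c(1L, 0L, 1L, 1L, 0L), c(1L, 0L, 1L, 1L, 0L))
  set.seed(2)
  for (k in 1:20) expect_identical(make_gamete(hom, m), hom[1, ])
  expect_error(make_gamete(hom, flat_map(4)), "loci")
})

test_that("recombination at 100 cM matches the Haldane map function", {
  m2 <- genetic_map(c("A", "B"), c(1, 1), c(0, 100))
  par <- rbind(c(1L, 1L), c(0L, 0L))
  n <- 2e4
  set.seed(3)
  rec <- replicate(n, {
    g <- make_gamete(par, m2)
    g[1] != g[2]
  })
  r <- mean(rec)
  haldane <- (1 - exp(-2)) / 2          # 0.43233...
  se <- sqrt(haldane * (1 - haldane) / n)
  expect_lt(abs(r - haldane), 3 * se)
})

test_that("crossover counts per chromosome are Poisson with the map-length mean", {
  # 2 Morgans of map; infer crossover count from switch points of a
  # fully-informative parent with one locus every 0.2 cM (counts parity-
  # detectable switches, a lower bound that almost surely equals the count
  # at this marker density).
  L <- 1001
  m <- genetic_map(paste0("L", seq_len(L)), rep(1, L),
                   seq(0, 200, length.out = L))
  par <- rbind(rep(1L, L), rep(0L, L))
  set.seed(4)
  counts <- replicate(5000, sum(diff(make_gamete(par, m)) != 0))
  brk <- c(-0.5, 0.5, 1.5, 2.5, 3.5, 4.5, Inf)
  obs <- table(cut(counts, brk))
  pr <- c(dpois(0:4, 2), 1 - ppois(4, 2))
  chi <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(chi$p.value, 0.01)
})

test_that("offspring panels obey the plan, the pedigree and Mendelian origin", {
  p <- random_panel(6, 40, seed = 6)
  m <- flat_map(40)
  pc <- matrix(0L, 6, 6)
  pc[1, 2] <- pc[2, 1] <- 3L
  pc[3, 4] <- pc[4, 3] <- 2L
  plan <- structure(list(pair_counts = pc, n_offspring = 5L),
                    class = "mate_plan")
  off <- make_offspring(p, plan, m, seed = 99)
  expect_identical(n_individuals(off), 5L)
  expect_identical(off$generation, p$generation + 1L)
  ped <- attr(off, "pedigree")
  expect_identical(nrow(ped), 5L)
  cnt <- table(factor(c(ped$parent1, ped$parent2), levels = p$ids))
  expect_equal(as.numeric(cnt), c(3, 3, 2, 2, 0, 0))
  # no mutation: each offspring allele exists in the designated parent
  for (o in seq_len(5)) {
    pi <- match(ped$parent1[o], p$ids)
    pj <- match(ped$parent2[o], p$ids)
    h1 <- off$alleles[2 * o - 1, ]
    h2 <- off$alleles[2 * o, ]
    par_i <- p$alleles[c(2 * pi - 1, 2 * pi), ]
    par_j <- p$alleles[c(2 * pj - 1, 2 * pj), ]
    expect_true(all(h1 == par_i[1, ] | h1 == par_i[2, ]))
    expect_true(all(h2 == par_j[1, ] | h2 == par_j[2, ]))
  }
  # determinism
  off2 <- make_offspring(p, plan, m, seed = 99)
  expect_identical(off$alleles, off2$alleles)
})

test_that("offspring homozygosity matches (L + G_ij) / 2 in expectation", {
  p <- random_panel(4, 60, seed = 7)
  m <- flat_map(60, length_cM = 150)
  X <- encode_genotypes(p)
  G <- compute_G(X)
  for (pair in list(c(1L, 2L), c(3L, 4L))) {
    n <- 3000
    pc <- matrix(0L, 4, 4)
    pc[pair[1], pair[2]] <- pc[pair[2], pair[1]] <- n
    plan <- structure(list(pair_counts = pc, n_offspring = as.integer(n)),
                      class = "mate_plan")
    off <- make_offspring(p, plan, m, seed = 11 + pair[1])
    Xo <- encode_genotypes(off)
    hom <- colSums(Xo^2)
    expected <- (60 + G[pair[1], pair[2]]) / 2
    se <- sd(hom) / sqrt(n)
    expect_lt(abs(mean(hom) - expected), 4 * se)
  }
})

test_that("neutral reproduction does not drift allele frequencies on average", {
  p <- random_panel(20, 30, seed = 8)
  m <- flat_map(30)
  g <- rep(2L, 20)   # uniform contributions, 20 offspring
  deltas <- sapply(1:20, function(s) {
    plan <- random_mating(g, seed = 500 + s)
    off <- make_offspring(p, plan, m, seed = 600 + s)
    mean(allele_frequency(off) - allele_frequency(p))
  })
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * max(se, 1e-4))
})
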