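# Genotype coding, allele frequencies, MAF filtering, shuffling, trait model.

test_that("genotype encoding follows the -1/0/1 convention", {
  # (1,1) -> 1, (0,0) -> -1, (0,1) -> 0
  a <- rbind(c(1, 0, 0), c(1, 0, 1))
  X <- encode_genotypes(haplotype_panel(a))
  expect_equal(drop(X), c(1, -1, 0), ignore_attr = TRUE)

  # all-heterozygous individual gives a column of zeros
  ahet <- rbind(rep(0L, 5), rep(1L, 5))
  expect_true(all(encode_genotypes(haplotype_panel(ahet)) == 0))

  # micro fixture columns
  X <- encode_genotypes(micro_panel())
  expect_equal(unname(X[, "A"]), c(1, 1, 0, -1))
  expect_equal(unname(X[, "B"]), c(1, -1, 0, 0))
  expect_equal(unname(X[, "C"]), c(0, 1, 1, 1))

  expect_error(haplotype_panel(rbind(c(1, 2), c(0, 0))), "0 or 1")
})

test_that("allele frequencies are haplotype means", {
  mono <- haplotype_panel(rbind(c(1, 0), c(1, 0)))
  expect_equal(unname(allele_frequency(mono)), c(1, 0))
  het1 <- haplotype_panel(rbind(1, 0))
  expect_equal(unname(allele_frequency(het1)), 0.5)
  expect_equal(unname(allele_frequency(micro_panel())[1]), 5 / 6)
})

test_that("MAF filter keeps loci strictly above the threshold and is idempotent", {
  p <- micro_panel()
  # locus frequencies: 5/6, 4/6, 3/6, 3/6
  f <- maf_filter(p, threshold = 0.3)
  expect_equal(f$keep, c(2L, 3L, 4L))
  expect_equal(n_loci(f$panel), 3L)

  # threshold 0 keeps polymorphic, drops monomorphic
  mono <- haplotype_panel(cbind(c(1, 1, 1, 1), c(1, 0, 0, 1)))
  f0 <- maf_filter(mono, threshold = 0)
  expect_equal(f0$keep, 2L)

  # a locus with p = 0.04 is dropped at threshold 0.05 ("higher than")
  a <- matrix(0L, nrow = 50, ncol = 1)
  a[1:2] <- 1L   # p = 0.04
  expect_equal(length(maf_filter(haplotype_panel(a), 0.05)$keep), 0L)

  # idempotence
  f2 <- maf_filter(f$panel, threshold = 0.3)
  expect_identical(f2$panel$alleles, f$panel$alleles)
})

test_that("allele shuffling preserves counts exactly and breaks LD", {
  fnd <- simulate_founders(founder_spec(n_individuals = 60, n_loci = 200,
                                        n_chromosomes = 2,
                                        mosaic_switch_rate = 0.02, seed = 3))
  p <- fnd$panel
  counts0 <- colSums(p$alleles)
  r2_0 <- mean(adjacent_r2(p, fnd$map))
  worse <- 0L
  for (s in 1:20) {
    sh <- shuffle_alleles(p, seed = s)
    expect_identical(colSums(sh$alleles), counts0)
    expect_identical(dim(sh$alleles), dim(p$alleles))
    if (mean(adjacent_r2(sh, fnd$map)) < r2_0) worse <- worse + 1L
  }
  expect_gte(worse, 19L)  # LD almost surely reduced at every seed
  # determinism
  expect_identical(shuffle_alleles(p, 7)$alleles, shuffle_alleles(p, 7)$alleles)
})

test_that("TBV is the effect-weighted genotype sum and is linear", {
  X <- encode_genotypes(micro_panel())
  expect_equal(unname(true_breeding_value(X, c(1, 2, -1, 0.5))),
               c(2.5, -1, 1.5))
  expect_equal(unname(true_breeding_value(X, rep(0, 4))), rep(0, 3))
  # single locus
  X1 <- matrix(c(-1L, 0L, 1L), nrow = 1)
  expect_equal(unname(true_breeding_value(X1, 2)), c(-2, 0, 2))
  # linearity
  set.seed(1)
  a1 <- rnorm(4); a2 <- rnorm(4)
  expect_equal(true_breeding_value(X, a1 + a2),
               true_breeding_value(X, a1) + true_breeding_value(X, a2))
  expect_error(true_breeding_value(X, 1:3), "does not match")
})

test_that("number of homozygous loci equals the squared-code sum", {
  p <- random_panel(8, 30, seed = 5)
  X <- encode_genotypes(p)
  hom_count <- rowSums(p$alleles[seq(1, 16, 2), ] == p$alleles[seq(2, 16, 2), ])
  expect_equal(unname(colSums(X^2)), unname(hom_count))
})

test_that("phenotype noise follows the (1 - h2) * sigma_g2 normal model", {
  tbv <- c(1, 2, 3)
  expect_equal(simulate_phenotypes(tbv, h2 = 1, sigma_g2 = 4, seed = 1), tbv)
  expect_equal(simulate_phenotypes(tbv, h2 = 0.3, sigma_g2 = 0, seed = 1), tbv)
  expect_error(simulate_phenotypes(tbv, h2 = 0, sigma_g2 = 1, seed = 1), "h2")

  big <- rep(0, 1e5)
  y <- simulate_phenotypes(big, h2 = 0.5, sigma_g2 = 4, seed = 42)
  v <- var(y)                       # expect 2, SE of variance ~ sqrt(2/n)*2
  se <- 2 * sqrt(2 / 1e5)
  expect_lt(abs(v - 2), 3 * se)
  # determinism
  expect_identical(y, simulate_phenotypes(big, 0.5, 4, seed = 42))
})
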