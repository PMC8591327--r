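# Synthetic founder generator: reproducibility, MAF guarantee, LD and
# structure control, effect drawing.

test_that("founder simulation is reproducible and respects the MAF floor", {
  spec <- founder_spec(n_individuals = 30, n_loci = 120, n_chromosomes = 3,
                       maf_min = 0.05, seed = 41)
  f1 <- simulate_founders(spec)
  f2 <- simulate_founders(spec)
  expect_identical(f1$panel$alleles, f2$panel$alleles)
  expect_identical(f1$map, f2$map)
  p <- allele_frequency(f1$panel)
  expect_true(all(pmin(p, 1 - p) > 0.05))
  expect_identical(nrow(f1$map), n_loci(f1$panel))
})

test_that("a single ancestral haplotype with no switching clones itself", {
  spec <- founder_spec(n_individuals = 10, n_loci = 60, n_chromosomes = 1,
                       n_ancestral_haplotypes = 1, mosaic_switch_rate = 0,
                       n_subpopulations = 1, maf_min = 0, seed = 42)
  f <- simulate_founders(spec)
  a <- f$panel$alleles
  expect_true(all(apply(a, 2, function(col) length(unique(col)) == 1L)))
})

test_that("lower mosaic switch rates give higher adjacent-locus LD", {
  med_r2 <- function(rate) {
    median(sapply(1:10, function(s) {
      f <- simulate_founders(founder_spec(
        n_individuals = 40, n_loci = 150, n_chromosomes = 2,
        mosaic_switch_rate = rate, n_subpopulations = 1, seed = 500 + s))
      mean(adjacent_r2(f$panel, f$map))
    }))
  }
  expect_gt(med_r2(0.01), med_r2(1))
})

test_that("LD decays with map distance under a positive switch rate", {
  f <- simulate_founders(founder_spec(n_individuals = 60, n_loci = 200,
                                      n_chromosomes = 1,
                                      mosaic_switch_rate = 0.05, seed = 43))
  a <- f$panel$alleles
  pos <- f$map$pos_cM
  set.seed(44)
  pairs <- cbind(sample(ncol(a), 3000, TRUE), sample(ncol(a), 3000, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  d <- abs(pos[pairs[, 1]] - pos[pairs[, 2]])
  r2 <- sapply(seq_len(nrow(pairs)), function(k) {
    x <- a[, pairs[k, 1]]; y <- a[, pairs[k, 2]]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)^2
  })
  bins <- cut(d, c(0, 5, 20, 50, 100), include.lowest = TRUE)
  med <- tapply(r2, bins, median, na.rm = TRUE)
  expect_true(all(diff(med) <= 0))
})

test_that("subpopulation differentiation is positive and grows with pool drift", {
  fst_at <- function(n_anc) {
    median(sapply(1:10, function(s) {
      f <- simulate_founders(founder_spec(
        n_individuals = 40, n_loci = 150, n_chromosomes = 2,
        n_ancestral_haplotypes = n_anc, n_subpopulations = 2,
        seed = 700 + s))
      hudson_fst(f$panel, f$subpopulation)
    }))
  }
  # fewer ancestral haplotypes = more drift from the common frequency
  # distribution = stronger differentiation
  fst <- c(fst_at(2), fst_at(8), fst_at(32))
  expect_true(all(fst > 0))
  expect_true(all(diff(fst) < 0))
})

test_that("effect drawing honors sparsity, scale and exact rescaling", {
  expect_identical(draw_effects(50, effect_sd = 0, seed = 1), rep(0, 50))
  a <- draw_effects(1000, sparsity = 0.1, seed = 2)
  expect_identical(sum(a != 0), 100L)
  pan <- random_panel(25, 80, seed = 3)
  eff <- draw_effects(80, seed = 4, panel = pan, target_tbv_sd = 25.9)
  tbv <- true_breeding_value(encode_genotypes(pan), eff)
  expect_equal(sd(tbv), 25.9, tolerance = 1e-9)
})
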