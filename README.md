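# hetocs

Genomic optimal contribution selection (GOCS) with explicit control of
heterozygote × homozygote relationships, inside a complete multigeneration
breeding-program simulator.

## The problem

Optimal contribution selection chooses each candidate's proportional
contribution *c* to the next generation so as to maximize expected genetic
gain *c*ᵀ*Y* while restraining expected coancestry *c*ᵀ*Gc*.  It is the
standard instrument for balancing short-term response against long-term
diversity in animal, crop and forest-tree breeding — particularly for
long-lived perennials, where a premature selection plateau is expensive to
undo.

Most formulations of the realized genomic relationship matrix score pairs of
individuals only by shared homozygosity, so classical GOCS is blind to the
Mendelian sampling potential carried by heterozygous loci.  `hetocs`
implements a formulation developed specifically for contribution
optimization: with genotypes coded −1/0/1 (homozygotes ±1, heterozygote 0)
and **G** = **X**ᵀ**X** left uncentered and unscaled,

- diagonal entries of **G** count an individual's homozygous loci,
- off-diagonals add +1 per shared homozygous state and −1 per opposite
  homozygous state, while any pair involving a heterozygote contributes 0.

A companion matrix **Q** counts, for every pair, the loci where exactly one
individual is heterozygous (He × Ho).  The transformed matrix

> **G\*** = **G** + β **Q**,  β ∈ [−1, 1]

assigns every He × Ho locus state the value β.  Negative β *favors*
candidates rich in He × Ho relationships — i.e., preserves segregation
potential — and satisfies the contribution identity
*c*ᵀ**G\****c* = *c*ᵀ**G***c* + β·*c*ᵀ**Q***c*, with
*c*ᵀ**Q***c* = 2·HeᵀHo for the contribution-weighted heterozygote and
homozygote frequency vectors.

Around this core the package provides:

- **`solve_ocs()`** — the scalarized quadratic program
  min α·*c*ᵀ**G\****c* − (1−α)·*c*ᵀ*Y* subject to Σ*c* = 1,
  0 ≤ *c* ≤ 0.5 (optionally *d*ᵀ*c* = 0.5 for dioecy), solved to KKT
  tolerance after a spectral projection of **G\*** onto positive definite
  matrices; **`pareto_sweep()`** traces the gain/coancestry Pareto front
  over α.
- **`solve_mating()`** — conversion of contributions into an integer mate
  plan by a degree-constrained linear program minimizing expected progeny
  homozygosity, E[#homozygous loci] = (L + G\*ᵢⱼ)/2 per mating, with
  `random_mating()` as control.
- **`make_offspring()`** — meiosis with Poisson (Haldane) crossovers along
  a genetic map, no mutation.
- **`fit_ridge()` / `predict_gebv()`** — RR-BLUP genomic evaluation on a
  cumulative reference population (always on **G**-coded genotypes, never
  **G\***).
- **`simulate_founders()` / `draw_effects()`** — synthetic founder panels
  with controllable linkage disequilibrium, population structure and MAF
  filtering, plus trait architectures calibrated to a target TBV spread.
- **`run_program()`** — the full generation loop (phenotype → evaluate →
  optimize contributions → allocate mates → meiosis) over replicates, with
  per-generation gain, true coancestry (always computed with the unmodified
  **G**), breeding potential and evaluation accuracy;
  **`anova_type1()`** and **`pareto_report()`** summarize scenario grids.

## Worked example

```r
library(hetocs)

# Synthetic founders: 100 individuals, ~500 SNPs on 5 chromosomes, LD-rich
fnd <- simulate_founders(founder_spec(seed = 11))
effects <- draw_effects(n_loci(fnd$panel), seed = 12,
                        panel = fnd$panel, target_tbv_sd = 25.9)

# One contribution optimization on the founders, favoring He x Ho (beta < 0)
X0 <- encode_genotypes(fnd$panel)
gebv <- true_breeding_value(X0, effects)
sol <- solve_ocs(relationship_set(X0, beta = -0.5)$Gstar_pd, gebv, alpha = 0.5)
sol
#> OCS solution (alpha = 0.5)
#>   c'Y  = 32.98339   c'Mc = 10.14359   KKT residual = 6.433492e-10
#>   36 of 100 candidates contribute

# A 10-generation breeding program, 5 replicates
cfg <- program_config(alpha = 0.5, beta = -0.5, n_generations = 10,
                      n_replicates = 5, root_seed = 1)
sim <- run_program(cfg, fnd$panel, fnd$map, effects)
sim
#> Breeding-program simulation: alpha = 0.5, beta = -0.5, mating = lp
#>   5 replicate(s), 10 generations; founder mean TBV = -3.82
#>   final mean TBV = 200.85, final true coancestry = 0.25

tail(summary(sim)[, c("generation", "gain", "true_coancestry",
                      "breeding_potential")], 3)
#>    generation     gain true_coancestry breeding_potential
#> 9           8 179.7315       0.2432199           166.9281
#> 10          9 190.5210       0.2447369           177.0087
#> 11         10 204.6677       0.2501231           190.6630
```

`c'Y` is the expected gain of the optimized parental pool and `c'Mc` its
expected coancestry under **G\***; in the trajectory, `gain` is mean TBV
relative to the founders, `true_coancestry` the per-locus-normalized
*c*ᵀ**G***c* with uniform weights, and `breeding_potential` the TBV mass
attributable to loci that still segregate.

A thin command-line front end over the same functions lives at
`inst/cli/hetocs.R` (`simulate-founders`, `run`, `anova` subcommands).

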