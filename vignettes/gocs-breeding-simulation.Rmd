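---
title: "Optimal contributions with heterozygote-homozygote control: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal contributions with heterozygote-homozygote control: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetocs)
```

## The selection model

Let $X$ be the $L \times N$ genotype matrix of the candidates, coded $-1$
and $1$ for the two homozygotes and $0$ for the heterozygote.  The package
works with the *unscaled* realized relationship matrix $G = X^\top X$: no
allele-frequency centering, no division by expected heterozygosity.  This
choice makes $G$ interpretable locus-by-locus — $G_{ii}$ is individual
$i$'s homozygous-locus count, and each locus contributes $+1$ (same
homozygote), $-1$ (opposite homozygotes) or $0$ (any heterozygote) to
$G_{ij}$ — at the cost of not being the matrix one would use for
prediction accuracy (prediction uses a ridge model, below).

The zero for heterozygote-involving pairs conflates two very different
situations: heterozygote × heterozygote (maximal joint segregation) and
heterozygote × homozygote (one-sided segregation).  The matrix $Q$, with
$Q_{ij}$ the count of loci where exactly one of $i, j$ is heterozygous and
$Q_{ii} = 0$, separates them:

$$G^\* = G + \beta\, Q, \qquad \beta \in [-1, 1],$$

which sets every per-pair, per-locus He×Ho value to exactly $\beta$.
Negative $\beta$ *lowers* the effective relationship of He×Ho-rich pairs
and therefore favors, in contribution optimization, candidates whose
heterozygosity complements the rest of the population.

With contributions $c$ ($c \ge 0$, $\sum c = 1$), writing $\mathrm{He}_l =
\sum_i c_i \mathbf{1}\{X_{li} = 0\}$ and $\mathrm{Ho} = 1 - \mathrm{He}$:

$$c^\top G^\* c = c^\top G c + \beta\, c^\top Q c,
  \qquad c^\top Q c = 2\, \mathrm{He}^\top \mathrm{Ho}.$$

**Convention.**  With $Q$ defined as the raw He×Ho locus count (the
definition that makes each matrix entry a count, consistent with $G$), the
quadratic form carries a factor 2 relative to $\mathrm{He}^\top\mathrm{Ho}$
— each unordered pair appears twice in the symmetric form.  An alternative
convention halves $Q$ to absorb the factor.  We keep the raw count: the
factor is absorbable into the free parameter $\beta$ and changes no
ordering of scenarios.  The identity above is asserted to $10^{-10}$ in
the test suite against an explicit pair-and-locus double loop.

`coancestry()` reports $c^\top M c / L$ by default, so values land on a
$[0,1]$-like per-locus scale (the raw form is available with
`normalized = FALSE`).  The *true* coancestry of a scenario is always
$c^\top G c / L$ with the unmodified $G$, whatever $\beta$ drove selection
— this is what makes runs at different $\beta$ comparable.

## The contribution program

Contributions solve the scalarized trade-off

$$\min_c\; \alpha\, c^\top G^\* c - (1 - \alpha)\, c^\top Y,
  \qquad 0 \le c \le 0.5,\; \textstyle\sum c = 1,$$

where $Y$ are the candidates' *estimated* breeding values — the optimizer
never sees true breeding values — and $\alpha \in [0,1]$ weights
coancestry against gain.  The cap $0.5$ forbids selfing; for a dioecious
population the single extra constraint $d^\top c = 0.5$ (with $d$ a 0/1
sex indicator) is supported.  Sweeping $\alpha$ traces the Pareto front of
$(c^\top G^\* c,\, c^\top Y)$: both coordinates are nonincreasing in
$\alpha$ and the solutions are mutually non-dominated, which the tests
assert on random instances.

Strict convexity — hence uniqueness — requires $G^\*$ positive definite,
which addition of $\beta Q$ can break.  `project_pd()` performs the
spectral projection: eigenvalues below a floor are raised to the floor,
which is the closest PD matrix in spectral norm at distance
$\max(0, \text{floor} - \lambda_{\min})$.  The default floor is
$10^{-8} \max(\lambda_{\max}, 1)$ — large enough to keep the QP strictly
convex in double precision, small enough to be negligible against entries
of order $L$.  The projected matrix enters only the QP; mate allocation
(below) uses the raw $G^\*$, whose exact entries are the quantity being
minimized.

The QP itself is solved by the Goldfarb–Idnani dual active-set method
(`quadprog`), which is deterministic and, on the problem sizes used here
($N$ up to a few hundred), reaches relative KKT residuals of $10^{-10}$ or
better; `solve_ocs()` recomputes and reports the residual independently of
the solver.  The degenerate case $\alpha = 0$ is a linear program with
possibly non-unique optima; it is regularized with an effective
$\alpha = 10^{-9}$ (the objective is rescaled by $1/\alpha$ so
conditioning does not degrade), which restores uniqueness and keeps the
result deterministic.

## Mate allocation

Fixing $c$ fixes the expected gain and coancestry of the parental pool;
what mating still controls is progeny homozygosity.  Under Mendelian
segregation an offspring of $i$ and $j$ has expected homozygous-locus
count $(L + G_{ij})/2$ — parents' relatedness up to a constant — so
minimizing the plan total of $G^\*_{ij}$ minimizes expected mean progeny
homozygosity under the same He×Ho valuation used for selection.

Contributions are first discretized by largest-remainder rounding of
$2 N_{\text{off}} c$ into per-parent gamete counts (ties broken by larger
contribution, then lower index; the $c \le 0.5$ cap guarantees no parent
exceeds half the gametes).  The plan then solves the degree-constrained
linear program over pair counts $n_{ij} \ge 0$, $\sum_{j \ne i} n_{ij} =
g_i$.  Basic solutions of this b-matching relaxation are half-integral;
fractional edges form even-degree cycles, which are repaired by the
cheaper of the two alternating $\pm\tfrac12$ assignments (even cycles) or,
for pairs of odd cycles, by the cheapest anchor-pair closure through one
connecting edge.  On all instances small enough to enumerate exhaustively
($N \le 5$, up to 4 offspring) the repaired plan attains the true integer
optimum in the test suite.  No LP backend being available, the LP is
solved by a dense two-phase revised simplex written for this problem
shape (vectorized pricing, explicit basis inverse, Dantzig pricing with a
Bland fallback, and a guard that pivots zero-level artificials out rather
than letting them regrow).

`random_mating()` realizes the same gamete counts by proportional random
pairing (with repair of dead-end states), providing the control against
which the value of optimized mating is measured.  Each unit of $n_{ij}$
produces exactly one offspring from one independent meiosis per parent —
repeated matings of a pair get independent meioses.

## Meiosis

Gametes are simulated under the Haldane (no-interference) model: per
chromosome, the crossover count is Poisson with mean equal to the map
length in Morgans, crossover positions are uniform in genetic distance,
and the starting strand is a fair coin.  No mutation is introduced.  This
is the minimal standard assumption when only a genetic map is available,
and it makes the closed-form recombination fraction
$r = (1 - e^{-2d})/2$ available for calibration: the suite checks
$r \approx 0.432$ at 100 cM against $10^5$ gametes, and the crossover
count distribution against a $\chi^2$ goodness-of-fit test.  A zero-length
chromosome degenerates to transmitting one whole parental haplotype.

## Genomic evaluation

Breeding values are estimated by ridge regression (RR-BLUP) on the
$-1/0/1$ code — explicitly on $G$-coded genotypes, never on $G^\*$, which
degrades predictive accuracy.  With heritability treated as known, the
penalty is the classical variance-ratio plug-in
$\lambda = \frac{1 - h^2}{h^2} \sum_l 2 p_l (1 - p_l)$, recomputed each
generation from the reference allele frequencies (configurable;
$h^2 \to 1$ returns a small positive floor).  The solver uses whichever of
the primal $L \times L$ or dual $n \times n$ normal equations is smaller;
the two agree to $10^{-8}$ on random instances.  The reference population
is cumulative — every generation's phenotyped individuals are appended and
the model refit from scratch, so evaluation accuracy grows over time and
no warm-start state can leak between replicates.

Phenotypes are TBV plus independent normal noise of variance
$(1 - h^2)\,\sigma_g^2$.  The genetic variance $\sigma_g^2$ is, by
default, the *current generation's* TBV variance, recomputed each cycle:
this keeps the realized heritability near its nominal value as selection
erodes variance.  The founder-fixed alternative (noise calibrated once on
the founders, so later generations are effectively evaluated at lower
realized $h^2$) is available as `sigma_g2_mode = "founder_fixed"`.

## Synthetic founders

`simulate_founders()` emulates the statistical features of a dense-SNP
perennial breeding population that this method is sensitive to — not its
genealogy.  Each founder haplotype is a mosaic over a small pool of
ancestral haplotypes (per-locus frequencies uniform on $(0.1, 0.9)$,
drawn independently per subpopulation), with exponential switch distances
along the map.  The knobs map directly onto testable properties:

| parameter | default | controls |
|---|---|---|
| `n_individuals` / `n_loci` | 100 / 500 | population and marker scale |
| `n_chromosomes` × `chromosome_length_cM` | 5 × 100 cM | map length (5 Morgans) |
| `mosaic_switch_rate` | 0.05 /cM | LD: expected ancestral segment 20 cM |
| `n_ancestral_haplotypes` | 10 per subpopulation | within-pool diversity; fewer = more drift |
| `n_subpopulations`, `admixture_weights` | 2, none | structure (positive Hudson $F_{ST}$) |
| `maf_min` | 0.05 | MAF floor after filtering (0 disables) |

The defaults are the desk-scale study conditions used throughout the
package's own tests: small enough that a 10-generation, 10-replicate
scenario runs in seconds, while exhibiting the properties that matter
(LD decaying with map distance, structure, MAF > 0.05, founder TBV spread
calibrated to 25.9 by `draw_effects(target_tbv_sd = )`, heritability
0.5134 as a trunk-circumference-like default).  A mosaic generator was
chosen over a coalescent simulator because it gives *direct* control of
LD and structure with trivial runtime; the price is no realistic allele
frequency spectrum, no demographic interpretation, and LD that decays
roughly exponentially rather than with a population-genetic shape.
Passing tests on these panels therefore demonstrate correctness of the
machinery and direction of the qualitative effects, not quantitative
transfer to any real population.

## The generation loop

`run_generation()` executes, in order: phenotype the candidates → append
to the reference and refit the ridge model → build $G$, $Q$, $G^\*$ and
project → solve the contribution QP on GEBVs → discretize to gametes →
allocate mates (LP on $G^\*$, or random) → meiosis.  Population size is
constant; generations do not overlap; no external germplasm enters.  Per
generation the trajectory records mean and sd of TBV, mean GEBV, the
contribution-weighted coancestries under $G^\*$ and $G$, the uniform
population coancestry under $G$, the breeding potential (TBV mass of
still-segregating loci, computed with *true* effects so the metric is
noise-free; estimated effects are a caller-side option), evaluation
accuracy, and the fixed-locus count.  The final generation contributes a
population-metrics row with contribution fields `NA`.

Scenario grids are compared with a sequential (type I) ANOVA of an
outcome on $\alpha + \beta + \alpha^2 + m$ (model 1) or $\beta + m$ at
fixed $\alpha$ (model 2), with $\alpha, \beta$ as numeric covariates and
$m$ the 0/1 mate-allocation indicator.  The quadratic $\alpha^2$ term
captures the boundary behaviour of the trade-off (flat at low $\alpha$,
steep near 1).  Fits use ordinary least squares; the sequential sums of
squares are verified against an explicit successive-projection oracle.

## Determinism

Every stochastic operation takes an explicit integer seed.  A program run
holds one root seed and derives one stream per (replicate, generation,
operation) via `derive_seed()`, so an entire trajectory is byte-for-byte
reproducible and any single generation can be replayed in isolation.  All
solvers are deterministic (no random initialization); remaining ties in
the gamete rounding are broken by contribution then index.

```{r determinism}
fnd <- simulate_founders(founder_spec(n_individuals = 30, n_loci = 100,
                                      n_chromosomes = 2, seed = 5))
eff <- draw_effects(n_loci(fnd$panel), seed = 6, panel = fnd$panel,
                    target_tbv_sd = 25.9)
cfg <- program_config(alpha = 0.5, beta = -0.5, n_generations = 2,
                      n_replicates = 1, root_seed = 42)
identical(run_program(cfg, fnd$panel, fnd$map, eff)$trajectory,
          run_program(cfg, fnd$panel, fnd$map, eff)$trajectory)
```

## Known limitations

- Additive gene action only: no dominance in the trait, the evaluation or
  the relationship matrices, although the He×Ho mechanism is precisely a
  lever one would expect to interact with dominance.
- Monoecious by default; dioecy is supported only through the
  $d^\top c = 0.5$ constraint, not through sex-specific maps or roles.
- No mutation, no crossover interference, non-overlapping generations,
  constant population size, constant $\alpha$ and $\beta$ across
  generations (time-varying schedules are out of scope).
- The ridge penalty assumes a known heritability rather than estimating
  variance components; the pedigree-based relationship matrix and
  centered/scaled $G$ formulations are intentionally not provided.
- Breeding-value inputs to the optimizer are GEBVs from the built-in
  evaluation; plugging in external evaluations is possible via
  `solve_ocs()` directly but not through the pipeline configuration.
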