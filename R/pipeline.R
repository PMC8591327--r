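# Multigeneration breeding-program simulation.
#
# Per generation: phenotype the candidates, refit the ridge evaluation on
# the cumulative reference, build G / Q / G* on the candidates, solve the
# contribution QP on the GEBVs, convert contributions to gametes, allocate
# mates (cost-minimizing LP on G*, or random control), and produce the
# next generation by simulated meiosis.  Population size is constant and
# generations do not overlap.

#' Configure a breeding-program scenario
#'
#' @param alpha Trade-off weight of coancestry versus gain in `[0, 1]`.
#' @param beta He x Ho value in `[-1, 1]` used to build `G*` for both the
#'   contribution QP and mate allocation (never for genomic evaluation).
#' @param mate_mode `"lp"` (minimize expected progeny homozygosity) or
#'   `"random"`.
#' @param n_generations Number of simulated generations (default 20).
#' @param n_replicates Independent replicates (default 1).
#' @param h2 Trait heritability used for phenotype noise and the ridge
#'   penalty (default 0.5134, a trunk-circumference-like trait).
#' @param population_size Constant population size; `NULL` uses the
#'   founder count.
#' @param upper_bound Per-individual contribution cap (default 0.5).
#' @param eig_floor Optional floor for the PD projection of `G*`.
#' @param lambda Ridge penalty, or `"auto"` for the variance-ratio
#'   plug-in recomputed on the reference each generation.
#' @param sigma_g2_mode `"per_generation"` (default: phenotype noise scaled
#'   by the current generation's TBV variance, keeping realized
#'   heritability near nominal as variance erodes) or `"founder_fixed"`.
#' @param root_seed Integer root seed; every replicate, generation and
#'   stochastic operation derives its own stream from it.
#' @return An object of class `program_config`.
#' @export
program_config <- function(alpha, beta = 0, mate_mode = c("lp", "random"),
                           n_generations = 20L, n_replicates = 1L,
                           h2 = 0.5134, population_size = NULL,
                           upper_bound = 0.5, eig_floor = NULL,
                           lambda = "auto",
                           sigma_g2_mode = c("per_generation", "founder_fixed"),
                           root_seed = 1L) {
  mate_mode <- match.arg(mate_mode)
  sigma_g2_mode <- match.arg(sigma_g2_mode)
  stopifnot(alpha >= 0, alpha <= 1, beta >= -1, beta <= 1,
            n_generations >= 1, n_replicates >= 1, h2 > 0, h2 <= 1)
  structure(list(alpha = alpha, beta = beta, mate_mode = mate_mode,
                 n_generations = as.integer(n_generations),
                 n_replicates = as.integer(n_replicates),
                 h2 = h2, population_size = population_size,
                 upper_bound = upper_bound, eig_floor = eig_floor,
                 lambda = lambda, sigma_g2_mode = sigma_g2_mode,
                 root_seed = as.integer(root_seed)),
            class = "program_config")
}

#' @export
print.program_config <- function(x, ...) {
  cat("Breeding program: alpha = ", x$alpha, ", beta = ", x$beta,
      ", mating = ", x$mate_mode, ", ", x$n_generations, " generations x ",
      x$n_replicates, " replicates\n", sep = "")
  invisible(x)
}

#' Breeding potential: GEBV mass of still-segregating loci
#'
#' A locus is fixed when one allele has frequency 0 or 1 in the panel;
#' fixed loci can no longer respond to selection.  The breeding potential
#' of individual `i` is `sum_{l not fixed} a_l X[l, i]`, and the
#' population value is the mean over individuals.  True allelic effects
#' are used so the metric is noise-free; pass estimated effects to score
#' what the evaluation believes instead.
#'
#' @param X `L x N` genotype matrix (-1/0/1).
#' @param effects Numeric effect vector of length `L`.
#' @return List with `population` (scalar), `per_individual` (length-`N`
#'   vector) and `n_fixed` (count of fixed loci).
#' @export
breeding_potential <- function(X, effects) {
  if (length(effects) != nrow(X)) stop("effects/loci mismatch")
  p <- (rowMeans(X) + 1) / 2           # "1" allele frequency per locus
  fixed <- p <= 0 | p >= 1
  nf <- !fixed
  per <- if (any(nf)) {
    drop(crossprod(X[nf, , drop = FALSE], effects[nf]))
  } else {
    rep(0, ncol(X))
  }
  list(population = mean(per), per_individual = per,
       n_fixed = sum(fixed))
}

# Variance-ratio ridge penalty from a reference genotype matrix.
lambda_from_X <- function(X, h2) {
  p <- (rowMeans(X) + 1) / 2
  max(((1 - h2) / h2) * sum(2 * p * (1 - p)), 1e-6)
}

#' Advance a breeding program by one generation
#'
#' Executes, in order: phenotyping of the current candidates, appending
#' them to the cumulative reference and refitting the ridge evaluation,
#' construction and PD projection of `G*`, the contribution QP on the
#' GEBVs, gamete discretization, mate allocation, and meiosis.  All
#' stochastic steps derive their streams from `seed`.
#'
#' @param state List with elements `panel` (a `haplotype_panel`), `map`,
#'   `trait` (a `trait_model`), `reference` (list `X`, `y`; may be empty)
#'   and `founder_sigma_g2`.
#' @param config A `program_config`.
#' @param seed Integer seed for this generation.
#' @return List with `state` (the advanced state) and `record` (one-row
#'   `data.frame` of the parental generation's metrics).
#' @export
run_generation <- function(state, config, seed) {
  panel <- state$panel
  map <- state$map
  trait <- state$trait
  N <- n_individuals(panel)
  L <- n_loci(panel)
  pop_size <- if (is.null(config$population_size)) N else config$population_size

  X <- encode_genotypes(panel)
  tbv <- true_breeding_value(X, trait)

  # (1) Phenotypes of the current candidates.
  sigma_g2 <- if (config$sigma_g2_mode == "per_generation") {
    stats::var(tbv)
  } else {
    state$founder_sigma_g2
  }
  y_new <- simulate_phenotypes(tbv, trait$h2, sigma_g2,
                               seed = derive_seed(seed, "pheno"))

  # (2) Cumulative reference and ridge GEBVs.
  X_ref <- if (is.null(state$reference$X)) X else cbind(state$reference$X, X)
  y_ref <- c(state$reference$y, y_new)
  lambda <- if (identical(config$lambda, "auto")) {
    lambda_from_X(X_ref, trait$h2)
  } else {
    config$lambda
  }
  model <- fit_ridge(X_ref, y_ref, lambda)
  gebv <- predict_gebv(model, X)

  # (3) Relationship matrices on the candidates.
  rs <- relationship_set(X, beta = config$beta, eig_floor = config$eig_floor)

  # (4) Optimal contributions on the GEBVs (never on TBVs).
  sol <- solve_ocs(rs$Gstar_pd, gebv, config$alpha,
                   upper_bound = config$upper_bound)

  # (5) Gametes and mate plan; the LP cost is the raw (unprojected) G*.
  ga <- contributions_to_gametes(sol$c, pop_size)
  plan <- if (config$mate_mode == "lp") {
    solve_mating(ga, rs$Gstar, ids = panel$ids)
  } else {
    random_mating(ga, seed = derive_seed(seed, "mate"), ids = panel$ids)
  }

  # (6) Next generation by meiosis.
  offspring <- make_offspring(panel, plan, map,
                              seed = derive_seed(seed, "meiosis"))

  # (7) Metrics of the parental generation.  True coancestry always uses
  # the unmodified G, whatever beta drove selection and mating.
  bp <- breeding_potential(X, trait$effects)
  record <- data.frame(
    generation = panel$generation,
    mean_TBV = mean(tbv),
    sd_TBV = stats::sd(tbv),
    mean_GEBV = mean(gebv),
    contribution_coancestry_Gstar = coancestry(sol$c, rs$Gstar, L),
    contribution_true_coancestry_G = coancestry(sol$c, rs$G, L),
    population_true_coancestry = coancestry(rep(1 / N, N), rs$G, L),
    breeding_potential = bp$population,
    evaluation_accuracy = suppressWarnings(stats::cor(gebv, tbv)),
    n_fixed_loci = bp$n_fixed)

  state$panel <- offspring
  state$reference <- list(X = X_ref, y = y_ref)
  list(state = state, record = record, solution = sol, plan = plan)
}

# Population-only metrics of a panel (used for the final generation).
population_record <- function(panel, trait) {
  X <- encode_genotypes(panel)
  tbv <- true_breeding_value(X, trait)
  N <- n_individuals(panel)
  L <- n_loci(panel)
  G <- compute_G(X)
  bp <- breeding_potential(X, trait$effects)
  data.frame(
    generation = panel$generation,
    mean_TBV = mean(tbv),
    sd_TBV = stats::sd(tbv),
    mean_GEBV = NA_real_,
    contribution_coancestry_Gstar = NA_real_,
    contribution_true_coancestry_G = NA_real_,
    population_true_coancestry = coancestry(rep(1 / N, N), G, L),
    breeding_potential = bp$population,
    evaluation_accuracy = NA_real_,
    n_fixed_loci = bp$n_fixed)
}

#' Run a multigeneration breeding program
#'
#' Simulates `n_replicates` independent replicates of `n_generations`
#' generations under one `program_config`, starting from a common founder
#' panel.  Rows are ordered by (replicate, generation) regardless of any
#' execution details; one trailing row per replicate carries the
#' population metrics of the final generation (its contribution metrics
#' are `NA` because no further selection is applied).
#'
#' @param config A `program_config`.
#' @param founders Founder `haplotype_panel` (generation 0).
#' @param map A `genetic_map` aligned with the founders.
#' @param effects Numeric vector of true allelic effects, or a
#'   `trait_model` (whose `h2` is overridden by `config$h2`).
#' @return An object of class `breeding_sim`: list with `trajectory`
#'   (data.frame of per-generation records with a `replicate` column),
#'   `config`, `founder_mean_TBV`, `founder_sd_TBV` and `failures`
#'   (per-replicate error messages, if any).
#' @export
run_program <- function(config, founders, map, effects) {
  stopifnot(inherits(config, "program_config"),
            inherits(founders, "haplotype_panel"))
  check_map_panel(map, founders)
  a <- if (inherits(effects, "trait_model")) effects$effects else effects
  trait <- trait_model(a, config$h2)
  X0 <- encode_genotypes(founders)
  tbv0 <- true_breeding_value(X0, trait)

  rows <- list()
  failures <- character(0)
  for (rep_id in seq_len(config$n_replicates)) {
    res <- tryCatch({
      state <- list(panel = founders, map = map, trait = trait,
                    reference = list(X = NULL, y = NULL),
                    founder_sigma_g2 = stats::var(tbv0))
      rec <- vector("list", config$n_generations + 1L)
      for (t in seq_len(config$n_generations)) {
        g <- run_generation(state, config,
                            seed = derive_seed(config$root_seed,
                                               "rep", rep_id, "gen", t))
        state <- g$state
        rec[[t]] <- g$record
      }
      rec[[config$n_generations + 1L]] <- population_record(state$panel, trait)
      do.call(rbind, rec)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("replicate %d: %s", rep_id, conditionMessage(res)))
    } else {
      res$replicate <- rep_id
      rows[[length(rows) + 1L]] <- res
    }
  }
  traj <- if (length(rows)) do.call(rbind, rows) else
    stop("all replicates failed:\n", paste(failures, collapse = "\n"))
  traj <- traj[, c("replicate", setdiff(names(traj), "replicate"))]
  rownames(traj) <- NULL
  structure(list(trajectory = traj, config = config,
                 founder_mean_TBV = mean(tbv0),
                 founder_sd_TBV = stats::sd(tbv0),
                 failures = failures),
            class = "breeding_sim")
}

#' @export
print.breeding_sim <- function(x, ...) {
  cfg <- x$config
  cat("Breeding-program simulation: alpha = ", cfg$alpha, ", beta = ",
      cfg$beta, ", mating = ", cfg$mate_mode, "\n", sep = "")
  nrep <- length(unique(x$trajectory$replicate))
  gmax <- max(x$trajectory$generation)
  cat("  ", nrep, " replicate(s), ", gmax, " generations; founder mean TBV = ",
      round(x$founder_mean_TBV, 2), "\n", sep = "")
  fin <- x$trajectory[x$trajectory$generation == gmax, ]
  cat("  final mean TBV = ", round(mean(fin$mean_TBV), 2),
      ", final true coancestry = ",
      round(mean(fin$population_true_coancestry), 3), "\n", sep = "")
  if (length(x$failures)) cat("  failures:", length(x$failures), "\n")
  invisible(x)
}

#' Summarize a simulated trajectory
#'
#' Mean and standard deviation over replicates, per generation, of the
#' main trajectory metrics.
#'
#' @param object A `breeding_sim`.
#' @param ... Unused.
#' @return A data.frame with one row per generation.
#' @export
summary.breeding_sim <- function(object, ...) {
  tr <- object$trajectory
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  gens <- sort(unique(tr$generation))
  out <- do.call(rbind, lapply(gens, function(g) {
    s <- tr[tr$generation == g, ]
    data.frame(generation = g,
               mean_TBV = mean(s$mean_TBV),
               sd_mean_TBV = stats::sd(s$mean_TBV),
               gain = mean(s$mean_TBV) - object$founder_mean_TBV,
               true_coancestry = mean(s$population_true_coancestry),
               sd_true_coancestry = stats::sd(s$population_true_coancestry),
               breeding_potential = mean(s$breeding_potential),
               n_fixed_loci = mean(s$n_fixed_loci))
  }))
  rownames(out) <- NULL
  out
}

#' @export
plot.breeding_sim <- function(x, ...) {
  s <- summary(x)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(s$generation, s$mean_TBV, type = "b", pch = 19,
                 xlab = "generation", ylab = "mean TBV", ...)
  graphics::plot(s$generation, s$true_coancestry, type = "b", pch = 19,
                 xlab = "generation", ylab = "true coancestry", ...)
  invisible(x)
}
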