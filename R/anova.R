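# Sequential (type I) analysis of variance of simulation outcomes.

#' Type I ANOVA of trajectory outcomes on the scenario factors
#'
#' Fits, by ordinary least squares, either
#' model 1: `Y ~ alpha + beta + alpha^2 + m` or
#' model 2: `Y ~ beta + m`,
#' with `alpha` and `beta` as numeric covariates and `m` the 0/1 mate
#' allocation indicator, and reports the sequential (type I) decomposition
#' in the stated term order: per term the coefficient estimate, sequential
#' sum of squares, percentage of total variance, F statistic and p-value,
#' plus the adjusted R-squared.  The quadratic `alpha^2` term captures the
#' boundary behaviour of the trade-off weight (flat response at low
#' `alpha`, steep at high `alpha`).
#'
#' @param results A data.frame with columns `Y`, `alpha`, `beta`, `m`.
#' @param model 1 (full) or 2 (fixed `alpha`: `beta` and `m` only).
#' @return An object of class `ocs_anova`: list with `table` (one row per
#'   term plus residuals: `estimate`, `ss`, `pct_variance`, `df`,
#'   `statistic`, `p_value`), `adj_r_squared`, `model`, and `constant_Y`
#'   flag.  Terms aliased by a degenerate design are dropped with a
#'   warning.
#' @export
anova_type1 <- function(results, model = 1) {
  req <- c("Y", if (model == 1) "alpha", "beta", "m")
  if (!all(req %in% names(results))) {
    stop("'results' must have columns ", paste(req, collapse = ", "))
  }
  if (!model %in% c(1, 2)) stop("'model' must be 1 or 2")
  dat <- results
  if (stats::var(dat$Y) == 0) {
    terms <- if (model == 1) c("alpha", "beta", "I(alpha^2)", "m") else c("beta", "m")
    tab <- data.frame(term = c(terms, "Residuals"), estimate = NA_real_,
                      ss = 0, pct_variance = 0, df = NA_real_,
                      statistic = NA_real_, p_value = NA_real_)
    return(structure(list(table = tab, adj_r_squared = 0, model = model,
                          constant_Y = TRUE),
                     class = "ocs_anova"))
  }
  form <- if (model == 1) Y ~ alpha + beta + I(alpha^2) + m else Y ~ beta + m
  fit <- stats::lm(form, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    warning("aliased term(s) dropped from the design: ",
            paste(dropped, collapse = ", "))
  }
  an <- stats::anova(fit)   # sequential (type I) by construction
  ss_total <- sum(an[["Sum Sq"]])
  terms <- rownames(an)
  est <- stats::coef(fit)
  est_map <- est[match(terms, names(est))]
  tab <- data.frame(term = terms,
                    estimate = as.numeric(est_map),
                    ss = an[["Sum Sq"]],
                    pct_variance = 100 * an[["Sum Sq"]] / ss_total,
                    df = an[["Df"]],
                    statistic = an[["F value"]],
                    p_value = an[["Pr(>F)"]])
  rownames(tab) <- NULL
  structure(list(table = tab,
                 adj_r_squared = summary(fit)$adj.r.squared,
                 model = model, constant_Y = FALSE, fit = fit),
            class = "ocs_anova")
}

#' @export
print.ocs_anova <- function(x, ...) {
  cat("Type I ANOVA (model ", x$model, "), adjusted R^2 = ",
      round(x$adj_r_squared, 4), if (x$constant_Y) "  [constant response]",
      "\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Final-generation Pareto report across scenarios
#'
#' Groups final-generation records by `(alpha, beta, mate_mode)` and
#' reports mean and standard deviation of gain and true coancestry per
#' group, plus pairwise dominance flags: group A dominates group B when it
#' achieves at least as much gain at no more coancestry, strictly better
#' in at least one of the two.
#'
#' @param records A data.frame with columns `alpha`, `beta`, `mate_mode`,
#'   `gain`, `true_coancestry` (one row per replicate).
#' @return List with `groups` (per-group means and sds) and `dominance`
#'   (data.frame of ordered group pairs with a logical `dominates`).
#' @export
pareto_report <- function(records) {
  req <- c("alpha", "beta", "mate_mode", "gain", "true_coancestry")
  if (!all(req %in% names(records))) {
    stop("'records' must have columns ", paste(req, collapse = ", "))
  }
  key <- interaction(records$alpha, records$beta, records$mate_mode,
                     drop = TRUE, sep = "/")
  if (nlevels(key) < 2L) stop("at least two scenario groups are required")
  groups <- do.call(rbind, lapply(levels(key), function(k) {
    s <- records[key == k, ]
    data.frame(group = k, alpha = s$alpha[1], beta = s$beta[1],
               mate_mode = s$mate_mode[1],
               mean_gain = mean(s$gain), sd_gain = stats::sd(s$gain),
               mean_coancestry = mean(s$true_coancestry),
               sd_coancestry = stats::sd(s$true_coancestry),
               n = nrow(s))
  }))
  rownames(groups) <- NULL
  pairs <- expand.grid(a = groups$group, b = groups$group,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  ga <- groups[match(pairs$a, groups$group), ]
  gb <- groups[match(pairs$b, groups$group), ]
  pairs$dominates <- (ga$mean_gain >= gb$mean_gain) &
    (ga$mean_coancestry <= gb$mean_coancestry) &
    ((ga$mean_gain > gb$mean_gain) | (ga$mean_coancestry < gb$mean_coancestry))
  rownames(pairs) <- NULL
  list(groups = groups, dominance = pairs)
}
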