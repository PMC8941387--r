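#' Screen covariates by Pearson correlation
#'
#' Computes Pearson's r and its two-sided p value between every analysis
#' variable and every candidate covariate; pairs with p < `alpha` are
#' flagged for inclusion in the covariance-adjusted group model.
#'
#' @param data data.frame holding variables and covariates.
#' @param variables character vector of analysis variable names.
#' @param covariates character vector of covariate names (default
#'   `c("facial_area", "age")`).
#' @param alpha inclusion threshold on the correlation p value.
#' @return data.frame: variable, covariate, pearson_r, p_value, include.
#' @export
screen_covariates <- function(data, variables,
                              covariates = c("facial_area", "age"),
                              alpha = 0.05) {
  miss <- setdiff(c(variables, covariates), names(data))
  if (length(miss) > 0L) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  rows <- list()
  for (v in variables) {
    for (cv in covariates) {
      ok <- complete.cases(data[[v]], data[[cv]])
      if (sum(ok) < 3L) stopf("fewer than 3 complete cases for %s ~ %s", v, cv)
      if (sd(data[[v]][ok]) == 0 || sd(data[[cv]][ok]) == 0) {
        stopf("zero-variance column in %s ~ %s", v, cv)
      }
      ct <- cor.test(data[[v]][ok], data[[cv]][ok], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, covariate = cv,
        pearson_r = unname(ct$estimate), p_value = ct$p.value,
        include = ct$p.value < alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Bonferroni-corrected per-test alpha
#'
#' @param family_size number of tests in the family (>= 1).
#' @param familywise_rate familywise error rate (default 0.05).
#' @return Per-test alpha, `familywise_rate / family_size`.
#' @export
bonferroni_alpha <- function(family_size, familywise_rate = 0.05) {
  if (family_size < 1) stopf("family_size must be >= 1")
  familywise_rate / family_size
}

#' Factorial ANCOVA group comparison for one variable
#'
#' Fits the linear model `variable ~ family_group + sex +
#' family_group:sex + covariates` with effects (sum-to-zero) coding and
#' reports Type-III F tests for the two main effects and the interaction,
#' plus a covariate-adjusted standardized effect size for the family-group
#' difference: `d = (adjusted autism mean - adjusted comparison mean) /
#' sqrt(MSE)`, positive when autism parents are larger (more masculine),
#' with a 95% CI obtained by inverting the noncentral-t distribution of
#' the corresponding t statistic. With `covariates = NULL` the model is
#' the plain two-way ANOVA.
#'
#' @param data data.frame with the variable, `family_group`, `sex` and the
#'   covariates; rows with missing values are dropped (with a message).
#' @param variable analysis variable name.
#' @param covariates covariate column names (default facial area and age).
#' @param alpha per-test significance threshold (after any multiplicity
#'   correction; default [bonferroni_alpha()] of a 10-variable family).
#' @return A one-row data.frame (class `group_comparison`) with the group,
#'   sex and interaction F/p, degrees of freedom, adjusted d and CI.
#' @export
ancova_test <- function(data, variable, covariates = c("facial_area", "age"),
                        alpha = bonferroni_alpha(10)) {
  need <- c(variable, "family_group", "sex", covariates)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  d0 <- data[, need, drop = FALSE]
  ok <- complete.cases(d0)
  if (any(!ok)) message(sprintf("ancova_test: %d incomplete case(s) dropped", sum(!ok)))
  d0 <- d0[ok, , drop = FALSE]
  d0$family_group <- factor(d0$family_group,
                            levels = c("autism_parent", "comparison_parent"))
  d0$sex <- factor(d0$sex, levels = c("male", "female"))
  if (any(table(d0$family_group, d0$sex) == 0L)) {
    stopf("empty design cell for variable '%s'", variable)
  }
  if (length(covariates) > 0L) {
    Xc <- as.matrix(d0[, covariates, drop = FALSE])
    kappa_c <- kappa(cbind(1, scale(Xc)), exact = TRUE)
    if (!is.finite(kappa_c) || kappa_c > 1e8) {
      stopf("covariates are (near-)collinear for variable '%s'", variable)
    }
  }
  rhs <- paste(c("family_group", "sex", "family_group:sex", covariates),
               collapse = " + ")
  fml <- stats::as.formula(paste0("`", variable, "` ~ ", rhs))
  mod <- lm(fml, data = d0,
            contrasts = list(family_group = "contr.sum", sex = "contr.sum"))
  a3 <- car::Anova(mod, type = 3)
  mse <- sum(stats::residuals(mod)^2) / mod$df.residual

  # effects coding: the family_group coefficient is half the adjusted
  # autism-minus-comparison difference
  cf <- summary(mod)$coefficients
  b_g <- cf["family_group1", ]
  adj_diff <- 2 * b_g["Estimate"]
  t_g <- unname(b_g["Estimate"] / b_g["Std. Error"])
  d_adj <- unname(adj_diff / sqrt(mse))
  scale_dt <- unname(2 * b_g["Std. Error"] / sqrt(mse))  # = d / t
  ncp <- ncp_limits(t_g, mod$df.residual)
  ci <- sort(ncp * scale_dt)

  row <- function(term) {
    c(F = a3[term, "F value"], p = a3[term, "Pr(>F)"],
      df1 = a3[term, "Df"])
  }
  g <- row("family_group"); s <- row("sex"); i <- row("family_group:sex")
  out <- data.frame(
    variable = variable,
    F_group = unname(g["F"]), p_group = unname(g["p"]),
    df1 = 1, df2 = mod$df.residual,
    d_adjusted = d_adj, d_ci_lower = ci[1], d_ci_upper = ci[2],
    F_sex = unname(s["F"]), p_sex = unname(s["p"]),
    F_interaction = unname(i["F"]), p_interaction = unname(i["p"]),
    n = nrow(d0),
    covariates = paste(covariates, collapse = ";"),
    alpha = alpha,
    significant = unname(g["p"]) < alpha,
    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", class(out))
  out
}

# 95% CI for a noncentrality parameter given an observed t and df
# (noncentral-t inversion; the standard CI method for standardized mean
# differences).
ncp_limits <- function(t_obs, df, level = 0.95) {
  a <- (1 - level) / 2
  # pt() with a noncentrality parameter routinely warns about final-digit
  # precision; that is far below the CI precision needed here
  f_lo <- function(ncp) suppressWarnings(pt(t_obs, df, ncp)) - (1 - a)
  f_hi <- function(ncp) suppressWarnings(pt(t_obs, df, ncp)) - a
  span <- abs(t_obs) + 10
  lo <- tryCatch(stats::uniroot(f_lo, c(t_obs - span, t_obs + span))$root,
                 error = function(e) NA_real_)
  hi <- tryCatch(stats::uniroot(f_hi, c(t_obs - span, t_obs + span))$root,
                 error = function(e) NA_real_)
  c(lo, hi)
}

#' Run the ANCOVA over a set of analysis variables
#'
#' @param data analysis data.frame.
#' @param variables character vector of variable names.
#' @param covariates covariates for every model.
#' @param familywise_rate familywise alpha before Bonferroni correction.
#' @param family_size Bonferroni family size (default: number of
#'   variables).
#' @return data.frame with one [ancova_test()] row per variable.
#' @export
group_comparison_table <- function(data, variables,
                                   covariates = c("facial_area", "age"),
                                   familywise_rate = 0.05,
                                   family_size = NULL) {
  family_size <- family_size %||% length(variables)
  alpha <- bonferroni_alpha(family_size, familywise_rate)
  do.call(rbind, lapply(variables, function(v) {
    ancova_test(data, v, covariates = covariates, alpha = alpha)
  }))
}

#' Cross-validated classification of child diagnosis status
#'
#' Stratified k-fold LDA accuracy for predicting family group (parent of
#' an autistic child versus comparison parent) from parent facial
#' variables — by default the masculinity score plus the six distances
#' that differ significantly between groups.
#'
#' @param data data.frame with `family_group` and the feature columns.
#' @param features character vector of predictor column names.
#' @param k folds (default 10).
#' @param seed integer seed.
#' @return Accuracy fraction.
#' @export
classify_diagnosis <- function(data, features, k = 10L, seed = 1L) {
  miss <- setdiff(c(features, "family_group"), names(data))
  if (length(miss) > 0L) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  as.numeric(cross_validate(data[, features, drop = FALSE],
                            data$family_group, k = k, seed = seed))
}

#' Per-cell score density summaries
#'
#' Boundary-corrected (reflection) Gaussian kernel density of the
#' masculinity scores within each sex-by-group cell, evaluated on a
#' uniform grid over `[0, 1]`. Scores are clipped to `[0, 1]` and the
#' bandwidth is Silverman's rule with a small floor so degenerate cells
#' stay well defined; reflection at both boundaries makes each density
#' integrate to 1 over the unit interval.
#'
#' @param scores numeric vector of masculinity scores.
#' @param metadata data.frame with `sex` and `family_group`, same order.
#' @param grid_n grid size (default 512).
#' @param min_cell minimum subjects per cell (default 5).
#' @return List with `grid` and `cells` (per cell: sex, group, n,
#'   bandwidth, mode and `density` vector over the grid).
#' @export
density_report <- function(scores, metadata, grid_n = 512L, min_cell = 5L) {
  if (length(scores) != nrow(metadata)) stopf("scores/metadata length mismatch")
  x <- pmin(1, pmax(0, scores))
  cell <- interaction(metadata$sex, metadata$family_group, drop = FALSE)
  grid <- seq(0, 1, length.out = grid_n)
  cells <- list()
  for (cl in levels(cell)) {
    xi <- x[cell == cl]
    if (length(xi) == 0L) stopf("empty cell '%s'", cl)
    if (length(xi) < min_cell) stopf("cell '%s' has %d < %d subjects", cl,
                                     length(xi), min_cell)
    bw <- if (sd(xi) == 0) 0.004 else max(bw.nrd0(xi), 0.004)
    # reflection at 0 and 1
    dens <- rowMeans(vapply(xi, function(c0) {
      dnorm(grid, c0, bw) + dnorm(grid, -c0, bw) + dnorm(grid, 2 - c0, bw)
    }, numeric(grid_n)))
    parts <- strsplit(cl, ".", fixed = TRUE)[[1L]]
    cells[[cl]] <- list(sex = parts[1L], family_group = parts[2L],
                        n = length(xi), bandwidth = bw,
                        mode = grid[which.max(dens)], density = dens)
  }
  list(grid = grid, cells = cells)
}
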