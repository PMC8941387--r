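test_that("covariate screening recovers exact and null correlations", {
  d <- data.frame(v = (1:20) * 2, facial_area = 1:20,
                  age = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3, 2, 3, 8, 4))
  res <- screen_covariates(d, "v")
  expect_equal(res$pearson_r[res$covariate == "facial_area"], 1)
  expect_true(res$include[res$covariate == "facial_area"])
  d$z <- 5
  expect_error(screen_covariates(d, "z"), "zero-variance")
})

test_that("independent pairs are flagged at the nominal 5% rate", {
  set.seed(41)
  n <- 355
  hits <- vapply(1:1000, function(i) {
    cor.test(rnorm(n), rnorm(n))$p.value < 0.05
  }, logical(1))
  # binomial 99% band around 0.05 at 1000 replicates
  expect_gte(mean(hits), 0.032)
  expect_lte(mean(hits), 0.068)
})

test_that("calibrated cohorts place covariate correlations in the reported band", {
  dv <- setdiff(rownames(reference_cell_stats()$means), "masculinity_score")
  ok <- vapply(1:30, function(s) {
    tab <- generate_feature_table(seed = s)
    rs <- c(vapply(dv, function(v) cor(tab$age, tab[[v]]), numeric(1)),
            vapply(dv, function(v) cor(tab$facial_area, tab[[v]]), numeric(1)))
    all(rs >= 0.12 & rs <= 0.56)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("bonferroni_alpha performs the family correction", {
  expect_identical(bonferroni_alpha(10), 0.005)
  expect_identical(bonferroni_alpha(1), 0.05)
  expect_identical(bonferroni_alpha(20), 0.0025)
  expect_error(bonferroni_alpha(0), "family_size")
})

test_that("the ANCOVA has the correct design degrees of freedom", {
  tab <- generate_feature_table(seed = 50)
  res <- ancova_test(tab, "e_nasal_tip_protrusion")
  expect_identical(res$df2, 349L)
  expect_identical(res$df1, 1)
  expect_identical(res$n, 355L)
  expect_true(res$F_group >= 0)
  expect_identical(res$significant, res$p_group < res$alpha)
  res0 <- ancova_test(tab, "e_nasal_tip_protrusion", covariates = NULL)
  expect_identical(res0$df2, 351L)
})

test_that("without covariates the ANCOVA reduces to the two-way ANOVA", {
  tab <- generate_feature_table(seed = 51)
  res <- ancova_test(tab, "g_forehead_width", covariates = NULL)
  # independent route: type-III F by explicit model comparison under
  # effects coding
  d <- tab
  d$family_group <- factor(d$family_group,
                           levels = c("autism_parent", "comparison_parent"))
  d$sex <- factor(d$sex, levels = c("male", "female"))
  ctr <- list(family_group = "contr.sum", sex = "contr.sum")
  full <- lm(g_forehead_width ~ family_group + sex + family_group:sex,
             data = d, contrasts = ctr)
  rss_f <- sum(residuals(full)^2)
  # drop the group main effect while keeping the other terms: refit on the
  # model matrix without the group column
  mm <- model.matrix(full)
  red <- lm.fit(mm[, colnames(mm) != "family_group1"], d$g_forehead_width)
  f_manual <- (sum(red$residuals^2) - rss_f) / (rss_f / full$df.residual)
  expect_equal(res$F_group, f_manual, tolerance = 1e-8)
})

test_that("group effect sign convention is autism-minus-comparison", {
  cfg <- null_cohort_config()
  cfg$means["e_nasal_tip_protrusion", c("father_autism", "mother_autism")] <-
    cfg$means["e_nasal_tip_protrusion", c("father_autism", "mother_autism")] + 3
  tab <- generate_feature_table(cfg, seed = 52)
  res <- ancova_test(tab, "e_nasal_tip_protrusion")
  expect_gt(res$d_adjusted, 0)
  expect_true(res$d_ci_lower < res$d_adjusted & res$d_adjusted < res$d_ci_upper)
  expect_true(res$significant)
})

test_that("degenerate designs and collinear covariates are rejected", {
  tab <- generate_feature_table(seed = 53)
  tab2 <- tab[tab$sex == "female" | tab$family_group == "autism_parent", ]
  expect_error(ancova_test(tab2, "e_nose_width"), "empty design cell")
  tab$area2 <- 2 * tab$facial_area
  expect_error(ancova_test(tab, "e_nose_width",
                           covariates = c("facial_area", "area2")),
               "collinear")
})

test_that("permuted family labels classify at chance on balanced resamples", {
  tab <- generate_feature_table(seed = 60)
  dv <- grep("^(e|g)_", names(tab), value = TRUE)
  accs <- vapply(1:20, function(s) {
    idx <- facemasc:::with_seed(100 + s, {
      a <- sample(which(tab$family_group == "autism_parent"), 150)
      b <- sample(which(tab$family_group == "comparison_parent"), 150)
      c(a, b)
    })
    sub <- tab[idx, ]
    sub$family_group <- facemasc:::with_seed(200 + s, sample(sub$family_group))
    classify_diagnosis(sub, dv, k = 10, seed = s)
  }, numeric(1))
  expect_gte(mean(accs), 0.45)
  expect_lte(mean(accs), 0.55)
})

test_that("a stronger group shift raises diagnosis classification accuracy", {
  acc_for_shift <- function(shift) {
    mean(vapply(1:8, function(s) {
      cfg <- cohort_config(group_sizes = c(40L, 60L, 40L, 60L),
                          group_shift = shift, seed = 500 + s)
      sim <- generate_cohort(cfg)
      feats <- extract_feature_table(sim$landmarks)  # Euclidean block only
      dv <- grep("^e_", names(feats), value = TRUE)
      d <- cbind(sim$subjects, feats[, dv])
      classify_diagnosis(d, dv, k = 10, seed = s)
    }, numeric(1)))
  }
  expect_gt(acc_for_shift(0.6), acc_for_shift(0.15))
})

test_that("score densities are proper probability densities per cell", {
  tab <- generate_feature_table(seed = 61)
  dv <- grep("^(e|g)_", names(tab), value = TRUE)
  model <- fit_gender_model(tab[, dv], tab$sex, feature_subset = dv, seed = 61)
  scores <- masculinity_score(model, tab)$score
  dr <- density_report(scores, tab[, c("sex", "family_group")])
  h <- diff(dr$grid[1:2])
  for (cl in dr$cells) {
    expect_true(all(cl$density >= 0))
    integral <- sum((head(cl$density, -1) + utils::tail(cl$density, -1)) / 2) * h
    expect_equal(integral, 1, tolerance = 1e-3)
  }
  male_meta <- data.frame(
    sex = factor(rep("male", sum(tab$sex == "male")),
                 levels = c("male", "female")),
    family_group = tab$family_group[tab$sex == "male"])
  expect_error(density_report(scores[tab$sex == "male"], male_meta),
               "empty cell")
})

test_that("autism-parent male score modes sit at or above comparison males", {
  hits <- vapply(1:20, function(s) {
    tab <- generate_feature_table(seed = s)
    dv <- grep("^(e|g)_", names(tab), value = TRUE)
    model <- fit_gender_model(tab[, dv], tab$sex, feature_subset = dv, seed = s)
    scores <- masculinity_score(model, tab)$score
    dr <- density_report(scores, tab[, c("sex", "family_group")])
    dr$cells[["male.autism_parent"]]$mode >=
      dr$cells[["male.comparison_parent"]]$mode
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("a degenerate cell concentrates its density at the shared value", {
  scores <- c(rep(0.6, 5), runif(20, 0, 1))
  meta <- data.frame(
    sex = c(rep("male", 5), rep("female", 20)),
    family_group = rep("autism_parent", 25))
  dr <- suppressWarnings(density_report(scores[1:5], data.frame(
    sex = rep("male", 5), family_group = rep("autism_parent", 5))))
  cl <- dr$cells[["male.autism_parent"]]
  h <- diff(dr$grid[1:2])
  inside <- abs(dr$grid - 0.6) <= 0.02
  mass <- sum(cl$density[inside]) * h
  expect_gte(mass, 0.99)
})
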