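test_that("fit_lda reproduces a hand-computed Fisher solution", {
  # class a: (0,0), (1,1), (1,0), (2,1); class b: (4,3), (5,4), (4,4), (5,3)
  # pooled Sw = [[3,1],[1,2]]/6, delta = (3.5, 3) => w proportional to (4.8, 6.6)
  X <- data.frame(x = c(0, 1, 1, 2, 4, 5, 4, 5),
                  y = c(0, 1, 0, 1, 3, 4, 4, 3))
  fit <- fit_lda(X, rep(c("a", "b"), each = 4), positive_class = "b")
  w <- fit$weights / sqrt(sum(fit$weights^2))
  w0 <- c(4.8, 6.6) / sqrt(sum(c(4.8, 6.6)^2))
  expect_equal(unname(w), w0, tolerance = 1e-8)
})

test_that("fit_lda agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  d <- two_class_data(40, 4, delta = 1.2, seed = 5)
  fit <- fit_lda(d$X, d$labels, positive_class = "a")
  ref <- MASS::lda(d$X, grouping = d$labels)
  w1 <- fit$weights / sqrt(sum(fit$weights^2))
  w2 <- drop(ref$scaling[, 1]); w2 <- w2 / sqrt(sum(w2^2))
  if (sum(w1 * w2) < 0) w2 <- -w2
  expect_equal(unname(w1), unname(w2), tolerance = 1e-6)
})

test_that("well-separated classes are classified perfectly in training", {
  set.seed(11)
  x <- data.frame(v = c(rnorm(100), rnorm(100, 10)))
  lab <- rep(c("f", "m"), each = 100)
  fit <- fit_lda(x, lab)
  expect_equal(mean(predict(fit, x) == lab), 1)
  # oracle: thresholding at the midpoint of the class means
  thr <- (mean(x$v[1:100]) + mean(x$v[101:200])) / 2
  expect_equal(predict(fit, x), ifelse(x$v >= thr, "m", "f"),
               ignore_attr = TRUE)
})

test_that("with identical class means the discriminant carries no signal", {
  set.seed(12)
  x <- as.data.frame(matrix(rnorm(4000 * 3), ncol = 3))
  lab <- rep(c("a", "b"), each = 2000)
  fit <- fit_lda(x, lab)
  sep <- abs(diff(fit$class_means)) /
    sd(facemasc:::lda_project(fit, x))
  expect_lt(sep, 0.2)
  expect_lt(abs(mean(predict(fit, x) == lab) - 0.5), 0.05)
})

test_that("degenerate covariance triggers the ridge fallback", {
  x <- data.frame(a = c(1, 2, 3, 4, 5, 6, 7, 8))
  x$b <- 2 * x$a  # singular pooled covariance
  lab <- rep(c("u", "v"), 4)
  expect_warning(fit <- fit_lda(x, lab), "ridge")
  expect_true(all(is.finite(fit$weights)))
  expect_error(fit_lda(x, rep("u", 8)), "2 classes")
})

test_that("cross-validation is stratified, deterministic and sane", {
  set.seed(13)
  x <- data.frame(v = c(rnorm(60, 0, 0.1), rnorm(60, 10, 0.1)))
  lab <- rep(c("f", "m"), each = 60)
  acc <- cross_validate(x, lab, k = 10, seed = 3)
  expect_equal(as.numeric(acc), 1)
  fold <- attr(acc, "folds")
  expect_true(all(table(fold, lab) == 6))
  expect_identical(as.numeric(cross_validate(x, lab, k = 10, seed = 3)),
                   as.numeric(acc))
  expect_error(cross_validate(x, lab, k = 1), "k must be")
  expect_error(cross_validate(x[1:65, , drop = FALSE], lab[1:65], k = 10),
               "fewer than k")
})

test_that("permuted sex labels give chance-level cross-validated accuracy", {
  tab <- generate_feature_table(seed = 21)
  dv <- grep("^(e|g)_", names(tab), value = TRUE)
  accs <- vapply(1:50, function(s) {
    perm <- facemasc:::with_seed(1000 + s, sample(tab$sex))
    as.numeric(cross_validate(tab[, dv], perm, k = 10, seed = s))
  }, numeric(1))
  expect_true(all(accs >= 0.40 & accs <= 0.60))
})

test_that("forward selection finds dimorphic features and rejects noise", {
  res <- vapply(1:10, function(s) {
    set.seed(3000 + s)
    n <- 400
    sex <- rep(c("male", "female"), each = n / 2)
    X <- as.data.frame(matrix(rnorm(n * 10), n, 10))
    names(X) <- paste0("noise_", sprintf("%02d", 1:10))
    X$dim_a <- rnorm(n) + 3.0 * (sex == "male")
    X$dim_b <- rnorm(n) + 3.0 * (sex == "male")
    sel <- gefs_select(X, sex, max_features = 10, k = 10, seed = s)
    c(both = all(c("dim_a", "dim_b") %in% sel),
      no_noise = !any(grepl("noise", sel)))
  }, logical(2))
  expect_gte(mean(res["both", ]), 0.9)
  expect_gte(mean(res["no_noise", ]), 0.9)
})

test_that("all-noise candidates terminate selection at chance accuracy", {
  set.seed(17)
  n <- 355
  X <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  sex <- rep_len(c("male", "female"), n)
  sel <- gefs_select(X, sex, max_features = 8, k = 10, seed = 2)
  expect_true(attr(sel, "accuracy") >= 0.40 && attr(sel, "accuracy") <= 0.60)
})

test_that("max_features = 1 returns the single most accurate feature", {
  set.seed(18)
  n <- 200
  sex <- rep(c("male", "female"), each = n / 2)
  X <- data.frame(strong = rnorm(n) + 4 * (sex == "male"),
                  weak = rnorm(n) + 0.5 * (sex == "male"),
                  none = rnorm(n))
  sel <- gefs_select(X, sex, max_features = 1, k = 10, seed = 1)
  expect_identical(as.character(sel), "strong")
  expect_error(gefs_select(X, sex, max_features = 0), "max_features")
})

test_that("greedy selection attains the exhaustive best-subset accuracy", {
  set.seed(19)
  n <- 120
  sex <- rep(c("male", "female"), each = n / 2)
  X <- data.frame(a = rnorm(n) + 2.5 * (sex == "male"),
                  b = rnorm(n) + 2.0 * (sex == "male"),
                  c = rnorm(n), d = rnorm(n), e = rnorm(n))
  ex <- gefs_select(X, sex, max_features = 5, k = 10, seed = 7,
                    method = "exhaustive")
  # independent oracle: enumerate subsets with the same fixed folds
  fold <- facemasc:::stratified_folds(sex, 10, seed = 7)
  Xm <- as.matrix(X)
  best <- -Inf
  for (size in 1:5) {
    for (s in utils::combn(names(X), size, simplify = FALSE)) {
      best <- max(best, facemasc:::cv_with_folds(Xm, sex, fold, s))
    }
  }
  expect_equal(attr(ex, "accuracy"), best)
  gr <- gefs_select(X, sex, max_features = 5, k = 10, seed = 7)
  expect_gte(attr(gr, "accuracy"), best - 0.005)
})

test_that("masculinity scores scale the training sample onto [0, 1] exactly", {
  tab <- generate_feature_table(seed = 30)
  dv <- grep("^(e|g)_", names(tab), value = TRUE)
  model <- fit_gender_model(tab[, dv], tab$sex, feature_subset = dv, seed = 30)
  sc <- masculinity_score(model, tab)
  expect_equal(max(sc$score), 1, tolerance = 1e-12)
  expect_equal(min(sc$score), 0, tolerance = 1e-12)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_identical(attr(sc, "n_clipped"), 0L)
  expect_error(masculinity_score(model, tab[, dv[-1]]), "missing selected")
})

test_that("a vector at the class-mean midpoint scores between the sex means", {
  tab <- generate_feature_table(seed = 31)
  dv <- grep("^(e|g)_", names(tab), value = TRUE)
  model <- fit_gender_model(tab[, dv], tab$sex, feature_subset = dv, seed = 31)
  X <- as.matrix(tab[, model$selected_features])
  mid <- (colMeans(X[tab$sex == "male", ]) + colMeans(X[tab$sex == "female", ])) / 2
  s_mid <- masculinity_score(model, as.data.frame(t(mid)))$score
  sc <- masculinity_score(model, tab)$score
  expect_gt(s_mid, mean(sc[tab$sex == "female"]))
  expect_lt(s_mid, mean(sc[tab$sex == "male"]))
  b <- model$scale_bounds
  expect_equal(s_mid, (0 - b[1]) / (b[2] - b[1]), tolerance = 1e-9)
})

test_that("scores are monotone along the discriminant axis", {
  tab <- generate_feature_table(seed = 32)
  dv <- grep("^(e|g)_", names(tab), value = TRUE)
  model <- fit_gender_model(tab[, dv], tab$sex, feature_subset = dv, seed = 32)
  w <- model$weights
  x0 <- colMeans(as.matrix(tab[, model$selected_features]))
  prev <- -Inf
  for (t in seq(-1, 1, length.out = 9)) {
    x <- x0 + t * w / sqrt(sum(w^2))
    s <- suppressMessages(masculinity_score(model, as.data.frame(t(x)))$score)
    expect_gte(s, prev)
    prev <- s
  }
})

test_that("calibrated cohorts order the scores by sex and family group", {
  for (s in 1:8) {
    tab <- generate_feature_table(seed = s)
    dv <- grep("^(e|g)_", names(tab), value = TRUE)
    model <- fit_gender_model(tab[, dv], tab$sex, feature_subset = dv, seed = s)
    tab$score <- masculinity_score(model, tab)$score
    cm <- tapply(tab$score, interaction(tab$sex, tab$family_group), mean)
    expect_gt(cm[["male.autism_parent"]], cm[["female.autism_parent"]])
    expect_gt(cm[["male.comparison_parent"]], cm[["female.comparison_parent"]])
    expect_gte(cm[["male.autism_parent"]], cm[["male.comparison_parent"]])
    expect_gte(cm[["female.autism_parent"]], cm[["female.comparison_parent"]])
  }
})

test_that("gender models serialize losslessly to JSON", {
  tab <- generate_feature_table(seed = 33)
  dv <- grep("^(e|g)_", names(tab), value = TRUE)
  model <- fit_gender_model(tab[, dv], tab$sex, seed = 33)
  path <- tempfile(fileext = ".json")
  write_gender_model(model, path)
  back <- read_gender_model(path)
  expect_identical(back$selected_features, model$selected_features)
  expect_equal(back$weights, model$weights)
  expect_equal(back$scale_bounds, model$scale_bounds)
  s1 <- masculinity_score(model, tab)$score
  s2 <- masculinity_score(back, tab)$score
  expect_equal(s2, s1, tolerance = 1e-12)
  unlink(path)
})
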