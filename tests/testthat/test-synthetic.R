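test_that("generate_cohort reproduces the configured cell counts", {
  sim <- generate_cohort(cohort_config(seed = 2))
  expect_identical(nrow(sim$subjects), 355L)
  tab <- table(sim$subjects$sex, sim$subjects$family_group)
  expect_identical(unname(tab["male", "autism_parent"]), 58L)
  expect_identical(unname(tab["female", "autism_parent"]), 134L)
  expect_identical(unname(tab["male", "comparison_parent"]), 50L)
  expect_identical(unname(tab["female", "comparison_parent"]), 113L)
  expect_length(sim$landmarks, 355L)
  expect_true(all(sim$subjects$age > 0))
})

test_that("the degenerate generator returns the template for every subject", {
  cfg <- cohort_config(group_sizes = c(3L, 3L, 3L, 3L), dimorphism_scale = 0,
                       group_shift = 0, noise_sd = 0, size_sd = 0,
                       age_slope = 0, seed = 9)
  sim <- generate_cohort(cfg)
  tmpl <- face_template("female")$points
  for (lm in sim$landmarks) expect_equal(lm$points, tmpl, tolerance = 1e-12)
})

test_that("cohort generation is deterministic and rejects empty cohorts", {
  cfg <- cohort_config(group_sizes = c(5L, 5L, 5L, 5L), seed = 77)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1, s2)
  expect_error(generate_cohort(cohort_config(group_sizes = c(0L, 0L, 0L, 0L))),
               "empty cohort")
  expect_error(generate_feature_table(
    feature_table_config(group_sizes = c(0L, 0L, 0L, 0L))), "empty cohort")
})

test_that("increasing group_shift increases the masculinization of autism cells", {
  D <- dimorphism_field()
  proj <- function(shift) {
    cfg <- cohort_config(group_sizes = c(40L, 0L, 0L, 0L), noise_sd = 0.2,
                         size_sd = 0, age_slope = 0, group_shift = shift,
                         seed = 4)
    sim <- generate_cohort(cfg)
    mean_pts <- Reduce(`+`, lapply(sim$landmarks, `[[`, "points")) /
      length(sim$landmarks)
    sum((mean_pts - face_template("female")$points) * D) / sum(D * D)
  }
  p <- vapply(c(0, 0.08, 0.2, 0.5), proj, numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("feature-table cell means converge on the configured statistics", {
  # per-statistic calibration: the empirical cell mean lies within 3
  # standard errors of the configured mean in >= 95% of seeds
  cfg <- feature_table_config()
  ref <- reference_cell_stats()
  cells <- facemasc::cohort_cells()
  n_seeds <- 200L
  hits <- array(0L, dim = dim(ref$means))
  for (s in seq_len(n_seeds)) {
    tab <- generate_feature_table(cfg, seed = s)
    for (ci in seq_len(nrow(cells))) {
      sub <- tab$sex == cells$sex[ci] & tab$family_group == cells$family_group[ci]
      se <- ref$sds[, ci] / sqrt(cells$n[ci])
      emp <- colMeans(tab[sub, rownames(ref$means)])
      hits[, ci] <- hits[, ci] + (abs(emp - ref$means[, ci]) <= 3 * se)
    }
  }
  expect_true(all(hits / n_seeds >= 0.95))
})

test_that("near-zero spread collapses every draw onto its cell mean", {
  ref <- reference_cell_stats()
  cfg <- feature_table_config(sds = ref$sds * 1e-9)
  tab <- generate_feature_table(cfg, seed = 5)
  cells <- facemasc::cohort_cells()
  for (ci in seq_len(nrow(cells))) {
    sub <- tab$sex == cells$sex[ci] & tab$family_group == cells$family_group[ci]
    emp <- colMeans(tab[sub, rownames(ref$means)])
    expect_equal(unname(emp), unname(ref$means[, ci]), tolerance = 1e-6)
  }
})

test_that("the age-feature correlation matches the configured loading", {
  # closed form: after marginal standardization the within-cell Pearson
  # r(age, distance) equals the age loading
  cfg <- feature_table_config(group_sizes = c(10000L, 0L, 0L, 0L))
  tab <- generate_feature_table(cfg, seed = 8)
  r <- cor(tab$age, tab$e_nasal_tip_protrusion)
  expect_gt(r, 0)
  expect_lt(abs(r - cfg$age_loading), 0.05)
})

test_that("invalid covariance requests are rejected as configuration errors", {
  expect_error(feature_table_config(age_loading = 0.9, size_loading = 0.9),
               "positive definite")
  expect_error(feature_table_config(dimorphism_suppression = 1),
               "positive definite")
  ref <- reference_cell_stats()
  expect_error(feature_table_config(sds = ref$sds * 0), "s.d.")
})

test_that("feature tables are bitwise deterministic given config and seed", {
  cfg <- feature_table_config()
  expect_identical(generate_feature_table(cfg, seed = 123),
                   generate_feature_table(cfg, seed = 123))
})

test_that("cohort facial areas centre near the reported adult mean", {
  # cells in the study's proportions; areas from the template surface
  # deformed onto each subject's landmarks
  cfg <- cohort_config(group_sizes = c(6L, 13L, 5L, 11L), seed = 14)
  sim <- generate_cohort(cfg, meshes = TRUE, mesh_resolution = 7)
  areas <- vapply(sim$meshes, facial_area, numeric(1))
  expect_lt(abs(mean(areas) - 35435) / 35435, 0.10)
})

test_that("fixture meshes have the advertised geometry", {
  pm <- fixture_mesh("plane", 8)
  expect_true(all(abs(pm$vertices[, 3]) < 1e-12))
  sm <- fixture_mesh("unit_sphere", 2)
  expect_lt(max(abs(sqrt(rowSums(sm$vertices^2)) - 1)), 1e-9)
  expect_error(fixture_mesh("torus"), "arg")

  # every template landmark is an exact vertex of the face surface
  fm <- fixture_mesh("face_template", 6)
  tmpl <- face_template("female")
  lv <- fm$landmark_vertices
  expect_length(lv, 21L)
  expect_equal(fm$vertices[lv, ], unname(tmpl$points), tolerance = 1e-9,
               ignore_attr = TRUE)

  # a deformed subject surface interpolates that subject's landmarks
  cfg <- cohort_config(group_sizes = c(1L, 0L, 0L, 0L), seed = 31)
  sim <- generate_cohort(cfg)
  sub_mesh <- mesh_from_landmarks(sim$landmarks[[1]], fm)
  d <- vapply(seq_len(21), function(i) {
    closest_surface_point(sub_mesh, sim$landmarks[[1]]$points[i, ])$distance
  }, numeric(1))
  expect_lt(max(d), 1e-8)
})
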