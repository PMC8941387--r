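## Study-cohort constants ----------------------------------------------------

#' Cell layout of the emulated 2 (family group) x 2 (sex) cohort
#'
#' Fathers and mothers of autistic children, and comparison fathers and
#' mothers, with the default cell sizes, age distributions and facial-area
#' parameters.
#'
#' @return data.frame with one row per cell.
#' @export
cohort_cells <- function() {
  data.frame(
    cell = c("father_autism", "mother_autism", "father_comparison",
             "mother_comparison"),
    sex = c("male", "female", "male", "female"),
    family_group = c("autism_parent", "autism_parent",
                     "comparison_parent", "comparison_parent"),
    n = c(58L, 134L, 50L, 113L),
    age_mean = c(43.4, 41.9, 41.9, 39.1),
    age_sd = c(7.40, 5.93, 8.32, 7.44),
    # per-cell facial area (mm^2): sex split chosen so the family-group
    # means are 35435 (autism parents) and 35142 (comparison parents)
    area_mean = c(38700, 34022, 38400, 33700),
    area_sd = c(3300, 3300, 3300, 3300),
    stringsAsFactors = FALSE
  )
}

#' Reference per-cell statistics of the analysis variables
#'
#' Per-cell means and standard deviations of the masculinity score and the
#' ten analysis distances (mm; geodesic values on the raw scale) used to
#' calibrate the synthetic generators; columns follow [cohort_cells()]
#' order.
#'
#' @return List with `means` and `sds` (variable x cell matrices).
#' @export
reference_cell_stats <- function() {
  vars <- c("masculinity_score",
            "e_nose_width", "e_nasal_tip_protrusion", "e_nasal_bridge_length",
            "e_upper_lip_height",
            "g_upper_facial_height", "g_outer_canthal_width",
            "g_forehead_width", "g_mandible_height",
            "g_upper_cheek_height_left", "g_upper_cheek_height_right")
  means <- rbind(
    c(0.85, 0.32, 0.80, 0.28),
    c(19.8, 18.2, 19.3, 17.6),
    c(21.1, 17.2, 19.5, 16.2),
    c(51.0, 46.3, 49.3, 45.4),
    c(25.5, 23.1, 24.8, 22.7),
    c(73.0, 67.7, 70.7, 65.5),
    c(120.6, 109.8, 117.3, 106.9),
    c(167.3, 153.1, 160.7, 150.1),
    c(77.7, 71.8, 76.0, 71.7),
    c(80.0, 73.9, 77.9, 73.2),
    c(79.6, 73.9, 77.4, 72.7))
  sds <- rbind(
    c(0.08, 0.12, 0.11, 0.09),
    c(1.86, 1.84, 2.11, 1.88),
    c(2.05, 2.22, 2.62, 2.50),
    c(3.86, 3.66, 2.83, 3.29),
    c(3.11, 2.73, 3.04, 2.71),
    c(4.57, 4.57, 4.51, 4.58),
    c(9.03, 7.82, 8.96, 7.92),
    c(11.5, 8.04, 11.7, 7.20),
    c(5.50, 4.79, 7.67, 4.77),
    c(5.06, 3.80, 4.00, 3.95),
    c(4.40, 3.59, 4.56, 3.81))
  rownames(means) <- rownames(sds) <- vars
  colnames(means) <- colnames(sds) <- cohort_cells()$cell
  list(means = means, sds = sds)
}

## Feature-level generator ---------------------------------------------------

#' Configuration for the distance-level cohort generator
#'
#' Defines a 2 (family group) x 2 (sex) cohort simulated directly at the
#' level of the analysis variables (masculinity score and ten facial
#' distances), each drawn per cell from a multivariate normal whose means
#' and standard deviations default to the reference adult-cohort
#' statistics. The within-cell correlation structure uses three shared
#' standardized factors:
#'
#' * an age factor (loading `age_loading` on every distance), tying the
#'   distances to the observed age covariate;
#' * a size factor (loading `size_loading`), tying them to facial area
#'   (area itself loads 0.9 on this factor);
#' * a residual block whose component along the standardized sex-difference
#'   direction is suppressed by `dimorphism_suppression` (a fraction in
#'   `[0, 1)` of that component's variance removed). This calibrates the
#'   joint sexual dimorphism of the distance block to the very large
#'   masculinity-score dimorphism observed in adult cohorts, which is much
#'   larger than the per-variable differences alone would produce.
#'
#' @param group_sizes named integer vector of cell sizes, in the order
#'   father_autism, mother_autism, father_comparison, mother_comparison.
#' @param means,sds numeric variable x cell matrices (defaults: reference
#'   statistics from [reference_cell_stats()]).
#' @param age_loading,size_loading shared-factor loadings for the distances.
#' @param score_loadings loadings of the masculinity-score variable on the
#'   age factor, the size factor and the dimorphism axis of the residual
#'   block.
#' @param dimorphism_suppression suppression fraction in `[0, 1)`.
#' @param group_effect optional named vector (variable -> shift in mm or
#'   score units) added to the two autism-parent cell means; use 0 shifts
#'   or identical group columns for null simulations.
#' @return A `feature_table_config` list.
#' @export
feature_table_config <- function(group_sizes = NULL, means = NULL, sds = NULL,
                                 age_loading = 0.19, size_loading = 0.09,
                                 score_loadings = c(age = 0.15, size = 0.12,
                                                    dimorphism = 0.5),
                                 dimorphism_suppression = 0.98,
                                 group_effect = NULL) {
  cells <- cohort_cells()
  if (!is.null(group_sizes)) {
    if (length(group_sizes) != 4L || any(group_sizes < 0)) {
      stopf("'group_sizes' must be 4 non-negative counts")
    }
    cells$n <- as.integer(group_sizes)
  }
  ref <- reference_cell_stats()
  means <- means %||% ref$means
  sds <- sds %||% ref$sds
  if (!identical(dim(means), dim(sds))) stopf("'means' and 'sds' differ in shape")
  if (any(sds <= 0)) stopf("all configured s.d. values must be > 0")
  if (age_loading^2 + size_loading^2 >= 1) {
    stopf("requested covariance is not positive definite: age and size loadings too large")
  }
  if (dimorphism_suppression < 0 || dimorphism_suppression >= 1) {
    stopf("requested covariance is not positive definite: 'dimorphism_suppression' must be in [0, 1)")
  }
  if (sum(score_loadings^2) >= 1) {
    stopf("requested covariance is not positive definite: score loadings too large")
  }
  if (!is.null(group_effect)) {
    bad <- setdiff(names(group_effect), rownames(means))
    if (length(bad) > 0L) stopf("unknown variable(s) in group_effect: %s",
                                paste(bad, collapse = ", "))
    means[names(group_effect), c("father_autism", "mother_autism")] <-
      means[names(group_effect), c("father_autism", "mother_autism")] +
      group_effect
  }
  structure(list(cells = cells, means = means, sds = sds,
                 age_loading = age_loading, size_loading = size_loading,
                 score_loadings = score_loadings,
                 dimorphism_suppression = dimorphism_suppression),
            class = "feature_table_config")
}

# Standardized male-female difference direction of the distance variables
# (unit vector), from the configured cell statistics.
dimorphism_direction <- function(config) {
  cells <- config$cells
  vars <- setdiff(rownames(config$means), "masculinity_score")
  n <- cells$n
  male <- cells$sex == "male"
  # the direction is a property of the configured statistics; cell counts
  # only weight it, with equal weights when a sex is absent from the design
  wts <- function(idx) {
    w <- n[idx]
    if (sum(w) == 0) w <- rep(1, length(w))
    w / sum(w)
  }
  wn <- pmax(n - 1L, 0L)
  if (sum(wn) == 0) wn <- rep(1L, length(n))
  pooled_sd <- sqrt(rowSums(sweep(config$sds[vars, , drop = FALSE]^2, 2,
                                  wn, "*")) / sum(wn))
  mmean <- config$means[vars, male, drop = FALSE] %*% wts(male)
  fmean <- config$means[vars, !male, drop = FALSE] %*% wts(!male)
  d <- as.vector(mmean - fmean) / pooled_sd
  d / sqrt(sum(d^2))
}

#' Fraction of within-cell distance variance unexplained by the covariates
#'
#' Under the generator's factor construction, regressing a distance on age
#' and facial area within a cell leaves residual variance
#' `1 - age_loading^2 - (0.9 * size_loading)^2` (as a fraction of the cell
#' variance). The square root converts a configured cell s.d. into the
#' residual s.d. that an analysis-of-covariance mean-square-error
#' estimates; effect-injection simulations use it to construct a known
#' covariate-adjusted standardized difference.
#'
#' @param config a [feature_table_config()].
#' @return Scalar fraction in (0, 1].
#' @export
residual_sd_fraction <- function(config) {
  sqrt(1 - config$age_loading^2 - (0.9 * config$size_loading)^2)
}

#' Simulate a cohort at the analysis-variable level
#'
#' Draws subject records (sex, family group, age, facial area) and the
#' masculinity score plus ten facial distances per subject from the
#' configured per-cell multivariate normal model. Empirical cell means
#' converge to the configured means as the cell sizes grow.
#'
#' @param config a [feature_table_config()].
#' @param seed integer seed; identical seed and config give an identical
#'   table.
#' @return A data.frame with columns `subject_id`, `sex`, `family_group`,
#'   `age`, `facial_area`, `masculinity_score` and the ten distance
#'   variables.
#' @export
generate_feature_table <- function(config = feature_table_config(), seed = 1L) {
  stopifnot(inherits(config, "feature_table_config"))
  cells <- config$cells
  if (sum(cells$n) == 0L) stopf("empty cohort: all cell counts are zero")
  vars <- rownames(config$means)
  dvars <- setdiff(vars, "masculinity_score")
  u <- dimorphism_direction(config)
  beta <- config$dimorphism_suppression
  la <- config$age_loading
  ls <- config$size_loading
  le <- sqrt(1 - la^2 - ls^2)
  sl <- config$score_loadings
  sle <- sqrt(1 - sum(sl^2))

  with_seed(seed, {
    rows <- lapply(seq_len(nrow(cells)), function(ci) {
      n <- cells$n[ci]
      if (n == 0L) return(NULL)
      A <- rnorm(n)                       # standardized age
      S <- rnorm(n)                       # latent size
      W <- matrix(rnorm(n * length(dvars)), n)
      # residual block with the dimorphism-axis component suppressed
      cshrink <- 1 - sqrt(1 - beta)
      E <- W - cshrink * (W %*% u) %*% t(u)
      E <- sweep(E, 2, sqrt(1 - beta * u^2), "/")   # unit marginals
      z <- la * A + ls * S
      Zd <- sweep(le * E, 1, z, "+")
      # standardized within-cell dimorphism axis of the residual block,
      # shared with the masculinity-score variable
      u_s <- u / sqrt(1 - beta * u^2)
      v_ax <- drop(t(u_s) %*% (diag(length(u)) - beta * u %*% t(u)) %*% u_s)
      ax <- (E %*% u) / sqrt(v_ax)
      age <- cells$age_mean[ci] + cells$age_sd[ci] * A
      area <- cells$area_mean[ci] +
        cells$area_sd[ci] * (0.9 * S + sqrt(1 - 0.81) * rnorm(n))
      out <- data.frame(
        subject_id = sprintf("%s_%03d", cells$cell[ci], seq_len(n)),
        sex = cells$sex[ci], family_group = cells$family_group[ci],
        age = age, facial_area = area, stringsAsFactors = FALSE)
      out$.A <- A; out$.S <- S; out$.cell <- ci
      feat <- sweep(Zd, 2, config$sds[dvars, ci], "*")
      feat <- sweep(feat, 2, config$means[dvars, ci], "+")
      colnames(feat) <- dvars
      out$.axis <- drop(ax)
      cbind(out, feat)
    })
    tab <- do.call(rbind, rows)
    # masculinity-score column
    if ("masculinity_score" %in% vars) {
      zm <- sl["age"] * tab$.A + sl["size"] * tab$.S +
        sl["dimorphism"] * tab$.axis + sle * rnorm(nrow(tab))
      ci <- tab$.cell
      tab$masculinity_score <- config$means["masculinity_score", ci] +
        config$sds["masculinity_score", ci] * zm
    }
    tab$.A <- tab$.S <- tab$.cell <- tab$.axis <- NULL
    ord <- c("subject_id", "sex", "family_group", "age", "facial_area",
             intersect(vars, names(tab)))
    rownames(tab) <- NULL
    tab[, ord]
  })
}

## Landmark-level generator --------------------------------------------------

#' Configuration for the landmark-level cohort generator
#'
#' Synthetic faces are built as
#' `template + c * dimorphism_field + size + noise`, where the
#' masculinization coefficient `c` combines sex
#' (`dimorphism_scale` for males, 0 for females), family group
#' (`group_shift` added for autism parents) and a linear age trend
#' (`age_slope * (age - 40)`); a global isotropic scale factor
#' `N(1, size_sd)` about the landmark centroid models overall head size
#' and per-landmark isotropic Gaussian jitter (`noise_sd`, mm) models
#' individual variation and annotation error.
#'
#' @param group_sizes named cell counts (father_autism, mother_autism,
#'   father_comparison, mother_comparison).
#' @param age_means,age_sds per-cell age distribution parameters (years).
#' @param dimorphism_scale multiplier on the male-female template
#'   displacement for male subjects.
#' @param group_shift extra multiple of the dimorphism field applied to
#'   autism-parent subjects (the masculinization shift).
#' @param noise_sd per-landmark isotropic jitter, mm.
#' @param size_sd s.d. of the global scale factor.
#' @param age_slope masculinization per year of age (multiple of the
#'   dimorphism field).
#' @param seed integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(father_autism = 58L,
                                          mother_autism = 134L,
                                          father_comparison = 50L,
                                          mother_comparison = 113L),
                          age_means = NULL, age_sds = NULL,
                          dimorphism_scale = 1, group_shift = 0.08,
                          noise_sd = 1.7, size_sd = 0.04,
                          age_slope = 0.004, seed = 1L) {
  cells <- cohort_cells()
  if (length(group_sizes) != 4L || any(group_sizes < 0)) {
    stopf("'group_sizes' must be 4 non-negative counts")
  }
  cells$n <- as.integer(group_sizes)
  if (!is.null(age_means)) cells$age_mean <- age_means
  if (!is.null(age_sds)) cells$age_sd <- age_sds
  if (noise_sd < 0 || size_sd < 0) stopf("'noise_sd' and 'size_sd' must be >= 0")
  structure(list(cells = cells, dimorphism_scale = dimorphism_scale,
                 group_shift = group_shift, noise_sd = noise_sd,
                 size_sd = size_sd, age_slope = age_slope,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic landmark cohort
#'
#' @param config a [cohort_config()].
#' @param meshes if `TRUE`, also return each subject's face mesh (the
#'   template surface deformed onto the subject's landmarks).
#' @param mesh_resolution grid spacing (mm) of the template mesh used when
#'   `meshes = TRUE`.
#' @return List with `subjects` (data.frame: subject_id, sex, family_group,
#'   age), `landmarks` (named list of [landmark_set()]), and `meshes`
#'   (named list of [face_mesh()], or `NULL`).
#' @export
generate_cohort <- function(config = cohort_config(), meshes = FALSE,
                            mesh_resolution = 7) {
  stopifnot(inherits(config, "cohort_config"))
  cells <- config$cells
  if (sum(cells$n) == 0L) stopf("empty cohort: all cell counts are zero")
  tmpl <- face_template("female")$points
  D <- dimorphism_field()
  ctr <- colMeans(tmpl)

  out <- with_seed(config$seed, {
    subj <- list(); lms <- list()
    for (ci in seq_len(nrow(cells))) {
      n <- cells$n[ci]
      if (n == 0L) next
      age <- cells$age_mean[ci] + cells$age_sd[ci] * rnorm(n)
      age <- pmax(age, 18)
      for (i in seq_len(n)) {
        id <- sprintf("%s_%03d", cells$cell[ci], i)
        coefd <- config$dimorphism_scale * (cells$sex[ci] == "male") +
          config$group_shift * (cells$family_group[ci] == "autism_parent") +
          config$age_slope * (age[i] - 40)
        pts <- tmpl + coefd * D
        s <- 1 + config$size_sd * rnorm(1)
        pts <- sweep(sweep(pts, 2, ctr) * s, 2, ctr, FUN = "+")
        pts <- pts + matrix(rnorm(length(pts), sd = config$noise_sd),
                            nrow(pts), 3L)
        subj[[id]] <- data.frame(subject_id = id, sex = cells$sex[ci],
                                 family_group = cells$family_group[ci],
                                 age = age[i], stringsAsFactors = FALSE)
        lms[[id]] <- landmark_set(pts, id)
      }
    }
    list(subjects = do.call(rbind, c(subj, list(make.row.names = FALSE))),
         landmarks = lms)
  })
  if (meshes) {
    template <- fixture_mesh("face_template", resolution = mesh_resolution)
    out$meshes <- lapply(out$landmarks, mesh_from_landmarks, template = template)
  } else {
    out$meshes <- NULL
  }
  out
}

#' Write cohort metadata to CSV
#'
#' @param subjects data.frame with subject_id, sex, family_group, age.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(subjects, path) {
  write.csv(subjects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cohort metadata from CSV
#'
#' @param path CSV with columns subject_id, sex, family_group, age.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "family_group", "age")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stopf("metadata lacks column(s): %s",
                               paste(miss, collapse = ", "))
  bad_sex <- setdiff(unique(df$sex), c("male", "female"))
  if (length(bad_sex) > 0L) stopf("unknown sex label(s): %s",
                                  paste(bad_sex, collapse = ", "))
  bad_grp <- setdiff(unique(df$family_group),
                     c("autism_parent", "comparison_parent"))
  if (length(bad_grp) > 0L) stopf("unknown family_group label(s): %s",
                                  paste(bad_grp, collapse = ", "))
  if (any(df$age <= 0)) stopf("ages must be positive")
  df
}
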