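# Small geometric fixtures and data helpers shared across tests.

unit_square_mesh <- function() {
  face_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
            rbind(c(1, 2, 3), c(1, 3, 4)))
}

right_triangle_mesh <- function(a = 3, b = 4) {
  face_mesh(rbind(c(0, 0, 0), c(a, 0, 0), c(0, b, 0)),
            matrix(c(1, 2, 3), 1))
}

rotation_xyz <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# A bilaterally symmetric landmark layout on the z = 0 plane (x mirrored
# about 50), for symmetry tests on the plane fixture.
planar_symmetric_landmarks <- function() {
  pts <- rbind(
    Ft_l = c(20, 90, 0), Ft_r = c(80, 90, 0),
    Ex_l = c(25, 70, 0), Ex_r = c(75, 70, 0),
    En_l = c(40, 70, 0), En_r = c(60, 70, 0),
    N = c(50, 72, 0),
    Al_l = c(44, 50, 0), Al_r = c(56, 50, 0),
    Sbal_l = c(46, 47, 0), Sbal_r = c(54, 47, 0),
    Ch_l = c(35, 30, 0), Ch_r = c(65, 30, 0),
    Pg = c(50, 8, 0), Tr = c(50, 97, 0), G = c(50, 80, 0),
    Prn = c(50, 55, 0), Sn = c(50, 45, 0), Sto = c(50, 25, 0),
    Ls = c(50, 33, 0), Li = c(50, 18, 0))
  landmark_set(pts, "planar_sym")
}

# Two-class Gaussian data for discriminant tests.
two_class_data <- function(n_per_class, p, delta, seed) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p), ncol = p)
  X[seq_len(n_per_class), ] <- X[seq_len(n_per_class), ] +
    rep(delta, length.out = p)[col(X[seq_len(n_per_class), , drop = FALSE])]
  labels <- rep(c("a", "b"), each = n_per_class)
  colnames(X) <- paste0("f", seq_len(p))
  list(X = as.data.frame(X), labels = labels)
}

# Null-by-construction cohort configuration: no family-group effect on any
# variable and equal covariate distributions across cells, with the
# within-cell covariate loadings still active.
null_cohort_config <- function(sd_scale = 1) {
  ref <- facemasc::reference_cell_stats()
  means <- ref$means
  means[, "father_autism"] <- means[, "father_comparison"]
  means[, "mother_autism"] <- means[, "mother_comparison"]
  sds <- ref$sds * sd_scale
  cfg <- feature_table_config(means = means, sds = sds)
  cfg$cells$age_mean <- rep(41, 4)
  cfg$cells$age_sd <- rep(7, 4)
  cfg$cells$area_mean <- rep(35300, 4)
  cfg$cells$area_sd <- rep(3300, 4)
  cfg
}
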