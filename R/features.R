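#' The 26 Farkas facial distances
#'
#' The fixed registry of the 26 inter-landmark distances, each measured in
#' both Euclidean and geodesic (over-the-surface) form, giving 52 distance
#' features per face. Landmark codes use `_l`/`_r` suffixes for the paired
#' landmarks; `side` records whether a distance is a left or right variant,
#' a midline measure, or a bilateral span.
#'
#' @return A data.frame with columns `index`, `name`, `label`, `from`,
#'   `to`, `side`; one row per distance, in registry order.
#' @export
distance_definitions <- function() {
  def <- rbind(
    c("forehead_width",           "forehead width",            "Ft_l",   "Ft_r",   "bilateral-span"),
    c("outer_canthal_width",      "outer canthal width",       "Ex_l",   "Ex_r",   "bilateral-span"),
    c("eye_fissure_length_left",  "eye fissure length (left)", "Ex_l",   "En_l",   "left"),
    c("eye_fissure_length_right", "eye fissure length (right)","Ex_r",   "En_r",   "right"),
    c("inter_canthal_width",      "inter canthal width",       "En_l",   "En_r",   "bilateral-span"),
    c("mid_face_width_left",      "mid face width (left)",     "Ex_l",   "N",      "left"),
    c("mid_face_width_right",     "mid face width (right)",    "Ex_r",   "N",      "right"),
    c("nasal_root_height_left",   "nasal root height (left)",  "En_l",   "N",      "left"),
    c("nasal_root_height_right",  "nasal root height (right)", "En_r",   "N",      "right"),
    c("nose_width",               "nose width",                "Al_l",   "Al_r",   "bilateral-span"),
    c("alar_base_width",          "alar-base width",           "Sbal_l", "Sbal_r", "bilateral-span"),
    c("mouth_width",              "mouth width",               "Ch_l",   "Ch_r",   "bilateral-span"),
    c("mandible_height_left",     "mandible height (left)",    "Ch_l",   "Pg",     "left"),
    c("mandible_height_right",    "mandible height (right)",   "Ch_r",   "Pg",     "right"),
    c("upper_cheek_height_left",  "upper cheek height (left)", "Ex_l",   "Ch_l",   "left"),
    c("upper_cheek_height_right", "upper cheek height (right)","Ex_r",   "Ch_r",   "right"),
    c("forehead_height",          "forehead height",           "Tr",     "G",      "midline"),
    c("nasal_bridge_length",      "nasal bridge length",       "N",      "Prn",    "midline"),
    c("nose_height",              "nose height",               "N",      "Sn",     "midline"),
    c("upper_facial_height",      "upper facial height",       "N",      "Sto",    "midline"),
    c("nasal_tip_protrusion",     "nasal tip protrusion",      "Sn",     "Prn",    "midline"),
    c("upper_lip_height",         "upper lip height",          "Sn",     "Sto",    "midline"),
    c("philtrum_length",          "philtrum length",           "Sn",     "Ls",     "midline"),
    c("upper_vermillion_height",  "upper vermillion height",   "Ls",     "Sto",    "midline"),
    c("lower_vermillion_height",  "lower vermillion height",   "Sto",    "Li",     "midline"),
    c("mandible_height",          "mandible height",           "Sto",    "Pg",     "midline")
  )
  data.frame(index = seq_len(nrow(def)), name = def[, 1], label = def[, 2],
             from = def[, 3], to = def[, 4], side = def[, 5],
             stringsAsFactors = FALSE)
}

#' Names of the 52 distance features
#'
#' Euclidean features are prefixed `e_`, geodesic features `g_`.
#'
#' @return Character vector of length 52.
#' @export
feature_names <- function() {
  d <- distance_definitions()$name
  c(paste0("e_", d), paste0("g_", d))
}

#' Extract the distance feature vector for one subject
#'
#' Computes the 26 Euclidean inter-landmark distances, and — when a mesh is
#' supplied — the 26 geodesic distances over the mesh surface and the total
#' facial area. Without a mesh the geodesic block and the area are `NA`.
#'
#' @param landmarks a [landmark_set()].
#' @param mesh optional [face_mesh()] for this subject (the surface the
#'   landmarks lie on, within `snap_tol`).
#' @param edge_points geodesic graph density (see [geodesic_graph()]).
#' @param snap_tol landmark-to-surface snap tolerance in mm.
#' @return A one-row data.frame: `subject_id`, the 52 `e_`/`g_` features
#'   (mm) and `facial_area` (mm^2).
#' @export
extract_features <- function(landmarks, mesh = NULL, edge_points = 4L,
                             snap_tol = 2) {
  stopifnot(inherits(landmarks, "landmark_set"))
  defs <- distance_definitions()
  pts <- landmarks$points
  eu <- vapply(seq_len(nrow(defs)), function(i) {
    euclidean_distance(pts[defs$from[i], ], pts[defs$to[i], ])
  }, numeric(1))
  if (any(eu <= 0)) {
    stopf("subject '%s': coincident landmarks give a zero distance (%s)",
          landmarks$subject_id, defs$name[which(eu <= 0)[1L]])
  }
  if (!is.null(mesh)) {
    gg <- if (inherits(mesh, "geodesic_graph")) mesh else
      geodesic_graph(mesh, edge_points)
    gmat <- geodesic_pairs(gg, pts, snap_tol = snap_tol)
    ge <- vapply(seq_len(nrow(defs)), function(i) {
      gmat[defs$from[i], defs$to[i]]
    }, numeric(1))
    area <- facial_area(gg$mesh)
  } else {
    ge <- rep(NA_real_, nrow(defs))
    area <- NA_real_
  }
  out <- data.frame(subject_id = landmarks$subject_id,
                    rbind(c(eu, ge, area)), stringsAsFactors = FALSE)
  names(out) <- c("subject_id", paste0("e_", defs$name), paste0("g_", defs$name),
                  "facial_area")
  out
}

#' Extract features for a cohort
#'
#' @param landmarks list of [landmark_set()] objects.
#' @param meshes optional list of [face_mesh()] objects (same order), or
#'   `TRUE` to build each subject's mesh from the deformed face template.
#' @param template face-template mesh used when `meshes = TRUE`.
#' @inheritParams extract_features
#' @return A data.frame with one row per subject.
#' @export
extract_feature_table <- function(landmarks, meshes = NULL, template = NULL,
                                  edge_points = 4L, snap_tol = 2) {
  build <- isTRUE(meshes)
  if (build && is.null(template)) template <- fixture_mesh("face_template")
  rows <- lapply(seq_along(landmarks), function(i) {
    mesh <- if (build) mesh_from_landmarks(landmarks[[i]], template)
            else if (is.list(meshes)) meshes[[i]]
    extract_features(landmarks[[i]], mesh, edge_points = edge_points,
                     snap_tol = snap_tol)
  })
  do.call(rbind, rows)
}

#' Variables log-transformed before analysis
#'
#' The two positively skewed geodesic distances whose natural logarithm is
#' analysed in place of the raw value.
#'
#' @return Character vector of feature names.
#' @export
log_transformed_features <- function() {
  c("g_forehead_width", "g_mandible_height")
}

#' Apply the fixed analysis transformations to a feature table
#'
#' Replaces the geodesic forehead width and geodesic mandible height by
#' their natural logarithms; all other columns pass through unchanged. A
#' skewness audit (warning when |skewness| > 1 for an untransformed
#' numeric variable) is reported but never changes the transform set, so
#' the analysis pipeline is identical across datasets.
#'
#' @param features data.frame of extracted features (and possibly scores).
#' @param audit_skewness if `TRUE`, warn about skewed untransformed columns.
#' @return The transformed data.frame, with attribute `"transforms"`
#'   recording the columns that were log-transformed.
#' @export
transform_features <- function(features, audit_skewness = TRUE) {
  if (!is.data.frame(features) || nrow(features) == 0L) {
    stopf("'features' must be a non-empty data.frame")
  }
  logged <- character(0)
  for (v in log_transformed_features()) {
    if (!v %in% names(features)) next
    x <- features[[v]]
    if (any(!is.na(x) & x <= 0)) {
      stopf("non-positive value in log-transformed column '%s'", v)
    }
    features[[v]] <- log(x)
    logged <- c(logged, v)
  }
  if (audit_skewness) {
    num <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                   logged)
    for (v in num) {
      x <- features[[v]]
      x <- x[is.finite(x)]
      if (length(x) < 8L || sd(x) == 0) next
      sk <- mean((x - mean(x))^3) / sd(x)^3
      if (abs(sk) > 1) {
        warnf("variable '%s' is skewed (skewness %.2f) but is not in the fixed transform set",
              v, sk)
      }
    }
  }
  attr(features, "transforms") <- logged
  features
}
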