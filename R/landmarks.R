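#' The 21 Farkas landmark codes
#'
#' Codes follow Farkas' craniofacial anthropometry, with `_l`/`_r` suffixes
#' for paired (left/right) landmarks and bare codes for midline landmarks:
#' Ft = frontotemporale, Ex = exocanthion, En = endocanthion, N = nasion,
#' Al = alare, Sbal = subalare, Ch = cheilion, Pg = pogonion, Tr = trichion,
#' G = glabella, Prn = pronasale, Sn = subnasale, Sto = stomion,
#' Ls = labiale superius, Li = labiale inferius.
#'
#' @return Character vector of the 21 landmark codes, in canonical order.
#' @export
landmark_codes <- function() {
  c("Ft_l", "Ft_r", "Ex_l", "Ex_r", "En_l", "En_r", "N", "Al_l", "Al_r",
    "Sbal_l", "Sbal_r", "Ch_l", "Ch_r", "Pg", "Tr", "G", "Prn", "Sn",
    "Sto", "Ls", "Li")
}

# Paired codes (left/right); used to validate bilateral completeness.
paired_landmark_codes <- function() {
  c("Ft", "Ex", "En", "Al", "Sbal", "Ch")
}

#' Construct a landmark set
#'
#' A landmark set holds the 21 named 3D landmark coordinates (in mm) for one
#' face, stored as a 21 x 3 matrix with landmark codes as row names.
#'
#' @param points numeric 21 x 3 matrix of coordinates in mm; row names must
#'   be the codes from [landmark_codes()] (any order; rows are reordered).
#' @param subject_id subject identifier.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, subject_id = "subject") {
  codes <- landmark_codes()
  points <- as.matrix(points)
  if (ncol(points) != 3L) stopf("landmark points must have 3 columns (x, y, z)")
  rn <- rownames(points)
  if (is.null(rn)) stopf("landmark points must have landmark codes as row names")
  unknown <- setdiff(rn, codes)
  if (length(unknown) > 0L) {
    stopf("subject '%s': unknown landmark code(s): %s",
          subject_id, paste(unknown, collapse = ", "))
  }
  missing <- setdiff(codes, rn)
  if (length(missing) > 0L) {
    stopf("subject '%s': missing landmark(s): %s",
          subject_id, paste(missing, collapse = ", "))
  }
  if (anyDuplicated(rn)) stopf("subject '%s': duplicated landmark codes", subject_id)
  if (!all(is.finite(points))) stopf("subject '%s': non-finite coordinates", subject_id)
  points <- points[codes, , drop = FALSE]
  colnames(points) <- c("x", "y", "z")
  structure(list(subject_id = as.character(subject_id), points = points),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> subject '%s': 21 landmarks (mm)\n", x$subject_id))
  print(round(head(x$points, 4L), 2))
  cat("...\n")
  invisible(x)
}

#' Template landmark geometry
#'
#' Fixed 21-point adult-average templates in mm. The coordinate frame is
#' x lateral (+ right), y vertical (+ up), z anterior (+ out of the face).
#' The female template is tuned so that its Euclidean inter-landmark
#' distances approximate the comparison-group female means reported for
#' adult cohorts; the male template applies a global isotropic enlargement
#' about the landmark centroid plus local nose adjustments (wider alae,
#' more protrusive pronasale), reproducing typical adult sexual dimorphism.
#'
#' @param sex `"female"` or `"male"`.
#' @return A `landmark_set` for the requested template.
#' @export
face_template <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  codes <- landmark_codes()
  fem <- rbind(
    Ft_l   = c(-55.0,  70.0, -30.0),
    Ft_r   = c( 55.0,  70.0, -30.0),
    Ex_l   = c(-44.0,  29.0,   6.0),
    Ex_r   = c( 44.0,  29.0,   6.0),
    En_l   = c(-16.5,  30.0,  21.0),
    En_r   = c( 16.5,  30.0,  21.0),
    N      = c(  0.0,  32.0,  25.0),
    Al_l   = c( -8.8, -11.0,  30.0),
    Al_r   = c(  8.8, -11.0,  30.0),
    Sbal_l = c( -6.5, -14.5,  28.5),
    Sbal_r = c(  6.5, -14.5,  28.5),
    Ch_l   = c(-25.0, -38.0,  14.0),
    Ch_r   = c( 25.0, -38.0,  14.0),
    Pg     = c(  0.0, -68.0,  24.0),
    Tr     = c(  0.0,  88.0,   4.0),
    G      = c(  0.0,  48.0,  28.0),
    Prn    = c(  0.0,  -9.0,  43.5),
    Sn     = c(  0.0, -14.0,  28.0),
    Sto    = c(  0.0, -36.6,  26.0),
    Ls     = c(  0.0, -27.0,  29.0),
    Li     = c(  0.0, -45.0,  26.5)
  )
  colnames(fem) <- c("x", "y", "z")
  fem <- fem[codes, , drop = FALSE]
  if (sex == "female") return(landmark_set(fem, "template_female"))
  landmark_set(fem + dimorphism_field(), "template_male")
}

#' Sexual-dimorphism displacement field
#'
#' The fixed per-landmark 3D displacement (mm) that carries the female
#' template onto the male template: a 1.08 isotropic enlargement about the
#' landmark centroid, an extra 10% lateral widening of the alae, and an
#' extra 2 mm anterior displacement of the pronasale along the
#' subnasale-to-pronasale direction. Sex enters the synthetic generator as a
#' multiple of this field; the family-group masculinization shift adds a
#' further fraction of the same field.
#'
#' @return 21 x 3 numeric matrix (mm), rows named by landmark code.
#' @export
dimorphism_field <- function() {
  fem <- face_template("female")$points
  ctr <- colMeans(fem)
  male <- sweep(sweep(fem, 2, ctr) * 1.08, 2, ctr, FUN = "+")
  # wider nose: extra lateral displacement of the alare points
  male[c("Al_l", "Al_r"), "x"] <- male[c("Al_l", "Al_r"), "x"] * 1.016
  # more protrusive nasal tip: push Prn along the Sn -> Prn direction
  dir <- male["Prn", ] - male["Sn", ]
  dir <- dir / sqrt(sum(dir^2))
  male["Prn", ] <- male["Prn", ] + 2.0 * dir
  male - fem
}

#' Read landmark coordinate files
#'
#' Landmark CSVs are long-format with columns `subject_id`, `landmark_code`,
#' `x`, `y`, `z` (coordinates in mm), 21 rows per subject.
#'
#' @param path CSV file path.
#' @return A named list of [landmark_set()] objects, one per subject.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stopf("landmark file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "landmark_code", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stopf("landmark file '%s' lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  }
  out <- lapply(split(df, df$subject_id), function(d) {
    m <- as.matrix(d[, c("x", "y", "z")])
    rownames(m) <- d$landmark_code
    landmark_set(m, d$subject_id[1L])
  })
  ids <- unique(df$subject_id)
  out[as.character(ids)]
}

#' Write landmark coordinate files
#'
#' @param landmarks a `landmark_set` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  if (inherits(landmarks, "landmark_set")) landmarks <- list(landmarks)
  rows <- lapply(landmarks, function(ls) {
    data.frame(subject_id = ls$subject_id,
               landmark_code = rownames(ls$points),
               x = ls$points[, 1], y = ls$points[, 2], z = ls$points[, 3],
               row.names = NULL)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Apply a rigid motion (and optional uniform scale) to a landmark set.
transform_landmarks <- function(ls, rotation = diag(3), translation = c(0, 0, 0),
                                scale = 1) {
  pts <- scale * (ls$points %*% t(rotation))
  pts <- sweep(pts, 2, translation, FUN = "+")
  rownames(pts) <- rownames(ls$points)
  landmark_set(pts, ls$subject_id)
}
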