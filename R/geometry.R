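# Geometric kernels for the radiological indices.
#
# Conventions (used throughout the package):
#   * canonical right-anterior-superior (RAS) frame, coordinates in mm;
#   * axial slice = constant superior (z) coordinate, slices ordered
#     caudocranial (ascending index);
#   * the coronal plane for the callosal angle is orthogonal to the AC-PC
#     segment and passes through the posterior commissure (PC);
#   * angles are held in full double precision and rounded only at
#     presentation (1 decimal).

#' Landmark triple defining an angle
#'
#' @param vertex,arm_a,arm_b 3D points in mm (numeric length 3).
#' @param plane `"axial"` or `"coronal"`.
#' @param slice slice index the landmarks were placed on.
#' @param plane_coord the constant coordinate (mm) of the declared plane.
#' @param tol_mm in-plane tolerance (half a voxel, default 0.5).
#' @param meta optional list (e.g. AC/PC points for coronal planes).
#' @export
landmark_angle <- function(vertex, arm_a, arm_b, plane = c("axial", "coronal"),
                           slice = NA_integer_, plane_coord = NULL,
                           tol_mm = 0.5, meta = list()) {
  plane <- match.arg(plane)
  pts <- rbind(vertex, arm_a, arm_b)
  stopifnot(ncol(pts) == 3L)
  if (any(apply(pts[2:3, , drop = FALSE], 1L,
                function(p) sqrt(sum((p - vertex)^2))) == 0)) {
    stop("arm points must be distinct from the vertex")
  }
  ax <- if (plane == "axial") 3L else 2L
  if (!is.null(plane_coord) && any(abs(pts[, ax] - plane_coord) > tol_mm)) {
    stop("landmarks lie off the declared ", plane, " plane by more than ",
         tol_mm, " mm")
  }
  structure(list(vertex = as.double(vertex), arm_a = as.double(arm_a),
                 arm_b = as.double(arm_b), plane = plane, slice = slice,
                 plane_coord = plane_coord, meta = meta),
            class = "landmark_angle")
}

#' One index measurement
#'
#' @param index one of `"EI"`, `"BCI"`, `"CA"`, `"SA"`.
#' @param value ratio (EI/BCI) or degrees (CA/SA).
#' @param slice slice index used.
#' @param landmarks landmark record (landmark_angle or width pairs).
#' @param rater free-text rater identifier.
#' @param warnings character vector of recorded warnings.
#' @export
angle_measurement <- function(index, value, slice = NA_integer_,
                              landmarks = NULL, rater = "auto",
                              warnings = character()) {
  index <- match.arg(index, c("EI", "BCI", "CA", "SA"))
  if (index %in% c("EI", "BCI")) {
    if (!(value > 0 && value <= 1)) stop(index, " must lie in (0, 1]")
  } else {
    if (!(value > 0 && value < 180)) stop(index, " must lie in (0, 180) degrees")
  }
  structure(list(index = index, value = as.double(value), slice = slice,
                 landmarks = landmarks, rater = rater, warnings = warnings),
            class = "angle_measurement")
}

#' @export
format.angle_measurement <- function(x, ...) {
  unit <- if (x$index %in% c("CA", "SA")) "°" else ""
  sprintf("%s = %.1f%s (slice %s)", x$index, x$value, unit,
          as.character(x$slice))
}

#' @export
print.angle_measurement <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Angle at a vertex between two rays
#'
#' Returns the angle in degrees at `vertex` between rays vertex->arm_a and
#' vertex->arm_b, in (0, 180\]. Collinear opposite rays give exactly 180;
#' coincident ray directions give 0 with a warning (degenerate landmark).
#'
#' @param vertex,arm_a,arm_b points (length 2 or 3).
#' @return angle in degrees.
#' @export
angle_between <- function(vertex, arm_a, arm_b) {
  u <- as.double(arm_a) - as.double(vertex)
  v <- as.double(arm_b) - as.double(vertex)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("arm point coincides with the vertex")
  # atan2 form is numerically stable near 0 and 180 degrees
  u <- u / nu; v <- v / nv
  ang <- rad2deg(2 * atan2(sqrt(sum((u - v)^2)), sqrt(sum((u + v)^2))))
  if (ang == 0) warning("degenerate angle: rays coincide")
  ang
}

#' Evans' index
#'
#' Ratio of the maximal frontal-horn width of the lateral ventricles to the
#' maximal internal cranial diameter, both on the same axial slice. Values
#' >= 0.30 indicate ventriculomegaly.
#'
#' @param frontal_horn_width mm.
#' @param inner_cranial_diameter mm.
#' @return the ratio, in (0, 1].
#' @export
evans_index <- function(frontal_horn_width, inner_cranial_diameter) {
  if (!is.finite(inner_cranial_diameter) || inner_cranial_diameter <= 0) {
    stop("inner cranial diameter must be positive")
  }
  if (!is.finite(frontal_horn_width) || frontal_horn_width < 0) {
    stop("frontal horn width must be non-negative")
  }
  if (frontal_horn_width > inner_cranial_diameter) {
    stop("implausible geometry: frontal horns wider than the cranium")
  }
  r <- frontal_horn_width / inner_cranial_diameter
  if (r == 1) warning("implausible geometry: horn width equals cranial diameter")
  r
}

#' Bicaudate index
#'
#' Intercaudate ventricular width over the cranial width at the same level;
#' >= 0.25 indicates ventriculomegaly.
#'
#' @param intercaudate_width mm.
#' @param cranial_width_at_level mm.
#' @export
bicaudate_index <- function(intercaudate_width, cranial_width_at_level) {
  if (!is.finite(cranial_width_at_level) || cranial_width_at_level <= 0) {
    stop("cranial width must be positive")
  }
  if (!is.finite(intercaudate_width) || intercaudate_width < 0) {
    stop("intercaudate width must be non-negative")
  }
  if (intercaudate_width > cranial_width_at_level) {
    stop("implausible geometry: ventricles wider than the cranium")
  }
  intercaudate_width / cranial_width_at_level
}

#' Callosal angle from roof landmarks
#'
#' The callosal angle (CA) is subtended by the roofs of the two lateral
#' ventricles on a coronal plane through the PC, orthogonal to the AC-PC
#' line. The landmark record must be coronal and should carry `meta$pc`
#' (the PC point); a plane more than `pc_tol_mm` from the PC is recorded as
#' a warning on the measurement rather than rejected.
#'
#' @param roof_landmarks a [landmark_angle()] on a coronal plane; vertex at
#'   the roof apex, arms along the two roofs.
#' @param pc_tol_mm allowed plane-to-PC distance (default 2).
#' @param rater rater tag.
#' @return an [angle_measurement()] with index `"CA"`.
#' @export
measure_ca <- function(roof_landmarks, pc_tol_mm = 2, rater = "auto") {
  stopifnot(inherits(roof_landmarks, "landmark_angle"))
  if (roof_landmarks$plane != "coronal") {
    stop("CA landmarks must lie on a coronal plane")
  }
  warns <- character()
  pc <- roof_landmarks$meta$pc
  if (!is.null(pc) && !is.null(roof_landmarks$plane_coord)) {
    off <- abs(roof_landmarks$plane_coord - pc[2L])
    if (off > pc_tol_mm) {
      warns <- c(warns, sprintf("coronal plane is %.1f mm from the PC", off))
    }
  }
  val <- angle_between(roof_landmarks$vertex, roof_landmarks$arm_a,
                       roof_landmarks$arm_b)
  angle_measurement("CA", val, slice = roof_landmarks$slice,
                    landmarks = roof_landmarks, rater = rater,
                    warnings = warns)
}

#' Select the splenial-angle slice
#'
#' Scrolling caudocranially, returns the first (lowest-index) axial slice on
#' which the red-encoded callosal body is complete. "Complete body" is
#' operationalised as: within a midline strip of half-width `strip_mm`, the
#' red-dominant callosal voxels form a connected component whose
#' anteroposterior extent reaches at least `extent_frac` of the maximum such
#' extent over all slices. When several consecutive slices qualify (the
#' thick-body case), the caudal-most is used.
#'
#' @param cfa a `color_fa_volume` (e1 used for red dominance).
#' @param callosal_mask logical array, the callosal candidate mask.
#' @param midline_x left-right coordinate (mm) of the midsagittal plane;
#'   `NULL` (default) detects it from the mask by mirror symmetry.
#' @param strip_mm midline strip half-width in mm (default 4).
#' @param extent_frac completeness fraction (default 0.9).
#' @return the slice index (1-based, caudocranial).
#' @export
select_sa_slice <- function(cfa, callosal_mask, midline_x = NULL,
                            strip_mm = 4, extent_frac = 0.9) {
  stopifnot(inherits(cfa, "color_fa_volume"))
  mask <- array(as.logical(callosal_mask), dim = cfa$dim)
  if (!any(mask)) stop("no complete callosal body: empty callosal mask")
  if (is.null(midline_x)) {
    midline_x <- detect_midline(mask, spacing = cfa$spacing)
  }
  ax <- grid_axes(cfa$dim, cfa$spacing)
  red <- cfa$e1_defined &
    abs(cfa$e1[, 1]) > abs(cfa$e1[, 2]) & abs(cfa$e1[, 1]) > abs(cfa$e1[, 3])
  strip_cols <- which(abs(ax[[1]] - midline_x) <= strip_mm)
  if (!length(strip_cols)) stop("midline strip contains no voxels")
  nz <- cfa$dim[3L]
  extent <- rep(0, nz)
  vy <- cfa$spacing[2L]
  redm <- mask & array(red, dim = cfa$dim)
  for (z in seq_len(nz)) {
    sl <- redm[strip_cols, , z, drop = FALSE][, , 1, drop = TRUE]
    sl <- matrix(sl, nrow = length(strip_cols))
    idx <- which(sl)
    if (!length(idx)) next
    labs <- label_components(idx, dim(sl))
    rows2 <- arrayInd(idx, dim(sl))[, 2L]
    ext_by_comp <- tapply(rows2, labs, function(r) (max(r) - min(r) + 1L) * vy)
    extent[z] <- max(ext_by_comp)
  }
  emax <- max(extent)
  if (emax <= 0) stop("no complete callosal body: no red callosal voxels in strip")
  ok <- which(extent >= extent_frac * emax)
  if (!length(ok)) stop("no complete callosal body")
  min(ok)
}

#' Splenial angle from pivot and limb directions
#'
#' The splenial angle (SA) is pivoted over the midline on the chosen axial
#' color-FA slice, with its arms aligned along the centres of the forceps
#' major limbs (which point posteriorly on opposite sides of the midline).
#'
#' @param slice axial slice index the measurement was made on.
#' @param pivot length-2 (x, y) or length-3 point in mm.
#' @param limb_dirs 2 x 2 or 2 x 3 matrix; rows are the two limb ray
#'   directions from the pivot.
#' @param midline_x midsagittal x coordinate in mm.
#' @param midline_tol_mm allowed pivot-to-midline distance (default 2).
#' @param rater rater tag.
#' @return an [angle_measurement()] with index `"SA"`.
#' @export
measure_sa <- function(slice, pivot, limb_dirs, midline_x = 0,
                       midline_tol_mm = 2, rater = "auto") {
  pivot <- as.double(pivot)
  limb_dirs <- as.matrix(limb_dirs)
  stopifnot(nrow(limb_dirs) == 2L)
  if (abs(pivot[1L] - midline_x) > midline_tol_mm) {
    stop(sprintf("pivot is %.1f mm off the midline (tolerance %.1f mm)",
                 abs(pivot[1L] - midline_x), midline_tol_mm))
  }
  if (any(limb_dirs[, 2L] >= 0)) {
    stop("limb rays must point posteriorly")
  }
  side <- sign(limb_dirs[, 1L])
  if (side[1L] == side[2L]) {
    stop("limb rays lie on the same side of the midline")
  }
  val <- angle_between(c(pivot[1:2], 0),
                       c(pivot[1:2] + limb_dirs[1L, 1:2], 0),
                       c(pivot[1:2] + limb_dirs[2L, 1:2], 0))
  angle_measurement("SA", val, slice = slice,
                    landmarks = list(pivot = pivot, limb_dirs = limb_dirs,
                                     midline_x = midline_x),
                    rater = rater)
}

#' Callosal-angle sensitivity to coronal plane mal-positioning
#'
#' Re-measures the CA of a digital phantom on coronal planes perturbed by
#' sagittal tilt (acute/obtuse mal-angulation about the left-right axis) and
#' by axial rotation (right-left mal-rotation about the superior axis). For
#' each perturbation the plane through the PC is resampled against the
#' phantom's continuous ventricle model, roof landmarks are re-derived by
#' fitting lines to the per-column roof points on each side, and the CA is
#' recomputed.
#'
#' @param phantom an `sa_phantom` (see [make_phantom()]).
#' @param sagittal_tilts degrees, within +/- 15.
#' @param axial_rotations degrees, within +/- 15.
#' @param step_mm in-plane sampling step (default 0.5).
#' @return data.frame with columns `kind` ("sagittal_tilt"/"axial_rotation"),
#'   `degrees`, `ca`, `flagged`.
#' @export
ca_tilt_experiment <- function(phantom, sagittal_tilts = seq(-10, 10, 2.5),
                               axial_rotations = seq(-10, 10, 2.5),
                               step_mm = 0.5) {
  stopifnot(inherits(phantom, "sa_phantom"))
  if (any(abs(c(sagittal_tilts, axial_rotations)) > 15)) {
    stop("perturbations must stay within +/- 15 degrees")
  }
  rows <- list()
  for (t in sagittal_tilts) {
    rows[[length(rows) + 1L]] <-
      c(kind = "sagittal_tilt", degrees = t,
        phantom_plane_ca(phantom, tilt_deg = t, rot_deg = 0, step_mm = step_mm))
  }
  for (r in axial_rotations) {
    rows[[length(rows) + 1L]] <-
      c(kind = "axial_rotation", degrees = r,
        phantom_plane_ca(phantom, tilt_deg = 0, rot_deg = r, step_mm = step_mm))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(kind = r[["kind"]], degrees = as.double(r[["degrees"]]),
               ca = as.double(r[["ca"]]), flagged = as.logical(r[["flagged"]]))
  }))
  rownames(out) <- NULL
  out
}
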