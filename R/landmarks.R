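# Automated splenial-angle landmarking on color-FA volumes.
#
# The chain emulates what a rater does at the workstation: isolate the
# red-encoded commissural callosal candidate, scroll caudocranially to the
# first slice with a complete callosal body, drop the angle pivot on the
# midline over the splenium, and align the arms along the forceps-major
# limbs. Every constant is exposed as an argument and recorded in the audit
# trail; there is no hidden randomness, so repeated runs are bit-identical.

#' Red-dominant commissural mask
#'
#' Voxels with FA at or above `fa_threshold` whose principal eigenvector is
#' dominated by the left-right component (red on the DEC map). The largest
#' 6-connected component crossing the midline is retained as the callosal
#' candidate.
#'
#' @param cfa a `color_fa_volume`.
#' @param fa_threshold FA floor (default 0.2).
#' @param midline_x midsagittal coordinate in mm; `NULL` detects it.
#' @return object of class `commissural_mask`: list with logical `mask`,
#'   `fa_threshold`, `rule`, `midline_x`, grid metadata.
#' @export
commissural_mask <- function(cfa, fa_threshold = 0.2, midline_x = NULL) {
  stopifnot(inherits(cfa, "color_fa_volume"))
  red <- cfa$fa >= fa_threshold & cfa$e1_defined &
    abs(cfa$e1[, 1]) > abs(cfa$e1[, 2]) & abs(cfa$e1[, 1]) > abs(cfa$e1[, 3])
  if (!any(red)) stop("no commissural voxels at FA threshold ", fa_threshold)
  if (is.null(midline_x)) {
    fg <- array(cfa$fa > 0, dim = cfa$dim)
    midline_x <- detect_midline(fg, spacing = cfa$spacing)
  }
  idx <- which(red)
  labs <- label_components(idx, cfa$dim)
  xs <- grid_axes(cfa$dim, cfa$spacing)[[1]][arrayInd(idx, cfa$dim)[, 1L]]
  half <- cfa$spacing[1L] / 2
  crosses <- tapply(xs, labs, function(x) {
    any(x < midline_x + half) && any(x > midline_x - half)
  })
  sizes <- tabulate(labs)
  cand <- as.integer(names(crosses))[crosses]
  if (!length(cand)) {
    warning("no red component crosses the midline; using largest component")
    cand <- seq_along(sizes)
  }
  keep <- cand[which.max(sizes[cand])]
  mask <- array(FALSE, cfa$dim)
  mask[idx[labs == keep]] <- TRUE
  structure(list(mask = mask, fa_threshold = fa_threshold,
                 rule = "red-dominant", midline_x = midline_x,
                 dim = cfa$dim, spacing = cfa$spacing),
            class = "commissural_mask")
}

#' Detect the midsagittal plane
#'
#' Finds the left-right coordinate that maximises the mirror-symmetry
#' overlap of the foreground mask, searched in half-voxel steps within
#' `search_mm` of the foreground's geometric centre. If the best symmetry
#' score (overlap fraction) falls below `floor`, the geometric centre is
#' returned with a warning.
#'
#' @param volume logical 3D array (foreground mask), or a `color_fa_volume`
#'   (foreground = FA > 0).
#' @param spacing voxel spacing mm (taken from the volume if available).
#' @param search_mm half-width of the search window (default 10).
#' @param floor minimum acceptable symmetry score (default 0.5).
#' @return midsagittal x coordinate in mm (centred grid convention).
#' @export
detect_midline <- function(volume, spacing = NULL, search_mm = 10,
                           floor = 0.5) {
  if (inherits(volume, "color_fa_volume")) {
    spacing <- volume$spacing
    volume <- array(volume$fa > 0, dim = volume$dim)
  }
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  spacing <- spacing %||% c(1, 1, 1)
  if (!any(volume)) stop("empty volume: cannot detect midline")
  dims <- dim(volume)
  nx <- dims[1L]
  ax <- grid_axes(dims, spacing)[[1]]
  M <- matrix(as.logical(volume), nrow = nx)
  colmass <- rowSums(M)
  centre <- sum(ax * colmass) / sum(colmass)
  sx <- spacing[1L]
  # candidate mirror centres in column-index units, half-voxel steps
  cand_idx <- seq(1, nx, by = 0.5)
  cand_mm <- ax[1L] + (cand_idx - 1) * sx
  cand_idx <- cand_idx[abs(cand_mm - centre) <= search_mm]
  cand_mm <- ax[1L] + (cand_idx - 1) * sx
  if (!length(cand_idx)) return(centre)
  total <- sum(colmass)
  score <- vapply(cand_idx, function(cc) {
    i <- seq_len(nx)
    j <- round(2 * cc - i)
    ok <- j >= 1 & j <= nx & i < j
    if (!any(ok)) return(0)
    2 * sum(M[i[ok], , drop = FALSE] & M[j[ok], , drop = FALSE]) / total
  }, numeric(1))
  best <- which.max(score)
  if (score[best] < floor) {
    warning(sprintf("midline symmetry score %.2f below floor %.2f; %s",
                    score[best], floor, "falling back to geometric centre"))
    return(centre)
  }
  cand_mm[best]
}

#' Fit the forceps-major limb rays on the splenial-angle slice
#'
#' Grid-searches the pivot along the midline (1 mm steps over the mask's
#' midline extent). For each candidate pivot, the limb voxels are the mask
#' voxels posterior to the pivot within a radial annulus, split left/right
#' of the midline; each limb's ray direction is the principal axis of its
#' voxel coordinates, oriented posteriorly. The pivot minimising the summed
#' orthogonal distance of limb voxels to the rays through it is retained.
#'
#' @param cmask a [commissural_mask()].
#' @param slice axial slice index (from [select_sa_slice()]).
#' @param midline_x midline coordinate mm (default: the mask's own).
#' @param annulus_mm radial window around the pivot, `c(inner, outer)`
#'   (default `c(5, 30)`).
#' @param pivot_step_mm pivot grid step (default 1).
#' @param min_limb_voxels minimum voxels per limb (default 10).
#' @param strip_mm midline strip half-width defining the pivot search extent
#'   (default 4).
#' @return list with `pivot` (x, y mm), `dir_left`, `dir_right` (unit,
#'   posterior-pointing), `residual` (mean orthogonal distance, mm),
#'   `n_left`, `n_right`.
#' @export
fit_forceps_rays <- function(cmask, slice, midline_x = NULL,
                             annulus_mm = c(5, 30), pivot_step_mm = 1,
                             min_limb_voxels = 10, strip_mm = 4) {
  stopifnot(inherits(cmask, "commissural_mask"))
  midline_x <- midline_x %||% cmask$midline_x
  sl <- cmask$mask[, , slice]
  idx <- which(sl)
  if (!length(idx)) stop("limb too sparse: empty mask on the chosen slice")
  ax <- grid_axes(cmask$dim, cmask$spacing)
  co <- arrayInd(idx, dim(sl))
  px <- ax[[1]][co[, 1L]]
  py <- ax[[2]][co[, 2L]]
  # pivot candidates span the mask's midline extent: voxels actually
  # straddling the midsagittal line (within one voxel), not the wider strip,
  # so that near-parallel limbs cannot drag the pivot toward their tips
  pivot_strip <- max(cmask$spacing[1L] * 0.75, 1)
  near_mid <- abs(px - midline_x) <= pivot_strip
  if (!any(near_mid)) near_mid <- abs(px - midline_x) <= strip_mm
  if (!any(near_mid)) stop("limb too sparse: no mask voxels near the midline")
  yr <- range(py[near_mid])
  cand_y <- seq(yr[1L], yr[2L], by = pivot_step_mm)
  inner2 <- annulus_mm[1L]^2; outer2 <- annulus_mm[2L]^2
  best <- NULL
  for (yc in cand_y) {
    dx <- px - midline_x
    dy <- py - yc
    r2 <- dx^2 + dy^2
    post <- dy < 0 & r2 >= inner2 & r2 <= outer2
    li <- post & dx < 0
    ri <- post & dx > 0
    if (sum(li) < min_limb_voxels || sum(ri) < min_limb_voxels) next
    fit_side <- function(sel) {
      P <- cbind(dx[sel], dy[sel])
      ctr <- colMeans(P)
      C <- crossprod(sweep(P, 2L, ctr)) / nrow(P)
      ev <- eigen(C, symmetric = TRUE)
      d <- ev$vectors[, 1L]
      if (sum(d * ctr) < 0) d <- -d          # point from pivot toward limb
      resid <- abs(P[, 1L] * d[2L] - P[, 2L] * d[1L])
      list(dir = d, cost = sum(resid), n = nrow(P))
    }
    L <- fit_side(li); R <- fit_side(ri)
    cost <- L$cost + R$cost
    if (is.null(best) || cost < best$cost - 1e-12) {
      best <- list(pivot = c(midline_x, yc), dir_left = L$dir,
                   dir_right = R$dir, cost = cost, n_left = L$n, n_right = R$n)
    }
  }
  if (is.null(best)) {
    stop("limb too sparse: fewer than ", min_limb_voxels,
         " voxels on a limb for every candidate pivot")
  }
  list(pivot = best$pivot, dir_left = best$dir_left,
       dir_right = best$dir_right,
       residual = best$cost / (best$n_left + best$n_right),
       n_left = best$n_left, n_right = best$n_right)
}

#' Fully automated splenial angle
#'
#' Composes [commissural_mask()], [select_sa_slice()], [detect_midline()],
#' [fit_forceps_rays()] and [measure_sa()] into a deterministic automated SA
#' measurement. All intermediate choices are recorded in the audit trail
#' (`attr(result, "audit")`), and stage failures are re-raised tagged with
#' the stage name.
#'
#' @param cfa a `color_fa_volume`.
#' @param fa_threshold FA floor for the commissural mask (default 0.2).
#' @param annulus_mm limb annulus (default `c(5, 30)`).
#' @param pivot_step_mm pivot grid step (default 1).
#' @param min_limb_voxels limb voxel floor (default 10).
#' @param strip_mm midline strip half-width (default 4).
#' @param extent_frac slice completeness fraction (default 0.9).
#' @return an [angle_measurement()] with index `"SA"` and an `"audit"`
#'   attribute.
#' @export
auto_sa <- function(cfa, fa_threshold = 0.2, annulus_mm = c(5, 30),
                    pivot_step_mm = 1, min_limb_voxels = 10, strip_mm = 4,
                    extent_frac = 0.9) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("auto_sa stage [", name, "]: ", conditionMessage(e), call. = FALSE)
    })
  }
  cm <- stage("commissural_mask",
              commissural_mask(cfa, fa_threshold = fa_threshold))
  mid <- stage("detect_midline", detect_midline(cfa))
  slc <- stage("select_sa_slice",
               select_sa_slice(cfa, cm$mask, midline_x = mid,
                               strip_mm = strip_mm,
                               extent_frac = extent_frac))
  rays <- stage("fit_forceps_rays",
                fit_forceps_rays(cm, slc, midline_x = mid,
                                 annulus_mm = annulus_mm,
                                 pivot_step_mm = pivot_step_mm,
                                 min_limb_voxels = min_limb_voxels,
                                 strip_mm = strip_mm))
  m <- stage("measure_sa",
             measure_sa(slc, rays$pivot, rbind(rays$dir_left, rays$dir_right),
                        midline_x = mid))
  attr(m, "audit") <- list(
    fa_threshold = fa_threshold, midline_x = mid, slice = slc,
    pivot = rays$pivot, dir_left = rays$dir_left, dir_right = rays$dir_right,
    residual_mm = rays$residual, n_left = rays$n_left, n_right = rays$n_right,
    annulus_mm = annulus_mm, pivot_step_mm = pivot_step_mm,
    strip_mm = strip_mm, extent_frac = extent_frac)
  m
}

#' Serialise an automated SA audit trail to JSON
#'
#' @param measurement result of [auto_sa()].
#' @param path output path.
#' @export
write_sa_audit <- function(measurement, path) {
  audit <- attr(measurement, "audit")
  if (is.null(audit)) stop("measurement carries no audit trail")
  audit$sa_degrees <- measurement$value
  jsonlite::write_json(audit, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
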