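# Parametric 3D digital phantoms with known ground-truth indices.
#
# The phantom is a stylised head in the canonical RAS frame: an ellipsoidal
# skull, two lateral ventricles whose tented roofs realise a prescribed
# callosal angle at the PC coronal plane and whose frontal horns realise a
# prescribed Evans' index, and a red-encoded callosal complex (genu, body
# band, splenium bridge, forceps minor, and forceps-major limbs meeting at a
# midline pivot with opening angle exactly `true_sa`). The ventriculomegaly
# factor `v >= 1` jointly widens the ventricles (EI up) and steepens the
# roofs (CA down), mimicking the coupled deformation seen in hydrocephalus.
#
# Tissue diffusivities (mm^2/s): callosum prolate (1.7, 0.3, 0.3)e-3 along
# the local fibre direction, CSF isotropic 3.0e-3, brain tissue isotropic
# 0.8e-3. The color-FA volume is generated analytically (the fast path); a
# tensor volume and simulated DWI are available on request.

#' Phantom specification
#'
#' @param dim grid dimensions (default `c(180, 180, 150)`).
#' @param spacing voxel spacing mm (default 1 mm isotropic).
#' @param skull_semiaxes ellipsoid semi-axes mm (default `c(70, 85, 60)`).
#' @param v ventriculomegaly factor, `>= 1`.
#' @param true_sa prescribed splenial angle, degrees in (0, 180).
#' @param septum_mm half-gap between the ventricles at the midline.
#' @param horn_mm frontal-horn half-width at `v = 1` beyond the septum.
#' @param ca_at_v1 callosal angle at `v = 1`, degrees.
#' @param ca_exponent exponent linking `v` to roof steepening (the derived
#'   `true_ca = 2 atan(tan(ca_at_v1 / 2) / v^ca_exponent)`).
#' @param noise_sigma additive Gaussian noise SD for simulated DWI.
#' @param diffusivities list with `callosum` (3 eigenvalues), `csf`, `tissue`.
#' @return object of class `phantom_spec` with derived fields `true_ca`,
#'   `true_ei`, `ac`, `pc`.
#' @export
phantom_spec <- function(dim = c(180L, 180L, 150L), spacing = c(1, 1, 1),
                         skull_semiaxes = c(70, 85, 60), v = 1,
                         true_sa = 75.7, septum_mm = 7, horn_mm = 10.5,
                         ca_at_v1 = 112, ca_exponent = 1.5, noise_sigma = 0,
                         diffusivities = list(
                           callosum = c(1.7, 0.3, 0.3) * 1e-3,
                           csf = 3.0e-3, tissue = 0.8e-3)) {
  if (v < 1) stop("ventriculomegaly factor v must be >= 1")
  if (!(true_sa > 0 && true_sa < 180)) stop("true_sa must lie in (0, 180)")
  true_ca <- rad2deg(2 * atan(tan(deg2rad(ca_at_v1) / 2) / v^ca_exponent))
  if (!(true_ca > 0 && true_ca < 180)) stop("derived true_ca out of (0, 180)")
  horn_half <- septum_mm + horn_mm * v
  if (horn_half >= skull_semiaxes[1L] - 3) {
    stop("ventricles exit the skull: horn half-width ", horn_half,
         " mm vs skull semi-axis ", skull_semiaxes[1L], " mm")
  }
  true_ei <- horn_half / skull_semiaxes[1L]
  spec <- structure(list(
    dim = as.integer(dim), spacing = as.double(spacing),
    skull_semiaxes = as.double(skull_semiaxes), v = v, true_sa = true_sa,
    true_ca = true_ca, true_ei = true_ei, septum_mm = septum_mm,
    horn_mm = horn_mm, ca_at_v1 = ca_at_v1, ca_exponent = ca_exponent,
    noise_sigma = noise_sigma, diffusivities = diffusivities,
    # anatomy constants (mm, RAS, grid centred on the skull centre)
    ac = c(0, 25, 0), pc = c(0, -10, 0),
    vent_floor = -18, roof_apex0 = 12 + 6 * (v - 1), roof_slope_y = 0.7,
    horn_y = c(18, 32), horn_z = c(-10, 10), body_y = c(-40, 20),
    body_frac = 0.85, pivot_y = -18, limb_len = 32, limb_halfwidth = 1.8,
    cc_z_lo = NA_real_, cc_z_hi = NA_real_, fibre_blend_deg = 30),
    class = "phantom_spec")
  spec$cc_z_lo <- spec$roof_apex0 + 4          # caudal edge of complete body
  spec$cc_z_hi <- spec$cc_z_lo + 6
  spec$cc_z_splenium_lo <- spec$cc_z_lo - 8    # splenium extends caudally
  # limb tips must stay inside the skull
  alpha <- deg2rad(true_sa / 2)
  tip <- c(spec$limb_len * sin(alpha), spec$pivot_y - spec$limb_len * cos(alpha),
           spec$cc_z_lo)
  if (sum((tip / skull_semiaxes)^2) >= 1) {
    stop("geometric infeasibility: forceps-major limbs exit the skull ",
         "(true_sa = ", true_sa, ", limb_len = ", spec$limb_len, ")")
  }
  spec
}

# roof height (mm) of the tented ventricle body at (y); slope along y makes
# the roof rise anteriorly so that plane mal-angulation mixes y into the
# apparent roof slope (the Fig-3-style confounder).
roof_apex_z <- function(spec, y) spec$roof_apex0 + spec$roof_slope_y * (y - spec$pc[2L])

roof_slope_m <- function(spec) 1 / tan(deg2rad(spec$true_ca) / 2)

skull_inside <- function(spec, x, y, z, margin = 0) {
  a <- spec$skull_semiaxes - margin
  (x / a[1L])^2 + (y / a[2L])^2 + (z / a[3L])^2 <= 1
}

# continuous ventricle indicator (used both for voxelisation and for the
# analytic plane-resampling in the CA tilt experiment)
ventricle_inside <- function(spec, x, y, z) {
  half <- spec$septum_mm + spec$horn_mm * spec$v
  g0 <- 2
  m <- roof_slope_m(spec)
  horn <- abs(x) >= g0 & abs(x) <= half &
    y >= spec$horn_y[1L] & y <= spec$horn_y[2L] &
    z >= spec$horn_z[1L] & z <= spec$horn_z[2L]
  body <- abs(x) >= g0 & abs(x) <= spec$body_frac * half &
    y >= spec$body_y[1L] & y <= spec$body_y[2L] &
    z >= spec$vent_floor & z <= roof_apex_z(spec, y) - m * abs(x)
  (horn | body) & skull_inside(spec, x, y, z, margin = 3)
}

#' Generate a digital phantom
#'
#' Voxelises a [phantom_spec()] into a color-FA volume with companion masks
#' and ground-truth measurements. The forceps-major limbs on the splenial
#' slice are straight segments meeting at a midline pivot with opening angle
#' exactly `true_sa`; limb fibre directions are the limb tangents partially
#' rotated toward the commissural (left-right) axis so that, as on real DEC
#' maps, the limbs stay red-dominant.
#'
#' @param spec a [phantom_spec()].
#' @param seed RNG seed (only used when DWI with noise is requested).
#' @param with_tensor also build the per-voxel tensor volume.
#' @param with_dwi also simulate a 20-direction b=0/1000 DWI set (implies
#'   `with_tensor`).
#' @return object of class `sa_phantom`: list with `spec`, `cfa`
#'   (a `color_fa_volume` with RGB filled), `masks` (callosum, ventricles,
#'   brain), `truth` (list with `sa`, `ca`, `ei`, `sa_slice`), and
#'   optionally `tensor`, `dwi`.
#' @export
make_phantom <- function(spec, seed = NULL, with_tensor = FALSE,
                         with_dwi = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dim
  ax <- grid_axes(dims, spec$spacing)
  X <- array(rep(ax[[1]], times = prod(dims[2:3])), dims)
  Y <- array(rep(rep(ax[[2]], each = dims[1L]), times = dims[3L]), dims)
  Z <- array(rep(ax[[3]], each = prod(dims[1:2])), dims)

  skull <- skull_inside(spec, X, Y, Z)
  vent <- ventricle_inside(spec, X, Y, Z)

  alpha <- deg2rad(spec$true_sa / 2)
  dL <- c(-sin(alpha), -cos(alpha))
  dR <- c(sin(alpha), -cos(alpha))
  py <- spec$pivot_y
  hw <- spec$limb_halfwidth
  in_slab <- Z >= spec$cc_z_splenium_lo & Z <= spec$cc_z_hi
  in_body_slab <- Z >= spec$cc_z_lo & Z <= spec$cc_z_hi

  limb_region <- function(d) {
    s <- (X - 0) * d[1L] + (Y - py) * d[2L]
    p <- (X - 0) * d[2L] - (Y - py) * d[1L]
    s >= 0 & s <= spec$limb_len & abs(p) <= hw & in_slab
  }
  limbL <- limb_region(dL)
  limbR <- limb_region(dR)
  body <- abs(X) <= 6 & Y >= py & Y <= 28 & in_body_slab
  genu <- abs(X) <= 12 & Y >= 24 & Y <= 30 & in_slab
  bridge <- abs(X) <= 5 & Y >= py - 1 & Y <= py + 2 & in_slab
  fm_dir <- function(sgn) c(sgn * sin(deg2rad(40)), cos(deg2rad(40)))
  minor_region <- function(d) {
    gy <- 27
    s <- X * d[1L] + (Y - gy) * d[2L]
    p <- X * d[2L] - (Y - gy) * d[1L]
    s >= 0 & s <= 18 & abs(p) <= hw & in_slab
  }
  minL <- minor_region(fm_dir(-1)); minR <- minor_region(fm_dir(1))
  callosum <- (limbL | limbR | body | genu | bridge | minL | minR) & skull & !vent

  lam <- spec$diffusivities$callosum
  fa_cc <- {
    lb <- mean(lam)
    sqrt(1.5) * sqrt(sum((lam - lb)^2)) / sqrt(sum(lam^2))
  }
  nvox <- prod(dims)
  fa <- numeric(nvox)
  e1 <- matrix(0, nvox, 3L)
  assign_fibre <- function(region, tangent2d) {
    idx <- which(region & callosum)
    if (!length(idx)) return(invisible(NULL))
    beta <- deg2rad(spec$fibre_blend_deg)
    d3 <- c(cos(beta) + sin(beta) * tangent2d[1L], sin(beta) * tangent2d[2L], 0)
    d3 <- d3 / sqrt(sum(d3^2))
    if (d3[which.max(abs(d3))] < 0) d3 <- -d3
    fa[idx] <<- fa_cc
    e1[idx, 1L] <<- d3[1L]; e1[idx, 2L] <<- d3[2L]; e1[idx, 3L] <<- d3[3L]
  }
  # pure commissural core first, limbs overwrite with blended tangents
  core <- (body | genu | bridge) & callosum
  fa[core] <- fa_cc
  e1[core, 1L] <- 1
  assign_fibre(limbL, dL)
  assign_fibre(limbR, dR)
  assign_fibre(minL, fm_dir(-1))
  assign_fibre(minR, fm_dir(1))

  cfa <- color_fa_volume(fa, e1, dim = dims, spacing = spec$spacing,
                         e1_defined = fa > 0)
  cfa <- color_encode(cfa)

  axz <- ax[[3]]
  sa_slice <- which(axz >= spec$cc_z_lo & axz <= spec$cc_z_hi)
  if (!length(sa_slice)) stop("grid does not cover the callosal body slab")
  sa_slice <- min(sa_slice)

  truth <- list(
    sa = spec$true_sa, ca = spec$true_ca, ei = spec$true_ei,
    sa_slice = sa_slice,
    sa_measurement = angle_measurement("SA", spec$true_sa, slice = sa_slice,
                                       rater = "ground-truth"),
    ca_measurement = angle_measurement("CA", spec$true_ca,
                                       rater = "ground-truth"),
    ei_measurement = angle_measurement("EI", spec$true_ei,
                                       rater = "ground-truth"))

  ph <- structure(list(spec = spec, cfa = cfa,
                       masks = list(callosum = callosum, ventricles = vent,
                                    brain = skull & !vent & !callosum),
                       truth = truth),
                  class = "sa_phantom")

  if (with_tensor || with_dwi) {
    D <- matrix(0, nvox, 6L)
    iso <- function(mask, d) {
      i <- which(mask)
      D[i, 1L] <<- d; D[i, 2L] <<- d; D[i, 3L] <<- d
    }
    iso(ph$masks$brain, spec$diffusivities$tissue)
    iso(vent, spec$diffusivities$csf)
    cc <- which(callosum)
    l1 <- lam[1L]; l23 <- lam[2L]
    E <- e1[cc, , drop = FALSE]
    D[cc, 1L] <- l23 + (l1 - l23) * E[, 1L]^2
    D[cc, 2L] <- l23 + (l1 - l23) * E[, 2L]^2
    D[cc, 3L] <- l23 + (l1 - l23) * E[, 3L]^2
    D[cc, 4L] <- (l1 - l23) * E[, 1L] * E[, 2L]
    D[cc, 5L] <- (l1 - l23) * E[, 1L] * E[, 3L]
    D[cc, 6L] <- (l1 - l23) * E[, 2L] * E[, 3L]
    ph$tensor <- tensor_volume(D, dims, spacing = spec$spacing,
                               foreground = as.vector(skull))
    if (with_dwi) {
      grad <- default_gradients()
      ph$dwi <- simulate_dwi(ph$tensor, grad$bvals, grad$bvecs, s0 = 1000,
                             noise_sigma = spec$noise_sigma, seed = seed)
    }
  }
  ph
}

# 20 b=1000 directions (electrostatic-style fixed set) + 2 b=0
default_gradients <- function() {
  golden <- pi * (3 - sqrt(5))
  k <- seq(0, 19)
  zc <- 1 - (k + 0.5) / 10           # in (-1, 1)
  th <- golden * k
  r <- sqrt(pmax(0, 1 - zc^2))
  g <- cbind(r * cos(th), r * sin(th), zc)
  g <- g / sqrt(rowSums(g^2))
  list(bvals = c(0, 0, rep(1000, 20)), bvecs = rbind(c(0, 0, 0), c(0, 0, 0), g))
}

#' Measure Evans' index on phantom masks
#'
#' Reads the maximal frontal-horn width and the internal cranial diameter
#' off the voxelised ventricle and skull masks, slice by slice, reproducing
#' what a rater does on the axial image. Widths are measured between outer
#' voxel centres; among slices tied for maximal horn width the one with the
#' largest cranial diameter is used.
#'
#' @param phantom an `sa_phantom`.
#' @return an [angle_measurement()] with index `"EI"`.
#' @export
measure_ei_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "sa_phantom"))
  dims <- phantom$spec$dim
  sx <- phantom$spec$spacing[1L]
  vent <- phantom$masks$ventricles
  skull <- vent | phantom$masks$brain | phantom$masks$callosum
  widths <- function(mask, z) {
    sl <- mask[, , z]
    cols <- which(apply(sl, 1L, any))
    if (!length(cols)) return(NA_real_)
    (max(cols) - min(cols)) * sx
  }
  nz <- dims[3L]
  hw <- vapply(seq_len(nz), function(z) widths(vent, z), numeric(1))
  cw <- vapply(seq_len(nz), function(z) widths(skull, z), numeric(1))
  if (all(is.na(hw))) stop("phantom has no ventricle voxels")
  hmax <- max(hw, na.rm = TRUE)
  tied <- which(!is.na(hw) & hw >= hmax - sx / 2)
  z <- tied[which.max(cw[tied])]
  angle_measurement("EI", evans_index(hw[z], cw[z]), slice = z,
                    landmarks = list(frontal_horn_width = hw[z],
                                     inner_cranial_diameter = cw[z]),
                    rater = "phantom-mask")
}

# CA measured on a (possibly mal-positioned) coronal plane through the PC by
# analytic resampling of the continuous ventricle model. tilt = rotation
# about the left-right axis (acute/obtuse mal-angulation); rot = rotation
# about the superior axis (right-left mal-rotation).
phantom_plane_ca <- function(phantom, tilt_deg = 0, rot_deg = 0,
                             step_mm = 0.5) {
  spec <- phantom$spec
  t <- deg2rad(tilt_deg); r <- deg2rad(rot_deg)
  eu <- c(cos(r), sin(r), 0)
  ew <- c(0, sin(t), cos(t))
  origin <- spec$pc
  us <- seq(-40, 40, by = step_mm)
  ws <- seq(spec$vent_floor - 5, roof_apex_z(spec, spec$pc[2L]) + 30,
            by = step_mm / 2)
  roof <- vapply(us, function(u) {
    p0 <- origin + u * eu
    xs <- p0[1L] + ws * ew[1L]
    ys <- p0[2L] + ws * ew[2L]
    zs <- p0[3L] + ws * ew[3L]
    inside <- ventricle_inside(spec, xs, ys, zs)
    if (!any(inside)) return(NA_real_)
    max(ws[inside])
  }, numeric(1))
  sel <- !is.na(roof) & abs(us) >= 3 & abs(us) <= 20
  left <- sel & us < 0
  right <- sel & us > 0
  if (sum(left) < 5 || sum(right) < 5) {
    return(list(ca = NA_real_, flagged = TRUE))
  }
  fitL <- stats::lm.fit(cbind(1, us[left]), roof[left])$coefficients
  fitR <- stats::lm.fit(cbind(1, us[right]), roof[right])$coefficients
  dirL <- c(-1, -fitL[2L]); dirR <- c(1, fitR[2L])
  ca <- angle_between(c(0, 0, 0), c(dirL, 0), c(dirR, 0))
  list(ca = ca, flagged = FALSE)
}

#' Measure the callosal angle of a phantom
#'
#' Convenience wrapper: [phantom_plane_ca()] on the true (unperturbed)
#' coronal plane through the PC, returned as a CA measurement.
#'
#' @param phantom an `sa_phantom`.
#' @param step_mm sampling step (default 0.5).
#' @return an [angle_measurement()] with index `"CA"`.
#' @export
measure_ca_phantom <- function(phantom, step_mm = 0.5) {
  res <- phantom_plane_ca(phantom, 0, 0, step_mm = step_mm)
  if (res$flagged) stop("ventricle roofs not recoverable on the PC plane")
  angle_measurement("CA", res$ca, rater = "phantom-plane")
}
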