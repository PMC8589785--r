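# angle kernel, width-ratio indices, CA, SA slice selection, tilt experiment

test_that("angle_between handles the canonical configurations", {
  v <- c(0, 0, 0)
  expect_equal(angle_between(v, c(1, 1, 0), c(-1, 1, 0)), 90)
  expect_equal(angle_between(v, c(0, 1, 0), c(0, -1, 0)), 180)
  expect_warning(a <- angle_between(v, c(0, 1, 0), c(0, 2, 0)),
                 "degenerate")
  expect_equal(a, 0)
  expect_error(angle_between(v, v, c(1, 0, 0)), "coincides")
})

test_that("angles are invariant to in-plane rigid motion", {
  set.seed(5)
  for (i in 1:20) {
    vert <- runif(2, -50, 50)
    a <- vert + runif(2, -30, 30)
    b <- vert + runif(2, -30, 30)
    ang0 <- angle_between(c(vert, 0), c(a, 0), c(b, 0))
    th <- deg <- runif(1, 0, 360) * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    shift <- runif(2, -20, 20)
    ang1 <- angle_between(c(R %*% vert + shift, 0), c(R %*% a + shift, 0),
                          c(R %*% b + shift, 0))
    expect_equal(ang1, ang0, tolerance = 1e-9)
  }
})

test_that("evans and bicaudate indices are guarded ratios", {
  expect_equal(evans_index(45.6, 120), 0.38)
  expect_equal(evans_index(30, 120), 0.25)
  expect_error(evans_index(50, 0), "positive")
  expect_error(evans_index(130, 120), "implausible")
  expect_warning(r <- evans_index(120, 120), "implausible")
  expect_equal(r, 1)
  # scale invariance (degree-0 homogeneity)
  for (s in c(0.5, 2, 10)) {
    expect_equal(evans_index(35 * s, 140 * s), evans_index(35, 140))
  }
  expect_equal(bicaudate_index(25, 100), 0.25)
  expect_equal(bicaudate_index(0, 100), 0)
  expect_equal(bicaudate_index(30, 100), 0.30)
  expect_error(bicaudate_index(10, -1), "positive")
})

test_that("measure_ca computes the roof angle and validates the plane", {
  # symmetric roofs at +/- 30 degrees from vertical -> CA = 60
  vert <- c(0, -10, 20)
  la <- landmark_angle(vert,
                       vert + c(-sin(pi / 6) * 20, 0, -cos(pi / 6) * 20),
                       vert + c(sin(pi / 6) * 20, 0, -cos(pi / 6) * 20),
                       plane = "coronal", plane_coord = -10,
                       meta = list(pc = c(0, -10, 0)))
  m <- measure_ca(la)
  expect_s3_class(m, "angle_measurement")
  expect_equal(m$value, 60, tolerance = 1e-9)
  expect_length(m$warnings, 0)
  # plane away from the PC -> warning recorded on the measurement
  la2 <- landmark_angle(c(0, -14, 20), c(-10, -14, 0), c(10, -14, 0),
                        plane = "coronal", plane_coord = -14,
                        meta = list(pc = c(0, -10, 0)))
  m2 <- measure_ca(la2)
  expect_match(m2$warnings, "from the PC")
  # landmarks off the declared plane are rejected outright
  expect_error(landmark_angle(c(0, -10, 20), c(-10, -8, 0), c(10, -10, 0),
                              plane = "coronal", plane_coord = -10),
               "off the declared")
  # axial landmarks cannot feed a CA measurement
  la3 <- landmark_angle(c(0, 0, 5), c(1, 1, 5), c(-1, 1, 5),
                        plane = "axial", plane_coord = 5)
  expect_error(measure_ca(la3), "coronal")
})

test_that("measure_ca on a phantom recovers the constructed roof angle", {
  ph <- cached_phantom(v = 1, true_sa = 75.7, coarse = TRUE)
  m <- measure_ca_phantom(ph)
  expect_lt(abs(m$value - ph$truth$ca), 2)
})

# --- SA slice selection ----------------------------------------------------

# stack builder: red bar of the given anteroposterior extent on each slice
slice_stack <- function(extents, nx = 21L, ny = 40L) {
  nz <- length(extents)
  dims <- c(nx, ny, nz)
  fa <- numeric(prod(dims))
  e1 <- matrix(0, prod(dims), 3)
  mask <- array(FALSE, dims)
  mid <- (nx + 1) / 2
  for (z in seq_len(nz)) {
    ext <- extents[z]
    if (ext <= 0) next
    ys <- seq_len(ext) + 5L
    xs <- (mid - 1):(mid + 1)
    for (y in ys) {
      idx <- (z - 1L) * nx * ny + (y - 1L) * nx + xs
      fa[idx] <- 0.8
      e1[idx, 1] <- 1
      mask[xs, y, z] <- TRUE
    }
  }
  list(cfa = color_fa_volume(fa, e1, dim = dims), mask = mask)
}

test_that("select_sa_slice applies the completeness criterion and caudal rule", {
  # criterion holds only on slice 10
  st <- slice_stack(c(rep(5, 9), 30, rep(5, 5)))
  expect_equal(select_sa_slice(st$cfa, st$mask, midline_x = 0), 10)
  # complete on slices 10 and 11 -> caudal slice wins
  st2 <- slice_stack(c(rep(5, 9), 30, 30, rep(5, 4)))
  expect_equal(select_sa_slice(st2$cfa, st2$mask, midline_x = 0), 10)
  # complete on >2 slices -> still the caudal-most
  st3 <- slice_stack(c(rep(4, 6), 28, 29, 30, 28))
  expect_equal(select_sa_slice(st3$cfa, st3$mask, midline_x = 0), 7)
  # empty mask
  expect_error(select_sa_slice(st$cfa, array(FALSE, dim = st$cfa$dim)),
               "empty")
  # no red voxels in the strip
  st4 <- slice_stack(c(5, 5))
  st4$cfa$e1[, ] <- rep(c(0, 1, 0), each = nrow(st4$cfa$e1))
  expect_error(select_sa_slice(st4$cfa, st4$mask, midline_x = 0),
               "no complete callosal body")
})

test_that("select_sa_slice is deterministic and voxel-order independent", {
  ph <- cached_phantom(v = 2, true_sa = 25)
  cm <- commissural_mask(ph$cfa)
  s1 <- select_sa_slice(ph$cfa, cm$mask, midline_x = 0)
  s2 <- select_sa_slice(ph$cfa, cm$mask, midline_x = 0)
  expect_identical(s1, s2)
  expect_equal(s1, ph$truth$sa_slice)
})

# --- SA from pivot and limbs -----------------------------------------------

test_that("measure_sa reproduces constructed opening angles", {
  # symmetric limbs 12.5 degrees off the midline axis -> SA 25
  m <- measure_sa(10, c(0, -18), rbind(c(-sin(deg <- 12.5 * pi / 180),
                                         -cos(deg)),
                                       c(sin(deg), -cos(deg))), midline_x = 0)
  expect_equal(m$value, 25, tolerance = 1e-9)
  # 37.85 degrees each side -> 75.7
  a <- 37.85 * pi / 180
  m2 <- measure_sa(10, c(0, -18), rbind(c(-sin(a), -cos(a)),
                                        c(sin(a), -cos(a))), midline_x = 0)
  expect_equal(m2$value, 75.7, tolerance = 1e-9)
  # mirror flip leaves the SA unchanged
  dirs <- rbind(c(-sin(a), -cos(a)), c(sin(a) * 0.8, -cos(a)))
  v1 <- measure_sa(10, c(0.5, -18), dirs, midline_x = 0)$value
  v2 <- measure_sa(10, c(-0.5, -18), dirs[, ] %*% diag(c(-1, 1)),
                   midline_x = 0)$value
  expect_equal(v1, v2, tolerance = 1e-12)
  # guards
  expect_error(measure_sa(10, c(5, -18), rbind(c(-1, -1), c(1, -1))),
               "off the midline")
  expect_error(measure_sa(10, c(0, -18), rbind(c(-1, 1), c(1, -1))),
               "posteriorly")
  expect_error(measure_sa(10, c(0, -18), rbind(c(1, -1), c(1, -2))),
               "same side")
})

# --- CA tilt experiment ----------------------------------------------------

test_that("ca_tilt_experiment reproduces the plane mal-positioning behaviour", {
  ph <- cached_phantom(v = 1, true_sa = 75.7, coarse = TRUE)
  tab <- ca_tilt_experiment(ph, sagittal_tilts = seq(-10, 10, 5),
                            axial_rotations = seq(-10, 10, 5))
  sag <- tab[tab$kind == "sagittal_tilt", ]
  axi <- tab[tab$kind == "axial_rotation", ]
  # identity: zero perturbation recovers the ground truth
  expect_lt(abs(sag$ca[sag$degrees == 0] - ph$truth$ca), 1)
  # monotone CA drift with increasing sagittal tilt
  expect_true(all(diff(sag$ca[order(sag$degrees)]) < 0))
  # acute/obtuse mal-angulation dominates right-left mal-rotation
  expect_gt(diff(range(sag$ca)), diff(range(axi$ca)))
  expect_error(ca_tilt_experiment(ph, sagittal_tilts = 20), "15")
})
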