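# tensor fitting, FA/e1 maps, and color encoding

grad <- splenial:::default_gradients()

test_that("fit_tensor recovers known tensors from noiseless signal", {
  # isotropic: S = S0 exp(-b d) for every direction -> d * Identity
  d <- 1.2e-3
  tv_iso <- tensor_volume(matrix(c(d, d, d, 0, 0, 0), 1), dim = c(1L, 1L, 1L))
  fit <- fit_tensor(simulate_dwi(tv_iso, grad$bvals, grad$bvecs))
  expect_equal(fit$D[1, 1:3], rep(d, 3), tolerance = 1e-12)
  expect_equal(fit$D[1, 4:6], rep(0, 3), tolerance = 1e-12)

  # prolate diag(1.7, 0.3, 0.3)e-3, 20 directions, noiseless
  d6 <- c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0)
  tv <- tensor_volume(matrix(d6, 1), dim = c(1L, 1L, 1L))
  fit <- fit_tensor(simulate_dwi(tv, grad$bvals, grad$bvecs))
  expect_lt(max(abs(fit$D[1, ] - d6)), 1e-9)

  # arbitrary rotated tensors, several at once
  set.seed(11)
  D <- t(replicate(8, rotate_tensor6(c(1.5e-3, 0.5e-3, 0.2e-3, 0, 0, 0),
                                     random_rotation())))
  tvr <- tensor_volume(D, dim = c(2L, 2L, 2L))
  fitr <- fit_tensor(simulate_dwi(tvr, grad$bvals, grad$bvecs))
  expect_lt(max(abs(fitr$D - D)), 1e-9)
})

test_that("degenerate gradient schemes are rejected", {
  vol <- array(1000, c(1, 1, 1, 3))
  expect_error(dwi_set(vol, c(1000, 1000, 1000), diag(3)),
               "b=0")
  dwi <- dwi_set(vol, c(0, 0, 0), matrix(0, 3, 3))
  expect_error(fit_tensor(dwi), "insufficient gradient scheme")
  # 6 collinear directions are rank deficient
  vol7 <- array(1000, c(1, 1, 1, 7))
  bv <- rbind(c(0, 0, 0), matrix(rep(c(1, 0, 0), 6), ncol = 3, byrow = TRUE))
  expect_error(fit_tensor(dwi_set(vol7, c(0, rep(1000, 6)), bv)),
               "insufficient gradient scheme")
})

test_that("background voxels are flagged and left zero", {
  d6 <- c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0)
  tv <- tensor_volume(rbind(d6, 0), dim = c(2L, 1L, 1L),
                      foreground = c(TRUE, FALSE))
  dwi <- simulate_dwi(tv, grad$bvals, grad$bvecs)
  fit <- fit_tensor(dwi)
  expect_false(fit$foreground[2])
  expect_equal(fit$D[2, ], rep(0, 6))
})

test_that("FA matches the closed formula and its limits", {
  # lambda = (1, 1, 1) -> FA 0; lambda = (1, 0, 0) -> FA 1
  tv <- tensor_volume(rbind(c(1, 1, 1, 0, 0, 0), c(1, 0, 0, 0, 0, 0)),
                      dim = c(2L, 1L, 1L))
  cfa <- compute_fa_e1(tv)
  expect_equal(cfa$fa, c(0, 1), tolerance = 1e-12)
  expect_equal(abs(cfa$e1[2, ]), c(1, 0, 0))
  expect_false(cfa$e1_defined[1])   # isotropic: e1 undefined

  # scalar formula oracle on the prolate tensor
  lam <- c(1.7, 0.3, 0.3) * 1e-3
  fa_oracle <- sqrt(3 / 2) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  tvp <- tensor_volume(matrix(c(lam, 0, 0, 0), 1), dim = c(1L, 1L, 1L))
  expect_equal(compute_fa_e1(tvp)$fa, fa_oracle, tolerance = 1e-12)

  # all-zero tensor: FA 0, e1 flagged undefined
  tv0 <- tensor_volume(matrix(0, 1, 6), dim = c(1L, 1L, 1L))
  cfa0 <- compute_fa_e1(tv0)
  expect_equal(cfa0$fa, 0)
  expect_false(cfa0$e1_defined[1])
})

test_that("FA is rotation invariant and bounded in [0, 1]", {
  set.seed(23)
  base <- c(1.9e-3, 0.7e-3, 0.1e-3, 0, 0, 0)
  fa0 <- compute_fa_e1(tensor_volume(matrix(base, 1), c(1L, 1L, 1L)))$fa
  for (i in 1:20) {
    d6 <- rotate_tensor6(base, random_rotation())
    fa <- compute_fa_e1(tensor_volume(matrix(d6, 1), c(1L, 1L, 1L)))$fa
    expect_equal(fa, fa0, tolerance = 1e-9)
  }
  # random PSD tensors stay in bounds
  for (i in 1:50) {
    lam <- sort(runif(3, 0, 3e-3), decreasing = TRUE)
    d6 <- rotate_tensor6(c(lam, 0, 0, 0), random_rotation())
    fa <- compute_fa_e1(tensor_volume(matrix(d6, 1), c(1L, 1L, 1L)))$fa
    expect_gte(fa, 0); expect_lte(fa, 1)
  }
})

test_that("e1 matches eigen() on random anisotropic tensors", {
  set.seed(31)
  for (i in 1:25) {
    lam <- c(2.5e-3, 0.8e-3, 0.3e-3)
    d6 <- rotate_tensor6(c(lam, 0, 0, 0), random_rotation())
    cfa <- compute_fa_e1(tensor_volume(matrix(d6, 1), c(1L, 1L, 1L)))
    A <- matrix(c(d6[1], d6[4], d6[5], d6[4], d6[2], d6[6],
                  d6[5], d6[6], d6[3]), 3, 3)
    v <- eigen(A, symmetric = TRUE)$vectors[, 1]
    expect_gt(abs(sum(cfa$e1[1, ] * v)), 1 - 1e-9)
  }
})

test_that("color encoding follows rgb = FA * |e1| on the RAS axes", {
  e1 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  fa <- c(0.8, 0.5, 0.3, 0)
  cfa <- color_fa_volume(fa, e1, dim = c(4L, 1L, 1L),
                         e1_defined = c(TRUE, TRUE, TRUE, FALSE))
  enc <- color_encode(cfa)
  expect_equal(enc$rgb[1, ], c(0.8, 0, 0))
  expect_equal(enc$rgb[2, ], c(0, 0.5, 0))
  expect_equal(enc$rgb[3, ], c(0, 0, 0.3))
  expect_equal(enc$rgb[4, ], c(0, 0, 0))          # FA 0 -> black
  # idempotent and channel-wise bounded by FA
  enc2 <- color_encode(enc)
  expect_identical(enc2$rgb, enc$rgb)
  expect_true(all(enc$rgb <= enc$fa + 1e-12))
  # missing orientation: no red axis assignable
  cfa$orientation <- NULL
  expect_error(color_encode(cfa), "orientation")
})

test_that("noiseless DWI round trip recovers FA to 1e-6", {
  ph <- make_phantom(coarse_spec(v = 1.5, true_sa = 50), with_dwi = TRUE)
  cfa <- compute_fa_e1(fit_tensor(ph$dwi))
  inside <- ph$masks$callosum | ph$masks$ventricles | ph$masks$brain
  expect_lt(max(abs(cfa$fa - ph$cfa$fa)[inside]), 1e-6)
})
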