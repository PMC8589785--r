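# Diffusion tensor fitting and directionally-encoded color FA maps.
#
# The tensor is the standard single-shell Gaussian diffusion model
#   S(g, b) = S0 * exp(-b * g' D g)
# fitted per voxel by unweighted log-linear least squares. Tensors are stored
# as a 6-column matrix of unique components (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
# over the voxel grid; anisotropy and principal directions come from a
# vectorised closed-form symmetric 3x3 eigendecomposition.

#' Construct a diffusion-weighted image set
#'
#' @param volumes 4D array (x, y, z, gradient) of signal intensities.
#' @param bvals numeric vector of b-values in s/mm^2, one per gradient.
#' @param bvecs n x 3 matrix of gradient directions; unit length for b > 0.
#' @param spacing voxel spacing in mm.
#' @param orientation axis-order tag; only `"RAS"` is supported.
#' @return object of class `dwi_set`.
#' @export
dwi_set <- function(volumes, bvals, bvecs, spacing = c(1, 1, 1),
                    orientation = "RAS") {
  stopifnot(length(dim(volumes)) == 4L)
  bvecs <- as.matrix(bvecs)
  if (dim(volumes)[4L] != length(bvals) || nrow(bvecs) != length(bvals)) {
    stop("number of volumes, b-values and b-vectors must agree")
  }
  nz <- bvals > 0
  if (!any(!nz)) stop("at least one b=0 volume is required")
  if (any(nz)) {
    nrm <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      stop("b-vectors for b > 0 must be unit length")
    }
  }
  structure(list(volumes = volumes, bvals = as.double(bvals), bvecs = bvecs,
                 spacing = as.double(spacing), orientation = orientation),
            class = "dwi_set")
}

# b-matrix row for one gradient: coefficients of the 6 unique tensor
# components in g' D g, with off-diagonal doubling.
bmatrix <- function(bvals, bvecs) {
  g <- bvecs
  bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

# rank check for the gradient scheme: need >= 6 independent b>0 rows
gradient_rank_ok <- function(bvals, bvecs) {
  nz <- bvals > 0
  if (sum(nz) < 6L) return(FALSE)
  B <- bmatrix(bvals[nz], bvecs[nz, , drop = FALSE])
  qr(B)$rank >= 6L
}

#' Fit the diffusion tensor per voxel
#'
#' Unweighted log-linear least-squares fit of the single tensor model to a
#' [dwi_set()]. Voxels whose mean b=0 signal falls below `bg_frac` of the
#' robust (98th percentile) maximum are flagged background and left zero.
#' Negative eigenvalues arising from noise are clamped to zero.
#'
#' @param dwi a [dwi_set()].
#' @param bg_frac background threshold as a fraction of the robust maximum
#'   b=0 signal (default 0.01).
#' @return object of class `tensor_volume`: list with `D` (n_voxel x 6
#'   matrix), `dim`, `spacing`, `orientation`, `foreground` (logical).
#' @export
fit_tensor <- function(dwi, bg_frac = 0.01) {
  stopifnot(inherits(dwi, "dwi_set"))
  if (!gradient_rank_ok(dwi$bvals, dwi$bvecs)) {
    stop("insufficient gradient scheme: need >= 6 non-collinear b > 0 directions")
  }
  dims <- dim(dwi$volumes)[1:3]
  nvox <- prod(dims)
  sig <- matrix(dwi$volumes, nrow = nvox)
  b0 <- dwi$bvals <= 0
  s0 <- rowMeans(sig[, b0, drop = FALSE])
  robust_max <- as.double(quantile(s0, 0.98, names = FALSE))
  fg <- s0 > bg_frac * robust_max & s0 > 0
  nz <- !b0
  B <- bmatrix(dwi$bvals[nz], dwi$bvecs[nz, , drop = FALSE])
  # solve B d = -log(S/S0) in least squares, all foreground voxels at once
  Bp <- solve(crossprod(B), t(B))             # 6 x ngrad
  D <- matrix(0, nvox, 6L)
  if (any(fg)) {
    S <- sig[fg, nz, drop = FALSE]
    S[S <= 0] <- .Machine$double.eps
    y <- -(log(S) - log(s0[fg]))              # ngrad per voxel
    D[fg, ] <- y %*% t(Bp)
    D[fg, ] <- clamp_negative_eigenvalues(D[fg, , drop = FALSE])
  }
  structure(list(D = D, dim = dims, spacing = dwi$spacing,
                 orientation = dwi$orientation, foreground = fg),
            class = "tensor_volume")
}

#' Construct a tensor volume directly
#'
#' @param D n_voxel x 6 matrix of components (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @param dim grid dimensions.
#' @param spacing voxel spacing mm.
#' @param orientation axis tag.
#' @param foreground logical per-voxel mask; defaults to nonzero tensors.
#' @export
tensor_volume <- function(D, dim, spacing = c(1, 1, 1), orientation = "RAS",
                          foreground = NULL) {
  D <- as.matrix(D)
  stopifnot(ncol(D) == 6L, nrow(D) == prod(dim))
  if (is.null(foreground)) foreground <- rowSums(abs(D)) > 0
  structure(list(D = D, dim = as.integer(dim), spacing = as.double(spacing),
                 orientation = orientation, foreground = foreground),
            class = "tensor_volume")
}

# Vectorised eigenvalues of many symmetric 3x3 matrices (rows of a 6-column
# matrix), descending order. Trigonometric closed form (stable for the
# diffusion regime; exact-diagonal rows short-circuit).
eig_sym3_values <- function(D) {
  a11 <- D[, 1]; a22 <- D[, 2]; a33 <- D[, 3]
  a12 <- D[, 4]; a13 <- D[, 5]; a23 <- D[, 6]
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  nz <- p > 0
  if (any(nz)) {
    b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
    b12 <- a12 / p; b13 <- a13 / p; b23 <- a23 / p
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- (q + 2 * p * cos(phi))[nz]
    l3[nz] <- (q + 2 * p * cos(phi + 2 * pi / 3))[nz]
    l2[nz] <- (3 * q - l1 - l3)[nz]
  }
  cbind(l1, l2, l3, deparse.level = 0)
}

# Principal eigenvector per row via the spectral projector
# (A - l2 I)(A - l3 I) = (l1-l2)(l1-l3) v1 v1'; take the largest column.
eig_sym3_e1 <- function(D, lambda) {
  n <- nrow(D)
  a <- array(0, c(n, 3, 3))
  a[, 1, 1] <- D[, 1]; a[, 2, 2] <- D[, 2]; a[, 3, 3] <- D[, 3]
  a[, 1, 2] <- a[, 2, 1] <- D[, 4]
  a[, 1, 3] <- a[, 3, 1] <- D[, 5]
  a[, 2, 3] <- a[, 3, 2] <- D[, 6]
  m1 <- a; m2 <- a
  for (i in 1:3) {
    m1[, i, i] <- m1[, i, i] - lambda[, 2]
    m2[, i, i] <- m2[, i, i] - lambda[, 3]
  }
  pr <- array(0, c(n, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    pr[, i, j] <- m1[, i, 1] * m2[, 1, j] + m1[, i, 2] * m2[, 2, j] +
      m1[, i, 3] * m2[, 3, j]
  }
  colnorm <- sapply(1:3, function(j) pr[, 1, j]^2 + pr[, 2, j]^2 + pr[, 3, j]^2)
  colnorm <- matrix(colnorm, nrow = n)
  best <- max.col(colnorm, ties.method = "first")
  e1 <- matrix(0, n, 3)
  for (j in 1:3) {
    sel <- best == j
    if (any(sel)) e1[sel, ] <- pr[sel, , j]
  }
  nrm <- sqrt(rowSums(e1^2))
  degenerate <- nrm < 1e-12 * pmax(abs(lambda[, 1]), 1e-300)^2 | nrm == 0
  nrm[nrm == 0] <- 1
  e1 <- e1 / nrm
  # sign convention: largest-|component| non-negative
  lead <- max.col(abs(e1), ties.method = "first")
  sgn <- sign(e1[cbind(seq_len(n), lead)])
  sgn[sgn == 0] <- 1
  e1 <- e1 * sgn
  attr(e1, "degenerate") <- degenerate
  e1
}

# Reconstruct tensors with negative eigenvalues clamped to zero. Only rows
# that actually have a negative eigenvalue are decomposed fully.
clamp_negative_eigenvalues <- function(D) {
  lambda <- eig_sym3_values(D)
  bad <- which(lambda[, 3] < 0)
  for (i in bad) {
    A <- matrix(c(D[i, 1], D[i, 4], D[i, 5],
                  D[i, 4], D[i, 2], D[i, 6],
                  D[i, 5], D[i, 6], D[i, 3]), 3, 3)
    e <- eigen(A, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    A2 <- e$vectors %*% diag(lam) %*% t(e$vectors)
    D[i, ] <- c(A2[1, 1], A2[2, 2], A2[3, 3], A2[1, 2], A2[1, 3], A2[2, 3])
  }
  D
}

#' Fractional anisotropy and principal eigenvector maps
#'
#' Computes per-voxel FA and the principal eigenvector e1 from a tensor
#' volume:
#'   FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2)).
#' The e1 sign ambiguity is resolved by making the largest-magnitude
#' component non-negative. All-zero tensors yield FA = 0 with e1 flagged
#' undefined.
#'
#' @param tv a `tensor_volume`.
#' @return object of class `color_fa_volume` with `fa`, `e1` (n x 3),
#'   `e1_defined`, grid metadata, and `rgb = NULL` until [color_encode()].
#' @export
compute_fa_e1 <- function(tv) {
  stopifnot(inherits(tv, "tensor_volume"))
  lambda <- eig_sym3_values(tv$D)
  lbar <- rowMeans(lambda)
  num <- sqrt(rowSums((lambda - lbar)^2))
  den <- sqrt(rowSums(lambda^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  fa <- pmin(pmax(fa, 0), 1)
  e1 <- eig_sym3_e1(tv$D, lambda)
  defined <- !attr(e1, "degenerate") & den > 0
  structure(list(fa = fa, e1 = e1, e1_defined = defined, rgb = NULL,
                 dim = tv$dim, spacing = tv$spacing,
                 orientation = tv$orientation),
            class = "color_fa_volume")
}

#' Construct a color-FA volume directly
#'
#' @param fa numeric vector of FA values in \[0, 1\], one per voxel.
#' @param e1 n x 3 matrix of unit principal eigenvectors.
#' @param dim,spacing,orientation grid metadata.
#' @param e1_defined logical per-voxel flag; defaults to `fa > 0`.
#' @export
color_fa_volume <- function(fa, e1, dim, spacing = c(1, 1, 1),
                            orientation = "RAS", e1_defined = NULL) {
  stopifnot(length(fa) == prod(dim), nrow(e1) == length(fa))
  if (any(fa < -1e-9 | fa > 1 + 1e-9)) stop("FA must lie in [0, 1]")
  structure(list(fa = pmin(pmax(as.double(fa), 0), 1), e1 = as.matrix(e1),
                 e1_defined = e1_defined %||% (fa > 0), rgb = NULL,
                 dim = as.integer(dim), spacing = as.double(spacing),
                 orientation = orientation),
            class = "color_fa_volume")
}

#' Directionally-encoded color map
#'
#' Fills the RGB channels of a color-FA volume:
#' `rgb = FA * (|e1.x|, |e1.y|, |e1.z|)`, with x the grid's left-right axis
#' (red = commissural), y anterior-posterior (green), z superior (blue).
#'
#' @param cfa a `color_fa_volume` with `fa` and `e1` present.
#' @return the volume with `rgb` (n x 3 matrix) filled.
#' @export
color_encode <- function(cfa) {
  stopifnot(inherits(cfa, "color_fa_volume"))
  if (is.null(cfa$orientation) || !identical(cfa$orientation, "RAS")) {
    stop("missing or non-RAS orientation metadata: cannot assign the red axis")
  }
  rgb <- abs(cfa$e1) * cfa$fa
  rgb[!cfa$e1_defined, ] <- 0
  cfa$rgb <- rgb
  cfa
}

#' Simulate diffusion-weighted signal from a tensor volume
#'
#' Forward model `S = S0 exp(-b g' D g)` per voxel and gradient, optionally
#' with additive Gaussian noise. Used for round-trip validation and DWI-level
#' phantoms.
#'
#' @param tv a `tensor_volume`.
#' @param bvals,bvecs gradient scheme.
#' @param s0 baseline signal (scalar or per-voxel).
#' @param noise_sigma additive Gaussian noise SD (0 = noiseless).
#' @param seed RNG seed used when `noise_sigma > 0`.
#' @return a [dwi_set()].
#' @export
simulate_dwi <- function(tv, bvals, bvecs, s0 = 1000, noise_sigma = 0,
                         seed = NULL) {
  stopifnot(inherits(tv, "tensor_volume"))
  B <- bmatrix(bvals, as.matrix(bvecs))          # ngrad x 6
  expo <- tv$D %*% t(B)                          # nvox x ngrad
  sig <- s0 * exp(-expo)
  sig[!tv$foreground, ] <- 0
  if (noise_sigma > 0) {
    sig <- sig + with_seed(seed, matrix(rnorm(length(sig), 0, noise_sigma),
                                        nrow = nrow(sig)))
    sig[sig < 0] <- 0
  }
  dwi_set(array(sig, c(tv$dim, length(bvals))), bvals, bvecs,
          spacing = tv$spacing, orientation = tv$orientation)
}
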