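# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# Benjamini-Hochberg step-up, written directly from the recursion:
# p_(m) stays, p_(i) = min(p_(i+1), m/i * p_(i)).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  adj[m] <- ps[m]
  if (m > 1L) {
    for (i in (m - 1L):1L) adj[i] <- min(adj[i + 1L], m / i * ps[i])
  }
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# ICC(A,1) from an independent aov() variance decomposition.
icc_a1_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- anova(lm(y ~ subj + rater, data = df))$`Mean Sq`
  msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Empirical AUC by exhaustive pair enumeration (higher score favours the
# positive class).
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# Exhaustive closest-to-top-left cutoff search (rule: score <= c positive).
cutoff_oracle_lower <- function(scores, labels) {
  cands <- sort(unique(scores))
  best <- NULL
  for (cc in cands) {
    pred <- scores <= cc
    se <- sum(pred & labels) / sum(labels)
    sp <- sum(!pred & !labels) / sum(!labels)
    d2 <- (1 - se)^2 + (1 - sp)^2
    if (is.null(best) || d2 < best$d2 - 1e-15 ||
        (abs(d2 - best$d2) <= 1e-15 && sp > best$sp + 1e-15)) {
      best <- list(cutoff = cc, d2 = d2, se = se, sp = sp)
    }
  }
  best
}

# random 3D rotation matrix
random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# rotate a 6-component tensor row by R
rotate_tensor6 <- function(d6, R) {
  A <- matrix(c(d6[1], d6[4], d6[5],
                d6[4], d6[2], d6[6],
                d6[5], d6[6], d6[3]), 3, 3)
  B <- R %*% A %*% t(R)
  c(B[1, 1], B[2, 2], B[3, 3], B[1, 2], B[1, 3], B[2, 3])
}

# small, fast phantom spec used throughout the suite (2 mm axial slices keep
# the grid at ~1.5M voxels; the geometry is unchanged)
test_spec <- function(v = 1, true_sa = 75.7, ...) {
  phantom_spec(dim = c(150L, 180L, 55L), spacing = c(1, 1, 2), v = v,
               true_sa = true_sa, ...)
}

# coarse spec for the cheap structural tests
coarse_spec <- function(v = 1, true_sa = 75.7, ...) {
  phantom_spec(dim = c(60L, 60L, 40L), spacing = c(2, 2, 2), v = v,
               true_sa = true_sa, ...)
}

# cached phantoms (built once per test run)
.phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(v = 1, true_sa = 75.7, coarse = FALSE) {
  key <- paste0("v", v, "_sa", true_sa, "_c", coarse)
  if (is.null(.phantom_cache[[key]])) {
    spec <- if (coarse) coarse_spec(v, true_sa) else test_spec(v, true_sa)
    .phantom_cache[[key]] <- make_phantom(spec)
  }
  .phantom_cache[[key]]
}
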