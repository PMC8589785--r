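# Synthetic cohorts and follow-up tables.
#
# The generator's stated world is the published case-control design: four
# groups (HC, PD, AD, NPH) of 19 age- and sex-matched subjects each, with
# per-group Gaussian marginals for EI, CA and SA given by the canonical
# moments table shipped in inst/extdata/group_moments.csv. The published
# study reports no EI/CA/SA covariance, so the default cross-index
# correlation is 0 (configurable). Truncation keeps EI in (0, 1) and angles
# in (0, 180) degrees by rejection resampling.

#' Canonical group moments
#'
#' Per-group means and SDs of EI, CA (degrees) and SA (degrees), plus age
#' moments and sex counts, for the four cohorts the package emulates.
#'
#' @return data.frame, one row per group (HC, PD, AD, NPH).
#' @export
default_group_moments <- function() {
  path <- system.file("extdata", "group_moments.csv", package = "splenial",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Canonical follow-up delta parameters
#'
#' One-year changes from baseline (mean and SD of the deltas of EI, CA, SA)
#' for shunted (n = 6) and non-shunted (n = 5) hydrocephalus patients.
#'
#' @return data.frame, one row per arm.
#' @export
default_followup_deltas <- function() {
  path <- system.file("extdata", "followup_deltas.csv", package = "splenial",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

# rejection-truncated multivariate normal draws for one group
draw_group <- function(n, mu, sd, corr, lower, upper, max_iter = 1000L) {
  p <- length(mu)
  R <- diag(p)
  R[upper.tri(R)] <- corr
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 && any(sd > 0)) stop("correlation matrix is not positive definite")
  Sigma <- diag(sd, p) %*% R %*% diag(sd, p)
  out <- matrix(NA_real_, n, p)
  need <- seq_len(n)
  it <- 0L
  while (length(need) && it < max_iter) {
    it <- it + 1L
    draw <- if (all(sd == 0)) {
      matrix(mu, length(need), p, byrow = TRUE)
    } else {
      MASS::mvrnorm(length(need), mu = mu, Sigma = Sigma)
    }
    draw <- matrix(draw, ncol = p)
    ok <- rep(TRUE, nrow(draw))
    for (j in seq_len(p)) ok <- ok & draw[, j] > lower[j] & draw[, j] < upper[j]
    out[need[ok], ] <- draw[ok, , drop = FALSE]
    need <- need[!ok]
    if (all(sd == 0)) break
  }
  if (length(need)) stop("truncation rejection failed to converge")
  out
}

#' Simulate a case-control cohort
#'
#' Draws per-subject (EI, CA, SA) from group-specific multivariate normals
#' with the given marginal moments, truncated to the physically admissible
#' ranges (EI in (0, 1), angles in (0, 180)). Ages are drawn from the group
#' age moments and sexes assigned to match the stated male/female counts.
#'
#' @param moments data.frame as returned by [default_group_moments()];
#'   groups with `n` overridden via the `n` argument.
#' @param seed RNG seed (determines the table completely).
#' @param correlation common cross-index correlation (default 0).
#' @param n optional per-group sample size overriding `moments$n`.
#' @return data.frame of class `cohort_table` with columns `id`, `group`,
#'   `age`, `sex`, `EI`, `CA`, `SA`.
#' @export
simulate_cohort <- function(moments = default_group_moments(), seed = NULL,
                            correlation = 0, n = NULL) {
  if (nrow(moments) < 2L) stop("need moments for at least two groups")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(moments)), function(i) {
      g <- moments[i, ]
      ng <- if (is.null(n)) g$n else n
      if (ng <= 0) stop("group sizes must be positive")
      vals <- draw_group(ng,
                         mu = c(g$ei_mean, g$ca_mean, g$sa_mean),
                         sd = c(g$ei_sd, g$ca_sd, g$sa_sd),
                         corr = correlation,
                         lower = c(0, 0, 0), upper = c(1, 180, 180))
      age <- if (!is.null(g$age_sd) && is.finite(g$age_sd)) {
        rnorm(ng, g$age_mean, g$age_sd)
      } else rep(NA_real_, ng)
      nm <- if (!is.null(g$n_male) && is.finite(g$n_male)) {
        round(g$n_male / g$n * ng)
      } else round(ng / 2)
      sex <- c(rep("M", nm), rep("F", ng - nm))
      data.frame(id = sprintf("%s%03d", g$group, seq_len(ng)),
                 group = g$group, age = age, sex = sex,
                 EI = vals[, 1L], CA = vals[, 2L], SA = vals[, 3L],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Simulate one-year follow-up for hydrocephalus subjects
#'
#' Assigns the given baseline rows to shunt / no-shunt arms and draws the
#' follow-up value of each measure as baseline + N(delta_mean, delta_sd^2)
#' per arm (signs as stated: angles widen after shunting, EI decreases).
#'
#' @param baseline `cohort_table` rows to follow up (typically NPH).
#' @param deltas data.frame as from [default_followup_deltas()].
#' @param seed RNG seed.
#' @return data.frame with columns `id`, `arm`, baseline/followup/delta
#'   columns per measure.
#' @export
simulate_followup <- function(baseline, deltas = default_followup_deltas(),
                              seed = NULL) {
  stopifnot(is.data.frame(baseline))
  n_needed <- sum(deltas$n)
  if (any(deltas$n < 2L)) stop("need at least 2 subjects per arm")
  if (nrow(baseline) < n_needed) {
    stop("baseline has ", nrow(baseline), " rows but the arms need ", n_needed)
  }
  with_seed(seed, {
    base <- baseline[seq_len(n_needed), , drop = FALSE]
    arm <- rep(deltas$arm, deltas$n)
    out <- data.frame(id = base$id, arm = arm, stringsAsFactors = FALSE)
    for (m in c("EI", "CA", "SA")) {
      mu <- deltas[[paste0(tolower(m), "_mean")]][match(arm, deltas$arm)]
      sdv <- deltas[[paste0(tolower(m), "_sd")]][match(arm, deltas$arm)]
      d <- rnorm(n_needed, mu, sdv)
      out[[paste0(m, "_baseline")]] <- base[[m]]
      out[[paste0(m, "_followup")]] <- base[[m]] + d
      out[[paste0(m, "_delta")]] <- d
    }
    out
  })
}
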