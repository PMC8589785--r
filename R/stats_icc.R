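# Reliability and group-comparison statistics.

#' Intraclass correlation, two-way model, absolute agreement, single measure
#'
#' ICC(A,1) in the McGraw-Wong nomenclature, the variant used for
#' inter-rater reliability of single measurements:
#'   ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)
#' from the two-way ANOVA decomposition (MSR rows/subjects, MSC
#' columns/raters, MSE error). The confidence interval is the standard
#' F-based interval with Satterthwaite degrees of freedom.
#'
#' @param ratings numeric matrix, subjects x raters; no missing cells.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `icc_result`: list with `icc`, `ci`, mean
#'   squares, `n`, `k`, `model`, `flagged` (TRUE when between-subject
#'   variance vanishes and the ICC is undefined).
#' @export
icc_absolute_single <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("missing cells are not supported")
  n <- nrow(x); k <- ncol(x)
  if (k < 2L) stop("need at least 2 raters")
  if (n < 5L) stop("need at least 5 subjects")
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sse <- sum((x - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  flagged <- ssr <= .Machine$double.eps * k * n * max(1, grand^2)
  icc <- if (denom == 0) NA_real_ else (msr - mse) / denom
  alpha <- 1 - conf_level
  ci <- c(NA_real_, NA_real_)
  if (!is.na(icc) && mse > 0) {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lo, hi)
  } else if (!is.na(icc) && mse == 0) {
    ci <- c(icc, icc)   # perfect agreement: degenerate interval
  }
  structure(list(icc = icc, ci = ci, msr = msr, msc = msc, mse = mse,
                 n = n, k = k, conf_level = conf_level,
                 model = "two-way, absolute agreement, single measurement",
                 flagged = flagged),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (%d%% CI %.3f, %.3f)%s\n", x$icc,
              round(100 * x$conf_level), x$ci[1L], x$ci[2L],
              if (x$flagged) " [flagged: no between-subject variance]" else ""))
  invisible(x)
}

#' One-way ANOVA across groups
#'
#' @param table `cohort_table` (or any data.frame with a `group` column).
#' @param measure column name to compare (e.g. `"SA"`).
#' @return list with `F`, `p`, `df`.
#' @export
group_anova <- function(table, measure) {
  g <- factor(table$group)
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(tabulate(g) < 2L)) stop("need at least two subjects per group")
  y <- table[[measure]]
  fit <- stats::anova(stats::lm(y ~ g))
  list(F = fit$`F value`[1L], p = fit$`Pr(>F)`[1L],
       df = c(fit$Df[1L], fit$Df[2L]))
}

#' Pairwise comparisons with Benjamini-Hochberg adjustment
#'
#' Two-sided pairwise Student t tests between all group pairs for one
#' measure, with BH (false-discovery-rate) step-up adjustment over all
#' pairs. The adjusted p-values are monotone in the raw p-value ranks and
#' never smaller than the raw values.
#'
#' @param table data.frame with `group` and the measure column.
#' @param measure column name.
#' @param var_equal use pooled-variance Student t (default TRUE).
#' @return list with `raw` and `adjusted` symmetric p-value matrices
#'   (groups x groups) and a long-format `pairs` data.frame.
#' @export
pairwise_bh <- function(table, measure, var_equal = TRUE) {
  g <- factor(table$group)
  if (nlevels(g) < 2L) stop("need at least two groups")
  y <- table[[measure]]
  lev <- levels(g)
  cmb <- utils::combn(lev, 2L)
  raw <- apply(cmb, 2L, function(pr) {
    stats::t.test(y[g == pr[1L]], y[g == pr[2L]],
                  var.equal = var_equal)$p.value
  })
  adj <- stats::p.adjust(raw, method = "BH")
  m_raw <- m_adj <- matrix(NA_real_, nlevels(g), nlevels(g),
                           dimnames = list(lev, lev))
  for (j in seq_len(ncol(cmb))) {
    a <- cmb[1L, j]; b <- cmb[2L, j]
    m_raw[a, b] <- m_raw[b, a] <- raw[j]
    m_adj[a, b] <- m_adj[b, a] <- adj[j]
  }
  list(raw = m_raw, adjusted = m_adj,
       pairs = data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ],
                          p_raw = raw, p_adjusted = adj,
                          stringsAsFactors = FALSE))
}

#' Between-arm t tests on follow-up changes
#'
#' For each measure, compares the deltas (follow-up minus baseline) between
#' the shunt and no-shunt arms with a two-sided Student t test (pooled
#' variance by default, Welch via `var_equal = FALSE`).
#'
#' @param followup table from [simulate_followup()] (needs `arm` and
#'   `*_delta` columns).
#' @param var_equal pooled-variance Student t (default TRUE).
#' @return data.frame, one row per measure, mirroring the published change
#'   table: per-arm mean and SD of the deltas plus the between-arm p-value.
#' @export
shunt_change_test <- function(followup, var_equal = TRUE) {
  arms <- unique(followup$arm)
  if (length(arms) != 2L) stop("need exactly two arms")
  if (any(table(followup$arm) < 2L)) stop("need at least 2 subjects per arm")
  a1 <- followup$arm == arms[1L]
  rows <- lapply(c("EI", "CA", "SA"), function(m) {
    d <- followup[[paste0(m, "_delta")]]
    tt <- stats::t.test(d[a1], d[!a1], var.equal = var_equal)
    data.frame(measure = m,
               arm1 = arms[1L], mean1 = mean(d[a1]), sd1 = sd(d[a1]),
               arm2 = arms[2L], mean2 = mean(d[!a1]), sd2 = sd(d[!a1]),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
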