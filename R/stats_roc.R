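# ROC screening analysis and stepwise logistic prediction.

#' Empirical ROC screening analysis
#'
#' Computes the empirical (Mann-Whitney) AUC, a DeLong confidence interval,
#' and the operating point closest to the top-left corner of the ROC plot
#' (minimising (1-sens)^2 + (1-spec)^2 over all observed cutoffs). Ties at
#' the optimal distance are broken toward higher specificity, then toward
#' the more extreme cutoff. The decision rule is `score <= cutoff` positive
#' when `direction = "lower"` (as for SA/CA, where narrower angles favour
#' disease) and `score >= cutoff` positive when `direction = "higher"` (EI).
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1): TRUE = positive class.
#' @param direction `"lower"` or `"higher"` (which scores favour positives).
#' @param conf_level CI level for the AUC (default 0.95).
#' @return object of class `roc_result`: `auc`, `auc_ci`, `cutoff`,
#'   `sensitivity`, `specificity`, `accuracy`, `ppv`, `npv`, `direction`,
#'   `n_pos`, `n_neg`.
#' @export
roc_screen <- function(scores, labels, direction = c("lower", "higher"),
                       conf_level = 0.95) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("missing values not supported")
  npos <- as.double(sum(labels)); nneg <- as.double(sum(!labels))
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  s <- if (direction == "lower") -scores else scores
  r <- rank(s)
  auc <- (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  # DeLong variance via placement values, computed from midranks
  pos <- s[labels]; neg <- s[!labels]
  v10 <- (rank(c(pos, neg))[seq_len(npos)] - rank(pos)) / nneg
  v01 <- 1 - (rank(c(neg, pos))[seq_len(nneg)] - rank(neg)) / npos
  vr <- if (npos > 1L) stats::var(v10) / npos else 0
  vc <- if (nneg > 1L) stats::var(v01) / nneg else 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(vr + vc)
  ci <- c(max(0, auc - half), min(1, auc + half))
  # exhaustive cutoff search over observed score values (cumulative counts)
  cands <- sort(unique(scores))
  np_at <- cumsum(tabulate(match(scores[labels], cands), length(cands)))
  nn_at <- cumsum(tabulate(match(scores[!labels], cands), length(cands)))
  if (direction == "lower") {
    sens <- np_at / npos                    # positives with score <= c
    spec <- 1 - nn_at / nneg                # negatives with score > c
  } else {
    sens <- (npos - c(0, np_at[-length(np_at)])) / npos   # score >= c
    spec <- c(0, nn_at[-length(nn_at)]) / nneg            # score < c
  }
  d2 <- (1 - sens)^2 + (1 - spec)^2
  best <- which(d2 == min(d2))
  if (length(best) > 1L) {
    best <- best[spec[best] == max(spec[best])]
    if (length(best) > 1L) {
      best <- if (direction == "lower") min(best) else max(best)
    }
  }
  cut <- cands[best]
  pred <- if (direction == "lower") scores <= cut else scores >= cut
  tp <- sum(pred & labels); tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels); fn <- sum(!pred & labels)
  structure(list(auc = auc, auc_ci = ci, cutoff = cut,
                 sensitivity = tp / npos, specificity = tn / nneg,
                 accuracy = (tp + tn) / length(scores),
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                 direction = direction, n_pos = npos, n_neg = nneg,
                 conf_level = conf_level),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f (%d%% CI %.3f, %.3f); cutoff %.1f (%s favours positive)\n",
    x$auc, round(100 * x$conf_level), x$auc_ci[1L], x$auc_ci[2L], x$cutoff,
    x$direction))
  cat(sprintf("  sens %.1f%%  spec %.1f%%  acc %.1f%%  ppv %.1f%%  npv %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy,
              100 * x$ppv, 100 * x$npv))
  invisible(x)
}

#' Closed-form binormal AUC
#'
#' For Gaussian score distributions in the two classes the AUC has the
#' closed form Phi(|mu_neg - mu_pos| / sqrt(sd_pos^2 + sd_neg^2)). Used as
#' the analytic oracle for simulation targets. With both SDs zero the score
#' is a step function: 1 when the means differ, 0.5 when they coincide.
#'
#' @param mu_pos,sd_pos positive-class mean and SD.
#' @param mu_neg,sd_neg negative-class mean and SD.
#' @return AUC in \[0.5, 1\].
#' @export
binormal_auc <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  if (sd_pos < 0 || sd_neg < 0) stop("SDs must be non-negative")
  s <- sqrt(sd_pos^2 + sd_neg^2)
  if (s == 0) return(if (mu_pos == mu_neg) 0.5 else 1)
  pnorm(abs(mu_neg - mu_pos) / s)
}

# ridge-penalised logistic regression by IRLS; fallback under separation
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 200L, tol = 1e-10) {
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(lambda, p); pen[1L, 1L] <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    zv <- eta + (y - mu) / w
    new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * zv))
    if (max(abs(new - beta)) < tol) { beta <- drop(new); break }
    beta <- drop(new)
  }
  names(beta) <- colnames(X)
  beta
}

#' Stepwise multivariable logistic prediction
#'
#' Predicts the positive group (default NPH vs all other groups pooled)
#' from the candidate measures by bidirectional stepwise selection (AIC,
#' starting from the full model). Reports the in-sample AUC with DeLong CI
#' for the standard model ladder (each single measure, SA + EI, SA + CA,
#' EI + CA + SA when the candidates are the three indices, otherwise every
#' single model plus the full model). Complete or quasi-complete separation
#' is detected, flagged, and the final model's coefficients are refit with
#' a small ridge penalty.
#'
#' @param table data.frame with `group` and candidate columns.
#' @param candidates character vector of predictor columns
#'   (default `c("EI", "CA", "SA")`).
#' @param positive group label treated as the outcome (default `"NPH"`).
#' @return object of class `stepwise_result`: `selected` (character),
#'   `models` (data.frame of per-model AUC + CI), `trace` (character),
#'   `separation` (logical), `coefficients` (final model, ridge-refit when
#'   separated).
#' @export
stepwise_logistic <- function(table, candidates = c("EI", "CA", "SA"),
                              positive = "NPH") {
  stopifnot(all(candidates %in% names(table)))
  y <- as.integer(table$group == positive)
  if (all(y == 0L) || all(y == 1L)) stop("outcome has a single class")
  dat <- data.frame(y = y, table[, candidates, drop = FALSE])
  full <- stats::as.formula(paste("y ~", paste(candidates, collapse = " + ")))
  sep_flag <- FALSE
  fit_full <- withCallingHandlers(
    stats::glm(full, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        sep_flag <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  trace_txt <- utils::capture.output(
    sel <- suppressWarnings(
      stats::step(fit_full, direction = "both", trace = 1,
                  scope = list(lower = y ~ 1, upper = full))))
  selected <- setdiff(all.vars(stats::formula(sel)), "y")
  fitted_p <- stats::fitted(sel)
  if (any(fitted_p < 1e-8 | fitted_p > 1 - 1e-8)) sep_flag <- TRUE
  coefs <- if (sep_flag && length(selected)) {
    ridge_logistic(dat[, selected, drop = FALSE], y)
  } else stats::coef(sel)
  model_sets <- if (setequal(candidates, c("EI", "CA", "SA"))) {
    list(EI = "EI", CA = "CA", SA = "SA", `SA + EI` = c("SA", "EI"),
         `SA + CA` = c("SA", "CA"), `EI + CA + SA` = c("EI", "CA", "SA"))
  } else {
    sets <- c(as.list(candidates), list(candidates))
    names(sets) <- c(candidates, paste(candidates, collapse = " + "))
    sets
  }
  models <- do.call(rbind, lapply(names(model_sets), function(nm) {
    f <- stats::as.formula(paste("y ~", paste(model_sets[[nm]], collapse = " + ")))
    g <- suppressWarnings(stats::glm(f, family = stats::binomial(), data = dat))
    r <- roc_screen(stats::predict(g), y == 1L, direction = "higher")
    data.frame(model = nm, auc = r$auc, ci_lo = r$auc_ci[1L],
               ci_hi = r$auc_ci[2L], stringsAsFactors = FALSE)
  }))
  structure(list(selected = selected, models = models, trace = trace_txt,
                 separation = sep_flag, coefficients = coefs),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Stepwise logistic prediction (AIC, bidirectional)\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = " + ")
      else "(intercept only)", "\n")
  if (x$separation) cat("  [flagged: separation; ridge-refit coefficients]\n")
  print(x$models, row.names = FALSE)
  invisible(x)
}
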