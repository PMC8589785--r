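# Replicated simulation of the published screening results.
#
# The headline screening numbers derive from a 76-subject case-control
# sample; they are reproduced stochastically by drawing cohorts of n = 19
# per group from Gaussians with the canonical Table-of-moments parameters
# and averaging the empirical ROC quantities over many seeded replicates.

#' Replicated screening-performance targets
#'
#' Simulates `replicates` cohorts (n per group from the canonical group
#' moments), runs the package's ROC and pairwise-comparison machinery on
#' each, and aggregates:
#' \describe{
#'   \item{sa_auc_nph_vs_hc}{mean empirical AUC of SA, NPH vs HC (lower SA
#'     favours NPH).}
#'   \item{sa_auc_pooled}{mean empirical AUC of SA, NPH vs pooled
#'     HC+PD+AD.}
#'   \item{ca_auc_min_pairwise}{minimum over the three NPH-vs-other pairs
#'     of the replicate-averaged CA AUC.}
#'   \item{ei_auc_pooled}{mean empirical AUC of EI, NPH vs pooled (higher
#'     EI favours NPH).}
#'   \item{sa_bh_max_p}{median over replicates of the maximum BH-adjusted
#'     p-value among the three NPH contrasts for SA (adjustment over all
#'     six pairs).}
#'   \item{ca_auc_pooled}{mean empirical AUC of CA, NPH vs pooled.}
#' }
#'
#' @param seed master seed; every replicate derives its own child seed.
#' @param replicates number of replicates (default 1000).
#' @param n per-group sample size (default 19, the study design).
#' @return named list of the aggregated values, with attribute
#'   `"replicates"`.
#' @export
screening_targets <- function(seed = 1, replicates = 1000, n = 19) {
  seeds <- derive_seeds(seed, replicates)
  mom <- default_group_moments()
  acc <- matrix(NA_real_, replicates, 8,
                dimnames = list(NULL, c("sa_hc", "sa_pool", "ca_hc", "ca_pd",
                                        "ca_ad", "ei_pool", "ca_pool",
                                        "sa_bh")))
  for (i in seq_len(replicates)) {
    tab <- simulate_cohort(mom, seed = seeds[i], n = n)
    nph <- tab$group == "NPH"
    pair_auc <- function(measure, other, dir) {
      sub <- tab[tab$group %in% c("NPH", other), ]
      roc_screen(sub[[measure]], sub$group == "NPH", direction = dir)$auc
    }
    acc[i, "sa_hc"] <- pair_auc("SA", "HC", "lower")
    acc[i, "sa_pool"] <- roc_screen(tab$SA, nph, "lower")$auc
    acc[i, "ca_hc"] <- pair_auc("CA", "HC", "lower")
    acc[i, "ca_pd"] <- pair_auc("CA", "PD", "lower")
    acc[i, "ca_ad"] <- pair_auc("CA", "AD", "lower")
    acc[i, "ei_pool"] <- roc_screen(tab$EI, nph, "higher")$auc
    acc[i, "ca_pool"] <- roc_screen(tab$CA, nph, "lower")$auc
    pw <- pairwise_bh(tab, "SA")$pairs
    is_nph <- pw$group1 == "NPH" | pw$group2 == "NPH"
    acc[i, "sa_bh"] <- max(pw$p_adjusted[is_nph])
  }
  m <- colMeans(acc)
  out <- list(
    sa_auc_nph_vs_hc = unname(m["sa_hc"]),
    sa_auc_pooled = unname(m["sa_pool"]),
    ca_auc_min_pairwise = unname(min(m[c("ca_hc", "ca_pd", "ca_ad")])),
    ei_auc_pooled = unname(m["ei_pool"]),
    sa_bh_max_p = unname(stats::median(acc[, "sa_bh"])),
    ca_auc_pooled = unname(m["ca_pool"]))
  attr(out, "replicates") <- replicates
  out
}

#' Follow-up power under the published change parameters
#'
#' Simulates the 6-vs-5 shunt / no-shunt follow-up design from the
#' canonical delta parameters and returns the fraction of replicates in
#' which the between-arm Student t test on the SA change is significant at
#' 0.05.
#'
#' @param seed master seed.
#' @param replicates number of replicates (default 500).
#' @return fraction of significant replicates.
#' @export
followup_power_sa <- function(seed = 1, replicates = 500) {
  seeds <- derive_seeds(seed, 2L * replicates)
  mom <- default_group_moments()
  sig <- vapply(seq_len(replicates), function(i) {
    base <- simulate_cohort(mom, seed = seeds[2L * i - 1L])
    f <- simulate_followup(base[base$group == "NPH", ], seed = seeds[2L * i])
    shunt_change_test(f)$p[3] < 0.05
  }, logical(1))
  mean(sig)
}
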