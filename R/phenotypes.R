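#' Per-replicate larval phenotype rates
#'
#' Computes the four assay rates from a long count table: production =
#' D-stage larvae / incubated eggs, survival = survivors / starting
#' D-larvae, adhesive = adherent / eye-spot larvae, and growth = relative
#' mean shell-height gain `(after - before) / before` (set
#' `growth_mode = "absolute"` for the plain height gain instead).
#'
#' @param tab `data.frame` with columns `trait` (one of `production`,
#'   `survival`, `growth`, `adhesive`), `group`, `replicate`, `numerator`,
#'   `denominator`.
#' @param growth_mode `"relative"` (default) or `"absolute"`.
#' @return The table with a `rate` column appended.
#' @examples
#' compute_rates(data.frame(trait = "production", group = "ctrl",
#'                          replicate = 1, numerator = 200, denominator = 400))
#' @export
compute_rates <- function(tab, growth_mode = c("relative", "absolute")) {
  growth_mode <- match.arg(growth_mode)
  need <- c("trait", "group", "replicate", "numerator", "denominator")
  if (!all(need %in% names(tab)))
    stop("trait table needs columns: ", paste(need, collapse = ", "))
  if (any(tab$denominator <= 0)) stop("zero or negative denominator")
  bad <- setdiff(unique(tab$trait),
                 c("production", "survival", "growth", "adhesive"))
  if (length(bad) > 0)
    stop("unknown trait(s): ", paste(bad, collapse = ", "))
  is_growth <- tab$trait == "growth"
  rate <- tab$numerator / tab$denominator
  if (growth_mode == "relative") {
    rate[is_growth] <- (tab$numerator[is_growth] - tab$denominator[is_growth]) /
      tab$denominator[is_growth]
  } else {
    rate[is_growth] <- tab$numerator[is_growth] - tab$denominator[is_growth]
  }
  tab$rate <- rate
  tab
}

#' One-way ANOVA for a trait across groups
#'
#' Classical fixed-effects one-way ANOVA (between/within mean-square F
#' ratio) of per-replicate rates across groups, with the usual significance
#' stars: `*` for p < 0.05 and `**` for p < 0.01.
#'
#' @param rate numeric response (per-replicate rates).
#' @param group group labels (coerced to factor).
#' @return A list: `f`, `p`, `df_between`, `df_within`, `stars`.
#' @export
one_way_anova <- function(rate, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("need at least 2 replicates per group")
  wss <- sum(tapply(rate, group, function(x) sum((x - mean(x))^2)))
  if (wss == 0)
    stop("degenerate within-group variance (all replicates identical)")
  fit <- aov(rate ~ group)
  sm <- summary(fit)[[1]]
  f <- sm[["F value"]][1]
  p <- sm[["Pr(>F)"]][1]
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(f = f, p = p, df_between = sm[["Df"]][1], df_within = sm[["Df"]][2],
       stars = stars)
}

#' Pairwise Welch t-tests with BH adjustment
#'
#' Post-hoc pairwise comparisons following the omnibus ANOVA: Welch
#' (unequal-variance) two-sample t-tests for every group pair, adjusted
#' across pairs by Benjamini-Hochberg.
#'
#' @inheritParams one_way_anova
#' @return The adjusted p-value matrix from [stats::pairwise.t.test()].
#' @export
pairwise_welch <- function(rate, group) {
  res <- pairwise.t.test(rate, factor(group), p.adjust.method = "BH",
                         pool.sd = FALSE)
  res$p.value
}

#' qPCR relative expression (2^-ddCt)
#'
#' Standard relative expression from cycle thresholds:
#' `ddCt = (Ct_target,test - Ct_ref,test) - (Ct_target,ctrl - Ct_ref,ctrl)`
#' and fold change `2^-ddCt`.
#'
#' @param ct_target_test,ct_ref_test,ct_target_ctrl,ct_ref_ctrl finite Ct
#'   values (vectorised).
#' @return The fold change(s).
#' @examples
#' relative_expression(20, 18, 22, 19)  # ddCt = -1, fold 2
#' @export
relative_expression <- function(ct_target_test, ct_ref_test,
                                ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
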