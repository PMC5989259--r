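#' Per-site F_ST estimator components
#'
#' Hudson-type estimator with finite-sample correction: for pool allele
#' frequencies `p1`, `p2` and effective sample sizes `n1`, `n2`,
#' the numerator is `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and the
#' denominator `p1(1-p2) + p2(1-p1)`. The numerator can be negative at a
#' single site (its expectation is zero under no differentiation); window
#' values are the ratio of summed numerators to summed denominators, so
#' negative site components must not be clamped. A Nei/Wright-style
#' alternative (`(p1-p2)^2 / 4` over `pbar * qbar`, no finite-sample
#' correction) is available for sensitivity checks.
#'
#' @param p1,p2 allele frequencies in `[0, 1]` (vectorised).
#' @param n1,n2 effective sample sizes (chromosomes); must be `>= 2` for the
#'   Hudson estimator.
#' @param estimator `"hudson"` (default) or `"nei"`.
#' @return A `data.frame` with `numerator` and `denominator`.
#' @examples
#' with(site_fst(0.9, 40, 0.1, 40), numerator / denominator)  # ~0.775
#' @export
site_fst <- function(p1, n1, p2, n2, estimator = c("hudson", "nei")) {
  estimator <- match.arg(estimator)
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1))
    stop("frequencies must be in [0, 1]")
  if (estimator == "hudson") {
    if (any(n1 <= 1 | n2 <= 1))
      stop("effective sample sizes must be > 1 for the Hudson estimator")
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    pbar <- (p1 + p2) / 2
    num <- (p1 - p2)^2 / 4
    den <- pbar * (1 - pbar)
  }
  data.frame(numerator = num, denominator = den)
}

#' Site F_ST components for two pools of a site table
#'
#' Computes per-site pool frequencies and estimator components between two
#' pools. The effective sample size per pool is `min(2 * pool_size, depth)`:
#' pooled reads cannot carry more information than the chromosomes in the
#' pool.
#'
#' @param sites a (filtered) pooled site table.
#' @param pool_a,pool_b pool names.
#' @param pool_size diploid individuals per pool.
#' @param estimator passed to [site_fst()].
#' @return A `data.frame` sorted by scaffold and position: `scaffold`,
#'   `pos`, `p_a`, `p_b`, `n_a`, `n_b`, `numerator`, `denominator`.
#' @export
fst_components <- function(sites, pool_a, pool_b, pool_size = 46,
                           estimator = c("hudson", "nei")) {
  estimator <- match.arg(estimator)
  pools <- .site_pools(sites)
  for (p in c(pool_a, pool_b))
    if (!p %in% pools) stop("pool '", p, "' not present in the site table")
  ra <- sites[[paste0("ref_", pool_a)]]; aa <- sites[[paste0("alt_", pool_a)]]
  rb <- sites[[paste0("ref_", pool_b)]]; ab <- sites[[paste0("alt_", pool_b)]]
  p_a <- pool_allele_frequency(ra, aa)
  p_b <- pool_allele_frequency(rb, ab)
  n_a <- pmin(2 * pool_size, ra + aa)
  n_b <- pmin(2 * pool_size, rb + ab)
  comp <- site_fst(p_a, n_a, p_b, n_b, estimator = estimator)
  out <- data.frame(scaffold = sites$scaffold, pos = sites$pos,
                    p_a = p_a, p_b = p_b, n_a = n_a, n_b = n_b,
                    numerator = comp$numerator,
                    denominator = comp$denominator)
  out <- out[order(out$scaffold, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Windowed F_ST over tiling windows
#'
#' Aggregates site components into non-overlapping windows of `window_size`
#' bp, with boundaries at multiples of `window_size` from the scaffold
#' start. The window F_ST is the ratio of summed numerators to summed
#' denominators over the SNPs in the window (ratio of averages). Windows
#' without SNPs are not represented; windows whose summed denominator is
#' zero carry `NA` and are excluded from ranking.
#'
#' @param comp site components from [fst_components()], sorted by scaffold
#'   and position.
#' @param window_size window width in bp (default 1000).
#' @return A `data.frame`: `scaffold`, `start` (0-based window start),
#'   `end`, `n_snps`, `numerator`, `denominator`, `fst`.
#' @export
window_fst <- function(comp, window_size = 1000) {
  if (window_size < 1) stop("`window_size` must be positive")
  if (nrow(comp) == 0) stop("no site components supplied")
  ord <- order(comp$scaffold, comp$pos)
  if (any(ord != seq_len(nrow(comp))))
    stop("site components must be sorted by scaffold and position")
  win_start <- ((comp$pos - 1L) %/% window_size) * window_size
  key <- paste(comp$scaffold, format(win_start, scientific = FALSE,
                                     trim = TRUE))
  agg <- rowsum(cbind(numerator = comp$numerator,
                      denominator = comp$denominator,
                      n_snps = 1), group = key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(scaffold = comp$scaffold[first],
                    start = win_start[first],
                    end = win_start[first] + window_size,
                    n_snps = as.integer(agg[, "n_snps"]),
                    numerator = agg[, "numerator"],
                    denominator = agg[, "denominator"])
  out$fst <- ifelse(out$denominator > 0,
                    out$numerator / out$denominator, NA_real_)
  out <- out[order(out$scaffold, out$start), ]
  rownames(out) <- NULL
  attr(out, "window_size") <- window_size
  out
}

#' Select the top F_ST windows
#'
#' Ranks the windows with defined F_ST (and at least `min_snps` SNPs) from
#' high to low and flags the top `ceiling(fraction * n_ranked)` as outlier
#' windows. Ties at the cutoff are broken by (scaffold, start) order so the
#' selection is deterministic.
#'
#' @param windows a window table from [window_fst()].
#' @param fraction fraction of ranked windows to select (default 0.01).
#' @param min_snps minimum SNPs for a window to be ranked (default 1).
#' @return The window table with `rank` (NA for unranked windows) and
#'   `is_outlier` columns added; the number selected is in
#'   `attr(, "n_selected")`.
#' @export
select_top_windows <- function(windows, fraction = 0.01, min_snps = 1) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  ranked <- !is.na(windows$fst) & windows$n_snps >= min_snps
  if (!any(ranked)) stop("no rankable windows (all empty or undefined)")
  k <- ceiling(fraction * sum(ranked))
  idx <- which(ranked)
  ord <- idx[order(-windows$fst[idx], windows$scaffold[idx],
                   windows$start[idx])]
  windows$rank <- NA_integer_
  windows$rank[ord] <- seq_along(ord)
  windows$is_outlier <- !is.na(windows$rank) & windows$rank <= k
  attr(windows, "n_selected") <- k
  windows
}
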