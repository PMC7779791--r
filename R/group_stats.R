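#' Two-sample t-test (pooled variance)
#'
#' Classical equal-variance two-sample t statistic with a two-sided p
#' value. The pooled form (rather than Welch) matches the conventional
#' "two samples t-test" phrasing; groups with degenerate pooled variance
#' return `NA` for both values.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 values.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`, `se_a`, `se_b`.
#' @export
two_sample_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  va <- var(group_a); vb <- var(group_b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  if (!is.finite(sp2) || sp2 <= 0)
    return(list(t = NA_real_, p = NA_real_, df = df,
                mean_a = mean(group_a), mean_b = mean(group_b),
                se_a = sqrt(va / na), se_b = sqrt(vb / nb)))
  t <- (mean(group_a) - mean(group_b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df), df = df,
       mean_a = mean(group_a), mean_b = mean(group_b),
       se_a = sqrt(va / na), se_b = sqrt(vb / nb))
}

#' Bonferroni-Holm step-down correction
#'
#' Step-down Holm adjustment: with p-values sorted ascending,
#' `adjusted_(i) = max_{j <= i} min(1, (m - j + 1) * p_(j))`, and the
#' rejection flags follow the sequential stopping rule at level `alpha`.
#' Holm rejects at least everything plain Bonferroni rejects.
#'
#' @param pvals numeric vector of raw p-values in \[0, 1\].
#' @param alpha family-wise error level, default 0.05.
#' @return list with `adjusted` (same order as input) and `reject`
#'   (logical).
#' @export
holm_correct <- function(pvals, alpha = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  m <- length(pvals)
  o <- order(pvals)
  adj_sorted <- cummax(pmin(1, (m - seq_len(m) + 1) * pvals[o]))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  # sequential rule: stop at the first sorted p exceeding its threshold
  thresholds <- alpha / (m - seq_len(m) + 1)
  pass <- pvals[o] <= thresholds
  k <- match(FALSE, pass, nomatch = m + 1L) - 1L
  reject <- logical(m)
  if (k >= 1) reject[o[seq_len(k)]] <- TRUE
  list(adjusted = adjusted, reject = reject)
}

signif_stars <- function(p) {
  ifelse(is.na(p), "ns",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' Univariate group comparison of DELPHI measures per hotspot
#'
#' For each measure and hotspot, a pooled two-sample t-test of healthy vs
#' injured values, Holm-corrected. The default correction family is all
#' hotspot cells within one measure panel (the per-panel asterisk
#' convention); `family = "global"` corrects across every
#' (measure, hotspot) cell instead.
#'
#' @param features data.frame from [delphi_features()] (needs a `group`
#'   column with two levels).
#' @param measures measure columns to compare.
#' @param family `"per_measure"` (default) or `"global"`.
#' @param alpha family-wise level for the rejection flags.
#' @return `ComparisonTable` data.frame: `measure`, `hotspot`, group means
#'   and standard errors, `t`, `p`, `p_adj`, `reject`, `stars`.
#' @export
compare_groups <- function(features,
                           measures = c("epd", "lpd", "wfa", "stp"),
                           family = c("per_measure", "global"),
                           alpha = 0.05) {
  family <- match.arg(family)
  grps <- sort(unique(features$group))
  if (length(grps) != 2) stop("exactly two groups are required, got: ",
                              paste(grps, collapse = ", "))
  hotspots <- unique(features$hotspot)
  grid <- expand.grid(measure = measures, hotspot = hotspots,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- features$hotspot == grid$hotspot[i]
    v <- features[[grid$measure[i]]][sel]
    g <- features$group[sel]
    ok <- !is.na(v)
    tt <- two_sample_t(v[ok & g == grps[1]], v[ok & g == grps[2]])
    data.frame(measure = grid$measure[i], hotspot = grid$hotspot[i],
               mean_healthy = tt$mean_a, se_healthy = tt$se_a,
               mean_injured = tt$mean_b, se_injured = tt$se_b,
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$p_adj <- NA_real_; tab$reject <- NA
  if (family == "global") {
    ok <- !is.na(tab$p)
    hc <- holm_correct(tab$p[ok], alpha)
    tab$p_adj[ok] <- hc$adjusted; tab$reject[ok] <- hc$reject
  } else {
    for (m in measures) {
      sel <- tab$measure == m & !is.na(tab$p)
      if (any(sel)) {
        hc <- holm_correct(tab$p[sel], alpha)
        tab$p_adj[sel] <- hc$adjusted; tab$reject[sel] <- hc$reject
      }
    }
  }
  tab$stars <- signif_stars(tab$p_adj)
  tab
}
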