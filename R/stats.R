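#' Average region metrics within subject, method, macro-region and pairing
#'
#' Metric values are averaged across brain regions separately for each
#' (subject, method, macro-region, pairing type) cell.  Undefined values
#' are excluded from the mean and counted in per-metric exclusion columns,
#' so failed or empty regions never bias a summary invisibly.
#'
#' @param rows long metrics table from \code{\link{evaluate_pairs}}.
#' @return summary data frame with mean \code{dsc}, \code{iou},
#'   \code{hd_mm}, \code{vd}, a region count \code{n_regions} and
#'   \code{*_excluded} counts.
#' @export
aggregate_metrics <- function(rows) {
  key <- interaction(rows$subject, rows$method, rows$macro_region,
                     rows$pairing_type, drop = TRUE)
  out <- lapply(split(rows, key), function(g) {
    data.frame(
      subject = g$subject[1], method = g$method[1],
      macro_region = g$macro_region[1], pairing_type = g$pairing_type[1],
      n_regions = nrow(g),
      dsc = mean(g$dsc, na.rm = TRUE), iou = mean(g$iou, na.rm = TRUE),
      hd_mm = mean(g$hd_mm, na.rm = TRUE), vd = mean(g$vd, na.rm = TRUE),
      dsc_excluded = sum(is.na(g$dsc)), iou_excluded = sum(is.na(g$iou)),
      hd_excluded = sum(is.na(g$hd_mm)), vd_excluded = sum(is.na(g$vd)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Nonparametric comparison of two methods
#'
#' Compares the per-subject summary values of one metric between two
#' methods within a macro-region and pairing type.  When both methods
#' cover identical subject sets a two-sided Wilcoxon signed-rank test on
#' the paired values is used; otherwise a two-sided Mann-Whitney U test.
#' All-zero paired differences are degenerate and flagged instead of
#' tested.
#'
#' @param summary summary table from \code{\link{aggregate_metrics}}.
#' @param method_a,method_b method names to compare.
#' @param metric one of \code{"dsc"}, \code{"iou"}, \code{"hd_mm"},
#'   \code{"vd"}.
#' @param macro_region macro-region to restrict to.
#' @param pairing_type pairing type to restrict to (\code{NULL} for
#'   designs without one, e.g. test-retest summaries).
#' @return one-row data frame: \code{comparison}, \code{macro_region},
#'   \code{pairing_type}, \code{metric}, \code{test_name},
#'   \code{statistic}, \code{p_raw}, \code{degenerate}, \code{n_a},
#'   \code{n_b}.
#' @export
compare_methods <- function(summary, method_a, method_b, metric,
                            macro_region, pairing_type = NULL) {
  stopifnot(metric %in% c("dsc", "iou", "hd_mm", "vd"))
  sel <- summary$macro_region == macro_region
  if (!is.null(pairing_type)) sel <- sel & summary$pairing_type == pairing_type
  sa <- summary[sel & summary$method == method_a, ]
  sb <- summary[sel & summary$method == method_b, ]
  if (nrow(sa) < 3 || nrow(sb) < 3)
    stop("need at least 3 observations per method")
  res <- data.frame(comparison = paste(method_a, "vs", method_b),
                    macro_region = macro_region,
                    pairing_type = pairing_type %||% NA_character_,
                    metric = metric, test_name = NA_character_,
                    statistic = NA_real_, p_raw = NA_real_,
                    degenerate = FALSE, n_a = nrow(sa), n_b = nrow(sb),
                    stringsAsFactors = FALSE)
  paired <- setequal(sa$subject, sb$subject) &&
    !anyDuplicated(sa$subject) && !anyDuplicated(sb$subject)
  if (paired) {
    x <- sa[[metric]][order(sa$subject)]
    y <- sb[[metric]][order(sb$subject)]
    if (all(abs(x - y) < 1e-12)) {
      res$degenerate <- TRUE
      return(res)
    }
    wt <- stats::wilcox.test(x, y, paired = TRUE, alternative = "two.sided")
    res$test_name <- "wilcoxon"
  } else {
    wt <- stats::wilcox.test(sa[[metric]], sb[[metric]],
                             alternative = "two.sided")
    res$test_name <- "mannwhitney"
  }
  res$statistic <- unname(wt$statistic)
  res$p_raw <- wt$p.value
  res
}

#' Benjamini-Hochberg correction per metric family
#'
#' Applies the step-up BH procedure to the raw p values, separately within
#' each evaluation metric's family of comparisons, and flags significance
#' at adjusted p < 0.05.  Degenerate (untested) rows are left \code{NA}.
#'
#' @param results data frame of stacked \code{\link{compare_methods}}
#'   rows.
#' @param alpha significance level (default 0.05).
#' @return \code{results} with \code{p_adjusted} and \code{significant}
#'   columns added.
#' @export
bh_adjust <- function(results, alpha = 0.05) {
  results$p_adjusted <- NA_real_
  for (m in unique(results$metric)) {
    sel <- results$metric == m & !is.na(results$p_raw)
    results$p_adjusted[sel] <- stats::p.adjust(results$p_raw[sel],
                                               method = "BH")
  }
  results$significant <- !is.na(results$p_adjusted) &
    results$p_adjusted < alpha
  results
}
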