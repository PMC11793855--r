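#' Confusion matrix for the perfusion classifier
#'
#' Builds the 2x2 confusion counts with the good-perfusion group as the
#' positive class: TP = good recognized as good, FP = good recognized as
#' poor, TN = poor recognized as poor, FN = poor recognized as good.
#'
#' @param truth,predicted Vectors of `"good"`/`"poor"` labels.
#' @return A one-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  ok <- c("good", "poor")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    abort("labels must be 'good' or 'poor'")
  }
  tibble(
    tp = sum(truth == "good" & predicted == "good"),
    fp = sum(truth == "good" & predicted == "poor"),
    tn = sum(truth == "poor" & predicted == "poor"),
    fn = sum(truth == "poor" & predicted == "good")
  )
}

#' Binary-classification metrics in percent
#'
#' Positive predictive value `100 tp / (tp + fp)`, sensitivity
#' `100 tp / (tp + fn)`, their harmonic mean (F-measure), and accuracy
#' `100 (tp + tn) / total`. A metric with a zero denominator is reported as
#' `NA`. Values are returned unrounded; the published tables use 2-decimal
#' display rounding.
#'
#' @param cm A confusion matrix: one-row data frame (or named list/vector)
#'   with `tp`, `fp`, `tn`, `fn`.
#' @return One-row tibble with `ppv`, `sensitivity`, `f_measure`,
#'   `accuracy`, all in percent.
#' @export
#' @examples
#' perf_metrics(data.frame(tp = 13, fp = 3, tn = 12, fn = 2))
perf_metrics <- function(cm) {
  cm <- as.list(cm)
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  if (any(c(tp, fp, tn, fn) < 0)) abort("confusion counts must be non-negative")
  total <- tp + fp + tn + fn
  safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  ppv <- safe(tp, tp + fp)
  sens <- safe(tp, tp + fn)
  f <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0) {
    2 * sens * ppv / (sens + ppv)
  } else NA_real_
  acc <- safe(tp + tn, total)
  tibble(ppv = ppv, sensitivity = sens, f_measure = f, accuracy = acc)
}

#' Reconstruct integer confusion matrices from printed percentages
#'
#' Published reports often give only the total count, PPV and sensitivity.
#' This exhaustively searches all integer `(tp, fp, tn, fn)` with the given
#' total whose PPV and sensitivity, rounded to 2 decimals, match the
#' printed values within `tol`, and returns every match with its implied
#' F-measure and accuracy.
#'
#' @param total Total number of classified trials.
#' @param ppv,sensitivity Printed percentages.
#' @param tol Tolerance on the 2-decimal-rounded percentages.
#' @return Tibble of matching matrices (possibly empty) with their metrics.
#' @export
#' @examples
#' reconstruct_confusion(30, 81.25, 86.67)
reconstruct_confusion <- function(total, ppv, sensitivity, tol = 0.005) {
  if (total < 1) abort("total must be at least 1")
  rows <- list()
  for (tp in 0:total) {
    for (fp in 0:(total - tp)) {
      for (fn in 0:(total - tp - fp)) {
        tn <- total - tp - fp - fn
        m <- perf_metrics(list(tp = tp, fp = fp, tn = tn, fn = fn))
        if (is.na(m$ppv) || is.na(m$sensitivity)) next
        if (abs(round(m$ppv, 2) - ppv) <= tol &&
            abs(round(m$sensitivity, 2) - sensitivity) <= tol) {
          rows[[length(rows) + 1L]] <-
            dplyr::bind_cols(tibble(tp = tp, fp = fp, tn = tn, fn = fn), m)
        }
      }
    }
  }
  if (!length(rows)) {
    return(tibble(tp = integer(), fp = integer(), tn = integer(),
                  fn = integer(), ppv = numeric(), sensitivity = numeric(),
                  f_measure = numeric(), accuracy = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Group-difference tests for perfusion index values
#'
#' Thin wrappers over the standard routines: two-sided pairwise t-tests
#' (Welch by default, pooled-variance via `var_equal = TRUE`) between every
#' pair of groups, plus a Kruskal-Wallis test across all groups.
#' Significance is flagged at `alpha`.
#'
#' @param data Data frame with a value column and a group column.
#' @param value,group Column names (strings).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param alpha Significance level for the flags.
#' @return List with `pairwise` (tibble: group pair, t-test p-value,
#'   significance flag; degenerate pairs get `NA`) and `kruskal_wallis`
#'   (one-row tibble).
#' @export
group_compare <- function(data, value, group, var_equal = FALSE,
                          alpha = 0.05) {
  v <- data[[value]]
  g <- as.character(data[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  lv <- sort(unique(g))
  if (length(lv) < 2) abort("need at least two groups")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  pw <- purrr::map(pairs, function(pr) {
    a <- v[g == pr[1]]; b <- v[g == pr[2]]
    p <- if (length(a) >= 2 && length(b) >= 2 && (sd(a) > 0 || sd(b) > 0)) {
      t.test(a, b, var.equal = var_equal)$p.value
    } else NA_real_
    tibble(group_1 = pr[1], group_2 = pr[2], n_1 = length(a),
           n_2 = length(b), p_value = p,
           significant = !is.na(p) & p < alpha)
  }) |> dplyr::bind_rows()
  kw <- kruskal.test(v, factor(g))
  list(
    pairwise = pw,
    kruskal_wallis = tibble(statistic = unname(kw$statistic),
                            df = unname(kw$parameter),
                            p_value = kw$p.value,
                            significant = kw$p.value < alpha)
  )
}
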