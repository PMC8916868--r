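check_scores <- function(score, label, positive) {
  if (length(score) != length(label)) {
    abort_validation("`score` and `label` must have the same length")
  }
  if (any(!is.finite(score))) abort_validation("scores must be finite")
  is_case <- label == positive
  if (!any(is_case) || all(is_case)) {
    abort_validation("need at least one case and one control")
  }
  is_case
}

#' ROC curve of a labeled score set
#'
#' Computes one operating point per distinct score threshold (a subject is
#' called a case when `score > threshold`; ties are grouped at a single
#' threshold), plus the `(0, 0)` and `(1, 1)` endpoints. Higher scores are
#' taken to indicate cases.
#'
#' @param data Data frame of per-subject scores.
#' @param score,label Columns (tidy-eval) holding the numeric score and the
#'   group label.
#' @param positive Label value identifying cases.
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, ordered from
#'   `(0, 0)` to `(1, 1)`; both coordinates are nondecreasing.
#' @examples
#' d <- tibble::tibble(score = c(0.9, 0.8, 0.1, 0.2),
#'                     group = c("case", "case", "control", "control"))
#' roc_curve(d, score, group)
#' @export
roc_curve <- function(data, score, label, positive = "case") {
  sc <- dplyr::pull(data, {{ score }})
  lb <- dplyr::pull(data, {{ label }})
  is_case <- check_scores(sc, lb, positive)
  n_case <- sum(is_case); n_ctrl <- sum(!is_case)
  thr <- sort(unique(sc), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(sc[is_case] > t) / n_case, numeric(1))
  fpr <- vapply(thr, function(t) sum(sc[!is_case] > t) / n_ctrl, numeric(1))
  tibble::tibble(threshold = c(Inf, thr, -Inf),
                 fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' Area under a ROC curve
#'
#' Trapezoidal area under the curve returned by [roc_curve()]. By the
#' grouped-tie construction of the curve this equals the Mann--Whitney
#' statistic: the fraction of case--control pairs in which the case scores
#' higher, counting ties as 1/2.
#'
#' @param roc Tibble of ROC points with columns `fpr` and `tpr`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  if (!all(c("fpr", "tpr") %in% names(roc)) || nrow(roc) < 2L) {
    abort_validation("`roc` must have fpr/tpr columns and >= 2 points")
  }
  fpr <- roc$fpr; tpr <- roc$tpr
  if (is.unsorted(fpr) || is.unsorted(tpr) ||
      fpr[1L] != 0 || tpr[1L] != 0 ||
      fpr[length(fpr)] != 1 || tpr[length(tpr)] != 1) {
    abort_validation("malformed ROC curve: coordinates must be nondecreasing from (0,0) to (1,1)")
  }
  sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1L]) / 2)
}

#' Optimal cutoff by Youden's J
#'
#' Scans candidate cutoffs (the midpoints between adjacent distinct sorted
#' scores) and returns the threshold maximizing
#' `J = sensitivity + specificity - 1`, calling a subject a case when
#' `score > threshold`. Ties in `J` are broken toward the smallest
#' threshold.
#'
#' @inheritParams roc_curve
#' @return One-row tibble with `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
youden_threshold <- function(data, score, label, positive = "case") {
  sc <- dplyr::pull(data, {{ score }})
  lb <- dplyr::pull(data, {{ label }})
  is_case <- check_scores(sc, lb, positive)
  u <- sort(unique(sc))
  cand <- if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2 else u
  sens <- vapply(cand, function(t) mean(sc[is_case] > t), numeric(1))
  spec <- vapply(cand, function(t) mean(sc[!is_case] <= t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1L]  # smallest threshold among ties
  tibble::tibble(threshold = cand[best], sensitivity = sens[best],
                 specificity = spec[best], youden_j = j[best])
}

#' Full diagnostic evaluation of a labeled score set
#'
#' Bundles [roc_curve()], [roc_auc()] and [youden_threshold()] into a single
#' result object with [tidy()], [glance()] and [autoplot()] methods.
#'
#' @inheritParams roc_curve
#' @return An object of class `diag_result` with fields `roc` (tibble),
#'   `auc`, `threshold`, `sensitivity`, `specificity`, `n_case`, `n_control`.
#' @export
diagnostic_eval <- function(data, score, label, positive = "case") {
  sc <- dplyr::pull(data, {{ score }})
  lb <- dplyr::pull(data, {{ label }})
  is_case <- check_scores(sc, lb, positive)
  d <- tibble::tibble(score = sc, label = ifelse(is_case, "case", "control"))
  roc <- roc_curve(d, score, label, positive = "case")
  yj <- youden_threshold(d, score, label, positive = "case")
  structure(
    list(roc = roc, auc = roc_auc(roc), threshold = yj$threshold,
         sensitivity = yj$sensitivity, specificity = yj$specificity,
         youden_j = yj$youden_j,
         n_case = sum(is_case), n_control = sum(!is_case)),
    class = "diag_result")
}

#' @export
print.diag_result <- function(x, ...) {
  cat("Diagnostic evaluation (", x$n_case, "cases,", x$n_control, "controls )\n")
  cat(sprintf("  AUC         %.4f\n", x$auc))
  cat(sprintf("  threshold  >%.4g (Youden)\n", x$threshold))
  cat(sprintf("  sensitivity %.3f   specificity %.3f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' @rdname diagnostic_eval
#' @param x A `diag_result`.
#' @param ... Unused.
#' @method tidy diag_result
#' @export
tidy.diag_result <- function(x, ...) x$roc

#' @rdname diagnostic_eval
#' @method glance diag_result
#' @export
glance.diag_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, threshold = x$threshold,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 n_case = x$n_case, n_control = x$n_control)
}

#' Lesion-stage summary table
#'
#' Counts per pathological stage (edema, sclerotic, atrophic) with percent
#' of all lesions, reported to two decimals.
#'
#' @param counts Named nonnegative integer vector of lesion counts per
#'   stage, or a data frame with columns `stage` and `count`.
#' @return Tibble with columns `stage`, `count`, `percent`.
#' @examples
#' stage_summary(c(edema = 7, sclerotic = 42, atrophic = 47))
#' @export
stage_summary <- function(counts) {
  if (is.data.frame(counts)) {
    if (!all(c("stage", "count") %in% names(counts))) {
      abort_validation("data frame input needs `stage` and `count` columns")
    }
    stage <- as.character(counts$stage); cnt <- counts$count
  } else {
    if (is.null(names(counts)) || !is.numeric(counts)) {
      abort_validation("`counts` must be a named numeric vector or data frame")
    }
    stage <- names(counts); cnt <- unname(counts)
  }
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    abort_validation("counts must be nonnegative integers", field = "count")
  }
  total <- sum(cnt)
  if (total == 0) abort_validation("total count must be positive", field = "count")
  tibble::tibble(stage = stage, count = as.integer(cnt),
                 percent = round(100 * cnt / total, 2))
}

#' Two-group comparison with a normality gate
#'
#' Compares a measurement between two groups the way clinical tables do:
#' if both groups pass a Shapiro--Wilk normality check at alpha = 0.05,
#' Welch's independent-sample t-test is used; otherwise a Wilcoxon rank-sum
#' test. Groups of fewer than 3 observations or with zero variance are
#' treated as non-normal.
#'
#' @param data Data frame of per-subject measurements.
#' @param value,group Columns (tidy-eval) holding the measurement and the
#'   two-level group label.
#' @return One-row tibble with `method` (`"welch_t"` or `"wilcoxon"`),
#'   `statistic` and `p_value`.
#' @export
compare_groups <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  lev <- unique(g)
  if (length(lev) != 2L) abort_validation("`group` must have exactly two levels")
  a <- v[g == lev[1L]]; b <- v[g == lev[2L]]
  if (length(a) < 2L || length(b) < 2L) {
    abort_validation("each group needs at least 2 observations")
  }
  looks_normal <- function(x) {
    if (length(x) < 3L || length(x) > 5000L || sd(x) == 0) return(FALSE)
    shapiro.test(x)$p.value >= 0.05
  }
  if (looks_normal(a) && looks_normal(b)) {
    ht <- t.test(a, b, var.equal = FALSE)
    tibble::tibble(method = "welch_t", statistic = unname(ht$statistic),
                   p_value = ht$p.value)
  } else {
    ht <- suppressWarnings(wilcox.test(a, b))
    tibble::tibble(method = "wilcoxon", statistic = unname(ht$statistic),
                   p_value = ht$p.value)
  }
}
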