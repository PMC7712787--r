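#' Classify Miller-Payne grades into responders and non-responders
#'
#' Grades 4 and 5 are responders; grades 1-3 are non-responders.
#'
#' @param grade integer vector with values in 1..5.
#' @return logical vector, `TRUE` for responders.
#' @export
classify_response <- function(grade) {
  if (length(grade) == 0L) return(logical(0))
  if (anyNA(grade) || any(grade != round(grade)) || any(grade < 1 | grade > 5))
    stop("grade must be an integer in 1..5 (Miller-Payne scale)")
  grade >= 4
}

#' ROC analysis with DeLong confidence interval and Youden-optimal cutoff
#'
#' The AUC is computed through the Mann-Whitney U identity (ties counted 1/2).
#' The score orientation is chosen so that the reported AUC is >= 0.5 and is
#' recorded in `direction`: `"responder_high"` means responders tend to have
#' higher scores (predict responder when score >= cutoff),
#' `"responder_low"` the opposite (predict responder when score <= cutoff).
#' The 95 percent CI uses the DeLong variance of the placement values and the
#' p-value tests AUC = 0.5 by normal approximation. The optimal cutoff
#' maximizes Youden's J (sensitivity + specificity - 1) over midpoints between
#' adjacent distinct observed scores; ties are broken towards higher
#' sensitivity, then the more extreme threshold (farther from the score
#' median), then the lower threshold.
#'
#' Missing scores are dropped pairwise with their labels.
#'
#' @param scores numeric vector.
#' @param labels logical vector (`TRUE` = responder), same length.
#' @param conf_level confidence level of the CI (default 0.95).
#' @return an object of class `roc_result`: `auc`, `ci_low`, `ci_high`, `se`,
#'   `p_value`, `cutoff`, `sensitivity`, `specificity` (percent), `direction`,
#'   `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels, conf_level = 0.95) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- as.numeric(scores[keep]); labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("roc_analysis needs at least one responder and one non-responder")

  auc_raw <- auc_mwu(scores, labels)
  direction <- if (auc_raw >= 0.5) "responder_high" else "responder_low"
  z <- if (direction == "responder_high") scores else -scores

  pos <- z[labels]; neg <- z[!labels]
  # DeLong placement values
  v10 <- vapply(pos, function(p) (sum(neg < p) + 0.5 * sum(neg == p)) / n_neg, numeric(1))
  v01 <- vapply(neg, function(q) (sum(pos > q) + 0.5 * sum(pos == q)) / n_pos, numeric(1))
  auc <- mean(v10)
  s10 <- if (n_pos > 1L) var(v10) else 0
  s01 <- if (n_neg > 1L) var(v01) else 0
  se <- sqrt(s10 / n_pos + s01 / n_neg)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * zq * se, 0), 1)
  p_value <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se) else if (auc == 0.5) 1 else 0

  cut <- youden_cutoff(z, labels)
  cutoff <- if (direction == "responder_high") cut$threshold else -cut$threshold

  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2], se = se,
                 p_value = p_value, cutoff = cutoff,
                 sensitivity = cut$sensitivity, specificity = cut$specificity,
                 direction = direction, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

# AUC via the Mann-Whitney U identity, ties counted 1/2 (responder-high sense)
auc_mwu <- function(scores, labels) {
  n_pos <- sum(labels); n_neg <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Youden-optimal threshold on oriented scores (responders high). Thresholds
# are midpoints between adjacent distinct scores; classify positive at
# score >= threshold.
youden_cutoff <- function(z, labels) {
  u <- sort(unique(z))
  thr <- if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2 else u
  pos <- z[labels]; neg <- z[!labels]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1)) * 100
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1)) * 100
  j <- sens + spec - 100
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1L) best <- best[sens[best] >= max(sens[best]) - 1e-12]
  if (length(best) > 1L) {
    extremity <- abs(thr[best] - median(z))
    best <- best[extremity >= max(extremity) - 1e-12]
  }
  best <- best[which.min(thr[best])]
  list(threshold = thr[best], sensitivity = sens[best], specificity = spec[best],
       j = j[best])
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$auc, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  cutoff %.4g (%s): sensitivity %.0f%%, specificity %.0f%% (n = %d/%d)\n",
              x$cutoff, x$direction, x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Filter patient records by molecular subtype
#'
#' `"HER2_negative"` keeps HER2-negative patients, `"triple_negative"` keeps
#' patients negative for ER, PR and HER2; `"all"` returns the input unchanged.
#' Patients with a missing flag needed by the filter are dropped.
#'
#' @param records a `data.frame` with logical columns `ER`, `PR`, `HER2`.
#' @param subtype one of `"all"`, `"HER2_negative"`, `"triple_negative"`.
#' @return the filtered `data.frame`.
#' @export
subgroup_filter <- function(records, subtype = c("all", "HER2_negative", "triple_negative")) {
  subtype <- match.arg(subtype)
  if (subtype == "all") return(records)
  if (!all(c("ER", "PR", "HER2") %in% names(records)))
    stop("records must have ER, PR and HER2 columns")
  keep <- switch(subtype,
                 HER2_negative = !is.na(records$HER2) & !records$HER2,
                 triple_negative = !is.na(records$ER) & !is.na(records$PR) &
                   !is.na(records$HER2) & !records$ER & !records$PR & !records$HER2)
  records[keep, , drop = FALSE]
}

#' Two-sided Mann-Whitney U comparison of two samples
#'
#' Used to compare classifier metrics before and after data augmentation.
#' For small samples (both groups <= 8) the p-value is computed by exhaustive
#' enumeration of all group assignments of the pooled ranks (ties handled by
#' midranks); for larger samples the normal approximation with tie correction
#' is used.
#'
#' @param values_pre,values_post non-empty numeric vectors.
#' @return two-sided p-value.
#' @export
rank_compare <- function(values_pre, values_post) {
  x <- as.numeric(values_pre); y <- as.numeric(values_post)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y), ties.method = "average")
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  if (m <= 8L && n <= 8L) {
    idx <- combn(N, m)
    dev_obs <- abs(u_obs - mu)
    devs <- abs(colSums(matrix(r[idx], nrow = m)) - m * (m + 1) / 2 - mu)
    return(mean(devs >= dev_obs - 1e-9))
  }
  ties <- table(r)
  sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  min(1, 2 * pnorm(-abs(u_obs - mu) / sqrt(sigma2)))
}
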