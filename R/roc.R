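#' Empirical AUC (Mann-Whitney form)
#'
#' Trapezoidal area under the empirical ROC curve, identical to the
#' Mann-Whitney concordance probability with ties counted 1/2, computed via
#' midranks.
#'
#' @param scores numeric predictor values (higher = more event-like).
#' @param labels binary event indicator (1 = positive / CHE).
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, labels) {
  y <- as.numeric(labels)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  if (length(pos) == 0L || length(neg) == 0L) stop("both classes are required")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# DeLong structural components: V10 (per positive), V01 (per negative)
.delong_components <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' ROC analysis with DeLong confidence interval and operating point
#'
#' Builds the empirical ROC over all score thresholds, computes the AUC with
#' a DeLong-variance 95% CI on the logit scale (clipped to \[0, 1\]), fixes
#' the operating threshold — either the Youden-maximizing threshold on the
#' supplied (training) scores or a fixed threshold carried over from
#' training — and reports accuracy, sensitivity and specificity at that
#' threshold with the event (CHE) as the positive class. A subject is called
#' positive when its score is >= the threshold.
#'
#' @param scores numeric scores (e.g. predicted probabilities).
#' @param labels binary event indicator (1 = positive) or labels coercible
#'   via `positive_class`.
#' @param operating `"youden"` to derive the threshold from these scores, or
#'   `"fixed"` to apply `threshold` unchanged (testing-set evaluation).
#' @param threshold required when `operating = "fixed"`.
#' @param positive_class used when `labels` is not already 0/1.
#' @return A `roc_result`: `thresholds`, `sensitivity`, `specificity`,
#'   `auc`, `auc_var`, `auc_ci_95`, `operating_threshold`, `acc`, `sen`,
#'   `spe`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels, operating = c("youden", "fixed"),
                         threshold = NULL, positive_class = "CHE") {
  operating <- match.arg(operating)
  y <- if (all(labels %in% c(0, 1))) as.numeric(labels)
       else as.numeric(as.character(labels) == positive_class)
  if (length(unique(y)) != 2L) stop("both classes are required")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  thr <- sort(unique(scores))
  sen <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  spe <- vapply(thr, function(t) mean(scores[y == 0] < t), numeric(1))
  comp <- .delong_components(scores, y)
  auc <- comp$auc
  v <- stats::var(comp$v10) / n_pos + stats::var(comp$v01) / n_neg
  ci <- if (v == 0 || auc %in% c(0, 1)) {
    c(auc, auc)
  } else {
    lg <- stats::qlogis(auc)
    se_lg <- sqrt(v) / (auc * (1 - auc))
    stats::plogis(lg + c(-1, 1) * stats::qnorm(0.975) * se_lg)
  }
  op <- if (operating == "youden") thr[which.max(sen + spe - 1)] else {
    if (is.null(threshold)) stop("operating = 'fixed' needs a threshold")
    threshold
  }
  call_pos <- scores >= op
  structure(
    list(thresholds = thr, sensitivity = sen, specificity = spe,
         auc = auc, auc_var = v, auc_ci_95 = pmin(pmax(ci, 0), 1),
         operating_threshold = op,
         acc = mean(call_pos == (y == 1)),
         sen = mean(call_pos[y == 1]),
         spe = mean(!call_pos[y == 0]),
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the same subjects
#' using the structural-component covariance; two-sided z-test. Degenerate
#' variance (e.g. a model compared to itself) returns p = 1 by convention.
#'
#' @param scores_a,scores_b score vectors on the same subjects.
#' @param labels binary event indicator (1 = positive).
#' @return List: `auc_a`, `auc_b`, `auc_diff`, `var_diff`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as.numeric(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(y))
    stop("paired test: both score vectors must cover the same subjects")
  ca <- .delong_components(scores_a, y)
  cb <- .delong_components(scores_b, y)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n_pos +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n_neg
  d <- ca$auc - cb$auc
  if (var_diff <= 0) {
    return(list(auc_a = ca$auc, auc_b = cb$auc, auc_diff = d,
                var_diff = max(var_diff, 0), z = 0, p_value = 1))
  }
  z <- d / sqrt(var_diff)
  list(auc_a = ca$auc, auc_b = cb$auc, auc_diff = d, var_diff = var_diff,
       z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
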