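#' Stratified train/test split
#'
#' Independently within each class, `floor(ratio * n_class)` subjects go to
#' the training set and the remainder to testing; the permutation is driven
#' entirely by `seed`. A 54/52 two-class cohort at ratio 0.7 therefore splits
#' into 73 training (37 + 36) and 33 testing (17 + 16) subjects.
#'
#' @param table data frame with `subject_id` and `group` columns.
#' @param ratio training fraction.
#' @param seed RNG seed for the permutation.
#' @return A `split_assignment`: `train_ids`, `test_ids`, `ratio`, `seed`.
#' @export
split_cohort <- function(table, ratio = 0.7, seed = 1L) {
  groups <- unique(table$group)
  if (length(groups) != 2L) stop("exactly two classes are required")
  counts <- table(table$group)
  if (any(counts < 2L)) stop("each class needs at least 2 members")
  set.seed(as.integer(seed))
  train_ids <- character(0)
  for (g in sort(groups)) {
    ids <- table$subject_id[table$group == g]
    n_train <- floor(ratio * length(ids))
    train_ids <- c(train_ids, sample(ids, n_train))
  }
  structure(
    list(train_ids = sort(train_ids),
         test_ids = sort(setdiff(table$subject_id, train_ids)),
         ratio = ratio, seed = as.integer(seed)),
    class = "split_assignment"
  )
}

#' Normality-gated univariate filter
#'
#' Per feature: Shapiro-Wilk within each group; if both groups pass at
#' p >= 0.05, a two-sided pooled-variance t-test compares the groups,
#' otherwise a two-sided Mann-Whitney U test (normal approximation with tie
#' and continuity correction). Features with p < `alpha` are kept; no
#' multiplicity correction is applied. A feature with zero variance in the
#' pooled sample is excluded with a logged reason (both tests are undefined
#' there); a feature constant within one group only is routed to the
#' Mann-Whitney branch (Shapiro-Wilk is undefined on constants).
#'
#' @param features data frame or matrix of training features (subjects x
#'   features).
#' @param labels factor/character vector of group labels, two classes.
#' @param alpha significance threshold.
#' @return A `univariate_result`: `kept` (names), `p_values` (named, NA for
#'   excluded-degenerate), `test_used`, `excluded_degenerate`.
#' @export
univariate_filter <- function(features, labels, alpha = 0.05) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes are required")
  if (min(table(labels)) < 3L) stop("both groups need at least 3 subjects")
  features <- as.data.frame(features)
  g1 <- labels == levels(labels)[1]
  p_values <- rep(NA_real_, ncol(features))
  test_used <- rep(NA_character_, ncol(features))
  names(p_values) <- names(test_used) <- colnames(features)
  for (j in seq_len(ncol(features))) {
    x <- features[[j]]
    a <- x[g1]; b <- x[!g1]
    if (stats::var(x) == 0) next  # degenerate: no test defined
    normal <- function(v) {
      if (stats::var(v) == 0) return(FALSE)
      stats::shapiro.test(v)$p.value >= 0.05
    }
    if (normal(a) && normal(b)) {
      p_values[j] <- stats::t.test(a, b, var.equal = TRUE)$p.value
      test_used[j] <- "t"
    } else {
      p_values[j] <- suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
      )
      test_used[j] <- "mann-whitney"
    }
  }
  excluded <- colnames(features)[is.na(p_values)]
  structure(
    list(kept = colnames(features)[!is.na(p_values) & p_values < alpha],
         p_values = p_values, test_used = test_used,
         excluded_degenerate = excluded, alpha = alpha),
    class = "univariate_result"
  )
}

#' Spearman redundancy pruning
#'
#' Features are scanned in order of ascending univariate p-value; a feature
#' is admitted only if its absolute Spearman correlation with every
#' already-admitted feature is <= `rho_threshold` (strictly greater triggers
#' exclusion). Of a correlated group, the most discriminative member (the
#' smallest univariate p) therefore survives.
#'
#' @param features training feature data frame.
#' @param kept candidate feature names (survivors of the univariate filter).
#' @param p_values named univariate p-values used for the scan order.
#' @param rho_threshold exclusion threshold on |rho|.
#' @return Character vector of surviving feature names.
#' @export
redundancy_filter <- function(features, kept, p_values, rho_threshold = 0.9) {
  if (length(kept) == 0L) stop("no candidate features to prune")
  features <- as.data.frame(features)
  ord <- kept[order(p_values[kept])]
  admitted <- character(0)
  rank_cache <- list()
  for (f in ord) {
    rf <- rank(features[[f]])
    ok <- TRUE
    for (a in admitted) {
      rho <- abs(stats::cor(rf, rank_cache[[a]]))
      if (is.na(rho) || rho > rho_threshold) { ok <- FALSE; break }
    }
    if (ok) {
      admitted <- c(admitted, f)
      rank_cache[[f]] <- rf
    }
  }
  admitted
}
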