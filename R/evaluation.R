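#' Build a nomogram from the R-C model
#'
#' Maps each predictor value to points on a 0-100 scale: the predictor with
#' the largest coefficient-times-range span covers exactly 0-100 and every
#' other predictor is scaled proportionally,
#' `points_j(v) = 100 * beta_j (v - ref_j) / max_k |beta_k| range_k`, with
#' `ref_j` the range endpoint giving 0 points (so points are never
#' negative). The total-points axis maps back to predicted probability
#' through the logistic inverse of the reconstructed linear predictor, so
#' reading a subject off the nomogram reproduces the model probability.
#'
#' @param model the fitted R-C classifier.
#' @param data data frame of the training predictor values (columns
#'   `radscore`, `nh3`, `child_pugh` as ordinal 1/2/3) defining each axis
#'   range.
#' @param n_axis_points grid points per predictor axis in the emitted table.
#' @return A `nomogram`: per-predictor point tables, `points_fun`
#'   (value -> points per predictor), `total_to_prob`, and the axis ranges.
#' @export
build_nomogram <- function(model, data, n_axis_points = 50L) {
  stopifnot(inherits(model, "fitted_classifier"), model$kind == "R-C")
  beta <- model$coefficients
  if (!all(is.finite(beta))) stop("nomogram needs finite model coefficients")
  preds <- model$predictors
  rng <- lapply(preds, function(p) range(data[[p]]))
  names(rng) <- preds
  span <- vapply(preds, function(p) abs(beta[[p]]) * diff(rng[[p]]), numeric(1))
  if (all(span == 0)) stop("all predictors have zero span; no points scale")
  dropped <- preds[span == 0]
  if (length(dropped) > 0L)
    warning("zero-range predictor(s) excluded from the points scale: ",
            paste(dropped, collapse = ", "))
  max_span <- max(span)
  ref <- vapply(preds, function(p) {
    if (beta[[p]] >= 0) rng[[p]][1] else rng[[p]][2]
  }, numeric(1))
  points_fun <- function(predictor, value) {
    100 * beta[[predictor]] * (value - ref[[predictor]]) / max_span
  }
  axes <- lapply(preds, function(p) {
    v <- if (p == "child_pugh") 1:3 else seq(rng[[p]][1], rng[[p]][2],
                                             length.out = n_axis_points)
    data.frame(predictor = p, value = v, points = points_fun(p, v))
  })
  names(axes) <- preds
  # lp = b0 + sum_j beta_j v_j = b0 + sum_j beta_j ref_j + max_span/100 * T
  lp0 <- beta[["(Intercept)"]] + sum(vapply(preds, function(p)
    beta[[p]] * ref[[p]], numeric(1)))
  total_to_prob <- function(total_points) {
    stats::plogis(lp0 + max_span / 100 * total_points)
  }
  structure(
    list(axes = axes, points_fun = points_fun, total_to_prob = total_to_prob,
         ranges = rng, ref = ref, max_span = max_span, model_kind = model$kind),
    class = "nomogram"
  )
}

#' Read subjects off a nomogram
#'
#' Sums the per-predictor points and converts total points to probability;
#' the round trip agrees with the model's own predicted probability.
#'
#' @param nomogram a [build_nomogram()] result.
#' @param data predictor data frame (`radscore`, `nh3`, `child_pugh`).
#' @return Numeric vector of nomogram-read probabilities.
#' @export
nomogram_probability <- function(nomogram, data) {
  total <- Reduce(`+`, lapply(names(nomogram$axes), function(p) {
    nomogram$points_fun(p, data[[p]])
  }))
  nomogram$total_to_prob(total)
}

#' Calibration bins and the Hosmer-Lemeshow test
#'
#' Groups subjects into `g` bins by deciles of predicted probability
#' (quantile cut, ties to the lower bin), compares observed event fractions
#' with mean predicted probabilities, and computes the Hosmer-Lemeshow
#' statistic `sum (O - E)^2 / (E (1 - E / n_bin))` on `g - 2` degrees of
#' freedom. Bins whose expected count is 0 or equal to the bin size are
#' merged with their neighbour and the degrees of freedom reduced.
#'
#' @param pred_probs predicted probabilities in \[0, 1\].
#' @param outcomes binary outcomes.
#' @param g number of bins.
#' @return A `calibration_result`: `bins` (mean predicted, observed
#'   fraction, n per bin), `hl_chi2`, `hl_df`, `hl_p`.
#' @export
calibration <- function(pred_probs, outcomes, g = 10L) {
  p <- as.numeric(pred_probs)
  y <- as.numeric(outcomes)
  if (any(p < 0 | p > 1)) stop("predicted probabilities must lie in [0, 1]")
  if (!all(y %in% c(0, 1))) stop("outcomes must be binary")
  if (length(p) < g) stop("need at least g subjects")
  qs <- unique(stats::quantile(p, probs = seq(0, 1, length.out = g + 1),
                               type = 2))
  if (length(qs) < 3L) qs <- c(-Inf, stats::median(p), Inf)
  bin <- cut(p, breaks = qs, include.lowest = TRUE, labels = FALSE)
  tab <- data.frame(
    bin = sort(unique(bin)),
    n = as.vector(table(bin)),
    mean_pred = as.vector(tapply(p, bin, mean)),
    obs_frac = as.vector(tapply(y, bin, mean)),
    expected = as.vector(tapply(p, bin, sum)),
    observed = as.vector(tapply(y, bin, sum))
  )
  # merge degenerate bins (expected 0 or n) into the neighbour
  merged <- 0L
  i <- 1L
  while (i <= nrow(tab)) {
    if (nrow(tab) > 1L && (tab$expected[i] <= 0 || tab$expected[i] >= tab$n[i])) {
      j <- if (i == nrow(tab)) i - 1L else i + 1L
      tab$n[j] <- tab$n[j] + tab$n[i]
      tab$expected[j] <- tab$expected[j] + tab$expected[i]
      tab$observed[j] <- tab$observed[j] + tab$observed[i]
      tab$mean_pred[j] <- tab$expected[j] / tab$n[j]
      tab$obs_frac[j] <- tab$observed[j] / tab$n[j]
      tab <- tab[-i, , drop = FALSE]
      merged <- merged + 1L
    } else i <- i + 1L
  }
  chi2 <- sum((tab$observed - tab$expected)^2 /
                (tab$expected * (1 - tab$expected / tab$n)))
  df <- max(1L, nrow(tab) - 2L)
  structure(
    list(bins = tab[, c("n", "mean_pred", "obs_frac")],
         hl_chi2 = chi2, hl_df = df,
         hl_p = stats::pchisq(chi2, df, lower.tail = FALSE),
         merged_bins = merged),
    class = "calibration_result"
  )
}

#' Spearman correlations between signature features and clinical variables
#'
#' Pairwise Spearman rho and p (t-approximation) between the signature
#' features plus Radscore and the clinical/cognitive variables (NCT-A, DST,
#' NH3, Child-Pugh as ordinal, age, sex as 0/1, education). No multiplicity
#' correction. A constant column yields an undefined rho, reported as NA.
#'
#' @param features feature data frame containing the signature columns.
#' @param clinical clinical data frame.
#' @param signature a `radscore_model` (adds the Radscore row); optional.
#' @param feature_names which feature columns to correlate; defaults to the
#'   signature's features.
#' @return A `correlation_report`: matrices `rho` and `p` (features x
#'   clinical variables).
#' @export
correlation_report <- function(features, clinical, signature = NULL,
                               feature_names = signature$feature_names) {
  if (is.null(feature_names)) stop("supply feature_names or a signature")
  clin <- data.frame(
    nct_a = clinical$nct_a,
    dst = clinical$dst,
    nh3 = clinical$nh3,
    child_pugh = child_pugh_ordinal(clinical$child_pugh),
    age = clinical$age,
    sex = as.numeric(clinical$sex == "M"),
    education = clinical$education
  )
  fmat <- features[, feature_names, drop = FALSE]
  if (!is.null(signature)) fmat$Radscore <- radscore(signature, features)
  if (nrow(fmat) < 5L) stop("need at least 5 complete pairs")
  rho <- matrix(NA_real_, ncol(fmat), ncol(clin),
                dimnames = list(colnames(fmat), colnames(clin)))
  pmat <- rho
  for (i in seq_len(ncol(fmat))) {
    for (j in seq_len(ncol(clin))) {
      x <- fmat[[i]]; z <- clin[[j]]
      if (stats::sd(x) == 0 || stats::sd(z) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(x, z, method = "spearman", exact = FALSE)
      )
      rho[i, j] <- unname(ct$estimate)
      pmat[i, j] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = pmat), class = "correlation_report")
}
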