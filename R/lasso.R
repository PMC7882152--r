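#' LASSO signature discovery with 10-fold cross-validation
#'
#' Minimizes the squared-error LASSO objective
#' \deqn{\frac{1}{n}\sum_i (y_i - \beta_0 - x_i\beta)^2 + \lambda \|\beta\|_1}
#' on 0/1-coded class labels by cyclic coordinate descent over a log-spaced
#' lambda path from `lambda_max` (the smallest lambda with an all-zero
#' solution, `max_j |(2/n) sum_i x_ij (y_i - ybar)|`) down four decades.
#' Features are z-scored (population sd) on training statistics; the
#' intercept is the label mean. `lambda_min` is the path point with minimum
#' mean squared prediction error under stratified k-fold cross-validation
#' (minimum rule, no 1-SE rule); fold assignment is a function of `seed`
#' only. The objective is checked non-increasing after every sweep; an
#' increase or failure to converge raises an error with diagnostics rather
#' than returning a silent partial fit.
#'
#' @param features training feature data frame/matrix (subjects x features).
#' @param labels two-class labels; the positive (CHE) class is coded 1.
#' @param n_folds cross-validation folds.
#' @param seed RNG seed for fold assignment.
#' @param positive_class label coded 1; defaults to `"CHE"` when present,
#'   else the first factor level.
#' @param n_lambda path length.
#' @param lambda_min_ratio smallest path lambda as a fraction of lambda_max;
#'   by the usual convention this defaults to 1e-4 when n > p and 0.01 in
#'   the overparameterized n <= p regime, where smaller lambdas only
#'   interpolate.
#' @return A `lasso_fit`: `lambda_path`, `cv_mean`, `cv_se`, `lambda_min`,
#'   `beta` (standardized scale), `intercept`, `center`/`scale`,
#'   `selected_names`, `n_folds`, `seed`.
#' @export
lasso_select <- function(features, labels, n_folds = 10L, seed = 1L,
                         positive_class = NULL, n_lambda = 100L,
                         lambda_min_ratio = NULL) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (is.null(lambda_min_ratio))
    lambda_min_ratio <- if (n > ncol(X)) 1e-4 else 0.01
  if (n < n_folds) stop("need at least n_folds subjects")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("exactly two classes are required")
  if (is.null(positive_class))
    positive_class <- if ("CHE" %in% classes) "CHE" else classes[1]
  y <- as.numeric(labels == positive_class)
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  if (any(scl == 0)) stop("zero-variance feature(s): ",
                          paste(colnames(X)[scl == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  lambda_max <- max(abs(2 / n * crossprod(Xs, y - mean(y))))
  lambda_path <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                         length.out = n_lambda))
  folds <- .stratified_folds(y, n_folds, seed)
  cv_se_mat <- matrix(NA_real_, n_folds, n_lambda)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    ctr_k <- colMeans(X[tr, , drop = FALSE])
    scl_k <- sqrt(colMeans(sweep(X[tr, , drop = FALSE], 2, ctr_k)^2))
    scl_k[scl_k == 0] <- 1  # constant-in-fold column carries no signal
    Xk <- sweep(sweep(X[tr, , drop = FALSE], 2, ctr_k), 2, scl_k, "/")
    Xv <- sweep(sweep(X[!tr, , drop = FALSE], 2, ctr_k), 2, scl_k, "/")
    yk <- y[tr]
    betas <- .cd_path(Xk, yk, lambda_path)
    pred <- sweep(Xv %*% betas, 2, rep(mean(yk), n_lambda), "+")
    cv_se_mat[k, ] <- colMeans((pred - y[!tr])^2)
  }
  cv_mean <- colMeans(cv_se_mat)
  cv_se <- apply(cv_se_mat, 2, stats::sd) / sqrt(n_folds)
  i_min <- which(cv_mean == min(cv_mean))[1]  # ties break to larger lambda
  betas_full <- .cd_path(Xs, y, lambda_path[seq_len(i_min)])
  beta <- betas_full[, i_min]
  names(beta) <- colnames(X)
  structure(
    list(lambda_path = lambda_path, cv_mean = cv_mean, cv_se = cv_se,
         lambda_min = lambda_path[i_min], beta = beta, intercept = mean(y),
         center = ctr, scale = scl,
         selected_names = colnames(X)[beta != 0],
         positive_class = positive_class,
         n_folds = n_folds, seed = as.integer(seed)),
    class = "lasso_fit"
  )
}

# stratified fold labels, a function of (y, n_folds, seed) only
.stratified_folds <- function(y, n_folds, seed) {
  set.seed(as.integer(seed))
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# coordinate descent over a decreasing lambda path with warm starts and an
# active-set strategy (iterate on the nonzero set, then one full sweep to
# re-check the KKT conditions); X columns centered/scaled so
# (1/n) sum x_j^2 = 1, intercept = mean(y). Convergence is declared when a
# full sweep changes no coefficient by more than tol or improves the
# objective by less than a 1e-10 relative margin; the objective is asserted
# non-increasing after every sweep.
.cd_path <- function(X, y, lambda_path, tol = 1e-6, max_sweeps = 10000L) {
  n <- nrow(X); p <- ncol(X)
  yc <- y - mean(y)
  xsq <- colMeans(X^2)          # 1 for standardized, kept general
  beta <- numeric(p)
  r <- yc                       # residual yc - X beta
  out <- matrix(0, p, length(lambda_path))
  env <- environment()
  sweep_set <- function(idx, lam) {
    delta_max <- 0
    for (j in idx) {
      if (xsq[j] == 0) next
      bj_old <- beta[j]
      z <- 2 / n * sum(X[, j] * r) + 2 * xsq[j] * bj_old
      bj_new <- sign(z) * max(abs(z) - lam, 0) / (2 * xsq[j])
      if (bj_new != bj_old) {
        env$r <- r - X[, j] * (bj_new - bj_old)
        env$beta[j] <- bj_new
        delta_max <- max(delta_max, abs(bj_new - bj_old))
      }
    }
    delta_max
  }
  objective <- function(lam) mean(r^2) + lam * sum(abs(beta))
  for (l in seq_along(lambda_path)) {
    lam <- lambda_path[l]
    obj_prev <- objective(lam)
    obj_tol <- 1e-10 * (1 + obj_prev)
    converged <- FALSE
    delta_max <- Inf
    for (sweep_i in seq_len(max_sweeps)) {
      full <- sweep_i == 1L || delta_max < tol
      idx <- if (full) seq_len(p) else which(beta != 0)
      delta_max <- sweep_set(idx, lam)
      obj <- objective(lam)
      if (obj > obj_prev + 1e-10) {
        stop("coordinate descent diverged at lambda = ", signif(lam, 6),
             ": objective rose from ", obj_prev, " to ", obj)
      }
      improved <- obj_prev - obj
      obj_prev <- obj
      if (full && (delta_max < tol || improved < obj_tol)) {
        converged <- TRUE
        break
      }
      if (!full && improved < obj_tol) delta_max <- 0  # force a full check
    }
    if (!converged) {
      stop("coordinate descent failed to converge at lambda = ",
           signif(lam, 6), " after ", max_sweeps,
           " sweeps (last max coefficient change ", delta_max, ")")
    }
    out[, l] <- beta
  }
  out
}

#' Run the full three-stage selection cascade
#'
#' Univariate filter, Spearman redundancy pruning, then LASSO, on the
#' training rows only. Stage survivor counts satisfy
#' |lasso| <= |redundancy| <= |univariate| <= total.
#'
#' @param features training feature data frame (subjects x features).
#' @param labels training class labels.
#' @param alpha univariate significance threshold.
#' @param rho_threshold Spearman exclusion threshold.
#' @param n_folds,seed cross-validation settings for [lasso_select()].
#' @return A `selection_report`: per-stage survivor name lists and counts,
#'   the `univariate_result` and the `lasso_fit`.
#' @export
select_features <- function(features, labels, alpha = 0.05,
                            rho_threshold = 0.9, n_folds = 10L, seed = 1L) {
  uni <- univariate_filter(features, labels, alpha = alpha)
  if (length(uni$kept) == 0L) stop("no feature survives the univariate filter")
  red <- redundancy_filter(features, uni$kept, uni$p_values, rho_threshold)
  fit <- lasso_select(features[, red, drop = FALSE], labels,
                      n_folds = n_folds, seed = seed)
  structure(
    list(counts = c(total = ncol(features), univariate = length(uni$kept),
                    redundancy = length(red), lasso = length(fit$selected_names)),
         univariate = uni, redundancy_kept = red, lasso_fit = fit,
         selected_names = fit$selected_names),
    class = "selection_report"
  )
}
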