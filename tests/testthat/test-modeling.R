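make_signature <- function(beta0, betas, center = NULL, scale = NULL) {
  structure(
    list(beta0 = beta0, betas = betas, feature_names = names(betas),
         center = if (is.null(center)) stats::setNames(rep(0, length(betas)), names(betas)) else center,
         scale = if (is.null(scale)) stats::setNames(rep(1, length(betas)), names(betas)) else scale),
    class = "radscore_model"
  )
}

test_that("Radscore is the stated linear combination", {
  sig <- make_signature(-0.553, c(f1 = 0.4, f2 = -0.2))
  zero <- data.frame(f1 = c(0, 0), f2 = c(0, 0))
  expect_equal(radscore(sig, zero), c(-0.553, -0.553))
  sig0 <- make_signature(-0.553, c(f1 = 0, f2 = 0))
  any_x <- data.frame(f1 = rnorm(3), f2 = rnorm(3))
  expect_equal(radscore(sig0, any_x), rep(-0.553, 3))
  # linearity in each term and invariance to term order
  x <- data.frame(f1 = 2, f2 = 3)
  x2 <- data.frame(f1 = 4, f2 = 3)
  expect_equal(radscore(sig, x2) - radscore(sig, x), 0.4 * 2)
  sig_r <- make_signature(-0.553, c(f2 = -0.2, f1 = 0.4))
  expect_equal(radscore(sig_r, x), radscore(sig, x))
  expect_error(radscore(sig, data.frame(f1 = 1)), "f2")
})

test_that("logistic refits recover the closed-form 2x2 odds ratio", {
  # cells (a, b, c, d) = (30, 10, 10, 30): OR = ad / bc = 9
  x <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  y <- c(rep(1, 40), rep(0, 40))
  labels <- ifelse(y == 1, "CHE", "nCHE")
  sig <- make_signature(0, c(x = 1))
  fit <- fit_r_model(data.frame(x = x), labels, sig)
  expect_equal(unname(exp(fit$coefficients["x"])), 9, tolerance = 1e-6)
  # deterministic refit
  fit2 <- fit_r_model(data.frame(x = x), labels, sig)
  expect_identical(fit$coefficients, fit2$coefficients)
})

test_that("Wald tests on null predictors reject at the nominal rate", {
  set.seed(30)
  n <- 80
  rej <- vapply(1:200, function(i) {
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.5)
    fit <- stats::glm(y ~ x, family = stats::binomial())
    summary(fit)$coefficients["x", "Pr(>|z|)"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("the AUC equals brute-force pairwise concordance", {
  scores <- c(0.1, 0.4, 0.4, 0.8, 0.2, 0.9, 0.4)
  labels <- c(0, 0, 1, 1, 0, 1, 0)
  expect_equal(auc_mw(scores, labels), bf_auc(scores, labels))
  set.seed(31)
  for (i in 1:5) {
    s <- sample(seq(0, 1, 0.05), 30, replace = TRUE)  # heavy ties
    l <- rbinom(30, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auc_mw(s, l), bf_auc(s, l))
  }
})

test_that("ROC analysis handles separation, symmetry and operating points", {
  sep_scores <- c(1:5 / 10, 6:10 / 10)
  sep_labels <- rep(c(0, 1), each = 5)
  r <- roc_analysis(sep_scores, sep_labels)
  expect_equal(r$auc, 1)
  expect_equal(r$sen, 1)
  expect_equal(r$spe, 1)
  set.seed(32)
  s <- rnorm(40); l <- rbinom(40, 1, 0.5)
  expect_equal(auc_mw(s, l) + auc_mw(-s, l), 1)
  # training-derived threshold applied unchanged to a testing set
  r_tr <- roc_analysis(s, l, operating = "youden")
  r_te <- roc_analysis(rnorm(40), rbinom(40, 1, 0.5), operating = "fixed",
                       threshold = r_tr$operating_threshold)
  expect_equal(r_te$operating_threshold, r_tr$operating_threshold)
  expect_true(all(diff(r_tr$sensitivity) <= 0))
  expect_true(r_tr$auc_ci_95[1] <= r_tr$auc && r_tr$auc <= r_tr$auc_ci_95[2])
})

test_that("the AUC and its DeLong machinery agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(33)
  y <- rbinom(60, 1, 0.5)
  s1 <- rnorm(60) + y
  s2 <- rnorm(60) + 0.5 * y
  r <- roc_analysis(s1, y)
  pr <- pROC::roc(y, s1, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  expect_equal(r$auc_var, as.numeric(pROC::var(pr, method = "delong")),
               tolerance = 1e-10)
  dt <- delong_test(s1, s2, y)
  pt <- pROC::roc.test(pr, pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(dt$p_value, as.numeric(pt$p.value), tolerance = 1e-10)
})

test_that("DeLong comparison is degenerate-safe and bootstrap-consistent", {
  set.seed(34)
  y <- rbinom(40, 1, 0.5)
  s <- rnorm(40)
  self <- delong_test(s, s, y)
  expect_equal(self$auc_diff, 0)
  expect_equal(self$p_value, 1)
  # paired bootstrap oracle for the variance of the AUC difference
  s1 <- rnorm(40) + 0.8 * y
  s2 <- rnorm(40) + 0.6 * y
  dl <- delong_test(s1, s2, y)
  boot <- vapply(1:2000, function(i) {
    idx <- sample(40, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    auc_mw(s1[idx], y[idx]) - auc_mw(s2[idx], y[idx])
  }, numeric(1))
  expect_lt(abs(stats::var(boot, na.rm = TRUE) - dl$var_diff) / dl$var_diff, 0.15)
})

test_that("informative clinical covariates lift the R-C model over R on training data", {
  set.seed(35)
  pf <- planted_features(seed = 35, p_null = 10)
  sel <- lasso_select(pf$X, pf$labels, n_folds = 5, seed = 3)
  sig <- radscore_model(sel)
  clin <- data.frame(
    nh3 = exp(rnorm(73, 3 + pf$y)),          # informative
    child_pugh = ifelse(stats::runif(73) < 0.3 + 0.4 * pf$y, "C", "A")
  )
  r <- suppressWarnings(fit_r_model(pf$X, pf$labels, sig))
  rc <- suppressWarnings(fit_rc_model(pf$X, clin, pf$labels, sig))
  auc_r <- auc_mw(predict_prob(r, pf$X), pf$y)
  auc_rc <- auc_mw(predict_prob(rc, pf$X, clin), pf$y)
  expect_gte(auc_rc, auc_r - 1e-8)
})
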