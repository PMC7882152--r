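# small fitted R-C bundle shared by the nomogram tests
fit_toy_rc <- function(seed = 40, n = 60) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n / 2)
  feat <- data.frame(f1 = rnorm(n) + 1.2 * y, f2 = rnorm(n) - 0.8 * y)
  clin <- data.frame(
    nh3 = exp(rnorm(n, 3 + 0.8 * y, 0.4)),
    child_pugh = sample(c("A", "B", "C"), n, TRUE)
  )
  labels <- ifelse(y == 1, "CHE", "nCHE")
  sig <- structure(
    list(beta0 = -0.553, betas = c(f1 = 0.9, f2 = -0.5),
         feature_names = c("f1", "f2"),
         center = c(f1 = 0, f2 = 0), scale = c(f1 = 1, f2 = 1)),
    class = "radscore_model"
  )
  rc <- suppressWarnings(fit_rc_model(feat, clin, labels, sig))
  list(rc = rc, feat = feat, clin = clin, y = y, sig = sig)
}

test_that("nomogram reading reproduces the model probabilities", {
  toy <- fit_toy_rc()
  data <- data.frame(
    radscore = radscore(toy$sig, toy$feat),
    nh3 = toy$clin$nh3,
    child_pugh = child_pugh_ordinal(toy$clin$child_pugh)
  )
  nom <- build_nomogram(toy$rc, data)
  direct <- predict_prob(toy$rc, toy$feat, toy$clin)
  via_nomogram <- nomogram_probability(nom, data)
  expect_lt(max(abs(via_nomogram - direct)), 0.01)
  # largest-span predictor covers exactly 0-100 points
  max_pts <- vapply(nom$axes, function(a) max(a$points), numeric(1))
  expect_equal(max(max_pts), 100)
  expect_true(all(unlist(lapply(nom$axes, function(a) a$points)) >= -1e-12))
})

test_that("nomogram point scaling follows the coefficient-range arithmetic", {
  # |b1 * range1| = 2 * |b2 * range2|: predictor 2 maxes at 50 points
  glmfake <- list(coefficients = c("(Intercept)" = -1, radscore = 2,
                                   nh3 = 0.01, child_pugh = 0))
  model <- structure(
    list(kind = "R-C", glm = NULL, coefficients = glmfake$coefficients,
         predictors = c("radscore", "nh3", "child_pugh")),
    class = "fitted_classifier"
  )
  data <- data.frame(radscore = c(0, 1), nh3 = c(0, 100), child_pugh = c(1, 3))
  nom <- suppressWarnings(build_nomogram(model, data))
  expect_equal(max(nom$axes$radscore$points), 100)
  expect_equal(max(nom$axes$nh3$points), 50)
  # zero-coefficient predictor: flat zero-point line
  expect_equal(unique(nom$axes$child_pugh$points), 0)
})

test_that("Hosmer-Lemeshow matches a hand-computed two-bin example", {
  # 20 subjects, g = 2: low bin p = 0.2 (3/10 observed), high p = 0.7 (6/10)
  p <- c(rep(0.2, 10), rep(0.7, 10))
  y <- c(rep(1, 3), rep(0, 7), rep(1, 6), rep(0, 4))
  res <- calibration(p, y, g = 2)
  e1 <- 2; e2 <- 7
  chi_hand <- (3 - e1)^2 / (e1 * (1 - e1 / 10)) + (6 - e2)^2 / (e2 * (1 - e2 / 10))
  expect_equal(res$hl_chi2, chi_hand, tolerance = 1e-10)
  expect_equal(res$hl_df, 1)  # g - 2 floored at 1
  expect_equal(sum(res$bins$n), 20)
})

test_that("perfectly calibrated bins give a zero HL statistic", {
  p <- rep(c(0.25, 0.75), each = 8)
  y <- c(rep(1, 2), rep(0, 6), rep(1, 6), rep(0, 2))
  res <- calibration(p, y, g = 2)
  expect_equal(res$hl_chi2, 0)
  expect_equal(res$hl_p, 1)
})

test_that("the HL test is calibrated under a well-specified model", {
  set.seed(41)
  n <- 500
  pvals <- vapply(1:200, function(i) {
    x <- rnorm(n)
    y <- rbinom(n, 1, stats::plogis(-0.4 + x))
    fit <- stats::glm(y ~ x, family = stats::binomial())
    calibration(fitted(fit), y, g = 10)$hl_p
  }, numeric(1))
  rej <- mean(pvals < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
  # approximate uniformity of the p-values
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("calibration slope is near one on a large well-specified cohort", {
  set.seed(42)
  n <- 2000
  x <- rnorm(n)
  pr <- stats::plogis(-0.5 + 1.2 * x)
  y <- rbinom(n, 1, pr)
  res <- calibration(pr, y, g = 10)
  slope <- stats::coef(stats::lm(res$bins$obs_frac ~ res$bins$mean_pred))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("Spearman correlation reports have the rank-invariance properties", {
  set.seed(43)
  n <- 30
  feat <- data.frame(f = rnorm(n), g = rnorm(n))
  clin <- data.frame(
    nct_a = feat$f + rnorm(n, sd = 0.2),  # strongly positively associated
    dst = -feat$f + rnorm(n, sd = 0.2),
    nh3 = exp(rnorm(n)), child_pugh = sample(c("A", "B", "C"), n, TRUE),
    age = rnorm(n, 55, 8), sex = sample(c("M", "F"), n, TRUE),
    education = rnorm(n, 9, 3)
  )
  rep1 <- correlation_report(feat, clin, feature_names = c("f", "g"))
  expect_gt(rep1$rho["f", "nct_a"], 0.8)
  expect_lt(rep1$rho["f", "dst"], -0.8)
  # self and negated-self correlations via a clinical alias
  clin2 <- clin; clin2$nct_a <- feat$f; clin2$dst <- -feat$f
  rep2 <- correlation_report(feat, clin2, feature_names = "f")
  expect_equal(unname(rep2$rho["f", "nct_a"]), 1)
  expect_equal(unname(rep2$rho["f", "dst"]), -1)
  # invariance under strictly monotone transforms
  feat3 <- feat; feat3$f <- exp(feat$f)
  rep3 <- correlation_report(feat3, clin, feature_names = c("f", "g"))
  expect_equal(rep3$rho["f", ], rep1$rho["f", ])
  # constant column: undefined, reported missing
  feat4 <- feat; feat4$g <- 1
  rep4 <- correlation_report(feat4, clin, feature_names = c("f", "g"))
  expect_true(all(is.na(rep4$rho["g", ])))
})
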