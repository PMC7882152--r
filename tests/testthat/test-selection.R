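test_that("stratified split reproduces the 54/52 -> 73/33 allocation", {
  tab <- data.frame(
    subject_id = sprintf("s%03d", 1:106),
    group = c(rep("CHE", 54), rep("nCHE", 52))
  )
  sp <- split_cohort(tab, ratio = 0.7, seed = 5)
  expect_length(sp$train_ids, 73)
  expect_length(sp$test_ids, 33)
  tr_groups <- tab$group[tab$subject_id %in% sp$train_ids]
  expect_equal(sum(tr_groups == "CHE"), 37)
  expect_equal(sum(tr_groups == "nCHE"), 36)
  te_groups <- tab$group[tab$subject_id %in% sp$test_ids]
  expect_equal(sum(te_groups == "CHE"), 17)
  expect_equal(sum(te_groups == "nCHE"), 16)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), tab$subject_id)
  # balanced 10 + 10 cohort
  tab2 <- data.frame(subject_id = sprintf("t%02d", 1:20),
                     group = rep(c("CHE", "nCHE"), each = 10))
  sp2 <- split_cohort(tab2, 0.7, seed = 1)
  expect_length(sp2$train_ids, 14)
  # determinism
  expect_identical(split_cohort(tab, 0.7, seed = 5), sp)
  expect_false(identical(split_cohort(tab, 0.7, seed = 6)$train_ids, sp$train_ids))
})

test_that("the univariate filter keeps strong effects and drops degenerates", {
  set.seed(8)
  n1 <- 37; n0 <- 36
  labels <- c(rep("CHE", n1), rep("nCHE", n0))
  X <- data.frame(
    strong = c(rnorm(n1, 5), rnorm(n0, 0)),   # > 5 sd separation: power ~ 1
    flat = rep(1, n1 + n0),                   # degenerate
    noise = rnorm(n1 + n0),
    skewed = exp(rnorm(n1 + n0))              # routes to Mann-Whitney
  )
  res <- univariate_filter(X, labels)
  expect_true("strong" %in% res$kept)
  expect_identical(res$excluded_degenerate, "flat")
  expect_true(is.na(res$p_values["flat"]))
  expect_identical(unname(res$test_used["skewed"]), "mann-whitney")
})

test_that("null features are kept at the nominal 5% rate", {
  set.seed(13)
  n1 <- 37; n0 <- 36; p <- 400
  labels <- c(rep("CHE", n1), rep("nCHE", n0))
  kept <- 0
  for (rep_i in 1:2) {  # 800 independent null decisions
    X <- as.data.frame(matrix(rnorm((n1 + n0) * p), n1 + n0))
    kept <- kept + length(univariate_filter(X, labels)$kept)
  }
  keep_rate <- kept / (2 * p)
  band <- 2 * sqrt(0.05 * 0.95 / (2 * p))
  expect_lt(abs(keep_rate - 0.05), band)
})

test_that("redundancy pruning keeps the most significant of a correlated group", {
  set.seed(14)
  n <- 40
  base <- rnorm(n)
  X <- data.frame(
    a = base,                     # p rank 2
    b = base + rnorm(n, sd = 1e-8),  # duplicate of a, p rank 3
    c = base + rnorm(n, sd = 1e-8),  # duplicate, p rank 1 (smallest)
    ind = rnorm(n)                # independent survivor
  )
  p_values <- c(a = 0.02, b = 0.03, c = 0.01, ind = 0.04)
  kept <- redundancy_filter(X, names(p_values), p_values, rho_threshold = 0.9)
  expect_identical(kept, c("c", "ind"))  # greedy scan in p order
  # mutually independent features all survive
  set.seed(15)
  Xi <- as.data.frame(matrix(rnorm(n * 5), n))
  pv <- stats::setNames(seq(0.01, 0.05, length.out = 5), names(Xi))
  expect_setequal(redundancy_filter(Xi, names(Xi), pv), names(Xi))
  # exact duplicate: exactly one survives
  Xd <- data.frame(x = base, y = base)
  pd <- c(x = 0.01, y = 0.02)
  expect_identical(redundancy_filter(Xd, c("x", "y"), pd), "x")
})

test_that("the cascade is monotone in survivor counts", {
  pf <- planted_features(seed = 16, p_null = 40)
  rep <- select_features(pf$X, pf$labels, n_folds = 5, seed = 1)
  cts <- rep$counts
  expect_true(cts["lasso"] <= cts["redundancy"])
  expect_true(cts["redundancy"] <= cts["univariate"])
  expect_true(cts["univariate"] <= cts["total"])
  expect_true(all(rep$selected_names %in% colnames(pf$X)))
})
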