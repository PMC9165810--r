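test_that("confusion counts and accuracy match a brute-force tally", {
  set.seed(40)
  n <- 200
  labels <- sample(0:2, n, replace = TRUE)
  preds <- sample(0:2, n, replace = TRUE)
  subj <- sample(1:5, n, replace = TRUE)
  ev <- confusion_and_accuracy(preds, labels, subj)
  for (i in 0:2) for (j in 0:2)
    expect_identical(ev$confusion[i + 1, j + 1],
                     sum(labels == i & preds == j))
  expect_equal(ev$accuracy, mean(preds == labels))
  for (s in 1:5)
    expect_equal(ev$per_subject$accuracy[ev$per_subject$subject == s],
                 mean((preds == labels)[subj == s]))
  # all-correct toy input: identity diagonal
  ev2 <- confusion_and_accuracy(0:2, 0:2)
  expect_equal(ev2$accuracy, 1)
  expect_true(all(ev2$confusion[upper.tri(ev2$confusion)] == 0))
  expect_error(confusion_and_accuracy(integer(), integer()), "empty")
})

test_that("Welch test reduces correctly on degenerate and summary inputs", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")
  # raw-sample path and summary path agree exactly
  set.seed(41)
  a <- rnorm(8); b <- rnorm(6, mean = 1)
  r1 <- welch_t_test(a, b)
  r2 <- welch_t_test(c(mean = mean(a), sd = sd(a), n = 8),
                     c(mean = mean(b), sd = sd(b), n = 6))
  expect_equal(r1$t, r2$t, tolerance = 1e-12)
  expect_equal(r1$df, r2$df, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  # independent oracle: stats::t.test without pooling
  tt <- t.test(a, b)
  expect_equal(r1$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r1$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(r1$p, tt$p.value, tolerance = 1e-10)
})

test_that("Welch p-values are symmetric and shift-invariant", {
  set.seed(42)
  for (rep in 1:20) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), mean = runif(1))
    r_ab <- welch_t_test(a, b); r_ba <- welch_t_test(b, a)
    expect_equal(r_ab$p, r_ba$p, tolerance = 1e-12)
    expect_equal(r_ab$t, -r_ba$t, tolerance = 1e-12)
    r_sh <- welch_t_test(a + 5, b + 5)
    expect_equal(r_ab$p, r_sh$p, tolerance = 1e-9)
  }
})

test_that("BH decisions match the exhaustive step-up on random vectors", {
  expect_identical(bh_fdr(rep(1, 6)), rep(FALSE, 6))
  expect_identical(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.2), 0.05),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_fdr(0.04, 0.05), TRUE)   # m = 1 reduces to p <= q
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(0.5, q = 1), "q must")
  set.seed(43)
  for (rep in 1:200) {
    m <- sample(1:20, 1)
    p <- round(runif(m), sample(1:3, 1))   # rounding creates ties
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(bh_fdr(p, q), brute_bh(p, q))
  }
})

test_that("variant comparison is order-invariant and self-comparison is null", {
  set.seed(44)
  v <- list(ref = rnorm(5, 0.85, 0.01), a = rnorm(5, 0.83, 0.01),
            b = rnorm(5, 0.80, 0.02), self = NULL)
  v$self <- v$ref
  tab <- compare_variants(v, reference = "ref")
  expect_equal(tab$p[tab$variant == "self"], 1)
  expect_false(tab$rejected[tab$variant == "self"])
  v_perm <- v[c("b", "ref", "self", "a")]
  tab2 <- compare_variants(v_perm, reference = "ref")
  for (nm in c("a", "b", "self"))
    expect_equal(tab$p[tab$variant == nm], tab2$p[tab2$variant == nm])
  expect_error(compare_variants(v, reference = "zzz"), "unknown reference")
})

test_that("cross-validation evaluates each fold on the fixed test subjects", {
  ds <- tiny_dataset(n_subjects = 6, trials_per_class = 2, seed = 45,
                     effect_channel = 3, effect = 0.9)
  plan <- make_split_plan(1:6, n_test = 2, n_folds = 2, seed = 5)
  cv <- run_cross_validation(tiny_config(), train_config(epochs = 2,
                                                         batch_size = 6,
                                                         seed = 9),
                             ds, plan)
  expect_length(cv$folds, 2)
  expect_equal(cv$mean_accuracy, mean(cv$accuracies))
  for (f in cv$folds) {
    expect_equal(sum(f$confusion),
                 sum(ds$subject %in% plan$test_subjects))
    expect_true(all(f$per_subject$subject %in% plan$test_subjects))
  }
  # leakage guard fires before training
  bad_plan <- plan
  bad_plan$folds[[1]]$train <- c(bad_plan$folds[[1]]$train,
                                 plan$test_subjects[1])
  expect_error(run_cross_validation(tiny_config(), train_config(epochs = 1),
                                    ds, bad_plan), "leakage")
})
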