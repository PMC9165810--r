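random_stack <- function(C = 5, Tn = 7, K = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(maps = array(rnorm(C * Tn * K), c(C, Tn, K)),
                 grads = array(rnorm(C * Tn * K), c(C, Tn, K)),
                 class_index = 0L, layer = "test", Z = C * Tn),
            class = "feature_map_stack")
}

test_that("alpha weights are global average pooled gradients", {
  s <- random_stack(seed = 50)
  s$grads[] <- 1
  expect_equal(alpha_weights(s), rep(1, 3))
  s$grads[] <- 0
  expect_equal(alpha_weights(s), rep(0, 3))
  s <- random_stack(seed = 51)
  expect_equal(alpha_weights(s), brute_alpha(s$grads), tolerance = 1e-12)
})

test_that("heatmaps are rectified weighted map sums", {
  s <- random_stack(C = 1, Tn = 2, K = 1)
  s$maps[, , 1] <- c(1, -1)
  expect_equal(unclass(cam_heatmap(s, alphas = 2))[1, ], c(2, 0))
  s$maps[, , 1] <- c(-1, -3)
  expect_true(all(cam_heatmap(s, alphas = 1) == 0))
  s2 <- random_stack(seed = 52)
  a <- alpha_weights(s2)
  expect_equal(unclass(cam_heatmap(s2, a)), brute_cam(s2$maps, a),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(cam_heatmap(s2, alphas = 1:2), "alpha length")
})

test_that("pre-ReLU combination is linear in the gradients", {
  s <- random_stack(seed = 53)
  a1 <- alpha_weights(s)
  s2 <- s; s2$grads <- 3 * s$grads
  expect_equal(alpha_weights(s2), 3 * a1, tolerance = 1e-12)
  pre <- function(stack, a) {
    L <- matrix(0, dim(stack$maps)[1], dim(stack$maps)[2])
    for (k in seq_along(a)) L <- L + a[k] * stack$maps[, , k]
    L
  }
  expect_equal(pre(s2, alpha_weights(s2)), 3 * pre(s, a1), tolerance = 1e-12)
})

test_that("captured stacks have layer geometry and finite-difference gradients", {
  set.seed(54)
  m <- tiny_model(dropout_p = 0, use_dropout = FALSE)
  x <- matrix(rnorm(4 * 40), 4)
  st <- capture_layer(m, x, class_index = 1, layer = "type1.2.conv")
  expect_identical(dim(st$maps), c(4L, 40L, 2L))   # channels x time x F1
  expect_identical(dim(st$grads), dim(st$maps))
  expect_identical(st$Z, 160L)
  # finite differences of y_c wrt the captured activation
  Xm <- reegnet:::batch_to_mat(x)
  yc <- function(repl) {
    fp <- reegnet:::forward_pass(m, Xm, 1, train = FALSE,
                                 replace = list(id = "type1.2.conv",
                                                value = repl))
    fp$out[2, 1]
  }
  fp0 <- reegnet:::forward_pass(m, Xm, 1, capture = "type1.2.conv")
  A0 <- fp0$captured$type1.2.conv$A
  for (probe in sample(length(A0), 8)) {
    eps <- 1e-4
    Ap <- A0; Ap[probe] <- Ap[probe] + eps
    An <- A0; An[probe] <- An[probe] - eps
    num <- (yc(Ap) - yc(An)) / (2 * eps)
    # map the flat F x (T*C) position back to (channel, time, map)
    f <- (probe - 1) %% 2 + 1
    col <- (probe - 1) %/% 2 + 1
    tt <- (col - 1) %% 40 + 1
    ch <- (col - 1) %/% 40 + 1
    expect_equal(st$grads[ch, tt, f], num, tolerance = 1e-3)
  }
  expect_error(capture_layer(m, x, 0, layer = "nope"), "unknown layer")
})

test_that("a class with a zeroed path has zero layer gradients", {
  m <- tiny_model(dropout_p = 0, use_dropout = FALSE)
  # zero the classifier row of class 2: its logit no longer depends on A
  ci <- length(m$blocks)
  m$blocks[[ci]]$layers[[1]]$W[3, ] <- 0
  m$blocks[[ci]]$layers[[1]]$b[3] <- 0
  x <- matrix(rnorm(4 * 40), 4)
  st <- capture_layer(m, x, class_index = 2, layer = "type1.2.conv",
                      score_from = "logits")
  expect_true(all(st$grads == 0))
})

test_that("correct-trial filtering groups maps by participant and task", {
  set.seed(55)
  ds <- tiny_dataset(n_subjects = 3, trials_per_class = 2, seed = 56)
  m <- tiny_model(seed = 4)
  fit <- train_model(m, subset_subjects(ds, 1:2), subset_subjects(ds, 3),
                     config = train_config(epochs = 1, batch_size = 6,
                                           seed = 3))
  groups <- gradcam_for_correct_trials(fit, ds, layer = "type1.2.conv")
  preds <- predict(fit, ds)
  expect_identical(groups$n_correct, sum(preds == ds$label))
  n_maps <- sum(unlist(lapply(groups$maps, function(task)
    vapply(task, length, 1L))))
  expect_identical(n_maps, groups$n_correct)
  # every map is non-negative
  for (task in groups$maps)
    for (subj in task)
      for (map in subj)
        expect_true(all(map >= 0))
})

test_that("channel scores and baselines follow the nested-mean arithmetic", {
  g <- structure(list(maps = list(
    rest = list(`1` = list(structure(matrix(2, 64, 10))),
                `2` = list(structure(matrix(0, 64, 10) +
                                       c(rep(0, 7), 6.4, rep(0, 56)))))),
    n_correct = 2L, n_total = 2L, layer = "x", score_from = "logp"),
    class = "gradcam_groups")
  tab <- channel_scores(g)
  expect_equal(unname(tab$rest$scores["1", ]), rep(2, 64))
  expect_equal(unname(tab$rest$baseline["1"]), 2)
  # map nonzero only on channel 8: score = its value, baseline = value/64
  expect_equal(unname(tab$rest$scores["2", 8]), 6.4)
  expect_equal(unname(tab$rest$scores["2", 9]), 0)
  expect_equal(unname(tab$rest$baseline["2"]), 0.1)
  # brute-force random case
  set.seed(57)
  trials <- lapply(1:3, function(i) matrix(abs(rnorm(64 * 5)), 64))
  g2 <- g
  g2$maps$rest <- list(`7` = trials)
  tab2 <- channel_scores(g2)
  mm <- (trials[[1]] + trials[[2]] + trials[[3]]) / 3
  expect_equal(unname(tab2$rest$scores["7", ]), unname(rowMeans(mm)),
               tolerance = 1e-12)
})

test_that("no channel beats the baseline when scores equal the baseline", {
  scores <- matrix(1, 5, 64)
  tab <- structure(list(rest = list(scores = scores,
                                    baseline = rowMeans(scores),
                                    participants = as.character(1:5))),
                   class = "channel_score_table")
  sig <- significance_vs_baseline(tab)
  expect_false(any(sig$rejected))
  expect_identical(nrow(sig), 64L)   # one family of 64 tests per task
})
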