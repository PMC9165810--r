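test_that("compiled convolutions match triple-loop oracles", {
  set.seed(20)
  for (rep in 1:5) {
    Fin <- sample(1:3, 1); Fout <- sample(1:4, 1)
    Tn <- sample(8:14, 1); K <- sample(2:5, 1); B <- sample(1:3, 1)
    pad <- (K - 1) %/% 2
    A <- matrix(rnorm(Fin * Tn * B), Fin)
    W <- matrix(rnorm(Fout * Fin * K), Fout)
    expect_equal(reegnet:::conv_time_fw(A, W, Tn, K, pad),
                 naive_conv_time(A, W, Tn, K, pad), tolerance = 1e-12)
    # depthwise = block-diagonal temporal conv
    wd <- matrix(rnorm(Fin * K), Fin)
    Od <- reegnet:::conv_dw_fw(A, wd, Tn, K, pad)
    for (f in seq_len(Fin))
      expect_equal(Od[f, , drop = FALSE],
                   naive_conv_time(A[f, , drop = FALSE],
                                   matrix(wd[f, ], 1), Tn, K, pad),
                   tolerance = 1e-12)
  }
  # spatial convolution collapses the channel blocks
  Fin <- 2; C <- 3; Tn <- 6; N <- 2; Fout <- 4
  A <- matrix(rnorm(Fin * Tn * C * N), Fin)
  W <- matrix(rnorm(Fout * Fin * C), Fout)
  expect_equal(reegnet:::conv_spatial_fw(A, W, Tn, C),
               naive_conv_spatial(A, W, Tn, C), tolerance = 1e-12)
})

test_that("log-softmax outputs normalize for arbitrary inputs", {
  set.seed(21)
  m <- tiny_model()
  for (rep in 1:5) {
    x <- array(rnorm(4 * 40 * 3, sd = sample(c(0.1, 1, 10), 1)), c(4, 40, 3))
    lp <- model_forward(m, x)
    expect_equal(rowSums(exp(lp)), rep(1, 3), tolerance = 1e-5)
  }
})

test_that("evaluation mode is deterministic; training mode uses dropout", {
  set.seed(22)
  m <- tiny_model()
  x <- array(rnorm(4 * 40 * 2), c(4, 40, 2))
  expect_identical(model_forward(m, x), model_forward(m, x))
  set.seed(1); a <- model_forward(m, x, train = TRUE)
  set.seed(2); b <- model_forward(m, x, train = TRUE)
  expect_false(identical(a, b))
  expect_error(model_forward(m, array(0, c(5, 40, 1))), "geometry")
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(23)
  m <- tiny_model(dropout_p = 0, use_dropout = FALSE)
  x <- array(rnorm(4 * 40 * 3), c(4, 40, 3)); lab <- c(0L, 1L, 2L)
  Xm <- reegnet:::batch_to_mat(x)
  for (train in c(FALSE, TRUE)) {
    f <- function(model, X = Xm)
      loss_nll(t(reegnet:::forward_pass(model, X, 3, train = train)$out), lab)
    fp <- reegnet:::forward_pass(m, Xm, 3, train = train)
    d <- matrix(0, 3, 3); d[cbind(lab + 1, 1:3)] <- -1 / 3
    bp <- reegnet:::backward_pass(m, fp$caches, d)
    # input gradient at random positions (absolute-relative mixed
    # tolerance: finite differences are noisy near zero)
    for (i in sample(length(Xm), 10)) {
      eps <- 1e-5
      Xp <- Xm; Xp[i] <- Xp[i] + eps
      Xn <- Xm; Xn[i] <- Xn[i] - eps
      num <- (f(m, Xp) - f(m, Xn)) / (2 * eps)
      expect_lt(abs(bp$dX[i] - num) / max(1, abs(num)), 1e-4)
    }
    # parameter gradients across every layer kind
    for (bi in seq_along(m$blocks))
      for (j in seq_along(m$blocks[[bi]]$layers)) {
        g <- bp$grads[[bi]][[j]]
        if (is.null(g)) next
        for (nm in names(g)) {
          p <- m$blocks[[bi]]$layers[[j]][[nm]]
          for (i in sample(length(p), min(3, length(p)))) {
            eps <- 1e-5
            mp <- m; mp$blocks[[bi]]$layers[[j]][[nm]][i] <- p[i] + eps
            mn <- m; mn$blocks[[bi]]$layers[[j]][[nm]][i] <- p[i] - eps
            num <- (f(mp) - f(mn)) / (2 * eps)
            expect_lt(abs(g[[nm]][i] - num) / max(1, abs(num)), 1e-4)
          }
        }
      }
  }
})

test_that("temporal extent is preserved through temporal blocks and divided by pools", {
  m <- tiny_model()
  s <- model_summary(m)
  expect_true(all(s$samples_out[s$block %in%
                                  c("type0", "type1.1", "type1.2")] == 40L))
  expect_identical(s$samples_out[s$block == "type2"], 20L)   # 40 / 2
  expect_identical(s$samples_out[s$block == "type4"], 10L)   # 20 / 2
})
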