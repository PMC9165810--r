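test_that("the default architecture traces 19 blocks with the stated extents", {
  model <- suppressMessages(build_model(model_config(), n_samples = 720))
  s <- model_summary(model)
  expect_identical(nrow(s), 19L)    # 1 + 10 + 1 + 5 + 1 + 1
  # residual temporal blocks preserve the full 64 x 720 geometry
  r10 <- s[s$block == "type1.10", ]
  expect_identical(r10$channels_out, 64L)
  expect_identical(r10$samples_out, 720L)
  expect_identical(r10$maps_out, 8L)
  # the spatial block emits F1*D = 16 maps, collapses channels, pools by 4
  r2 <- s[s$block == "type2", ]
  expect_identical(r2$maps_out, 16L)
  expect_identical(r2$channels_out, 1L)
  expect_identical(r2$samples_out, 180L)
  # second pooling: 180 %/% 8 = 22 time points enter the classifier
  expect_identical(s[s$block == "type4", "samples_out"], 22L)
  expect_identical(s[s$block == "classifier", "samples_out"], 1L)
  # the derived classifier kernel is logged when it differs from 23
  withr::local_options(reegnet.quiet = FALSE)
  expect_message(build_model(model_config(), n_samples = 720),
                 "classifier kernel")
})

test_that("config invariants are enforced", {
  expect_warning(model_config(F1 = 8, D = 2, F2 = 12), "F2")
  expect_error(model_config(n_type1_blocks = 0), ">= 1")
  expect_error(model_config(dropout_p = 1), "dropout_p")
  expect_error(model_config(maxnorm_c = 0), "maxnorm_c")
})

test_that("removing shortcuts changes outputs but not parameter counts", {
  set.seed(2)
  m_res <- tiny_model(seed = 3)
  m_plain <- tiny_model(seed = 3, use_residual = FALSE)
  s1 <- model_summary(m_res); s2 <- model_summary(m_plain)
  expect_identical(s1$n_params, s2$n_params)   # the shortcut is parameter-free
  expect_false(any(s2$residual))
  x <- array(rnorm(4 * 40 * 2), c(4, 40, 2))
  expect_false(identical(model_forward(m_res, x), model_forward(m_plain, x)))
})

test_that("batch-norm and dropout ablations strip exactly those layers", {
  m_nobn <- tiny_model(use_batchnorm = FALSE)
  kinds <- unlist(lapply(m_nobn$blocks, function(b)
    vapply(b$layers, function(l) l$kind, "")))
  expect_false("bn" %in% kinds)
  m_nodrop <- tiny_model(use_dropout = FALSE)
  kinds2 <- unlist(lapply(m_nodrop$blocks, function(b)
    vapply(b$layers, function(l) l$kind, "")))
  expect_false("dropout" %in% kinds2)
  # both still run forward
  x <- array(rnorm(4 * 40), c(4, 40, 1))
  expect_silent(model_forward(m_nobn, x))
  expect_silent(model_forward(m_nodrop, x))
})

test_that("residual addition is an identity shortcut with strict shapes", {
  a <- matrix(rnorm(12), 3)
  z <- matrix(0, 3, 4)
  expect_identical(residual_add(a, z), a)
  expect_identical(residual_add(z, a), a)
  b <- matrix(rnorm(12), 3)
  expect_identical(residual_add(a, b), a + b)
  expect_error(residual_add(a, matrix(0, 4, 3)), "identical shapes")
})

test_that("max-norm projection caps filter norms at c", {
  w <- matrix(c(2, 0, 0, 0.3, 0.4, 0), 2, byrow = TRUE)
  p <- project_maxnorm(w, 1)
  expect_equal(p[1, ], c(1, 0, 0))          # norm 2 -> halved
  expect_equal(p[2, ], c(0.3, 0.4, 0))      # norm 0.5 -> unchanged
  set.seed(6)
  w2 <- matrix(rnorm(50, sd = 2), 10)
  n0 <- sqrt(rowSums(w2^2))
  n1 <- sqrt(rowSums(project_maxnorm(w2, 1)^2))
  expect_equal(n1, pmin(n0, 1), tolerance = 1e-6)
  expect_error(project_maxnorm(w2, 0), "> 0")
})

test_that("zeroed-conv identity-BN residual temporal stack is the identity map", {
  model <- suppressMessages(build_model(model_config(), n_samples = 720))
  for (bi in seq_along(model$blocks))
    if (startsWith(model$blocks[[bi]]$name, "type1"))
      model$blocks[[bi]]$layers[[1]]$W[] <- 0
  set.seed(10)
  x <- array(rnorm(64 * 720), c(64, 720, 1))
  fp <- reegnet:::forward_pass(model, reegnet:::batch_to_mat(x), 1,
                               capture = c("type0", "type1.10"))
  expect_identical(fp$captured$type1.10$A, fp$captured$type0$A)
})
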