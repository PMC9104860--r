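test_that("parameter count equals the closed-form sum over the layer shapes", {
  # independent arithmetic: first conv 3*3*N*M + M, seven dilated plus the
  # dilation-1 level: 8 * (3*3*M*M + M), adaptive norm per level: 2 mixing
  # scalars + 2M channel scale/offset, head: M + 1
  for (case in list(c(N = 1, M = 64), c(N = 2, M = 8), c(N = 3, M = 4))) {
    N <- case[["N"]]; M <- case[["M"]]
    expected <- (9 * N * M + M) + 8 * (9 * M * M + M) + 9 * (2 + 2 * M) +
      M + 1
    cfg <- can_config(N, M, 64)
    expect_equal(can_num_params(cfg), expected)
    expect_length(build_can(cfg, seed = 1)$params, expected)
  }
  # dilation schedule doubles through the eighth level then resets
  cfg <- can_config(1, 4, 64)
  expect_equal(cfg$dilations, c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L, 1L))
  # receptive field after the dilated levels covers a 256-pixel input
  expect_equal(1 + 2 * sum(cfg$dilations[1:8]), 511)
  expect_gte(511, 256)
})

test_that("forward pass preserves shape, is finite and deterministic", {
  cfg <- can_config(2, 4, 32)
  m <- build_can(cfg, seed = 5)
  x <- array(0, dim = c(32, 32, 2))
  out <- predict_can(m, x)
  expect_equal(dim(out), c(32, 32))
  expect_true(all(is.finite(out)))
  set.seed(99)
  xs <- lapply(1:3, function(i) array(rnorm(32 * 32 * 2), dim = c(32, 32, 2)))
  outs <- predict_can(m, xs)
  expect_length(outs, 3)
  # order preserved and deterministic given fixed weights
  expect_identical(outs[[2]], predict_can(m, xs[[2]]))
  m2 <- build_can(cfg, seed = 5)
  expect_identical(predict_can(m2, xs[[1]]), outs[[1]])
  expect_error(predict_can(m, array(0, dim = c(32, 32, 3))), "channels")
})

test_that("analytic gradients match finite differences", {
  cfg <- can_config(2, 4, 16)
  m <- build_can(cfg, seed = 7)
  set.seed(1)
  x <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 2))
  y <- matrix(rnorm(16 * 16), 16)
  fg <- canqpi:::.can_loss_grad_cpp(x, y, m$params, cfg$cin, cfg$cout,
                                    cfg$dilations, cfg$lrelu)
  # loss head equivalence: reported loss is the mean squared pixel residual
  expect_equal(fg$loss, mean((fg$pred - y)^2), tolerance = 1e-12)
  idx <- sample(length(m$params), 40)
  eps <- 1e-6
  for (i in idx) {
    p1 <- m$params; p1[i] <- p1[i] + eps
    p2 <- m$params; p2[i] <- p2[i] - eps
    num <- (canqpi:::.can_loss_grad_cpp(x, y, p1, cfg$cin, cfg$cout,
                                        cfg$dilations, cfg$lrelu)$loss -
            canqpi:::.can_loss_grad_cpp(x, y, p2, cfg$cin, cfg$cout,
                                        cfg$dilations, cfg$lrelu)$loss) /
      (2 * eps)
    expect_equal(fg$grad[i], num, tolerance = 1e-5)
  }
})

test_that("adaptive normalization reduces to identity when its mix weight is zero", {
  cfg <- can_config(1, 3, 16)
  m <- build_can(cfg, seed = 3)
  # zero every norm-branch weight b; then gamma/beta must not matter
  p <- m$params
  off <- 0
  for (l in seq_along(cfg$dilations)) {
    ci <- cfg$cin[l]; co <- cfg$cout[l]
    p[off + 9 * ci * co + co + 2] <- 0 # b (mix weight of the norm branch)
    off <- off + 9 * ci * co + co + 2 + 2 * co
  }
  m_a <- m; m_a$params <- p
  p_b <- p
  off <- 0
  for (l in seq_along(cfg$dilations)) {
    ci <- cfg$cin[l]; co <- cfg$cout[l]
    base <- off + 9 * ci * co + co + 2
    p_b[(base + 1):(base + 2 * co)] <- rnorm(2 * co) # scramble gamma/beta
    off <- base + 2 * co
  }
  m_b <- m; m_b$params <- p_b
  set.seed(8)
  x <- array(rnorm(16 * 16), dim = c(16, 16, 1))
  expect_equal(predict_can(m_a, x), predict_can(m_b, x), tolerance = 1e-12)
})

test_that("channel switch-off zeros exactly the selected channel", {
  set.seed(17)
  x <- array(rnorm(8 * 8 * 3), dim = c(8, 8, 3))
  a <- ablate_channel(x, 2)
  expect_true(all(a[, , 2] == 0))
  expect_identical(a[, , c(1, 3)], x[, , c(1, 3)])
  expect_identical(ablate_channel(a, 2), a) # idempotent
  all_off <- ablate_channel(ablate_channel(ablate_channel(x, 1), 2), 3)
  expect_true(all(all_off == 0))
  expect_error(ablate_channel(x, 4))
})

test_that("training reduces the loss and is seed-deterministic", {
  set.seed(23)
  # small well-posed synthetic task: smooth maps in, linear mix out
  recs <- lapply(1:6, function(i) {
    x <- gauss_filter2(matrix(rnorm(256), 16), sigma = 2, win = 9)
    list(inputs = array(x, dim = c(16, 16, 1)), label = 0.5 * x + 0.2)
  })
  cfg <- can_config(1, 4, 16)
  tc <- train_config(learning_rate = 1e-3, epochs = 15, seed = 2)
  m <- train_can(build_can(cfg, seed = 4), recs, tc)
  h <- m$history
  expect_equal(nrow(h), 15)
  expect_lt(h$train_loss[15], 0.5 * h$train_loss[1])
  # smoothed trend non-increasing overall
  expect_lt(mean(tail(h$train_loss, 5)), mean(head(h$train_loss, 5)))
  m_rep <- train_can(build_can(cfg, seed = 4), recs, tc)
  expect_identical(m_rep$history$train_loss[1], h$train_loss[1])
  expect_identical(m_rep$params, m$params)
  expect_error(train_can(build_can(cfg, seed = 1), list(), tc), "empty")
})

test_that("models round-trip through save/load with their provenance sidecar", {
  cfg <- can_config(1, 3, 16)
  m <- build_can(cfg, seed = 9)
  path <- tempfile(fileext = ".rds")
  save_can(m, path)
  m2 <- load_can(path)
  expect_identical(m2$params, m$params)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$n_params, length(m$params))
  unlink(c(path, paste0(path, ".json")))
})
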