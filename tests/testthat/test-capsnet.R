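# tiny toy discrimination task: class 1 images bright on the right half,
# class 0 bright on the left, plus noise
toyTask <- function(n = 24, H = 10, seed = 1) {
  set.seed(seed)
  xs <- list(); y <- integer(n)
  for (i in seq_len(n)) {
    y[i] <- as.integer(i %% 2 == 0)
    img <- matrix(rnorm(H * H, sd = 0.3), H, H)
    cols <- if (y[i] == 1L) (H / 2 + 1):H else 1:(H / 2)
    img[, cols] <- img[, cols] + 1.5
    xs[[i]] <- array((img - mean(img)) / sd(img), c(H, H, 1))
  }
  list(x = xs, y = y)
}

toyConfig <- function(H = 10, epochs = 15L, seed = 2L)
  capsNetConfig(c(H, H, 1L), conv1Channels = 8L, conv1Kernel = 3L,
                primaryKernel = 2L, primaryStride = 2L,
                primaryCapsChannels = 2L, primaryDim = 8L, classDim = 16L,
                epochs = epochs, batchSize = 8L, learningRate = 5e-3,
                seed = seed)

test_that("squash keeps direction and maps norms to [0, 1)", {
  expect_identical(squash(c(0, 0, 0)), c(0, 0, 0))
  v <- squash(c(1, 0)); expect_equal(sqrt(sum(v^2)), 0.5)
  big <- squash(c(1000, 0))
  expect_lt(abs(sqrt(sum(big^2)) - 1), 1e-5)
  set.seed(4)
  for (i in 1:20) {
    s <- rnorm(8) * 10^runif(1, -2, 2)
    q <- squash(s)
    n <- sqrt(sum(q^2))
    expect_true(n >= 0 && n < 1)
    expect_equal(q / n, s / sqrt(sum(s^2)), tolerance = 1e-10)
  }
})

test_that("routing: coupling coefficients are a per-capsule simplex at every iteration", {
  set.seed(7)
  for (rep in 1:5) {
    votes <- array(rnorm(16 * 12 * 3), c(16, 12, 3))
    rt <- dynamicRouting(votes, iters = 4, trace = TRUE)
    for (cm in attr(rt, "couplingTrace")) {
      expect_lt(max(abs(rowSums(cm) - 1)), 1e-8)
      expect_true(all(cm >= 0))
    }
    expect_true(all(sqrt(colSums(rt$v^2)) < 1))
  }
})

test_that("degenerate routing with one capsule and one class returns squash(vote)", {
  set.seed(8)
  vote <- rnorm(16)
  for (iters in 1:4) {
    rt <- dynamicRouting(array(vote, c(16, 1, 1)), iters = iters)
    expect_equal(as.vector(rt$v), squash(vote), tolerance = 1e-12)
  }
})

test_that("identical votes route to the common vote direction", {
  set.seed(9)
  vote <- rnorm(16)
  votes <- array(rep(vote, times = 20), c(16, 20, 1))
  rt <- dynamicRouting(votes, iters = 3)
  out <- as.vector(rt$v)
  expect_equal(out / sqrt(sum(out^2)), vote / sqrt(sum(vote^2)),
               tolerance = 1e-10)
})

test_that("margin loss reproduces the closed-form evaluations exactly", {
  expect_identical(marginLoss(c(0.9, 0.1), 0L), 0)
  expect_equal(marginLoss(c(0, 0), 0L), 0.81)
  expect_equal(marginLoss(c(0.5, 0.6), 0L), 0.285)
  expect_error(marginLoss(c(1.2, 0), 0L), "\\[0, 1\\]")
  expect_error(marginLoss(c(0.5, 0.5), 2L), "out of range")
})

test_that("margin loss is non-negative, zero exactly on the margin condition", {
  set.seed(10)
  for (i in 1:200) {
    sc <- runif(3)
    tc <- sample(0:2, 1)
    L <- marginLoss(sc, tc)
    expect_gte(L, 0)
    shouldBeZero <- sc[tc + 1] >= 0.9 && all(sc[-(tc + 1)] <= 0.1)
    expect_identical(L == 0, shouldBeZero)
  }
})

test_that("analytic margin-loss gradient matches finite differences at 1e-5", {
  set.seed(11)
  eps <- 1e-7
  for (i in 1:50) {
    sc <- runif(2, 0.02, 0.98)
    tc <- sample(0:1, 1)
    g <- marginLossGrad(sc, tc)
    for (j in 1:2) {
      up <- sc; up[j] <- up[j] + eps
      dn <- sc; dn[j] <- dn[j] - eps
      fd <- (marginLoss(up, tc) - marginLoss(dn, tc)) / (2 * eps)
      expect_lt(abs(fd - g[j]), 1e-5)
    }
  }
})

test_that("training descends on a separable toy task and predicts it back", {
  task <- toyTask(n = 24, seed = 5)
  mod <- trainCapsNet(task$x, task$y, toyConfig(epochs = 15L))
  h <- trainingHistory(mod)
  expect_lt(h$loss[nrow(h)], h$loss[1])
  pr <- predictCapsNet(mod, task$x)
  expect_gte(mean(pr$predicted == task$y), 0.95)
  expect_true(all(pr$score_0 >= 0 & pr$score_0 < 1))
  expect_true(all(pr$score_1 >= 0 & pr$score_1 < 1))
})

test_that("training and prediction are deterministic under a fixed seed", {
  task <- toyTask(n = 12, seed = 6)
  m1 <- trainCapsNet(task$x, task$y, toyConfig(epochs = 4L, seed = 3L))
  m2 <- trainCapsNet(task$x, task$y, toyConfig(epochs = 4L, seed = 3L))
  expect_identical(m1@params, m2@params)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  p1 <- predictCapsNet(m1, task$x)
  p2 <- predictCapsNet(m1, task$x)
  expect_identical(p1, p2)
})

test_that("model serialisation round-trips predictions exactly", {
  task <- toyTask(n = 8, seed = 7)
  mod <- trainCapsNet(task$x, task$y, toyConfig(epochs = 2L))
  p <- withr::local_tempfile(fileext = ".rds")
  saveCapsNetModel(mod, p)
  back <- loadCapsNetModel(p)
  expect_identical(predictCapsNet(back, task$x), predictCapsNet(mod, task$x))
  expect_identical(back@config@seed, mod@config@seed)
})

test_that("config validity rejects kernels that do not tile the input", {
  expect_error(capsNetConfig(c(12L, 12L, 1L)), "does not tile")  # 9x9 twice
  expect_error(capsNetConfig(c(10L, 10L, 1L), conv1Kernel = 3L,
                             primaryKernel = 3L, primaryStride = 2L),
               "does not tile")
  cfg <- defaultCapsConfig(c(12L, 12L, 3L))
  expect_s4_class(cfg, "CapsNetConfig")
  expect_error(predictCapsNet(
    trainCapsNet(toyTask(8, seed = 1)$x, toyTask(8, seed = 1)$y, toyConfig(epochs = 1L)),
    list(array(0, c(4, 4, 1)))), "shape")
})
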