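test_that("forward pass follows the encoder/decoder composition", {
  # zero weights, sigmoid: hidden pinned at 0.5
  p <- ae_layer(matrix(0, 3, 4), matrix(0, 4, 3), rep(0, 3), rep(0, 4))
  fw <- ae_forward(c(1, 2, 3, 4), p)
  expect_identical(fw$h, rep(0.5, 3))
  expect_length(fw$x_star, 4L)

  # identity linear layers reconstruct exactly
  id <- ae_layer(diag(3), diag(3), rep(0, 3), rep(0, 3),
                 s_f = "linear", s_g = "linear")
  x <- c(-1, 0.5, 2)
  expect_identical(ae_forward(x, id)$x_star, x)

  # hand-evaluated 3x2 case
  W <- matrix(c(1, 0, -1, 2, 1, 1), nrow = 3)        # 3x2
  Wp <- matrix(c(1, -1, 0, 1, 2, -2), nrow = 2)      # 2x3
  p2 <- ae_layer(W, Wp, b_h = c(0.5, -0.5, 0), b_x = c(0, 1),
                 s_f = "sigmoid", s_g = "linear")
  x2 <- c(1, -1)
  h_hand <- 1 / (1 + exp(-(W %*% x2 + c(0.5, -0.5, 0))))
  xs_hand <- Wp %*% h_hand + c(0, 1)
  fw2 <- ae_forward(x2, p2)
  expect_equal(fw2$h, as.numeric(h_hand))
  expect_equal(fw2$x_star, as.numeric(xs_hand))

  expect_error(ae_forward(c(1, 2, 3), p2), "does not match")
})

test_that("layer constructor enforces shape consistency", {
  expect_error(ae_layer(matrix(0, 3, 4), matrix(0, 3, 4), rep(0, 3), rep(0, 4)),
               "transposed")
  expect_error(ae_layer(matrix(0, 3, 4), matrix(0, 4, 3), rep(0, 2), rep(0, 4)),
               "bias")
  expect_error(ae_layer(matrix(Inf, 3, 4), matrix(0, 4, 3), rep(0, 3),
                        rep(0, 4)), "finite")
})

test_that("corruption zeroes exactly the requested fraction", {
  x <- runif(10) + 1      # strictly positive so zeros are attributable
  expect_identical(corrupt(x, 0), x)
  expect_identical(corrupt(x, 1), rep(0, 10))
  for (f in c(0.3, 0.5)) {
    xc <- corrupt(x, f, seed = 4)
    expect_identical(sum(xc == 0), as.integer(round(f * 10)))
    expect_identical(xc[xc != 0], x[xc != 0])
  }
  expect_error(corrupt(x, 1.5), "fraction")
})

test_that("each position is corrupted at the nominal rate (Monte Carlo)", {
  x <- rep(1, 10)
  hits <- rowSums(vapply(1:4000, function(s) corrupt(x, 0.5, seed = s) == 0,
                         logical(10)))
  rate <- hits / 4000
  expect_true(all(abs(rate - 0.5) < 0.02))
})

test_that("reconstruction cost matches hand evaluation and is mean-stable", {
  id <- ae_layer(diag(3), diag(3), rep(0, 3), rep(0, 3),
                 s_f = "linear", s_g = "linear")
  X <- matrix(runif(12), 4, 3)
  cfg0 <- train_config(corruption_fraction = 0, seed = 1)
  expect_identical(ae_cost(X, id, cfg0), 0)

  # single 2-vector, fixed tiny params, squared error, no corruption
  W <- matrix(c(0.2, -0.1), 1, 2); Wp <- matrix(c(0.3, 0.4), 2, 1)
  p <- ae_layer(W, Wp, 0.1, c(0, 0))
  x <- c(1, 0)
  h <- 1 / (1 + exp(-(0.2 * 1 - 0.1 * 0 + 0.1)))
  xs <- 1 / (1 + exp(-c(0.3 * h, 0.4 * h)))
  expect_equal(ae_cost(matrix(x, 1), p, cfg0), sum((x - xs)^2))

  # duplicating rows leaves the mean cost unchanged (corruption off)
  X2 <- rbind(X, X)
  expect_equal(ae_cost(X2, p3 <- tiny_layer(d_in = 3), cfg0),
               ae_cost(X, p3, cfg0))

  expect_error(ae_cost(matrix(c(-1, 2), 1), p,
                       train_config(loss = "cross_entropy",
                                    corruption_fraction = 0)),
               "\\[0, 1\\]")
})

test_that("analytic gradient matches central finite differences", {
  fd_check <- function(loss, s_g, seed) {
    lincae:::with_seed(seed, {
      n <- sample(2:6, 1); d <- sample(2:8, 1); dh <- sample(2:8, 1)
      X <- matrix(runif(n * d), n, d)
      p <- lincae:::init_ae_layer(d, dh, "sigmoid", s_g)
      M <- lincae:::draw_masks(n, d, 0.3)
      g <- lincae:::ae_cost_grad_masked(X, M, p, loss)$grad
      eps <- 1e-6
      worst <- 0
      for (field in c("W", "W_prime", "b_h", "b_x")) {
        v <- p[[field]]
        for (i in seq_along(v)) {
          p_hi <- p; p_hi[[field]][i] <- v[i] + eps
          p_lo <- p; p_lo[[field]][i] <- v[i] - eps
          num <- (lincae:::ae_cost_grad_masked(X, M, p_hi, loss, FALSE)$cost -
                  lincae:::ae_cost_grad_masked(X, M, p_lo, loss, FALSE)$cost) /
                 (2 * eps)
          rel <- abs(g[[field]][i] - num) / max(1, abs(num))
          worst <- max(worst, rel)
        }
      }
      worst
    })
  }
  for (seed in 1:5)
    expect_lt(fd_check("squared_error", "sigmoid", seed), 1e-5)
  for (seed in 6:8)
    expect_lt(fd_check("cross_entropy", "sigmoid", seed), 1e-5)
  for (seed in 9:10)
    expect_lt(fd_check("squared_error", "linear", seed), 1e-5)
})

test_that("cost_update takes a descending step and leaves input unmodified", {
  lincae:::with_seed(3, {
    X <- matrix(runif(40), 8, 5)
    p <- lincae:::init_ae_layer(5, 3)
  })
  cfg <- train_config(learning_rate = 0.05, corruption_fraction = 0.1,
                      seed = 7)
  p_snapshot <- unserialize(serialize(p, NULL))
  p2 <- cost_update(p, X, cfg)
  expect_identical(p, p_snapshot)              # no in-place mutation
  expect_lt(ae_cost(X, p2, cfg), ae_cost(X, p, cfg))

  # learning_rate -> 0 limit: parameters unchanged
  cfg0 <- train_config(learning_rate = 1e-300, seed = 7)
  p3 <- cost_update(p, X, cfg0)
  expect_equal(p3$W, p$W, tolerance = 1e-12)
})

test_that("pretraining descends and is bitwise deterministic", {
  lincae:::with_seed(2, X <- matrix(runif(500), 50, 10))
  cfg <- train_config(epochs = 100, seed = 1)
  res <- pretrain_layer(X, 6, cfg)
  expect_length(res$trace, 100L)
  expect_lt(res$trace[100], res$trace[1])

  res2 <- pretrain_layer(X, 6, cfg)
  expect_identical(res$params, res2$params)

  res0 <- pretrain_layer(X, 6, train_config(epochs = 0, seed = 1))
  init <- lincae:::with_seed(1, lincae:::init_ae_layer(10, 6))
  expect_identical(res0$params, init)
  expect_length(res0$trace, 0L)
})

test_that("build_network chains layer shapes", {
  net <- build_network(90, c(64, 32))
  expect_length(net$layers, 2L)
  expect_identical(dim(net$layers[[1]]$W), c(64L, 90L))
  expect_identical(dim(net$layers[[2]]$W), c(32L, 64L))
  expect_length(net$output$w, 32L)

  net1 <- build_network(15, 8)
  expect_length(net1$layers, 1L)
  expect_error(build_network(15, c(8, 0)), "zero-size")
})

test_that("greedy stacking trains layer k on layer k-1 hidden outputs", {
  lincae:::with_seed(4, X <- matrix(runif(300), 30, 10))
  cfg <- train_config(epochs = 5, seed = 9)

  net1 <- build_network(10, 6, seed = 9)
  net1 <- pretrain_stack(net1, X, cfg)
  solo <- pretrain_layer(X, 6, cfg)
  expect_identical(net1$layers[[1]]$W, solo$params$W)

  net2 <- build_network(10, c(6, 4), seed = 9)
  net2 <- pretrain_stack(net2, X, cfg)
  expect_identical(net2$layers[[1]]$W, solo$params$W)  # greedy: layer 1 same
  # second layer trained on the first layer's hidden outputs
  H1 <- t(apply(X, 1, function(r) ae_forward(r, net2$layers[[1]])$h))
  cfg2 <- cfg; cfg2$seed <- cfg$seed + 1L
  solo2 <- pretrain_layer(H1, 4, cfg2)
  expect_equal(net2$layers[[2]]$W, solo2$params$W, tolerance = 1e-12)
  expect_true(all(lengths(net2$pretrain_trace) == 5L))
})

test_that("fine-tuning separates a linearly separable toy problem", {
  lincae:::with_seed(6, {
    n <- 120
    y <- rep(c(0, 1), each = n / 2)
    X <- matrix(runif(n * 4), n, 4)
    X[, 1] <- X[, 1] + 2 * y            # separable coordinate
  })
  net <- build_network(4, c(5, 3), seed = 6)
  cfg <- train_config(epochs = 60, seed = 6, validation_fraction = 0.1)
  net_t <- finetune(net, X, y, cfg)
  expect_identical(mean(classify(net_t, X) == y), 1)

  # logistic-regression oracle agrees the features separate
  glm_fit <- suppressWarnings(stats::glm(y ~ X, family = stats::binomial()))
  expect_identical(mean((stats::fitted(glm_fit) >= 0.5) == y), 1)

  expect_identical(finetune(net, X, y, train_config(epochs = 0)), net)
  expect_error(finetune(net, X, rep(1, n), cfg), "single class")

  net_t2 <- finetune(net, X, y, cfg)
  expect_identical(predict_proba(net_t2, X), predict_proba(net_t, X))
})

test_that("prediction interface: ties, bounds, batch/per-sample equality", {
  net <- build_network(5, c(4, 3), seed = 2)
  net$layers <- lapply(net$layers, function(l) {
    l$W[] <- 0; l$b_h[] <- 0; l
  })
  net$output$w[] <- 0; net$output$b <- 0
  expect_identical(predict_proba(net, rep(0, 5)), 0.5)
  expect_identical(classify(net, rep(0, 5)), 1L)   # tie goes positive

  net2 <- build_network(5, 3, seed = 3)
  X <- matrix(rnorm(40), 8, 5)
  p_batch <- predict_proba(net2, X)
  expect_true(all(p_batch > 0 & p_batch < 1))
  for (i in 1:8)   # batch BLAS path may differ from single-row in the last ulp
    expect_equal(p_batch[i], predict_proba(net2, X[i, ]), tolerance = 1e-12)
  expect_error(predict_proba(net2, rep(0, 4)), "does not match")
})

test_that("model serialization round-trips with bitwise-stable predictions", {
  sch <- build_scheme("EIIP", scale = c(0, 1))
  ds <- generate_dataset(30, 30, motif_model("donor"), seed = 8)
  enc <- encode_batch(ds, sch)
  net <- build_network(ncol(enc$x), c(6, 4), seed = 8)
  net <- pretrain_stack(net, enc$x, train_config(epochs = 3, seed = 8))
  net <- finetune(net, enc$x, enc$y, train_config(epochs = 3, seed = 8))

  f <- withr::local_tempfile(fileext = ".json")
  save_model(net, sch, f)
  m <- load_model(f)
  expect_identical(m$scheme$table, sch$table)
  expect_identical(m$network$threshold, net$threshold)
  expect_identical(predict_proba(m$network, enc$x), predict_proba(net, enc$x))
})
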