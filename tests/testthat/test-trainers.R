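test_that("init_network is seeded, shaped and reproducible", {
  n1 <- init_network(7, "tansig", seed = 42)
  n2 <- init_network(7, "tansig", seed = 42)
  expect_identical(n1, n2)
  expect_length(n1$input_weights, 7)
  expect_length(n1$hidden_biases, 7)
  expect_length(n1$output_weights, 7)
  expect_false(identical(n1, init_network(7, "tansig", seed = 43)))
  params <- c(n1$input_weights, n1$hidden_biases, n1$output_weights,
              n1$output_bias)
  expect_true(all(params >= -0.5 & params <= 0.5))
  expect_error(init_network(0), "positive")

  # does not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(init_network(5, seed = 1)); after <- runif(3)
  expect_identical(before, after)
})

test_that("analytic gradients match central finite differences", {
  set.seed(21)
  acts <- c("purelin", "tansig", "logsig_standard", "logsig_paper")
  for (k in 1:100) {
    net <- rand_net(sample(1:8, 1), acts[1 + (k %% 4)], seed = 1000 + k)
    n <- sample(2:15, 1)
    cs <- runif(n, -2, 2)
    ys <- runif(n, -1, 1)
    expect_grad_close(compute_gradients(net, cs, ys),
                      oracle_fd_gradients(net, cs, ys), tol = 1e-5)
  }
})

test_that("gradients vanish at zero residual and match OLS closed form", {
  net <- rand_net(4, "tansig", seed = 5)
  cs <- runif(10, -1, 1)
  g <- compute_gradients(net, cs, predict_batch(net, cs))
  expect_true(all(abs(unlist(g)) < 1e-12))

  # H = 1 purelin network: hand-derived least-squares gradient
  w1 <- 0.3; bi <- -0.2; lw <- 1.7; bj <- 0.4
  net1 <- ann_network(w1, bi, lw, bj)
  cs <- runif(12, 0, 1); ys <- runif(12, 0, 1)
  r <- (lw * (w1 * cs + bi) + bj) - ys
  g1 <- compute_gradients(net1, cs, ys)
  expect_equal(g1$output_bias, mean(2 * r), tolerance = 1e-12)
  expect_equal(g1$output_weights, mean(2 * r * (w1 * cs + bi)), tolerance = 1e-12)
  expect_equal(g1$hidden_biases, mean(2 * r * lw), tolerance = 1e-12)
  expect_equal(g1$input_weights, mean(2 * r * lw * cs), tolerance = 1e-12)
})

test_that("a zero learning rate leaves parameters untouched", {
  net <- init_network(3, "purelin", seed = 2)
  cs <- seq(0, 1, length.out = 10); ys <- 2 * cs
  for (alg in c("gda", "seq")) {
    cfg <- trainer_config(alg, lr0 = 0, max_epochs = 50)
    res <- if (alg == "gda") train_gda(net, cs, ys, cfg)
           else train_seq(net, cs, ys, cfg)
    expect_equal(res$net$input_weights, net$input_weights, tolerance = 0)
    expect_equal(res$net$output_bias, net$output_bias, tolerance = 0)
  }
})

test_that("resilient backprop leaves a perfectly fitted network unchanged", {
  # dyadic-rational parameters and inputs make the forward pass exact, so the
  # targets below give a gradient of exactly zero at initialization
  net <- ann_network(c(0.5, 0.25, -0.5), c(0, 0.5, 1), c(1, 2, 4), 0.25)
  cs <- c(0, 0.5, 1, 2)
  ys <- predict_batch(net, cs)
  res <- train_rp(net, cs, ys, trainer_config("rp", max_epochs = 20,
                                              goal_mse = 0))
  expect_equal(res$net$input_weights, net$input_weights, tolerance = 0)
  expect_equal(res$net$hidden_biases, net$hidden_biases, tolerance = 0)
  expect_equal(res$final_mse, 0)
})

test_that("all trainers drive noiseless linear data to near-zero error", {
  cs <- seq(0, 1, length.out = 18)
  ys <- 2 * cs
  net <- init_network(3, "purelin", seed = 4)

  gda <- train_gda(net, cs, ys,
                   trainer_config("gda", max_epochs = 2000, goal_mse = 1e-7))
  expect_lt(gda$final_mse, 1e-6)

  rp <- train_rp(net, cs, ys,
                 trainer_config("rp", max_epochs = 2000, goal_mse = 1e-7))
  expect_lt(rp$final_mse, 1e-6)

  seq_res <- train_seq(net, cs, ys,
                       trainer_config("seq", lr0 = 0.05, max_epochs = 5000,
                                      goal_mse = 1e-7))
  expect_lt(seq_res$final_mse, 1e-4)
})

test_that("gda accepted-MSE sequence never grows by more than max_perf_inc", {
  set.seed(31)
  cs <- runif(18); ys <- 0.8 * cs + 0.1 + rnorm(18, 0, 0.02)
  cfg <- trainer_config("gda", lr0 = 0.5, max_epochs = 300)  # aggressive rate
  res <- train_gda(init_network(5, "tansig", seed = 3), cs, ys, cfg)
  h <- res$mse_history
  expect_true(all(h[-1] <= cfg$max_perf_inc * h[-length(h)] + 1e-15))
  expect_equal(res$final_mse, h[length(h)])
})

test_that("one gda epoch equals an explicit R gradient step", {
  # dual route: the C++ epoch must reproduce compute_gradients() exactly
  net <- init_network(4, "logsig_standard", seed = 9)
  cs <- runif(12); ys <- runif(12)
  cfg <- trainer_config("gda", lr0 = 0.02, max_epochs = 1)
  res <- train_gda(net, cs, ys, cfg)
  g <- compute_gradients(net, cs, ys)
  expect_equal(res$net$input_weights, net$input_weights - 0.02 * g$input_weights,
               tolerance = 1e-14)
  expect_equal(res$net$hidden_biases, net$hidden_biases - 0.02 * g$hidden_biases,
               tolerance = 1e-14)
  expect_equal(res$net$output_weights,
               net$output_weights - 0.02 * g$output_weights, tolerance = 1e-14)
  expect_equal(res$net$output_bias, net$output_bias - 0.02 * g$output_bias,
               tolerance = 1e-14)
})

test_that("seq training on a single sample equals batch descent on it", {
  net <- init_network(3, "tansig", seed = 12)
  cfg_seq <- trainer_config("seq", lr0 = 0.05, max_epochs = 5)
  cfg_gda <- trainer_config("gda", lr0 = 0.05, lr_inc = 1 + 1e-12,
                            max_perf_inc = 1e12, max_epochs = 5)
  s <- train_seq(net, 0.4, 0.9, cfg_seq)
  g <- train_gda(net, 0.4, 0.9, cfg_gda)
  expect_equal(s$net$input_weights, g$net$input_weights, tolerance = 1e-9)
  expect_equal(s$net$output_bias, g$net$output_bias, tolerance = 1e-9)
})

test_that("every trainer recovers the effective affine map on noiseless data", {
  cs <- seq(0, 1, length.out = 18)
  a <- 0.8; b <- 0.1
  ys <- a * cs + b
  for (alg in c("gda", "rp", "seq")) {
    cfg <- switch(alg,
      gda = trainer_config("gda", max_epochs = 4000, goal_mse = 1e-12),
      rp = trainer_config("rp", max_epochs = 4000, goal_mse = 1e-12),
      seq = trainer_config("seq", lr0 = 0.05, max_epochs = 8000,
                           goal_mse = 1e-12))
    net <- init_network(3, "purelin", seed = 6)
    res <- switch(alg,
      gda = train_gda(net, cs, ys, cfg),
      rp = train_rp(net, cs, ys, cfg),
      seq = train_seq(net, cs, ys, cfg))
    a_eff <- sum(res$net$input_weights * res$net$output_weights)
    b_eff <- sum(res$net$hidden_biases * res$net$output_weights) +
      res$net$output_bias
    expect_lt(abs(a_eff - a), 1e-3, label = paste(alg, "slope"))
    expect_lt(abs(b_eff - b), 1e-3, label = paste(alg, "intercept"))
  }
})

test_that("training is bit-identical under identical data, config and seed", {
  prof <- make_profile("common_carp", seed = 17)
  d <- generate_dataset(prof)
  cs <- minmax_normalize(d$concentration_uL_per_L)$scaled
  ys <- minmax_normalize(d$IT_s)$scaled
  for (alg in c("gda", "rp", "seq")) {
    cfg <- trainer_config(alg, max_epochs = 200, seed = 5)
    run <- function() {
      net <- init_network(6, "tansig", seed = 5)
      switch(alg,
        gda = train_gda(net, cs, ys, cfg),
        rp = train_rp(net, cs, ys, cfg),
        seq = train_seq(net, cs, ys, cfg))
    }
    r1 <- run(); r2 <- run()
    expect_identical(r1, r2, label = alg)
  }
})

test_that("lower generator noise gives lower median final training error", {
  meds <- vapply(c(0, 0.03, 0.10), function(cv) {
    finals <- vapply(1:10, function(s) {
      d <- generate_dataset(make_profile("common_carp", noise_cv = cv,
                                         seed = 100 + s))
      cs <- minmax_normalize(d$concentration_uL_per_L)$scaled
      ys <- minmax_normalize(d$IT_s)$scaled
      train_rp(init_network(6, "purelin", seed = s), cs, ys,
               trainer_config("rp", max_epochs = 300, goal_mse = 0))$final_mse
    }, numeric(1))
    median(finals)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("mismatched algorithm/config and bad data are rejected", {
  net <- init_network(2, seed = 1)
  expect_error(train_gda(net, 1:3, 1:3, trainer_config("rp")), "gda")
  expect_error(train_rp(net, 1:3, 1:2, trainer_config("rp")), "equal length")
})
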