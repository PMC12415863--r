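# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised code paths: scalar loops and inline formulas only.

# per-neuron scalar forward pass (independent of forward/predict_batch)
oracle_forward <- function(net, c) {
  scalar_act <- function(kind, x) {
    if (kind == "purelin") x
    else if (kind == "tansig") 2 / (1 + exp(-2 * x)) - 1
    else if (kind == "logsig_standard") 1 / (1 + exp(-x))
    else 2 / (1 + exp(-x))
  }
  total <- net$output_bias
  for (i in seq_along(net$input_weights)) {
    z <- c * net$input_weights[i] + net$hidden_biases[i]
    total <- total + scalar_act(net$hidden_activation, z) * net$output_weights[i]
  }
  scalar_act(net$output_activation, total)
}

# naive two-pass loop metrics
oracle_rmse <- function(a, p) {
  s <- 0
  for (k in seq_along(a)) s <- s + (a[k] - p[k])^2
  sqrt(s / length(a))
}

oracle_r2_paper <- function(a, p) {
  num <- 0; den <- 0
  for (k in seq_along(a)) {
    num <- num + (a[k] - p[k])^2
    den <- den + p[k]^2
  }
  1 - num / den
}

oracle_r2_conventional <- function(a, p) {
  m <- sum(a) / length(a)
  num <- 0; den <- 0
  for (k in seq_along(a)) {
    num <- num + (a[k] - p[k])^2
    den <- den + (a[k] - m)^2
  }
  1 - num / den
}

# central finite-difference gradient of the batch MSE
oracle_fd_gradients <- function(net, cs, ys, h = 1e-6) {
  loss_with <- function(w1, bi, lw, bj) {
    n2 <- ann_network(w1, bi, lw, bj,
                      hidden_activation = net$hidden_activation,
                      output_activation = net$output_activation)
    mean((predict_batch(n2, cs) - ys)^2)
  }
  H <- length(net$input_weights)
  fd <- function(which, i) {
    bump <- function(v, i, d) { v[i] <- v[i] + d; v }
    plus <- switch(which,
      w1 = loss_with(bump(net$input_weights, i, h), net$hidden_biases,
                     net$output_weights, net$output_bias),
      bi = loss_with(net$input_weights, bump(net$hidden_biases, i, h),
                     net$output_weights, net$output_bias),
      lw = loss_with(net$input_weights, net$hidden_biases,
                     bump(net$output_weights, i, h), net$output_bias),
      bj = loss_with(net$input_weights, net$hidden_biases,
                     net$output_weights, net$output_bias + h))
    minus <- switch(which,
      w1 = loss_with(bump(net$input_weights, i, -h), net$hidden_biases,
                     net$output_weights, net$output_bias),
      bi = loss_with(net$input_weights, bump(net$hidden_biases, i, -h),
                     net$output_weights, net$output_bias),
      lw = loss_with(net$input_weights, net$hidden_biases,
                     bump(net$output_weights, i, -h), net$output_bias),
      bj = loss_with(net$input_weights, net$hidden_biases,
                     net$output_weights, net$output_bias - h))
    (plus - minus) / (2 * h)
  }
  list(
    input_weights = vapply(seq_len(H), function(i) fd("w1", i), numeric(1)),
    hidden_biases = vapply(seq_len(H), function(i) fd("bi", i), numeric(1)),
    output_weights = vapply(seq_len(H), function(i) fd("lw", i), numeric(1)),
    output_bias = fd("bj", 1)
  )
}

# random small network for property tests
rand_net <- function(H, hidden_activation, seed, scale = 1) {
  set.seed(seed)
  ann_network(runif(H, -scale, scale), runif(H, -scale, scale),
              runif(H, -scale, scale), runif(1, -scale, scale),
              hidden_activation = hidden_activation)
}

# gradient-check comparison: absolute error relative to max(1, |reference|)
expect_grad_close <- function(ga, gf, tol = 1e-5) {
  a <- unlist(ga); f <- unlist(gf)
  expect_true(all(abs(a - f) <= tol * pmax(1, abs(f))),
              label = sprintf("max scaled gradient error %.2e",
                              max(abs(a - f) / pmax(1, abs(f)))))
}
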