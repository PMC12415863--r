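#' Training configuration
#'
#' Hyperparameters for the three training algorithms. Defaults follow the
#' canonical published values for these schemes: adaptive-learning-rate
#' gradient descent grows the rate by \code{lr_inc} after an improving epoch,
#' shrinks it by \code{lr_dec} and discards the step when the epoch would
#' raise the MSE by more than a factor \code{max_perf_inc}; resilient
#' backpropagation adapts a per-parameter step size between \code{delta0} and
#' \code{delta_max} by factors \code{delta_inc}/\code{delta_dec} on
#' consecutive gradient sign agreement/flips; sequential incremental training
#' applies per-sample gradient steps at fixed rate \code{lr0}.
#'
#' @param algorithm \code{"gda"} (batch gradient descent, adaptive learning
#'   rate), \code{"rp"} (resilient backpropagation) or \code{"seq"}
#'   (sequential per-sample updates).
#' @param lr0 Initial (gda) or fixed (seq) learning rate.
#' @param lr_inc,lr_dec,max_perf_inc Adaptive-rate controls (gda).
#' @param delta0,delta_max,delta_inc,delta_dec Step-size controls (rp).
#' @param max_epochs Maximum number of epochs.
#' @param goal_mse Stop once the epoch MSE reaches this goal (on whatever
#'   scale the caller trains on; the pipeline trains on 0-1 normalized data).
#' @param seed Integer seed recorded with the configuration; used by callers
#'   that initialize networks.
#' @return A list of class \code{trainer_config}.
#' @export
trainer_config <- function(algorithm = c("gda", "rp", "seq"),
                           lr0 = 0.01, lr_inc = 1.05, lr_dec = 0.7,
                           max_perf_inc = 1.04,
                           delta0 = 0.07, delta_max = 50,
                           delta_inc = 1.2, delta_dec = 0.5,
                           max_epochs = 1000L, goal_mse = 1e-5,
                           seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(
    lr0 >= 0, lr_inc > 1, lr_dec > 0, lr_dec < 1, max_perf_inc > 1,
    delta0 > 0, delta_max > 0, delta_inc > 1, delta_dec > 0, delta_dec < 1,
    max_epochs >= 1, goal_mse >= 0
  )
  structure(
    list(algorithm = algorithm, lr0 = lr0, lr_inc = lr_inc, lr_dec = lr_dec,
         max_perf_inc = max_perf_inc, delta0 = delta0, delta_max = delta_max,
         delta_inc = delta_inc, delta_dec = delta_dec,
         max_epochs = as.integer(max_epochs), goal_mse = goal_mse,
         seed = as.integer(seed)),
    class = "trainer_config"
  )
}

#' Seeded random initialization of a 1-H-1 network
#'
#' Draws all weights and biases uniformly from \eqn{[-0.5, 0.5]} under the
#' given seed, so initialization is exactly reproducible. The caller's global
#' RNG state is left untouched.
#'
#' @param H Number of hidden neurons (\eqn{\ge 1}).
#' @param hidden_activation Hidden transfer function (see [activate()]).
#' @param seed Integer seed.
#' @return An [ann_network()] with purelin output.
#' @export
init_network <- function(H, hidden_activation = "logsig_standard", seed = 1L) {
  if (!is.numeric(H) || length(H) != 1L || H < 1) {
    stop("init_network(): H must be a positive integer", call. = FALSE)
  }
  H <- as.integer(H)
  draws <- with_preserved_seed(seed, stats::runif(3L * H + 1L, -0.5, 0.5))
  ann_network(
    input_weights = draws[seq_len(H)],
    hidden_biases = draws[H + seq_len(H)],
    output_weights = draws[2L * H + seq_len(H)],
    output_bias = draws[3L * H + 1L],
    hidden_activation = hidden_activation,
    output_activation = "purelin"
  )
}

# run expr under set.seed(seed) and restore the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Analytic gradients of the batch MSE
#'
#' Exact backpropagation gradients of
#' \eqn{\mathrm{MSE} = \frac{1}{N}\sum_n (\hat y_n - y_n)^2} with respect to
#' every weight and bias of a 1-H-1 network with purelin output. Derivatives
#' of the hidden transfer function are evaluated through the activation value
#' (see [activation_derivative()]).
#'
#' @param net An [ann_network()] with purelin output.
#' @param cs,ys Numeric input/target vectors of equal length \eqn{\ge 1}.
#' @return A list with elements \code{input_weights}, \code{hidden_biases},
#'   \code{output_weights} (each length H) and \code{output_bias} (scalar).
#' @export
compute_gradients <- function(net, cs, ys) {
  stopifnot(inherits(net, "ann_network"))
  if (net$output_activation != "purelin") {
    stop("compute_gradients() supports purelin output networks", call. = FALSE)
  }
  cs <- as.numeric(cs); ys <- as.numeric(ys)
  n <- length(cs)
  if (n < 1L || length(ys) != n) {
    stop("compute_gradients(): cs and ys must have equal length >= 1",
         call. = FALSE)
  }
  H <- hidden_size(net)
  z <- outer(cs, net$input_weights) + matrix(net$hidden_biases, n, H, byrow = TRUE)
  f <- activate(net$hidden_activation, z)
  yhat <- drop(f %*% net$output_weights) + net$output_bias
  e <- 2 * (yhat - ys) / n                       # dMSE/dyhat per sample
  d <- (e * activation_derivative(net$hidden_activation, f)) *
    matrix(net$output_weights, n, H, byrow = TRUE)
  list(
    input_weights = drop(crossprod(d, cs)),
    hidden_biases = colSums(d),
    output_weights = drop(crossprod(f, e)),
    output_bias = sum(e)
  )
}

#' Train a 1-H-1 network
#'
#' `train_gda()` runs batch gradient descent with an adaptive learning rate:
#' a step that would raise the MSE by more than \code{max_perf_inc} is
#' discarded and the rate shrunk; an improving step grows the rate.
#' `train_rp()` runs resilient backpropagation: each parameter moves by its
#' own step size \eqn{\Delta} against the gradient sign, growing \eqn{\Delta}
#' on consecutive same-sign gradients and shrinking it (with retraction of
#' the previous step) on sign flips, clipped at \code{delta_max}.
#' `train_seq()` applies per-sample gradient steps in dataset presentation
#' order at a fixed learning rate; one epoch is one full ordered pass.
#'
#' All three stop at \code{goal_mse} or \code{max_epochs} and are
#' deterministic given (data, starting network, config).
#'
#' @param net Starting [ann_network()] (purelin output), e.g. from
#'   [init_network()].
#' @param cs,ys Training inputs and targets (equal length).
#' @param config A [trainer_config()] whose \code{algorithm} matches the
#'   function called.
#' @return A list of class \code{train_result}: \code{net} (trained
#'   [ann_network()]), \code{epochs_run}, \code{final_mse},
#'   \code{mse_history} (accepted MSE after each epoch) and \code{converged}
#'   (\code{TRUE} iff \code{final_mse <= goal_mse}).
#' @export
train_gda <- function(net, cs, ys, config = trainer_config("gda")) {
  run_trainer("gda", net, cs, ys, config)
}

#' @rdname train_gda
#' @export
train_rp <- function(net, cs, ys, config = trainer_config("rp")) {
  run_trainer("rp", net, cs, ys, config)
}

#' @rdname train_gda
#' @export
train_seq <- function(net, cs, ys, config = trainer_config("seq")) {
  run_trainer("seq", net, cs, ys, config)
}

run_trainer <- function(algorithm, net, cs, ys, config) {
  stopifnot(inherits(net, "ann_network"), inherits(config, "trainer_config"))
  if (config$algorithm != algorithm) {
    stop("config$algorithm is '", config$algorithm, "' but ", algorithm,
         " training was requested", call. = FALSE)
  }
  if (net$output_activation != "purelin") {
    stop("training supports purelin output networks", call. = FALSE)
  }
  cs <- as.numeric(cs); ys <- as.numeric(ys)
  if (length(cs) < 1L || length(cs) != length(ys)) {
    stop("training data must be nonempty vectors of equal length",
         call. = FALSE)
  }
  out <- .train_cpp(algorithm, net$input_weights, net$hidden_biases,
                    net$output_weights, net$output_bias,
                    activation_code(net$hidden_activation),
                    cs, ys, unclass(config))
  structure(
    list(
      net = ann_network(out$input_weights, out$hidden_biases,
                        out$output_weights, out$output_bias,
                        hidden_activation = net$hidden_activation,
                        output_activation = "purelin"),
      epochs_run = out$epochs_run,
      final_mse = out$final_mse,
      mse_history = out$mse_history,
      converged = isTRUE(out$converged)
    ),
    class = "train_result"
  )
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result  epochs %d  final MSE %.3g  converged: %s>\n",
              x$epochs_run, x$final_mse, x$converged))
  invisible(x)
}
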