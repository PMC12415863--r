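#' Construct a 1-H-1 feed-forward network
#'
#' A 1-H-1 network maps a single input (anesthetic concentration \eqn{C}) to a
#' single output (one endpoint) through \code{H} hidden neurons. Hidden neuron
#' \eqn{i} computes \eqn{F_i = f(C \cdot W_{1i} + \theta_i)} with transfer
#' function \eqn{f}; the output neuron computes
#' \eqn{\sum_i F_i L_{wi} + \theta_j} (all published models use a linear
#' output).
#'
#' @param input_weights Numeric vector of length H: per-unit-concentration
#'   input weights \eqn{W_1}.
#' @param hidden_biases Numeric vector of length H: hidden biases
#'   \eqn{\theta_i}.
#' @param output_weights Numeric vector of length H: hidden-to-output weights
#'   \eqn{L_w}.
#' @param output_bias Scalar output bias \eqn{\theta_j}.
#' @param hidden_activation,output_activation Activation kinds (see
#'   [activate()]). Output defaults to \code{"purelin"}.
#' @return An object of class \code{ann_network}.
#' @examples
#' net <- ann_network(1, 0, 1, 0)  # identity chain
#' forward(net, 5)                 # 5
#' @export
ann_network <- function(input_weights, hidden_biases, output_weights,
                        output_bias,
                        hidden_activation = "purelin",
                        output_activation = "purelin") {
  input_weights <- as.numeric(input_weights)
  hidden_biases <- as.numeric(hidden_biases)
  output_weights <- as.numeric(output_weights)
  H <- length(input_weights)
  if (H < 1L) {
    stop("invalid model: need at least one hidden neuron", call. = FALSE)
  }
  if (length(hidden_biases) != H || length(output_weights) != H) {
    stop("invalid model: input_weights, hidden_biases and output_weights ",
         "must share length H (got ", H, ", ", length(hidden_biases), ", ",
         length(output_weights), ")", call. = FALSE)
  }
  if (length(output_bias) != 1L) {
    stop("invalid model: output_bias must be a scalar", call. = FALSE)
  }
  vals <- c(input_weights, hidden_biases, output_weights, output_bias)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("invalid model: all parameters must be finite", call. = FALSE)
  }
  structure(
    list(
      input_weights = input_weights,
      hidden_biases = hidden_biases,
      output_weights = output_weights,
      output_bias = as.numeric(output_bias),
      hidden_activation = match_activation(hidden_activation),
      output_activation = match_activation(output_activation)
    ),
    class = "ann_network"
  )
}

#' @export
print.ann_network <- function(x, ...) {
  cat(sprintf("<ann_network 1-%d-1  hidden: %s  output: %s>\n",
              hidden_size(x), x$hidden_activation, x$output_activation))
  invisible(x)
}

#' Number of hidden neurons of a network
#' @param net An [ann_network()].
#' @return Integer H.
#' @export
hidden_size <- function(net) {
  stopifnot(inherits(net, "ann_network"))
  length(net$input_weights)
}

#' Forward pass of a 1-H-1 network
#'
#' Evaluates \eqn{g(\sum_i f(c W_{1i} + \theta_i) L_{wi} + \theta_j)} where
#' \eqn{f} is the hidden and \eqn{g} the output transfer function.
#'
#' @param net An [ann_network()].
#' @param c Scalar concentration (or any scalar input).
#' @return Scalar prediction.
#' @export
forward <- function(net, c) {
  if (!inherits(net, "ann_network")) {
    stop("invalid model: not an ann_network", call. = FALSE)
  }
  if (length(c) != 1L || !is.numeric(c) || !is.finite(c)) {
    stop("forward(): `c` must be a finite scalar", call. = FALSE)
  }
  f <- activate(net$hidden_activation, c * net$input_weights + net$hidden_biases)
  y <- sum(f * net$output_weights) + net$output_bias
  activate(net$output_activation, y)
}

#' Vectorised forward pass
#'
#' @param net An [ann_network()].
#' @param cs Numeric vector of concentrations (may be empty).
#' @return Numeric vector of predictions, order and length preserved.
#' @export
predict_batch <- function(net, cs) {
  if (!inherits(net, "ann_network")) {
    stop("invalid model: not an ann_network", call. = FALSE)
  }
  cs <- as.numeric(cs)
  if (length(cs) == 0L) return(numeric(0))
  if (anyNA(cs) || any(!is.finite(cs))) {
    stop("predict_batch(): concentrations must be finite", call. = FALSE)
  }
  z <- outer(cs, net$input_weights) +
    matrix(net$hidden_biases, length(cs), hidden_size(net), byrow = TRUE)
  f <- activate(net$hidden_activation, z)
  activate(net$output_activation,
           drop(f %*% net$output_weights) + net$output_bias)
}
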