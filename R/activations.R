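#' Neuron transfer (activation) functions
#'
#' The four transfer functions used by the 1-H-1 dose-response networks:
#' \describe{
#'   \item{\code{purelin}}{identity, \eqn{f(x) = x}.}
#'   \item{\code{tansig}}{hyperbolic-tangent sigmoid,
#'     \eqn{f(x) = 2/(1+e^{-2x}) - 1}, range \eqn{(-1, 1)}.}
#'   \item{\code{logsig_standard}}{canonical logistic sigmoid,
#'     \eqn{f(x) = 1/(1+e^{-x})}, range \eqn{(0, 1)}.}
#'   \item{\code{logsig_paper}}{the two-scaled logistic dialect that appears in
#'     the published weight tables, \eqn{f(x) = 2/(1+e^{-x})}, range
#'     \eqn{(0, 2)}. It equals \code{2 * logsig_standard(x)}.}
#' }
#'
#' Both logistic dialects are provided because the published tables print the
#' two-scaled form while the canonical form is what training software normally
#' means by "logsig"; zoo entries default to the printed dialect and training
#' defaults to the canonical one.
#'
#' @param kind One of \code{"purelin"}, \code{"tansig"},
#'   \code{"logsig_paper"}, \code{"logsig_standard"}.
#' @param x Numeric vector of pre-activations; must be finite.
#' @return \code{activate}: numeric vector of activations, same length as
#'   \code{x}. \code{activation_derivative}: the derivative \eqn{f'(x)}
#'   expressed through the activation value \code{fx}.
#' @examples
#' activate("tansig", 0)        # 0
#' activate("logsig_paper", 0)  # 1
#' @export
activate <- function(kind, x) {
  kind <- match_activation(kind)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("activate(): `x` must be finite numeric", call. = FALSE)
  }
  switch(kind,
    purelin         = x,
    tansig          = 2 / (1 + exp(-2 * x)) - 1,
    logsig_standard = 1 / (1 + exp(-x)),
    logsig_paper    = 2 / (1 + exp(-x))
  )
}

#' @rdname activate
#' @param fx Activation values \eqn{f(x)} at which to evaluate the derivative.
#' @export
activation_derivative <- function(kind, fx) {
  kind <- match_activation(kind)
  switch(kind,
    purelin         = rep(1, length(fx)),
    tansig          = 1 - fx^2,
    logsig_standard = fx * (1 - fx),
    logsig_paper    = fx * (1 - fx / 2)
  )
}

activation_kinds <- c("purelin", "tansig", "logsig_standard", "logsig_paper")

match_activation <- function(kind) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% activation_kinds) {
    stop("unknown activation kind: ", paste(kind, collapse = ", "),
         " (expected one of ", paste(activation_kinds, collapse = ", "), ")",
         call. = FALSE)
  }
  kind
}

# integer codes shared with the C++ training loops
activation_code <- function(kind) {
  match(match_activation(kind), activation_kinds) - 1L
}
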