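#' Logistic activation with adjustable slope
#'
#' The squashing nonlinearity used by the candidate-memory, gating and
#' (optionally) output units: `sigma(u) = 1 / (1 + exp(-rho * u))`. The slope
#' `rho` steepens the transition around zero; all experiments here use
#' `rho = 2`.
#'
#' @param u Numeric scalar, vector or matrix of pre-activations.
#' @param rho Positive slope of the sigmoid.
#' @return Values in (0, 1), same shape as `u`.
#' @examples
#' sigmoid(0)           # 0.5
#' sigmoid(1, rho = 2)  # 1 / (1 + exp(-2))
#' @export
sigmoid <- function(u, rho = 2) {
  1 / (1 + exp(-rho * u))
}

#' Derivative of the logistic activation
#'
#' Evaluated at the pre-activation `u`: `rho * sigma(u) * (1 - sigma(u))`.
#' Used by the synaptic-trace recursions, which need the local slope of the
#' unit's activation function.
#'
#' @inheritParams sigmoid
#' @return Derivative values, same shape as `u`.
#' @export
sigmoid_deriv <- function(u, rho = 2) {
  s <- sigmoid(u, rho)
  rho * s * (1 - s)
}
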