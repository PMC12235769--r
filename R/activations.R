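#' Exponential linear unit
#'
#' `elu(x) = x` for `x > 0` and `gamma * (exp(x) - 1)` for `x <= 0`.
#' Unlike ReLU it admits small negative outputs, which keeps mean
#' activations closer to zero; `gamma` controls the negative saturation
#' level.
#'
#' @param x numeric scalar or array.
#' @param gamma positive saturation constant (default 1).
#' @return object of the same shape as `x`.
#' @examples
#' elu(c(-1, 0, 2))
#' @export
elu <- function(x, gamma = 1) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("'gamma' must be a positive scalar")
  ifelse(x > 0, x, gamma * (exp(x) - 1))
}

#' Hard sigmoid
#'
#' Piecewise-linear approximation of the sigmoid used as a fast gate
#' activation: `max(0, min(1, 0.2 * a + 0.5))`. It saturates exactly at 0
#' and 1 for `|a| >= 2.5`, which accelerates convergence of the gate and
#' sharpens feature selection.
#'
#' @param a numeric scalar or array.
#' @return values in `[0, 1]`, same shape as `a`.
#' @examples
#' hard_sigmoid(c(-3, 0, 1, 3))
#' @export
hard_sigmoid <- function(a) {
  pmax(0, pmin(1, 0.2 * a + 0.5))
}

# numerically stable softmax of a vector (max-subtracted)
softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}
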