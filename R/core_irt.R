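# Core item-response probability model and the training objective.

#' Logistic (sigmoid) function
#'
#' Numerically standard logistic transform \eqn{\sigma(x) = 1 / (1 + e^{-x})},
#' the link used throughout the one-parameter logistic (1PL, Rasch) model
#' family implemented in this package.
#'
#' @param x Numeric vector of finite values.
#' @return Numeric vector of probabilities in the open interval (0, 1).
#' @examples
#' sigmoid(0)          # 0.5
#' sigmoid(c(-2, 2))   # complement-symmetric pair
#' @export
sigmoid <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be numeric and finite", call. = FALSE)
  # two-branch form: never evaluates exp of a large positive argument, so
  # deep negative inputs underflow gracefully instead of dividing by Inf
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  e <- exp(x[!pos])
  out[!pos] <- e / (1 + e)
  out
}

#' Probability of a correct response under the state-aware 1PL model
#'
#' Computes \eqn{P(y = 1) = \sigma(\theta - (\beta + \phi))}: ability
#' \eqn{\theta} raises the probability, item difficulty \eqn{\beta} and the
#' per-trial state \eqn{\phi} (relative subjective difficulty) lower it.
#' With \code{phi = 0} this is exactly the plain 1PL model
#' \eqn{\sigma(\theta - \beta)}.
#'
#' @param theta Student ability (logit scale), numeric.
#' @param beta Item difficulty (logit scale), numeric.
#' @param phi Per-trial state (logit scale), numeric; defaults to 0.
#' @return Probability of a correct response; vectorised over the inputs.
#' @examples
#' probCorrect(0, 0)        # 0.5
#' probCorrect(2, 0)        # ability 2 logits above difficulty
#' probCorrect(0, 1, 1)     # state adds to difficulty
#' @export
probCorrect <- function(theta, beta, phi = 0) {
  if (any(!is.finite(theta)) || any(!is.finite(beta)) || any(!is.finite(phi)))
    stop("all parameters must be finite", call. = FALSE)
  sigmoid(theta - (beta + phi))
}

#' Classify a predicted probability as a binary response
#'
#' The decision rule is \code{p >= 0.5} maps to class 1 (correct); the tie at
#' exactly 0.5 is classified as correct.
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @return Integer vector of 0/1 predicted responses.
#' @export
classifyResponse <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("'p' must contain probabilities in [0, 1]", call. = FALSE)
  as.integer(p >= 0.5)
}

# Clipping bound applied to probabilities before taking logs, so that a
# saturated network output cannot produce an infinite loss.
.probEps <- 1e-7

#' Summed binary cross-entropy loss
#'
#' The training objective: the negated Bernoulli log-likelihood
#' \eqn{-\sum_n [y_n \log p_n + (1 - y_n)\log(1 - p_n)]}, summed (not
#' averaged) over the collection. Probabilities are clipped to
#' \eqn{[10^{-7}, 1 - 10^{-7}]} before the logarithm.
#'
#' @param responses Binary 0/1 vector of observed responses.
#' @param probabilities Vector of predicted probabilities, same length.
#' @return A single non-negative number.
#' @examples
#' crossEntropyLoss(1, 0.5)              # -log(0.5)
#' crossEntropyLoss(c(1, 0), c(0.8, 0.2))
#' @export
crossEntropyLoss <- function(responses, probabilities) {
  if (length(responses) == 0L)
    stop("empty collection", call. = FALSE)
  if (length(responses) != length(probabilities))
    stop("'responses' and 'probabilities' must have equal length",
         call. = FALSE)
  if (!all(responses %in% c(0, 1)))
    stop("'responses' must be binary 0/1", call. = FALSE)
  p <- pmin(pmax(probabilities, .probEps), 1 - .probEps)
  -sum(responses * log(p) + (1 - responses) * log(1 - p))
}
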