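#' Geometric mean of non-negative values
#'
#' Computed in the log domain with an exact early exit on zero, so products
#' over many small per-cell-type means neither underflow nor overflow.
#' Two conventions close the formula over all valid inputs:
#' an empty vector returns 0 (absent machinery contributes no signal), and
#' any zero propagates to a zero mean (a silent gene kills the product).
#'
#' @param x Numeric vector of non-negative values (may be empty).
#' @return A single non-negative number.
#' @examples
#' geometric_mean(c(4, 9))    # 6
#' geometric_mean(c(2, 0, 8)) # 0
#' geometric_mean(numeric(0)) # 0
#' @export
geometric_mean <- function(x) {
  if (!is.numeric(x)) stop("geometric_mean: input must be numeric", call. = FALSE)
  if (anyNA(x)) stop("geometric_mean: input contains NA", call. = FALSE)
  if (length(x) == 0L) return(0)
  if (any(x < 0)) stop("geometric_mean: negative values are not allowed", call. = FALSE)
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

#' Net enzyme expression for a metabolite
#'
#' The geometric mean of the producer-enzyme means minus the geometric mean
#' of the consumer-enzyme means, each taken over the sender cell type.
#' Either set may be empty (contributing 0), and the result may be negative
#' when consumption dominates production.
#'
#' @param producer_means Non-negative means of producer enzymes (length m >= 0).
#' @param consumer_means Non-negative means of consumer enzymes (length n >= 0).
#' @return Net enzyme expression E (any sign).
#' @examples
#' enzyme_net_expression(c(2, 8), 1) # 4 - 1 = 3
#' enzyme_net_expression(1, 4)       # -3
#' @export
enzyme_net_expression <- function(producer_means, consumer_means) {
  geometric_mean(producer_means) - geometric_mean(consumer_means)
}

#' Transporter expression for a metabolite
#'
#' Geometric mean of the transporter-gene means in the sender cell type;
#' 0 when the metabolite has no annotated transporter.
#'
#' @param transporter_means Non-negative means (length k >= 0).
#' @return Transporter expression T >= 0.
#' @export
transporter_expression <- function(transporter_means) {
  geometric_mean(transporter_means)
}

#' Extracellular metabolite availability
#'
#' Euclidean-norm combination M = sqrt(E^2 + T^2) of net enzyme expression E
#' and transporter expression T. Because E enters squared, a strongly
#' net-consuming sender (E < 0) raises M under the literal form; the
#' \code{"clamp"} policy replaces E with max(E, 0) first for users who want
#' consumption never to look like supply.
#'
#' @param E Net enzyme expression (any sign).
#' @param Tr Transporter expression, >= 0.
#' @param policy \code{"literal"} (default) or \code{"clamp"}.
#' @return Availability M >= 0.
#' @examples
#' metabolite_availability(3, 4)            # 5
#' metabolite_availability(-3, 4, "clamp")  # 4
#' @export
metabolite_availability <- function(E, Tr, policy = c("literal", "clamp")) {
  policy <- match.arg(policy)
  if (any(Tr < 0)) stop("metabolite_availability: T must be non-negative", call. = FALSE)
  e <- if (policy == "clamp") pmax(E, 0) else E
  sqrt(e^2 + Tr^2)
}

#' Receptor(-complex) expression
#'
#' Geometric mean of the q subunit means in the receiver cell type. A complex
#' with any unexpressed subunit scores 0: every subunit must be present for
#' the receptor to function.
#'
#' @param subunit_means Non-negative means, length q >= 1.
#' @return Receptor expression R >= 0.
#' @export
receptor_expression <- function(subunit_means) {
  if (length(subunit_means) == 0L)
    stop("receptor_expression: a receptor must have at least one subunit", call. = FALSE)
  geometric_mean(subunit_means)
}

#' Communication score for one (sender, receiver, interaction) triple
#'
#' MR = sqrt(M^2 + R^2): the Euclidean norm balances metabolite availability
#' and receptor expression, is symmetric in its arguments, and satisfies
#' max(M, R) <= MR <= M + R. Vectorized over its arguments.
#'
#' @param M Metabolite availability, >= 0.
#' @param R Receptor expression, >= 0.
#' @return MR score, >= 0.
#' @examples
#' mr_score(6, 8) # 10
#' @export
mr_score <- function(M, R) {
  if (any(M < 0) || any(R < 0))
    stop("mr_score: M and R must be non-negative", call. = FALSE)
  sqrt(M^2 + R^2)
}
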