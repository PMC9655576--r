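#' Crop-dependent response probabilities
#'
#' The per-timestep probabilities that govern an ant's behaviour are
#' sigmoidal (Hill-type) functions of its current crop load `Q`. The
#' probability of acting as a food donor increases with crop content,
#'
#' \deqn{\theta(Q) = \theta(0) \cdot \frac{Q^n}{k^n + Q^n},}
#'
#' while the probabilities of receiving food and of leaving the nest
#' decrease with crop content,
#'
#' \deqn{\gamma(Q) = \gamma(0) \cdot \frac{k^n}{k^n + Q^n}, \qquad
#'       \alpha(Q) = \alpha(0) \cdot \frac{k^n}{k^n + Q^n}.}
#'
#' `k` is the half-saturation crop load (in food units; at `Q = k` each
#' function sits at half its maximum) and `n` sets the steepness of the
#' response. The two Hill terms are complementary: for equal `k` and `n`,
#' `donor_probability(1, Q, k, n) + receiver_probability(1, Q, k, n) == 1`.
#'
#' @param theta0,gamma0,alpha_max Maximal per-timestep probability, attained
#'   at `Q = Inf` (donor) or `Q = 0` (receiver, leaving). Must lie in
#'   `[0, 1]`. For leaving, pass the non-forager maximum or the (larger)
#'   post-first-visit forager maximum as appropriate.
#' @param Q Current crop load, food units, `>= 0`. Vectorised.
#' @param k Half-saturation crop load, food units, `> 0`.
#' @param n Hill steepness, dimensionless, `> 0`.
#'
#' @return A numeric vector of probabilities, bounded by the supplied
#'   maximum.
#'
#' @examples
#' donor_probability(0.5, 120, k = 120, n = 2)    # half-max: 0.25
#' receiver_probability(0.4, 0, k = 120, n = 2)   # empty crop: maximum
#' leaving_probability(0.01, 240, k = 120, n = 2)
#' @name response_functions
NULL

hill_increasing <- function(Q, k, n) {
  # Q^n / (k^n + Q^n), computed on the (Q/k) scale to avoid overflow
  r <- (Q / k)^n
  ifelse(is.infinite(r), 1, r / (1 + r))
}

check_response_args <- function(maximum, Q, k, n, what) {
  if (any(!is.finite(maximum)) || any(maximum < 0) || any(maximum > 1)) {
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  }
  if (any(is.na(Q)) || any(Q < 0)) stop("crop load Q must be >= 0", call. = FALSE)
  if (any(!is.finite(k)) || any(k <= 0)) stop("half-saturation k must be > 0", call. = FALSE)
  if (any(!is.finite(n)) || any(n <= 0)) stop("Hill steepness n must be > 0", call. = FALSE)
  invisible(NULL)
}

#' @rdname response_functions
#' @export
donor_probability <- function(theta0, Q, k, n) {
  check_response_args(theta0, Q, k, n, "theta0")
  theta0 * hill_increasing(Q, k, n)
}

#' @rdname response_functions
#' @export
receiver_probability <- function(gamma0, Q, k, n) {
  check_response_args(gamma0, Q, k, n, "gamma0")
  gamma0 * (1 - hill_increasing(Q, k, n))
}

#' @rdname response_functions
#' @export
leaving_probability <- function(alpha_max, Q, k, n) {
  check_response_args(alpha_max, Q, k, n, "alpha_max")
  alpha_max * (1 - hill_increasing(Q, k, n))
}

#' Probability that a trophallactic pair forms
#'
#' Two ants in the nest exchange food with a probability equal to the
#' product of the donor's current giving probability and the receiver's
#' current receiving probability.
#'
#' @param theta_i Donor's current giving probability `theta(Q_i)`.
#' @param gamma_j Receiver's current receiving probability `gamma(Q_j)`.
#' @return `theta_i * gamma_j`, vectorised.
#' @examples
#' pair_formation_probability(0.1, 0.2)
#' @export
pair_formation_probability <- function(theta_i, gamma_j) {
  if (any(theta_i < 0 | theta_i > 1) || any(gamma_j < 0 | gamma_j > 1)) {
    stop("pair-formation inputs must be probabilities in [0, 1]", call. = FALSE)
  }
  theta_i * gamma_j
}
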