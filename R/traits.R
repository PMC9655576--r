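#' Specify an interindividual trait distribution
#'
#' Giving (`theta(0)`) and receiving (`gamma(0)`) maxima are drawn once per
#' ant at colony setup from one of three distributions of increasing
#' heterogeneity, all sharing the same population mean `mean`:
#'
#' * `"delta"` — every ant gets exactly `mean` (the no-variability null).
#' * `"uniform"` — draws from `U(0, 2 * mean)`, the widest nonnegative
#'   uniform with that mean.
#' * `"exponential"` — draws from an exponential law with mean `mean`,
#'   the right-skewed case where a few ants are much more engaged than the
#'   rest.
#'
#' Draws above 1 are rejected and redrawn, so all sampled values are valid
#' probabilities and no probability mass piles up at 1. (For the
#' exponential with the small means used here the rejection is rare and the
#' realised mean sits imperceptibly below the nominal one.)
#'
#' @param kind One of `"delta"`, `"uniform"`, `"exponential"`.
#' @param mean Population mean of the trait, in `(0, 1]` (and `<= 0.5` for
#'   `"uniform"` so the support stays inside `[0, 1]`).
#' @return A `trait_spec` object.
#' @examples
#' sample_trait(trait_spec("exponential", 1/9), 5)
#' @export
trait_spec <- function(kind = c("delta", "uniform", "exponential"), mean) {
  kind <- match.arg(kind)
  if (!is.numeric(mean) || length(mean) != 1 || !is.finite(mean) ||
      mean <= 0 || mean > 1) {
    stop("trait mean must be a single value in (0, 1]", call. = FALSE)
  }
  if (kind == "uniform" && mean > 0.5) {
    stop("uniform trait mean must be <= 0.5 (support [0, 2*mean] within [0, 1])",
         call. = FALSE)
  }
  structure(list(kind = kind, mean = mean), class = "trait_spec")
}

#' @export
print.trait_spec <- function(x, ...) {
  cat("<trait_spec> ", x$kind, " distribution, mean ", format(x$mean), "\n", sep = "")
  invisible(x)
}

#' Draw individual trait values
#'
#' @param spec A [trait_spec()].
#' @param n Number of draws.
#' @return Numeric vector of `n` probabilities in `[0, 1]` with population
#'   mean `spec$mean` (exactly for `"delta"`; slightly below for
#'   `"exponential"` because draws above 1 are redrawn).
#' @export
sample_trait <- function(spec, n = 1) {
  stopifnot(inherits(spec, "trait_spec"))
  switch(spec$kind,
    delta = rep(spec$mean, n),
    uniform = stats::runif(n, 0, 2 * spec$mean),
    exponential = {
      x <- stats::rexp(n, rate = 1 / spec$mean)
      # truncate to (0, 1] by resampling, not clipping
      while (any(bad <- x > 1)) x[bad] <- stats::rexp(sum(bad), rate = 1 / spec$mean)
      x
    }
  )
}

#' Specify the distribution of nest-leaving maxima
#'
#' The maximal per-second probability `alpha(0)` of leaving the nest for
#' the first time is strongly right-skewed across workers: a few ants
#' visit the source readily while most almost never do. It is modelled as
#' a bounded power law (Pareto) on `[min_value, max_value]` with density
#' proportional to `x^-exponent`. After an ant's first visit to the source
#' its leaving maximum is raised to
#' `alpha0_forager = min(1, forager_multiplier * alpha0)`.
#'
#' Setting `kind = "delta"` (or `min_value == max_value`) gives every ant
#' the same leaving maximum.
#'
#' @param kind `"power_law"` or `"delta"`.
#' @param exponent Power-law exponent, `> 1`.
#' @param min_value,max_value Support bounds, probabilities with
#'   `0 < min_value <= max_value <= 1`. For `"delta"`, `min_value` is the
#'   common value.
#' @param forager_multiplier Factor (`>= 1`) applied to `alpha0` after the
#'   first source visit.
#' @return An `alpha_spec` object.
#' @export
alpha_spec <- function(kind = c("power_law", "delta"), exponent = 2,
                       min_value = 1e-4, max_value = 0.1,
                       forager_multiplier = 1) {
  kind <- match.arg(kind)
  if (kind == "delta") max_value <- min_value
  stopifnot(is.numeric(min_value), is.numeric(max_value),
            min_value > 0, max_value <= 1, forager_multiplier >= 1)
  if (min_value > max_value) stop("alpha bounds: min_value > max_value", call. = FALSE)
  if (kind == "power_law" && exponent <= 1) {
    stop("power-law exponent must be > 1", call. = FALSE)
  }
  structure(list(kind = kind, exponent = exponent, min_value = min_value,
                 max_value = max_value, forager_multiplier = forager_multiplier),
            class = "alpha_spec")
}

#' @export
print.alpha_spec <- function(x, ...) {
  if (x$kind == "delta" || x$min_value == x$max_value) {
    cat("<alpha_spec> delta at", format(x$min_value))
  } else {
    cat("<alpha_spec> bounded power law, exponent ", format(x$exponent),
        ", support [", format(x$min_value), ", ", format(x$max_value), "]", sep = "")
  }
  cat(", forager multiplier", format(x$forager_multiplier), "\n")
  invisible(x)
}

#' Draw nest-leaving maxima
#'
#' Inverse-transform sampling of the bounded Pareto: with
#' `a = 1 - exponent`, `F(x) = (min^a - x^a) / (min^a - max^a)` on the
#' support, so `x = (min^a - u * (min^a - max^a))^(1/a)`.
#'
#' @param spec An [alpha_spec()].
#' @param n Number of draws.
#' @return Numeric vector of `n` values in `[min_value, max_value]`.
#' @export
sample_alpha0 <- function(spec, n = 1) {
  stopifnot(inherits(spec, "alpha_spec"))
  if (spec$kind == "delta" || spec$min_value == spec$max_value) {
    return(rep(spec$min_value, n))
  }
  a <- 1 - spec$exponent
  u <- stats::runif(n)
  (spec$min_value^a - u * (spec$min_value^a - spec$max_value^a))^(1 / a)
}

#' Define the caste regime of the colony
#'
#' Two behavioural regimes are supported:
#'
#' * `"OC"` (one caste): giving/receiving traits are identical for
#'   foragers and non-foragers and never change; only the specs for the
#'   single caste need be given.
#' * `"TEC"` (two emergent castes): every ant starts with non-forager
#'   traits; on its first visit to the food source its `theta(0)` and
#'   `gamma(0)` are freshly resampled from the forager specs, with
#'   `mean(theta_F) > mean(theta_NF)` (no ordering is imposed on the
#'   receiving means: the reference calibration fits forager receiving
#'   maxima above the non-forager ones).
#'   Pre- and post-promotion values are uncorrelated.
#'
#' @param kind `"OC"` or `"TEC"`.
#' @param theta_nf,gamma_nf [trait_spec()]s for non-forager giving and
#'   receiving maxima.
#' @param theta_f,gamma_f Forager specs; for `"OC"` these default to the
#'   non-forager specs and must equal them if supplied.
#' @return A `caste_regime` object.
#' @examples
#' caste_regime("TEC",
#'   theta_nf = trait_spec("exponential", 1/23),
#'   gamma_nf = trait_spec("exponential", 1/27),
#'   theta_f  = trait_spec("exponential", 1/9),
#'   gamma_f  = trait_spec("exponential", 1/9))
#' @export
caste_regime <- function(kind = c("OC", "TEC"), theta_nf, gamma_nf,
                         theta_f = NULL, gamma_f = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(theta_nf, "trait_spec"), inherits(gamma_nf, "trait_spec"))
  if (kind == "OC") {
    if ((!is.null(theta_f) && !identical(theta_f, theta_nf)) ||
        (!is.null(gamma_f) && !identical(gamma_f, gamma_nf))) {
      stop("OC regime requires identical forager and non-forager specs", call. = FALSE)
    }
    theta_f <- theta_nf
    gamma_f <- gamma_nf
  } else {
    stopifnot(inherits(theta_f, "trait_spec"), inherits(gamma_f, "trait_spec"))
    if (theta_f$mean <= theta_nf$mean) {
      stop("TEC regime requires mean(theta_F) > mean(theta_NF)", call. = FALSE)
    }
  }
  structure(list(kind = kind, theta_nf = theta_nf, gamma_nf = gamma_nf,
                 theta_f = theta_f, gamma_f = gamma_f),
            class = "caste_regime")
}

#' @export
print.caste_regime <- function(x, ...) {
  cat("<caste_regime> ", x$kind, "\n", sep = "")
  cat("  theta_NF: ", x$theta_nf$kind, " mean ", format(x$theta_nf$mean), "\n", sep = "")
  cat("  gamma_NF: ", x$gamma_nf$kind, " mean ", format(x$gamma_nf$mean), "\n", sep = "")
  if (x$kind == "TEC") {
    cat("  theta_F:  ", x$theta_f$kind, " mean ", format(x$theta_f$mean), "\n", sep = "")
    cat("  gamma_F:  ", x$gamma_f$kind, " mean ", format(x$gamma_f$mean), "\n", sep = "")
  }
  invisible(x)
}

#' Draw the full trait table for a colony
#'
#' Samples one row per ant: non-forager giving/receiving maxima, the
#' (initially latent) forager values that take effect on promotion, and
#' the nest-leaving maxima before and after the first source visit.
#' Under OC the forager columns simply copy the non-forager ones; under
#' TEC they are independent draws from the forager specs.
#'
#' @param n_ants Colony size.
#' @param regime A [caste_regime()].
#' @param alpha An [alpha_spec()].
#' @return A tibble with columns `id`, `theta0_nf`, `gamma0_nf`,
#'   `theta0_f`, `gamma0_f`, `alpha0`, `alpha0_forager`.
#' @export
draw_colony_traits <- function(n_ants, regime, alpha) {
  stopifnot(inherits(regime, "caste_regime"), inherits(alpha, "alpha_spec"),
            n_ants > 1)
  theta0_nf <- sample_trait(regime$theta_nf, n_ants)
  gamma0_nf <- sample_trait(regime$gamma_nf, n_ants)
  if (regime$kind == "OC") {
    theta0_f <- theta0_nf
    gamma0_f <- gamma0_nf
  } else {
    theta0_f <- sample_trait(regime$theta_f, n_ants)
    gamma0_f <- sample_trait(regime$gamma_f, n_ants)
  }
  alpha0 <- sample_alpha0(alpha, n_ants)
  tibble::tibble(
    id = seq_len(n_ants),
    theta0_nf = theta0_nf, gamma0_nf = gamma0_nf,
    theta0_f = theta0_f, gamma0_f = gamma0_f,
    alpha0 = alpha0,
    alpha0_forager = pmin(1, alpha$forager_multiplier * alpha0)
  )
}

#' Promote an ant to forager status
#'
#' Applies the caste switch that occurs on an ant's first visit to the
#' food source: the caste label becomes `"F"` permanently, the leaving
#' maximum switches to its forager value and, under the two-emergent-caste
#' regime, the giving/receiving maxima switch to the (independently drawn)
#' forager values. Idempotent: promoting a forager changes nothing.
#'
#' This is the reference implementation used for testing; the simulation
#' core applies the identical switch internally.
#'
#' @param ant A one-row data frame (or list) with fields `caste`,
#'   `theta0`, `gamma0`, `alpha_max`, plus the latent columns produced by
#'   [draw_colony_traits()] (`theta0_f`, `gamma0_f`, `alpha0_forager`).
#' @return The updated ant.
#' @export
promote_to_forager <- function(ant) {
  if (identical(ant$caste, "F")) return(ant)
  ant$caste <- "F"
  ant$theta0 <- ant$theta0_f
  ant$gamma0 <- ant$gamma0_f
  ant$alpha_max <- ant$alpha0_forager
  ant
}
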