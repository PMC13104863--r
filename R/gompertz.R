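# Gompertz-Makeham mortality core: hazard, per-step death probability, and
# the mapping from allele (V, L) scores to (alpha, beta) parameters.

#' Gompertz-Makeham parameter set
#'
#' Bundles the three parameters of the Gompertz-Makeham hazard
#' \eqn{h(n) = \alpha e^{\beta n} + \gamma}: `alpha`, the baseline hazard at
#' age 0 (inverse of "vitality"); `beta`, the exponential rate at which the
#' hazard grows with age (inverse of "longevity"); and `gamma`, the
#' age-independent (Makeham) hazard.
#'
#' @param alpha Baseline hazard at age 0, per time unit. Must be > 0.
#' @param beta Exponential hazard-growth rate, per time unit. Must be >= 0.
#' @param gamma Age-independent hazard, per time unit. Must be >= 0.
#' @return An object of class `gompertz_params`.
#' @examples
#' gompertz_params(alpha = 0.125, beta = 0.15)
#' @export
gompertz_params <- function(alpha, beta, gamma = 0) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma),
            length(alpha) == 1L, length(beta) == 1L, length(gamma) == 1L)
  if (!is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a positive finite number")
  if (!is.finite(beta) || beta < 0)
    stop("`beta` must be a nonnegative finite number")
  if (!is.finite(gamma) || gamma < 0)
    stop("`gamma` must be a nonnegative finite number")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("Gompertz-Makeham parameters: alpha = %g, beta = %g, gamma = %g\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Gompertz-Makeham hazard rate
#'
#' Evaluates \eqn{h(n) = \alpha e^{\beta n} + \gamma} at ages `n`.
#'
#' @param params A [gompertz_params()] object.
#' @param n Vector of nonnegative ages, in time units.
#' @return Hazard rate(s), same length as `n`.
#' @examples
#' hazard(gompertz_params(0.125, 0.15), n = c(0, 10))
#' @export
hazard <- function(params, n) {
  stopifnot(inherits(params, "gompertz_params"), is.numeric(n))
  if (any(n < 0)) stop("age `n` must be nonnegative")
  params$alpha * exp(params$beta * n) + params$gamma
}

#' Probability of death within one time step
#'
#' Probability that an individual of age `n` dies before reaching age
#' `n + dt`, obtained by integrating the Gompertz-Makeham hazard over the
#' step:
#' \deqn{D_n = 1 - \exp\left[-\frac{\alpha}{\beta} e^{\beta n}
#'   (e^{\beta dt} - 1) - \gamma\, dt\right].}
#' When `beta == 0` the exact constant-hazard limit
#' \eqn{1 - e^{-(\alpha+\gamma) dt}} is used (a closed-form branch, not a
#' small-beta approximation).
#'
#' @param params A [gompertz_params()] object.
#' @param n Vector of nonnegative ages.
#' @param dt Step length, > 0.
#' @return Death probabilities in `[0, 1)`, same length as `n`.
#' @examples
#' death_probability(gompertz_params(0.125, 0.15), n = 0, dt = 1)
#' @export
death_probability <- function(params, n, dt = 1) {
  stopifnot(inherits(params, "gompertz_params"), is.numeric(n),
            is.numeric(dt), length(dt) == 1L)
  if (any(n < 0)) stop("age `n` must be nonnegative")
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive")
  with(params, {
    cum_haz <- if (beta == 0) {
      rep((alpha + gamma) * dt, length(n))
    } else {
      (alpha / beta) * exp(beta * n) * (exp(beta * dt) - 1) + gamma * dt
    }
    -expm1(-cum_haz)
  })
}

#' Heritable allele with a vitality/longevity tradeoff
#'
#' An allele carries a vitality score `V` (dimensionless; inversely related
#' to the baseline hazard `alpha`) and a longevity score `L` (time units;
#' the mortality-doubling half-life, inversely related to `beta`), plus a
#' dominance flag used by the diploid simulators.
#'
#' @param label Identifier string.
#' @param V Vitality score, > 0.
#' @param L Longevity score (mortality-doubling time), > 0.
#' @param dominant Logical; is this allele dominant over its competitor?
#' @return An object of class `allele`.
#' @examples
#' allele("vitality", V = 1000, L = 9, dominant = TRUE)
#' allele("longevity", V = 900, L = 10)
#' @export
allele <- function(label, V, L, dominant = FALSE) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(V), length(V) == 1L,
            is.numeric(L), length(L) == 1L,
            is.logical(dominant), length(dominant) == 1L)
  if (!is.finite(V) || V <= 0) stop("`V` must be positive")
  if (!is.finite(L) || L <= 0) stop("`L` must be positive")
  structure(list(label = label, V = V, L = L, dominant = dominant),
            class = "allele")
}

#' @export
print.allele <- function(x, ...) {
  cat(sprintf("Allele '%s': V = %g, L = %g%s\n", x$label, x$V, x$L,
              if (isTRUE(x$dominant)) " (dominant)" else ""))
  invisible(x)
}

#' Configuration of the (V, L) to (alpha, beta) mapping
#'
#' The mapping is anchored at a reference vitality `V_ref` that maps to the
#' baseline hazard `alpha_ref`, and is inverse in both traits:
#' `alpha = alpha_ref * V_ref / V` and `beta = log(2) / L`, so `L` is the
#' half-life over which mortality doubles (about 9 years in humans). The
#' default `alpha_ref` places the reference allele's median lifespan on the
#' order of tens of time units, so that a time unit plays the role of a
#' fraction of a year of life. `rule` is kept as an extension point for
#' alternative monotone-inverse mappings.
#'
#' @param alpha_ref Baseline hazard assigned to `V = V_ref`.
#' @param V_ref Reference vitality score.
#' @param rule Mapping rule name; only `"inverse"` is implemented.
#' @return An object of class `mapping_config`.
#' @export
mapping_config <- function(alpha_ref = 0.005, V_ref = 1000, rule = "inverse") {
  stopifnot(is.numeric(alpha_ref), alpha_ref > 0,
            is.numeric(V_ref), V_ref > 0)
  rule <- match.arg(rule, "inverse")
  structure(list(alpha_ref = alpha_ref, V_ref = V_ref, rule = rule),
            class = "mapping_config")
}

#' Map an allele's (V, L) scores to Gompertz-Makeham parameters
#'
#' @param allele An [allele()] object.
#' @param mapping A [mapping_config()] object.
#' @param gamma Age-independent hazard to install in the result.
#' @return A [gompertz_params()] object.
#' @examples
#' allele_to_gompertz(allele("longevity", 900, 10), mapping_config())
#' @export
allele_to_gompertz <- function(allele, mapping = mapping_config(), gamma = 0) {
  stopifnot(inherits(allele, "allele"), inherits(mapping, "mapping_config"))
  gompertz_params(alpha = mapping$alpha_ref * mapping$V_ref / allele$V,
                  beta = log(2) / allele$L,
                  gamma = gamma)
}

#' Vitality/longevity tradeoff point
#'
#' A point `(x, y)` of fractional changes applied to a reference parameter
#' set: the competitor's hazard is \eqn{(1-x)\alpha e^{(1-y)\beta n} + \gamma}.
#' A genuine tradeoff has `x` and `y` of opposite signs (a gain in one trait
#' paid for by a loss in the other); `tradeoff_point()` enforces this, with
#' zero allowed on either axis.
#'
#' @param x Fractional change in `alpha` (positive x lowers alpha: higher
#'   vitality).
#' @param y Fractional change in `beta` (positive y lowers beta: higher
#'   longevity).
#' @return An object of class `tradeoff_point`.
#' @export
tradeoff_point <- function(x, y) {
  stopifnot(is.numeric(x), length(x) == 1L, is.numeric(y), length(y) == 1L)
  if (x != 0 && y != 0 && sign(x) == sign(y))
    stop("`x` and `y` must have opposite signs when both are nonzero")
  structure(list(x = x, y = y), class = "tradeoff_point")
}

#' Apply a tradeoff point to a reference parameter set
#'
#' @param base A [gompertz_params()] object.
#' @param pt A [tradeoff_point()] object.
#' @return `gompertz_params((1 - x) * alpha, (1 - y) * beta, gamma)`.
#' @examples
#' apply_tradeoff(gompertz_params(0.05, 0.077), tradeoff_point(0.5, -0.5))
#' @export
apply_tradeoff <- function(base, pt) {
  stopifnot(inherits(base, "gompertz_params"), inherits(pt, "tradeoff_point"))
  if (pt$x >= 1) stop("`x` >= 1 would make alpha nonpositive")
  if (pt$y >= 1 && base$beta > 0) stop("`y` >= 1 would make beta nonpositive")
  gompertz_params(alpha = (1 - pt$x) * base$alpha,
                  beta = (1 - pt$y) * base$beta,
                  gamma = base$gamma)
}
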