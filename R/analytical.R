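# Deterministic age-structured two-allele competition: survivorship-based
# fitness difference, update equations for linear and saturating-exponential
# birth laws, steady states, carrying-capacity matching, and nullclines.

#' Survivorship curve under a Gompertz-Makeham hazard
#'
#' Returns the probability of surviving from age 0 to age `n` time steps,
#' \eqn{l_n = \prod_{k=0}^{n-1}(1 - D_k)}, for `n = 1, 2, ...`, truncated
#' once `l_n` drops below `tail_tol`. Because the per-step death
#' probabilities integrate the hazard exactly, the product telescopes to
#' \eqn{\exp(-\int_0^{n\,dt} h)}; truncation at `tail_tol` therefore loses at
#' most `tail_tol * (1 - D)/D` of the summed series (a geometric bound with
#' `D` the death probability at the truncation age).
#'
#' @param params A [gompertz_params()] object.
#' @param dt Step length.
#' @param tail_tol Truncation threshold on survivorship.
#' @param n_max Optional hard cap on the number of age classes.
#' @return Numeric vector `l_1, ..., l_N`.
#' @export
survivorship <- function(params, dt = 1, tail_tol = 1e-12, n_max = NULL) {
  stopifnot(inherits(params, "gompertz_params"))
  if (is.null(n_max)) {
    # closed-form inversion of l_n < tail_tol bounds the vector length
    n_max <- if (params$beta > 0) {
      target <- -log(tail_tol)
      ceiling(log1p(params$beta * target / params$alpha) /
                (params$beta * dt)) + 2L
    } else {
      ceiling(-log(tail_tol) / ((params$alpha + params$gamma) * dt)) + 2L
    }
    n_max <- min(n_max, 100000L)
  }
  ages <- (seq_len(n_max) - 1L) * dt
  surv_step <- 1 - death_probability(params, ages, dt)
  l <- cumprod(surv_step)
  keep <- which(l >= tail_tol)
  if (length(keep) == 0L) return(l[1L])
  l[seq_len(max(keep))]
}

#' Summed survivorship (the fitness functional)
#'
#' The sum \eqn{F = \sum_{n \ge 1} l_n} of survivorship over all positive
#' ages. The difference of this quantity between two alleles decides
#' competitive exclusion; see [delta_F()].
#'
#' @inheritParams survivorship
#' @return A single number.
#' @export
fitness_sum <- function(params, dt = 1, tail_tol = 1e-12) {
  sum(survivorship(params, dt = dt, tail_tol = tail_tol))
}

#' Fitness difference between two competing alleles
#'
#' \deqn{\Delta F = \sum_{n=1}^{\infty} \prod_{k=0}^{n-1} (1 - D_k)
#'              - \sum_{n=1}^{\infty} \prod_{k=0}^{n-1} (1 - d_k)}
#' where \eqn{D_k} and \eqn{d_k} are the per-step death probabilities of
#' alleles A and B. Its sign decides the age-structured competition:
#' positive means A competitively excludes B, negative the reverse. The
#' result applies to any birth law of the shared-factor form
#' \eqn{X_i = p_i H(A, B)}, which covers both the linear (single-queen) and
#' saturating-exponential laws implemented here.
#'
#' @param paramsA,paramsB [gompertz_params()] for the two alleles.
#' @param dt Step length.
#' @param tail_tol Series truncation threshold (see [survivorship()]).
#' @return The scalar fitness difference.
#' @examples
#' pA <- gompertz_params(0.05, log(2) / 9)
#' pB <- gompertz_params(0.05 / 0.9, log(2) / 10)
#' delta_F(pA, pB)
#' @export
delta_F <- function(paramsA, paramsB, dt = 1, tail_tol = 1e-12) {
  fitness_sum(paramsA, dt, tail_tol) - fitness_sum(paramsB, dt, tail_tol)
}

#' Birth law for the age-structured model
#'
#' @param mode `"linear"` (a single queen produces `g` offspring per step)
#'   or `"exponential"` (all females reproduce, saturating at population
#'   scale `Ns`).
#' @param g Per-interval fecundity (offspring per reproducing female per
#'   `dt`).
#' @param Ns Saturation population size (exponential mode only; must be
#'   > 2).
#' @return An object of class `growth_law`.
#' @export
growth_law <- function(mode = c("linear", "exponential"), g, Ns = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(g), length(g) == 1L, g > 0)
  if (mode == "exponential") {
    stopifnot(is.numeric(Ns), length(Ns) == 1L)
    if (Ns <= 2) stop("`Ns` must exceed 2 in exponential mode")
  }
  structure(list(mode = mode, g = g, Ns = Ns), class = "growth_law")
}

#' Offspring allele counts under linear (single-queen) reproduction
#'
#' A queen produces `g` offspring per interval; alleles are transmitted in
#' proportion to their current population frequency, so
#' `A0 = g * Atot / (Atot + Btot)` and likewise for B.
#'
#' @param Atot,Btot Total allele counts in the population.
#' @param g Queen fecundity per interval.
#' @return Named numeric vector `c(A0, B0)`; `c(0, 0)` for an empty
#'   population (extinction is absorbing: no queen, no births).
#' @export
births_linear <- function(Atot, Btot, g) {
  stopifnot(Atot >= 0, Btot >= 0, g > 0)
  tot <- Atot + Btot
  if (tot <= 0) return(c(A0 = 0, B0 = 0))
  c(A0 = g * Atot / tot, B0 = g * Btot / tot)
}

#' Saturating effective-female count
#'
#' The saturation function \eqn{S(x) = N_s x / (N_s + x - 2)} that caps the
#' number of effectively reproducing females in the exponential birth law:
#' `S(2) = 2` (a founding pair reproduces unhindered) and `S(x) -> Ns` as
#' `x` grows.
#'
#' @param x Total population size.
#' @param Ns Saturation scale, > 2.
#' @return Effective female-count scale.
#' @export
saturation <- function(x, Ns) {
  stopifnot(is.numeric(x), is.numeric(Ns))
  denom <- Ns + x - 2
  if (any(denom <= 0)) stop("saturation denominator Ns + x - 2 must be positive")
  Ns * x / denom
}

#' Offspring allele counts under saturating exponential reproduction
#'
#' \deqn{A_0 = \frac{g N_s A}{2 (N_s + A + B - 2)}}
#' and likewise for B: each allele's births are its frequency times the
#' shared factor \eqn{g S(N)/2}, with `N = Atot + Btot`.
#'
#' @inheritParams births_linear
#' @param Ns Saturation scale, > 2.
#' @return Named numeric vector `c(A0, B0)`.
#' @export
births_exponential <- function(Atot, Btot, g, Ns) {
  stopifnot(Atot >= 0, Btot >= 0, g > 0, Ns > 2)
  tot <- Atot + Btot
  if (tot <= 0) return(c(A0 = 0, B0 = 0))
  shared <- g * Ns / (2 * (Ns + tot - 2))
  c(A0 = shared * Atot, B0 = shared * Btot)
}

#' Age-structured two-allele state
#'
#' @param abundA,abundB Nonnegative abundance-by-age vectors (age 0 first).
#' @param t Time stamp.
#' @return An object of class `age_structured_state`.
#' @export
age_structured_state <- function(abundA, abundB, t = 0) {
  stopifnot(is.numeric(abundA), is.numeric(abundB))
  if (any(abundA < 0) || any(abundB < 0))
    stop("abundances must be nonnegative")
  n <- max(length(abundA), length(abundB))
  length(abundA) <- n; length(abundB) <- n
  abundA[is.na(abundA)] <- 0; abundB[is.na(abundB)] <- 0
  structure(list(abundA = abundA, abundB = abundB, t = t),
            class = "age_structured_state")
}

#' @export
print.age_structured_state <- function(x, ...) {
  cat(sprintf("Age-structured state at t = %g: %d age classes, total A = %.4g, total B = %.4g\n",
              x$t, length(x$abundA), sum(x$abundA), sum(x$abundB)))
  invisible(x)
}

#' Total abundance and mean age of a state
#'
#' @param state An [age_structured_state()].
#' @return `state_total`: summed abundance over both alleles and all ages.
#'   `state_mean_age`: abundance-weighted mean age (in steps).
#' @export
state_total <- function(state) sum(state$abundA) + sum(state$abundB)

#' @rdname state_total
#' @export
state_mean_age <- function(state) {
  w <- state$abundA + state$abundB
  if (sum(w) == 0) return(NA_real_)
  ages <- seq_along(w) - 1
  sum(ages * w) / sum(w)
}

# number of age classes needed so cumulative survivorship < tail_tol
max_age_classes <- function(paramsA, paramsB, dt = 1, tail_tol = 1e-12) {
  max(length(survivorship(paramsA, dt, tail_tol)),
      length(survivorship(paramsB, dt, tail_tol))) + 1L
}

#' Advance the age-structured model one time step
#'
#' Survival acts first (each age class advances with probability
#' `1 - D_n`), then newborns from the growth law are placed at age 0, so
#' the age-0 class at `t + dt` reflects abundances at `t`.
#'
#' @param state An [age_structured_state()].
#' @param growth A [growth_law()].
#' @param paramsA,paramsB Mortality parameters for the two alleles.
#' @param dt Step length.
#' @return The updated state.
#' @export
step_age_structured <- function(state, growth, paramsA, paramsB, dt = 1) {
  stopifnot(inherits(state, "age_structured_state"),
            inherits(growth, "growth_law"))
  Atot <- sum(state$abundA)
  Btot <- sum(state$abundB)
  births <- if (Atot + Btot <= 0) {
    c(A0 = 0, B0 = 0)
  } else if (growth$mode == "linear") {
    births_linear(Atot, Btot, growth$g)
  } else {
    births_exponential(Atot, Btot, growth$g, growth$Ns)
  }
  n <- length(state$abundA)
  ages <- (seq_len(n) - 1L) * dt
  survA <- 1 - death_probability(paramsA, ages, dt)
  survB <- 1 - death_probability(paramsB, ages, dt)
  newA <- c(births[["A0"]], (survA * state$abundA)[-n])
  newB <- c(births[["B0"]], (survB * state$abundB)[-n])
  age_structured_state(newA, newB, t = state$t + dt)
}

#' Iterate the age-structured model to its steady state
#'
#' Repeatedly applies [step_age_structured()] until the largest change in
#' any age-class abundance falls below `tol`. With both alleles present the
#' attainable steady states are the two competitive-exclusion states; the
#' winner matches the sign of [delta_F()].
#'
#' @inheritParams step_age_structured
#' @param init Initial state; default splits age class 0 equally (g/2 per
#'   allele).
#' @param tol Convergence tolerance on the max abundance change.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @param winner_tol Relative abundance (fraction of the total) below which
#'   an allele is declared excluded.
#' @return A list with elements `state`, `winner` (`"A"`, `"B"`, `"both"`,
#'   or `"none"`), `total`, `mean_age`, and `iterations`.
#' @export
steady_state <- function(growth, paramsA, paramsB, init = NULL, dt = 1,
                         tol = 1e-9, max_iter = 100000L, winner_tol = 1e-6) {
  n_cls <- max_age_classes(paramsA, paramsB, dt)
  if (is.null(init)) {
    a0 <- rep(0, n_cls); b0 <- rep(0, n_cls)
    a0[1] <- growth$g / 2; b0[1] <- growth$g / 2
    init <- age_structured_state(a0, b0)
  } else {
    # pad to the capped number of age classes
    init <- age_structured_state(c(init$abundA, rep(0, max(0, n_cls - length(init$abundA)))),
                                 c(init$abundB, rep(0, max(0, n_cls - length(init$abundB)))),
                                 t = init$t)
  }
  state <- init
  for (i in seq_len(max_iter)) {
    nxt <- step_age_structured(state, growth, paramsA, paramsB, dt)
    delta <- max(abs(nxt$abundA - state$abundA), abs(nxt$abundB - state$abundB))
    state <- nxt
    if (delta < tol) {
      Atot <- sum(state$abundA); Btot <- sum(state$abundB)
      tot <- Atot + Btot
      # exclusion is judged on relative abundance: the losing allele
      # decays geometrically and can sit at any absolute level when the
      # per-step change first drops below tol
      winner <- if (tot == 0) "none"
      else if (Atot > winner_tol * tot && Btot > winner_tol * tot) "both"
      else if (Atot >= Btot) "A"
      else "B"
      return(list(state = state, winner = winner, total = state_total(state),
                  mean_age = state_mean_age(state), iterations = i))
    }
  }
  stop(sprintf(paste0("steady_state did not converge in %d iterations ",
                      "(last max change %.3g, total %.6g)"),
               max_iter, delta, state_total(state)))
}

# single-allele steady-state population size, by iteration
single_allele_ss <- function(growth, params, dt = 1, tol = 1e-9) {
  ss <- steady_state(growth, params, params, dt = dt, tol = tol,
                     init = {
                       n_cls <- max_age_classes(params, params, dt)
                       a0 <- rep(0, n_cls); a0[1] <- growth$g
                       age_structured_state(a0, rep(0, n_cls))
                     })
  ss
}

#' Match carrying capacities by adjusting the age-independent hazard
#'
#' At equal mortality parameters the saturating-exponential population
#' equilibrates larger than the linear one. This routine raises the
#' age-independent (Makeham) component of the exponential population's
#' hazard from `gamma` to `gamma_prime >= gamma` until the two single-allele
#' steady-state population sizes agree, leaving the age-dependent component
#' untouched. After matching, the exponential population is younger on
#' average than the linear one.
#'
#' @param params Mortality parameters shared by both populations (the
#'   `gamma` slot is the linear population's value and the lower bracket for
#'   the search).
#' @param g Fecundity per female per interval (shared).
#' @param Ns Saturation scale of the exponential population.
#' @param dt Step length.
#' @param tol Absolute tolerance on the steady-state size difference.
#' @param gamma_upper Upper search bracket for `gamma_prime`.
#' @return A list: `gamma_prime`, the matched sizes `N_linear` and
#'   `N_exponential`, mean ages of both matched populations, and the
#'   residual size difference.
#' @export
match_gamma <- function(params, g, Ns, dt = 1, tol = 1e-6, gamma_upper = 5) {
  lin <- single_allele_ss(growth_law("linear", g = g), params, dt)
  target <- lin$total
  exp_size <- function(gam) {
    p <- gompertz_params(params$alpha, params$beta, gam)
    single_allele_ss(growth_law("exponential", g = g, Ns = Ns), p, dt)$total
  }
  at_gamma <- exp_size(params$gamma)
  if (at_gamma < target - tol)
    stop(sprintf(paste0("exponential steady state (%.4g) at gamma = %g is already ",
                        "below the linear target (%.4g); no gamma_prime >= gamma exists"),
                 at_gamma, params$gamma, target))
  if (abs(at_gamma - target) <= tol) {
    gamma_prime <- params$gamma
  } else {
    if (exp_size(gamma_upper) > target)
      stop("gamma_upper bracket too small: exponential population still larger")
    gamma_prime <- stats::uniroot(function(gam) exp_size(gam) - target,
                                  lower = params$gamma, upper = gamma_upper,
                                  tol = 1e-10)$root
  }
  pm <- gompertz_params(params$alpha, params$beta, gamma_prime)
  exp_ss <- single_allele_ss(growth_law("exponential", g = g, Ns = Ns), pm, dt)
  list(gamma_prime = gamma_prime,
       N_linear = target, N_exponential = exp_ss$total,
       mean_age_linear = lin$mean_age, mean_age_exponential = exp_ss$mean_age,
       residual = exp_ss$total - target)
}

#' Fitness nullcline in vitality-longevity tradeoff space
#'
#' For each fractional vitality change `x` on a grid, solves for the
#' fractional longevity change `y` such that the reference allele and the
#' tradeoff allele \eqn{(1-x)\alpha e^{(1-y)\beta n} + \gamma} are exactly
#' neutral (\eqn{\Delta F = 0}). The curve passes through the origin; for
#' the exponential population, pass `base` with the matched `gamma_prime`
#' from [match_gamma()] installed.
#'
#' The fitness difference is monotone in `y`, so each root is bracketed by
#' a sign change before refinement; grid points whose bracket contains no
#' sign change are reported with `y = NA` rather than extrapolated.
#'
#' @param base Reference [gompertz_params()] (with the gamma in force).
#' @param x_grid Vector of fractional vitality changes (each < 1).
#' @param dt Step length.
#' @param y_range Search interval for `y`.
#' @param tol Root tolerance on `y`.
#' @return A data.frame with columns `x`, `y`, and `deltaF_residual` (the
#'   fitness difference re-evaluated at the solved point).
#' @export
nullcline <- function(base, x_grid, dt = 1, y_range = c(-0.95, 0.95),
                      tol = 1e-10) {
  stopifnot(inherits(base, "gompertz_params"))
  f <- function(x, y) {
    delta_F(base, apply_tradeoff(base, structure(list(x = x, y = y),
                                                 class = "tradeoff_point")),
            dt = dt)
  }
  res <- lapply(x_grid, function(x) {
    if (x == 0) return(c(x = 0, y = 0, deltaF_residual = 0))
    lo <- y_range[1]; hi <- y_range[2]
    flo <- f(x, lo); fhi <- f(x, hi)
    if (is.na(flo) || is.na(fhi) || sign(flo) == sign(fhi))
      return(c(x = x, y = NA_real_, deltaF_residual = NA_real_))
    root <- stats::uniroot(function(y) f(x, y), lower = lo, upper = hi,
                           tol = tol)$root
    c(x = x, y = root, deltaF_residual = f(x, root))
  })
  as.data.frame(do.call(rbind, res))
}

#' Nullcline slope at the origin
#'
#' Finite-difference estimate of `dy/dx` of the fitness nullcline at the
#' neutral point `(0, 0)`; its magnitude measures how much longevity must
#' change to offset a small vitality change.
#'
#' @inheritParams nullcline
#' @param h Finite-difference step in `x`.
#' @return Scalar slope estimate.
#' @export
nullcline_slope_origin <- function(base, dt = 1, h = 0.01) {
  pts <- nullcline(base, c(-h, h), dt = dt)
  (pts$y[2] - pts$y[1]) / (2 * h)
}
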