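# Queen-effects-only model: match population size and age structure between
# linear and exponential populations, then measure the fixation bias of
# invading higher-vitality/lower-longevity alleles.

# First zero crossing of y(x) by sign-change bracketing and linear
# interpolation; NA when the grid contains no sign change (censored).
interp_zero <- function(x, y) {
  s <- which(diff(sign(y)) != 0)
  if (length(s) == 0L) return(NA_real_)
  i <- s[1L]
  x[i] + (0 - y[i]) * (x[i + 1L] - x[i]) / (y[i + 1L] - y[i])
}

# Demographic summary of a single-allele population under cfg: long-run
# mean size, per-tick birth flow, and pooled age samples.
measure_demography <- function(cfg, resident, burn_in, sample_ticks,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- abm_context(cfg, resident, resident)
  pop <- init_population(cfg, init_freq = 1)
  for (t in seq_len(burn_in)) pop <- abm_tick(pop, cfg, ctx)
  Ns <- numeric(sample_ticks); births <- numeric(sample_ticks)
  ages <- vector("list", sample_ticks)
  for (t in seq_len(sample_ticks)) {
    n_before <- pop_size(pop)
    pop <- abm_tick(pop, cfg, ctx)
    births[t] <- sum(pop$age == 0L)
    Ns[t] <- pop_size(pop)
    if (t %% 10L == 0L) ages[[t]] <- pop$age
    if (Ns[t] == 0) break
  }
  list(mean_N = mean(Ns), birth_flow = mean(births), ages = unlist(ages),
       pop = pop)
}

# maximum absolute difference between two empirical age CDFs
age_ecdf_distance <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  grid <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
}

#' Match linear and exponential populations demographically
#'
#' Adjusts the queen's fecundity (`litter_size`) in the linear
#' configuration and the per-female reproduction probability (`p_repro`)
#' in the exponential configuration until the two single-allele
#' populations agree in long-run mean size (within `size_tol`,
#' fractional) and approximately in age structure (maximum absolute
#' difference between pooled empirical age distribution functions,
#' target `age_tol`). Matching the per-tick birth flows is the control
#' signal for age structure: with equal sizes, equal birth flows, and
#' identical mortality configuration, the stationary age distributions
#' coincide.
#'
#' @param linear_cfg,exp_cfg [abm_config()]s in the respective modes;
#'   density parameters, maturity and the allele mapping should be shared.
#' @param resident The resident [allele()] used for the match.
#' @param size_tol Fractional tolerance on mean population size.
#' @param age_tol Target maximum ECDF difference between age
#'   distributions.
#' @param burn_in Ticks discarded before measuring.
#' @param sample_ticks Ticks measured per iteration.
#' @param max_iter Adjustment iterations.
#' @param seed RNG seed (the verification pass uses fresh seeds).
#' @return A list: `linear_cfg` and `exp_cfg` (adjusted), `matched`
#'   (logical: both tolerances met on the out-of-sample verification run),
#'   and `report` (data.frame of achieved sizes, ages, and distances).
#' @export
match_populations <- function(linear_cfg, exp_cfg, resident,
                              size_tol = 0.05, age_tol = 0.05,
                              burn_in = 300L, sample_ticks = 1200L,
                              max_iter = 8L, seed = 1) {
  stopifnot(linear_cfg$mode == "linear", exp_cfg$mode == "exponential")
  seeds <- derive_seeds(seed, 2L * max_iter + 6L)
  consecutive_ok <- 0L
  for (i in seq_len(max_iter)) {
    dl <- measure_demography(linear_cfg, resident, burn_in, sample_ticks,
                             seeds[2L * i - 1L])
    de <- measure_demography(exp_cfg, resident, burn_in, sample_ticks,
                             seeds[2L * i])
    if (de$mean_N < 5 || de$birth_flow == 0) {
      # exponential population collapsed: the last fecundity cut was too
      # deep; step back up and re-measure
      exp_cfg$p_repro <- min(1, exp_cfg$p_repro * 2)
      next
    }
    size_ok <- abs(de$mean_N - dl$mean_N) / dl$mean_N < size_tol / 2
    flow_ratio <- dl$birth_flow / de$birth_flow
    flow_ok <- abs(flow_ratio - 1) < 0.1
    if (size_ok && flow_ok) {
      # one noisy window can fake a pass; demand two in a row
      consecutive_ok <- consecutive_ok + 1L
      if (consecutive_ok >= 2L) break
      next
    }
    consecutive_ok <- 0L
    if (!size_ok) {
      # queen fecundity controls the linear population's size (damped);
      # one knob per iteration: sizes first, then age structure
      linear_cfg$litter_size <-
        min(50, max(1, linear_cfg$litter_size *
                      (de$mean_N / dl$mean_N)^0.8))
    } else {
      # per-female fecundity controls the exponential age structure; keep
      # it viable (lifetime reproduction must clear replacement)
      exp_cfg$p_repro <- min(1, max(0.05, exp_cfg$p_repro * flow_ratio^0.8))
    }
  }
  # out-of-sample verification on fresh seeds, with one bounded retouch of
  # the queen fecundity if the verification window disagrees
  for (v in 1:2) {
    dl <- measure_demography(linear_cfg, resident, burn_in, sample_ticks,
                             seeds[2L * max_iter + 2L * v - 1L])
    de <- measure_demography(exp_cfg, resident, burn_in, sample_ticks,
                             seeds[2L * max_iter + 2L * v])
    dist <- age_ecdf_distance(dl$ages, de$ages)
    size_dev <- abs(de$mean_N - dl$mean_N) / dl$mean_N
    matched <- size_dev < size_tol && !is.na(dist) && dist < age_tol
    if (matched || v == 2L) break
    linear_cfg$litter_size <-
      min(50, max(1, linear_cfg$litter_size * (de$mean_N / dl$mean_N)^0.8))
  }
  if (!matched)
    warning(sprintf(paste0("populations not matched to tolerance: size ",
                           "deviation %.3f (tol %.3f), age ECDF distance ",
                           "%.3f (tol %.3f)"),
                    size_dev, size_tol, dist, age_tol))
  list(linear_cfg = linear_cfg, exp_cfg = exp_cfg, matched = matched,
       report = data.frame(
         mean_N_linear = dl$mean_N, mean_N_exponential = de$mean_N,
         size_deviation = size_dev,
         median_age_linear = stats::median(dl$ages),
         median_age_exponential = stats::median(de$ages),
         age_ecdf_distance = dist))
}

#' Invasion specification
#'
#' @param resident,invader [allele()] objects.
#' @param n_invaders Number of invader homozygotes introduced (must be
#'   small relative to the resident population).
#' @param n_reps Number of invasion replicates.
#' @param seed Master seed.
#' @return An object of class `invasion_spec`.
#' @export
invasion_spec <- function(resident, invader, n_invaders = 5L, n_reps = 500L,
                          seed = 1) {
  stopifnot(inherits(resident, "allele"), inherits(invader, "allele"),
            n_invaders >= 1, n_reps >= 1)
  structure(list(resident = resident, invader = invader,
                 n_invaders = as.integer(n_invaders),
                 n_reps = as.integer(n_reps), seed = seed),
            class = "invasion_spec")
}

# default burn-in: ten times the age by which resident survivorship has
# fallen below 1%
default_burn_in <- function(cfg, resident) {
  p <- allele_to_gompertz(resident, cfg$mapping, cfg$gamma)
  10L * length(survivorship(p, tail_tol = 0.01))
}

# introduce invader homozygotes (mature, sexes alternating) into pop;
# invader is allele code 2
introduce_invaders <- function(pop, n_invaders, maturity_age) {
  k <- n_invaders
  new_population(c(pop$age, rep(maturity_age, k)),
                 c(pop$female, rep(c(FALSE, TRUE), length.out = k)),
                 c(pop$g1, rep(2L, k)),
                 c(pop$g2, rep(2L, k)),
                 c(pop$queen, rep(FALSE, k)))
}

#' Invasion experiment and fixation bias
#'
#' Burns a monomorphic resident population in to demographic steady state
#' (ten times the resident's ~1% survivorship age by default), introduces
#' `n_invaders` invader homozygotes, and runs to fixation or loss.
#' Replicates are seeded independently; a fresh burn-in population is
#' drawn for every `fresh_burnin_every` replicates (burn-ins are shared
#' within a block to keep the cost manageable; invader introduction and
#' all subsequent dynamics remain replicate-specific). The fixation bias
#' is `FB = f / p0 - 1` where `f` is the fraction of replicates in which
#' the invader fixed and `p0` its initial frequency.
#'
#' @param spec An [invasion_spec()].
#' @param cfg An [abm_config()] (either mode).
#' @param burn_in Burn-in ticks before introduction; `NULL` for the
#'   default.
#' @param fresh_burnin_every Replicates per independent burn-in
#'   population.
#' @return A `fixation_bias_result` list: `f`, `p0`, `FB`, the Wald `ci`
#'   on `f`, `FB_ci`, counts, and the number of discarded replicates
#'   (resident extinct before introduction).
#' @export
invasion_experiment <- function(spec, cfg, burn_in = NULL,
                                fresh_burnin_every = 25L) {
  stopifnot(inherits(spec, "invasion_spec"), inherits(cfg, "abm_config"))
  if (is.null(burn_in)) burn_in <- default_burn_in(cfg, spec$resident)
  ctx <- abm_context(cfg, spec$resident, spec$invader)
  seeds <- derive_seeds(spec$seed, spec$n_reps)
  n_fixed <- 0L; n_lost <- 0L; n_undecided <- 0L; n_discarded <- 0L
  p0s <- numeric(0)
  base_pop <- NULL
  for (i in seq_len(spec$n_reps)) {
    set.seed(seeds[i])
    if (is.null(base_pop) || (i - 1L) %% fresh_burnin_every == 0L) {
      base_pop <- init_population(cfg, init_freq = 1)
      for (t in seq_len(burn_in)) base_pop <- abm_tick(base_pop, cfg, ctx)
    }
    if (pop_size(base_pop) == 0L) {
      n_discarded <- n_discarded + 1L
      base_pop <- NULL
      next
    }
    pop <- introduce_invaders(base_pop, spec$n_invaders, cfg$maturity_age)
    p0s <- c(p0s, spec$n_invaders / pop_size(pop))
    t <- 0L
    repeat {
      f <- allele_freq(pop)           # resident (code 1) frequency
      if (is.nan(f) || f == 1) { n_lost <- n_lost + 1L; break }
      if (f == 0) { n_fixed <- n_fixed + 1L; break }
      if (t >= cfg$max_ticks) { n_undecided <- n_undecided + 1L; break }
      pop <- abm_tick(pop, cfg, ctx)
      t <- t + 1L
    }
  }
  n_eff <- n_fixed + n_lost + n_undecided
  if (n_eff == 0L) stop("all replicates discarded: resident went extinct")
  p0 <- mean(p0s)
  ci <- wald_ci(n_fixed, n_eff)
  structure(list(f = ci[["estimate"]], p0 = p0,
                 FB = ci[["estimate"]] / p0 - 1,
                 ci = ci, FB_ci = c(ci[["low"]], ci[["high"]]) / p0 - 1,
                 counts = c(fixed = n_fixed, lost = n_lost,
                            undecided = n_undecided,
                            discarded = n_discarded),
                 n = n_eff),
            class = "fixation_bias_result")
}

#' @export
print.fixation_bias_result <- function(x, ...) {
  cat(sprintf("Invasion: f = %.4f (p0 = %.4f), FB = %.3f [%.3f, %.3f], n = %d\n",
              x$f, x$p0, x$FB, x$FB_ci[1], x$FB_ci[2], x$n))
  invisible(x)
}

#' Scan vitality advantages for the neutral (FB = 0) threshold
#'
#' Holds the invader's longevity loss fixed, varies its vitality advantage
#' over a grid, measures the fixation bias at each point, and locates the
#' vitality advantage at which FB crosses zero by bracketing and linear
#' interpolation. The population type (linear vs exponential `cfg`) whose
#' crossing is smaller needs less of a vitality gain to pay for the same
#' longevity loss, i.e. it cares less about longevity.
#'
#' @param resident The resident [allele()].
#' @param longevity_loss Fractional reduction of the invader's `L`
#'   relative to the resident.
#' @param vitality_grid Vector of fractional vitality advantages to test.
#' @param cfg An [abm_config()].
#' @param n_invaders,n_reps,seed Passed to [invasion_spec()].
#' @param burn_in Passed to [invasion_experiment()].
#' @return A list: `table` (data.frame of `vitality_advantage`, `f`, `p0`,
#'   `FB`, `ci_low`, `ci_high`), `crossing` (interpolated FB = 0 vitality
#'   advantage, `NA` if censored), and `crossing_ci` (interpolated from
#'   the CI envelopes).
#' @export
neutral_threshold_scan <- function(resident, longevity_loss, vitality_grid,
                                   cfg, n_invaders = 5L, n_reps = 400L,
                                   seed = 1, burn_in = NULL) {
  seeds <- derive_seeds(seed, length(vitality_grid))
  rows <- vector("list", length(vitality_grid))
  for (i in seq_along(vitality_grid)) {
    v <- vitality_grid[i]
    invader <- allele(sprintf("invader_v%+.3f", v),
                      V = resident$V * (1 + v),
                      L = resident$L * (1 - longevity_loss))
    res <- invasion_experiment(
      invasion_spec(resident, invader, n_invaders, n_reps, seeds[i]),
      cfg, burn_in = burn_in)
    rows[[i]] <- data.frame(vitality_advantage = v, f = res$f, p0 = res$p0,
                            FB = res$FB, ci_low = res$FB_ci[1],
                            ci_high = res$FB_ci[2])
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       crossing = interp_zero(tab$vitality_advantage, tab$FB),
       crossing_ci = c(interp_zero(tab$vitality_advantage, tab$ci_high),
                       interp_zero(tab$vitality_advantage, tab$ci_low)))
}
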