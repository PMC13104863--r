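# Colony-level metapopulation simulator: exponential colony reproduction
# superimposed on linear (single-queen) within-colony reproduction, in two
# styles. Ant mode: colonies are founded by lone queens carrying sperm from
# a mating flight, and die with their queen. Mole-rat mode: colonies send
# out groups of pioneers, replace dead queens after a delay, and face
# occasional colony-wide disasters.

#' Metapopulation configuration
#'
#' @param mode `"ant"` or `"molerat"`.
#' @param colony_cfg An [abm_config()] in `"linear"` mode governing
#'   within-colony demography (its `K` is the per-colony density midpoint;
#'   its `init_size` the size of founding colonies at initialization).
#' @param threshold_colony_size Member count at which a colony starts
#'   sending out founders.
#' @param C_cap Colony-count scale of the founding logistic: a founding
#'   attempt succeeds with probability `1 / (1 + exp((C - C_cap) / w_c))`
#'   where `C` is the current number of colonies.
#' @param w_c Width of the founding logistic.
#' @param p_disaster Per-colony per-tick probability of a disaster
#'   (mole-rat mode).
#' @param p_disaster_kill Per-member death probability during a disaster.
#' @param ticks_to_queen_replacement Delay before a dead queen is replaced
#'   (mole-rat mode).
#' @param pioneers_per_event Number of members leaving to found a colony
#'   (mole-rat mode; capped so the source keeps at least one member).
#' @param flight_interval Ticks between mating-flight/founding
#'   opportunities.
#' @param n_colonies_init Number of colonies at initialization.
#' @param max_ticks Tick cap for a run.
#' @param snapshot_every Interval for pooled age snapshots.
#' @return An object of class `metapop_config`.
#' @export
metapop_config <- function(mode = c("ant", "molerat"),
                           colony_cfg = abm_config("linear", init_size = 16L,
                                                   K = 60, w = 6),
                           threshold_colony_size = 30L,
                           C_cap = 15, w_c = 2,
                           p_disaster = 0.045,
                           p_disaster_kill = 0.9,
                           ticks_to_queen_replacement = 5L,
                           pioneers_per_event = 10L,
                           flight_interval = 1L,
                           n_colonies_init = 8L,
                           max_ticks = 20000L,
                           snapshot_every = 50L) {
  mode <- match.arg(mode)
  stopifnot(inherits(colony_cfg, "abm_config"), colony_cfg$mode == "linear",
            threshold_colony_size >= 2, C_cap > 0, w_c > 0,
            p_disaster >= 0, p_disaster <= 1,
            p_disaster_kill >= 0, p_disaster_kill <= 1,
            ticks_to_queen_replacement >= 0, pioneers_per_event >= 1,
            flight_interval >= 1, n_colonies_init >= 1, max_ticks >= 1)
  structure(list(mode = mode, colony_cfg = colony_cfg,
                 threshold_colony_size = as.integer(threshold_colony_size),
                 C_cap = C_cap, w_c = w_c,
                 p_disaster = p_disaster, p_disaster_kill = p_disaster_kill,
                 ticks_to_queen_replacement = as.integer(ticks_to_queen_replacement),
                 pioneers_per_event = as.integer(pioneers_per_event),
                 flight_interval = as.integer(flight_interval),
                 n_colonies_init = as.integer(n_colonies_init),
                 max_ticks = as.integer(max_ticks),
                 snapshot_every = as.integer(snapshot_every)),
            class = "metapop_config")
}

# A colony: population + mode-specific bookkeeping.
new_colony <- function(pop, stored_sperm = NULL, founded_at = 0L,
                       queenless_since = NA_integer_) {
  list(pop = pop, stored_sperm = stored_sperm, founded_at = founded_at,
       queenless_since = queenless_since)
}

colony_allele_counts <- function(col) {
  c(sum(col$pop$g1 == 1L) + sum(col$pop$g2 == 1L),
    sum(col$pop$g1 == 2L) + sum(col$pop$g2 == 2L))
}

# One within-colony tick (linear reproduction). Differs from abm_tick()
# in the father source (ant mode: stored sperm) and queen-replacement
# policy. Returns the updated colony, or NULL if the colony dies
# (ant mode: with its queen; both modes: when empty or irrecoverably
# female-free and queenless).
colony_tick <- function(col, mcfg, ctx, t) {
  cfg <- mcfg$colony_cfg
  pop <- col$pop
  N <- length(pop$age)
  if (N == 0L) return(NULL)
  # disasters (mole-rat mode)
  if (mcfg$mode == "molerat" && mcfg$p_disaster > 0 &&
      stats::runif(1) < mcfg$p_disaster) {
    alive <- stats::runif(N) >= mcfg$p_disaster_kill
    pop <- subset_population(pop, alive)
    N <- length(pop$age)
    if (N == 0L) return(NULL)
  }
  # mortality
  gcls <- pop$g1 + pop$g2 - 1L
  amax <- ncol(ctx$D)
  D_age <- ctx$D[cbind(gcls, pmin(pop$age, amax - 1L) + 1L)]
  d_dens <- stats::plogis((N - cfg$K) / cfg$w)
  alive <- stats::runif(N) >= 1 - (1 - D_age) * (1 - d_dens)
  pop <- subset_population(pop, alive)
  if (length(pop$age) == 0L) return(NULL)
  # queen status
  if (!any(pop$queen)) {
    if (mcfg$mode == "ant") return(NULL)  # colony dies with its queen
    if (is.na(col$queenless_since)) col$queenless_since <- t
    if (t - col$queenless_since >= mcfg$ticks_to_queen_replacement) {
      cand <- which(pop$female)
      if (length(cand) > 0L) {
        pop$queen[cand[sample.int(length(cand), 1L)]] <- TRUE
        col$queenless_since <- NA_integer_
      } else {
        return(NULL)  # no queen and no females: cannot recover
      }
    }
  } else {
    col$queenless_since <- NA_integer_
  }
  # births
  q <- which(pop$queen)
  n_new <- 0L
  if (length(q) == 1L && pop$age[q] >= cfg$maturity_age &&
      stats::runif(1) < cfg$p_repro) {
    father <- if (mcfg$mode == "ant") {
      col$stored_sperm
    } else {
      males <- which(!pop$female & pop$age >= cfg$maturity_age)
      if (length(males) > 0L)
        c(pop$g1[males[sample.int(length(males), 1L)]],
          pop$g2[males[sample.int(length(males), 1L)]])
      else NULL
    }
    if (!is.null(father)) {
      n_new <- draw_litter(cfg$litter_size)
      if (n_new > 0L) {
        g1 <- ifelse(stats::runif(n_new) < 0.5, pop$g1[q], pop$g2[q])
        g2 <- ifelse(stats::runif(n_new) < 0.5, father[1L], father[2L])
        newborn_female <- stats::runif(n_new) < 0.5
      }
    }
  }
  pop$age <- pop$age + 1L
  if (n_new > 0L) {
    pop <- fast_population(c(pop$age, integer(n_new)),
                                 c(pop$female, newborn_female),
                                 c(pop$g1, as.integer(g1)),
                                 c(pop$g2, as.integer(g2)),
                                 c(pop$queen, logical(n_new)))
  }
  col$pop <- pop
  col
}

# founding-success probability as a logistic in the current colony count
founding_prob <- function(C, mcfg) stats::plogis((mcfg$C_cap - C) / mcfg$w_c)

#' Ant-mode colony founding
#'
#' A source colony at or above the threshold size sends out a new queen: a
#' daughter of the source queen (bred from the stored sperm), who mates on
#' a mating flight with a random mature male drawn from all
#' threshold-size colonies and stores his genotype as an inexhaustible
#' sperm supply. Establishment succeeds with the founding-logistic
#' probability in the current colony count.
#'
#' @param source A colony (internal list representation).
#' @param sperm_pool Integer matrix with columns `g1`, `g2`: genotypes of
#'   mating-flight males.
#' @param n_colonies Current colony count.
#' @param mcfg A [metapop_config()].
#' @return A new colony or `NULL`.
#' @keywords internal
ant_found_colony <- function(source, sperm_pool, n_colonies, mcfg) {
  cfg <- mcfg$colony_cfg
  if (length(source$pop$age) < mcfg$threshold_colony_size) return(NULL)
  if (is.null(sperm_pool) || nrow(sperm_pool) == 0L) return(NULL)
  if (stats::runif(1) >= founding_prob(n_colonies, mcfg)) return(NULL)
  q <- which(source$pop$queen)
  if (length(q) != 1L) return(NULL)
  # daughter queen: one allele from the source queen, one from its sperm
  qg1 <- if (stats::runif(1) < 0.5) source$pop$g1[q] else source$pop$g2[q]
  qg2 <- source$stored_sperm[[1L + (stats::runif(1) < 0.5)]]
  sperm <- sperm_pool[sample.int(nrow(sperm_pool), 1L), ]
  pop <- new_population(age = cfg$maturity_age, female = TRUE,
                        g1 = qg1, g2 = qg2, queen = TRUE)
  new_colony(pop, stored_sperm = as.integer(sperm))
}

#' Mole-rat-mode colony founding
#'
#' `pioneers_per_event` members (capped at source size minus one) leave the
#' source colony. If at least one pioneer is female and the
#' founding-logistic draw succeeds, a new colony forms with a random
#' pioneer female as queen; otherwise the pioneers are lost. The source
#' always loses the pioneers.
#'
#' @param source A colony (internal list representation).
#' @param n_colonies Current colony count.
#' @param mcfg A [metapop_config()].
#' @return A list `(source = updated source, new = new colony or NULL)`.
#' @keywords internal
molerat_seed <- function(source, n_colonies, mcfg) {
  n <- length(source$pop$age)
  if (n < mcfg$threshold_colony_size) return(list(source = source, new = NULL))
  k <- min(mcfg$pioneers_per_event, n - 1L)
  idx <- sample.int(n, k)
  pioneers <- subset_population(source$pop, idx)
  pioneers$queen[] <- FALSE
  source$pop <- subset_population(source$pop, -idx)
  new <- NULL
  fem <- which(pioneers$female)
  if (length(fem) > 0L && stats::runif(1) < founding_prob(n_colonies, mcfg)) {
    pioneers$queen[fem[sample.int(length(fem), 1L)]] <- TRUE
    new <- new_colony(pioneers)
  }
  list(source = source, new = new)
}

# initial mixed colony: linear-mode founders plus, in ant mode, stored
# sperm from a random founding male
init_colony <- function(mcfg, init_freq = 0.5) {
  cfg <- mcfg$colony_cfg
  pop <- init_population(cfg, init_freq)
  qcand <- which(pop$female)
  pop$queen[qcand[sample.int(length(qcand), 1L)]] <- TRUE
  sperm <- NULL
  if (mcfg$mode == "ant") {
    males <- which(!pop$female)
    m <- males[sample.int(length(males), 1L)]
    sperm <- c(pop$g1[m], pop$g2[m])
  }
  new_colony(pop, stored_sperm = sperm)
}

#' Run a metapopulation competition to fixation
#'
#' Initializes `n_colonies_init` colonies, each internally mixed at
#' `init_freq`, and ticks the metapopulation: within-colony linear
#' reproduction (and mole-rat disasters), colony deaths, and colony
#' founding, until one allele fixes metapopulation-wide, the
#' metapopulation goes extinct, or `max_ticks` elapses.
#'
#' @param mcfg A [metapop_config()].
#' @param alleleA,alleleB Competing [allele()]s.
#' @param init_freq Initial frequency of allele A.
#' @param seed Optional RNG seed.
#' @return A `sim_result` with additional elements `colony_series` (colony
#'   count per tick) and `single_allele_fraction_series` (fraction of
#'   colonies internally fixed for one allele, sampled every
#'   `snapshot_every` ticks).
#' @export
metapop_run <- function(mcfg, alleleA, alleleB, init_freq = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- abm_context(mcfg$colony_cfg, alleleA, alleleB)
  colonies <- lapply(seq_len(mcfg$n_colonies_init),
                     function(i) init_colony(mcfg, init_freq))
  freq <- numeric(0); Ns <- numeric(0); Cs <- integer(0)
  mono <- numeric(0); snaps <- integer(0)
  outcome <- "none"; extinct <- FALSE
  t <- 0L
  repeat {
    counts <- vapply(colonies, colony_allele_counts, numeric(2))
    totA <- sum(counts[1, ]); totB <- sum(counts[2, ])
    tot <- totA + totB
    freq[t + 1L] <- if (tot > 0) totA / tot else NaN
    Ns[t + 1L] <- tot / 2
    Cs[t + 1L] <- length(colonies)
    if (length(colonies) == 0L || tot == 0) { extinct <- TRUE; break }
    if (totB == 0) { outcome <- "fixed_A"; break }
    if (totA == 0) { outcome <- "fixed_B"; break }
    if (t >= mcfg$max_ticks) break
    if (t > 0L && t %% mcfg$snapshot_every == 0L) {
      mono <- c(mono, mean(counts[1, ] == 0 | counts[2, ] == 0))
      snaps <- c(snaps, unlist(lapply(colonies, function(cl) cl$pop$age)))
    }
    # within-colony dynamics (and mole-rat disasters / queen policy)
    colonies <- Filter(Negate(is.null),
                       lapply(colonies, colony_tick, mcfg = mcfg, ctx = ctx,
                              t = t))
    # founding
    if (length(colonies) > 0L && t %% mcfg$flight_interval == 0L) {
      C <- length(colonies)
      sizes <- vapply(colonies, function(cl) length(cl$pop$age), integer(1))
      eligible <- which(sizes >= mcfg$threshold_colony_size)
      if (length(eligible) > 0L) {
        if (mcfg$mode == "ant") {
          pool <- do.call(rbind, lapply(colonies[eligible], function(cl) {
            sel <- !cl$pop$female & cl$pop$age >= mcfg$colony_cfg$maturity_age
            cbind(g1 = cl$pop$g1[sel], g2 = cl$pop$g2[sel])
          }))
          for (i in eligible) {
            nc <- ant_found_colony(colonies[[i]], pool, length(colonies), mcfg)
            if (!is.null(nc)) colonies[[length(colonies) + 1L]] <- nc
          }
        } else {
          for (i in eligible) {
            res <- molerat_seed(colonies[[i]], length(colonies), mcfg)
            colonies[[i]] <- res$source
            if (!is.null(res$new)) colonies[[length(colonies) + 1L]] <- res$new
          }
        }
      }
    }
    t <- t + 1L
  }
  final_ages <- unlist(lapply(colonies, function(cl) cl$pop$age))
  structure(list(outcome = outcome, extinct = extinct, ticks_elapsed = t,
                 freq_series = freq, N_series = Ns, colony_series = Cs,
                 single_allele_fraction_series = mono,
                 age_snapshots = snaps,
                 final_ages = if (is.null(final_ages)) integer(0) else final_ages),
            class = "sim_result")
}

#' Replicated metapopulation fixation experiment
#'
#' @inheritParams metapop_run
#' @param n_reps Number of replicates.
#' @param seed Master seed, expanded via [derive_seeds()].
#' @return An `experiment_summary` (see [fixation_experiment()]).
#' @export
metapop_experiment <- function(mcfg, alleleA, alleleB, n_reps = 50,
                               init_freq = 0.5, seed = 1) {
  seeds <- derive_seeds(seed, n_reps)
  outcomes <- character(n_reps); ticks <- numeric(n_reps)
  mono <- numeric(0)
  for (i in seq_len(n_reps)) {
    r <- metapop_run(mcfg, alleleA, alleleB, init_freq, seed = seeds[i])
    outcomes[i] <- r$outcome
    ticks[i] <- r$ticks_elapsed
    mono <- c(mono, r$single_allele_fraction_series)
  }
  kA <- sum(outcomes == "fixed_A"); kB <- sum(outcomes == "fixed_B")
  undecided <- n_reps - kA - kB
  decided <- kA + kB
  row <- function(lbl, k) {
    ci <- wald_ci(k, n_reps)
    cid <- if (decided > 0) wald_ci(k, decided) else c(NA, NA, NA)
    data.frame(allele = lbl, n_fixed = k,
               prop_all = ci[["estimate"]], ci_low = ci[["low"]],
               ci_high = ci[["high"]],
               prop_decided = cid[[1]], ci_low_decided = cid[[2]],
               ci_high_decided = cid[[3]], stringsAsFactors = FALSE)
  }
  structure(list(
    counts = c(fixed_A = kA, fixed_B = kB, undecided = undecided),
    summary = rbind(row(alleleA$label, kA), row(alleleB$label, kB)),
    pooled_ages = integer(0), pooled_sizes = numeric(0),
    mean_single_allele_fraction = if (length(mono)) mean(mono) else NA_real_,
    mean_ticks = mean(ticks), n_reps = n_reps,
    config_hash = config_hash(mcfg), seed = seed, seeds = seeds
  ), class = "experiment_summary")
}
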