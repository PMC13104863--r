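# Diploid agent-based simulator of two-allele competition under linear
# (single-queen) or exponential (all mature females) reproduction, with
# Gompertz age-dependent mortality plus logistic density-dependent
# mortality.
#
# A population is a plain list of parallel vectors (age, female, g1, g2,
# queen) for speed; alleles are coded 1 (A) and 2 (B).

#' Construct a population from parallel vectors
#'
#' @param age Integer ages in ticks.
#' @param female Logical sex indicator.
#' @param g1,g2 Allele codes (1 or 2) for the two gene copies.
#' @param queen Logical queen flags (at most one `TRUE`).
#' @return An object of class `population`.
#' @export
new_population <- function(age, female, g1, g2, queen = rep(FALSE, length(age))) {
  n <- length(age)
  stopifnot(length(female) == n, length(g1) == n, length(g2) == n,
            length(queen) == n, sum(queen) <= 1L)
  structure(list(age = as.integer(age), female = female,
                 g1 = as.integer(g1), g2 = as.integer(g2), queen = queen),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Population of %d individuals (%d female), allele A frequency %.3f\n",
              length(x$age), sum(x$female), allele_freq(x)))
  invisible(x)
}

#' Population size and allele-A frequency
#'
#' @param pop A `population`.
#' @return `pop_size`: number of living individuals. `allele_freq`: the
#'   frequency of allele A (code 1) among all `2 N` gene copies (`NaN` for
#'   an empty population).
#' @export
pop_size <- function(pop) length(pop$age)

#' @rdname pop_size
#' @export
allele_freq <- function(pop) {
  n <- length(pop$g1)
  if (n == 0L) return(NaN)
  (sum(pop$g1 == 1L) + sum(pop$g2 == 1L)) / (2 * n)
}

# validation-free constructor for internal hot paths
fast_population <- function(age, female, g1, g2, queen) {
  structure(list(age = age, female = female, g1 = g1, g2 = g2, queen = queen),
            class = "population")
}

subset_population <- function(pop, keep) {
  fast_population(pop$age[keep], pop$female[keep], pop$g1[keep],
                  pop$g2[keep], pop$queen[keep])
}

#' Simulator configuration
#'
#' Parameters of the individual-reproduction agent-based model. Density
#' dependence adds an age-independent death probability
#' `d(N) = 1 / (1 + exp(-(N - K) / w))`, a logistic in population size with
#' midpoint `K` and width `w`, combined with the Gompertz risk as
#' independent hazards. The Makeham term defaults to 0 in the simulator:
#' density mortality plays the age-independent role.
#'
#' @param mode `"linear"` (single queen reproduces) or `"exponential"`
#'   (every mature female reproduces).
#' @param maturity_age Age in ticks at which individuals can reproduce.
#' @param p_repro Per-tick probability that a (the) mature female
#'   reproduces.
#' @param litter_size Offspring per reproduction event. Non-integer values
#'   are realized stochastically (floor plus a Bernoulli on the fraction).
#' @param K Density-mortality midpoint (population size at which the
#'   density death probability reaches 1/2).
#' @param w Density-mortality logistic width.
#' @param dominance `"flag"` uses each allele's `dominant` flag (the flagged
#'   allele masks the other in heterozygotes); `"codominant"` averages V and
#'   L.
#' @param init_size Number of founding individuals.
#' @param max_ticks Tick cap; runs still polymorphic at the cap are
#'   reported as undecided.
#' @param mapping A [mapping_config()] for the (V, L) to (alpha, beta) map.
#' @param gamma Makeham (age-independent) hazard passed to the mapping.
#' @param snapshot_every Interval (ticks) at which age snapshots are pooled.
#' @return An object of class `abm_config`.
#' @export
abm_config <- function(mode = c("linear", "exponential"),
                       maturity_age = 5L,
                       p_repro = 1,
                       litter_size = 1,
                       K = 400,
                       w = 40,
                       dominance = c("flag", "codominant"),
                       init_size = 100L,
                       max_ticks = 20000L,
                       mapping = mapping_config(alpha_ref = 0.005),
                       gamma = 0,
                       snapshot_every = 50L) {
  mode <- match.arg(mode)
  dominance <- match.arg(dominance)
  stopifnot(maturity_age >= 0, p_repro >= 0, p_repro <= 1, litter_size >= 1,
            K > 0, w > 0, init_size >= 2, max_ticks >= 1)
  structure(list(mode = mode, maturity_age = as.integer(maturity_age),
                 p_repro = p_repro, litter_size = litter_size,
                 K = K, w = w, dominance = dominance,
                 init_size = as.integer(init_size),
                 max_ticks = as.integer(max_ticks),
                 mapping = mapping, gamma = gamma,
                 snapshot_every = as.integer(snapshot_every)),
            class = "abm_config")
}

#' Phenotype of a diploid genotype
#'
#' Homozygotes express their allele's (V, L). Heterozygotes express the
#' dominant allele's values under the `"flag"` rule (exactly one of the two
#' alleles should be flagged dominant), or the arithmetic mean of V and of
#' L under `"codominant"`.
#'
#' @param genotype Integer pair (codes 1 and/or 2).
#' @param alleleA,alleleB The two [allele()] objects (codes 1 and 2).
#' @param dominance `"flag"` or `"codominant"`.
#' @return Named numeric vector `c(V, L)`.
#' @export
phenotype <- function(genotype, alleleA, alleleB, dominance = "flag") {
  stopifnot(length(genotype) == 2L, all(genotype %in% c(1L, 2L)))
  if (all(genotype == 1L)) return(c(V = alleleA$V, L = alleleA$L))
  if (all(genotype == 2L)) return(c(V = alleleB$V, L = alleleB$L))
  if (dominance == "codominant")
    return(c(V = (alleleA$V + alleleB$V) / 2, L = (alleleA$L + alleleB$L) / 2))
  dom <- if (isTRUE(alleleA$dominant)) alleleA
  else if (isTRUE(alleleB$dominant)) alleleB
  else stop("heterozygote under the 'flag' rule needs one dominant allele")
  c(V = dom$V, L = dom$L)
}

#' Mendelian offspring genotype
#'
#' One gene copy drawn uniformly from each parent; sex assigned
#' male/female with probability 1/2.
#'
#' @param mother,father `population`-row genotypes as integer pairs.
#' @return A list with `g1` (maternal copy), `g2` (paternal copy), and
#'   `female`.
#' @export
mendelian_offspring <- function(mother, father) {
  list(g1 = mother[[sample.int(2L, 1L)]],
       g2 = father[[sample.int(2L, 1L)]],
       female = stats::runif(1) < 0.5)
}

# Precompute per-genotype-class death probabilities by age.
# Classes: 1 = AA, 2 = AB/BA, 3 = BB. Rows = class, cols = age 0..(amax-1).
death_table <- function(alleleA, alleleB, cfg, amax = 400L) {
  phen <- list(phenotype(c(1L, 1L), alleleA, alleleB, cfg$dominance),
               phenotype(c(1L, 2L), alleleA, alleleB, cfg$dominance),
               phenotype(c(2L, 2L), alleleA, alleleB, cfg$dominance))
  ages <- 0:(amax - 1L)
  t(vapply(phen, function(ph) {
    p <- allele_to_gompertz(allele("tmp", ph[["V"]], ph[["L"]]),
                            cfg$mapping, gamma = cfg$gamma)
    death_probability(p, ages, dt = 1)
  }, numeric(amax)))
}

#' Per-individual death probability
#'
#' Combines the Gompertz age-dependent risk (from the individual's
#' phenotype) with the logistic density risk as independent hazards:
#' `p_total = 1 - (1 - D_age) * (1 - d(N))`.
#'
#' @param ind A list with `age` and `genotype` (integer pair).
#' @param N Current population size.
#' @param cfg An [abm_config()].
#' @param alleleA,alleleB The competing [allele()]s.
#' @return Death probability in `[0, 1]`.
#' @export
mortality_probability <- function(ind, N, cfg, alleleA, alleleB) {
  ph <- phenotype(ind$genotype, alleleA, alleleB, cfg$dominance)
  p <- allele_to_gompertz(allele("tmp", ph[["V"]], ph[["L"]]),
                          cfg$mapping, gamma = cfg$gamma)
  D_age <- death_probability(p, ind$age, dt = 1)
  d_dens <- stats::plogis((N - cfg$K) / cfg$w)
  1 - (1 - D_age) * (1 - d_dens)
}

# realized litter size for possibly non-integer configuration value
draw_litter <- function(litter_size, n = 1L) {
  base <- floor(litter_size)
  frac <- litter_size - base
  as.integer(base + (stats::runif(n) < frac))
}

# Internal context bundling precomputed tables so tick() stays fast.
abm_context <- function(cfg, alleleA, alleleB) {
  list(D = death_table(alleleA, alleleB, cfg),
       alleleA = alleleA, alleleB = alleleB)
}

#' Advance the agent-based population one tick
#'
#' Update order within a tick: (1) mortality draws for every individual
#' (Gompertz by phenotype and age, combined with logistic density
#' mortality); (2) queen replacement in linear mode (uniform among living
#' mature females; if none is mature the position stays vacant until a
#' female matures); (3) births (linear: the queen, with probability
#' `p_repro`, mates a uniformly random living mature male; exponential:
#' every mature female independently with probability `p_repro`, each with
#' a uniformly random mature male); (4) ages of pre-existing individuals
#' increment. Newborns enter at age 0 and neither die nor reproduce in
#' their birth tick.
#'
#' @param pop A `population`.
#' @param cfg An [abm_config()].
#' @param ctx Context from `eusim:::abm_context()`; built automatically if
#'   `NULL`.
#' @param alleleA,alleleB The competing [allele()]s (used only when `ctx`
#'   is `NULL`).
#' @return The updated `population`.
#' @export
abm_tick <- function(pop, cfg, ctx = NULL, alleleA = NULL, alleleB = NULL) {
  if (is.null(ctx)) ctx <- abm_context(cfg, alleleA, alleleB)
  N <- length(pop$age)
  if (N == 0L) return(pop)
  # 1. deaths
  gcls <- pop$g1 + pop$g2 - 1L            # 1=AA, 2=het, 3=BB
  amax <- ncol(ctx$D)
  D_age <- ctx$D[cbind(gcls, pmin(pop$age, amax - 1L) + 1L)]
  d_dens <- stats::plogis((N - cfg$K) / cfg$w)
  p_die <- 1 - (1 - D_age) * (1 - d_dens)
  alive <- stats::runif(N) >= p_die
  pop <- subset_population(pop, alive)
  n <- length(pop$age)
  if (n == 0L) return(pop)
  # 2. queen replacement (linear mode): uniform among all living females;
  # a queen younger than maturity_age holds the position but does not
  # reproduce until she matures
  if (cfg$mode == "linear" && !any(pop$queen)) {
    cand <- which(pop$female)
    if (length(cand) > 0L)
      pop$queen[cand[sample.int(length(cand), 1L)]] <- TRUE
  }
  # 3. births
  mature <- pop$age >= cfg$maturity_age
  males <- which(!pop$female & mature)
  mothers <- integer(0)
  if (length(males) > 0L) {
    if (cfg$mode == "linear") {
      q <- which(pop$queen)
      if (length(q) == 1L && pop$age[q] >= cfg$maturity_age &&
          stats::runif(1) < cfg$p_repro)
        mothers <- q
    } else {
      fem <- which(pop$female & mature)
      if (length(fem) > 0L)
        mothers <- fem[stats::runif(length(fem)) < cfg$p_repro]
    }
  }
  n_new <- 0L
  if (length(mothers) > 0L) {
    litters <- draw_litter(cfg$litter_size, length(mothers))
    mom_of <- rep(mothers, litters)
    n_new <- length(mom_of)
    if (n_new > 0L) {
      dad_of <- males[sample.int(length(males), n_new, replace = TRUE)]
      from_mom <- stats::runif(n_new) < 0.5
      from_dad <- stats::runif(n_new) < 0.5
      g1 <- ifelse(from_mom, pop$g1[mom_of], pop$g2[mom_of])
      g2 <- ifelse(from_dad, pop$g1[dad_of], pop$g2[dad_of])
      newborn_female <- stats::runif(n_new) < 0.5
    }
  }
  # 4. aging (pre-existing individuals only)
  pop$age <- pop$age + 1L
  if (n_new > 0L) {
    pop <- fast_population(c(pop$age, integer(n_new)),
                           c(pop$female, newborn_female),
                           c(pop$g1, as.integer(g1)),
                           c(pop$g2, as.integer(g2)),
                           c(pop$queen, logical(n_new)))
  }
  pop
}

# Founding population: mature homozygous adults at the target allele
# frequency. Genotypes are split as evenly as possible within each sex so
# that neither allele starts with a sex (and hence queenship) advantage.
init_population <- function(cfg, init_freq = 0.5) {
  n <- cfg$init_size
  n_f <- ceiling(n / 2); n_m <- n - n_f
  nA <- round(init_freq * n)
  nA_f <- min(n_f, max(nA - n_m, round(nA / 2)))
  nA_m <- nA - nA_f
  geno_f <- rep(c(1L, 2L), c(nA_f, n_f - nA_f))
  geno_m <- rep(c(2L, 1L), c(n_m - nA_m, nA_m))
  geno <- c(geno_f, geno_m)
  new_population(age = rep(cfg$maturity_age, n),
                 female = rep(c(TRUE, FALSE), c(n_f, n_m)),
                 g1 = geno, g2 = geno)
}

#' Run one two-allele competition to fixation
#'
#' Starts from `init_size` mature founders at allele frequency `init_freq`
#' (homozygotes, sexes alternating) and ticks until one allele reaches
#' frequency 1, the population dies out, or `max_ticks` elapses.
#'
#' @param cfg An [abm_config()].
#' @param alleleA,alleleB The competing [allele()]s (A is coded 1).
#' @param init_freq Initial frequency of allele A.
#' @param seed Optional RNG seed for a reproducible run.
#' @return A `sim_result` list: `outcome` (`"fixed_A"`, `"fixed_B"`, or
#'   `"none"`), `extinct`, `ticks_elapsed`, `freq_series`, `N_series`,
#'   `age_snapshots` (pooled ages sampled every `snapshot_every` ticks),
#'   and `final_ages`.
#' @export
run_competition <- function(cfg, alleleA, alleleB, init_freq = 0.5,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- abm_context(cfg, alleleA, alleleB)
  pop <- init_population(cfg, init_freq)
  freq <- numeric(0); Ns <- numeric(0); snaps <- integer(0)
  outcome <- "none"; extinct <- FALSE
  t <- 0L
  repeat {
    f <- allele_freq(pop)
    N <- pop_size(pop)
    freq[t + 1L] <- f; Ns[t + 1L] <- N
    if (N == 0L) { extinct <- TRUE; break }
    if (f == 1) { outcome <- "fixed_A"; break }
    if (f == 0) { outcome <- "fixed_B"; break }
    if (t >= cfg$max_ticks) break
    if (t > 0L && t %% cfg$snapshot_every == 0L)
      snaps <- c(snaps, pop$age)
    pop <- abm_tick(pop, cfg, ctx)
    t <- t + 1L
  }
  structure(list(outcome = outcome, extinct = extinct, ticks_elapsed = t,
                 freq_series = freq, N_series = Ns,
                 age_snapshots = snaps, final_ages = pop$age),
            class = "sim_result")
}

#' Replicated fixation experiment
#'
#' Runs [run_competition()] over `n_reps` seeded replicates and tallies
#' fixation outcomes. Proportions come with 95% Wald confidence intervals
#' and are reported both over all replicates and over decided replicates
#' (excluding runs still polymorphic at the tick cap).
#'
#' @inheritParams run_competition
#' @param n_reps Number of replicates.
#' @param seed Master seed, expanded via [derive_seeds()].
#' @param keep_snapshots Pool age and size snapshots across replicates
#'   (costs memory; on by default).
#' @return An `experiment_summary` list: `counts`, the `summary`
#'   data.frame (allele, n fixed, proportions and CIs over all and over
#'   decided runs), `pooled_ages`, `pooled_sizes`, `mean_ticks`,
#'   `config_hash`, `seed`.
#' @export
fixation_experiment <- function(cfg, alleleA, alleleB, n_reps = 100,
                                init_freq = 0.5, seed = 1,
                                keep_snapshots = TRUE) {
  seeds <- derive_seeds(seed, n_reps)
  outcomes <- character(n_reps)
  ticks <- numeric(n_reps)
  ages <- vector("list", n_reps); sizes <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    r <- run_competition(cfg, alleleA, alleleB, init_freq, seed = seeds[i])
    outcomes[i] <- r$outcome
    ticks[i] <- r$ticks_elapsed
    if (keep_snapshots) {
      ages[[i]] <- r$age_snapshots
      sizes[[i]] <- r$N_series[r$N_series > 0]
    }
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
    pooled_ages = unlist(ages), pooled_sizes = unlist(sizes),
    mean_ticks = mean(ticks), n_reps = n_reps,
    config_hash = config_hash(cfg), seed = seed, seeds = seeds
  ), class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("Fixation experiment: %d replicates (%d undecided), config %s\n",
              x$n_reps, x$counts[["undecided"]], substr(x$config_hash, 1, 8)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
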