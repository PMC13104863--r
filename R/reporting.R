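# Experiment statistics, per-replicate seed derivation, fixtures, config I/O.

#' Wald confidence interval for a binomial proportion
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`, clipped to `[0, 1]`.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, >= 1.
#' @param level Confidence level.
#' @return Named numeric vector `c(estimate, low, high)`.
#' @examples
#' wald_ci(534, 1000)
#' @export
wald_ci <- function(k, n, level = 0.95) {
  stopifnot(is.numeric(k), is.numeric(n), length(k) == 1L, length(n) == 1L)
  if (n < 1) stop("`n` must be at least 1")
  if (k < 0 || k > n) stop("`k` must lie in [0, n]")
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(estimate = p, low = max(0, p - half), high = min(1, p + half))
}

#' Derive per-replicate RNG seeds from one master seed
#'
#' Expands a single integer seed into `n` replicate seeds through a seeded
#' draw, so experiments are reproducible replicate-by-replicate and
#' replicates can be re-run in isolation.
#'
#' @param seed Master seed (integer).
#' @param n Number of replicate seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed), n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Hash of an effective configuration
#'
#' Stable hash of a configuration object, attached to experiment outputs
#' for provenance.
#'
#' @param cfg Any R object (typically an `abm_config` or `metapop_config`).
#' @return A character hash.
#' @export
config_hash <- function(cfg) rlang::hash(cfg)

#' Read / write a configuration as YAML
#'
#' Round-trips the flat list representation of a configuration; reading a
#' written file reproduces the effective parameters (and hence the
#' [config_hash()]).
#'
#' @param cfg A configuration list.
#' @param path File path.
#' @return `read_config()` returns the configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass_deep(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Summarize a simulation time series
#'
#' @param result A `sim_result` from [run_competition()] or [metapop_run()].
#' @return A one-row data.frame: outcome, ticks elapsed, mean and final
#'   population size, median and mean age at the last snapshot.
#' @export
summarize_run <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  ages <- result$final_ages
  data.frame(outcome = result$outcome,
             ticks = result$ticks_elapsed,
             mean_N = mean(result$N_series),
             final_N = result$N_series[length(result$N_series)],
             median_age = if (length(ages)) stats::median(ages) else NA_real_,
             mean_age = if (length(ages)) mean(ages) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Build a deterministic fixture population
#'
#' Constructs a population from a specification data.frame with columns
#' `n` (count), `sex` (`"F"`/`"M"`), `age`, and `genotype` (two characters
#' from `{"A", "B"}`, e.g. `"AA"`, `"AB"`). Intended for unit tests where
#' exact allele bookkeeping must be known in advance.
#'
#' @param spec A data.frame as described; zero rows give an empty
#'   population.
#' @return A `population` object (see [new_population()]).
#' @export
make_fixture_population <- function(spec) {
  if (nrow(spec) == 0L)
    return(new_population(age = integer(), female = logical(),
                          g1 = integer(), g2 = integer()))
  stopifnot(all(c("n", "sex", "age", "genotype") %in% names(spec)))
  if (!all(spec$genotype %in% c("AA", "AB", "BA", "BB")))
    stop("genotype labels must be two characters from {A, B}")
  idx <- rep(seq_len(nrow(spec)), spec$n)
  geno <- spec$genotype[idx]
  new_population(
    age = as.integer(spec$age[idx]),
    female = spec$sex[idx] == "F",
    g1 = ifelse(substr(geno, 1, 1) == "A", 1L, 2L),
    g2 = ifelse(substr(geno, 2, 2) == "A", 1L, 2L)
  )
}

#' Variance effective population size from an allele-frequency series
#'
#' Temporal (variance) estimator: under pure drift the per-step frequency
#' increments satisfy \eqn{E[(\Delta p)^2] = p(1-p)/(2 N_e)}, so
#' \deqn{\hat N_e = \frac{\sum_t p_t (1 - p_t)}{2 \sum_t (\Delta p_t)^2}}
#' over the polymorphic part of the series. The estimate is per time step
#' of the series; convert by the generation time to compare with
#' per-generation effective sizes. Queen-bottlenecked (linear-mode)
#' populations give values far below their census size.
#'
#' @param freq Numeric vector of allele frequencies over time.
#' @return The effective-size estimate (`NA` if the series has fewer than
#'   two polymorphic steps).
#' @export
effective_size <- function(freq) {
  stopifnot(is.numeric(freq))
  keep <- !is.na(freq) & freq > 0 & freq < 1
  # use the polymorphic prefix: increments into fixation are not drift-like
  end <- which(!keep)[1]
  p <- if (is.na(end)) freq[keep] else freq[seq_len(end - 1L)]
  if (length(p) < 2L) return(NA_real_)
  dp <- diff(p)
  het <- p[-length(p)] * (1 - p[-length(p)])
  sum(het) / (2 * sum(dp^2))
}
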