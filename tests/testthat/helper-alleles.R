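# Shared fixtures: the standard allele pair and small, fast configurations.

vitality_allele <- function() allele("vitality", V = 1000, L = 9, dominant = TRUE)
longevity_allele <- function() allele("longevity", V = 900, L = 10)

# small population, quick fixation; for stochastic unit tests
small_cfg <- function(mode, ...) {
  args <- list(mode = mode, init_size = 32L, K = 100, w = 10)
  override <- list(...)
  args[names(override)] <- override
  do.call(abm_config, args)
}
small_linear_cfg <- function(...) small_cfg("linear", ...)
small_exp_cfg <- function(...) small_cfg("exponential", ...)

# closed-form survivorship to age n (exact telescoped product of Eq.-8
# step survivals): independent oracle for series-based code
survivorship_closed <- function(params, n, dt = 1) {
  with(params, {
    cum <- if (beta == 0) (alpha + gamma) * n * dt
    else (alpha / beta) * (exp(beta * n * dt) - 1) + gamma * n * dt
    exp(-cum)
  })
}
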