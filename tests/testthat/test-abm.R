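# Agent-based simulator: genetics, mortality, tick mechanics, competitions.

test_that("phenotype follows dominance rules", {
  aV <- vitality_allele(); aL <- longevity_allele()
  expect_equal(phenotype(c(1L, 1L), aV, aL), c(V = 1000, L = 9))
  expect_equal(phenotype(c(2L, 2L), aV, aL), c(V = 900, L = 10))
  expect_equal(phenotype(c(1L, 2L), aV, aL, "flag"), c(V = 1000, L = 9))
  expect_equal(phenotype(c(2L, 1L), aV, aL, "codominant"), c(V = 950, L = 9.5))
  # reversed dominance flag
  aL2 <- allele("longevity", 900, 10, dominant = TRUE)
  aV2 <- allele("vitality", 1000, 9)
  expect_equal(phenotype(c(1L, 2L), aV2, aL2, "flag"), c(V = 900, L = 10))
})

test_that("Mendelian transmission is uniform per parent and reproducible", {
  set.seed(1)
  off <- mendelian_offspring(c(1L, 1L), c(2L, 2L))
  expect_equal(off$g1, 1L)
  expect_equal(off$g2, 2L)
  # AB x AB gives 1:2:1 genotype ratios
  set.seed(99)
  draws <- replicate(10000, {
    o <- mendelian_offspring(c(1L, 2L), c(1L, 2L))
    o$g1 + o$g2
  })
  counts <- table(factor(draws, levels = 2:4))
  expect_gt(stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 1e-4)
  # determinism under seeding
  set.seed(7); a <- replicate(20, unlist(mendelian_offspring(c(1L, 2L), c(1L, 2L))))
  set.seed(7); b <- replicate(20, unlist(mendelian_offspring(c(1L, 2L), c(1L, 2L))))
  expect_identical(a, b)
})

test_that("total mortality combines Gompertz and density risks independently", {
  cfg <- small_linear_cfg(w = 5)  # narrow logistic: negligible at low N
  aV <- vitality_allele(); aL <- longevity_allele()
  ind <- list(age = 8, genotype = c(1L, 1L))
  pg <- allele_to_gompertz(vitality_allele(), cfg$mapping, cfg$gamma)
  Dn <- death_probability(pg, 8, 1)
  # far below the density midpoint the Gompertz term dominates
  expect_equal(mortality_probability(ind, N = 2, cfg, aV, aL), Dn,
               tolerance = 1e-3)
  # at N = K the density term is exactly 1/2
  expect_equal(mortality_probability(ind, N = cfg$K, cfg, aV, aL),
               1 - (1 - Dn) * 0.5, tolerance = 1e-12)
  # independent-risk combination dominates each component
  for (N in c(10, 50, 100, 200)) {
    p <- mortality_probability(ind, N, cfg, aV, aL)
    expect_gte(p, Dn)
    expect_gte(p, stats::plogis((N - cfg$K) / cfg$w))
  }
})

test_that("fixture populations have exact composition", {
  empty <- make_fixture_population(data.frame(n = integer(), sex = character(),
                                              age = integer(),
                                              genotype = character()))
  expect_equal(pop_size(empty), 0)
  pop <- make_fixture_population(data.frame(
    n = c(10, 4, 6), sex = c("F", "M", "F"), age = c(5, 3, 1),
    genotype = c("AA", "AB", "BB")))
  expect_equal(pop_size(pop), 20)
  expect_equal(sum(pop$g1 == 1L) + sum(pop$g2 == 1L), 24)  # 20 + 4
  expect_equal(allele_freq(pop), 24 / 40)
  expect_equal(sum(pop$female), 16)
  expect_error(make_fixture_population(data.frame(n = 1, sex = "F", age = 1,
                                                  genotype = "AC")),
               "genotype")
})

test_that("a tick respects birth rules and bookkeeping", {
  aV <- vitality_allele(); aL <- longevity_allele()
  cfg <- small_linear_cfg(p_repro = 1, litter_size = 3)
  ctx <- eusim:::abm_context(cfg, aV, aL)
  # no mature males: no births
  fem <- make_fixture_population(data.frame(n = 5, sex = "F", age = 10,
                                            genotype = "AA"))
  fem$queen[1] <- TRUE
  set.seed(2)
  after <- abm_tick(fem, cfg, ctx)
  expect_equal(sum(after$age == 0L), 0)
  # linear mode births are capped by the litter size
  mixed <- make_fixture_population(data.frame(n = c(6, 6), sex = c("F", "M"),
                                              age = 10, genotype = c("AA", "BB")))
  set.seed(3)
  for (i in 1:10) {
    before_n <- sum(mixed$age == 0L)
    mixed <- abm_tick(mixed, cfg, ctx)
    expect_lte(sum(mixed$age == 0L), cfg$litter_size)
  }
  # allele-copy bookkeeping: 2N copies at every tick
  expect_equal(sum(mixed$g1 %in% 1:2) + sum(mixed$g2 %in% 1:2),
               2 * pop_size(mixed))
  # exactly one queen whenever females exist
  expect_equal(sum(mixed$queen), if (any(mixed$female)) 1L else 0L)
})

test_that("seeded runs are bit-reproducible", {
  cfg <- small_linear_cfg(max_ticks = 400)
  a <- run_competition(cfg, vitality_allele(), longevity_allele(), seed = 5)
  b <- run_competition(cfg, vitality_allele(), longevity_allele(), seed = 5)
  expect_identical(a$freq_series, b$freq_series)
  expect_identical(a$N_series, b$N_series)
  expect_identical(a$outcome, b$outcome)
})

test_that("competitions run to fixation with sensible outcomes", {
  cfg <- small_linear_cfg()
  # allele B absent at start: immediate fixation of A
  r <- run_competition(cfg, vitality_allele(), longevity_allele(),
                       init_freq = 1, seed = 1)
  expect_equal(r$outcome, "fixed_A")
  expect_equal(r$ticks_elapsed, 0L)
  # a lethal parameter set drives extinction, flagged as such
  doomed <- small_linear_cfg(mapping = mapping_config(alpha_ref = 5))
  r2 <- run_competition(doomed, vitality_allele(), longevity_allele(), seed = 1)
  expect_true(r2$extinct)
  expect_equal(r2$outcome, "none")
})

test_that("replicated experiments tally outcomes with Wald intervals", {
  cfg <- small_linear_cfg(max_ticks = 2000)
  e <- fixation_experiment(cfg, vitality_allele(), longevity_allele(),
                           n_reps = 12, seed = 4, keep_snapshots = FALSE)
  expect_equal(sum(e$counts), 12)
  expect_equal(e$summary$n_fixed[1], e$counts[["fixed_A"]])
  expect_true(all(e$summary$ci_low >= 0 & e$summary$ci_high <= 1))
  # single-replicate degenerate case
  e1 <- fixation_experiment(cfg, vitality_allele(), longevity_allele(),
                            n_reps = 1, init_freq = 1, seed = 1,
                            keep_snapshots = FALSE)
  expect_equal(e1$summary$prop_all[1], 1)
  expect_equal(e1$summary$ci_high[1], 1)
})

test_that("population equilibrates where births balance deaths", {
  # exponential mode equilibrates near the density midpoint K; linear mode
  # (one queen's worth of births) well below it
  aV <- vitality_allele()
  ecfg <- small_exp_cfg(max_ticks = 300, p_repro = 0.5, litter_size = 2)
  r <- run_competition(ecfg, aV, aV, init_freq = 1, seed = 8)
  # identical alleles: runs to max_ticks at fixation freq 1 from start
  expect_equal(r$outcome, "fixed_A")
  lcfg <- small_linear_cfg(max_ticks = 300)
  ctxL <- eusim:::abm_context(lcfg, aV, aV)
  ctxE <- eusim:::abm_context(ecfg, aV, aV)
  popL <- eusim:::init_population(lcfg, 1)
  popE <- eusim:::init_population(ecfg, 1)
  set.seed(9)
  NL <- NE <- numeric(200)
  for (i in 1:200) {
    popL <- abm_tick(popL, lcfg, ctxL); NL[i] <- pop_size(popL)
    popE <- abm_tick(popE, ecfg, ctxE); NE[i] <- pop_size(popE)
  }
  expect_gt(mean(NE[101:200]), 0.7 * ecfg$K)
  expect_lt(mean(NL[101:200]), 0.5 * lcfg$K)
})
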