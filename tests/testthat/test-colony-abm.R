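# Metapopulation simulator: founding mechanics, disasters, degenerate cases.

molerat_test_mcfg <- function(...) {
  args <- list(mode = "molerat",
               colony_cfg = abm_config("linear", K = 60, w = 6,
                                       init_size = 12L, litter_size = 2),
               threshold_colony_size = 15L, C_cap = 6, w_c = 1.5,
               n_colonies_init = 4L, pioneers_per_event = 6L,
               p_disaster = 0.01, flight_interval = 4L)
  override <- list(...)
  args[names(override)] <- override
  do.call(metapop_config, args)
}

test_that("founding probability saturates to zero in crowded landscapes", {
  mcfg <- molerat_test_mcfg()
  expect_lt(eusim:::founding_prob(1000, mcfg), 1e-10)
  expect_gt(eusim:::founding_prob(0, mcfg), 0.95)
})

test_that("mole-rat pioneer groups conserve individuals and need a female", {
  mcfg <- molerat_test_mcfg()
  pop <- make_fixture_population(data.frame(
    n = c(10, 10), sex = c("F", "M"), age = 10, genotype = c("AA", "BB")))
  pop$queen[1] <- TRUE
  src <- eusim:::new_colony(pop)
  set.seed(1)
  res <- eusim:::molerat_seed(src, n_colonies = 1, mcfg)
  expect_equal(pop_size(res$source$pop) +
                 (if (is.null(res$new)) mcfg$pioneers_per_event
                  else pop_size(res$new$pop)),
               20)
  if (!is.null(res$new)) {
    expect_equal(sum(res$new$pop$queen), 1L)
    expect_true(res$new$pop$female[which(res$new$pop$queen)])
  }
  # all-male pioneer draws can never found a colony
  allm <- make_fixture_population(data.frame(
    n = c(1, 19), sex = c("F", "M"), age = 10, genotype = "AA"))
  allm$queen[1] <- TRUE
  src2 <- eusim:::new_colony(allm)
  set.seed(2)
  found <- 0L
  for (i in 1:50) {
    r <- eusim:::molerat_seed(src2, 0, mcfg)
    if (!is.null(r$new)) {
      found <- found + 1L
      expect_true(any(r$new$pop$female))
    }
  }
  # pioneer count capped so the source keeps at least one member
  tiny <- make_fixture_population(data.frame(
    n = c(2, 2), sex = c("F", "M"), age = 10, genotype = "AA"))
  tinycfg <- molerat_test_mcfg(threshold_colony_size = 2L)
  set.seed(3)
  r <- eusim:::molerat_seed(eusim:::new_colony(tiny), 0, tinycfg)
  expect_gte(pop_size(r$source$pop), 1)
})

test_that("ant founding needs a threshold-size source and a sperm pool", {
  ccfg <- abm_config("linear", K = 60, w = 6, init_size = 12L, litter_size = 4)
  mcfg <- metapop_config("ant", colony_cfg = ccfg,
                         threshold_colony_size = 15L, C_cap = 6)
  pop <- make_fixture_population(data.frame(
    n = c(10, 10), sex = c("F", "M"), age = 10, genotype = c("AA", "BB")))
  pop$queen[1] <- TRUE
  src <- eusim:::new_colony(pop, stored_sperm = c(2L, 2L))
  pool <- cbind(g1 = 1L, g2 = 2L)
  set.seed(4)
  nc <- eusim:::ant_found_colony(src, pool, n_colonies = 1, mcfg)
  expect_false(is.null(nc))
  expect_equal(pop_size(nc$pop), 1)
  expect_true(nc$pop$queen[1] && nc$pop$female[1])
  expect_true(all(nc$stored_sperm %in% 1:2))
  # below threshold or empty pool: no founding
  small_src <- eusim:::new_colony(make_fixture_population(
    data.frame(n = 5, sex = "F", age = 10, genotype = "AA")))
  expect_null(eusim:::ant_found_colony(small_src, pool, 1, mcfg))
  expect_null(eusim:::ant_found_colony(src, pool[0, , drop = FALSE], 1, mcfg))
})

test_that("disasters follow their configured probabilities", {
  # p_disaster = 0: colonies never hit; population persists normally
  mcfg0 <- molerat_test_mcfg(p_disaster = 0, max_ticks = 60L)
  r0 <- metapop_run(mcfg0, vitality_allele(), longevity_allele(), seed = 11)
  expect_false(r0$extinct)
  # p_disaster = 1 with certain kill: every colony collapses immediately
  mcfg1 <- molerat_test_mcfg(p_disaster = 1, p_disaster_kill = 1,
                             max_ticks = 10L)
  r1 <- metapop_run(mcfg1, vitality_allele(), longevity_allele(), seed = 12)
  expect_true(r1$extinct)
  expect_lte(r1$ticks_elapsed, 2L)
})

test_that("a single colony with dispersal disabled reduces to the linear
           individual model", {
  mcfg <- metapop_config("molerat",
                         colony_cfg = abm_config("linear", K = 60, w = 6,
                                                 init_size = 12L,
                                                 litter_size = 2),
                         threshold_colony_size = 10000L,  # never disperses
                         p_disaster = 0, n_colonies_init = 1L,
                         max_ticks = 3000L)
  r <- metapop_run(mcfg, vitality_allele(), longevity_allele(), seed = 13)
  expect_true(r$outcome %in% c("fixed_A", "fixed_B"))
  expect_true(all(r$colony_series == 1L))
})

test_that("seeded metapopulation runs are reproducible and keep books", {
  mcfg <- molerat_test_mcfg(max_ticks = 150L)
  a <- metapop_run(mcfg, vitality_allele(), longevity_allele(), seed = 14)
  b <- metapop_run(mcfg, vitality_allele(), longevity_allele(), seed = 14)
  expect_identical(a$freq_series, b$freq_series)
  expect_identical(a$colony_series, b$colony_series)
  # frequencies are proper frequencies and colony counts nonnegative
  expect_true(all(a$freq_series >= 0 & a$freq_series <= 1, na.rm = TRUE))
  expect_true(all(a$colony_series >= 0))
})

test_that("colonies drift to internal fixation before the metapopulation
           decides", {
  mcfg <- molerat_test_mcfg(max_ticks = 4000L)
  e <- metapop_experiment(mcfg, vitality_allele(), longevity_allele(),
                          n_reps = 6, seed = 15)
  expect_gt(e$mean_single_allele_fraction, 0.5)
})

test_that("the founding logistic caps colony numbers near its scale", {
  mcfg <- molerat_test_mcfg(max_ticks = 600L)
  r <- metapop_run(mcfg, vitality_allele(), longevity_allele(), seed = 23)
  counts <- r$colony_series[-(1:100)]
  # founding balances collapse where the logistic has decayed: the count
  # equilibrates within a few logistic widths of C_cap
  expect_gt(mean(counts), 0)
  expect_lt(mean(counts), mcfg$C_cap + 5 * mcfg$w_c)
  expect_lt(stats::sd(counts), mean(counts))  # fluctuation, not runaway
})
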