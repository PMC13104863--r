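# Age-structured two-allele competition: birth laws, update step, fitness
# difference, steady states, carrying-capacity matching, nullclines.

test_that("linear births split fecundity by allele frequency", {
  expect_equal(births_linear(30, 10, 4), c(A0 = 3, B0 = 1))
  expect_equal(births_linear(7, 7, 4), c(A0 = 2, B0 = 2))
  expect_equal(births_linear(5, 0, 4), c(A0 = 4, B0 = 0))
  expect_equal(sum(births_linear(13, 29, 6)), 6)  # A0 + B0 = g always
  expect_equal(births_linear(0, 0, 4), c(A0 = 0, B0 = 0))  # extinction
})

test_that("saturation function pins S(2) = 2 and saturates at Ns", {
  for (Ns in c(10, 100, 1e4)) expect_equal(saturation(2, Ns), 2)
  expect_equal(saturation(1e12, 100), 100, tolerance = 1e-9)
  expect_equal(saturation(52, 100), 5200 / 150, tolerance = 1e-12)
  expect_error(saturation(-200, 100), "positive")
})

test_that("exponential births share a common saturating factor", {
  # g Ns A / (2 (Ns + A + B - 2)) with A=30, B=10, Ns=100: denominator 276
  expect_equal(births_exponential(30, 10, g = 4, Ns = 100),
               c(A0 = 12000 / 276, B0 = 4000 / 276))
  b <- births_exponential(12, 12, g = 3, Ns = 50)
  expect_equal(b[["A0"]], b[["B0"]])
  # single allele reduces to g S(N) / 2
  N <- 40
  expect_equal(births_exponential(N, 0, g = 4, Ns = 100)[["A0"]],
               4 * saturation(N, 100) / 2, tolerance = 1e-12)
  # Ns -> infinity approaches the unsaturated g N / 2 x frequency form
  expect_equal(births_exponential(30, 10, g = 4, Ns = 1e9)[["A0"]],
               4 * 40 / 2 * (30 / 40), tolerance = 1e-6)
})

test_that("one age-structured step survives then births at age 0", {
  pA <- gompertz_params(0.1, 0.2)
  pB <- gompertz_params(0.15, 0.1)
  st <- age_structured_state(c(10, 5, 2), c(4, 3, 1))
  gl <- growth_law("linear", g = 4)
  nxt <- step_age_structured(st, gl, pA, pB)
  # hand application of the update equations
  DA <- death_probability(pA, 0:2, 1)
  DB <- death_probability(pB, 0:2, 1)
  births <- 4 * c(17, 8) / 25
  expect_equal(nxt$abundA, c(births[1], (1 - DA[1]) * 10, (1 - DA[2]) * 5))
  expect_equal(nxt$abundB, c(births[2], (1 - DB[1]) * 4, (1 - DB[2]) * 3))
  expect_equal(nxt$t, 1)
  # extinction is absorbing
  zero <- age_structured_state(c(0, 0), c(0, 0))
  after <- step_age_structured(zero, gl, pA, pB)
  expect_equal(state_total(after), 0)
})

test_that("fitness difference is zero for identical alleles and matches the
           geometric closed form at constant hazard", {
  p <- gompertz_params(0.07, 0.11, 0.01)
  expect_equal(delta_F(p, p), 0)
  # per-step death D = 0.5 vs d = 0.25: geometric series (1-D)/D - (1-d)/d
  pD <- gompertz_params(log(2), 0)        # 1 - exp(-log 2) = 0.5
  pd <- gompertz_params(log(4 / 3), 0)    # 1 - exp(-log 4/3) = 0.25
  expect_equal(delta_F(pD, pd), 1 - 3, tolerance = 1e-9)
})

test_that("fitness difference agrees with a brute-force closed-form summation", {
  m <- mapping_config()
  pA <- allele_to_gompertz(vitality_allele(), m)
  pB <- allele_to_gompertz(longevity_allele(), m)
  brute <- function(p) sum(survivorship_closed(p, 1:1e5))
  expect_equal(delta_F(pA, pB), brute(pA) - brute(pB), tolerance = 1e-9)
  expect_equal(sign(delta_F(pA, pB)), sign(brute(pA) - brute(pB)))
})

test_that("fitness difference is antisymmetric and monotone in the
           competitor's parameters", {
  set.seed(42)
  for (i in 1:25) {
    pA <- gompertz_params(runif(1, 0.01, 0.3), runif(1, 0.02, 0.3),
                          runif(1, 0, 0.05))
    pB <- gompertz_params(runif(1, 0.01, 0.3), runif(1, 0.02, 0.3),
                          runif(1, 0, 0.05))
    expect_equal(delta_F(pA, pB), -delta_F(pB, pA), tolerance = 1e-10)
  }
  pA <- gompertz_params(0.05, 0.1)
  dF_alpha <- vapply(seq(0.02, 0.3, by = 0.04), function(a)
    delta_F(pA, gompertz_params(a, 0.1)), numeric(1))
  expect_true(all(diff(dF_alpha) > 0))
  dF_beta <- vapply(seq(0.02, 0.4, by = 0.05), function(b)
    delta_F(pA, gompertz_params(0.05, b)), numeric(1))
  expect_true(all(diff(dF_beta) > 0))
})

test_that("steady state excludes one allele, consistent with the fitness sign", {
  pA <- gompertz_params(0.05, 0.12)
  pB <- gompertz_params(0.08, 0.09)
  gl <- growth_law("linear", g = 4)
  # start with only A: B can never appear
  n_cls <- length(survivorship(pA)) + 1L
  onlyA <- age_structured_state(c(4, rep(0, n_cls - 1)), rep(0, n_cls))
  ssA <- steady_state(gl, pA, pB, init = onlyA)
  expect_equal(sum(ssA$state$abundB), 0)
  expect_equal(ssA$winner, "A")
  # mixed start: winner matches sign of delta_F
  ss <- steady_state(gl, pA, pB)
  expect_equal(ss$winner, if (delta_F(pA, pB) > 0) "A" else "B")
})

test_that("linear single-allele steady-state size equals g (1 + sum of
           survivorships)", {
  p <- gompertz_params(0.04, 0.09, 0.01)
  gl <- growth_law("linear", g = 3)
  ss <- eusim:::single_allele_ss(gl, p)
  expect_equal(ss$total, 3 * (1 + fitness_sum(p)), tolerance = 1e-6)
})

test_that("exponential single-allele steady state matches its fixed-point
           closed form", {
  # N = (1 + F) g Ns / 2 - Ns + 2 from equating births to the stationary
  # age-0 inflow
  p <- gompertz_params(0.04, 0.09, 0.3)
  g <- 4; Ns <- 30
  ss <- eusim:::single_allele_ss(growth_law("exponential", g = g, Ns = Ns), p)
  expect_equal(ss$total, (1 + fitness_sum(p)) * g * Ns / 2 - Ns + 2,
               tolerance = 1e-5)
})

test_that("gamma matching equalizes carrying capacities and youthens the
           exponential population", {
  base <- allele_to_gompertz(vitality_allele(), mapping_config())
  mg <- match_gamma(base, g = 4, Ns = 30)
  expect_gte(mg$gamma_prime, base$gamma)
  expect_lt(abs(mg$N_exponential - mg$N_linear), 1e-4)
  expect_lt(mg$mean_age_exponential, mg$mean_age_linear)
  # unattainable target: exponential floor above the linear size
  expect_error(match_gamma(base, g = 4, Ns = 2000), "bracket|below")
})

test_that("nullcline passes through the origin and solves to tolerance", {
  base <- allele_to_gompertz(vitality_allele(), mapping_config())
  nc <- nullcline(base, c(-0.2, -0.1, 0, 0.1, 0.2))
  expect_equal(nc$y[nc$x == 0], 0)
  expect_true(all(abs(nc$deltaF_residual) < 1e-8, na.rm = TRUE))
  # monotone curve, x and y of opposite signs off the origin
  expect_true(all(diff(nc$y) < 0))
  expect_true(all(sign(nc$x[nc$x != 0]) != sign(nc$y[nc$x != 0])))
})
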