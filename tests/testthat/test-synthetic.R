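test_that("generation is reproducible given the seed", {
  sc <- gender_scenario(N_m = 5000, N_f = 5000, p_m = 0.02, p_f = 0.01,
                        n_ctrl_m = 100, n_ctrl_f = 100)
  p1 <- generate_population(sc, seed = 51)
  p2 <- generate_population(sc, seed = 51)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  s1 <- sample_case_control(p1, seed = 52)
  s2 <- sample_case_control(p2, seed = 52)
  expect_identical(as.data.frame(s1$data), as.data.frame(s2$data))
})

test_that("null-model case counts are binomial around N * R0", {
  sc <- lexpit_scenario(
    strata = tibble::tibble(stratum = "all", population_size = 1000000,
                            n_controls = 1000),
    gamma0 = qlogis(0.002), tau = 1)
  pop <- generate_population(sc, seed = 53)
  expect_lt(abs(sum(pop$case) - 2000), 4 * sqrt(2000 * 0.998))
})

test_that("a two-stratum gender truth realizes the published example risks", {
  sc <- gender_scenario(N_m = 775758, N_f = 851956,
                        p_m = 0.0019813, p_f = 0.0004766,
                        n_ctrl_m = 1617, n_ctrl_f = 499)
  pop <- generate_population(sc, seed = 54)
  realized <- tapply(pop$case, pop$stratum, mean)
  expect_lt(abs(realized[["male"]] - 0.00198),
            4 * sqrt(0.00198 / 775758))
  expect_lt(abs(realized[["female"]] - 0.00048),
            4 * sqrt(0.00048 / 851956))
  # sampling + fitting recovers the generating risk difference
  study <- sample_case_control(pop, seed = 55)
  fit <- quiet_fit(study$data, additive = "female", design = study$design)
  se <- sqrt(diag(vcov(fit)))[["female"]]
  expect_lt(abs(coef(fit)[["female"]] - (-0.0015047)), 4 * se)
})

test_that("control weights recomputed from the emitted design expand exactly", {
  sc <- gender_scenario(N_m = 20000, N_f = 25000, n_ctrl_m = 200,
                        n_ctrl_f = 250)
  pop <- generate_population(sc, seed = 56)
  # census frame: weighted controls reconstruct the full stratum population
  st_pop <- sample_case_control(pop, seed = 57, frame = "population")
  tot <- expansion_totals(add_sampling_weights(st_pop$data, st_pop$design))
  expect_equal(tot$weighted_controls,
               st_pop$design$population_size[match(tot$stratum,
                                                   st_pop$design$stratum)],
               tolerance = 1e-9)
  # non-case frame: weighted controls reconstruct population minus cases
  st_nc <- sample_case_control(pop, seed = 57, frame = "noncases")
  tot2 <- expansion_totals(add_sampling_weights(st_nc$data, st_nc$design))
  m <- match(tot2$stratum, st_nc$design$stratum)
  expect_equal(tot2$weighted_controls,
               st_nc$design$population_size[m], tolerance = 1e-9)
  expect_equal(st_nc$design$population_size + st_nc$design$n_cases,
               st_pop$design$population_size)
})

test_that("oversampling a stratum's non-cases is an error naming the stratum", {
  sc <- gender_scenario(N_m = 500, N_f = 500, p_m = 0.2, p_f = 0.2,
                        n_ctrl_m = 490, n_ctrl_f = 10)
  pop <- generate_population(sc, seed = 58)
  expect_error(sample_case_control(pop, seed = 59), "male")
})

test_that("a stratum with zero requested controls contributes cases only", {
  sc <- gender_scenario(N_m = 30000, N_f = 30000, n_ctrl_m = 0,
                        n_ctrl_f = 300)
  pop <- generate_population(sc, seed = 60)
  study <- sample_case_control(pop, seed = 61)
  expect_equal(sum(study$data$case == 0 & study$data$stratum == "male"), 0)
  fit <- quiet_fit(study$data, additive = "female", design = study$design)
  expect_true(fit$converged)
})

test_that("infeasible true risks are rejected before outcomes are drawn", {
  sc <- lexpit_scenario(
    strata = tibble::tibble(stratum = c("a", "b"), population_size = c(50, 50),
                            n_controls = c(5, 5), female = c(0L, 1L)),
    additive = "female", beta = -0.5, gamma0 = qlogis(0.01), tau = 1)
  expect_error(generate_population(sc, seed = 62), "outside \\[0, 1\\]")
})

test_that("estimation error shrinks as the population grows", {
  err <- function(Nscale, seeds) {
    sapply(seeds, function(s) {
      sc <- gender_scenario(N_m = 20000 * Nscale, N_f = 20000 * Nscale,
                            p_m = 0.01, p_f = 0.004,
                            n_ctrl_m = 200 * Nscale, n_ctrl_f = 200 * Nscale)
      study <- sample_case_control(generate_population(sc, seed = s),
                                   seed = s + 1000)
      fit <- quiet_fit(study$data, additive = "female", design = study$design,
                       variance = "none")
      abs(coef(fit)[["female"]] - (-0.006))
    })
  }
  e_small <- mean(err(1, 1:12))
  e_big <- mean(err(4, 1:12))
  expect_lt(e_big, e_small)
})

test_that("the EAGLE-flavored scenario has feasible risks and realistic case yield", {
  sc <- eagle_scenario(scale = 0.1)
  pop <- generate_population(sc, seed = 63)
  expect_true(all(pop$.risk >= 0 & pop$.risk <= 1))
  # a few hundred cases at one tenth of the study base
  expect_gt(sum(pop$case), 100)
  expect_lt(sum(pop$case), 1500)
  study <- sample_case_control(pop, seed = 64)
  expect_s3_class(study$design, "cc_design")
  expect_equal(design_tau(study$design), 3)
})
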