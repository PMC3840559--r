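# shared fixtures, all generated in code

# two-stratum gender-only scenario: risk differs by gender only, so each
# stratum's true risk is constant and closed forms are available
gender_scenario <- function(N_m = 80000, N_f = 90000,
                            p_m = 0.003, p_f = 0.0015,
                            n_ctrl_m = 800, n_ctrl_f = 500) {
  lexpit_scenario(
    strata = tibble::tibble(
      stratum = c("male", "female"),
      population_size = c(N_m, N_f),
      n_controls = c(n_ctrl_m, n_ctrl_f),
      female = c(0L, 1L)
    ),
    additive = "female",
    beta = p_f - p_m,
    gamma0 = qlogis(p_m),
    tau = 3
  )
}

# small random cohort with a binary additive and a continuous multiplicative
# covariate; unit weights
random_cohort <- function(n, beta = 0.05, gamma0 = -3, gamma1 = 0.8,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- rbinom(n, 1L, 0.5)
  z <- rnorm(n)
  risk <- beta * a + plogis(gamma0 + gamma1 * z)
  stopifnot(all(risk > 0 & risk < 1))
  tibble::tibble(a = a, z = z, case = rbinom(n, 1L, risk))
}

quiet_fit <- function(...) suppressWarnings(suppressMessages(lexpit(...)))

expect_psd <- function(V) {
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10 * sum(abs(diag(V)))))
}
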