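test_that("pseudo-log-likelihood matches hand-computed weighted Bernoulli sums", {
  # all fitted risks 1/2: -n log 2 regardless of outcomes
  y <- c(1, 0, 1, 1, 0)
  expect_equal(lexpit_loglik(numeric(0), 0, numeric(0), y = y),
               -5 * log(2))
  # 3-row toy, weights (1, 5, 5), arithmetic written out independently
  yy <- c(1, 0, 1); xx <- c(0, 1, 1); zz <- c(0.5, -1, 2); ww <- c(1, 5, 5)
  beta <- 0.02; g0 <- -2; g1 <- 0.5
  r <- beta * xx + 1 / (1 + exp(-(g0 + g1 * zz)))
  hand <- 1 * log(r[1]) + 5 * log(1 - r[2]) + 5 * log(r[3])
  expect_equal(lexpit_loglik(beta, g0, g1, y = yy, x = xx, z = zz, w = ww),
               hand)
  # unit weights equal the ordinary Bernoulli log-likelihood
  expect_equal(lexpit_loglik(beta, g0, g1, y = yy, x = xx, z = zz),
               sum(yy * log(r) + (1 - yy) * log(1 - r)))
})

test_that("risks outside (0,1) give -Inf, not an error", {
  expect_identical(lexpit_loglik(2, 0, numeric(0), y = c(1, 0), x = c(1, 1)),
                   -Inf)
  expect_identical(lexpit_loglik(-0.6, qlogis(0.5), numeric(0),
                                 y = 0, x = 1), -Inf)
})

test_that("feasible region deduplicates observed covariate patterns", {
  dat <- tibble::tibble(case = rep(c(1, 0), 10), x1 = 1, z1 = 2)
  expect_equal(nrow(feasible_region(dat, "x1", "z1")), 1L)
  dat2 <- tibble::tibble(case = rep(0, 9), x1 = rep(c(1, 2, 3), each = 3),
                         z1 = rep(c(0, 1, 0), 3))
  fr <- feasible_region(dat2, "x1", "z1")
  expect_equal(nrow(fr), nrow(unique(dat2[c("x1", "z1")])))
  expect_equal(sum(fr$n_obs), nrow(dat2))
  # gender-only study: two patterns
  expect_equal(nrow(feasible_region(eagle_gender_data(), "female")), 2L)
})

test_that("empty additive block reproduces an independent weighted logistic fit", {
  set.seed(21)
  n <- 600
  z1 <- rnorm(n); z2 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1.5 + 0.8 * z1 - 0.5 * z2))
  w <- sample(c(1, 4, 10), n, replace = TRUE)
  dat <- tibble::tibble(case = y, z1 = z1, z2 = z2, w = w)
  fit <- quiet_fit(dat, multiplicative = c("z1", "z2"), weights = "w")
  oracle <- glm(y ~ z1 + z2, family = quasibinomial(), weights = w)
  expect_equal(unname(coef(fit)[c("(Intercept)", "z1", "z2")]),
               unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(fit$loglik,
               lexpit_loglik(numeric(0), coef(oracle)[1], coef(oracle)[-1],
                             y = y, z = cbind(z1, z2), w = w),
               tolerance = 1e-9)
})

test_that("empty multiplicative block with unit weights equals group proportions", {
  set.seed(22)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, 0.15 + 0.2 * x)
  dat <- tibble::tibble(case = y, x = x)
  fit <- quiet_fit(dat, additive = "x")
  p0 <- mean(y[x == 0]); p1 <- mean(y[x == 1])
  expect_equal(coef(fit)[["x"]], p1 - p0, tolerance = 1e-7)
  expect_equal(plogis(coef(fit)[["(Intercept)"]]), p0, tolerance = 1e-7)
})

test_that("the constrained optimum matches a dense grid search on a 2-parameter toy", {
  set.seed(23)
  n <- 150
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, 0.1 + 0.25 * x)
  dat <- tibble::tibble(case = y, x = x)
  fit <- quiet_fit(dat, additive = "x")
  betas <- seq(-0.2, 0.6, by = 0.002)
  g0s <- qlogis(seq(0.01, 0.5, by = 0.002))
  grid <- expand.grid(beta = betas, g0 = g0s)
  ll <- mapply(function(b, g) lexpit_loglik(b, g, numeric(0), y = y, x = x),
               grid$beta, grid$g0)
  best <- grid[which.max(ll), ]
  expect_lt(abs(coef(fit)[["x"]] - best$beta), 0.002)
  expect_lt(abs(plogis(coef(fit)[["(Intercept)"]]) - plogis(best$g0)), 0.002)
  expect_gte(fit$loglik, max(ll) - 1e-8)
})

test_that("the optimizer improves on its start and is deterministic", {
  dat <- random_cohort(1500, seed = 24)
  f1 <- quiet_fit(dat, additive = "a", multiplicative = "z")
  f2 <- quiet_fit(dat, additive = "a", multiplicative = "z")
  expect_gte(f1$loglik, f1$loglik_start)
  expect_identical(coef(f1), coef(f2))
  expect_true(f1$converged)
})

test_that("fits are invariant to row order, weight scaling, and row splitting", {
  dat <- random_cohort(800, seed = 25)
  dat$w <- sample(c(1, 3), nrow(dat), replace = TRUE)
  f0 <- quiet_fit(dat, additive = "a", multiplicative = "z", weights = "w")
  # row order
  set.seed(1); perm <- sample(nrow(dat))
  f1 <- quiet_fit(dat[perm, ], additive = "a", multiplicative = "z",
                  weights = "w")
  expect_equal(coef(f1), coef(f0), tolerance = 1e-7)
  # weight scaling by c > 0
  dat2 <- dplyr::mutate(dat, w = w * 7.5)
  f2 <- quiet_fit(dat2, additive = "a", multiplicative = "z", weights = "w")
  expect_equal(coef(f2), coef(f0), tolerance = 1e-7)
  # duplicate one row, halving its weight
  i <- 17L
  dat3 <- dplyr::bind_rows(dat, dat[i, ])
  dat3$w[c(i, nrow(dat3))] <- dat$w[i] / 2
  f3 <- quiet_fit(dat3, additive = "a", multiplicative = "z", weights = "w")
  expect_equal(coef(f3), coef(f0), tolerance = 1e-7)
})

test_that("every observed pattern's fitted risk respects the [0,1] constraints", {
  for (seed in 1:8) {
    set.seed(100 + seed)
    n <- 300
    x <- rbinom(n, 1, 0.5)
    z <- rnorm(n)
    # strong negative additive effect pushes patterns toward the 0 boundary
    risk <- pmin(pmax(-0.04 * x + plogis(-3 + 1.2 * z), 1e-4), 1 - 1e-4)
    dat <- tibble::tibble(case = rbinom(n, 1, risk), x = x, z = z)
    fit <- quiet_fit(dat, additive = "x", multiplicative = "z",
                     variance = "none")
    expect_true(all(fit$pattern_risks >= -1e-8))
    expect_true(all(fit$pattern_risks <= 1 + 1e-8))
  }
})

test_that("degenerate inputs are rejected with named errors", {
  dat <- random_cohort(100, seed = 26)
  dat$flat <- 1
  expect_error(quiet_fit(dat, additive = "flat"), "flat")
  expect_error(quiet_fit(dat[0, ], additive = "a"), "complete cases|empty")
  all_case <- dplyr::mutate(dat, case = 1)
  expect_error(quiet_fit(all_case, additive = "a"), "case and one control")
})

test_that("missing rows are dropped with a reported count", {
  dat <- random_cohort(200, seed = 27)
  dat$z[c(3, 10)] <- NA
  expect_message(fit <- suppressWarnings(lexpit(dat, multiplicative = "z")),
                 "2 row")
  expect_equal(fit$n, 198)
})
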