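test_that("the weighted Hosmer-Lemeshow statistic is 0 for a saturated fit", {
  # two risk groups whose fitted risk equals the weighted group event rate
  risk <- c(rep(0.2, 10), rep(0.5, 10))
  y <- c(rep(1, 2), rep(0, 8), rep(1, 5), rep(0, 5))
  gof <- hosmer_lemeshow(risk, y = y, groups = 2)
  expect_equal(gof$statistic, 0)
  expect_equal(gof$n_groups, 2L)
})

test_that("unit weights reproduce the classical Hosmer-Lemeshow statistic", {
  set.seed(41)
  n <- 500
  z <- rnorm(n)
  p <- plogis(-1 + z)
  y <- rbinom(n, 1, p)
  gof <- hosmer_lemeshow(p, y = y, groups = 10)
  # independent classical computation: equal-count deciles of risk
  ord <- order(p)
  grp <- ceiling(seq_len(n) / (n / 10))
  O <- tapply(y[ord], grp, sum)
  E <- tapply(p[ord], grp, sum)
  ng <- tapply(rep(1, n), grp, sum)
  classical <- sum((O - E)^2 / (E * (1 - E / ng)))
  expect_equal(gof$statistic, classical, tolerance = 1e-12)
})

test_that("the weighted statistic matches hand arithmetic on a 2-group toy", {
  # tabulated toy: (risk, weight, outcome)
  risk <- c(0.1, 0.1, 0.4, 0.4)
  w <- c(10, 30, 5, 5)
  y <- c(1, 0, 1, 0)
  # group 1 = the 0.1 rows, group 2 = the 0.4 rows
  O1 <- 10 * 1 + 30 * 0;  E1 <- 0.1 * 40;  W1 <- 40
  O2 <- 5;                E2 <- 0.4 * 10;  W2 <- 10
  hand <- (O1 - E1)^2 / (E1 * (1 - E1 / W1)) +
    (O2 - E2)^2 / (E2 * (1 - E2 / W2))
  gof <- hosmer_lemeshow(risk, y = y, w = w, groups = 2)
  expect_equal(gof$statistic, hand)
  # group weights conserve the total weight
  expect_equal(sum(gof$table$weight), sum(w))
})

test_that("the statistic is invariant to row order, including tied risks", {
  set.seed(42)
  risk <- rep(round(runif(30), 1), each = 4)
  y <- rbinom(length(risk), 1, risk)
  w <- sample(1:5, length(risk), replace = TRUE)
  g0 <- hosmer_lemeshow(risk, y = y, w = w, groups = 6)
  perm <- sample(length(risk))
  g1 <- hosmer_lemeshow(risk[perm], y = y[perm], w = w[perm], groups = 6)
  expect_identical(g0$statistic, g1$statistic)
})

test_that("degenerate risk groups are merged with a neighbor", {
  risk <- c(rep(0, 10), rep(0.5, 10))
  y <- c(rep(0, 10), rep(1, 5), rep(0, 5))
  expect_message(gof <- hosmer_lemeshow(risk, y = y, groups = 2), "Merging")
  expect_lt(gof$n_groups, 2 + 1)
  expect_true(is.finite(gof$statistic))
})

test_that("risk-exposure scatter conserves weight and flags too few bins", {
  set.seed(43)
  n <- 2000
  u <- runif(n)
  dat <- tibble::tibble(case = rbinom(n, 1, 0.1), u = u,
                        w = sample(c(1, 10), n, replace = TRUE))
  sc <- risk_exposure_scatter(dat, "u", weights = "w", bins = 8)
  expect_equal(sum(sc$weight), sum(dat$w))
  expect_equal(nrow(sc), 8L)
  dat$flat <- 1
  expect_error(risk_exposure_scatter(dat, "flat"), "2 nonempty")
})

test_that("a flat exposure-outcome relationship yields flat bin risks", {
  set.seed(44)
  n <- 30000
  dat <- tibble::tibble(u = runif(n), case = rbinom(n, 1, 0.2))
  sc <- risk_exposure_scatter(dat, "u", bins = 6)
  expect_true(all(abs(sc$risk - 0.2) < 4 * sqrt(0.2 * 0.8 / (n / 6))))
})

test_that("bin risks recover a linear-in-exposure generating slope", {
  set.seed(45)
  n <- 50000
  u <- runif(n)
  slope <- 0.3
  dat <- tibble::tibble(u = u, case = rbinom(n, 1, 0.02 + slope * u))
  sc <- risk_exposure_scatter(dat, "u", bins = 10)
  est <- coef(lm(risk ~ exposure, data = sc))[["exposure"]]
  expect_lt(abs(est - slope) / slope, 0.2)
})

test_that("dual-scale comparison reports three models with GOF statistics", {
  dat <- random_cohort(3000, beta = 0.05, seed = 46)
  res <- suppressWarnings(suppressMessages(
    dual_scale_comparison(dat, "a", multiplicative = "z")))
  expect_setequal(unique(res$model), c("additive", "multiplicative", "both"))
  gof <- attr(res, "gof")
  expect_equal(names(gof), c("additive", "multiplicative", "both"))
  expect_true(all(is.finite(gof)))
  joint <- res[res$model == "both", ]
  expect_true(all(c("a", "z") %in% joint$term))
  expect_true(all(!is.na(joint$statistic[joint$term == "a"])))
})

test_that("the dominant |z| in the joint model identifies the generating scale", {
  # additive truth: the additive coefficient should carry the larger z
  n_add <- 0L; n_mult <- 0L
  reps <- 30L
  set.seed(47)
  for (i in seq_len(reps)) {
    dat_a <- random_cohort(8000, beta = 0.06, gamma0 = -3, gamma1 = 0.8)
    fa <- quiet_fit(dat_a, additive = "a", multiplicative = c("z", "a"))
    za <- tidy(fa)
    z_add <- abs(za$statistic[za$block == "additive" & za$term == "a"])
    z_mul <- abs(za$statistic[za$block == "multiplicative" & za$term == "a"])
    if (isTRUE(z_add > z_mul)) n_add <- n_add + 1L
    # multiplicative truth, same machinery with roles reversed
    a <- rbinom(8000, 1, 0.5); z <- rnorm(8000)
    dat_m <- tibble::tibble(a = a, z = z,
                            case = rbinom(8000, 1, plogis(-3 + 0.8 * z + 0.9 * a)))
    fm <- quiet_fit(dat_m, additive = "a", multiplicative = c("z", "a"))
    zm <- tidy(fm)
    z_add_m <- abs(zm$statistic[zm$block == "additive" & zm$term == "a"])
    z_mul_m <- abs(zm$statistic[zm$block == "multiplicative" & zm$term == "a"])
    if (isTRUE(z_mul_m > z_add_m)) n_mult <- n_mult + 1L
  }
  expect_gte(n_add / reps, 0.8)
  expect_gte(n_mult / reps, 0.8)
})
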