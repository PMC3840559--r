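# Synthetic finite populations and stratified case-control samples with known
# truth, for validating estimation, variance and diagnostics.

#' Define a synthetic-study scenario
#'
#' A scenario is a finite population partitioned into sampling strata, a
#' covariate model, and a true lexpit parameterization. [generate_population()]
#' realizes the population (covariates + Bernoulli outcomes under the true
#' risk); [sample_case_control()] then ascertains all cases and draws a
#' within-stratum simple random sample of controls, emitting the matching
#' [cc_design()].
#'
#' @param strata Data frame with columns `stratum`, `population_size`,
#'   optionally `n_controls` (default control sample sizes) and any
#'   stratum-level covariate columns (e.g. `female`, age-band bounds) that the
#'   covariate model needs.
#' @param covariate_model `NULL`, or `function(pop)` receiving the expanded
#'   population (one row per individual, stratum-level columns replicated) and
#'   returning it with individual covariate columns added.
#' @param additive,multiplicative Character vectors of term labels of the true
#'   model (as in [lexpit()]).
#' @param beta,gamma0,gamma True coefficients, matching the design-matrix
#'   columns the term labels generate.
#' @param tau Risk-period length the true risks refer to.
#' @return A `lexpit_scenario` list.
#' @export
lexpit_scenario <- function(strata, covariate_model = NULL, additive = NULL,
                            multiplicative = NULL, beta = numeric(0),
                            gamma0, gamma = numeric(0), tau = 1) {
  strata <- tibble::as_tibble(strata)
  if (!all(c("stratum", "population_size") %in% names(strata))) {
    abort("`strata` needs columns `stratum` and `population_size`.")
  }
  if (anyDuplicated(strata$stratum)) abort("Stratum labels must be unique.")
  if (any(strata$population_size < 0)) abort("`population_size` must be non-negative.")
  if (!is.numeric(gamma0) || length(gamma0) != 1L || !is.finite(gamma0)) {
    abort("`gamma0` must be a finite scalar.")
  }
  structure(list(strata = strata, covariate_model = covariate_model,
                 additive = additive, multiplicative = multiplicative,
                 beta = beta, gamma0 = gamma0, gamma = gamma, tau = tau),
            class = "lexpit_scenario")
}

#' Generate a finite population under a scenario
#'
#' Expands the strata to one row per individual, draws covariates from the
#' scenario's covariate model, computes each individual's true risk under the
#' lexpit truth, validates that every risk lies in `[0, 1]` (the scenario is
#' rejected before any outcome is drawn otherwise), and draws the outcome
#' `case ~ Bernoulli(risk)`. Reproducible given `seed`.
#'
#' @param scenario A [lexpit_scenario()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per individual: stratum-level columns,
#'   covariates, true `.risk` and realized `case`; the scenario is attached as
#'   an attribute.
#' @export
generate_population <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "lexpit_scenario"))
  if (!is.null(seed)) set.seed(seed)
  st <- scenario$strata
  st <- st[st$population_size > 0, , drop = FALSE]
  keep <- setdiff(names(st), c("population_size", "n_controls"))
  idx <- rep.int(seq_len(nrow(st)), st$population_size)
  pop <- tibble::as_tibble(lapply(st[keep], function(col) col[idx]))
  if (!is.null(scenario$covariate_model)) {
    pop <- scenario$covariate_model(pop)
  }
  blocks <- build_blocks(pop, scenario$additive, scenario$multiplicative)
  if (ncol(blocks$X) != length(scenario$beta)) {
    abort(sprintf("True `beta` has length %d but the additive terms generate %d column(s).",
                  length(scenario$beta), ncol(blocks$X)))
  }
  if (ncol(blocks$Z) != length(scenario$gamma)) {
    abort(sprintf("True `gamma` has length %d but the multiplicative terms generate %d column(s).",
                  length(scenario$gamma), ncol(blocks$Z)))
  }
  risk <- predict_risk(scenario$beta, scenario$gamma0, scenario$gamma,
                       x = if (ncol(blocks$X)) blocks$X,
                       z = if (ncol(blocks$Z)) blocks$Z)
  if (any(risk < 0 | risk > 1)) {
    abort(sprintf("Scenario rejected: %d individual(s) have true risk outside [0, 1].",
                  sum(risk < 0 | risk > 1)))
  }
  pop$.risk <- risk
  pop$case <- rbinom(nrow(pop), 1L, risk)
  attr(pop, "scenario") <- scenario
  pop
}

#' Draw a stratified case-control sample from a generated population
#'
#' Complete case ascertainment (every case enters the sample) plus simple
#' random sampling without replacement of controls among each stratum's
#' non-cases. Emits the sampled data together with the [cc_design()] that a
#' real study of this base would record.
#'
#' @param population Output of [generate_population()].
#' @param n_controls Controls per stratum: a named vector, a data frame with
#'   `stratum`/`n_controls`, or `NULL` to use the scenario's `n_controls`
#'   column. Strata omitted (or 0) contribute cases only.
#' @param frame What the design records as `population_size`: `"population"`
#'   (default) uses the full stratum count, mirroring census-based sampling
#'   frames whose counts include future cases; `"noncases"` uses the non-case
#'   count, so control weights expand to the non-case population exactly.
#' @param seed Optional integer seed.
#' @return A `cc_study` list: `data` (sampled subjects), `design`
#'   ([cc_design()] with the realized counts), `truth` (the scenario's
#'   parameters) and `population` (per-stratum totals and case counts).
#' @export
sample_case_control <- function(population, n_controls = NULL,
                                frame = c("population", "noncases"),
                                seed = NULL) {
  frame <- match.arg(frame)
  scenario <- attr(population, "scenario")
  if (is.null(scenario)) abort("`population` must come from generate_population().")
  if (!is.null(seed)) set.seed(seed)

  s <- as.character(population$stratum)
  psum <- tibble::tibble(stratum = s, case = population$case) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(population_size = dplyr::n(), n_cases = sum(.data$case),
                     .groups = "drop")

  nc <- resolve_n_controls(n_controls, scenario, psum$stratum)
  psum$n_requested <- nc[psum$stratum]
  avail <- psum$population_size - psum$n_cases
  over <- psum$n_requested > avail
  if (any(over)) {
    abort(paste0("Requested more controls than available non-cases in stratum ",
                 toString(psum$stratum[over]), "."))
  }

  case_idx <- which(population$case == 1L)
  ctrl_pool <- split(which(population$case == 0L), s[population$case == 0L])
  ctrl_idx <- unlist(lapply(psum$stratum, function(lab) {
    k <- nc[[lab]]
    if (k <= 0) return(integer(0))
    pool <- ctrl_pool[[lab]]
    pool[sample.int(length(pool), k)]
  }), use.names = FALSE)

  take <- c(case_idx, ctrl_idx)
  dat <- population[take, setdiff(names(population), ".risk"), drop = FALSE]
  attr(dat, "scenario") <- NULL

  design_strata <- tibble::tibble(
    stratum = psum$stratum,
    population_size = if (frame == "population") psum$population_size else
      psum$population_size - psum$n_cases,
    n_controls = psum$n_requested,
    n_cases = psum$n_cases
  )
  structure(list(
    data = dat,
    design = cc_design(design_strata, tau = scenario$tau),
    truth = scenario[c("beta", "gamma0", "gamma", "additive",
                       "multiplicative", "tau")],
    population = psum[, c("stratum", "population_size", "n_cases")]
  ), class = "cc_study")
}

resolve_n_controls <- function(n_controls, scenario, strata_labels) {
  if (is.null(n_controls)) {
    if (!"n_controls" %in% names(scenario$strata)) {
      abort("No `n_controls` given and the scenario's strata carry none.")
    }
    nc <- setNames(scenario$strata$n_controls,
                   as.character(scenario$strata$stratum))
  } else if (is.data.frame(n_controls)) {
    nc <- setNames(n_controls$n_controls, as.character(n_controls$stratum))
  } else {
    nc <- n_controls
    if (is.null(names(nc))) {
      if (length(nc) == 1L) {
        nc <- setNames(rep(nc, length(strata_labels)), strata_labels)
      } else {
        abort("`n_controls` must be named by stratum (or length 1).")
      }
    }
  }
  out <- setNames(rep(0L, length(strata_labels)), strata_labels)
  known <- intersect(names(nc), strata_labels)
  out[known] <- nc[known]
  out
}

#' @export
print.cc_study <- function(x, ...) {
  cat(sprintf("<cc_study> %d subjects (%d cases, %d controls) from %d strata; population %s\n",
              nrow(x$data), sum(x$data$case == 1), sum(x$data$case == 0),
              nrow(x$design),
              format(sum(x$population$population_size), big.mark = ",")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# EAGLE-flavored default scenario
# ---------------------------------------------------------------------------

#' Sampling strata of the EAGLE lung-cancer study base
#'
#' The published design of the EAGLE population-based case-control study
#' (Lombardy, Northern Italy): 90 strata of residence region x 5-year age band
#' x gender, each with its census control-population size and the number of
#' sampled controls. One stratum (Pavia, women 35-39) is empty. These counts
#' drive the default synthetic scenario and the worked gender-only example.
#'
#' @return A tibble: `stratum`, `region`, `age_lo`, `age_hi`, `female`,
#'   `population_size`, `n_controls`.
#' @export
eagle_strata <- function() {
  regions <- c("Milan", "Monza", "Brescia", "Pavia", "Varese")
  lo <- c(35, 40, 45, 50, 55, 60, 65, 70, 75)
  hi <- c(39, 44, 49, 54, 59, 64, 69, 74, 80)
  pop_m <- c(70630, 12352, 22479, 9202, 9866,
             58166, 10045, 18816, 7958, 8156,
             50727, 9143, 16644, 7046, 7698,
             55952, 9677, 17760, 7508, 8155,
             51407, 8281, 14665, 5951, 6783,
             55106, 9083, 14682, 6765, 7127,
             45477, 7043, 11334, 5855, 5765,
             35965, 5423, 8995, 4518, 4640,
             24960, 3430, 6291, 3417, 3278)
  ctl_m <- c(3, 1, 1, 2, 1,  9, 4, 2, 1, 3,  25, 3, 3, 5, 2,
             56, 3, 18, 3, 7,  145, 8, 33, 8, 25,  209, 17, 47, 15, 20,
             251, 26, 42, 30, 41,  242, 22, 30, 20, 27,  149, 10, 18, 8, 22)
  pop_f <- c(68084, 11717, 20391, 0, 9509,
             57734, 10122, 17455, 7410, 8061,
             53942, 9387, 16248, 6979, 7754,
             63060, 10307, 17739, 7424, 8545,
             58781, 9022, 15140, 6085, 7099,
             63452, 9607, 15885, 7352, 7675,
             56296, 8152, 12439, 7199, 6822,
             50119, 7090, 13220, 6763, 6083,
             43166, 5610, 11221, 5732, 5404)
  ctl_f <- c(5, 1, 1, 0, 2,  2, 1, 1, 4, 1,  13, 4, 7, 3, 6,
             27, 1, 3, 7, 2,  61, 2, 7, 5, 6,  43, 5, 8, 4, 3,
             73, 5, 9, 7, 4,  63, 3, 7, 4, 4,  62, 1, 10, 3, 9)
  grid <- tidyr::expand_grid(female = c(0L, 1L),
                             age_lo = lo,
                             region = regions)
  grid$age_hi <- hi[match(grid$age_lo, lo)]
  grid$population_size <- c(pop_m, pop_f)
  grid$n_controls <- c(ctl_m, ctl_f)
  grid$stratum <- sprintf("%s_%d-%d_%s", grid$region, grid$age_lo, grid$age_hi,
                          ifelse(grid$female == 1, "F", "M"))
  grid[, c("stratum", "region", "age_lo", "age_hi", "female",
           "population_size", "n_controls")]
}

#' EAGLE-flavored synthetic scenario with known truth
#'
#' The default validation scenario: the 90 strata (region x age band x gender)
#' and control sample sizes of [eagle_strata()], individual covariates drawn
#' from simple parametric stand-ins (age uniform within its band; smoking
#' prevalence 75% in men and 43% in women; pack-years among smokers
#' gamma-distributed with mean 35 in men and 22 in women, capped at 120), and
#' true effects near the published multiple-variable analysis: additive
#' 3-year risk differences of 4.6e-5 for female, 52.9e-5 per 10 pack-years and
#' -39.3e-5 for their interaction, with a multiplicative age effect of
#' log(1.12) per year (age centered at 60). The baseline log-odds is set so
#' the study base yields a realistic few thousand cases. No attempt is made to
#' copy real study microdata.
#'
#' Scaling down the populations while keeping the published control counts
#' (`control_scale = 1`) preserves the per-stratum control sample sizes that
#' the weighted estimator's small-sample behavior depends on. Since region
#' carries no risk signal in the truth, `collapse_regions = TRUE` merges the
#' five regions into 18 gender-by-age strata (control counts summed), which
#' removes the single-control strata of the full design; useful for replicate
#' validation studies.
#'
#' @param scale Multiplies every stratum's population size (rounded).
#' @param control_scale Multiplies the control sample sizes (defaults to
#'   `scale`).
#' @param collapse_regions Merge regions into gender-by-age strata.
#' @return A [lexpit_scenario()].
#' @export
eagle_scenario <- function(scale = 1, control_scale = scale,
                           collapse_regions = FALSE) {
  st <- eagle_strata()
  if (collapse_regions) {
    st <- st |>
      dplyr::group_by(.data$female, .data$age_lo, .data$age_hi) |>
      dplyr::summarise(population_size = sum(.data$population_size),
                       n_controls = sum(.data$n_controls), .groups = "drop")
    st$stratum <- sprintf("%d-%d_%s", st$age_lo, st$age_hi,
                          ifelse(st$female == 1, "F", "M"))
  }
  st$population_size <- round(st$population_size * scale)
  st$n_controls <- pmin(round(st$n_controls * control_scale),
                        st$population_size)
  covm <- function(pop) {
    n <- nrow(pop)
    pop$age <- runif(n, pop$age_lo, pop$age_hi + 1)
    pop$age_c <- pop$age - 60
    smoker <- rbinom(n, 1L, ifelse(pop$female == 1, 0.43, 0.75))
    packyears <- smoker * pmin(rgamma(n, shape = 2,
                                      scale = ifelse(pop$female == 1, 11, 17.5)),
                               120)
    pop$py10 <- packyears / 10
    pop
  }
  lexpit_scenario(
    strata = st,
    covariate_model = covm,
    additive = c("female", "py10", "female:py10"),
    multiplicative = "age_c",
    beta = c(4.6e-5, 52.9e-5, -39.3e-5),
    gamma0 = qlogis(6e-4),
    gamma = log(1.12),
    tau = 3
  )
}

#' Worked two-stratum gender example
#'
#' `eagle_gender_design()` is the gender-only collapse of the EAGLE design:
#' 1,617 male controls representing 774,221 men and 499 female controls
#' representing 851,550 women, risk period 3 years. `eagle_gender_data()` is
#' the matching subject table: 1,537 male and 406 female cases plus the
#' sampled controls, one row per subject, with a `female` indicator. Fitting
#' `lexpit(additive = "female")` to these reproduces the weighted absolute
#' risks (about 2.0 and 0.5 per 1,000) and their risk difference of about
#' -1.5 per 1,000.
#'
#' @return A [cc_design()] / a tibble with columns `case`, `female`, `stratum`.
#' @export
eagle_gender_design <- function() {
  cc_design(tibble::tibble(
    stratum = c("male", "female"),
    population_size = c(774221, 851550),
    n_controls = c(1617, 499),
    n_cases = c(1537, 406)
  ), tau = 3)
}

#' @rdname eagle_gender_design
#' @export
eagle_gender_data <- function() {
  counts <- tibble::tibble(
    case = c(1L, 1L, 0L, 0L),
    female = c(0L, 1L, 0L, 1L),
    n = c(1537L, 406L, 1617L, 499L)
  )
  out <- counts[rep.int(seq_len(4L), counts$n), c("case", "female")]
  out$stratum <- ifelse(out$female == 1, "female", "male")
  tibble::as_tibble(out)
}
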