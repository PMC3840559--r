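# Design-aware variance estimation for lexpit fits.
#
# The estimator solves the weighted score equation sum_ij w_ij s_ij(theta) = 0.
# Linearization: the influence of observation ij is
#   d_ij = w_ij * H^{-1} s_ij,
# with s_ij the per-observation score of the pseudo-log-likelihood summand and
# H the weighted observed information at the optimum. The parameter covariance
# is the estimated variance of the influence total. Under complete case
# ascertainment the case set is a realization of population Bernoulli
# outcomes, so cases contribute model-based (uncentered) outer products; the
# within-stratum simple random sampling of controls contributes the usual
# stratified between-unit (centered) variance. With no design and unit
# weights this collapses to the ordinary sandwich estimator.

#' Influence vectors of a lexpit fit
#'
#' Returns the per-observation influence \eqn{d_{ij} = w_{ij} \hat H^{-1}
#' s_{ij}}, one row per observation and one column per parameter. At an
#' interior optimum the influence vectors sum to zero (the score condition).
#'
#' @param fit A converged [lexpit()] fit.
#' @return An object of class `lexpit_influence`: a list with `d` (numeric
#'   matrix), `stratum`, `case` and `w`.
#' @export
influence_vectors <- function(fit) {
  stopifnot(inherits(fit, "lexpit"))
  if (!fit$converged) abort("Fit did not converge; influence vectors undefined.")
  r <- fit$fitted_raw
  p <- risk_eval(unname(fit$coefficients), fit$X, fit$Z)$p
  pq <- p * (1 - p)
  A <- cbind(fit$X, pq, if (ncol(fit$Z)) fit$Z * pq)
  S <- A * ((fit$y - r) / (r * (1 - r)))   # per-observation scores
  H <- -fit$hessian                        # weighted observed information
  Hinv <- tryCatch(solve(H), error = function(e) {
    abort("Observed information is singular; consider simplifying the model.")
  })
  kappa <- max(abs(diag(H))) / max(min(abs(diag(H))), .Machine$double.xmin)
  if (!all(is.finite(Hinv))) {
    abort("Observed information is numerically singular; consider simplifying the model.")
  }
  D <- (S * fit$w) %*% Hinv
  colnames(D) <- names(fit$coefficients)
  structure(list(d = D, stratum = fit$stratum, case = fit$y == 1, w = fit$w,
                 condition = kappa),
            class = "lexpit_influence")
}

#' Linearized (influence-function) covariance of a lexpit fit
#'
#' Stratified design-based variance of the influence totals. Control strata
#' contribute centered between-unit variance \eqn{\frac{n_j}{n_j - 1}
#' \sum_i (d_{ij} - \bar d_j)(d_{ij} - \bar d_j)'}; under the default
#' `case_component = "model"` the completely ascertained cases contribute
#' uncentered outer products \eqn{\sum_i d_i d_i'}, reflecting the Bernoulli
#' outcome randomness of the study base. `case_component = "resampling"`
#' instead centers the cases as one self-representing stratum, which estimates
#' the smaller variance conditional on the total case count and matches a
#' bootstrap that resamples a fixed number of cases. For a cohort fit (no
#' design, unit weights) every observation is model-based and the result is
#' the ordinary sandwich estimator.
#'
#' @param fit A converged [lexpit()] fit.
#' @param fpc Apply the finite-population correction `1 - n_j/N_j` to control
#'   strata (requires a design).
#' @param case_component `"model"` (default) or `"resampling"`; see Details.
#' @return A symmetric positive semi-definite matrix with `method` and
#'   `df_note` attributes.
#' @export
linearized_vcov <- function(fit, fpc = FALSE,
                            case_component = c("model", "resampling")) {
  case_component <- match.arg(case_component)
  inf <- influence_vectors(fit)
  D <- inf$d
  dpar <- ncol(D)
  V <- matrix(0, dpar, dpar)
  if (fit$cohort) {
    V <- crossprod(D)
    note <- "cohort (unit weights): unstratified sandwich over all observations"
  } else {
    is_case <- inf$case
    # cases: self-representing under complete ascertainment
    Dc <- D[is_case, , drop = FALSE]
    if (case_component == "model") {
      V <- V + crossprod(Dc)
    } else if (nrow(Dc) > 1L) {
      ctr <- sweep(Dc, 2, colMeans(Dc))
      V <- V + nrow(Dc) / (nrow(Dc) - 1L) * crossprod(ctr)
    }
    # controls: stratified SRS
    s <- inf$stratum[!is_case] %||% rep("(all)", sum(!is_case))
    Du <- D[!is_case, , drop = FALSE]
    tab <- table(s)
    single <- names(tab)[tab < 2L]
    if (length(single)) {
      groups <- collapse_singletons(sort(names(tab)), single)
      warn(paste0("Control stratum(s) with a single sampled unit collapsed with the nearest stratum by label order: ",
                  toString(single), "."))
      s <- groups[s]
    }
    fpc_factor <- function(lab) {
      if (!fpc || is.null(fit$design)) return(1)
      i <- match(lab, fit$design$stratum)
      if (is.na(i)) return(1)
      max(0, 1 - fit$design$n_controls[i] / fit$design$population_size[i])
    }
    for (lab in unique(s)) {
      Dj <- Du[s == lab, , drop = FALSE]
      nj <- nrow(Dj)
      if (nj < 2L) next
      ctr <- sweep(Dj, 2, colMeans(Dj))
      V <- V + fpc_factor(lab) * nj / (nj - 1L) * crossprod(ctr)
    }
    note <- sprintf(
      "cases self-representing (%s); controls stratified by sampling stratum (%d strata)%s",
      case_component, length(unique(s)), if (fpc) ", with FPC" else "")
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(D), colnames(D))
  structure(V, method = "linearized", df_note = note)
}

# map each singleton stratum to its nearest neighbour in label order
collapse_singletons <- function(labs, single) {
  groups <- setNames(labs, labs)
  for (lab in single) {
    i <- match(lab, labs)
    others <- setdiff(seq_along(labs), which(labs %in% single))
    if (!length(others)) next
    j <- others[which.min(abs(others - i))]
    groups[lab] <- labs[j]
  }
  groups
}

#' Stratified bootstrap covariance of a lexpit fit
#'
#' Resamples cases with replacement as one stratum and controls with
#' replacement within each sampling stratum, refits, and returns the
#' empirical covariance of the coefficient draws.
#'
#' @param fit A converged [lexpit()] fit.
#' @param reps Number of bootstrap replicates.
#' @param seed Optional RNG seed for reproducibility.
#' @return A covariance matrix with attributes `method = "bootstrap"`,
#'   `draws` (replicate coefficients) and `n_failed`.
#' @export
boot_vcov <- function(fit, reps = 500L, seed = NULL) {
  stopifnot(inherits(fit, "lexpit"))
  if (!is.null(seed)) set.seed(seed)
  idx_case <- which(fit$y == 1)
  idx_ctrl <- which(fit$y == 0)
  strat <- if (!is.null(fit$stratum)) fit$stratum[idx_ctrl] else rep("(all)", length(idx_ctrl))
  ctrl_by_s <- split(idx_ctrl, strat)
  theta0 <- unname(fit$coefficients)
  ctl <- lexpit_control(mu0 = 1e-4)
  draws <- matrix(NA_real_, reps, length(theta0))
  for (b in seq_len(reps)) {
    take <- c(sample(idx_case, length(idx_case), replace = TRUE),
              unlist(lapply(ctrl_by_s, function(ii) sample(ii, length(ii), replace = TRUE)),
                     use.names = FALSE))
    fitb <- tryCatch({
      start <- if (feasible_at(theta0,
                               fit$X[take, , drop = FALSE],
                               fit$Z[take, , drop = FALSE])) {
        theta0
      } else {
        c(rep(0, ncol(fit$X)), start_values(fit$y[take], fit$Z[take, , drop = FALSE],
                                            fit$w[take]))
      }
      lexpit_engine(fit$y[take], fit$X[take, , drop = FALSE],
                    fit$Z[take, , drop = FALSE], fit$w[take],
                    start = start, control = ctl)
    }, error = function(e) NULL)
    if (!is.null(fitb) && fitb$converged) draws[b, ] <- fitb$theta
  }
  ok <- stats::complete.cases(draws)
  if (sum(ok) < 2L) abort("Bootstrap failed: fewer than 2 successful replicates.")
  V <- cov(draws[ok, , drop = FALSE])
  dimnames(V) <- list(names(fit$coefficients), names(fit$coefficients))
  structure(V, method = "bootstrap", draws = draws,
            n_failed = sum(!ok))
}

#' Wald confidence intervals for lexpit parameters
#'
#' `estimate +/- z * SE` on the coefficient scale. Residual-odds-ratio
#' intervals are obtained by exponentiating the endpoints of the
#' multiplicative coefficients (see [tidy.lexpit()] /
#' [risk_difference_report()]).
#'
#' @param object A [lexpit()] fit with a covariance estimate.
#' @param parm Parameters to include (names or indices; default all).
#' @param level Confidence level.
#' @param ... Unused.
#' @return A matrix with lower/upper columns.
#' @export
confint.lexpit <- function(object, parm, level = 0.95, ...) {
  est <- coef(object)
  V <- vcov(object)
  if (is.null(V)) abort("No covariance estimate available; refit with variance != 'none'.")
  se <- sqrt(pmax(diag(V), 0))
  zq <- qnorm((1 + level) / 2)
  ci <- cbind(est - zq * se, est + zq * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, (1 + level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
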