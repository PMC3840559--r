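#' Inverse-logit (expit) function
#'
#' `expit(u) = exp(u) / (1 + exp(u))` maps log-odds to the probability scale.
#' Computed via [stats::plogis()], which is numerically stable for large `|u|`
#' (no overflow; values saturate at 0/1 only at floating precision).
#'
#' @param u Numeric vector of log-odds.
#' @return Numeric vector of probabilities.
#' @examples
#' expit(0)            # 0.5
#' expit(c(-3, 0, 3))
#' @export
expit <- function(u) plogis(u)

#' Absolute risk under the lexpit model
#'
#' The lexpit model writes the absolute (cumulative) risk of disease within a
#' fixed risk period as the sum of a linear and an inverse-logit component:
#' \deqn{R(x, z) = \beta'x + \mathrm{expit}(\gamma_0 + \gamma'z).}
#' Additive coefficients \eqn{\beta} are risk differences on the probability
#' scale; \eqn{\exp(\gamma)} are residual odds ratios acting on the risk that
#' remains after subtracting the additive component. The baseline risk is
#' \eqn{R_0 = \mathrm{expit}(\gamma_0)} (no constraint needed to keep it in
#' \eqn{[0,1]}).
#'
#' @param beta Numeric vector of additive coefficients (may be length 0).
#' @param gamma0 Scalar baseline log-odds.
#' @param gamma Numeric vector of multiplicative coefficients (may be length 0).
#' @param x Numeric vector or matrix of additive covariates. A matrix has one
#'   row per observation and `length(beta)` columns.
#' @param z Numeric vector or matrix of multiplicative covariates, matching
#'   `gamma` the same way.
#' @return Numeric vector of risks, one per observation.
#' @seealso [incidence_rate()], [residual_odds_ratio()], [lexpit()]
#' @examples
#' # empty additive block reduces to a logistic probability
#' predict_risk(numeric(0), -2, 0.5, x = NULL, z = 1.2)
#' predict_risk(-0.0015, qlogis(0.00198), numeric(0), x = 1, z = NULL)
#' @export
predict_risk <- function(beta, gamma0, gamma, x = NULL, z = NULL) {
  X <- as_block(x, length(beta), "x", "beta")
  Z <- as_block(z, length(gamma), "z", "gamma")
  n <- max(nrow(X), nrow(Z), 1L)
  lin <- if (ncol(X)) drop(X %*% beta) else 0
  eta <- gamma0 + (if (ncol(Z)) drop(Z %*% gamma) else 0)
  drop(lin + plogis(eta)) + numeric(n)
}

# coerce a covariate block to a matrix with the dimension its coefficients imply
as_block <- function(v, p, what, coefname) {
  if (is.null(v)) {
    if (p > 0) {
      abort(sprintf("`%s` is NULL but `%s` has length %d.", what, coefname, p))
    }
    return(matrix(numeric(0), nrow = 1L, ncol = 0L))
  }
  m <- if (is.matrix(v)) v else {
    # a bare vector is one observation when it matches the coefficient length,
    # otherwise a column of observations for a single covariate
    if (p == 1L) matrix(v, ncol = 1L) else matrix(v, nrow = 1L)
  }
  if (ncol(m) != p) {
    abort(sprintf("`%s` has %d column(s) but `%s` has length %d.",
                  what, ncol(m), coefname, p))
  }
  m
}

#' Average incidence rate implied by a cumulative risk
#'
#' Divides the absolute risk over the risk period by the period length
#' `tau`, assuming constant risk over the period: rate = \eqn{R(x,z)/\tau}.
#'
#' @inheritParams predict_risk
#' @param tau Positive risk-period length, in the user's time unit (e.g. years).
#' @return Numeric vector of rates per person-time-unit.
#' @examples
#' incidence_rate(numeric(0), qlogis(0.00198), numeric(0), tau = 34 / 12)
#' @export
incidence_rate <- function(beta, gamma0, gamma, x = NULL, z = NULL, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    abort("`tau` must be a single positive number.")
  }
  predict_risk(beta, gamma0, gamma, x, z) / tau
}

#' Residual odds ratio for a multiplicative coefficient
#'
#' Multiplicative lexpit coefficients are log-odds ratios of the *residual*
#' odds \eqn{(R - \beta'x) / (1 - R)}, i.e. the odds of the risk remaining
#' after the additive component is subtracted. The residual odds ratio for a
#' `delta`-unit increase in the covariate is `exp(gamma_k * delta)`.
#'
#' @param gamma_k Numeric vector of multiplicative coefficients.
#' @param delta Size of the covariate increase (default 1 unit).
#' @return `exp(gamma_k * delta)`.
#' @examples
#' residual_odds_ratio(log(2), delta = 3)  # 8
#' @export
residual_odds_ratio <- function(gamma_k, delta = 1) {
  exp(gamma_k * delta)
}
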