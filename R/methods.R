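#' @export
coef.lexpit <- function(object, ...) object$coefficients

#' @export
vcov.lexpit <- function(object, ...) object$vcov

#' @export
logLik.lexpit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
fitted.lexpit <- function(object, ...) object$fitted

#' Predicted absolute risks and incidence rates
#'
#' @param object A [lexpit()] fit.
#' @param newdata Optional data frame; defaults to the fitting data. The
#'   centering/scaling recorded in the fit is re-applied.
#' @param type `"risk"` for the absolute risk over the risk period (clipped to
#'   `[0, 1]`), `"rate"` for the average incidence rate `risk / tau`.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.lexpit <- function(object, newdata = NULL,
                           type = c("risk", "rate"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    r <- object$fitted
  } else {
    pdat <- apply_center_scale(tibble::as_tibble(newdata),
                               object$center, object$scale)
    blocks <- build_blocks(pdat, object$terms$additive,
                           object$terms$multiplicative, xlev = object$xlev)
    px <- ncol(object$X)
    pz <- ncol(object$Z)
    th <- split_theta(unname(object$coefficients), px, pz)
    r <- predict_risk(th$beta, th$gamma0, th$gamma,
                      x = if (px) blocks$X, z = if (pz) blocks$Z)
    r <- unname(pmin(pmax(r, 0), 1))
  }
  if (type == "rate") r / object$tau else r
}

#' @export
print.lexpit <- function(x, digits = 4, ...) {
  cat("Lexpit regression: absolute risk = beta'x + expit(gamma0 + gamma'z)\n")
  if (!x$converged) {
    cat("*** WARNING: FIT DID NOT CONVERGE (", x$message, ") ***\n", sep = "")
  }
  cat(sprintf("n = %d (%d cases), weighted study base = %s, tau = %g\n",
              x$n, x$n_cases, format(round(x$weight_total), big.mark = ","),
              x$tau))
  if (length(x$blocks$additive)) {
    cat("\nAdditive (risk difference) coefficients:\n")
    print(signif(x$coefficients[x$blocks$additive], digits))
  }
  cat("\nMultiplicative (residual log-odds) coefficients:\n")
  print(signif(x$coefficients[c("(Intercept)", x$blocks$multiplicative)], digits))
  cat(sprintf("\nBaseline risk expit(gamma0) = %.3g; pseudo-logLik = %.6g\n",
              plogis(x$coefficients[["(Intercept)"]]), x$loglik))
  if (length(x$active_constraints)) {
    cat(sprintf("%d active feasibility constraint(s) at the optimum.\n",
                length(x$active_constraints)))
  }
  invisible(x)
}

#' Tidy a lexpit fit
#'
#' Broom-style coefficient table. Each row is a model term with its block
#' (`"additive"` terms are risk differences; `"multiplicative"` terms are
#' residual log-odds ratios, `gamma0` is the baseline log-odds).
#'
#' @param x A [lexpit()] fit.
#' @param conf.int Include Wald confidence limits.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with columns `term`, `block`, `estimate`, `std.error`,
#'   `statistic`, `p.value` (and `conf.low`, `conf.high`).
#' @method tidy lexpit
#' @export
tidy.lexpit <- function(x, conf.int = TRUE, conf.level = 0.95, ...) {
  est <- coef(x)
  block <- c(rep("additive", length(x$blocks$additive)),
             "baseline",
             rep("multiplicative", length(x$blocks$multiplicative)))
  out <- tibble::tibble(term = names(est), block = block, estimate = unname(est))
  if (!is.null(vcov(x))) {
    se <- sqrt(pmax(diag(vcov(x)), 0))
    out$std.error <- unname(se)
    out$statistic <- out$estimate / ifelse(se > 0, se, NA_real_)
    out$p.value <- 2 * pnorm(-abs(out$statistic))
    if (conf.int) {
      zq <- qnorm((1 + conf.level) / 2)
      out$conf.low <- out$estimate - zq * out$std.error
      out$conf.high <- out$estimate + zq * out$std.error
    }
  }
  out
}

#' @method glance lexpit
#' @export
glance.lexpit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    n = x$n,
    n_cases = x$n_cases,
    weight_total = x$weight_total,
    n_patterns = x$n_patterns,
    n_active = length(x$active_constraints),
    converged = x$converged,
    n_iter = x$n_iter,
    tau = x$tau
  )
}

#' Risk-difference and residual-odds-ratio report
#'
#' Renders the fit the way applied analyses present it: additive effects as
#' risk differences rescaled to a convenient population unit (default per
#' 100,000 persons per risk period) with Wald intervals on the same scale, and
#' multiplicative effects as residual odds ratios with intervals from
#' exponentiated endpoints. If no covariance is available the report carries
#' point estimates only and is flagged.
#'
#' @param fit A [lexpit()] fit.
#' @param scale Reporting scale for risk differences (e.g. `1e5` = per
#'   100,000 persons).
#' @param conf.level Confidence level.
#' @return A tibble with `term`, `effect`, `estimate`, `conf.low`,
#'   `conf.high`; attribute `scale` records the reporting unit and attribute
#'   `has_ci` whether intervals are present.
#' @export
risk_difference_report <- function(fit, scale = 1e5, conf.level = 0.95) {
  stopifnot(inherits(fit, "lexpit"))
  td <- tidy(fit, conf.int = TRUE, conf.level = conf.level)
  has_ci <- "conf.low" %in% names(td)
  if (!has_ci) {
    warn("No covariance available: reporting point estimates only.")
    td$conf.low <- NA_real_
    td$conf.high <- NA_real_
  }
  add <- td[td$block == "additive", ]
  mul <- td[td$block == "multiplicative", ]
  base <- td[td$block == "baseline", ]
  out <- dplyr::bind_rows(
    tibble::tibble(term = add$term,
                   effect = sprintf("risk difference (per %s)",
                                    format(scale, big.mark = ",", scientific = FALSE)),
                   estimate = add$estimate * scale,
                   conf.low = add$conf.low * scale,
                   conf.high = add$conf.high * scale),
    tibble::tibble(term = mul$term,
                   effect = "residual odds ratio",
                   estimate = exp(mul$estimate),
                   conf.low = exp(mul$conf.low),
                   conf.high = exp(mul$conf.high)),
    tibble::tibble(term = "baseline risk expit(gamma0)",
                   effect = sprintf("absolute risk (per %s)",
                                    format(scale, big.mark = ",", scientific = FALSE)),
                   estimate = plogis(base$estimate) * scale,
                   conf.low = plogis(base$conf.low) * scale,
                   conf.high = plogis(base$conf.high) * scale)
  )
  structure(out, scale = scale, has_ci = has_ci, tau = fit$tau,
            converged = fit$converged)
}

#' Summarize a lexpit fit
#'
#' @param object A [lexpit()] fit.
#' @param scale Risk-difference reporting scale (per `scale` persons).
#' @param conf.level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A `summary.lexpit` object; printing shows the effect table plus a
#'   metadata block (tau, scale, sample sizes, weight totals, convergence and
#'   active constraints).
#' @export
summary.lexpit <- function(object, scale = 1e5, conf.level = 0.95, ...) {
  structure(list(
    report = risk_difference_report(object, scale = scale,
                                    conf.level = conf.level),
    fit = object, scale = scale, conf.level = conf.level
  ), class = "summary.lexpit")
}

#' @export
print.summary.lexpit <- function(x, digits = 4, ...) {
  f <- x$fit
  if (!f$converged) {
    cat("*============================================*\n")
    cat("*  WARNING: FIT DID NOT CONVERGE             *\n")
    cat("*  ", f$message, "\n", sep = "")
    cat("*============================================*\n")
  }
  cat("Lexpit regression summary\n")
  cat(sprintf("  risk period tau = %g; risk differences per %s persons; %.0f%% CIs (%s)\n",
              f$tau, format(x$scale, big.mark = ","), 100 * x$conf.level,
              f$variance))
  cat(sprintf("  n = %d (%d cases, %d controls); weighted study base = %s\n",
              f$n, f$n_cases, f$n - f$n_cases,
              format(round(f$weight_total), big.mark = ",")))
  if (length(f$active_constraints)) {
    cat(sprintf("  %d active feasibility constraint(s): Wald inference at the boundary is unreliable\n",
                length(f$active_constraints)))
  }
  cat("\n")
  rep_df <- as.data.frame(x$report)
  rep_df[] <- lapply(rep_df, function(col) if (is.numeric(col)) signif(col, digits) else col)
  print(rep_df, row.names = FALSE)
  invisible(x)
}

#' Plot fitted absolute risks of a lexpit model
#'
#' Weighted histogram-style view of fitted risks for cases and controls; a
#' quick calibration-oriented look at the fit.
#'
#' @param object A [lexpit()] fit.
#' @param bins Number of bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lexpit
#' @export
autoplot.lexpit <- function(object, bins = 30, ...) {
  df <- tibble::tibble(
    risk = object$fitted,
    group = ifelse(object$y == 1, "cases", "controls"),
    w = object$w
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$risk, weight = .data$w,
                                   fill = .data$group)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.5) +
    ggplot2::scale_x_continuous(name = sprintf("fitted %g-unit absolute risk",
                                               object$tau)) +
    ggplot2::labs(y = "weighted count", fill = NULL,
                  title = "Fitted absolute risk by case status")
}
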