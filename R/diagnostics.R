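# Goodness of fit and effect-scale diagnostics.

#' Weighted Hosmer-Lemeshow goodness-of-fit statistic
#'
#' Observations are ranked by fitted risk and partitioned into groups of
#' (nearly) equal total weight; per group the weighted observed events
#' \eqn{O_g = \sum w y} are compared with the weighted expected events
#' \eqn{E_g = \sum w \hat R} via
#' \deqn{X^2 = \sum_g \frac{(O_g - E_g)^2}{E_g (1 - E_g / W_g)},}
#' with \eqn{W_g} the group's total weight. With unit weights this is the
#' classical Hosmer-Lemeshow statistic. Lower values indicate better fit; no
#' p-value is attached by default because the reference distribution under
#' expansion weighting is nonstandard — the statistic is meant for comparing
#' candidate models fit to the same data.
#'
#' Ties in the fitted risk are kept in a single group (grouping is over unique
#' fitted values by cumulative weight), which makes the statistic exactly
#' invariant to row order. Groups whose expected events are degenerate
#' (\eqn{E_g = 0} or \eqn{E_g = W_g}) are merged with a neighbor.
#'
#' @param x A [lexpit()] fit, or a numeric vector of fitted risks.
#' @param ... Passed to methods.
#' @return A `lexpit_gof` object: list with `statistic`, `n_groups`, and
#'   `table` (per-group weighted observed, expected and total weight).
#' @export
hosmer_lemeshow <- function(x, ...) UseMethod("hosmer_lemeshow")

#' @rdname hosmer_lemeshow
#' @param groups Number of groups (default 10; must be at least 2).
#' @export
hosmer_lemeshow.lexpit <- function(x, groups = 10, ...) {
  hosmer_lemeshow(x$fitted, y = x$y, w = x$w, groups = groups)
}

#' @rdname hosmer_lemeshow
#' @param y 0/1 outcomes (default method).
#' @param w Weights (default 1).
#' @export
hosmer_lemeshow.default <- function(x, y, w = rep(1, length(y)), groups = 10,
                                    ...) {
  if (groups < 2) abort("`groups` must be at least 2.")
  stopifnot(length(x) == length(y), length(w) == length(y))
  # aggregate over unique fitted risks so the grouping is row-order invariant
  agg <- tibble::tibble(r = x, w = w, o = w * y) |>
    dplyr::group_by(.data$r) |>
    dplyr::summarise(w = sum(.data$w), o = sum(.data$o), .groups = "drop") |>
    dplyr::arrange(.data$r)
  W <- sum(agg$w)
  cum_mid <- cumsum(agg$w) - agg$w / 2
  g <- pmin(groups, floor(groups * cum_mid / W) + 1L)
  tab <- tibble::tibble(
    g = g, w = agg$w, o = agg$o, e = agg$r * agg$w
  ) |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(weight = sum(.data$w), observed = sum(.data$o),
                     expected = sum(.data$e), .groups = "drop")
  # merge degenerate groups (expected 0 or equal to full weight) into a neighbor
  repeat {
    bad <- which(tab$expected <= 0 | tab$expected >= tab$weight)
    if (!length(bad) || nrow(tab) <= 1L) break
    i <- bad[1L]
    j <- if (i == 1L) 2L else i - 1L
    inform(sprintf("Merging degenerate risk group %d with its neighbor.", i))
    tab$weight[j] <- tab$weight[j] + tab$weight[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab <- tab[-i, ]
  }
  tab$g <- seq_len(nrow(tab))
  ok <- tab$expected > 0 & tab$expected < tab$weight
  stat <- sum((tab$observed[ok] - tab$expected[ok])^2 /
                (tab$expected[ok] * (1 - tab$expected[ok] / tab$weight[ok])))
  structure(list(statistic = stat, n_groups = nrow(tab),
                 table = dplyr::rename(tab, group = "g")),
            class = "lexpit_gof")
}

#' @export
print.lexpit_gof <- function(x, ...) {
  cat(sprintf("Weighted Hosmer-Lemeshow X^2 = %.4g on %d risk groups (lower = better fit)\n",
              x$statistic, x$n_groups))
  invisible(x)
}

#' @method glance lexpit_gof
#' @export
glance.lexpit_gof <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, n_groups = x$n_groups)
}

#' @method tidy lexpit_gof
#' @export
tidy.lexpit_gof <- function(x, ...) x$table

#' @method autoplot lexpit_gof
#' @export
autoplot.lexpit_gof <- function(object, ...) {
  df <- tidyr::pivot_longer(object$table, c("observed", "expected"),
                            names_to = "kind", values_to = "events")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$group), y = .data$events,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "risk group (increasing fitted risk)",
                  y = "weighted events", fill = NULL,
                  title = "Weighted observed vs expected events")
}

#' Crude risk by exposure level (risk-exposure scatter)
#'
#' Bins a continuous exposure into groups of (nearly) equal total weight and
#' computes the crude weighted risk \eqn{\sum w y / \sum w} per bin — with
#' expansion weights this estimates the absolute risk at that exposure level
#' in the study base. An approximately linear trend supports an additive
#' effect; a trend that bends like an expit supports a multiplicative effect.
#'
#' @param data Data frame.
#' @param exposure Name of a numeric exposure column.
#' @param outcome Name of the 0/1 outcome column.
#' @param design Optional [cc_design()] used to build weights.
#' @param stratum Stratum column name (with `design`).
#' @param weights Optional explicit weight column name.
#' @param bins Number of bins (at least 2 must be nonempty).
#' @return A `lexpit_scatter` tibble: `bin`, `exposure` (weighted mean),
#'   `risk`, `weight`, `n`, plus bin edges.
#' @export
risk_exposure_scatter <- function(data, exposure, outcome = "case",
                                  design = NULL, stratum = "stratum",
                                  weights = NULL, bins = 10) {
  data <- tibble::as_tibble(data)
  y <- check_outcome(data, outcome)
  if (!exposure %in% names(data)) {
    abort(paste0("Exposure column `", exposure, "` not found."))
  }
  e <- data[[exposure]]
  if (!is.numeric(e)) abort("`exposure` must be numeric.")
  w <- if (!is.null(design) || !is.null(weights)) {
    add_sampling_weights(data, design, outcome, stratum, weights)$.w
  } else {
    rep(1, nrow(data))
  }
  agg <- tibble::tibble(e = e, w = w, o = w * y) |>
    dplyr::group_by(.data$e) |>
    dplyr::summarise(w = sum(.data$w), o = sum(.data$o), .groups = "drop") |>
    dplyr::arrange(.data$e)
  W <- sum(agg$w)
  cum_mid <- cumsum(agg$w) - agg$w / 2
  g <- pmin(bins, floor(bins * cum_mid / W) + 1L)
  out <- tibble::tibble(g = g, e = agg$e, w = agg$w, o = agg$o) |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(
      exposure = sum(.data$e * .data$w) / sum(.data$w),
      risk = sum(.data$o) / sum(.data$w),
      weight = sum(.data$w),
      low = min(.data$e), high = max(.data$e),
      .groups = "drop"
    )
  if (nrow(out) < 2L) {
    abort("Fewer than 2 nonempty exposure bins; decrease `bins` or check the exposure.")
  }
  out$bin <- seq_len(nrow(out))
  out <- out[, c("bin", "exposure", "risk", "weight", "low", "high")]
  class(out) <- c("lexpit_scatter", class(out))
  out
}

#' @method autoplot lexpit_scatter
#' @export
autoplot.lexpit_scatter <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$exposure, y = .data$risk)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(x = "exposure (bin weighted mean)",
                  y = "crude weighted risk", size = "bin weight",
                  title = "Risk-exposure scatter")
}

#' Compare additive vs multiplicative scale for one exposure
#'
#' Fits three lexpit models — the exposure additive-only, multiplicative-only,
#' and on both scales jointly — and reports each model's coefficients with
#' standard errors, Wald z statistics, and weighted Hosmer-Lemeshow statistic.
#' In the joint model the relative size of the two |z| values indicates which
#' scale carries the effect; no automatic verdict is made. If the joint model
#' is not identified or does not converge, the report degrades to the two
#' single-scale fits and is flagged.
#'
#' @param data Data frame.
#' @param variable Exposure column name to test on both scales.
#' @param additive,multiplicative Background terms for the two blocks (the
#'   tested variable is added on top).
#' @param design Optional [cc_design()].
#' @param gof_groups Groups for the Hosmer-Lemeshow statistic.
#' @param ... Passed on to [lexpit()].
#' @return A `lexpit_scale_check`: tibble of per-model terms with attributes
#'   `gof` (per-model statistic) and `joint_ok`.
#' @export
dual_scale_comparison <- function(data, variable, additive = NULL,
                                  multiplicative = NULL, design = NULL,
                                  gof_groups = 10, ...) {
  if (variable %in% c(additive, multiplicative)) {
    abort("`variable` should not already appear in the background terms.")
  }
  fit_one <- function(add, mult) {
    suppressWarnings(
      tryCatch(lexpit(data, additive = add, multiplicative = mult,
                      design = design, ...),
               error = function(e) NULL)
    )
  }
  fits <- list(
    additive = fit_one(c(additive, variable), multiplicative),
    multiplicative = fit_one(additive, c(multiplicative, variable)),
    both = fit_one(c(additive, variable), c(multiplicative, variable))
  )
  joint_ok <- !is.null(fits$both) && fits$both$converged
  if (!joint_ok) {
    warn("Joint (both-scale) model unavailable or non-converged; reporting single-scale fits only.")
    fits$both <- NULL
  }
  rows <- purrr::imap(fits, function(f, nmod) {
    if (is.null(f)) return(NULL)
    td <- tidy(f)
    td$model <- nmod
    td
  })
  tab <- dplyr::bind_rows(rows) |>
    dplyr::relocate("model")
  gof <- purrr::map_dbl(fits, function(f) {
    if (is.null(f)) return(NA_real_)
    hosmer_lemeshow(f, groups = gof_groups)$statistic
  })
  structure(tab, gof = gof, joint_ok = joint_ok, variable = variable,
            class = c("lexpit_scale_check", class(tab)))
}

#' @export
print.lexpit_scale_check <- function(x, digits = 4, ...) {
  cat(sprintf("Dual-scale comparison for `%s`\n", attr(x, "variable")))
  if (!attr(x, "joint_ok")) cat("(joint both-scale model unavailable)\n")
  gof <- attr(x, "gof")
  cat("Weighted Hosmer-Lemeshow by model (lower = better):\n")
  print(signif(gof, digits))
  cat("\n")
  df <- as.data.frame(x)
  df[] <- lapply(df, function(col) if (is.numeric(col)) signif(col, digits) else col)
  print(df, row.names = FALSE)
  invisible(x)
}
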