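#' Stratified case-control sampling design
#'
#' Describes the study base of a population-based case-control study: sampling
#' strata with their population sizes and sampled-control counts, plus the
#' risk-period length `tau` over which absolute risk is defined. The design is
#' the source of expansion weights: cases are completely ascertained (weight
#' 1) and controls in stratum *j* carry weight \eqn{N_j / n_j}, the inverse of
#' their sampling fraction.
#'
#' @param strata A data frame with columns `stratum` (unique labels),
#'   `population_size` (\eqn{N_j}, persons in the study base) and `n_controls`
#'   (\eqn{n_j}, sampled controls). An optional `n_cases` column records the
#'   ascertained case count.
#' @param tau Positive risk-period length (time units chosen by the user,
#'   e.g. years).
#' @return A `cc_design`: a tibble of strata with `tau` attached as an
#'   attribute (retrievable with `design_tau()`).
#' @examples
#' cc_design(data.frame(
#'   stratum = c("male", "female"),
#'   population_size = c(774221, 851550),
#'   n_controls = c(1617, 499)
#' ), tau = 3)
#' @export
cc_design <- function(strata, tau = 1) {
  strata <- tibble::as_tibble(strata)
  need <- c("stratum", "population_size", "n_controls")
  miss <- setdiff(need, names(strata))
  if (length(miss)) {
    abort(paste0("`strata` is missing column(s): ", toString(miss), "."))
  }
  if (anyDuplicated(strata$stratum)) {
    dup <- unique(strata$stratum[duplicated(strata$stratum)])
    abort(paste0("Stratum labels must be unique; duplicated: ",
                 toString(dup), "."))
  }
  if (any(strata$population_size < 0) || any(strata$n_controls < 0)) {
    abort("`population_size` and `n_controls` must be non-negative.")
  }
  bad <- strata$n_controls > strata$population_size
  if (any(bad)) {
    abort(paste0("`n_controls` exceeds `population_size` in stratum ",
                 toString(strata$stratum[bad]), "."))
  }
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    abort("`tau` must be a single positive number.")
  }
  strata$stratum <- as.character(strata$stratum)
  structure(strata, tau = tau, class = c("cc_design", class(strata)))
}

#' @rdname cc_design
#' @param design A `cc_design`.
#' @export
design_tau <- function(design) {
  attr(design, "tau") %||% 1
}

#' @export
print.cc_design <- function(x, ...) {
  cat(sprintf(
    "<cc_design> %d strata, tau = %g; population %s, controls %s\n",
    nrow(x), design_tau(x),
    format(sum(x$population_size), big.mark = ","),
    format(sum(x$n_controls), big.mark = ",")
  ))
  NextMethod()
}

#' Attach expansion (sampling) weights to a case-control dataset
#'
#' Adds a weight column `.w`: 1 for every case, \eqn{N_j / n_j} for controls
#' in stratum *j*. Row order is preserved. If `weights` names an existing
#' column it is used as-is (with a warning when a design is also supplied),
#' which accommodates designs whose sampling fractions come from elsewhere.
#' An optional `case_weights` column overrides the unit case weight for
#' incomplete ascertainment.
#'
#' @param data Data frame of subjects with a binary outcome column and a
#'   stratum column.
#' @param design A [cc_design()]; may be `NULL` when `weights` is given.
#' @param outcome Name of the 0/1 case-indicator column.
#' @param stratum Name of the stratum-label column.
#' @param weights Optional name of an explicit weight column (wins over the
#'   design).
#' @param case_weights Optional name of a column of case weights.
#' @return `data` as a tibble with a `.w` column appended.
#' @examples
#' d <- cc_design(data.frame(stratum = "m", population_size = 774221,
#'                           n_controls = 1617), tau = 3)
#' dat <- data.frame(case = c(1, 0), stratum = "m")
#' add_sampling_weights(dat, d)
#' @export
add_sampling_weights <- function(data, design = NULL, outcome = "case",
                                 stratum = "stratum", weights = NULL,
                                 case_weights = NULL) {
  data <- tibble::as_tibble(data)
  y <- check_outcome(data, outcome)
  if (!is.null(weights)) {
    if (!weights %in% names(data)) {
      abort(paste0("Weight column `", weights, "` not found."))
    }
    if (!is.null(design)) {
      warn("Both a design and an explicit weight column were given; the explicit column wins.")
    }
    w <- data[[weights]]
    if (any(!is.finite(w) | w <= 0)) abort("Weights must be positive and finite.")
    data$.w <- w
    return(data)
  }
  if (is.null(design)) {
    abort("Either `design` or `weights` must be supplied.")
  }
  if (!stratum %in% names(data)) {
    abort(paste0("Stratum column `", stratum, "` not found."))
  }
  s <- as.character(data[[stratum]])
  unknown <- setdiff(unique(s), design$stratum)
  if (length(unknown)) {
    abort(paste0("Stratum label(s) not in the design: ", toString(unknown), "."))
  }
  unused <- setdiff(design$stratum, unique(s))
  if (length(unused)) {
    inform(paste0("Design stratum(s) with no observations ignored: ",
                  toString(unused), "."))
  }
  idx <- match(s, design$stratum)
  nj <- design$n_controls[idx]
  Nj <- design$population_size[idx]
  ctrl <- y == 0
  bad <- ctrl & nj == 0
  if (any(bad)) {
    abort(paste0("Control(s) observed in stratum ",
                 toString(unique(s[bad])),
                 " but the design records 0 sampled controls there."))
  }
  w <- rep(1, nrow(data))
  w[ctrl] <- Nj[ctrl] / nj[ctrl]
  if (!is.null(case_weights)) {
    if (!case_weights %in% names(data)) {
      abort(paste0("Case-weight column `", case_weights, "` not found."))
    }
    w[!ctrl] <- data[[case_weights]][!ctrl]
  }
  data$.w <- w
  data
}

#' Weighted expansion totals by stratum
#'
#' Sums control weights and counts cases per stratum. With design-derived
#' weights the weighted control total reconstructs the stratum population
#' exactly (\eqn{(N_j/n_j) \cdot n_j = N_j}), i.e. the sample expanded to the
#' study base.
#'
#' @inheritParams add_sampling_weights
#' @param weights Name of the weight column (default `.w` from
#'   [add_sampling_weights()]).
#' @return A tibble with one row per stratum: `n_cases`, `n_controls`,
#'   `weighted_controls`, `weighted_total`.
#' @export
expansion_totals <- function(data, outcome = "case", stratum = "stratum",
                             weights = ".w") {
  data <- tibble::as_tibble(data)
  y <- check_outcome(data, outcome)
  if (!weights %in% names(data)) {
    abort(paste0("Weight column `", weights, "` not found; run add_sampling_weights() first."))
  }
  tibble::tibble(
    stratum = as.character(data[[stratum]]),
    y = y,
    w = data[[weights]]
  ) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n_cases = sum(.data$y == 1),
      n_controls = sum(.data$y == 0),
      weighted_controls = sum(.data$w[.data$y == 0]),
      weighted_total = sum(.data$w),
      .groups = "drop"
    )
}

# validate and return the 0/1 outcome vector
check_outcome <- function(data, outcome) {
  if (!outcome %in% names(data)) {
    abort(paste0("Outcome column `", outcome, "` not found."))
  }
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  vals <- unique(y[!is.na(y)])
  if (!is.numeric(y) || length(setdiff(vals, c(0, 1)))) {
    abort(paste0("Outcome `", outcome, "` must be coded 0/1; found values {",
                 toString(sort(vals)), "}."))
  }
  y
}
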