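#' Fit a lexpit (additive-multiplicative absolute risk) regression
#'
#' Maximizes the sampling-weighted pseudo-log-likelihood of the lexpit model
#' \deqn{R(x, z) = \beta'x + \mathrm{expit}(\gamma_0 + \gamma'z)}
#' subject to the feasibility constraints \eqn{0 \le R \le 1} at every unique
#' observed covariate pattern. For a population-based case-control study,
#' supply a [cc_design()]: cases get weight 1 (complete ascertainment) and
#' controls get expansion weights \eqn{N_j/n_j}, so fitted risks are absolute
#' risks in the study base over the design's risk period `tau`. With no design
#' and unit weights the fit is the exact cohort maximum likelihood.
#'
#' Additive coefficients are risk differences per unit of covariate;
#' exponentiated multiplicative coefficients are residual odds ratios. The
#' optimizer is deterministic: a log-barrier interior-point method with damped
#' Newton steps, started from a weighted logistic fit of the multiplicative
#' block (`beta = 0`), followed by a feasibility-guarded Newton polish.
#'
#' @param data Data frame of subjects.
#' @param additive Character vector of additive term labels (interactions as
#'   `"a:b"`; factors expand against their reference level). May be `NULL`.
#' @param multiplicative Character vector of multiplicative term labels; the
#'   baseline log-odds intercept `gamma0` is always included. May be `NULL`.
#' @param design A [cc_design()], or `NULL` for cohort data / explicit weights.
#' @param outcome,stratum Column names of the 0/1 case indicator and the
#'   stratum label.
#' @param weights Optional name of an explicit weight column (overrides the
#'   design, with a warning).
#' @param tau Risk-period length; defaults to the design's `tau`, else 1.
#' @param center,scale Optional named numeric vectors: each named covariate is
#'   shifted by `center` and divided by `scale` before model matrices are
#'   built (e.g. `center = c(age = 60)`, `scale = c(pack_years = 10)`). The
#'   applied offsets are recorded in the fit and reported.
#' @param variance One of `"linearized"` (influence-function, the default),
#'   `"bootstrap"` (stratified resampling) or `"none"`.
#' @param boot_reps,seed Bootstrap replicate count and RNG seed (bootstrap
#'   variance only).
#' @param fpc Apply the finite-population correction `1 - n_j/N_j` to control
#'   strata in the linearized variance (off by default; population-based
#'   sampling fractions are typically tiny).
#' @param control A [lexpit_control()] list of optimizer settings.
#' @return An object of class `lexpit` with `coef()`, `vcov()`, `predict()`,
#'   `fitted()`, `logLik()`, `confint()`, `tidy()`, `glance()`, `summary()`
#'   and `autoplot()` methods.
#' @examples
#' design <- cc_design(data.frame(
#'   stratum = c("male", "female"),
#'   population_size = c(774221, 851550),
#'   n_controls = c(1617, 499)
#' ), tau = 3)
#' dat <- eagle_gender_data()
#' fit <- lexpit(dat, additive = "female", design = design)
#' coef(fit)
#' risk_difference_report(fit, scale = 1000)
#' @export
lexpit <- function(data, additive = NULL, multiplicative = NULL, design = NULL,
                   outcome = "case", stratum = "stratum", weights = NULL,
                   tau = NULL, center = NULL, scale = NULL,
                   variance = c("linearized", "bootstrap", "none"),
                   boot_reps = 500L, seed = NULL, fpc = FALSE,
                   control = lexpit_control()) {
  variance <- match.arg(variance)
  cl <- match.call()
  both <- intersect(additive, multiplicative)
  if (length(both)) {
    warn(paste0("Term(s) in both blocks (", toString(both),
                "): a dual-scale effect is generally weakly identified and is meant for dual_scale_comparison()."))
  }
  data <- tibble::as_tibble(data)
  if (is.null(tau)) tau <- if (!is.null(design)) design_tau(design) else 1

  all_terms <- c(additive, multiplicative)
  vars <- unique(c(outcome,
                   if (!is.null(design) && is.null(weights)) stratum,
                   if (!is.null(weights)) weights,
                   if (length(all_terms)) all.vars(reformulate(all_terms))))
  miss <- setdiff(vars, names(data))
  if (length(miss)) abort(paste0("Column(s) not found: ", toString(miss), "."))

  cc <- stats::complete.cases(data[vars])
  if (any(!cc)) {
    inform(sprintf("Dropped %d row(s) with missing values (complete-case analysis).",
                   sum(!cc)))
    data <- data[cc, , drop = FALSE]
  }
  if (!nrow(data)) abort("No complete cases left.")

  y <- check_outcome(data, outcome)
  if (!any(y == 1) || !any(y == 0)) {
    abort("Need at least one case and one control.")
  }

  has_stratum <- stratum %in% names(data)
  if (is.null(weights) && is.null(design)) {
    w <- rep(1, nrow(data))
    wdat <- data
  } else {
    wdat <- add_sampling_weights(data, design = design, outcome = outcome,
                                 stratum = stratum, weights = weights)
    w <- wdat$.w
  }

  pdat <- apply_center_scale(data, center, scale)
  blocks <- build_blocks(pdat, additive, multiplicative)
  X <- blocks$X
  Z <- blocks$Z
  for (M in list(X, Z)) {
    if (ncol(M)) {
      const <- apply(M, 2, function(col) diff(range(col)) == 0)
      if (any(const)) {
        abort(paste0("Covariate(s) constant across the sample: ",
                     toString(colnames(M)[const]), "."))
      }
    }
  }
  xlev <- xlevels_of(pdat, c(additive, multiplicative))

  start <- c(rep(0, ncol(X)), start_values(y, Z, w))
  eng <- lexpit_engine(y, X, Z, w, start = start, control = control)
  if (!eng$converged) {
    warn(paste0("lexpit fit ", eng$message))
  }
  if (length(eng$active)) {
    warn(sprintf(
      "%d covariate pattern(s) have fitted risk at the [0,1] boundary; Wald inference for boundary parameters is unreliable.",
      length(eng$active)))
  }

  px <- ncol(X); pz <- ncol(Z)
  nm <- c(colnames(X), "(Intercept)", colnames(Z))
  theta <- setNames(eng$theta, nm)
  raw_fitted <- risk_eval(eng$theta, X, Z)$r

  fit <- structure(list(
    coefficients = theta,
    blocks = list(additive = colnames(X), multiplicative = colnames(Z)),
    terms = list(additive = additive, multiplicative = multiplicative),
    loglik = eng$loglik,
    loglik_start = eng$loglik_start,
    gradient = eng$gradient,
    hessian = eng$hessian,
    converged = eng$converged,
    n_iter = eng$n_iter,
    message = eng$message,
    active_constraints = eng$active,
    pattern_risks = eng$pattern_risks,
    n_patterns = nrow(eng$patterns$Xu),
    fitted = pmin(pmax(raw_fitted, 0), 1),
    fitted_raw = raw_fitted,
    y = y,
    X = X,
    Z = Z,
    w = w,
    stratum = if (has_stratum) as.character(data[[stratum]]) else NULL,
    design = design,
    cohort = is.null(design) && is.null(weights),
    tau = tau,
    center = center,
    scale = scale,
    xlev = xlev,
    n = nrow(data),
    n_cases = sum(y == 1),
    weight_total = sum(w),
    variance = "none",
    vcov = NULL,
    call = cl
  ), class = "lexpit")

  if (variance == "linearized" && fit$converged) {
    fit$vcov <- tryCatch(linearized_vcov(fit, fpc = fpc),
                         error = function(e) {
                           warn(paste0("Linearized variance unavailable: ",
                                       conditionMessage(e)))
                           NULL
                         })
    if (!is.null(fit$vcov)) fit$variance <- "linearized"
  } else if (variance == "bootstrap" && fit$converged) {
    fit$vcov <- boot_vcov(fit, reps = boot_reps, seed = seed)
    fit$variance <- "bootstrap"
  }
  fit
}

apply_center_scale <- function(data, center, scale) {
  for (nm in names(center)) {
    if (!nm %in% names(data)) abort(paste0("`center` names unknown column `", nm, "`."))
    data[[nm]] <- data[[nm]] - center[[nm]]
  }
  for (nm in names(scale)) {
    if (!nm %in% names(data)) abort(paste0("`scale` names unknown column `", nm, "`."))
    if (scale[[nm]] == 0) abort("`scale` entries must be nonzero.")
    data[[nm]] <- data[[nm]] / scale[[nm]]
  }
  data
}

xlevels_of <- function(data, terms_chr) {
  if (!length(terms_chr)) return(NULL)
  vars <- all.vars(reformulate(terms_chr))
  lv <- lapply(data[intersect(vars, names(data))], function(col) {
    if (is.factor(col)) levels(col) else if (is.character(col)) unique(col) else NULL
  })
  lv[!vapply(lv, is.null, logical(1))]
}

# weighted logistic start for the multiplicative block; beta = 0
start_values <- function(y, Z, w) {
  g <- tryCatch({
    df <- data.frame(y = y)
    f <- if (ncol(Z)) {
      df <- cbind(df, as.data.frame(Z))
      names(df) <- c("y", paste0("V", seq_len(ncol(Z))))
      reformulate(names(df)[-1L], response = "y")
    } else y ~ 1
    suppressWarnings(glm(f, data = df, family = quasibinomial(),
                         weights = w))
  }, error = function(e) NULL)
  if (is.null(g) || !g$converged) {
    warn("Weighted logistic start failed (possible separation or degenerate multiplicative block); starting from the marginal rate.")
    return(c(qlogis(min(max(weighted.mean(y, w), 1e-6), 1 - 1e-6)),
             numeric(ncol(Z))))
  }
  co <- coef(g)
  if (any(!is.finite(co))) co[!is.finite(co)] <- 0
  unname(co)
}
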