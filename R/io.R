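# Reading study tables and round-tripping fitted models.

#' Read a sampling-design table
#'
#' Delimited text (comma or tab, sniffed from the header line) with columns
#' `stratum`, `population_size`, `n_controls`; validated on load.
#'
#' @param path File path.
#' @param tau Risk-period length to attach.
#' @return A [cc_design()].
#' @export
read_design_table <- function(path, tau = 1) {
  cc_design(read_delim_sniff(path), tau = tau)
}

#' Read a subject-level table
#'
#' Delimited text with a header. The outcome column must be coded 0/1 (a
#' named error otherwise). Character covariates become factors whose reference
#' level is the first observed (overridable via `reference`); ordinal
#' variables listed in `trend` are converted to 0-based numeric trend codes in
#' the stated level order. Indicator expansion against the recorded reference
#' happens inside [lexpit()] when model matrices are built.
#'
#' @param path File path.
#' @param outcome Outcome column name.
#' @param trend Named list: column -> character vector of levels in increasing
#'   order; the column is recoded 0, 1, 2, ...
#' @param reference Named character vector: column -> reference level.
#' @return A tibble.
#' @export
read_subject_table <- function(path, outcome = "case", trend = list(),
                               reference = character()) {
  dat <- read_delim_sniff(path)
  check_outcome(dat, outcome)
  for (nm in names(trend)) {
    if (!nm %in% names(dat)) abort(paste0("`trend` names unknown column `", nm, "`."))
    lev <- trend[[nm]]
    bad <- setdiff(unique(stats::na.omit(dat[[nm]])), lev)
    if (length(bad)) {
      abort(paste0("Column `", nm, "` has value(s) outside its trend levels: ",
                   toString(bad), "."))
    }
    dat[[nm]] <- match(dat[[nm]], lev) - 1L
  }
  for (nm in setdiff(names(dat), c(outcome, names(trend)))) {
    if (is.character(dat[[nm]]) && nm != "stratum") {
      lv <- unique(stats::na.omit(dat[[nm]]))
      ref <- reference[nm]
      if (!is.na(ref)) {
        if (!ref %in% lv) {
          abort(paste0("Reference level `", ref, "` not found in column `", nm, "`."))
        }
        lv <- c(ref, setdiff(lv, ref))
      }
      dat[[nm]] <- factor(dat[[nm]], levels = lv)
    }
  }
  dat
}

read_delim_sniff <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Write / read a fitted lexpit model as JSON
#'
#' A machine-readable serialization (coefficients at full double precision,
#' covariance, convergence metadata, blocks, tau, centering). Re-reading
#' reproduces the coefficients bit-exactly.
#'
#' @param fit A [lexpit()] fit.
#' @param path Output path (`.json`).
#' @return `write_lexpit` returns `path` invisibly; `read_lexpit` returns a
#'   list mirroring the stored fields, with `coefficients` and `vcov`
#'   restored as named numeric structures.
#' @export
write_lexpit <- function(fit, path) {
  stopifnot(inherits(fit, "lexpit"))
  obj <- list(
    coefficients = as.list(fit$coefficients),
    blocks = fit$blocks,
    vcov = if (!is.null(fit$vcov)) unclass(fit$vcov[seq_len(nrow(fit$vcov)),
                                                    , drop = FALSE]),
    variance = fit$variance,
    loglik = fit$loglik,
    converged = fit$converged,
    n_iter = fit$n_iter,
    message = fit$message,
    n = fit$n,
    n_cases = fit$n_cases,
    weight_total = fit$weight_total,
    n_active_constraints = length(fit$active_constraints),
    tau = fit$tau,
    center = as.list(fit$center),
    scale = as.list(fit$scale)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_lexpit
#' @export
read_lexpit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  if (!is.null(obj$vcov)) {
    m <- as.matrix(obj$vcov)
    dimnames(m) <- list(names(obj$coefficients), names(obj$coefficients))
    obj$vcov <- m
  }
  obj
}
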