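# Constrained maximum pseudo-likelihood engine.
#
# Parameter vector theta = (beta, gamma0, gamma). The weighted
# pseudo-log-likelihood
#   l(theta) = sum_ij w_ij [ y_ij logit(R_ij) + log(1 - R_ij) ]
#            = sum_ij w_ij [ y_ij log R_ij + (1 - y_ij) log(1 - R_ij) ]
# is maximized over the feasible region F = { 0 <= R(x,z) <= 1 at every
# unique observed covariate pattern }. A log-barrier on the pattern risks
# keeps iterates strictly feasible; damped Newton solves each barrier
# subproblem; a guarded Newton polish removes the barrier bias when the
# optimum is interior.

#' Weighted pseudo-log-likelihood of the lexpit model
#'
#' Returns \eqn{\sum_{ij} w_{ij} [y_{ij} \log R_{ij} + (1-y_{ij})
#' \log(1-R_{ij})]} with \eqn{R = \beta'x + \mathrm{expit}(\gamma_0 +
#' \gamma'z)}. By convention the value is `-Inf` (never an error) whenever any
#' observation's risk falls outside the open interval (0, 1), which signals an
#' infeasible point to the optimizer. With unit weights this is the exact
#' Bernoulli log-likelihood of a cohort sample.
#'
#' @inheritParams predict_risk
#' @param y 0/1 outcome vector.
#' @param w Positive weights (default all 1).
#' @return A single number, possibly `-Inf`.
#' @export
lexpit_loglik <- function(beta, gamma0, gamma, y, x = NULL, z = NULL,
                          w = rep(1, length(y))) {
  r <- predict_risk(beta, gamma0, gamma, x, z)
  if (length(r) == 1L) r <- rep(r, length(y))
  if (length(r) != length(y)) {
    abort("Risk and outcome lengths differ; check covariate dimensions.")
  }
  if (any(r <= 0 | r >= 1)) return(-Inf)
  sum(w * (y * log(r) + (1 - y) * log1p(-r)))
}

#' Feasibility constraints at the observed covariate patterns
#'
#' Deduplicates the observed additive/multiplicative covariate patterns. Each
#' unique pattern contributes the constraint pair
#' \eqn{0 \le \beta'x + \mathrm{expit}(\gamma_0 + \gamma'z) \le 1} to the
#' feasible region of the constrained maximization.
#'
#' @param data Data frame of observations.
#' @param additive,multiplicative Character vectors of term labels (as in
#'   [lexpit()]).
#' @return A tibble with one row per unique pattern, a `pattern` id, the
#'   covariate columns, and `n_obs`, the number of observations sharing it.
#' @export
feasible_region <- function(data, additive = NULL, multiplicative = NULL) {
  if (nrow(as.data.frame(data)) == 0L) abort("`data` is empty.")
  mm <- build_blocks(data, additive, multiplicative)
  U <- unique_patterns(mm$X, mm$Z)
  out <- tibble::as_tibble(as.data.frame(cbind(U$Xu, U$Zu)))
  names(out) <- c(colnames(mm$X), colnames(mm$Z))
  dplyr::bind_cols(tibble::tibble(pattern = seq_len(nrow(out))), out,
                   tibble::tibble(n_obs = tabulate(U$map, nrow(out))))
}

# design matrices for the two blocks; factors expand against a reference level
build_blocks <- function(data, additive, multiplicative, xlev = NULL) {
  data <- as.data.frame(data)
  one <- function(terms_chr) {
    if (is.null(terms_chr) || !length(terms_chr)) {
      return(matrix(numeric(0), nrow = nrow(data), ncol = 0L))
    }
    f <- reformulate(terms_chr, intercept = TRUE)
    mf <- model.frame(f, data, na.action = na.pass, xlev = xlev)
    model.matrix(f, mf)[, -1L, drop = FALSE]
  }
  list(X = one(additive), Z = one(multiplicative))
}

unique_patterns <- function(X, Z) {
  P <- cbind(X, Z)
  if (ncol(P) == 0L) {
    return(list(Xu = X[1L, , drop = FALSE], Zu = Z[1L, , drop = FALSE],
                map = rep(1L, nrow(X))))
  }
  key <- do.call(paste, c(lapply(seq_len(ncol(P)), function(j) P[, j]),
                          sep = "\r"))
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(Xu = X[first, , drop = FALSE], Zu = Z[first, , drop = FALSE], map = map)
}

# --- internal likelihood pieces on prebuilt matrices ------------------------

split_theta <- function(theta, px, pz) {
  list(beta = theta[seq_len(px)],
       gamma0 = theta[px + 1L],
       gamma = theta[px + 1L + seq_len(pz)])
}

risk_eval <- function(theta, X, Z) {
  px <- ncol(X); pz <- ncol(Z)
  th <- split_theta(theta, px, pz)
  eta <- th$gamma0 + (if (pz) drop(Z %*% th$gamma) else 0)
  p <- plogis(eta)
  r <- (if (px) drop(X %*% th$beta) else 0) + p
  list(r = r, p = p)
}

# negative loglik, gradient and Hessian; NULL pieces skipped for speed
nll_parts <- function(theta, y, X, Z, w, hess = TRUE) {
  px <- ncol(X); pz <- ncol(Z)
  re <- risk_eval(theta, X, Z)
  r <- re$r; p <- re$p
  if (any(r <= 0 | r >= 1)) return(list(f = Inf))
  f <- -sum(w * (y * log(r) + (1 - y) * log1p(-r)))
  pq <- p * (1 - p)
  A <- cbind(X, pq, if (pz) Z * pq)
  u <- w * (y - r) / (r * (1 - r))
  g <- -colSums(A * u)
  out <- list(f = f, g = g, r = r, p = p, A = A, u = u)
  if (hess) {
    c1 <- w * (y / r^2 + (1 - y) / (1 - r)^2)
    H <- crossprod(A, A * c1)
    # curvature of the expit itself (second derivative of R in the gamma block)
    V <- cbind(1, Z)
    t2 <- u * pq * (1 - 2 * p)
    idx <- (px + 1L):(px + 1L + pz)
    H[idx, idx] <- H[idx, idx] - crossprod(V, V * t2)
    out$H <- H
  }
  out
}

barrier_parts <- function(theta, Xu, Zu, hess = TRUE) {
  px <- ncol(Xu); pz <- ncol(Zu)
  re <- risk_eval(theta, Xu, Zu)
  r <- re$r; p <- re$p
  if (any(r <= 0 | r >= 1)) return(list(f = Inf))
  f <- -sum(log(r) + log1p(-r))
  pq <- p * (1 - p)
  A <- cbind(Xu, pq, if (pz) Zu * pq)
  u1 <- -1 / r + 1 / (1 - r)
  g <- colSums(A * u1)
  out <- list(f = f, g = g)
  if (hess) {
    c1 <- 1 / r^2 + 1 / (1 - r)^2
    H <- crossprod(A, A * c1)
    V <- cbind(1, Zu)
    t2 <- u1 * pq * (1 - 2 * p)
    idx <- (px + 1L):(px + 1L + pz)
    H[idx, idx] <- H[idx, idx] + crossprod(V, V * t2)
    out$H <- H
  }
  out
}

feasible_at <- function(theta, Xu, Zu) {
  r <- risk_eval(theta, Xu, Zu)$r
  all(r > 0 & r < 1)
}

# damped Newton minimization of f(theta) = nll + mu * barrier; stops on the
# Newton decrement g' H^{-1} g (scale-invariant), never on raw gradient size
newton_solve <- function(theta, y, X, Z, w, Xu, Zu, mu, max_iter,
                         dtol = 1e-15) {
  fval <- function(th) {
    a <- nll_parts(th, y, X, Z, w, hess = FALSE)
    if (!is.finite(a$f)) return(Inf)
    b <- if (mu > 0) barrier_parts(th, Xu, Zu, hess = FALSE) else list(f = 0)
    a$f + mu * b$f
  }
  iter <- 0L
  f_cur <- fval(theta)
  g_max <- Inf
  decrement <- Inf
  repeat {
    iter <- iter + 1L
    a <- nll_parts(theta, y, X, Z, w, hess = TRUE)
    if (mu > 0) {
      b <- barrier_parts(theta, Xu, Zu, hess = TRUE)
      g <- a$g + mu * b$g
      H <- a$H + mu * b$H
    } else {
      g <- a$g
      H <- a$H
    }
    g_max <- max(abs(g))
    ridge <- 0
    repeat {
      ch <- tryCatch(chol(H + diag(ridge, nrow(H))), error = function(e) NULL)
      if (!is.null(ch)) break
      ridge <- max(ridge * 10, 1e-8 * (1 + max(abs(diag(H)))))
    }
    step <- -backsolve(ch, forwardsolve(t(ch), g))
    decrement <- -sum(g * step) / 2      # ~ expected objective decrease
    if (!is.finite(decrement) || decrement <= dtol * (1 + abs(f_cur))) break
    t_ls <- 1
    improved <- FALSE
    for (k in 1:40) {
      th_new <- theta + t_ls * step
      f_new <- fval(th_new)
      if (is.finite(f_new) && f_new <= f_cur + 1e-14 * (1 + abs(f_cur))) {
        theta <- th_new
        improved <- TRUE
        f_cur <- f_new
        break
      }
      t_ls <- t_ls / 2
    }
    if (!improved || iter >= max_iter) break
  }
  list(theta = theta, f = f_cur, g_max = g_max, decrement = decrement,
       iter = iter)
}

# full constrained fit on prebuilt matrices; start must be strictly feasible
lexpit_engine <- function(y, X, Z, w, start, control = lexpit_control()) {
  U <- unique_patterns(X, Z)
  Xu <- U$Xu; Zu <- U$Zu
  m <- nrow(Xu)
  theta <- start
  if (!feasible_at(theta, Xu, Zu)) {
    abort("Starting values are infeasible; supply a feasible start.")
  }
  l_start <- -nll_parts(theta, y, X, Z, w, hess = FALSE)$f
  scale0 <- max(1, abs(l_start))
  mu <- control$mu0 * scale0 / m
  mu_min <- 1e-12 * scale0 / m
  total_iter <- 0L
  l_prev <- l_start
  rel_change <- Inf
  while (mu > mu_min) {
    ns <- newton_solve(theta, y, X, Z, w, Xu, Zu, mu,
                       max_iter = control$inner_iter)
    theta <- ns$theta
    total_iter <- total_iter + ns$iter
    l_cur <- -nll_parts(theta, y, X, Z, w, hess = FALSE)$f
    rel_change <- abs(l_cur - l_prev) / (1 + abs(l_cur))
    l_prev <- l_cur
    mu <- mu * control$mu_shrink
    if (total_iter > control$max_iter) break
  }
  # polish: barrier-free Newton with feasibility-guarded line search
  ns <- newton_solve(theta, y, X, Z, w, Xu, Zu, mu = 0,
                     max_iter = control$inner_iter)
  decrement <- ns$decrement
  if (feasible_at(ns$theta, Xu, Zu)) {
    theta <- ns$theta
    total_iter <- total_iter + ns$iter
  }
  fin <- nll_parts(theta, y, X, Z, w, hess = TRUE)
  ru <- risk_eval(theta, Xu, Zu)$r
  active <- which(ru <= control$active_tol | ru >= 1 - control$active_tol)
  g_max <- max(abs(fin$g))
  converged <- (is.finite(decrement) &&
                  decrement <= control$grad_tol * (1 + abs(fin$f))) ||
    (g_max <= control$grad_tol * max(1, abs(fin$f))) ||
    (length(active) > 0 && rel_change < control$loglik_tol)
  message_txt <- if (converged) {
    if (length(active)) {
      sprintf("converged with %d active feasibility constraint(s)", length(active))
    } else "converged (interior optimum)"
  } else {
    sprintf("did not converge: Newton decrement %.2e, max |gradient| %.2e after %d iterations",
            decrement, g_max, total_iter)
  }
  list(
    theta = theta,
    decrement = decrement,
    loglik = -fin$f,
    loglik_start = l_start,
    gradient = -fin$g,
    hessian = -fin$H,          # Hessian of the loglik (negative definite)
    converged = converged,
    n_iter = total_iter,
    message = message_txt,
    active = active,
    pattern_risks = ru,
    patterns = list(Xu = Xu, Zu = Zu, map = U$map)
  )
}

#' Control parameters for the lexpit optimizer
#'
#' @param grad_tol Convergence tolerance on the maximum component of the
#'   pseudo-log-likelihood gradient, relative to `max(1, |loglik|)`.
#' @param loglik_tol Relative pseudo-log-likelihood change below which a
#'   boundary solution is declared converged.
#' @param max_iter Cap on the total number of Newton iterations.
#' @param inner_iter Newton iteration cap per barrier subproblem.
#' @param mu0 Initial barrier weight, scaled by `|loglik|/m` for `m` unique
#'   covariate patterns.
#' @param mu_shrink Barrier reduction factor per stage.
#' @param active_tol Fitted pattern risks within this distance of 0 or 1 are
#'   reported as active constraints.
#' @return A named list of class `lexpit_control`.
#' @export
lexpit_control <- function(grad_tol = 1e-9, loglik_tol = 1e-9, max_iter = 500L,
                           inner_iter = 60L, mu0 = 1e-2, mu_shrink = 0.1,
                           active_tol = 1e-6) {
  structure(list(grad_tol = grad_tol, loglik_tol = loglik_tol,
                 max_iter = max_iter, inner_iter = inner_iter, mu0 = mu0,
                 mu_shrink = mu_shrink, active_tol = active_tol),
            class = "lexpit_control")
}
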