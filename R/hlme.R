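#' Maximum-likelihood nested random-intercept mixed model
#'
#' Fits, by direct maximization of the marginal Gaussian likelihood, the
#' linear mixed-effects model
#' \deqn{y = X\beta + \sum_l Z_l u_l + \varepsilon,\qquad
#'       u_l \sim N(0, \sigma^2_l I),\ \varepsilon \sim N(0, \sigma^2_0 I),}
#' where the random-intercept levels are strictly nested (for the 2D
#' migration design: laboratory / person / experiment / technical replicate
#' / cell, with the time-point residual as innermost, "temporal" variance).
#' The fixed part is an intercept plus, optionally, a two-level condition
#' indicator (treatment effect `delta`).
#'
#' The likelihood is evaluated in one bottom-up sweep over the nesting
#' tree: each unit's observations are collapsed into sufficient statistics
#' (`1'V^-1 1`, `X'V^-1 1`, `X'V^-1 y`, `X'V^-1 X`, `y'V^-1 y`, `log|V|`)
#' and a rank-one Woodbury update absorbs that unit's intercept variance,
#' so one evaluation costs O(n) regardless of how unbalanced the design
#' is.  Fixed effects are profiled out; the variances are optimized on the
#' log scale by a quasi-Newton method from method-of-moments starting
#' values, and components whose unconstrained optimum collapses to the
#' boundary are reported as exactly zero.  The fit is deterministic: no
#' randomness, fixed starting values.
#'
#' Level identifiers are interpreted locally, as in nested grouping-factor
#' notation: the unit key at level *l* is the tuple of all level columns
#' from the outermost down to *l*, so e.g. "person P1" in two different
#' labs denotes two different units.  Replicate identifiers must therefore
#' be unique within an experiment (the simulator embeds the condition
#' label in the replicate id for this reason).
#'
#' @param table Long-format observation table.
#' @param response Name of the numeric response column.
#' @param levels Ordered (outermost to innermost) random-intercept level
#'   column names.
#' @param fixed Optional name of a two-level condition column to include
#'   as a fixed effect; its first sorted value is the reference.
#' @param reml If `TRUE` use restricted maximum likelihood instead of ML
#'   (offered for sensitivity checks; ML is the default and the method of
#'   record).
#' @param control List of optimizer settings, see [hlme_control()].
#' @return An object of class `migvar_hlme` with elements `beta0`, `delta`
#'   (NA when no fixed condition term), `sigma2` (named vector over levels
#'   plus `"residual"`), `loglik`, `convergence` and bookkeeping needed by
#'   [predict_random_intercepts()] and [remove_batch_effects()].
#' @seealso [predict_random_intercepts()], [decompose_variance()]
#' @examples
#' sim <- simulate_migration_study(design_spec(n_cells = 3, n_timepoints = 6))
#' fit <- fit_nested_lme(sim$table, "ics", fixed = "condition")
#' fit
#' @export
fit_nested_lme <- function(table, response,
                           levels = c("lab", "person", "experiment",
                                      "replicate", "cell"),
                           fixed = NULL, reml = FALSE,
                           control = hlme_control()) {
  assert_columns(table, c(response, levels, fixed), "observation table")
  y <- table[[response]]
  if (!is.numeric(y) || anyNA(y)) {
    mv_schema_stop(sprintf("response column `%s` must be numeric with no NA",
                           response))
  }
  n <- length(y)
  if (n < 2L) mv_stop("need at least 2 observations",
                      class = "migvar_parameter_error")
  for (lv in levels) {
    if (anyNA(table[[lv]])) {
      mv_stop(sprintf("level column `%s` contains NA: hierarchy keys must be complete",
                      lv), class = "migvar_structure_error")
    }
  }

  # fixed-effects design
  if (!is.null(fixed)) {
    cond <- as.character(table[[fixed]])
    lev <- sort(unique(cond))
    if (length(lev) != 2L) {
      mv_stop(sprintf(
        "fixed condition column `%s` must have exactly 2 levels (found %d): the treatment effect is undefined otherwise",
        fixed, length(lev)), class = "migvar_fixed_error")
    }
    X <- cbind(1, as.numeric(cond == lev[2L]))
    colnames(X) <- c("(Intercept)", paste0(fixed, lev[2L]))
  } else {
    lev <- NULL
    X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  }
  p <- ncol(X)

  # nested unit structure
  L <- length(levels)
  ids <- lapply(seq_len(L), function(l) path_id(table, levels[seq_len(l)]))
  names(ids) <- levels
  units <- lapply(ids, unique)
  idx <- mapply(function(id, u) match(id, u), ids, units, SIMPLIFY = FALSE)
  n_units <- lengths(units)
  if (any(n_units < 2L)) {
    warning(sprintf("fewer than 2 units at level(s): %s",
                    paste(levels[n_units < 2L], collapse = ", ")),
            call. = FALSE)
  }
  if (!is.null(fixed)) {
    # condition must be constant within innermost units
    first <- !duplicated(ids[[L]])
    cond_by_unit <- cond[first][idx[[L]]]
    if (any(cond_by_unit != cond)) {
      mv_stop(sprintf(
        "condition `%s` varies within level `%s` units: not a nested design",
        fixed, levels[L]), class = "migvar_structure_error")
    }
  }

  # grouping chain: observations -> innermost units -> ... -> outermost
  groups <- vector("list", L)
  groups[[L]] <- idx[[L]]
  if (L > 1L) {
    for (l in seq_len(L - 1L)) {
      first_child <- !duplicated(ids[[l + 1L]])
      groups[[l]] <- idx[[l]][first_child]
    }
  }

  st <- list(n = n, p = p, L = L, y = y, X = X, groups = groups)
  ols <- stats::lm.fit(X, y)
  r <- ols$residuals
  vtot <- sum(r^2) / max(n - p, 1L)

  # degenerate: response exactly linear in the fixed part
  if (vtot < 1e-24 * max(1, mean(y^2))) {
    sigma2 <- c(stats::setNames(rep(0, L), levels), residual = 0)
    fit <- list(beta = ols$coefficients, sigma2 = sigma2, loglik = Inf,
                convergence = list(converged = TRUE, degenerate = TRUE,
                                   iterations = 0L, message = "degenerate fit: zero residual variance"))
  } else {
    fit <- hlme_optimize(st, vtot, reml = reml, control = control)
    names(fit$sigma2) <- c(levels, "residual")
  }

  beta <- fit$beta
  structure(list(
    beta0 = unname(beta[1L]),
    delta = if (p == 2L) unname(beta[2L]) else NA_real_,
    beta = beta,
    sigma2 = fit$sigma2,
    loglik = fit$loglik,
    reml = reml,
    convergence = fit$convergence,
    response = response,
    levels = levels,
    fixed = fixed,
    fixed_levels = lev,
    n = n,
    internals = list(y = y, X = X, ids = ids, units = units, idx = idx,
                     groups = groups)
  ), class = "migvar_hlme")
}

#' Optimizer control for [fit_nested_lme()]
#'
#' @param max_iter Maximum quasi-Newton iterations.
#' @param rel_tol Relative convergence tolerance on the objective.
#' @param abs_tol Absolute convergence tolerance on the objective
#'   (log-likelihood scale).
#' @param boundary_tol Variance components whose estimate falls below
#'   `boundary_tol` times the response variance are candidates for the
#'   boundary: each is tested against an exact-zero refit (smallest
#'   first) and reported as 0 only when the profiled likelihood does not
#'   measurably prefer the interior value.
#' @return A list of settings.
#' @export
hlme_control <- function(max_iter = 500L, rel_tol = 1e-12, abs_tol = 1e-8,
                         boundary_tol = 1e-2) {
  list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
       abs_tol = abs_tol, boundary_tol = boundary_tol)
}

# ---- likelihood machinery ----------------------------------------------

# Sufficient-statistic columns: s, m, q, t[p], b[p], A[p(p+1)/2]; the
# log-determinant accumulates separately as a scalar.
hlme_base_stats <- function(st) {
  X <- st$X; y <- st$y; p <- st$p
  cols <- list(s = rep(1, st$n), m = y, q = y * y)
  for (j in seq_len(p)) cols[[paste0("t", j)]] <- X[, j]
  for (j in seq_len(p)) cols[[paste0("b", j)]] <- X[, j] * y
  for (j in seq_len(p)) for (k in j:p) {
    cols[[paste0("A", j, k)]] <- X[, j] * X[, k]
  }
  do.call(cbind, cols)
}

# Profiled -2 log likelihood for variances tau2 (per level) and s0
# (residual).  st must carry the base statistics pre-aggregated to the
# innermost units in $R0c (they are linear in 1/s0, so the expensive
# observation-level sweep happens once per fit, not once per evaluation).
hlme_nll2 <- function(tau2, s0, st) {
  p <- st$p
  M <- st$R0c / s0
  d <- st$n * log(s0)
  for (l in rev(seq_len(st$L))) {
    if (l < st$L) M <- rowsum(M, st$groups[[l]], reorder = TRUE)
    if (tau2[l] > 0) {
      s <- M[, 1L]
      f <- tau2[l] / (1 + tau2[l] * s)
      shrink <- 1 / (1 + tau2[l] * s)
      d <- d + sum(log1p(tau2[l] * s))
      m <- M[, 2L]
      tcols <- 3L + seq_len(p)
      bcols <- 3L + p + seq_len(p)
      acols <- 3L + 2L * p + seq_len(p * (p + 1L) / 2L)
      tmat <- M[, tcols, drop = FALSE]
      # order matters: q, b, A use pre-update t and m
      M[, 3L] <- M[, 3L] - f * m * m
      M[, bcols] <- M[, bcols, drop = FALSE] - f * tmat * m
      ai <- 0L
      for (j in seq_len(p)) for (k in j:p) {
        ai <- ai + 1L
        M[, acols[ai]] <- M[, acols[ai]] - f * tmat[, j] * tmat[, k]
      }
      M[, 1L] <- s * shrink
      M[, 2L] <- m * shrink
      M[, tcols] <- tmat * shrink
    }
  }
  tot <- colSums(M)
  A <- matrix(0, p, p)
  ai <- 0L
  for (j in seq_len(p)) for (k in j:p) {
    ai <- ai + 1L
    A[j, k] <- A[k, j] <- tot[3L + 2L * p + ai]
  }
  b <- tot[3L + p + seq_len(p)]
  q <- tot[3L]
  beta <- tryCatch(solve(A, b), error = function(e) rep(NA_real_, p))
  if (anyNA(beta)) return(list(nll2 = Inf, beta = beta))
  quad <- unname(q) - sum(b * beta)
  nll2 <- st$n * log(2 * pi) + unname(d) + quad
  if (isTRUE(st$reml)) {
    nll2 <- nll2 - st$p * log(2 * pi) + determinant(A)$modulus[1L]
  }
  list(nll2 = nll2, beta = beta)
}

# Method-of-moments starting values from between-unit variances of OLS
# residuals, floored to keep the log parameterization well defined.
hlme_start <- function(st, r, vtot) {
  L <- st$L
  B <- numeric(L)
  cur <- r
  grp <- st$groups
  # unit means, innermost to outermost
  means <- vector("list", L)
  m <- r
  for (l in rev(seq_len(L))) {
    m <- as.numeric(rowsum(m, grp[[l]]) / rowsum(rep(1, length(m)), grp[[l]]))
    means[[l]] <- m
  }
  for (l in seq_len(L)) {
    B[l] <- if (length(means[[l]]) > 1L) stats::var(means[[l]]) else 0
  }
  s <- diff(c(0, B))
  pmax(s, 1e-3 * vtot)
}

hlme_optimize <- function(st, vtot, reml, control) {
  st$R0c <- rowsum(hlme_base_stats(st), st$groups[[st$L]], reorder = TRUE)
  st$reml <- reml
  L <- st$L
  r <- st$y - st$X %*% stats::lm.fit(st$X, st$y)$coefficients
  start_tau <- hlme_start(st, as.numeric(r), vtot)
  start <- log(c(start_tau, max(vtot / 2, 1e-3 * vtot)) / vtot)

  obj <- function(par, active = rep(TRUE, L)) {
    if (any(!is.finite(par))) return(1e12)
    tau2 <- numeric(L)
    tau2[active] <- exp(par[seq_len(sum(active))]) * vtot
    s0 <- exp(par[length(par)]) * vtot
    v <- hlme_nll2(tau2, s0, st)$nll2
    if (!is.finite(v)) 1e12 else v
  }

  opt <- stats::nlminb(start, obj,
                       lower = rep(-34, L + 1L), upper = rep(12, L + 1L),
                       control = list(iter.max = control$max_iter,
                                      eval.max = 4L * control$max_iter,
                                      rel.tol = control$rel_tol,
                                      abs.tol = 0))
  par <- opt$par
  tau2 <- exp(par[seq_len(L)]) * vtot
  s0 <- exp(par[L + 1L]) * vtot
  nll_full <- opt$objective

  # boundary handling: small variance components are tested one by one
  # (smallest first) against an exact-zero refit; a component is snapped
  # to the boundary only when the profiled likelihood is indifferent
  conv_msg <- opt$message %||% ""
  iter <- opt$iterations
  active <- rep(TRUE, L)
  snap_tol <- max(1e-6, 2 * control$abs_tol)
  candidates <- order(tau2)
  candidates <- candidates[tau2[candidates] < control$boundary_tol * vtot]
  for (l in candidates) {
    trial <- active
    trial[l] <- FALSE
    if (any(trial)) {
      start2 <- c(log(pmax(tau2[trial], 1e-12 * vtot) / vtot), log(s0 / vtot))
      opt2 <- stats::nlminb(start2, obj, active = trial,
                            lower = rep(-34, sum(trial) + 1L),
                            upper = rep(12, sum(trial) + 1L),
                            control = list(iter.max = control$max_iter,
                                           rel.tol = control$rel_tol,
                                           abs.tol = 0))
      nll_snap <- opt2$objective
      par2 <- opt2$par
    } else {
      # all level variances zero: only the residual remains free
      opt2 <- stats::optimize(function(lp) obj(lp, active = trial),
                              interval = c(-34, 12), tol = 1e-12)
      nll_snap <- opt2$objective
      par2 <- opt2$minimum
    }
    if (nll_snap <= nll_full + snap_tol) {
      active <- trial
      tau2[l] <- 0
      if (any(active)) {
        tau2[active] <- exp(par2[seq_len(sum(active))]) * vtot
      }
      s0 <- exp(par2[length(par2)]) * vtot
      nll_full <- min(nll_full, nll_snap)
      iter <- iter + (opt2$iterations %||% 0L)
    }
  }

  final <- hlme_nll2(tau2, s0, st)
  list(beta = stats::setNames(final$beta, colnames(st$X)),
       sigma2 = c(tau2, residual = s0),
       loglik = -final$nll2 / 2,
       convergence = list(
         converged = opt$convergence == 0 ||
           grepl("convergence", conv_msg, ignore.case = TRUE),
         degenerate = FALSE, iterations = iter,
         message = conv_msg))
}

# Evaluate the profiled log-likelihood of a fitted model's data at
# arbitrary variance components (used for diagnostics and testing).
hlme_loglik_at <- function(model, sigma2) {
  it <- model$internals
  st <- list(n = model$n, p = ncol(it$X), L = length(model$levels),
             y = it$y, X = it$X, groups = it$groups, reml = model$reml)
  st$R0c <- rowsum(hlme_base_stats(st), st$groups[[st$L]], reorder = TRUE)
  L <- st$L
  -hlme_nll2(sigma2[seq_len(L)], sigma2[[L + 1L]], st)$nll2 / 2
}

#' @export
print.migvar_hlme <- function(x, ...) {
  cat("Nested random-intercept mixed model (",
      if (x$reml) "REML" else "ML", ")\n", sep = "")
  cat(sprintf("  response: %s, n = %d\n", x$response, x$n))
  cat(sprintf("  beta0 = %.6g", x$beta0))
  if (!is.na(x$delta)) cat(sprintf(", delta(%s) = %.6g", x$fixed, x$delta))
  cat("\n  variance components:\n")
  for (nm in names(x$sigma2)) {
    cat(sprintf("    %-10s %.6g\n", nm, x$sigma2[[nm]]))
  }
  cat(sprintf("  log-likelihood: %.6g\n", x$loglik))
  if (!x$convergence$converged) cat("  ** optimizer did not report convergence\n")
  invisible(x)
}

#' @export
logLik.migvar_hlme <- function(object, ...) {
  structure(object$loglik,
            df = length(object$beta) + length(object$sigma2),
            nobs = object$n, class = "logLik")
}
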