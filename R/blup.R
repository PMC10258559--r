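#' Predict random intercepts (BLUPs)
#'
#' Empirical-Bayes predictions of every unit's random intercept from a
#' fitted nested mixed model, obtained by solving the mixed-model
#' (Henderson) equations at the ML variance estimates with a sparse
#' Cholesky factorization.  Levels whose variance component is exactly
#' zero receive BLUPs of exactly zero.  Within each level the
#' precision-weighted predictions shrink unit-mean deviations toward zero;
#' for a single balanced level the prediction reduces to the closed form
#' `n s2 / (n s2 + s2_res) * (unit mean - grand mean)`.
#'
#' @param model A fitted [fit_nested_lme()] model.
#' @param table Optional table of observations to attach per-observation
#'   predictions to; defaults to the fitting data.  Every observation must
#'   belong to units seen at fit time.
#' @return An object of class `migvar_blups`: a named list with one
#'   numeric vector per level (named by unit path), plus attributes
#'   `obs_index` (per-level observation-to-unit index for `table`) and
#'   `levels`.
#' @export
predict_random_intercepts <- function(model, table = NULL) {
  stopifnot(inherits(model, "migvar_hlme"))
  it <- model$internals
  levels <- model$levels
  L <- length(levels)
  sigma2 <- model$sigma2
  s0 <- sigma2[["residual"]]
  n <- model$n

  u <- stats::setNames(vector("list", L), levels)
  active <- which(sigma2[seq_len(L)] > 0)
  for (l in seq_len(L)) u[[l]] <- stats::setNames(rep(0, length(it$units[[l]])),
                                                  it$units[[l]])

  if (length(active) && s0 > 0) {
    Xs <- Matrix::Matrix(it$X, sparse = TRUE)
    Zs <- lapply(active, function(l) {
      Matrix::sparseMatrix(i = seq_len(n), j = it$idx[[l]],
                           x = 1, dims = c(n, length(it$units[[l]])))
    })
    W <- do.call(cbind, c(list(Xs), Zs))
    C <- Matrix::crossprod(W)
    pen <- c(rep(0, ncol(Xs)),
             unlist(lapply(active, function(l) {
               rep(s0 / sigma2[[l]], length(it$units[[l]]))
             })))
    C <- C + Matrix::Diagonal(x = pen)
    rhs <- Matrix::crossprod(W, it$y)
    sol <- as.numeric(Matrix::solve(C, rhs))
    off <- ncol(Xs)
    for (l in active) {
      k <- length(it$units[[l]])
      u[[levels[l]]] <- stats::setNames(sol[off + seq_len(k)], it$units[[l]])
      off <- off + k
    }
  }

  if (is.null(table)) {
    obs_index <- it$idx
  } else {
    assert_columns(table, levels, "table")
    obs_index <- lapply(seq_len(L), function(l) {
      id <- path_id(table, levels[seq_len(l)])
      m <- match(id, it$units[[l]])
      if (anyNA(m)) {
        mv_stop(sprintf("table contains `%s` unit(s) unseen at fit time: %s",
                        levels[l],
                        paste(utils::head(unique(id[is.na(m)]), 3L),
                              collapse = ", ")),
                class = "migvar_structure_error")
      }
      m
    })
    names(obs_index) <- levels
  }

  structure(u, obs_index = obs_index, levels = levels,
            class = "migvar_blups")
}

#' @export
print.migvar_blups <- function(x, ...) {
  cat("Predicted random intercepts (BLUPs)\n")
  for (nm in attr(x, "levels")) {
    v <- x[[nm]]
    cat(sprintf("  %-10s %4d unit(s), sd = %.4g\n", nm, length(v),
                stats::sd(v)))
  }
  invisible(x)
}

#' Decompose feature variance into level components
#'
#' Collects the estimated variance components of one or more fitted
#' models into a tidy table of absolute variances and relative shares,
#' and splits the total into a technical part (replicate, experiment,
#' person, laboratory) and a biological part (cell identity plus the
#' temporal residual).
#'
#' @param models A fitted [fit_nested_lme()] model or a named list of them
#'   (one per feature).
#' @param technical_levels Level names counted as technical variability.
#' @return An object of class `migvar_vartable`: a data.frame with columns
#'   `feature`, `level`, `variance`, `share`, and attributes
#'   `technical_share` (named per-feature vector) and
#'   `median_technical_share`.
#' @examples
#' sim <- simulate_migration_study(design_spec(n_cells = 3, n_timepoints = 6))
#' fit <- fit_nested_lme(sim$table, "ics", fixed = "condition")
#' decompose_variance(fit)
#' @export
decompose_variance <- function(models,
                               technical_levels = c("lab", "person",
                                                    "experiment",
                                                    "replicate")) {
  if (inherits(models, "migvar_hlme")) {
    models <- stats::setNames(list(models), models$response)
  }
  stopifnot(length(models) > 0,
            all(vapply(models, inherits, TRUE, "migvar_hlme")))
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) m$response, character(1))
  }
  rows <- lapply(names(models), function(feat) {
    s2 <- models[[feat]]$sigma2
    total <- sum(s2)
    data.frame(feature = feat, level = names(s2),
               variance = unname(s2),
               share = if (total > 0) unname(s2) / total else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tech <- vapply(names(models), function(feat) {
    s2 <- models[[feat]]$sigma2
    total <- sum(s2)
    if (total > 0) sum(s2[names(s2) %in% technical_levels]) / total
    else NA_real_
  }, numeric(1))
  structure(out,
            technical_levels = technical_levels,
            technical_share = tech,
            median_technical_share = stats::median(tech, na.rm = TRUE),
            class = c("migvar_vartable", "data.frame"))
}

#' @export
print.migvar_vartable <- function(x, ...) {
  cat("Variance components per feature\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  ts <- attr(x, "technical_share")
  cat(sprintf("technical share: %s (median %.3f)\n",
              paste(sprintf("%s=%.3f", names(ts), ts), collapse = ", "),
              attr(x, "median_technical_share")))
  invisible(x)
}
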