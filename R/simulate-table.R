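#' Simulate a multi-site cell-migration feature table
#'
#' Generates a long-format observation table on a nested multi-laboratory
#' design, together with its complete ground truth.  Each feature value is
#' built as
#' \deqn{y = \beta_0 + \delta\,1[\mathrm{treated}] + u_{lab} + u_{person} +
#'       u_{exp} + u_{rep} + u_{cell} + \varepsilon,}
#' with independent centred Gaussian random intercepts per unit at each
#' level and i.i.d. Gaussian residuals per time point.  The identity above
#' holds exactly (to the last bit) for every generated observation, so the
#' output doubles as a validation harness for the mixed-model estimator.
#'
#' Random intercepts are drawn independently across levels; residuals carry
#' no temporal autocorrelation.  When several features are requested they
#' are drawn independently (no cross-feature correlation) from per-feature
#' streams derived from `params$seed`, so the same seed always reproduces a
#' byte-identical table.
#'
#' @param design A [design_spec()].
#' @param params A [generative_params()]; `params$seed` drives all draws.
#' @param features Character vector of feature column names to simulate.
#' @return An object of class `migvar_sim`: a list with elements
#'   `table` (data.frame with columns `lab`, `person`, `experiment`,
#'   `condition`, `replicate`, `cell`, `time_min` and one column per
#'   feature), `truth` (named list, one data.frame per feature holding the
#'   per-observation intercepts `u_lab` ... `u_cell`, residual `eps` and
#'   the reassembled `value`), `design`, `params` and `features`.
#' @examples
#' sim <- simulate_migration_study(design_spec(n_cells = 2, n_timepoints = 3))
#' head(sim$table)
#' @export
simulate_migration_study <- function(design = design_spec(),
                                     params = generative_params(),
                                     features = "ics") {
  stopifnot(inherits(design, "migvar_design"),
            inherits(params, "migvar_params"))
  if (!is.character(features) || !length(features) ||
      anyDuplicated(features)) {
    mv_stop("`features` must be distinct feature names",
            class = "migvar_parameter_error")
  }

  key <- build_design_table(design)
  n <- nrow(key)
  treated <- as.numeric(key$condition != design$conditions[1L])

  # unit paths, outermost to innermost
  ids <- list(
    lab        = path_id(key, "lab"),
    person     = path_id(key, c("lab", "person")),
    experiment = path_id(key, c("lab", "person", "experiment")),
    replicate  = path_id(key, c("lab", "person", "experiment", "replicate")),
    cell       = path_id(key, c("lab", "person", "experiment", "replicate",
                                "cell"))
  )
  idx <- lapply(ids, function(id) match(id, unique(id)))
  n_units <- vapply(ids, function(id) length(unique(id)), integer(1))

  table <- key
  truth <- vector("list", length(features))
  names(truth) <- features
  for (feat in features) {
    set.seed(derive_seed(params$seed, paste0("feature:", feat)))
    u <- mapply(function(nu, s2) stats::rnorm(nu, 0, sqrt(s2)),
                n_units, params$sigma2, SIMPLIFY = FALSE)
    eps <- stats::rnorm(n, 0, sqrt(params$sigma2_residual))
    u_obs <- mapply(function(uu, ii) uu[ii], u, idx, SIMPLIFY = FALSE)
    value <- params$beta0 + params$delta * treated +
      u_obs$lab + u_obs$person + u_obs$experiment +
      u_obs$replicate + u_obs$cell + eps
    table[[feat]] <- value
    truth[[feat]] <- data.frame(
      key,
      u_lab = u_obs$lab, u_person = u_obs$person,
      u_experiment = u_obs$experiment, u_replicate = u_obs$replicate,
      u_cell = u_obs$cell, eps = eps, value = value,
      stringsAsFactors = FALSE
    )
  }

  structure(list(table = table, truth = truth, design = design,
                 params = params, features = features),
            class = "migvar_sim")
}

# Key table in canonical order: time fastest, then cell, replicate,
# condition, experiment, person, lab.  Replicate labels embed the
# condition so that (lab, person, experiment, replicate) is a unique path.
build_design_table <- function(design) {
  labs <- sprintf("L%d", seq_len(design$n_labs))
  persons <- sprintf("P%d", seq_len(design$n_persons))
  exps <- sprintf("E%d", seq_len(design$n_experiments))
  reps <- sprintf("r%d", seq_len(design$n_replicates))
  cells <- sprintf("c%03d", seq_len(design$n_cells))
  times <- seq_len(design$n_timepoints) * design$frame_interval

  g <- expand.grid(time_min = times, cell = cells, replicate = reps,
                   condition = design$conditions, experiment = exps,
                   person = persons, lab = labs,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$replicate <- paste(g$condition, g$replicate, sep = ".")
  g[, MV_KEY_COLS]
}

#' @export
print.migvar_sim <- function(x, ...) {
  cat(sprintf("Simulated multi-site study: %d observations, %d feature(s)\n",
              nrow(x$table), length(x$features)))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  print(x$design)
  invisible(x)
}

#' Write / read an observation table as CSV
#'
#' Long-format tables use UTF-8 encoding and `.` as decimal separator.
#'
#' @param table A data.frame keyed by the design hierarchy.
#' @param path File path.
#' @return `read_observation_table` returns a data.frame.
#' @export
write_observation_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_observation_table
#' @export
read_observation_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
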