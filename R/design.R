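#' Multi-site study design
#'
#' Describes the nested acquisition design of a multi-laboratory live-cell
#' migration study: laboratories, persons per laboratory, independent
#' experiments per person, treatment conditions, technical replicates per
#' condition, cells per replicate, and the acquisition schedule.  The
#' defaults reproduce the reference design of three laboratories, three
#' persons per laboratory, three experiments per person, two conditions
#' (control and ROCK-inhibitor treated), three technical replicates per
#' condition, about 50 cells per replicate and 72 time points at a 5-minute
#' frame interval (6 h of imaging).
#'
#' @param n_labs Number of laboratories.
#' @param n_persons Persons per laboratory.
#' @param n_experiments Independent experiments per person.
#' @param conditions Character vector of condition labels; the first is the
#'   reference (control) condition.
#' @param n_replicates Technical replicates per condition.
#' @param n_cells Cells per technical replicate.
#' @param n_timepoints Time points recorded per cell.
#' @param frame_interval Acquisition interval in minutes.
#' @return An object of class `migvar_design`.
#' @examples
#' design_spec()                       # the full reference design
#' design_spec(n_cells = 10, n_timepoints = 24)  # a reduced design
#' @export
design_spec <- function(n_labs = 3, n_persons = 3, n_experiments = 3,
                        conditions = c("control", "treated"),
                        n_replicates = 3, n_cells = 50, n_timepoints = 72,
                        frame_interval = 5) {
  d <- list(
    n_labs = assert_count(n_labs, "n_labs"),
    n_persons = assert_count(n_persons, "n_persons"),
    n_experiments = assert_count(n_experiments, "n_experiments"),
    conditions = as.character(conditions),
    n_replicates = assert_count(n_replicates, "n_replicates"),
    n_cells = assert_count(n_cells, "n_cells"),
    n_timepoints = assert_count(n_timepoints, "n_timepoints"),
    frame_interval = assert_positive(frame_interval, "frame_interval")
  )
  if (length(d$conditions) < 1L || anyDuplicated(d$conditions)) {
    mv_stop("`conditions` must be a non-empty set of distinct labels",
            class = "migvar_parameter_error")
  }
  structure(d, class = "migvar_design")
}

#' @export
print.migvar_design <- function(x, ...) {
  cat("Multi-site study design\n")
  cat(sprintf("  %d lab(s) x %d person(s) x %d experiment(s)\n",
              x$n_labs, x$n_persons, x$n_experiments))
  cat(sprintf("  conditions: %s; %d replicate(s) per condition\n",
              paste(x$conditions, collapse = ", "), x$n_replicates))
  cat(sprintf("  %d cell(s) per replicate, %d time point(s) every %g min\n",
              x$n_cells, x$n_timepoints, x$frame_interval))
  invisible(x)
}

#' Generative parameters for the hierarchical feature model
#'
#' Parameters of the Gaussian random-intercept model used to simulate a
#' feature observed on the nested design: a fixed baseline `beta0`, a
#' treatment effect `delta` added under every non-reference condition, one
#' variance per random level (laboratory, person, experiment, technical
#' replicate, cell) and a residual variance capturing temporal variability
#' within a cell.  The default variances make the laboratory level the
#' dominant technical source, mirroring what multi-site imaging studies
#' observe, with substantial cell-to-cell and temporal biological spread.
#'
#' @param beta0 Baseline feature value (feature units).
#' @param delta Additive treatment fixed effect (feature units).
#' @param sigma2 Named numeric vector of random-intercept variances with
#'   names `lab`, `person`, `experiment`, `replicate`, `cell`
#'   (feature units squared, all `>= 0`).
#' @param sigma2_residual Residual (temporal) variance, `>= 0`.
#' @param seed Integer seed controlling all random draws.
#' @return An object of class `migvar_params`.
#' @examples
#' generative_params(beta0 = 5, delta = 0,
#'                   sigma2 = c(lab = 0, person = 0, experiment = 0,
#'                              replicate = 0, cell = 0),
#'                   sigma2_residual = 0)
#' @export
generative_params <- function(beta0 = 10, delta = 3,
                              sigma2 = c(lab = 4, person = 1,
                                         experiment = 0.5, replicate = 0.25,
                                         cell = 2),
                              sigma2_residual = 2, seed = 1L) {
  need <- c("lab", "person", "experiment", "replicate", "cell")
  if (!is.numeric(sigma2) || !all(need %in% names(sigma2))) {
    mv_stop(sprintf("`sigma2` must be a named numeric vector with names %s",
                    paste(need, collapse = ", ")),
            class = "migvar_parameter_error")
  }
  sigma2 <- sigma2[need]
  if (any(!is.finite(sigma2)) || any(sigma2 < 0)) {
    mv_stop("all random-intercept variances must be finite and >= 0",
            class = "migvar_parameter_error")
  }
  if (!is.finite(sigma2_residual) || sigma2_residual < 0) {
    mv_stop("`sigma2_residual` must be finite and >= 0",
            class = "migvar_parameter_error")
  }
  structure(list(beta0 = as.numeric(beta0), delta = as.numeric(delta),
                 sigma2 = sigma2,
                 sigma2_residual = as.numeric(sigma2_residual),
                 seed = as.integer(seed)),
            class = "migvar_params")
}

#' @export
print.migvar_params <- function(x, ...) {
  cat("Hierarchical feature model parameters\n")
  cat(sprintf("  beta0 = %g, delta = %g\n", x$beta0, x$delta))
  cat("  sigma2:", paste(sprintf("%s = %g", names(x$sigma2), x$sigma2),
                         collapse = ", "),
      sprintf("residual = %g\n", x$sigma2_residual))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}
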