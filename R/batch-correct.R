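#' Remove technical batch effects by random-intercept subtraction
#'
#' Corrects each observation by subtracting the predicted (BLUP) random
#' intercepts of its technical units — laboratory, person, experiment and
#' technical replicate — while leaving the fixed effects (baseline and
#' treatment) and the biological variation (cell identity and temporal
#' residual) untouched:
#' \deqn{y^{corr} = y - (\hat u_{lab} + \hat u_{person} + \hat u_{exp} +
#'       \hat u_{rep}).}
#' The model must have been fitted on the complete two-condition dataset
#' with the condition as fixed effect, so that the treatment contrast is
#' carried by the fixed part rather than leaking into the intercepts.
#' Because only technical-level intercepts are subtracted, the fixed
#' effects need no re-addition; within-level BLUPs average to
#' approximately zero, so the grand mean is preserved.
#'
#' @param table Observation table; must use the same hierarchy keys as
#'   the fitting data.
#' @param model A [fit_nested_lme()] fit on `table` (or on data covering
#'   all of its units) with the condition fixed effect when the table has
#'   two conditions.
#' @param levels_to_remove Random levels whose intercepts are subtracted.
#' @param response Response column to correct; defaults to the model's.
#' @return The corrected table: identical schema and row order, corrected
#'   response values, plus a `batch_correction` column holding the amount
#'   subtracted from each observation.
#' @examples
#' sim <- simulate_migration_study(design_spec(n_cells = 3, n_timepoints = 6))
#' fit <- fit_nested_lme(sim$table, "ics", fixed = "condition")
#' corr <- remove_batch_effects(sim$table, fit)
#' @export
remove_batch_effects <- function(table, model,
                                 levels_to_remove = c("lab", "person",
                                                      "experiment",
                                                      "replicate"),
                                 response = NULL) {
  stopifnot(inherits(model, "migvar_hlme"))
  response <- response %||% model$response
  assert_columns(table, c(response, model$levels), "table")
  bad <- setdiff(levels_to_remove, model$levels)
  if (length(bad)) {
    mv_stop(sprintf("model has no random level(s): %s",
                    paste(bad, collapse = ", ")),
            class = "migvar_parameter_error")
  }
  if ("condition" %in% names(table) &&
      length(unique(table$condition)) > 1L && is.null(model$fixed)) {
    mv_stop(paste("table has two conditions but the model was fitted without",
                  "a condition fixed effect; fit the complete dataset with",
                  "`fixed = \"condition\"` first"),
            class = "migvar_fixed_error")
  }

  blups <- predict_random_intercepts(model, table = table)
  obs_index <- attr(blups, "obs_index")
  correction <- rep(0, nrow(table))
  for (lv in levels_to_remove) {
    correction <- correction + blups[[lv]][obs_index[[lv]]]
  }
  table[[response]] <- table[[response]] - correction
  table$batch_correction <- correction
  table
}

#' Batch correction for 3D spheroid invasion distances
#'
#' Applies the random-intercept subtraction to per-nucleus migration
#' distances from a multi-laboratory spheroid invasion study.  The
#' hierarchy is laboratory / experiment / technical replicate / spheroid
#' with the per-nucleus residual innermost; the collagen-density condition
#' enters as the fixed effect, and only the technical levels (laboratory,
#' experiment, replicate) are corrected, retaining spheroid-level and
#' per-nucleus variation.
#'
#' @param table Distance table with columns `lab`, `experiment`,
#'   `replicate`, `spheroid`, a condition column and the response.
#' @param response Response column (default `"distance"`, in micrometres).
#' @param condition Condition column (default `"condition"`, e.g. collagen
#'   concentration).
#' @return A list with elements `table` (corrected, as in
#'   [remove_batch_effects()]) and `model` (the underlying fit).
#' @export
correct_3d <- function(table, response = "distance",
                       condition = "condition") {
  assert_columns(table, c("lab", "experiment", "replicate", "spheroid",
                          condition, response), "distance table")
  if (length(unique(table$lab)) < 2L) {
    mv_stop("3D batch correction requires data from at least 2 laboratories",
            class = "migvar_parameter_error")
  }
  if (length(unique(table[[condition]])) != 2L) {
    mv_stop(sprintf("condition column `%s` must have exactly 2 levels",
                    condition), class = "migvar_fixed_error")
  }
  model <- fit_nested_lme(table, response,
                          levels = c("lab", "experiment", "replicate",
                                     "spheroid"),
                          fixed = condition)
  corrected <- remove_batch_effects(table, model,
                                    levels_to_remove = c("lab", "experiment",
                                                         "replicate"),
                                    response = response)
  list(table = corrected, model = model)
}

#' Before/after correction summary per condition and laboratory
#'
#' Mean and standard deviation of a response per condition, overall and
#' per laboratory — the headline numbers of a batch-correction figure.
#'
#' @param before,after Observation tables before and after correction.
#' @param response Response column name.
#' @param condition Condition column name.
#' @return A data.frame with columns `stage`, `condition`, `lab`
#'   (`"all"` for the aggregate), `mean` and `sd`.
#' @export
correction_summary <- function(before, after, response,
                               condition = "condition") {
  one <- function(tab, stage) {
    grp <- list(condition = tab[[condition]], lab = tab$lab)
    agg <- stats::aggregate(tab[[response]], grp,
                            function(v) c(mean = mean(v), sd = stats::sd(v)))
    per_lab <- data.frame(stage = stage, condition = agg$condition,
                          lab = agg$lab, mean = agg$x[, "mean"],
                          sd = agg$x[, "sd"], stringsAsFactors = FALSE)
    aggall <- stats::aggregate(tab[[response]],
                               list(condition = tab[[condition]]),
                               function(v) c(mean = mean(v), sd = stats::sd(v)))
    all_labs <- data.frame(stage = stage, condition = aggall$condition,
                           lab = "all", mean = aggall$x[, "mean"],
                           sd = aggall$x[, "sd"], stringsAsFactors = FALSE)
    rbind(all_labs, per_lab)
  }
  rbind(one(before, "before"), one(after, "after"))
}

#' Replicate-level distance matrix in PC space
#'
#' Averages the first two principal-component scores per technical
#' replicate and returns the Euclidean distance matrix between replicates,
#' ordered by hierarchical clustering — the heatmap ingredient used to
#' visualize how batch correction collapses replicate separation.
#'
#' @param scores Data.frame with hierarchy key columns and PC score
#'   columns `PC1`, `PC2`.
#' @return A list with `dist` (matrix), `order` (hclust leaf order) and
#'   `key` (replicate key table).
#' @export
replicate_distance_matrix <- function(scores) {
  assert_columns(scores, c("lab", "person", "experiment", "condition",
                           "replicate", "PC1", "PC2"), "scores")
  id <- path_id(scores, c("lab", "person", "experiment", "replicate"))
  agg <- rowsum(cbind(PC1 = scores$PC1, PC2 = scores$PC2, n = 1), id,
                reorder = TRUE)
  centers <- agg[, c("PC1", "PC2")] / agg[, "n"]
  first <- !duplicated(id)
  key <- scores[first, c("lab", "person", "experiment", "condition",
                         "replicate")]
  key <- key[order(id[first]), ]
  rownames(key) <- NULL
  d <- as.matrix(stats::dist(centers))
  ord <- stats::hclust(stats::as.dist(d), method = "average")$order
  list(dist = d, order = ord, key = key)
}
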