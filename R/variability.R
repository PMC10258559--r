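#' Enumerate consistent subdatasets of the design hierarchy
#'
#' Lists every subdataset of a hypothetical design of increasing
#' complexity: `k` units chosen at one level (technical replicate,
#' experiment, person or laboratory) that share a single complete path
#' above them, together with all units below them.  Combinations of units
#' that do not share the same origin in the next-higher level are never
#' formed, which keeps each subdataset internally consistent.  The number
#' of subdatasets is (number of complete paths above the level) times
#' `choose(n_level, k)`.
#'
#' The enumeration operates on a single condition at a time, since mixing
#' conditions would confound the treatment effect with technical spread.
#'
#' @param table Observation table (one condition).
#' @param level One of `"replicate"`, `"experiment"`, `"person"`, `"lab"`.
#' @param k Number of units to combine at `level` (2 or 3 in the reference
#'   design).
#' @return A list of subdataset specifications; each is a list with
#'   elements `level`, `k`, `path` (named character vector of ancestor
#'   unit labels) and `units` (chosen unit labels at `level`).
#' @examples
#' sim <- simulate_migration_study(design_spec(n_cells = 1, n_timepoints = 2))
#' ctrl <- sim$table[sim$table$condition == "control", ]
#' length(enumerate_subdatasets(ctrl, "lab", 2))        # choose(3, 2)
#' @export
enumerate_subdatasets <- function(table, level, k) {
  hier <- c("lab", "person", "experiment", "replicate")
  if (!level %in% hier) {
    mv_stop(sprintf("`level` must be one of %s",
                    paste(hier, collapse = ", ")),
            class = "migvar_parameter_error")
  }
  assert_columns(table, hier, "table")
  if ("condition" %in% names(table) &&
      length(unique(table$condition)) > 1L) {
    mv_stop("table must contain a single condition; filter first",
            class = "migvar_parameter_error")
  }
  k <- assert_count(k, "k")
  above <- hier[seq_len(match(level, hier) - 1L)]
  key <- unique(table[, c(above, level), drop = FALSE])
  paths <- if (length(above)) {
    split(key[[level]], path_id(key, above))
  } else {
    list(all = key[[level]])
  }
  out <- list()
  for (pid in names(paths)) {
    units <- sort(unique(paths[[pid]]))
    if (k > length(units)) {
      mv_stop(sprintf("k = %d exceeds the %d unit(s) available at level `%s`",
                      k, length(units), level),
              class = "migvar_parameter_error")
    }
    combos <- utils::combn(units, k, simplify = FALSE)
    path <- if (length(above)) {
      row <- key[path_id(key, above) == pid, above, drop = FALSE][1L, ,
                                                                  drop = FALSE]
      stats::setNames(as.character(unlist(row)), above)
    } else {
      character(0)
    }
    out <- c(out, lapply(combos, function(u) {
      list(level = level, k = k, path = path, units = u)
    }))
  }
  out
}

# Per-replicate means of one feature for a single-condition table.
replicate_means <- function(table, feature) {
  assert_columns(table, c("lab", "person", "experiment", "replicate",
                          feature), "table")
  id <- path_id(table, c("lab", "person", "experiment", "replicate"))
  agg <- rowsum(cbind(v = table[[feature]], n = 1), id, reorder = TRUE)
  first <- !duplicated(id)
  key <- table[first, c("lab", "person", "experiment", "replicate"),
               drop = FALSE]
  key <- key[order(id[first]), , drop = FALSE]
  key$mean <- agg[, "v"] / agg[, "n"]
  rownames(key) <- NULL
  key
}

# Variance of replicate means covered by one subdataset spec, computed on
# a precomputed replicate-means table.
subdataset_variance <- function(spec, means) {
  keep <- rep(TRUE, nrow(means))
  for (nm in names(spec$path)) keep <- keep & means[[nm]] == spec$path[[nm]]
  keep <- keep & means[[spec$level]] %in% spec$units
  v <- means$mean[keep]
  if (length(v) < 2L) {
    mv_stop("subdataset covers fewer than 2 replicate means",
            class = "migvar_parameter_error")
  }
  stats::var(v)
}

#' Variance of replicate means within one subdataset
#'
#' The per-subdataset statistic of the cumulative-variability analysis:
#' the sample variance (n-1 denominator) of per-technical-replicate mean
#' feature values across all replicates contained in the subdataset.
#'
#' @param spec One specification from [enumerate_subdatasets()].
#' @param table Observation table covering the subdataset (one condition).
#' @param feature Feature column name.
#' @return A single variance value.
#' @export
cumulative_variance <- function(spec, table, feature) {
  subdataset_variance(spec, replicate_means(table, feature))
}

#' Cumulative-variability curves across design levels
#'
#' Computes, for each hierarchy level (technical replicate, experiment,
#' person, laboratory) and each multiplicity `k`, the variance of
#' replicate means within every consistent subdataset, yielding the
#' distribution whose mean traces how technical variability accumulates
#' as progressively higher design levels are allowed to vary.  With
#' `randomize = TRUE` the replicate means are globally permuted across
#' the design before enumeration (preserving within-replicate structure),
#' which flattens the curve and serves as a negative control.
#'
#' @param table Observation table.
#' @param feature Feature column name.
#' @param ks Multiplicities to evaluate at each level.
#' @param condition Condition label to analyse; defaults to the first
#'   sorted label when the table has several.
#' @param randomize Permute replicate means before enumeration.
#' @param seed Seed for the permutation (required when `randomize`).
#' @return A data.frame with columns `level` (ordered factor
#'   replicate < experiment < person < lab), `k`, `subdataset`, `variance`
#'   and `randomized`.
#' @examples
#' sim <- simulate_migration_study(design_spec(n_cells = 2, n_timepoints = 4))
#' cv <- cumulative_variability(sim$table, "ics")
#' aggregate(variance ~ level, cv, mean)
#' @export
cumulative_variability <- function(table, feature, ks = c(2L, 3L),
                                   condition = NULL, randomize = FALSE,
                                   seed = NULL) {
  assert_columns(table, c("condition", feature), "table")
  conds <- sort(unique(table$condition))
  if (is.null(condition)) condition <- conds[1L]
  table <- table[table$condition == condition, , drop = FALSE]
  if (!nrow(table)) {
    mv_stop(sprintf("no observations for condition `%s`", condition),
            class = "migvar_parameter_error")
  }

  means <- replicate_means(table, feature)
  if (randomize) {
    if (is.null(seed)) {
      mv_stop("`seed` is required when randomize = TRUE",
              class = "migvar_parameter_error")
    }
    set.seed(derive_seed(seed, "cumulative-randomization"))
    means$mean <- means$mean[sample.int(nrow(means))]
  }

  levels_ord <- c("replicate", "experiment", "person", "lab")
  rows <- list()
  for (lv in levels_ord) {
    for (k in ks) {
      specs <- enumerate_subdatasets(table, lv, k)
      v <- vapply(specs, subdataset_variance, numeric(1), means = means)
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv, k = k, subdataset = seq_along(v), variance = v,
        randomized = randomize, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$level <- factor(out$level, levels = levels_ord, ordered = TRUE)
  out
}

#' @rdname cumulative_variability
#' @export
randomized_control <- function(table, feature, seed, ks = c(2L, 3L),
                               condition = NULL) {
  cumulative_variability(table, feature, ks = ks, condition = condition,
                         randomize = TRUE, seed = seed)
}

#' Mean cumulative-variance per level
#'
#' Averages the subdataset variance distribution of
#' [cumulative_variability()] over subdatasets and multiplicities,
#' giving the red-dot curve value per level.
#'
#' @param curves Output of [cumulative_variability()].
#' @return A data.frame with columns `level` and `mean_variance`.
#' @export
cumulative_level_means <- function(curves) {
  agg <- stats::aggregate(variance ~ level, curves, mean)
  names(agg)[2L] <- "mean_variance"
  agg
}
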