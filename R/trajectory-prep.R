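#' Trajectory and measurement quality control
#'
#' Removes unreliable records before statistical modelling, mirroring the
#' preprocessing of multi-site migration studies:
#' \enumerate{
#'   \item merged trajectories: two nucleus tracks mapped to one cell
#'     label in the same frame and replicate — both whole tracks removed
#'     (requires a `cell_label` column; skipped otherwise);
#'   \item duplicated trajectories: two tracks sharing at least half of
#'     their identical centroid records (same time and rounded position;
#'     requires `nuc_x_um`/`nuc_y_um`; skipped otherwise) — the
#'     later-sorted track removed;
#'   \item oversized cells: cells whose mean area exceeds Q3 +
#'     `iqr_k` * IQR of all per-cell mean areas (debris aggregates);
#'     the threshold rule is re-applied until stable, which makes the
#'     filter idempotent;
#'   \item undersized nuclei: observations with nucleus area below
#'     `nucleus_min_area` (default 100 um^2, cell debris).
#' }
#' Quantiles use linear interpolation between order statistics (type 7).
#'
#' @param table Observation table with `area` and `nucleus_area` columns;
#'   cells are identified by the hierarchy key columns present plus
#'   `cell`.
#' @param nucleus_min_area Minimum nucleus area (um^2).
#' @param iqr_k Multiplier of the interquartile range above the third
#'   quartile.
#' @return A list with `table` (retained records) and `report`
#'   (class `migvar_qc_report`: per-rule removal counts and thresholds;
#'   removed + retained = input count).
#' @examples
#' tab <- data.frame(cell = c("a", "b"), area = c(500, 520),
#'                   nucleus_area = c(150, 80))
#' qc_filter(tab)$report
#' @export
qc_filter <- function(table, nucleus_min_area = 100, iqr_k = 1.5) {
  assert_columns(table, c("area", "nucleus_area"), "observation table")
  n_in <- nrow(table)
  id_cols <- intersect(c("lab", "person", "experiment", "condition",
                         "replicate"), names(table))
  cell_col <- if ("cell" %in% names(table)) "cell" else NULL
  if (is.null(cell_col)) {
    mv_schema_stop("observation table must have a `cell` column")
  }
  cid <- path_id(table, c(id_cols, cell_col))
  removed <- c(merged_trajectory = 0L, duplicated_trajectory = 0L,
               oversized_cell = 0L, undersized_nucleus = 0L)
  drop <- rep(FALSE, n_in)

  # (1) merged: >1 nucleus track on one cell label in a frame
  if (all(c("cell_label", "frame") %in% names(table))) {
    rid <- path_id(table, c(id_cols, "frame", "cell_label"))
    tab_by_rid <- rowsum(rep(1L, n_in), rid)
    merged_ids <- rownames(tab_by_rid)[tab_by_rid > 1L]
    if (length(merged_ids)) {
      bad_cells <- unique(cid[rid %in% merged_ids])
      hit <- cid %in% bad_cells & !drop
      removed["merged_trajectory"] <- sum(hit)
      drop <- drop | hit
    }
  }

  # (2) duplicated: two tracks sharing >= 50% identical centroid records
  if (all(c("nuc_x_um", "nuc_y_um", "time_min") %in% names(table))) {
    keep_idx <- which(!drop)
    rec <- paste(path_id(table, id_cols),
                 table$time_min,
                 round(table$nuc_x_um, 6), round(table$nuc_y_um, 6),
                 sep = "\r")[keep_idx]
    cc <- cid[keep_idx]
    dup_rec <- rec[duplicated(rec) | duplicated(rec, fromLast = TRUE)]
    if (length(dup_rec)) {
      by_rec <- split(cc, rec)
      by_rec <- by_rec[lengths(by_rec) > 1L]
      pair_counts <- table(unlist(lapply(by_rec, function(cells) {
        cells <- sort(unique(cells))
        if (length(cells) < 2L) return(character(0))
        utils::combn(cells, 2L, paste, collapse = "\r")
      })))
      if (length(pair_counts)) {
        track_len <- table(cc)
        bad <- character(0)
        for (p in names(pair_counts)) {
          cells <- strsplit(p, "\r", fixed = TRUE)[[1L]]
          shorter <- min(track_len[cells[1L]], track_len[cells[2L]])
          if (pair_counts[[p]] / shorter >= 0.5) {
            bad <- c(bad, sort(cells)[2L])   # remove the later-sorted track
          }
        }
        if (length(bad)) {
          hit <- cid %in% unique(bad) & !drop
          removed["duplicated_trajectory"] <- sum(hit)
          drop <- drop | hit
        }
      }
    }
  }

  # (3) oversized cells via Q3 + k * IQR on per-cell mean areas,
  #     iterated to a fixed point
  thr <- NA_real_
  repeat {
    keep_idx <- which(!drop)
    if (!length(keep_idx)) break
    means <- tapply(table$area[keep_idx], cid[keep_idx], mean)
    q <- stats::quantile(means, c(0.25, 0.75), type = 7, names = FALSE)
    thr <- q[2L] + iqr_k * (q[2L] - q[1L])
    bad_cells <- names(means)[means > thr]
    if (!length(bad_cells)) break
    hit <- cid %in% bad_cells & !drop
    removed["oversized_cell"] <- removed["oversized_cell"] + sum(hit)
    drop <- drop | hit
  }

  # (4) undersized nuclei, per observation
  hit <- !is.na(table$nucleus_area) & table$nucleus_area < nucleus_min_area &
    !drop
  removed["undersized_nucleus"] <- sum(hit)
  drop <- drop | hit

  report <- structure(list(
    input_records = n_in,
    retained_records = sum(!drop),
    removed = as.list(removed),
    thresholds = list(cell_area_max = unname(thr),
                      nucleus_min_area = nucleus_min_area,
                      iqr_k = iqr_k)),
    class = "migvar_qc_report")
  list(table = table[!drop, , drop = FALSE], report = report)
}

#' @export
print.migvar_qc_report <- function(x, ...) {
  cat(sprintf("QC: %d of %d record(s) retained\n", x$retained_records,
              x$input_records))
  for (nm in names(x$removed)) {
    cat(sprintf("  removed (%s): %d\n", nm, x$removed[[nm]]))
  }
  cat(sprintf("  cell area threshold: %.4g; nucleus min area: %.4g\n",
              x$thresholds$cell_area_max %||% NA,
              x$thresholds$nucleus_min_area))
  invisible(x)
}

#' Rolling-window trajectory smoothing
#'
#' Centred moving average of each coordinate with an odd window (default
#' 9 frames).  At trajectory edges the window shrinks symmetrically to
#' the largest odd size that fits, so the output has the same length as
#' the input and constant/linear trajectories pass through unchanged in
#' the interior.
#'
#' @param xy Numeric matrix or data.frame of coordinates (rows = frames).
#' @param window Odd window size `>= 1`.
#' @return Smoothed coordinates, same shape as `xy`.
#' @export
smooth_trajectory <- function(xy, window = 9L) {
  if (window < 1 || window %% 2 == 0) {
    mv_stop("`window` must be an odd positive integer",
            class = "migvar_parameter_error")
  }
  M <- as.matrix(xy)
  n <- nrow(M)
  if (n == 0L) return(xy)
  half <- (window - 1L) %/% 2L
  h <- pmin(half, seq_len(n) - 1L, n - seq_len(n))
  out <- M
  for (j in seq_len(ncol(M))) {
    cs <- cumsum(c(0, M[, j]))
    lo <- seq_len(n) - h
    hi <- seq_len(n) + h
    out[, j] <- (cs[hi + 1L] - cs[lo]) / (2 * h + 1)
  }
  if (is.data.frame(xy)) as.data.frame(out) else out
}

#' Instantaneous speed along a trajectory
#'
#' Euclidean displacement between consecutive (smoothed) positions
#' divided by the time step, in micrometres per minute; one value per
#' inter-frame interval, assigned to the later frame, so a trajectory of
#' `m` frames yields `m - 1` speeds (a 73-frame, 6-h movie at 5-min
#' intervals gives 72 values).
#'
#' @param xy Numeric matrix/data.frame of positions in micrometres.
#' @param frame_interval Time step in minutes (scalar), or a vector of
#'   time stamps in minutes (one per row of `xy`).
#' @return Numeric vector of length `nrow(xy) - 1` (empty for a
#'   single-point trajectory).
#' @export
instantaneous_speed <- function(xy, frame_interval) {
  M <- as.matrix(xy)
  n <- nrow(M)
  if (n < 2L) return(numeric(0))
  disp <- sqrt(rowSums(diff(M)^2))
  dt <- if (length(frame_interval) == 1L) {
    rep(assert_positive(frame_interval, "frame_interval"), n - 1L)
  } else {
    d <- diff(as.numeric(frame_interval))
    if (any(d <= 0)) mv_stop("time stamps must be strictly increasing",
                             class = "migvar_parameter_error")
    d
  }
  disp / dt
}

#' Add smoothed instantaneous cell speed (ICS) to a feature table
#'
#' Groups the table by cell, smooths the nucleus-centroid trajectory with
#' a centred rolling window and derives the instantaneous cell speed,
#' written to an `ics` column (NA at each cell's first frame).
#'
#' @param table Observation table with `time_min` and nucleus centroid
#'   columns.
#' @param window Odd smoothing window (frames).
#' @param coords Names of the x/y centroid columns (micrometres).
#' @return The table with an added/overwritten `ics` column (um/min).
#' @export
add_instantaneous_speed <- function(table, window = 9L,
                                    coords = c("nuc_x_um", "nuc_y_um")) {
  assert_columns(table, c("time_min", coords), "observation table")
  id_cols <- intersect(c("lab", "person", "experiment", "condition",
                         "replicate", "cell"), names(table))
  if (!"cell" %in% id_cols) {
    mv_schema_stop("observation table must have a `cell` column")
  }
  cid <- path_id(table, id_cols)
  table$ics <- rep(NA_real_, nrow(table))
  for (cc in unique(cid)) {
    ii <- which(cid == cc)
    ii <- ii[order(table$time_min[ii])]
    if (length(ii) < 2L) next
    sm <- smooth_trajectory(as.matrix(table[ii, coords]), window = window)
    table$ics[ii[-1L]] <- instantaneous_speed(sm, table$time_min[ii])
  }
  table
}

#' Z-score standardization of feature columns
#'
#' Centres and scales each feature to mean 0 and sample standard
#' deviation 1 over all pooled observations.  Zero-spread features are
#' dropped with a warning.
#'
#' @param table Observation table.
#' @param features Feature column names.
#' @return The table with standardized feature columns (constant features
#'   removed); attributes `center` and `scale` record the transformation.
#' @export
zscore_features <- function(table, features) {
  assert_columns(table, features, "observation table")
  if (nrow(table) < 2L) {
    mv_stop("z-scoring needs at least 2 observations",
            class = "migvar_parameter_error")
  }
  center <- scale_ <- stats::setNames(numeric(length(features)), features)
  dropped <- character(0)
  for (f in features) {
    v <- table[[f]]
    if (anyNA(v)) mv_schema_stop(sprintf("feature `%s` contains NA", f))
    center[f] <- mean(v)
    scale_[f] <- stats::sd(v)
    if (scale_[f] == 0) {
      dropped <- c(dropped, f)
    } else {
      table[[f]] <- (v - center[f]) / scale_[f]
    }
  }
  if (length(dropped)) {
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    table <- table[, setdiff(names(table), dropped), drop = FALSE]
  }
  keep <- setdiff(features, dropped)
  attr(table, "center") <- center[keep]
  attr(table, "scale") <- scale_[keep]
  attr(table, "features") <- keep
  table
}

#' Principal component analysis of a standardized feature table
#'
#' PCA of z-scored features with components ordered by decreasing
#' explained variance and a deterministic sign convention (the
#' largest-magnitude loading of each component is positive).
#'
#' @param table Output of [zscore_features()] (or any table whose feature
#'   columns are already standardized).
#' @param features Feature column names; defaults to the `features`
#'   attribute left by [zscore_features()].
#' @return An object of class `migvar_pca`: list with `loadings`
#'   (feature x component), `explained` (fractions summing to 1),
#'   `scores` (observation x component matrix) and `table` (the
#'   non-feature key columns bound to the scores).
#' @export
run_pca <- function(table, features = attr(table, "features")) {
  if (is.null(features)) {
    mv_stop("`features` must be given (or use zscore_features() first)",
            class = "migvar_parameter_error")
  }
  assert_columns(table, features, "table")
  if (nrow(table) < 2L) {
    mv_stop("PCA needs at least 2 observations",
            class = "migvar_parameter_error")
  }
  M <- as.matrix(table[, features, drop = FALSE])
  pc <- stats::prcomp(M, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) {
    if (v[which.max(abs(v))] < 0) -1 else 1
  })
  loadings <- sweep(pc$rotation, 2L, flip, "*")
  scores <- sweep(pc$x, 2L, flip, "*")
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  keys <- table[, setdiff(names(table), features), drop = FALSE]
  structure(list(loadings = loadings, explained = explained,
                 scores = scores,
                 table = cbind(keys, as.data.frame(scores))),
            class = "migvar_pca")
}

#' @export
print.migvar_pca <- function(x, ...) {
  cat(sprintf("PCA of %d feature(s), %d observation(s)\n",
              nrow(x$loadings), nrow(x$scores)))
  k <- min(5L, length(x$explained))
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}
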