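#' The feature inventory
#'
#' Names of the 18 per-cell-per-frame variables the extractor emits: 15
#' segmentation-derived morphology/dynamics variables plus the 3
#' mask-differencing region areas.
#'
#' @return A list with character vectors `segmentation` (15 names),
#'   `dynamic_regions` (3 names) and `all` (18 names).
#' @export
feature_inventory <- function() {
  segmentation <- c("area", "perimeter", "form_factor", "eccentricity",
                    "solidity", "extent", "major_axis", "minor_axis",
                    "equiv_diameter", "nucleus_area", "nucleus_perimeter",
                    "nucleus_form_factor", "nucleus_cell_ratio", "speed",
                    "nucleus_offset")
  dynamic_regions <- c("protrusion_area", "retraction_area",
                       "shortlived_area")
  list(segmentation = segmentation, dynamic_regions = dynamic_regions,
       all = c(segmentation, dynamic_regions))
}

#' Static morphology features of one frame
#'
#' Per-label shape measurements of a cell mask and its matching nucleus
#' mask (shared label space), in physical units: areas (um^2), perimeters
#' (um), form factor `4 pi A / P^2`, eccentricity, solidity, extent, axis
#' lengths and equivalent diameter (um), nucleus-to-cell area ratio and
#' nucleus-to-cell centroid offset (um).  Nucleus labels without a cell
#' label are excluded and reported in the `flagged` attribute.
#'
#' @param cell_mask,nucleus_mask Integer label matrices.
#' @param pixel_size Micrometres per pixel.
#' @return A data.frame with one row per cell label, centroid columns
#'   (`cx_um`, `cy_um`, `nuc_x_um`, `nuc_y_um`) and the static feature
#'   columns; attribute `flagged` lists orphan nucleus labels.
#' @export
static_features <- function(cell_mask, nucleus_mask, pixel_size) {
  assert_positive(pixel_size, "pixel_size")
  cf <- shape_features(cell_mask, pixel_size)
  nf <- shape_features(nucleus_mask, pixel_size)
  orphans <- setdiff(nf$label, cf$label)
  nf <- nf[nf$label %in% cf$label, , drop = FALSE]
  m <- match(cf$label, nf$label)
  out <- data.frame(
    label = cf$label,
    area = cf$area, perimeter = cf$perimeter,
    form_factor = cf$form_factor, eccentricity = cf$eccentricity,
    solidity = cf$solidity, extent = cf$extent,
    major_axis = cf$major_axis, minor_axis = cf$minor_axis,
    equiv_diameter = cf$equiv_diameter,
    nucleus_area = nf$area[m], nucleus_perimeter = nf$perimeter[m],
    nucleus_form_factor = nf$form_factor[m],
    nucleus_cell_ratio = nf$area[m] / cf$area,
    nucleus_offset = sqrt((nf$cx_um[m] - cf$cx_um)^2 +
                            (nf$cy_um[m] - cf$cy_um)^2),
    cx_um = cf$cx_um, cy_um = cf$cy_um,
    nuc_x_um = nf$cx_um[m], nuc_y_um = nf$cy_um[m])
  attr(out, "flagged") <- orphans
  out
}

#' Protrusion, retraction and short-lived region areas
#'
#' Compares a cell's mask across three consecutive frames: protrusions
#' are pixels present now but absent in the previous frame, retractions
#' pixels present now but absent in the next, and short-lived regions
#' pixels present at this time point only (absent from both neighbours,
#' lifetime under one frame interval).  Areas are pixel counts times
#' `pixel_size^2`.  At the first (last) frame of a movie the protrusion
#' (retraction) is undefined and reported as NA; a label present in the
#' current frame but in neither neighbour is a whole-cell appearance and
#' is excluded (all three NA) and flagged.
#'
#' @param mask_prev,mask_curr,mask_next Integer label matrices sharing a
#'   label space; `mask_prev`/`mask_next` may be NULL at movie edges.
#' @param pixel_size Micrometres per pixel.
#' @return Data.frame with one row per label of `mask_curr`:
#'   `protrusion_area`, `retraction_area`, `shortlived_area` (um^2) and
#'   logical `flagged`.
#' @export
dynamic_regions <- function(mask_prev, mask_curr, mask_next, pixel_size) {
  assert_positive(pixel_size, "pixel_size")
  labels <- sort(setdiff(unique(as.integer(mask_curr)), 0L))
  a <- pixel_size^2
  pixset <- function(mask, lab) if (is.null(mask)) NULL else which(mask == lab)
  out <- data.frame(label = labels, protrusion_area = NA_real_,
                    retraction_area = NA_real_, shortlived_area = NA_real_,
                    flagged = FALSE)
  for (i in seq_along(labels)) {
    lab <- labels[i]
    cur <- which(mask_curr == lab)
    prev <- pixset(mask_prev, lab)
    nxt <- pixset(mask_next, lab)
    if (!is.null(mask_prev) && !is.null(mask_next) &&
        length(prev) == 0L && length(nxt) == 0L) {
      out$flagged[i] <- TRUE
      next
    }
    if (!is.null(mask_prev)) {
      out$protrusion_area[i] <- length(setdiff(cur, prev)) * a
    }
    if (!is.null(mask_next)) {
      out$retraction_area[i] <- length(setdiff(cur, nxt)) * a
    }
    if (!is.null(mask_prev) && !is.null(mask_next)) {
      out$shortlived_area[i] <- length(setdiff(cur, union(prev, nxt))) * a
    }
  }
  out
}

#' Track cells across frames by nucleus distance
#'
#' Greedy nearest-neighbour frame-to-frame linking of nucleus centroids:
#' candidate links between open track ends and next-frame centroids are
#' accepted in order of increasing distance (ties broken by lower label
#' id), one-to-one; links longer than `max_link_distance` are never made,
#' ending the track and starting a new one.
#'
#' @param centroids_per_frame List (one element per frame) of data.frames
#'   with columns `label`, `x`, `y` (micrometres).
#' @param max_link_distance Maximum link length in micrometres.
#' @return Data.frame with columns `track`, `frame`, `label`, `x`, `y`;
#'   empty for an empty movie.
#' @export
track_cells <- function(centroids_per_frame, max_link_distance) {
  assert_positive(max_link_distance, "max_link_distance")
  empty <- data.frame(track = integer(0), frame = integer(0),
                      label = integer(0), x = numeric(0), y = numeric(0))
  if (!length(centroids_per_frame)) return(empty)
  rows <- list()
  next_track <- 1L
  open <- NULL   # data.frame: track, label, x, y
  for (t in seq_along(centroids_per_frame)) {
    cur <- centroids_per_frame[[t]]
    if (is.null(cur) || !nrow(cur)) {
      open <- NULL
      next
    }
    cur <- cur[order(cur$label), , drop = FALSE]
    assign_track <- rep(NA_integer_, nrow(cur))
    if (!is.null(open) && nrow(open)) {
      d <- sqrt(outer(open$x, cur$x, "-")^2 + outer(open$y, cur$y, "-")^2)
      cand <- which(d <= max_link_distance, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d[cand], open$label[cand[, 1L]],
                     cur$label[cand[, 2L]])
        cand <- cand[ord, , drop = FALSE]
        used_o <- logical(nrow(open)); used_c <- logical(nrow(cur))
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1L]; j <- cand[r, 2L]
          if (!used_o[i] && !used_c[j]) {
            used_o[i] <- used_c[j] <- TRUE
            assign_track[j] <- open$track[i]
          }
        }
      }
    }
    new <- which(is.na(assign_track))
    if (length(new)) {
      assign_track[new] <- next_track + seq_along(new) - 1L
      next_track <- next_track + length(new)
    }
    rows[[t]] <- data.frame(track = assign_track, frame = t,
                            label = cur$label, x = cur$x, y = cur$y)
    open <- data.frame(track = assign_track, label = cur$label,
                       x = cur$x, y = cur$y)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$track, out$frame), , drop = FALSE]
}

#' Extract the full feature table from a mask movie
#'
#' Runs static shape measurement, cell-centroid speed and
#' protrusion/retraction/short-lived differencing on every frame of a
#' labeled movie and assembles a long-format observation table with the
#' 18-variable inventory of [feature_inventory()], one row per cell and
#' frame.  Speed is the displacement of the cell centroid between
#' consecutive frames divided by the frame interval (um/min, assigned to
#' the later frame).  Hierarchy labels, when given, are prepended as key
#' columns so that tables from many replicates can be concatenated.
#'
#' @param movie A `migvar_movie` (from [simulate_mask_movie()] or
#'   [read_mask_movie()]).
#' @param hierarchy Optional named list/vector with entries `lab`,
#'   `person`, `experiment`, `condition`, `replicate`.
#' @return Data.frame with key columns (if any), `cell` (`"cell<label>"`),
#'   `cell_label`, `frame`, `time_min`, the 18 feature columns, and
#'   centroid columns (`cx_um`, `cy_um`, `nuc_x_um`, `nuc_y_um`) used by
#'   tracking-level QC.
#' @export
extract_features <- function(movie, hierarchy = NULL) {
  stopifnot(inherits(movie, "migvar_movie"))
  nf <- movie$n_frames
  ps <- movie$pixel_size
  static <- vector("list", nf)
  for (t in seq_len(nf)) {
    s <- static_features(movie$cell_masks[[t]], movie$nucleus_masks[[t]], ps)
    if (nrow(s)) s$frame <- t
    static[[t]] <- s
  }
  st <- do.call(rbind, static)
  if (is.null(st) || !nrow(st)) {
    mv_stop("movie contains no labeled cells", class = "migvar_schema_error")
  }

  dyn <- vector("list", nf)
  for (t in seq_len(nf)) {
    d <- dynamic_regions(if (t > 1L) movie$cell_masks[[t - 1L]],
                         movie$cell_masks[[t]],
                         if (t < nf) movie$cell_masks[[t + 1L]], ps)
    if (nrow(d)) d$frame <- t
    dyn[[t]] <- d
  }
  dy <- do.call(rbind, dyn)

  out <- merge(st, dy, by = c("label", "frame"), all.x = TRUE, sort = FALSE)
  out <- out[order(out$label, out$frame), , drop = FALSE]

  # cell-centroid speed, assigned to the later frame
  out$speed <- NA_real_
  for (lab in unique(out$label)) {
    ii <- which(out$label == lab)
    if (length(ii) > 1L) {
      dx <- diff(out$cx_um[ii]); dy_ <- diff(out$cy_um[ii])
      dt <- diff(out$frame[ii]) * movie$frame_interval
      out$speed[ii[-1L]] <- sqrt(dx^2 + dy_^2) / dt
    }
  }

  out$time_min <- (out$frame - 1) * movie$frame_interval
  out$cell <- sprintf("cell%d", out$label)
  out$cell_label <- out$label

  keys <- NULL
  if (!is.null(hierarchy)) {
    hierarchy <- as.list(hierarchy)
    keys <- as.data.frame(hierarchy[intersect(
      c("lab", "person", "experiment", "condition", "replicate"),
      names(hierarchy))], stringsAsFactors = FALSE)
  }
  cols <- c("cell", "cell_label", "frame", "time_min",
            feature_inventory()$all, "cx_um", "cy_um", "nuc_x_um",
            "nuc_y_um")
  out <- out[, cols]
  rownames(out) <- NULL
  if (!is.null(keys) && ncol(keys)) out <- cbind(keys, out, row.names = NULL)
  out
}
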