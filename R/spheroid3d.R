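#' Sphere through four points
#'
#' The unique sphere passing through four non-coplanar points, obtained
#' from the linear system expressing equal distance of the centre to all
#' points.  Used to reconstruct the spheroid-core reference sphere from
#' four manually annotated surface points.
#'
#' @param p1,p2,p3,p4 Numeric xyz coordinates (micrometres).
#' @param max_condition Degeneracy guard: a geometry error is raised when
#'   the reciprocal condition number of the system falls below
#'   `1/max_condition` (near-coplanar points).
#' @return A list with `center` (length-3 numeric) and `radius`.
#' @examples
#' s <- circumsphere(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
#' s$center; s$radius  # origin, sqrt(3)
#' @export
circumsphere <- function(p1, p2, p3, p4, max_condition = 1e12) {
  P <- rbind(p1, p2, p3, p4)
  if (!is.numeric(P) || any(dim(P) != c(4L, 3L)) || anyNA(P)) {
    mv_stop("four finite xyz points are required",
            class = "migvar_geometry_error")
  }
  A <- 2 * sweep(P[2:4, , drop = FALSE], 2, P[1L, ])
  rhs <- rowSums(P[2:4, , drop = FALSE]^2) - sum(P[1L, ]^2)
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1 / max_condition) {
    mv_stop("the four points are coplanar or nearly so: no unique sphere",
            class = "migvar_geometry_error")
  }
  center <- as.numeric(solve(A, rhs))
  list(center = center, radius = sqrt(sum((P[1L, ] - center)^2)))
}

#' Signed migration distance from the spheroid core
#'
#' Distance of a nucleus centroid to the surface of the core reference
#' sphere, `||x - center|| - radius`: positive outside the core
#' (invasion), negative inside.
#'
#' @param nucleus Numeric xyz coordinate, or a matrix with one nucleus per
#'   row.
#' @param sphere A list with `center` and `radius`, as returned by
#'   [circumsphere()].
#' @return Signed distance(s) in the units of the coordinates.
#' @export
migration_distance <- function(nucleus, sphere) {
  M <- if (is.matrix(nucleus)) nucleus else matrix(nucleus, ncol = 3L)
  if (ncol(M) != 3L || anyNA(M)) {
    mv_stop("nucleus coordinates must be xyz", class = "migvar_geometry_error")
  }
  sqrt(colSums((t(M) - sphere$center)^2)) - sphere$radius
}

#' Precision and recall of nucleus detection
#'
#' One-to-one matching between segmented and annotated nucleus centroids:
#' candidate pairs within `match_radius` are accepted greedily by
#' increasing distance (ties broken by lower indices), each point matched
#' at most once.  Precision is true positives over all segmented nuclei,
#' recall over all annotated nuclei.
#'
#' @param segmented,annotated Matrices of xyz centroids (one per row);
#'   either may be empty.
#' @param match_radius Maximum centre-to-centre distance (micrometres)
#'   for a true positive.
#' @return A list with `precision` (NA when the segmentation is empty),
#'   `recall`, `n_true_positive` and the matched index pairs.
#' @export
match_precision_recall <- function(segmented, annotated, match_radius = 5) {
  seg <- as_xyz(segmented)
  ann <- as_xyz(annotated)
  ns <- nrow(seg); na <- nrow(ann)
  if (ns == 0L) {
    return(list(precision = NA_real_, recall = 0,
                n_true_positive = 0L,
                matches = data.frame(segmented = integer(0),
                                     annotated = integer(0))))
  }
  pairs <- NULL
  if (na > 0L) {
    d <- sqrt(pmax(outer(rowSums(seg^2), rowSums(ann^2), "+") -
                     2 * seg %*% t(ann), 0))
    ok <- which(d <= match_radius, arr.ind = TRUE)
    if (nrow(ok)) {
      ord <- order(d[ok], ok[, 1L], ok[, 2L])
      ok <- ok[ord, , drop = FALSE]
      used_s <- logical(ns); used_a <- logical(na)
      keep <- logical(nrow(ok))
      for (i in seq_len(nrow(ok))) {
        s <- ok[i, 1L]; a <- ok[i, 2L]
        if (!used_s[s] && !used_a[a]) {
          used_s[s] <- used_a[a] <- TRUE
          keep[i] <- TRUE
        }
      }
      pairs <- ok[keep, , drop = FALSE]
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  list(precision = tp / ns,
       recall = if (na > 0L) tp / na else NA_real_,
       n_true_positive = tp,
       matches = data.frame(
         segmented = if (tp) pairs[, 1L] else integer(0),
         annotated = if (tp) pairs[, 2L] else integer(0)))
}

as_xyz <- function(x) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0L) || !length(x)) {
    return(matrix(numeric(0), 0L, 3L))
  }
  M <- if (is.matrix(x)) x else matrix(x, ncol = 3L, byrow = FALSE)
  if (ncol(M) != 3L) mv_stop("centroids must have xyz columns",
                             class = "migvar_geometry_error")
  M
}

#' Remove centroids near the scene border
#'
#' Border-touching segments are unreliable in stack-based nucleus
#' segmentation; this filter drops centroids within `margin` of the
#' bounding box of the scene.
#'
#' @param centroids Matrix of xyz centroids.
#' @param bounds A 2x3 matrix (rows: min, max) defining the scene box.
#' @param margin Margin width in coordinate units.
#' @return The retained centroid rows.
#' @export
filter_border_centroids <- function(centroids, bounds, margin = 0) {
  M <- as_xyz(centroids)
  keep <- rep(TRUE, nrow(M))
  for (j in 1:3) {
    keep <- keep & M[, j] >= bounds[1L, j] + margin &
      M[, j] <= bounds[2L, j] - margin
  }
  M[keep, , drop = FALSE]
}
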