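#' Simulate an annotated spheroid invasion scene
#'
#' Builds one 3D scene with known ground truth: four non-coplanar core
#' surface points lying exactly on a sphere of the requested centre and
#' radius (a randomly rotated regular tetrahedron inscribed in the core),
#' and nucleus centroids placed at recorded signed radial offsets from the
#' core surface along random directions.  The recorded offsets are, by
#' construction, the true migration distances.
#'
#' @param core_center Numeric xyz centre of the spheroid core (um).
#' @param core_radius Core radius (um), `> 0`.
#' @param nucleus_radial_offsets Signed radial offsets of the nuclei from
#'   the core surface (um); positive = outside (invaded).
#' @param seed Integer seed for the rotation and nucleus directions.
#' @return An object of class `migvar_scene`: a list with `core_points`
#'   (4 x 3 matrix), `sphere` (`center`, `radius`), `nuclei` (matrix of
#'   centroids) and `offsets` (the ground-truth distances).
#' @examples
#' sc <- simulate_spheroid_scene(c(0, 0, 0), 100, c(50, -10), seed = 1)
#' migration_distance(sc$nuclei, circumsphere(sc$core_points[1, ],
#'   sc$core_points[2, ], sc$core_points[3, ], sc$core_points[4, ]))
#' @export
simulate_spheroid_scene <- function(core_center = c(0, 0, 0),
                                    core_radius = 100,
                                    nucleus_radial_offsets = numeric(0),
                                    seed = 1L) {
  assert_positive(core_radius, "core_radius")
  if (length(core_center) != 3L || anyNA(core_center)) {
    mv_stop("`core_center` must be a finite xyz coordinate",
            class = "migvar_parameter_error")
  }
  set.seed(derive_seed(seed, "spheroid-scene"))
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  R <- random_rotation()
  core_points <- sweep(tetra %*% t(R) * core_radius, 2, core_center, "+")

  k <- length(nucleus_radial_offsets)
  nuclei <- matrix(numeric(0), 0L, 3L)
  if (k > 0L) {
    dirs <- matrix(stats::rnorm(3L * k), k, 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    nuclei <- sweep(dirs * (core_radius + nucleus_radial_offsets), 2,
                    core_center, "+")
  }
  colnames(core_points) <- colnames(nuclei) <- c("x", "y", "z")
  structure(list(core_points = core_points,
                 sphere = list(center = as.numeric(core_center),
                               radius = as.numeric(core_radius)),
                 nuclei = nuclei,
                 offsets = as.numeric(nucleus_radial_offsets)),
            class = "migvar_scene")
}

# Uniform random rotation from a QR decomposition of a Gaussian matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Write / read a spheroid scene as CSV
#'
#' Plain-text exchange format: one row per point with a `role` column
#' (`core_point` or `nucleus`), xyz coordinates in micrometres, and the
#' ground-truth `offset` for nuclei (NA for core points).
#'
#' @param scene A `migvar_scene`.
#' @param path File path.
#' @return `read_spheroid_scene` returns a `migvar_scene` (with the
#'   fitted rather than generative sphere when offsets are absent).
#' @export
write_spheroid_scene <- function(scene, path) {
  df <- rbind(
    data.frame(role = "core_point", scene$core_points, offset = NA_real_),
    if (nrow(scene$nuclei)) {
      data.frame(role = "nucleus", scene$nuclei, offset = scene$offsets)
    }
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spheroid_scene
#' @export
read_spheroid_scene <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("role", "x", "y", "z"), "scene CSV")
  cp <- as.matrix(df[df$role == "core_point", c("x", "y", "z")])
  if (nrow(cp) != 4L) {
    mv_stop("scene must contain exactly 4 core points",
            class = "migvar_geometry_error")
  }
  nu <- as.matrix(df[df$role == "nucleus", c("x", "y", "z")])
  sph <- circumsphere(cp[1L, ], cp[2L, ], cp[3L, ], cp[4L, ])
  offsets <- if ("offset" %in% names(df)) {
    df$offset[df$role == "nucleus"]
  } else {
    rep(NA_real_, nrow(nu))
  }
  structure(list(core_points = cp, sphere = sph, nuclei = nu,
                 offsets = offsets),
            class = "migvar_scene")
}

#' Simulate a two-laboratory 3D spheroid invasion study
#'
#' Emulates a multi-site spheroid invasion design: laboratories run
#' independent experiments, each with technical replicates per collagen
#' condition and several spheroids per replicate.  Per-nucleus migration
#' distances follow a nested Gaussian random-intercept model (laboratory,
#' experiment, replicate, spheroid levels plus per-nucleus noise) around
#' condition-specific means, with cells invading farther in low-density
#' collagen.  Every spheroid is materialized as an annotated scene
#' ([simulate_spheroid_scene()]) and its distances are recovered through
#' the geometry pipeline (four-point sphere fit + signed distance), so the
#' generated table exercises the full 3D path.
#'
#' @param n_labs,n_experiments,n_replicates,n_spheroids,n_nuclei Design
#'   counts (defaults: 2 laboratories, 3 experiments, 3 replicates per
#'   condition, 3 spheroids per replicate, 30 nuclei per spheroid).
#' @param conditions Condition labels (collagen density, mg/ml).
#' @param mean_distance Named mean migration distance per condition (um).
#' @param sigma2 Named variances of the random intercepts
#'   (`lab`, `experiment`, `replicate`, `spheroid`), in um^2.
#' @param sigma_nucleus Per-nucleus standard deviation (um).
#' @param core_radius Core radius used for all scenes (um).
#' @param seed Integer seed.
#' @return A list with `table` (columns `lab`, `experiment`, `condition`,
#'   `replicate`, `spheroid`, `nucleus`, `distance`, `true_offset`),
#'   `truth` (per-unit intercepts) and `scenes` (named list of
#'   `migvar_scene` objects).
#' @export
simulate_invasion_study <- function(n_labs = 2, n_experiments = 3,
                                    n_replicates = 3, n_spheroids = 3,
                                    n_nuclei = 30,
                                    conditions = c("2.5", "6.0"),
                                    mean_distance = c("2.5" = 80,
                                                      "6.0" = 40),
                                    sigma2 = c(lab = 100, experiment = 25,
                                               replicate = 9,
                                               spheroid = 16),
                                    sigma_nucleus = 30,
                                    core_radius = 150, seed = 1L) {
  for (nm in c("n_labs", "n_experiments", "n_replicates", "n_spheroids",
               "n_nuclei")) assert_count(get(nm), nm)
  need <- c("lab", "experiment", "replicate", "spheroid")
  stopifnot(all(need %in% names(sigma2)), all(sigma2 >= 0),
            all(conditions %in% names(mean_distance)))
  set.seed(derive_seed(seed, "invasion-study"))

  labs <- sprintf("L%d", seq_len(n_labs))
  exps <- sprintf("E%d", seq_len(n_experiments))
  reps <- sprintf("r%d", seq_len(n_replicates))
  sphs <- sprintf("s%d", seq_len(n_spheroids))

  u_lab <- stats::setNames(stats::rnorm(n_labs, 0, sqrt(sigma2[["lab"]])),
                           labs)
  key <- expand.grid(spheroid = sphs, replicate = reps,
                     condition = conditions, experiment = exps, lab = labs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key$replicate <- paste(key$condition, key$replicate, sep = ".")

  eid <- path_id(key, c("lab", "experiment"))
  rid <- path_id(key, c("lab", "experiment", "replicate"))
  sid <- path_id(key, c("lab", "experiment", "replicate", "spheroid"))
  u_exp <- stats::setNames(
    stats::rnorm(length(unique(eid)), 0, sqrt(sigma2[["experiment"]])),
    unique(eid))
  u_rep <- stats::setNames(
    stats::rnorm(length(unique(rid)), 0, sqrt(sigma2[["replicate"]])),
    unique(rid))
  u_sph <- stats::setNames(
    stats::rnorm(length(unique(sid)), 0, sqrt(sigma2[["spheroid"]])),
    unique(sid))

  scenes <- vector("list", nrow(key))
  names(scenes) <- sid
  rows <- vector("list", nrow(key))
  for (i in seq_len(nrow(key))) {
    mu <- mean_distance[[key$condition[i]]] + u_lab[[key$lab[i]]] +
      u_exp[[eid[i]]] + u_rep[[rid[i]]] + u_sph[[sid[i]]]
    offsets <- stats::rnorm(n_nuclei, mu, sigma_nucleus)
    scene <- simulate_spheroid_scene(
      core_center = stats::runif(3, -50, 50), core_radius = core_radius,
      nucleus_radial_offsets = offsets,
      seed = derive_seed(seed, paste0("scene:", sid[i])))
    scenes[[i]] <- scene
    sph_fit <- circumsphere(scene$core_points[1L, ], scene$core_points[2L, ],
                            scene$core_points[3L, ], scene$core_points[4L, ])
    d <- migration_distance(scene$nuclei, sph_fit)
    rows[[i]] <- data.frame(
      key[i, , drop = FALSE], nucleus = sprintf("n%03d", seq_len(n_nuclei)),
      distance = d, true_offset = offsets, row.names = NULL,
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table,
       truth = list(u_lab = u_lab, u_experiment = u_exp, u_replicate = u_rep,
                    u_spheroid = u_sph,
                    mean_distance = mean_distance, sigma2 = sigma2,
                    sigma_nucleus = sigma_nucleus),
       scenes = scenes)
}
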