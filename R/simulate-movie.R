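#' Scripted cell program for a synthetic mask movie
#'
#' Describes one cell of a synthetic labeled movie: a disk of fixed radius
#' whose centroid translates by a scripted per-frame displacement, plus
#' optional scripted "bump" events — extra membrane regions appearing at a
#' boundary angle for a limited lifetime, which create known protrusion /
#' retraction / short-lived regions.
#'
#' @param label Positive integer label, stable across frames.
#' @param centroid Initial centroid `c(x, y)` in pixels (pixel-centre
#'   coordinates, origin at the top-left pixel, x rightward, y downward).
#' @param radius Disk radius in pixels.
#' @param displacement Per-frame displacement `c(dx, dy)` in pixels,
#'   recycled, or an `(n_frames - 1) x 2` matrix.
#' @param bumps List of bump events, each a list with `frame` (first frame
#'   of appearance), `area` (approximate extra area in pixels), `lifetime`
#'   (number of frames present, `>= 1`) and `angle` (radians, boundary
#'   position).
#' @return A `migvar_cell_program` list.
#' @export
cell_program <- function(label, centroid, radius, displacement = c(0, 0),
                         bumps = list()) {
  assert_count(label, "label")
  assert_positive(radius, "radius")
  stopifnot(length(centroid) == 2L, is.numeric(centroid))
  for (b in bumps) {
    stopifnot(all(c("frame", "area", "lifetime", "angle") %in% names(b)),
              b$lifetime >= 1L, b$area > 0)
  }
  structure(list(label = as.integer(label), centroid = as.numeric(centroid),
                 radius = as.numeric(radius), displacement = displacement,
                 bumps = bumps),
            class = "migvar_cell_program")
}

#' Specification of a synthetic labeled mask movie
#'
#' @param n_frames Number of frames.
#' @param image_size `c(width, height)` in pixels.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param frame_interval Frame interval in minutes.
#' @param cells List of [cell_program()]s.
#' @param nucleus_fraction Nucleus radius as a fraction of the cell
#'   radius, in (0, 1): the nucleus disk is strictly inside its cell.
#' @return A `migvar_movie_spec` list.
#' @export
mask_movie_spec <- function(n_frames, image_size = c(256L, 256L),
                            pixel_size = 0.826, frame_interval = 5,
                            cells = list(), nucleus_fraction = 0.4) {
  assert_count(n_frames, "n_frames")
  assert_positive(pixel_size, "pixel_size")
  assert_positive(frame_interval, "frame_interval")
  stopifnot(length(image_size) == 2L, all(image_size >= 8))
  if (nucleus_fraction <= 0 || nucleus_fraction >= 1) {
    mv_stop("`nucleus_fraction` must be in (0, 1)",
            class = "migvar_parameter_error")
  }
  labels <- vapply(cells, function(p) p$label, integer(1))
  if (anyDuplicated(labels)) {
    mv_stop("cell labels must be distinct", class = "migvar_parameter_error")
  }
  structure(list(n_frames = as.integer(n_frames),
                 image_size = as.integer(image_size),
                 pixel_size = as.numeric(pixel_size),
                 frame_interval = as.numeric(frame_interval),
                 cells = cells,
                 nucleus_fraction = as.numeric(nucleus_fraction)),
            class = "migvar_movie_spec")
}

# pixel-centre rasterization of a disk into linear indices of an
# (h rows x w cols) matrix; pixel (r, c) has centre (x, y) = (c-1, r-1)
disk_pixels <- function(center, radius, w, h) {
  cx <- center[1L]; cy <- center[2L]
  c0 <- max(1L, floor(cx - radius) + 1L); c1 <- min(w, ceiling(cx + radius) + 1L)
  r0 <- max(1L, floor(cy - radius) + 1L); r1 <- min(h, ceiling(cy + radius) + 1L)
  if (c0 > c1 || r0 > r1) return(integer(0))
  cc <- c0:c1; rr <- r0:r1
  dx2 <- ((cc - 1) - cx)^2
  dy2 <- ((rr - 1) - cy)^2
  inside <- outer(dy2, dx2, "+") <= radius^2
  idx <- which(inside)
  ri <- rr[(idx - 1L) %% length(rr) + 1L]
  ci <- cc[(idx - 1L) %/% length(rr) + 1L]
  (ci - 1L) * h + ri
}

#' Simulate a labeled mask movie with recorded ground truth
#'
#' Renders the scripted cells of a [mask_movie_spec()] into per-frame
#' cell- and nucleus-label images (pixel-centre-in-shape rasterization)
#' and records the ground truth that a feature extractor must reproduce:
#' per-frame pixel areas and centroids of every cell and nucleus, scripted
#' speeds, and protrusion / retraction / short-lived pixel counts obtained
#' by set differences of the rendered per-cell masks.  Scripted cells may
#' never overlap or touch the image border; violating scripts raise a
#' generation error.
#'
#' @param spec A [mask_movie_spec()].
#' @return A list with `movie` (class `migvar_movie`: `cell_masks` and
#'   `nucleus_masks` as lists of integer label matrices, `pixel_size`,
#'   `frame_interval`) and `truth` (data.frame keyed by frame and label
#'   with `area_um2`, `centroid_x_um`, `centroid_y_um`, nucleus
#'   counterparts, `speed_um_min`, `protrusion_um2`, `retraction_um2`,
#'   `shortlived_um2`).
#' @export
simulate_mask_movie <- function(spec) {
  stopifnot(inherits(spec, "migvar_movie_spec"))
  w <- spec$image_size[1L]; h <- spec$image_size[2L]
  nf <- spec$n_frames
  ps <- spec$pixel_size

  # per-cell per-frame pixel sets
  cell_pix <- list(); nuc_pix <- list()
  centroids <- list()
  for (prog in spec$cells) {
    disp <- prog$displacement
    if (is.matrix(disp)) {
      if (nrow(disp) != nf - 1L || ncol(disp) != 2L) {
        mv_stop("displacement matrix must be (n_frames - 1) x 2",
                class = "migvar_generation_error")
      }
      steps <- disp
    } else {
      steps <- matrix(rep(as.numeric(disp), length.out = 2L * max(nf - 1L, 0L)),
                      ncol = 2L, byrow = TRUE)
    }
    pos <- rbind(prog$centroid,
                 if (nf > 1L) sweep(apply(steps, 2L, cumsum), 2,
                                    prog$centroid, "+"))
    pos <- matrix(pos, ncol = 2L)
    key <- as.character(prog$label)
    cp <- vector("list", nf); np <- vector("list", nf)
    for (t in seq_len(nf)) {
      pix <- disk_pixels(pos[t, ], prog$radius, w, h)
      for (b in prog$bumps) {
        if (t >= b$frame && t < b$frame + b$lifetime) {
          bc <- pos[t, ] + prog$radius * c(cos(b$angle), sin(b$angle))
          pix <- union(pix, disk_pixels(bc, sqrt(b$area / pi), w, h))
        }
      }
      rr <- (pix - 1L) %% h + 1L
      cc <- (pix - 1L) %/% h + 1L
      if (!length(pix)) {
        mv_stop(sprintf("cell %s renders to zero pixels at frame %d", key, t),
                class = "migvar_generation_error")
      }
      if (any(rr == 1L | rr == h | cc == 1L | cc == w)) {
        mv_stop(sprintf("cell %s touches the image border at frame %d",
                        key, t),
                class = "migvar_generation_error")
      }
      cp[[t]] <- pix
      np[[t]] <- disk_pixels(pos[t, ], spec$nucleus_fraction * prog$radius,
                             w, h)
    }
    cell_pix[[key]] <- cp
    nuc_pix[[key]] <- np
    centroids[[key]] <- pos
  }

  labels <- names(cell_pix)
  cell_masks <- vector("list", nf); nucleus_masks <- vector("list", nf)
  for (t in seq_len(nf)) {
    m <- matrix(0L, h, w); nm <- matrix(0L, h, w)
    for (key in labels) {
      pix <- cell_pix[[key]][[t]]
      if (any(m[pix] != 0L)) {
        mv_stop(sprintf("cells overlap at frame %d", t),
                class = "migvar_generation_error")
      }
      m[pix] <- as.integer(key)
      nm[nuc_pix[[key]][[t]]] <- as.integer(key)
    }
    cell_masks[[t]] <- m; nucleus_masks[[t]] <- nm
  }

  # ground truth from the rendered pixel sets
  rows <- list()
  for (key in labels) {
    cp <- cell_pix[[key]]; np <- nuc_pix[[key]]
    for (t in seq_len(nf)) {
      pix <- cp[[t]]
      rr <- (pix - 1L) %% h + 1L; cc <- (pix - 1L) %/% h + 1L
      npx <- np[[t]]
      nr <- (npx - 1L) %% h + 1L; ncc <- (npx - 1L) %/% h + 1L
      prot <- if (t > 1L) length(setdiff(pix, cp[[t - 1L]])) else NA_integer_
      retr <- if (t < nf) length(setdiff(pix, cp[[t + 1L]])) else NA_integer_
      shrt <- if (t > 1L && t < nf) {
        length(setdiff(pix, union(cp[[t - 1L]], cp[[t + 1L]])))
      } else NA_integer_
      spd <- if (t > 1L) {
        sqrt(sum((centroids[[key]][t, ] - centroids[[key]][t - 1L, ])^2)) *
          ps / spec$frame_interval
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t, label = as.integer(key),
        time_min = (t - 1) * spec$frame_interval,
        area_um2 = length(pix) * ps^2,
        centroid_x_um = mean(cc - 1) * ps, centroid_y_um = mean(rr - 1) * ps,
        nucleus_area_um2 = length(npx) * ps^2,
        nucleus_x_um = mean(ncc - 1) * ps, nucleus_y_um = mean(nr - 1) * ps,
        speed_um_min = spd,
        protrusion_um2 = prot * ps^2, retraction_um2 = retr * ps^2,
        shortlived_um2 = shrt * ps^2)
    }
  }
  truth <- do.call(rbind, rows)

  movie <- structure(list(cell_masks = cell_masks,
                          nucleus_masks = nucleus_masks,
                          pixel_size = ps,
                          frame_interval = spec$frame_interval,
                          n_frames = nf, image_size = spec$image_size),
                     class = "migvar_movie")
  list(movie = movie, truth = truth)
}

#' @export
print.migvar_movie <- function(x, ...) {
  cat(sprintf("Labeled mask movie: %d frame(s), %d x %d px, %.4g um/px, %g min/frame\n",
              x$n_frames, x$image_size[1L], x$image_size[2L], x$pixel_size,
              x$frame_interval))
  invisible(x)
}

#' Random non-overlapping cell programs
#'
#' Places cells on a spaced grid and gives each a bounded random-walk
#' displacement and random bump events, guaranteeing by construction that
#' cells never overlap nor touch the border.  Used to generate arbitrary
#' valid movies for property testing.
#'
#' @param n_cells Number of cells.
#' @param n_frames Number of frames.
#' @param image_size `c(width, height)` pixels; enlarged automatically if
#'   the grid does not fit.
#' @param radius_range Cell radius range (pixels).
#' @param max_step Maximum per-axis displacement per frame (pixels).
#' @param bump_prob Probability that a cell carries a bump event.
#' @param seed Integer seed.
#' @return A list with `programs` and the possibly enlarged `image_size`.
#' @export
random_cell_programs <- function(n_cells, n_frames, image_size = c(256, 256),
                                 radius_range = c(18, 26), max_step = 1.5,
                                 bump_prob = 0.5, seed = 1L) {
  set.seed(derive_seed(seed, "cell-programs"))
  rmax <- radius_range[2L]
  drift <- max_step * (n_frames - 1L)
  bump_r <- sqrt(60 / pi)
  spacing <- ceiling(2 * (rmax + bump_r) + 2 * min(drift, 12) + 6)
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  need <- c(ncol_grid, nrow_grid) * spacing + 2 * spacing
  image_size <- pmax(image_size, need)
  programs <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    gx <- (i - 1L) %% ncol_grid
    gy <- (i - 1L) %/% ncol_grid
    center <- c(gx + 1, gy + 1) * spacing
    r <- stats::runif(1, radius_range[1L], radius_range[2L])
    steps <- matrix(stats::runif(2L * max(n_frames - 1L, 0L),
                                 -max_step, max_step), ncol = 2L)
    if (n_frames > 1L) {
      # clamp the cumulative walk so the cell stays in its grid slot
      lim <- min(drift, 12)
      cum <- apply(steps, 2L, cumsum)
      cum <- pmin(pmax(cum, -lim), lim)
      steps <- rbind(cum[1L, ], apply(cum, 2L, diff))
      steps <- matrix(steps, ncol = 2L)
    }
    bumps <- list()
    if (n_frames >= 3L && stats::runif(1) < bump_prob) {
      bumps <- list(list(frame = sample(2:(n_frames - 1L), 1L),
                         area = stats::runif(1, 20, 60),
                         lifetime = sample(1:2, 1L),
                         angle = stats::runif(1, 0, 2 * pi)))
    }
    programs[[i]] <- cell_program(label = i, centroid = center, radius = r,
                                  displacement = steps, bumps = bumps)
  }
  list(programs = programs, image_size = as.integer(image_size))
}

#' Write / read a mask movie as multi-frame TIFF plus sidecar metadata
#'
#' Writes `cells.tif` and `nuclei.tif` (16-bit multi-page label images,
#' frame order = time order) and `movie.yaml` holding `pixel_size`
#' (micrometres per pixel) and `frame_interval` (minutes).
#'
#' @param movie A `migvar_movie`.
#' @param dir Output directory (created if needed).
#' @return `read_mask_movie` returns a `migvar_movie`.
#' @export
write_mask_movie <- function(movie, dir) {
  stopifnot(inherits(movie, "migvar_movie"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mx <- max(vapply(movie$cell_masks, max, numeric(1)))
  if (mx > 65535) mv_stop("labels exceed 16-bit range",
                          class = "migvar_generation_error")
  to_pages <- function(masks) lapply(masks, function(m) m / 65535)
  tiff::writeTIFF(to_pages(movie$cell_masks), file.path(dir, "cells.tif"),
                  bits.per.sample = 16L, compression = "none")
  tiff::writeTIFF(to_pages(movie$nucleus_masks), file.path(dir, "nuclei.tif"),
                  bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(list(pixel_size = movie$pixel_size,
                        frame_interval = movie$frame_interval,
                        n_frames = movie$n_frames,
                        image_size = as.integer(movie$image_size)),
                   file.path(dir, "movie.yaml"))
  invisible(dir)
}

#' @rdname write_mask_movie
#' @export
read_mask_movie <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "movie.yaml"))
  pages <- function(f) {
    p <- tiff::readTIFF(file.path(dir, f), all = TRUE)
    if (!is.list(p)) p <- list(p)
    lapply(p, function(m) {
      storage.mode(m) <- "double"
      matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
    })
  }
  cells <- pages("cells.tif")
  nuclei <- pages("nuclei.tif")
  structure(list(cell_masks = cells, nucleus_masks = nuclei,
                 pixel_size = meta$pixel_size,
                 frame_interval = meta$frame_interval,
                 n_frames = length(cells),
                 image_size = c(ncol(cells[[1L]]), nrow(cells[[1L]]))),
            class = "migvar_movie")
}
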