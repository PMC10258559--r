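make_mask <- function(h, w, pix, lab = 1L) {
  m <- matrix(0L, h, w)
  m[pix] <- lab
  m
}

test_that("static features recover analytic shapes", {
  # 10x10 filled square at 1 um/px
  sq <- matrix(0L, 24, 24)
  sq[8:17, 6:15] <- 1L
  nuc <- matrix(0L, 24, 24)
  nuc[11:14, 9:12] <- 1L
  f <- static_features(sq, nuc, pixel_size = 1)
  expect_equal(f$area, 100)
  expect_equal(f$extent, 1)
  expect_equal(f$nucleus_area, 16)
  expect_equal(f$solidity, 1)
  expect_equal(f$eccentricity, 0)

  # rasterized disk of radius 20 px approaches the analytic circle
  d <- migvar:::disk_pixels(c(30, 30), 20, 64, 64)
  cm <- make_mask(64, 64, d)
  nm <- make_mask(64, 64, migvar:::disk_pixels(c(30, 30), 8, 64, 64))
  fd <- static_features(cm, nm, pixel_size = 1)
  expect_lt(abs(fd$area - pi * 400) / (pi * 400), 0.02)
  expect_gte(fd$form_factor, 0.95)
  expect_lt(fd$eccentricity, 0.1)
  expect_equal(fd$major_axis, 40, tolerance = 0.05)
  expect_equal(fd$equiv_diameter, 2 * sqrt(fd$area / pi))
  expect_equal(fd$nucleus_cell_ratio, fd$nucleus_area / fd$area)
})

test_that("areas equal the per-pixel count oracle on random blobs", {
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(0L, 32, 32)
    m[sample(seq(2, 31), 1) + 32 * sample(seq(2, 28), 1) +
        sample(0:2, 40, replace = TRUE) + 32 * sample(0:2, 40,
                                                      replace = TRUE)] <- 1L
    n <- matrix(0L, 32, 32)
    n[which(m == 1L)[1:3]] <- 1L
    f <- static_features(m, n, pixel_size = 0.5)
    expect_identical(f$area, sum(m == 1L) * 0.25)
  }
})

test_that("orphan nucleus labels are flagged and excluded", {
  cm <- make_mask(32, 32, migvar:::disk_pixels(c(10, 10), 5, 32, 32), 1L)
  nm <- make_mask(32, 32, migvar:::disk_pixels(c(10, 10), 2, 32, 32), 1L)
  nm[25, 25] <- 7L   # nucleus with no cell
  f <- static_features(cm, nm, pixel_size = 1)
  expect_identical(f$label, 1L)
  expect_identical(attr(f, "flagged"), 7L)
})

test_that("dynamic regions implement the three-frame set differences", {
  base <- migvar:::disk_pixels(c(20, 20), 8, 48, 48)
  bump <- setdiff(migvar:::disk_pixels(c(28, 20), 4, 48, 48), base)
  prev <- make_mask(48, 48, base)
  curr <- make_mask(48, 48, c(base, bump))
  d <- dynamic_regions(prev, curr, prev, pixel_size = 1)
  expect_equal(d$protrusion_area, length(bump))
  expect_equal(d$retraction_area, length(bump))
  expect_equal(d$shortlived_area, length(bump))

  same <- dynamic_regions(prev, prev, prev, pixel_size = 1)
  expect_equal(unlist(same[, c("protrusion_area", "retraction_area",
                               "shortlived_area")]),
               c(0, 0, 0), ignore_attr = TRUE)

  # movie edges: undefined sides reported as missing
  e <- dynamic_regions(NULL, curr, prev, pixel_size = 1)
  expect_true(is.na(e$protrusion_area))
  expect_false(is.na(e$retraction_area))

  # whole-cell appearance is excluded and flagged
  gone <- make_mask(48, 48, integer(0))
  a <- dynamic_regions(gone, curr, gone, pixel_size = 1)
  expect_true(a$flagged)
  expect_true(is.na(a$protrusion_area))
})

test_that("shifted disks match the per-pixel set oracle", {
  f1 <- make_mask(48, 48, migvar:::disk_pixels(c(18, 20), 8, 48, 48))
  f2 <- make_mask(48, 48, migvar:::disk_pixels(c(21, 20), 8, 48, 48))
  f3 <- make_mask(48, 48, migvar:::disk_pixels(c(24, 20), 8, 48, 48))
  d <- dynamic_regions(f1, f2, f3, pixel_size = 0.8)
  o <- oracle_dynamic_regions(f1, f2, f3, 1L, 0.8)
  expect_identical(d$protrusion_area, o$protrusion)
  expect_identical(d$retraction_area, o$retraction)
  expect_identical(d$shortlived_area, o$shortlived)
})

test_that("feature extraction reproduces the generator ground truth", {
  rp <- random_cell_programs(3, n_frames = 5, seed = 8)
  spec <- mask_movie_spec(n_frames = 5, image_size = rp$image_size,
                          pixel_size = 0.826, cells = rp$programs)
  mv <- simulate_mask_movie(spec)
  feats <- extract_features(mv$movie, hierarchy = list(lab = "L1"))
  expect_identical(feats$lab, rep("L1", nrow(feats)))
  m <- merge(feats, mv$truth, by.x = c("cell_label", "frame"),
             by.y = c("label", "frame"))
  expect_identical(m$area, m$area_um2)
  expect_identical(m$nucleus_area, m$nucleus_area_um2)
  expect_identical(m$protrusion_area, m$protrusion_um2)
  expect_identical(m$retraction_area, m$retraction_um2)
  expect_identical(m$shortlived_area, m$shortlived_um2)
  # centroids to within half a pixel
  expect_lt(max(abs(m$cx_um - m$centroid_x_um)), 0.5 * 0.826)
  expect_lt(max(abs(m$cy_um - m$centroid_y_um)), 0.5 * 0.826)
})

test_that("greedy nucleus tracking matches the assignment oracle", {
  # single static nucleus: one trajectory covering all frames
  cents <- replicate(10, data.frame(label = 1L, x = 5, y = 5),
                     simplify = FALSE)
  tk <- track_cells(cents, max_link_distance = 20)
  expect_identical(unique(tk$track), 1L)
  expect_identical(nrow(tk), 10L)

  # two distant nuclei moving 2 um/frame: no identity swap
  cents2 <- lapply(1:6, function(t) {
    data.frame(label = c(1L, 2L), x = c(2 * t, 100 + 2 * t), y = c(0, 0))
  })
  tk2 <- track_cells(cents2, max_link_distance = 20)
  expect_identical(length(unique(tk2$track)), 2L)
  expect_true(all(tapply(tk2$x > 50, tk2$track, function(v) {
    all(v) || !any(v)
  })))
  # frame-by-frame agreement with the brute-force optimal assignment
  for (t in 2:6) {
    prev <- cents2[[t - 1L]]
    cur <- cents2[[t]]
    best <- oracle_assignment(prev, cur, 20)
    expect_identical(nrow(best), 2L)
    expect_identical(best[, "open"], best[, "new"])
  }

  # a 50-um jump with a 20-um gate ends the track
  cents3 <- lapply(1:4, function(t) {
    data.frame(label = 1L, x = ifelse(t <= 2, 0, 50), y = 0)
  })
  tk3 <- track_cells(cents3, max_link_distance = 20)
  expect_identical(length(unique(tk3$track)), 2L)

  # empty movie is an empty result, not an error
  expect_identical(nrow(track_cells(list(), 10)), 0L)
})
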