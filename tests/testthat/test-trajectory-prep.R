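test_that("QC removes undersized nuclei and oversized cells", {
  tab <- data.frame(cell = sprintf("c%d", 1:101),
                    area = c(1:100, 1000),
                    nucleus_area = c(80, rep(150, 100)))
  res <- qc_filter(tab)
  expect_identical(res$report$removed$oversized_cell, 1L)
  expect_identical(res$report$removed$undersized_nucleus, 1L)
  expect_false("c101" %in% res$table$cell)   # the 1000-area cell
  expect_false("c1" %in% res$table$cell)     # the 80-um2 nucleus
  # the threshold equals the independent type-7 quantile computation
  q3 <- oracle_quantile7(1:100, 0.75)
  q1 <- oracle_quantile7(1:100, 0.25)
  expect_equal(res$report$thresholds$cell_area_max, q3 + 1.5 * (q3 - q1))
  expect_identical(res$report$input_records,
                   res$report$retained_records +
                     sum(unlist(res$report$removed)))
})

test_that("QC is idempotent and handles empty tables", {
  set.seed(31)
  tab <- data.frame(cell = rep(sprintf("c%d", 1:200), each = 3),
                    area = rep(exp(rnorm(200, 6, 0.4)), each = 3),
                    nucleus_area = 150)
  r1 <- qc_filter(tab)
  r2 <- qc_filter(r1$table)
  expect_identical(r2$report$retained_records, nrow(r1$table))
  expect_identical(sum(unlist(r2$report$removed)), 0L)

  e <- qc_filter(tab[0, , drop = FALSE])
  expect_identical(nrow(e$table), 0L)
  expect_identical(sum(unlist(e$report$removed)), 0L)
})

test_that("QC removes merged and duplicated trajectories whole", {
  base <- data.frame(cell = rep(c("a", "b", "c"), each = 4),
                     frame = rep(1:4, 3),
                     time_min = rep((0:3) * 5, 3),
                     area = 400, nucleus_area = 150,
                     cell_label = rep(c(1L, 2L, 3L), each = 4),
                     nuc_x_um = c(1:4, 11:14, 21:24),
                     nuc_y_um = 0)
  # duplicate track: d shares all centroid records with a
  dup <- base[base$cell == "a", ]
  dup$cell <- "d"
  dup$cell_label <- 4L
  r <- qc_filter(rbind(base, dup))
  expect_identical(r$report$removed$duplicated_trajectory, 4L)
  expect_false("d" %in% r$table$cell)
  expect_true("a" %in% r$table$cell)

  # merged: two nucleus tracks on one cell label in one frame
  mrg <- base
  mrg$cell_label[mrg$cell == "b" & mrg$frame == 2] <- 1L
  r2 <- qc_filter(mrg)
  expect_identical(r2$report$removed$merged_trajectory, 8L)
  expect_true(all(!c("a", "b") %in% r2$table$cell))
})

test_that("trajectory smoothing equals the brute-force windowed mean", {
  const <- cbind(x = rep(3, 20), y = rep(-1, 20))
  expect_equal(smooth_trajectory(const, 9), const)

  lin <- cbind(x = 1:30, y = 2 * (1:30))
  sm <- smooth_trajectory(lin, 9)
  expect_equal(sm[5:26, ], lin[5:26, ])   # interior of a linear path

  set.seed(7)
  xy <- cbind(x = rnorm(72), y = rnorm(72))
  sm2 <- smooth_trajectory(xy, 9)
  expect_equal(sm2[, 1], oracle_moving_average(xy[, 1], 9))
  expect_equal(sm2[, 2], oracle_moving_average(xy[, 2], 9))

  expect_error(smooth_trajectory(xy, 4), class = "migvar_parameter_error")
})

test_that("instantaneous speed follows the acquisition schedule", {
  expect_identical(instantaneous_speed(cbind(rep(1, 5), rep(2, 5)), 5),
                   rep(0, 4))
  # 10 um per 5-min frame = 2 um/min; 73 frames (6 h) give 72 values
  xy <- cbind(seq(0, 720, by = 10), 0)
  ics <- instantaneous_speed(xy, 5)
  expect_identical(length(ics), 72L)
  expect_equal(ics, rep(2, 72))
  expect_identical(instantaneous_speed(xy[1, , drop = FALSE], 5),
                   numeric(0))
})

test_that("speeds from a scripted movie match the ground truth", {
  spec <- mask_movie_spec(n_frames = 12, image_size = c(160, 64),
                          pixel_size = 1, frame_interval = 5,
                          cells = list(cell_program(1, c(20, 30), 8,
                                                    displacement = c(5, 0))))
  mv <- simulate_mask_movie(spec)
  feats <- extract_features(mv$movie)
  out <- add_instantaneous_speed(feats, window = 9)
  # constant-velocity path: smoothing leaves the interior unchanged
  interior <- out$ics[out$frame >= 6 & out$frame <= 8]
  expect_equal(interior, rep(1, length(interior)), tolerance = 0.05)
})

test_that("ICS scales linearly with spatial rescaling", {
  set.seed(12)
  xy <- apply(cbind(rnorm(40), rnorm(40)), 2, cumsum)
  s1 <- instantaneous_speed(smooth_trajectory(xy, 9), 5)
  s2 <- instantaneous_speed(smooth_trajectory(xy * 2.5, 9), 5)
  expect_equal(s2, 2.5 * s1)
})

test_that("z-scoring standardizes pooled features", {
  tab <- data.frame(f = c(1, 2, 3))
  z <- zscore_features(tab, "f")
  expect_equal(z$f, c(-1, 0, 1))
  z2 <- zscore_features(z, "f")
  expect_equal(z2$f, z$f, tolerance = 1e-12)

  set.seed(3)
  big <- data.frame(a = rnorm(200, 5, 3), b = runif(200))
  zb <- zscore_features(big, c("a", "b"))
  expect_lt(max(abs(colMeans(zb[, c("a", "b")]))), 1e-12)
  expect_equal(apply(zb[, c("a", "b")], 2, sd), c(a = 1, b = 1),
               tolerance = 1e-12)

  cz <- data.frame(a = rnorm(10), k = rep(1, 10))
  expect_warning(out <- zscore_features(cz, c("a", "k")),
                 "zero-variance")
  expect_false("k" %in% names(out))
})

test_that("PCA orders, signs and reconstructs deterministically", {
  set.seed(21)
  a <- rnorm(300)
  perf <- data.frame(a = a, b = 2 * a)
  z <- zscore_features(perf, c("a", "b"))
  pc <- run_pca(z)
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)

  tab <- data.frame(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  tab$d <- tab$a + 0.5 * tab$b + rnorm(300, 0, 0.3)
  z2 <- zscore_features(tab, c("a", "b", "c", "d"))
  pc2 <- run_pca(z2)
  # scores are uncorrelated and reconstruct the input
  cv <- crossprod(pc2$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
  rec <- pc2$scores %*% t(pc2$loadings)
  expect_lt(max(abs(rec - as.matrix(z2[, c("a", "b", "c", "d")]))), 1e-8)
  # deterministic sign: dominant loading positive
  for (j in seq_len(ncol(pc2$loadings))) {
    v <- pc2$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_true(all(diff(pc2$explained) <= 1e-12))
  expect_error(run_pca(z2[1, , drop = FALSE],
                       features = c("a", "b", "c", "d")),
               class = "migvar_parameter_error")
})
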