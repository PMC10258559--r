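test_that("data without technical structure pass through unchanged", {
  p <- generative_params(sigma2 = c(lab = 0, person = 0, experiment = 0,
                                    replicate = 0, cell = 2),
                         sigma2_residual = 2, seed = 3)
  sim <- simulate_migration_study(design_spec(n_cells = 4, n_timepoints = 6),
                                  p)
  fit <- fit_nested_lme(sim$table, "ics", fixed = "condition")
  # technical components land on the boundary, so all BLUPs are zero
  expect_true(all(fit$sigma2[c("lab", "person", "experiment",
                               "replicate")] == 0))
  corr <- remove_batch_effects(sim$table, fit)
  expect_identical(corr$ics, sim$table$ics)
  expect_true(all(corr$batch_correction == 0))
})

test_that("correction strips technical variance and preserves the effect", {
  sim <- simulate_migration_study(design_spec(n_cells = 6, n_timepoints = 8),
                                  generative_params(seed = 41))
  fit <- fit_nested_lme(sim$table, "ics", fixed = "condition")
  corr <- remove_batch_effects(sim$table, fit)
  refit <- fit_nested_lme(corr, "ics", fixed = "condition")
  tech <- c("lab", "person", "experiment", "replicate")
  expect_lt(sum(refit$sigma2[tech]), 0.1 * sum(fit$sigma2[tech]))
  # biological components survive
  expect_gt(refit$sigma2[["cell"]], 1)
  expect_gt(refit$sigma2[["residual"]], 1)
  # treatment contrast essentially untouched
  gap <- function(tab) {
    mean(tab$ics[tab$condition == "treated"]) -
      mean(tab$ics[tab$condition == "control"])
  }
  expect_lt(abs(gap(corr) - gap(sim$table)) / abs(gap(sim$table)), 0.02)
  # schema preserved
  expect_identical(nrow(corr), nrow(sim$table))
  expect_identical(corr[, c("lab", "person", "experiment", "condition",
                            "replicate", "cell", "time_min")],
                   sim$table[, c("lab", "person", "experiment", "condition",
                                 "replicate", "cell", "time_min")])
})

test_that("correction is idempotent and mean-preserving", {
  sim <- simulate_migration_study(design_spec(n_cells = 4, n_timepoints = 6),
                                  generative_params(seed = 3))
  fit <- fit_nested_lme(sim$table, "ics", fixed = "condition")
  corr <- remove_batch_effects(sim$table, fit)
  expect_lt(abs(mean(corr$ics) - mean(sim$table$ics)),
            1e-8 * max(1, sd(sim$table$ics)))
  refit <- fit_nested_lme(corr, "ics", fixed = "condition")
  corr2 <- remove_batch_effects(corr[, names(sim$table)], refit)
  expect_lt(max(abs(corr2$ics - corr$ics)), 1e-6 * sd(sim$table$ics))
})

test_that("two-condition tables demand a condition fixed effect", {
  sim <- simulate_migration_study(design_spec(n_cells = 2, n_timepoints = 3))
  ctrl <- sim$table[sim$table$condition == "control", ]
  fit0 <- fit_nested_lme(ctrl, "ics")   # control-only, no fixed term
  expect_error(remove_batch_effects(sim$table, fit0),
               class = "migvar_fixed_error")
})

test_that("3D correction removes a pure between-lab offset", {
  set.seed(11)
  key <- expand.grid(spheroid = c("s1", "s2", "s3"),
                     replicate = c("r1", "r2", "r3"),
                     condition = c("2.5", "6.0"),
                     experiment = c("E1", "E2", "E3"),
                     lab = c("L1", "L2"), stringsAsFactors = FALSE)
  key$replicate <- paste(key$condition, key$replicate, sep = ".")
  key <- key[rep(seq_len(nrow(key)), each = 10), ]
  c_off <- 30
  key$distance <- ifelse(key$condition == "2.5", 80, 40) +
    ifelse(key$lab == "L1", c_off, -c_off) + rnorm(nrow(key), 0, 1e-5)
  res <- correct_3d(key)
  labgap <- function(tab) {
    abs(mean(tab$distance[tab$lab == "L1"]) -
          mean(tab$distance[tab$lab == "L2"]))
  }
  expect_gt(labgap(key), 59)
  expect_lt(labgap(res$table) / (2 * c_off), 1e-6)
})

test_that("3D correction on simulated data reduces lab variance, keeps the dose effect", {
  inv <- simulate_invasion_study(seed = 14)
  res <- correct_3d(inv$table)
  cond_lab_means <- function(tab) {
    stats::aggregate(distance ~ lab + condition, tab, mean)
  }
  before <- cond_lab_means(inv$table)
  after <- cond_lab_means(res$table)
  var_between_labs <- function(df) {
    mean(tapply(df$distance, df$condition, stats::var))
  }
  expect_lt(var_between_labs(after), 0.05 * var_between_labs(before))
  gap <- function(tab) {
    mean(tab$distance[tab$condition == "2.5"]) -
      mean(tab$distance[tab$condition == "6.0"])
  }
  expect_lt(abs(gap(res$table) - gap(inv$table)) / abs(gap(inv$table)),
            0.02)
  expect_error(correct_3d(inv$table[inv$table$lab == "L1", ]),
               class = "migvar_parameter_error")
  one_cond <- inv$table[inv$table$condition == "2.5", ]
  expect_error(correct_3d(one_cond), class = "migvar_fixed_error")
})

test_that("correction summaries and PC distance matrices are well-formed", {
  sim <- simulate_migration_study(design_spec(n_cells = 2, n_timepoints = 3),
                                  features = c("ics", "area"))
  fit <- fit_nested_lme(sim$table, "ics", fixed = "condition")
  corr <- remove_batch_effects(sim$table, fit)
  summ <- correction_summary(sim$table, corr, "ics")
  expect_setequal(unique(summ$stage), c("before", "after"))
  expect_true(all(c("all", "L1", "L2", "L3") %in% summ$lab))

  z <- zscore_features(sim$table, c("ics", "area"))
  pc <- run_pca(z)
  dm <- replicate_distance_matrix(pc$table)
  n_reps <- as.integer(3 * 3 * 3 * 2 * 3)
  expect_identical(dim(dm$dist), c(n_reps, n_reps))
  expect_identical(sort(dm$order), seq_len(n_reps))
  expect_true(all(diag(dm$dist) == 0))
})
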