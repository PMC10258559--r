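test_that("constant data collapse to the boundary fit", {
  tab <- expand.grid(lab = c("L1", "L2"), cell = c("a", "b"), t = 1:3,
                     stringsAsFactors = FALSE)
  tab$y <- 5
  fit <- fit_nested_lme(tab, "y", levels = c("lab", "cell"))
  expect_equal(fit$beta0, 5)
  expect_true(all(fit$sigma2 == 0))

  tab2 <- rbind(tab, tab)
  tab2$condition <- rep(c("control", "treated"), each = nrow(tab))
  tab2$cell <- paste(tab2$condition, tab2$cell)
  tab2$y <- ifelse(tab2$condition == "control", 5, 8)
  fit2 <- fit_nested_lme(tab2, "y", levels = c("lab", "cell"),
                         fixed = "condition")
  expect_equal(fit2$beta0, 5)
  expect_equal(fit2$delta, 3)
  expect_true(all(fit2$sigma2 == 0))
})

test_that("the collapsed likelihood equals the dense evaluation", {
  oc <- random_tiny_dataset(101)
  fit <- fit_nested_lme(oc$table, "y", levels = oc$levels,
                        fixed = oc$fixed)
  id_list <- lapply(oc$levels, function(l) oc$table[[l]])
  X <- if (is.null(oc$fixed)) {
    matrix(1, nrow(oc$table), 1)
  } else {
    cbind(1, as.numeric(oc$table$condition == "b"))
  }
  L <- length(oc$levels)
  for (s in 1:5) {
    set.seed(s)
    tau2 <- runif(L, 0, 2)
    s0 <- runif(1, 0.3, 2)
    mine <- migvar:::hlme_loglik_at(fit, c(tau2, s0))
    dense <- -oracle_dense_nll2(tau2, s0, oc$table$y, X, id_list) / 2
    expect_equal(mine, dense, tolerance = 1e-10)
  }
})

test_that("ML estimates agree with a dense-covariance oracle", {
  for (seed in c(7, 23, 55)) {
    oc <- random_tiny_dataset(seed)
    fit <- fit_nested_lme(oc$table, "y", levels = oc$levels,
                          fixed = oc$fixed)
    X <- if (is.null(oc$fixed)) {
      matrix(1, nrow(oc$table), 1)
    } else {
      cbind(1, as.numeric(oc$table$condition == "b"))
    }
    oracle <- oracle_dense_ml(oc$table$y, X,
                              lapply(oc$levels, function(l) oc$table[[l]]))
    expect_lt(abs(fit$loglik - oracle$loglik), 1e-4)
  }
})

test_that("the fit matches lme4 maximum likelihood", {
  skip_if_not_installed("lme4")
  sim <- simulate_migration_study(design_spec(n_cells = 4, n_timepoints = 6),
                                  generative_params(seed = 2))
  fit <- fit_nested_lme(sim$table, "ics", fixed = "condition")
  m <- lme4::lmer(
    ics ~ condition + (1 | lab) + (1 | lab:person) +
      (1 | lab:person:experiment) +
      (1 | lab:person:experiment:replicate) +
      (1 | lab:person:experiment:replicate:cell),
    data = sim$table, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  expect_equal(fit$delta, unname(lme4::fixef(m)[2]), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(m))
  lme4_sigma2 <- c(
    lab = vc$vcov[vc$grp == "lab"],
    person = vc$vcov[vc$grp == "lab:person"],
    experiment = vc$vcov[vc$grp == "lab:person:experiment"],
    replicate = vc$vcov[vc$grp == "lab:person:experiment:replicate"],
    cell = vc$vcov[vc$grp == "lab:person:experiment:replicate:cell"],
    residual = vc$vcov[vc$grp == "Residual"])
  expect_equal(unname(fit$sigma2), unname(lme4_sigma2), tolerance = 1e-3)
})

test_that("the optimizer lands on a local maximum", {
  oc <- random_tiny_dataset(303)
  fit <- fit_nested_lme(oc$table, "y", levels = oc$levels, fixed = oc$fixed)
  L <- length(oc$levels)
  s2 <- unname(fit$sigma2)
  base <- migvar:::hlme_loglik_at(fit, s2)
  expect_equal(base, fit$loglik, tolerance = 1e-9)
  for (j in seq_len(L + 1)) {
    for (eps in c(-1, 1) * max(s2[j] * 0.05, 1e-4)) {
      pert <- s2
      pert[j] <- max(pert[j] + eps, 0)
      expect_lte(migvar:::hlme_loglik_at(fit, pert), base + 1e-6)
    }
  }
})

test_that("BLUPs shrink unit means by the closed-form factor", {
  set.seed(77)
  units <- sprintf("u%d", 1:8)
  tab <- data.frame(unit = rep(units, each = 12))
  tab$y <- rnorm(96) + rep(rnorm(8, 0, 1.5), each = 12)
  fit <- fit_nested_lme(tab, "y", levels = "unit")
  bl <- predict_random_intercepts(fit)
  s2 <- fit$sigma2[["unit"]]
  s0 <- fit$sigma2[["residual"]]
  um <- tapply(tab$y, tab$unit, mean)[units]
  closed <- (12 * s2 / (12 * s2 + s0)) * (um - fit$beta0)
  expect_equal(as.numeric(bl$unit[units]), as.numeric(closed),
               tolerance = 1e-8)
  expect_lt(abs(mean(bl$unit)), 1e-6)
})

test_that("zero-variance levels get exactly zero BLUPs", {
  p <- generative_params(sigma2 = c(lab = 4, person = 0, experiment = 0.5,
                                    replicate = 0.25, cell = 2), seed = 5)
  sim <- simulate_migration_study(design_spec(n_cells = 2, n_timepoints = 4),
                                  p)
  fit <- fit_nested_lme(sim$table, "ics", fixed = "condition")
  bl <- predict_random_intercepts(fit)
  for (lv in names(fit$sigma2)[-6]) {
    if (fit$sigma2[[lv]] == 0) expect_true(all(bl[[lv]] == 0))
  }
})

test_that("BLUPs track the true intercepts on simulated data", {
  cor_exp <- cor_cell <- numeric(3)
  for (i in 1:3) {
    sim <- simulate_migration_study(design_spec(n_cells = 10,
                                                n_timepoints = 24),
                                    generative_params(seed = 12 + i))
    fit <- fit_nested_lme(sim$table, "ics", fixed = "condition")
    bl <- predict_random_intercepts(fit)
    tr <- sim$truth$ics
    # experiment level: 27 units with generative variance 0.5.  With only
    # three experiments per person, the mean of their intercepts is
    # absorbed by the person level, so the estimable quantity is the
    # within-person-centred intercept.
    eid <- migvar:::path_id(tr, c("lab", "person", "experiment"))
    u_true <- tapply(tr$u_experiment, eid, function(v) v[1])
    pid <- sub("\r[^\r]*$", "", names(u_true))
    u_centred <- u_true - ave(u_true, pid)
    cor_exp[i] <- cor(bl$experiment[names(u_true)], u_centred)
    # cell level: many units with generative variance 2
    cid <- migvar:::path_id(tr, c("lab", "person", "experiment",
                                  "replicate", "cell"))
    c_true <- tapply(tr$u_cell, cid, function(v) v[1])
    cor_cell[i] <- cor(bl$cell[names(c_true)], c_true)
  }
  expect_gt(mean(cor_exp), 0.9)
  expect_gt(mean(cor_cell), 0.9)
})

test_that("structural and fixed-effect errors are explicit", {
  sim <- simulate_migration_study(design_spec(n_cells = 2, n_timepoints = 3))
  ctrl <- sim$table[sim$table$condition == "control", ]
  expect_error(fit_nested_lme(ctrl, "ics", fixed = "condition"),
               class = "migvar_fixed_error")

  bad <- sim$table
  bad$cell <- "same"   # one cell spanning both conditions
  bad$replicate <- "same"
  bad$experiment <- "same"
  expect_error(
    suppressWarnings(fit_nested_lme(bad, "ics", fixed = "condition")),
    class = "migvar_structure_error")

  nas <- sim$table
  nas$lab[1] <- NA
  expect_error(fit_nested_lme(nas, "ics"), class = "migvar_structure_error")
  expect_error(fit_nested_lme(sim$table, "nope"),
               class = "migvar_schema_error")

  bl_fit <- fit_nested_lme(sim$table, "ics", fixed = "condition")
  alien <- sim$table[1:3, ]
  alien$lab <- "L9"
  expect_error(predict_random_intercepts(bl_fit, table = alien),
               class = "migvar_structure_error")
})

test_that("variance decomposition arithmetic and recovery", {
  fake <- structure(list(
    response = "f",
    sigma2 = c(lab = 4, person = 1, experiment = 0.5, replicate = 0.5,
               cell = 2, residual = 2)), class = "migvar_hlme")
  vt <- decompose_variance(fake)
  expect_equal(unname(attr(vt, "technical_share")), 0.6)
  expect_equal(sum(vt$share), 1)

  fake0 <- fake
  fake0$sigma2[c("lab", "person", "experiment", "replicate")] <- 0
  expect_equal(unname(attr(decompose_variance(fake0), "technical_share")), 0)
})

test_that("a structure-free dataset yields a near-zero technical share", {
  p <- generative_params(delta = 0,
                         sigma2 = c(lab = 0, person = 0, experiment = 0,
                                    replicate = 0, cell = 2),
                         sigma2_residual = 2, seed = 17)
  sim <- simulate_migration_study(design_spec(n_cells = 5, n_timepoints = 6),
                                  p)
  fit <- fit_nested_lme(sim$table, "ics", fixed = "condition")
  vt <- decompose_variance(fit)
  expect_lte(unname(attr(vt, "technical_share")), 0.1)
})

test_that("REML is available as a sensitivity flag", {
  skip_if_not_installed("lme4")
  tab <- random_tiny_dataset(404)$table
  lv <- setdiff(names(tab), c("y", "condition"))
  fit <- fit_nested_lme(tab, "y", levels = lv, reml = TRUE)
  fml <- stats::as.formula(paste("y ~ 1 +",
                                 paste(sprintf("(1 | %s)", lv),
                                       collapse = " + ")))
  m <- lme4::lmer(fml, data = tab, REML = TRUE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-4)
})
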