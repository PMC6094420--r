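test_that("rmse computes the root mean square error", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  withr::with_seed(41, {
    y <- rnorm(50); p <- rnorm(50)
    acc <- 0
    for (i in seq_along(y)) acc <- acc + (p[i] - y[i])^2  # loop oracle
    expect_equal(rmse(y, p), sqrt(acc / 50), tolerance = 1e-12)
  })
  expect_error(rmse(1:3, 1:4), "length mismatch")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("per-sample REP% reproduces the reference arithmetic", {
  expect_equal(round(rep_per_sample(21e-7, 20.79e-7), 2), -1.00)
  expect_equal(round(rep_per_sample(34e-7, 34.12e-7), 2), 0.35)
  expect_equal(rep_per_sample(5e-7, 5e-7), 0)
  expect_error(rep_per_sample(0, 1), "> 0")
})

test_that("aggregate REP% is 100 * RMSE / mean(y)", {
  expect_equal(rep_aggregate(rep(10, 4), rep(10, 4) + 0.1), 1.0)
  expect_equal(rep_aggregate(c(1, 2, 3), c(1, 2, 3)), 0)
  withr::with_seed(43, {
    y <- runif(30, 1, 5); p <- y + rnorm(30, sd = 0.2)
    expect_equal(rep_aggregate(y, p), 100 * sqrt(mean((p - y)^2)) / mean(y),
                 tolerance = 1e-12)
  })
  expect_error(rep_aggregate(c(-1, 1), c(0, 0)), "> 0")
})

test_that("r_squared is the coefficient of determination", {
  y <- c(1, 2, 3, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  withr::with_seed(44, {
    yy <- rnorm(40); pp <- yy + rnorm(40, sd = 0.3)
    ss_res <- sum((yy - pp)^2); ss_tot <- sum((yy - mean(yy))^2)
    expect_equal(r_squared(yy, pp), 1 - ss_res / ss_tot, tolerance = 1e-12)
  })
  expect_error(r_squared(rep(2, 5), rnorm(5)), "constant")
})

test_that("LOD/LOQ follow the 3 and 10 sigma-blank rule", {
  expect_equal(lod_loq(rep(0, 5)), list(lod = 0, loq = 0, s_b = 0))
  blanks <- c(0.00e-7, 0.02e-7, -0.01e-7, 0.01e-7)
  out <- lod_loq(blanks)
  expect_equal(out$lod, 3 * sd(blanks))
  expect_equal(out$loq / out$lod, 10 / 3)
  expect_lte(out$lod, out$loq)
  expect_error(lod_loq(0.1e-7), "at least 2")
})

test_that("LOO selection concentrates on the true latent dimension", {
  # two latent factors (analyte + one interferent), low noise
  picks <- vapply(1:5, function(s) {
    g <- wavelength_grid(seq(240, 264, 4), seq(300, 460, 8))
    d <- simulation_design(
      g, fluorophore(251, 6, 362.5, 22, 1e8),
      concentrations = withr::with_seed(s, runif(15, 0.5e-7, 5e-7)),
      interferents = list(fluorophore(246, 10, 330, 30, 1)),
      interferent_ranges = list(c(10, 30)),
      noise_sd = 0.3, seed = s
    )
    u <- unfold_cube(simulate_cube(d))
    model <- fit_pca(u$values, k = 5)
    y <- concentrations(simulate_cube(d))
    sel <- select_n_pcs(model$scores, y, candidates = 1:5, n_hidden = 4,
                        config = train_config(0.5, 0.5, 150, patience = Inf,
                                              seed = s))
    expect_length(sel$rmse_cv, 5)       # RMSEcv reported for every candidate
    expect_true(all(sel$rmse_cv >= 0))
    sel$n_pc
  }, numeric(1))
  expect_true(all(picks <= 5))
  expect_gte(sum(picks %in% 2:3), 3)
})

test_that("singleton candidate ranges are returned as-is", {
  scores <- withr::with_seed(45, matrix(rnorm(24), 8, 3))
  y <- withr::with_seed(46, runif(8, 1e-7, 5e-7))
  sel <- select_n_pcs(scores, y, candidates = 3, n_hidden = 2,
                      config = train_config(0.5, 0.5, 50, patience = Inf))
  expect_equal(sel$n_pc, 3)
  expect_error(select_n_pcs(scores, y, candidates = integer(0)), "empty")
})

test_that("surface scans return finite surfaces and a well-specified argmin", {
  withr::with_seed(47, {
    X <- matrix(rnorm(30 * 2), 30, 2)
    y <- 3e-7 + 1e-7 * X[, 1]
    data <- list(X_cal = X[1:20, ], y_cal = y[1:20],
                 X_val = X[21:25, ], y_val = y[21:25],
                 X_test = X[26:30, ], y_test = y[26:30])
    one <- surface_scan(list(name = "n_hidden", values = 3),
                        list(name = "epochs", values = 100),
                        data, train_config(seed = 1), n_hidden = 3)
    expect_equal(dim(one$mse), c(1, 1))
    expect_equal(one$best$n_hidden, 3)
    expect_equal(one$best$epochs, 100)
    # a nearly untrained cell cannot beat a trained one on a noiseless problem
    surf <- surface_scan(list(name = "n_hidden", values = 3),
                         list(name = "epochs", values = c(1, 500)),
                         data, train_config(seed = 2), n_hidden = 3)
    expect_true(all(is.finite(surf$mse)) && all(surf$mse >= 0))
    expect_equal(surf$best$epochs, 500)
    expect_lt(surf$mse[1, 2], surf$mse[1, 1])
  })
})

test_that("the pipeline recovers noiseless concentrations almost exactly", {
  conc <- withr::with_seed(48, runif(24, 0.5e-7, 5e-7))
  cube <- simulate_cube(small_bilinear_design(conc, noise_sd = 0, seed = 4))
  cfg <- pipeline_config(seed = 4, max_pcs = 4, pc_candidates = NULL,
                         n_pc = 1, n_hidden = 3, epochs = 12000,
                         learning_rate = 1, momentum = 0.9, patience = Inf)
  fit <- run_pipeline(cube, cfg)
  expect_lte(fit$fom$rmse_prediction, 1e-3 * max(conc))
  expect_gte(fit$fom$r2_prediction, 0.999)
})

test_that("pipeline reruns are bitwise identical and report coherent merit figures", {
  conc <- withr::with_seed(49, runif(20, 0.5e-7, 5e-7))
  design <- small_bilinear_design(c(conc, 0, 0, 0), noise_sd = 0.5,
                                  interferents = TRUE, seed = 5,
                                  roles = c(rep("unknown", 20),
                                            rep("blank", 3)))
  cube <- simulate_cube(design)
  cfg <- pipeline_config(seed = 5, max_pcs = 5, pc_candidates = 1:3,
                         n_hidden = 3, epochs = 300,
                         loo_config = train_config(0.5, 0.5, 100,
                                                   patience = Inf))
  f1 <- run_pipeline(cube, cfg)
  f2 <- run_pipeline(cube, cfg)
  expect_identical(f1$fom, f2$fom)
  expect_identical(f1$predictions, f2$predictions)
  # report invariants
  expect_lte(f1$fom$lod, f1$fom$loq)
  expect_gte(f1$fom$rmse_cv, 0)
  expect_equal(f1$fom$dynamic_range,
               range(f1$predictions$nominal_molar[
                 f1$predictions$set == "calibration"]))
  expect_lte(f1$fom$r2_prediction, 1)
  expect_equal(nrow(f1$predictions), 20)
  expect_equal(sort(unique(f1$predictions$set)),
               c("calibration", "test", "validation"))
  tab <- fom_table(f1)
  expect_equal(tab$prediction[tab$parameter == "R2"], f1$fom$r2_prediction)
})

test_that("LOD scales linearly with the injected noise level", {
  # noise-only blanks around a small calibration: S_b (hence LOD) should
  # scale with sigma; compare two noise levels with matched seeds
  lod_at <- function(sigma) {
    conc <- withr::with_seed(50, runif(18, 1e-7, 5e-7))
    design <- small_bilinear_design(c(conc, rep(0, 8)), noise_sd = sigma,
                                    interferents = FALSE, seed = 6,
                                    roles = c(rep("unknown", 18),
                                              rep("blank", 8)))
    cfg <- pipeline_config(seed = 6, max_pcs = 4, pc_candidates = NULL,
                           n_pc = 2, n_hidden = 3, epochs = 500,
                           patience = Inf)
    run_pipeline(simulate_cube(design), cfg)$fom$lod
  }
  l1 <- lod_at(0.5)
  l2 <- lod_at(1.0)
  expect_gt(l2 / l1, 2 * (1 - 0.35))
  expect_lt(l2 / l1, 2 * (1 + 0.35))
})

test_that("pipeline refuses non-blank samples without concentrations", {
  cube <- tiny_cube(list(matrix(1:4, 2, 2), matrix(2:5, 2, 2),
                         matrix(3:6, 2, 2)))
  expect_error(run_pipeline(cube, pipeline_config()), "concentrations")
})
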