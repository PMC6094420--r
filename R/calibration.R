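#' Root mean square error
#'
#' `RMSE = sqrt(sum((yhat - y)^2) / n)`, in the units of `y` (molar for
#' concentration calibration).
#'
#' @param y_true,y_pred Equal-length nonempty numeric vectors.
#' @return Non-negative scalar.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty vectors", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch between y_true and y_pred", call. = FALSE)
  }
  sqrt(mean((y_pred - y_true)^2))
}

#' Per-sample relative error of prediction (%)
#'
#' Signed per-sample relative error `100 * (predicted - nominal) / nominal`,
#' the per-sample REP% convention of calibration result tables.
#'
#' @param nominal Known concentrations, strictly positive.
#' @param predicted Predicted concentrations.
#' @return Vector of signed percentages.
#' @export
#' @examples
#' rep_per_sample(21e-7, 20.79e-7)  # -1.00
rep_per_sample <- function(nominal, predicted) {
  if (any(nominal <= 0)) {
    stop("nominal concentrations must be > 0 for relative error",
         call. = FALSE)
  }
  100 * (predicted - nominal) / nominal
}

#' Aggregate relative error of prediction (%)
#'
#' `REP% = 100 * RMSE / mean(y_true)` — the RMSE normalised by the mean
#' nominal concentration of the set.
#'
#' @param y_true,y_pred Equal-length numeric vectors; `mean(y_true)` must be
#'   positive.
#' @return Non-negative percentage.
#' @export
rep_aggregate <- function(y_true, y_pred) {
  m <- mean(y_true)
  if (m <= 0) stop("mean of y_true must be > 0", call. = FALSE)
  100 * rmse(y_true, y_pred) / m
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; 1 means a perfect
#' fit, 0 means no better than predicting the mean.
#'
#' @param y_true,y_pred Equal-length numeric vectors; `y_true` must not be
#'   constant.
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch between y_true and y_pred", call. = FALSE)
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("constant y_true: R^2 undefined", call. = FALSE)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Limit of detection and quantification from blank predictions
#'
#' Univariate definition: `S_b` is the sample standard deviation of the
#' concentrations predicted for blank samples; `LOD = 3 * S_b` and
#' `LOQ = 10 * S_b` (so LOQ/LOD = 10/3 always).
#'
#' @param blank_predictions Predicted concentrations for >= 2 blank samples
#'   (molar).
#' @return Named list `lod`, `loq`, `s_b` (molar).
#' @export
lod_loq <- function(blank_predictions) {
  if (length(blank_predictions) < 2) {
    stop("at least 2 blank predictions are required", call. = FALSE)
  }
  s_b <- stats::sd(blank_predictions)
  list(lod = 3 * s_b, loq = 10 * s_b, s_b = s_b)
}

# train-with-early-stopping on raw scores/concentrations; scaling fitted on
# the training block only
train_on_scores <- function(X_cal, y_cal, X_val, y_val, n_hidden, config) {
  scaling <- fit_nn_scaling(X_cal, y_cal)
  state <- init_network(ncol(as.matrix(X_cal)), n_hidden, seed = config$seed)
  fit <- train_network(
    state,
    scale_inputs(scaling, X_cal), scale_targets(scaling, y_cal),
    scale_inputs(scaling, X_val), scale_targets(scaling, y_val),
    config
  )
  list(fit = fit, scaling = scaling)
}

#' Select the number of principal components by leave-one-out CV
#'
#' For each candidate count n, trains the network on all-but-one calibration
#' sample (using the leading n score columns) and predicts the left-out
#' sample, cycling through the whole calibration set; the candidate with
#' minimal RMSEcv wins, ties going to the smaller model.
#'
#' Inside the LOO loop the left-out sample doubles as the early-stopping
#' monitor, so each fold's training uses only the remaining samples.
#'
#' @param scores Calibration score matrix (samples x components).
#' @param y Calibration concentrations (molar).
#' @param candidates Integer vector of component counts to try.
#' @param n_hidden Hidden-layer size used during selection.
#' @param config A [train_config()] for the selection fits.
#' @return List: `n_pc` (chosen count), `rmse_cv` (named vector, one RMSEcv
#'   per candidate).
#' @export
select_n_pcs <- function(scores, y, candidates = 1:8, n_hidden = 5,
                         config = train_config(learning_rate = 0.5,
                                               momentum = 0.5,
                                               max_epochs = 500)) {
  if (length(candidates) == 0) stop("empty candidate range", call. = FALSE)
  scores <- as.matrix(scores)
  m <- nrow(scores)
  if (m < 3) stop("LOO selection needs at least 3 calibration samples",
                  call. = FALSE)
  stopifnot(max(candidates) <= ncol(scores))
  loo_pred <- lapply(candidates, function(n) {
    vapply(seq_len(m), function(i) {
      Xi <- scores[-i, seq_len(n), drop = FALSE]
      xi <- scores[i, seq_len(n), drop = FALSE]
      tr <- train_on_scores(Xi, y[-i], xi, y[i], n_hidden,
                            train_config(config$learning_rate,
                                         config$momentum, config$max_epochs,
                                         patience = config$patience,
                                         seed = config$seed + i))
      nn_predict(tr$fit$state, tr$scaling, xi)
    }, numeric(1))
  })
  rmse_cv <- vapply(loo_pred, function(p) rmse(y, p), numeric(1))
  names(rmse_cv) <- names(loo_pred) <- as.character(candidates)
  best <- candidates[which.min(rmse_cv)]  # first minimum -> smallest n on ties
  list(n_pc = best, rmse_cv = rmse_cv, loo_predictions = loo_pred, y = y)
}

#' Response-surface scan over two hyperparameter axes
#'
#' Trains one model per grid cell (with a deterministic per-cell seed
#' derived from the base seed and cell index), records the test-set MSE of
#' the predictions in concentration units, and returns the surface with its
#' argmin. Ties break toward the smaller model: cells are scanned with
#' axis values ascending and only a strictly smaller MSE displaces the
#' incumbent.
#'
#' @param axis1,axis2 Named lists `list(name =, values =)`; recognised names
#'   are `"n_hidden"`, `"epochs"`, `"learning_rate"`, `"momentum"`.
#' @param data List with `X_cal`, `y_cal`, `X_val`, `y_val`, `X_test`,
#'   `y_test` (raw scores / molar concentrations).
#' @param base_config A [train_config()] supplying the parameters not on an
#'   axis, plus the base seed.
#' @param n_hidden Hidden size when not on an axis.
#' @return An object of class `selection_surface`: `mse` matrix
#'   (axis1 x axis2), `axis1`, `axis2`, `best` (named values at the argmin).
#' @export
surface_scan <- function(axis1, axis2, data, base_config = train_config(),
                         n_hidden = 5) {
  stopifnot(length(axis1$values) > 0, length(axis2$values) > 0)
  mse <- matrix(NA_real_, length(axis1$values), length(axis2$values),
                dimnames = list(axis1$values, axis2$values))
  best <- list(mse = Inf, i = 1L, j = 1L)
  cell <- 0L
  for (i in seq_along(axis1$values)) {
    for (j in seq_along(axis2$values)) {
      cell <- cell + 1L
      pars <- list(n_hidden = n_hidden,
                   epochs = base_config$max_epochs,
                   learning_rate = base_config$learning_rate,
                   momentum = base_config$momentum)
      pars[[axis1$name]] <- axis1$values[i]
      pars[[axis2$name]] <- axis2$values[j]
      cfg <- train_config(pars$learning_rate, pars$momentum, pars$epochs,
                          patience = base_config$patience,
                          seed = base_config$seed + cell)
      tr <- train_on_scores(data$X_cal, data$y_cal, data$X_val, data$y_val,
                            pars$n_hidden, cfg)
      pred <- nn_predict(tr$fit$state, tr$scaling, data$X_test)
      mse[i, j] <- mean((pred - data$y_test)^2)
      if (mse[i, j] < best$mse) best <- list(mse = mse[i, j], i = i, j = j)
    }
  }
  out <- list(mse = mse, axis1 = axis1, axis2 = axis2,
              best = stats::setNames(
                list(axis1$values[best$i], axis2$values[best$j]),
                c(axis1$name, axis2$name)),
              best_mse = best$mse)
  class(out) <- "selection_surface"
  out
}

#' @export
print.selection_surface <- function(x, ...) {
  cat(sprintf("<selection_surface> %s x %s (%d x %d cells); argmin: %s=%g, %s=%g (test MSE %.3g)\n",
              x$axis1$name, x$axis2$name, nrow(x$mse), ncol(x$mse),
              x$axis1$name, x$best[[1]], x$axis2$name, x$best[[2]],
              x$best_mse))
  invisible(x)
}

#' Pipeline configuration
#'
#' Defaults mirror the reference workflow: KS split fractions 0.65/0.15/0.20,
#' PC candidates chosen by LOO-CV with a 5-node net at learning rate and
#' momentum 0.5 over 500 epochs, and a final 5-hidden-node network trained
#' for up to 300 epochs at learning rate 0.7 and momentum 0.2. Scans over
#' (hidden nodes x epochs) and (learning rate x momentum) are off by
#' default; when enabled they replace the final-network defaults with the
#' scan argmin.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param fractions Calibration/validation/test fractions for the KS split.
#' @param max_pcs Number of components extracted by PCA.
#' @param pc_candidates Candidate component counts for LOO selection
#'   (`NULL` skips selection and uses `n_pc`).
#' @param n_pc Component count when selection is skipped.
#' @param n_hidden,epochs,learning_rate,momentum Final network parameters.
#' @param patience Early-stopping patience (epochs).
#' @param loo_config `train_config` for the LOO selection fits.
#' @param scan_architecture,scan_rates Optional lists
#'   `list(axis1_values, axis2_values)` enabling the response-surface scans
#'   over (n_hidden x epochs) and (learning_rate x momentum).
#' @param outlier_threshold Robust-distance multiple for score screening.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            fractions = c(0.65, 0.15, 0.20),
                            max_pcs = 10,
                            pc_candidates = 1:8,
                            n_pc = 6,
                            n_hidden = 5, epochs = 300,
                            learning_rate = 0.7, momentum = 0.2,
                            patience = 50,
                            loo_config = train_config(0.5, 0.5, 500,
                                                      patience = Inf),
                            scan_architecture = NULL,
                            scan_rates = NULL,
                            outlier_threshold = 3) {
  structure(
    list(seed = as.integer(seed), fractions = fractions, max_pcs = max_pcs,
         pc_candidates = pc_candidates, n_pc = n_pc, n_hidden = n_hidden,
         epochs = epochs, learning_rate = learning_rate, momentum = momentum,
         patience = patience, loo_config = loo_config,
         scan_architecture = scan_architecture, scan_rates = scan_rates,
         outlier_threshold = outlier_threshold),
    class = "pipeline_config"
  )
}

#' Run the full UPCA-ANN calibration pipeline
#'
#' unfold -> PCA -> score-plot outlier screening -> Kennard-Stone
#' calibration/validation/test split of the scores -> LOO-CV selection of
#' the number of components -> optional response-surface scans -> final
#' network training with early stopping -> prediction of every set and
#' figures of merit. Blank samples are excluded from the split and used for
#' LOD/LOQ. Fully deterministic given the cube and config.
#'
#' @param cube An [eem_cube()] whose non-blank samples carry concentrations.
#' @param config A [pipeline_config()].
#' @return An object of class `upca_ann_fit` containing the figure-of-merit
#'   report (`fom`), per-sample prediction table (`predictions`), and stage
#'   artifacts (`pca`, `split`, `selection`, `scans`, `network`, `scaling`,
#'   `train_result`, `outliers`, `config`).
#' @export
run_pipeline <- function(cube, config = pipeline_config()) {
  stopifnot(inherits(cube, "eem_cube"), inherits(config, "pipeline_config"))
  meta <- cube_metadata(cube)
  unfolded <- unfold_cube(cube)
  is_blank <- meta$role == "blank"
  work <- which(!is_blank)
  if (any(is.na(meta$concentration_molar[work]))) {
    stop("pipeline stage 'split': non-blank samples must carry concentrations",
         call. = FALSE)
  }
  m_work <- length(work)
  k <- min(config$max_pcs, m_work - 1, ncol(unfolded$values))

  # PCA on the non-blank samples (blanks are later projected for LOD)
  pca <- fit_pca(unfolded$values[work, , drop = FALSE], k = k)
  outliers <- flag_score_outliers(pca, threshold = config$outlier_threshold)

  split <- three_way_split(pca$scores, config$fractions,
                           ids = meta$sample_id[work])
  y_all <- meta$concentration_molar[work]
  sets <- list(calibration = split$calibration, validation = split$validation,
               test = split$test)

  scores_cal <- pca$scores[sets$calibration, , drop = FALSE]
  y_cal <- y_all[sets$calibration]

  # number of components: LOO cross-validation on the calibration set
  selection <- NULL
  n_pc <- config$n_pc
  if (!is.null(config$pc_candidates)) {
    loo_cfg <- config$loo_config
    loo_cfg$seed <- config$seed + 1000L
    selection <- select_n_pcs(scores_cal, y_cal,
                              candidates = config$pc_candidates,
                              n_hidden = config$n_hidden, config = loo_cfg)
    n_pc <- selection$n_pc
  }

  sc <- function(idx) pca$scores[idx, seq_len(n_pc), drop = FALSE]
  data <- list(X_cal = sc(sets$calibration), y_cal = y_cal,
               X_val = sc(sets$validation), y_val = y_all[sets$validation],
               X_test = sc(sets$test), y_test = y_all[sets$test])

  # optional response-surface scans refine the final hyperparameters
  scans <- list()
  n_hidden <- config$n_hidden
  epochs <- config$epochs
  lr <- config$learning_rate
  mom <- config$momentum
  if (!is.null(config$scan_architecture)) {
    scans$architecture <- surface_scan(
      list(name = "n_hidden", values = config$scan_architecture$axis1_values),
      list(name = "epochs", values = config$scan_architecture$axis2_values),
      data,
      train_config(lr, mom, epochs, patience = Inf,
                   seed = config$seed + 2000L),
      n_hidden = n_hidden
    )
    n_hidden <- scans$architecture$best$n_hidden
    epochs <- scans$architecture$best$epochs
  }
  if (!is.null(config$scan_rates)) {
    scans$rates <- surface_scan(
      list(name = "learning_rate", values = config$scan_rates$axis1_values),
      list(name = "momentum", values = config$scan_rates$axis2_values),
      data,
      train_config(lr, mom, epochs, patience = Inf,
                   seed = config$seed + 3000L),
      n_hidden = n_hidden
    )
    lr <- scans$rates$best$learning_rate
    mom <- scans$rates$best$momentum
  }

  final_cfg <- train_config(lr, mom, epochs, patience = config$patience,
                            seed = config$seed + 4000L)
  tr <- train_on_scores(data$X_cal, data$y_cal, data$X_val, data$y_val,
                        n_hidden, final_cfg)

  predict_set <- function(X) nn_predict(tr$fit$state, tr$scaling, X)
  pred <- list(calibration = predict_set(data$X_cal),
               validation = predict_set(data$X_val),
               test = predict_set(data$X_test))

  # cross-validation statistics at the chosen size, from the LOO selection
  rmse_cv <- NA_real_
  r2_cv <- NA_real_
  if (!is.null(selection)) {
    rmse_cv <- unname(selection$rmse_cv[as.character(n_pc)])
    r2_cv <- r_squared(y_cal, selection$loo_predictions[[as.character(n_pc)]])
  }

  # blanks: project onto the PCA model, predict, estimate LOD/LOQ
  lod <- NULL
  blank_pred <- numeric(0)
  if (sum(is_blank) >= 2) {
    blank_scores <- project_scores(pca,
                                   unfolded$values[is_blank, , drop = FALSE],
                                   n_pc = n_pc)
    blank_pred <- nn_predict(tr$fit$state, tr$scaling, blank_scores)
    lod <- lod_loq(blank_pred)
  }

  fom <- list(
    rmse_calibration = rmse(data$y_cal, pred$calibration),
    rmse_validation = rmse(data$y_val, pred$validation),
    rmse_prediction = rmse(data$y_test, pred$test),
    rmse_cv = rmse_cv, r2_cv = r2_cv,
    r2_calibration = r_squared(data$y_cal, pred$calibration),
    r2_validation = r_squared(data$y_val, pred$validation),
    r2_prediction = r_squared(data$y_test, pred$test),
    rep_pct_aggregate = rep_aggregate(data$y_test, pred$test),
    lod = if (is.null(lod)) NA_real_ else lod$lod,
    loq = if (is.null(lod)) NA_real_ else lod$loq,
    dynamic_range = range(y_cal),
    n_pc = n_pc, n_hidden = n_hidden, epochs = epochs,
    learning_rate = lr, momentum = mom
  )

  set_of <- character(m_work)
  set_of[sets$calibration] <- "calibration"
  set_of[sets$validation] <- "validation"
  set_of[sets$test] <- "test"
  pred_all <- rep(NA_real_, m_work)
  pred_all[sets$calibration] <- pred$calibration
  pred_all[sets$validation] <- pred$validation
  pred_all[sets$test] <- pred$test
  predictions <- data.frame(
    sample_id = meta$sample_id[work],
    set = set_of,
    nominal_molar = y_all,
    predicted_molar = pred_all,
    rep_pct = rep_per_sample(y_all, pred_all),
    stringsAsFactors = FALSE
  )

  structure(
    list(fom = fom, predictions = predictions, pca = pca, split = split,
         selection = selection, scans = scans, network = tr$fit$state,
         scaling = tr$scaling, train_result = tr$fit, outliers = outliers,
         blank_predictions = blank_pred, config = config),
    class = "upca_ann_fit"
  )
}

#' @export
print.upca_ann_fit <- function(x, ...) {
  f <- x$fom
  cat("<upca_ann_fit> UPCA-ANN calibration\n")
  cat(sprintf("  architecture: %d-%d-1, %d epochs, learning rate %.2f, momentum %.2f\n",
              f$n_pc, f$n_hidden, f$epochs, f$learning_rate, f$momentum))
  cat(sprintf("  split: %d calibration / %d validation / %d test\n",
              length(x$split$calibration), length(x$split$validation),
              length(x$split$test)))
  cat(sprintf("  R2: calibration %.4f, validation %.4f, prediction %.4f\n",
              f$r2_calibration, f$r2_validation, f$r2_prediction))
  cat(sprintf("  RMSE (M): calibration %.3g, validation %.3g, prediction %.3g; RMSEcv %.3g\n",
              f$rmse_calibration, f$rmse_validation, f$rmse_prediction,
              f$rmse_cv))
  cat(sprintf("  REP%% (test, aggregate): %.2f\n", f$rep_pct_aggregate))
  if (!is.na(f$lod)) {
    cat(sprintf("  LOD %.3g M, LOQ %.3g M; dynamic range %.3g-%.3g M\n",
                f$lod, f$loq, f$dynamic_range[1], f$dynamic_range[2]))
  }
  if (length(x$outliers)) {
    cat("  score-plot outliers flagged:",
        paste(x$predictions$sample_id[x$outliers], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Figure-of-merit report as a data.frame
#'
#' Statistics table of a fitted pipeline: one row per parameter with
#' calibration / validation / prediction columns where applicable.
#'
#' @param fit An `upca_ann_fit`.
#' @return A data.frame.
#' @export
fom_table <- function(fit) {
  f <- fit$fom
  data.frame(
    parameter = c("R2", "R2_cv", "RMSE_molar", "RMSEcv_molar", "REP_pct",
                  "LOD_molar", "LOQ_molar", "dynamic_range_min_molar",
                  "dynamic_range_max_molar"),
    calibration = c(f$r2_calibration, f$r2_cv, f$rmse_calibration, f$rmse_cv,
                    NA, NA, NA, NA, NA),
    validation = c(f$r2_validation, NA, f$rmse_validation, NA, NA, NA, NA,
                   NA, NA),
    prediction = c(f$r2_prediction, NA, f$rmse_prediction, NA,
                   f$rep_pct_aggregate, f$lod, f$loq, f$dynamic_range[1],
                   f$dynamic_range[2]),
    stringsAsFactors = FALSE
  )
}
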