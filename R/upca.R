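#' Unfold an EEM cube into a samples x variables matrix
#'
#' Matricization of the three-way cube: each sample's emission x excitation
#' landscape becomes one long row, with emission varying fastest within each
#' excitation block. This turns second-order data into a first-order matrix
#' that PCA can decompose; a 61 x 30 x 401 cube unfolds to 61 x 12030.
#'
#' @param cube An [eem_cube()].
#' @return An object of class `unfolded_eem`: list with `values` (m x l
#'   matrix, rownames = sample ids), `column_map` (data.frame `column`,
#'   `ex_nm`, `em_nm`), `grid`, and `metadata` (see [cube_metadata()]).
#' @export
#' @seealso [refold_matrix()] for the exact inverse.
unfold_cube <- function(cube) {
  stopifnot(inherits(cube, "eem_cube"))
  n_em <- length(cube$grid$emission)
  n_ex <- length(cube$grid$excitation)
  m <- length(cube$samples)
  vals <- matrix(NA_real_, nrow = m, ncol = n_em * n_ex)
  for (i in seq_len(m)) {
    # column-major vectorisation = emission fastest within each excitation
    vals[i, ] <- as.vector(cube$samples[[i]]$intensities)
  }
  rownames(vals) <- vapply(cube$samples, function(s) s$sample_id, character(1))
  column_map <- data.frame(
    column = seq_len(n_em * n_ex),
    ex_nm = rep(cube$grid$excitation, each = n_em),
    em_nm = rep(cube$grid$emission, times = n_ex)
  )
  structure(
    list(values = vals, column_map = column_map, grid = cube$grid,
         metadata = cube_metadata(cube)),
    class = "unfolded_eem"
  )
}

#' @export
print.unfolded_eem <- function(x, ...) {
  cat(sprintf("<unfolded_eem> %d samples x %d variables (%d ex x %d em)\n",
              nrow(x$values), ncol(x$values), length(x$grid$excitation),
              length(x$grid$emission)))
  invisible(x)
}

#' Refold an unfolded matrix back into an EEM cube
#'
#' Exact inverse of [unfold_cube()] for a matching grid.
#'
#' @param unfolded An `unfolded_eem`, or a plain numeric matrix with one row
#'   per sample in the [unfold_cube()] column order.
#' @param grid A [wavelength_grid()]; defaults to the grid stored in
#'   `unfolded`.
#' @param metadata Optional data.frame with `sample_id`, `role`,
#'   `concentration_molar` per row.
#' @return An [eem_cube()].
#' @export
refold_matrix <- function(unfolded, grid = NULL, metadata = NULL) {
  if (inherits(unfolded, "unfolded_eem")) {
    if (is.null(grid)) grid <- unfolded$grid
    if (is.null(metadata)) metadata <- unfolded$metadata
    vals <- unfolded$values
  } else {
    vals <- as.matrix(unfolded)
  }
  if (is.null(grid)) stop("a wavelength_grid is required", call. = FALSE)
  n_em <- length(grid$emission)
  n_ex <- length(grid$excitation)
  if (ncol(vals) != n_em * n_ex) {
    stop(sprintf(
      "size mismatch: %d columns cannot refold onto a %d x %d (= %d) grid",
      ncol(vals), n_ex, n_em, n_em * n_ex), call. = FALSE)
  }
  m <- nrow(vals)
  if (is.null(metadata)) {
    metadata <- data.frame(
      sample_id = if (!is.null(rownames(vals))) rownames(vals) else
        sprintf("S%02d", seq_len(m)),
      role = "unknown", concentration_molar = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  samples <- lapply(seq_len(m), function(i) {
    eem_sample(metadata$sample_id[i],
               matrix(vals[i, ], nrow = n_em, ncol = n_ex),
               role = metadata$role[i],
               concentration = metadata$concentration_molar[i])
  })
  eem_cube(grid, samples)
}

#' Principal component analysis of an unfolded EEM matrix
#'
#' Column-mean-centred PCA by singular value decomposition:
#' `A_centred = T P'` with orthonormal loadings `P` and scores `T = U D`.
#' Eigenvalues follow the sample-covariance convention `d_j^2 / (m - 1)`;
#' explained variance percentages are relative to the total variance of the
#' centred matrix, so `variance_pct` over all `min(m-1, l)` components sums
#' to 100.
#'
#' @param x An `unfolded_eem` or a numeric samples x variables matrix.
#' @param k Number of components to retain, `1 <= k <= min(m - 1, l)`.
#' @return An object of class `pca_model`: `column_means`, `loadings`
#'   (l x k), `scores` (m x k), `eigenvalues`, `variance_pct`,
#'   `cumulative_pct`, `total_variance`, `n_samples`.
#' @export
fit_pca <- function(x, k) {
  X <- if (inherits(x, "unfolded_eem")) x$values else as.matrix(x)
  m <- nrow(X)
  l <- ncol(X)
  if (m < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  if (k < 1 || k > min(m - 1, l)) {
    stop(sprintf("k must be in [1, %d], got %d", min(m - 1, l), k),
         call. = FALSE)
  }
  column_means <- colMeans(X)
  Xc <- sweep(X, 2, column_means)
  sv <- svd(Xc, nu = k, nv = k)
  all_eigen <- sv$d^2 / (m - 1)
  total_var <- sum(all_eigen)
  if (total_var <= 0) {
    stop("constant matrix: zero total variance, PCA undefined", call. = FALSE)
  }
  eigenvalues <- all_eigen[seq_len(k)]
  scores <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(k))
  colnames(sv$v) <- paste0("PC", seq_len(k))
  variance_pct <- 100 * eigenvalues / total_var
  structure(
    list(column_means = column_means, loadings = sv$v, scores = scores,
         eigenvalues = eigenvalues, variance_pct = variance_pct,
         cumulative_pct = cumsum(variance_pct), total_variance = total_var,
         n_samples = m),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat(sprintf("<pca_model> %d components over %d variables (%d samples)\n",
              k, nrow(x$loadings), x$n_samples))
  cat(sprintf("  cumulative variance after %d PCs: %.2f%%\n", k,
              x$cumulative_pct[k]))
  invisible(x)
}

#' Variance-accounting table of a PCA model
#'
#' One row per retained component: eigenvalue, percent of total variance
#' explained, and the running (cumulative) percentage. Values are exact
#' prefix sums; rounding is left to display.
#'
#' @param model A `pca_model`, or a numeric vector of per-component variance
#'   percentages (eigenvalues then taken as `NA`).
#' @return A data.frame with columns `pc`, `eigenvalue`, `variance_pct`,
#'   `cumulative_pct`.
#' @export
#' @examples
#' variance_table(c(39.79, 20.21, 8.24, 6.89, 5.02, 4.30))
variance_table <- function(model) {
  if (is.numeric(model)) {
    v <- as.numeric(model)
    ev <- rep(NA_real_, length(v))
  } else {
    stopifnot(inherits(model, "pca_model"))
    v <- model$variance_pct
    ev <- model$eigenvalues
  }
  data.frame(
    pc = seq_along(v),
    eigenvalue = ev,
    variance_pct = v,
    cumulative_pct = cumsum(v)
  )
}

#' Project new samples onto a fitted PCA model
#'
#' Centres rows with the training column means and projects onto the leading
#' `n_pc` loadings. Projecting the training matrix itself reproduces the
#' stored scores.
#'
#' @param model A `pca_model`.
#' @param x An `unfolded_eem`, matrix, or single numeric row vector with the
#'   training number of variables.
#' @param n_pc Number of components to use (default: all retained).
#' @return Scores matrix (rows = samples, columns = PCs).
#' @export
project_scores <- function(model, x, n_pc = ncol(model$loadings)) {
  stopifnot(inherits(model, "pca_model"))
  X <- if (inherits(x, "unfolded_eem")) x$values else x
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != nrow(model$loadings)) {
    stop(sprintf("column-count mismatch: model has %d variables, data has %d",
                 nrow(model$loadings), ncol(X)), call. = FALSE)
  }
  if (n_pc < 1 || n_pc > ncol(model$loadings)) {
    stop("n_pc out of range", call. = FALSE)
  }
  sweep(X, 2, model$column_means) %*% model$loadings[, seq_len(n_pc),
                                                     drop = FALSE]
}

#' Flag score-plot outliers on the PC1-PC2 plane
#'
#' Reproducible replacement for visual score-plot screening: a sample is
#' flagged when its Euclidean distance from the componentwise median of the
#' (PC1, PC2) scores exceeds the median distance by more than `threshold`
#' times the median absolute deviation (scaled, 1.4826) of the distances —
#' a robust z-score on the centroid distances. When the distance spread is
#' exactly zero, any distance strictly above the median is flagged. Flagged
#' samples are reported, not removed.
#'
#' @param model A `pca_model` with at least 2 components.
#' @param threshold Robust-distance multiple (default 3).
#' @return Integer vector of flagged sample indices (possibly empty).
#' @export
flag_score_outliers <- function(model, threshold = 3) {
  stopifnot(inherits(model, "pca_model"))
  if (ncol(model$scores) < 2) {
    stop("outlier screening needs at least 2 components", call. = FALSE)
  }
  s <- model$scores[, 1:2, drop = FALSE]
  centre <- apply(s, 2, stats::median)
  d <- sqrt((s[, 1] - centre[1])^2 + (s[, 2] - centre[2])^2)
  scale <- stats::mad(d)
  which(d - stats::median(d) > threshold * scale)
}
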