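#' Kennard-Stone maximin ordering of samples
#'
#' Classic deterministic design-coverage ordering: the first two indices are
#' the pair at maximum Euclidean distance; every subsequent index maximises
#' its minimum distance to all already-selected points. Ties are broken by
#' the lowest index, so the ordering is fully deterministic.
#'
#' @param points Numeric m x d matrix of sample coordinates (typically PC
#'   scores), m >= 2, finite.
#' @return Integer permutation of `1:m`, most design-covering samples first.
#' @export
#' @examples
#' ks_rank(cbind(c(0, 10, 5)))  # starts with the extreme pair 1, 2
ks_rank <- function(points) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (m < 2) stop("Kennard-Stone needs at least 2 points", call. = FALSE)
  if (!all(is.finite(points))) stop("points must be finite", call. = FALSE)
  D <- as.matrix(stats::dist(points))
  # seed pair: maximum distance, ties to the lexicographically lowest (i, j)
  best <- c(1L, 2L)
  best_d <- -Inf
  for (i in seq_len(m - 1)) {
    for (j in seq((i + 1), m)) {
      if (D[i, j] > best_d) {
        best_d <- D[i, j]
        best <- c(i, j)
      }
    }
  }
  selected <- best
  remaining <- setdiff(seq_len(m), selected)
  min_d <- pmin(D[, selected[1]], D[, selected[2]])
  while (length(remaining) > 0) {
    cand <- remaining[which.max(min_d[remaining])]  # which.max -> lowest index tie-break
    selected <- c(selected, cand)
    remaining <- setdiff(remaining, cand)
    min_d <- pmin(min_d, D[, cand])
  }
  selected
}

#' Three-way Kennard-Stone split into calibration / validation / test sets
#'
#' Orders samples by [ks_rank()] and assigns, down the ranking, the first
#' block to calibration, the next to validation, and the last to test.
#' Set sizes are `round(f * m)` for validation and test with the remainder
#' going to calibration, so 61 samples at fractions (0.65, 0.15, 0.20)
#' split 40 / 9 / 12.
#'
#' @param points Numeric m x d matrix (e.g. PC scores of all samples).
#' @param fractions Length-3 numeric `(calibration, validation, test)`,
#'   positive, summing to 1.
#' @param ids Optional sample identifiers (default `1:m`).
#' @return An object of class `split_assignment`: disjoint, exhaustive
#'   `calibration_ids`, `validation_ids`, `test_ids` plus the underlying
#'   index vectors `calibration`, `validation`, `test`.
#' @export
#' @examples
#' pts <- cbind(seq_len(61))
#' sp <- three_way_split(pts, c(0.65, 0.15, 0.20))
#' lengths(sp[c("calibration", "validation", "test")])  # 40 9 12
three_way_split <- function(points, fractions = c(0.65, 0.15, 0.20),
                            ids = NULL) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be 3 positive values summing to 1", call. = FALSE)
  }
  n_val <- round(fractions[2] * m)
  n_test <- round(fractions[3] * m)
  n_cal <- m - n_val - n_test
  if (n_cal < 1 || n_val < 1 || n_test < 1) {
    stop("every set must receive at least one sample", call. = FALSE)
  }
  if (is.null(ids)) ids <- seq_len(m)
  stopifnot(length(ids) == m)
  ord <- ks_rank(points)
  cal <- sort(ord[seq_len(n_cal)])
  val <- sort(ord[n_cal + seq_len(n_val)])
  tst <- sort(ord[n_cal + n_val + seq_len(n_test)])
  structure(
    list(calibration = cal, validation = val, test = tst,
         calibration_ids = ids[cal], validation_ids = ids[val],
         test_ids = ids[tst]),
    class = "split_assignment"
  )
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> calibration %d, validation %d, test %d\n",
              length(x$calibration), length(x$validation), length(x$test)))
  invisible(x)
}
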