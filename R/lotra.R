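## Core transform: distance matrices, 8-bit local-binary-pattern codes,
## code-band masks, thresholded recurrence matrices, epsilon calibration.

# neighbour enumeration for the 3x3 window around (i, j): row/col offsets in
# bit order g1..g8, starting at the preceding-time corner (i-1, j-1) and
# moving around the centre. Positional weights are 2^(n-1).
.lbp_offsets <- cbind(
  di = c(-1L, -1L, -1L,  0L,  1L,  1L,  1L,  0L),
  dj = c(-1L,  0L,  1L,  1L,  1L,  0L, -1L, -1L))
.lbp_weights <- as.integer(2^(0:7))

#' Pairwise Euclidean distance matrix of a trajectory
#'
#' @param traj numeric matrix, one phase-space point per row.
#' @return Symmetric `N x N` matrix of Euclidean norms with a zero diagonal.
#'   Exact symmetry holds because each pair is computed once and mirrored.
#' @export
distance_matrix <- function(traj) {
  tm <- as_series_matrix(traj, min_n = 3L)
  as.matrix(dist(tm))
}

#' 8-bit code of a single 3x3 neighbourhood
#'
#' Encodes the inequality pattern of eight neighbours `g1..g8` against the
#' centre `g0`: bit `n` is set when `g_n >= g0` (ties count as set), and the
#' code is `sum(bit_n * 2^(n-1))`, giving integers 0..255.
#'
#' @param g0 centre value.
#' @param neighbors numeric vector of exactly 8 neighbour values, in the
#'   fixed enumeration order documented for [lotra_transform()].
#' @return Integer in 0..255.
#' @examples
#' lbp_code(1, rep(1, 8))  # all ties -> 255
#' lbp_code(5, rep(0, 8))  # centre strictly largest -> 0
#' @export
lbp_code <- function(g0, neighbors) {
  if (length(neighbors) != 8L) stop("exactly 8 neighbors required")
  sum(.lbp_weights[neighbors - g0 >= 0])
}

#' Local-binary-pattern transform of a distance matrix
#'
#' The un-thresholded recurrence transform: every interior cell `(i, j)` of
#' the distance matrix is replaced by the 8-bit code of its 3x3
#' neighbourhood, capturing the local inequality (curvature/directionality)
#' structure of the phase-space trajectory instead of a hard distance cutoff.
#'
#' @param D symmetric distance matrix (`N x N`, `N >= 3`), e.g. from
#'   [distance_matrix()].
#' @return An integer matrix of class `"code_matrix"`, size
#'   `(N-2) x (N-2)`, values 0..255, with attribute `index_offset = 1`:
#'   code cell `(i, j)` describes distance cell `(i+1, j+1)`. Border rows and
#'   columns of `D` produce no code (no padding is invented). Codes on the
#'   image of the line of identity are always 255, since the centre distance
#'   there is 0 and every neighbour is `>= 0`.
#' @details Neighbour bit order (weights `2^0..2^7`) starts at the
#'   preceding-time corner and proceeds around the centre:
#'   `(i-1,j-1), (i-1,j), (i-1,j+1), (i,j+1), (i+1,j+1), (i+1,j), (i+1,j-1),
#'   (i,j-1)`. Ties (`g_n == g0`) set the bit.
#' @export
lotra_transform <- function(D) {
  if (!is.matrix(D) || !is.numeric(D)) stop("D must be a numeric matrix")
  n <- nrow(D)
  if (n != ncol(D)) stop("D must be square")
  if (n < 3L) stop("matrix too small for 3x3 neighborhoods")
  if (!all(is.finite(D))) stop("D contains non-finite values")
  ii <- 2:(n - 1L)
  centre <- D[ii, ii, drop = FALSE]
  codes <- matrix(0L, n - 2L, n - 2L)
  for (b in seq_len(8L)) {
    di <- .lbp_offsets[b, "di"]; dj <- .lbp_offsets[b, "dj"]
    codes <- codes + .lbp_weights[b] *
      (D[ii + di, ii + dj, drop = FALSE] >= centre)
  }
  storage.mode(codes) <- "integer"
  structure(codes, index_offset = 1L, class = c("code_matrix", "matrix", "array"))
}

#' Binary mask of a code band
#'
#' Selects the cells of a code matrix whose codes fall in an inclusive band.
#' The default band 64--191 keeps the "high-curvature" codes associated with
#' vertices of the trajectory, producing the binary sparse matrix used for
#' feature extraction.
#'
#' @param codes `"code_matrix"` from [lotra_transform()] (or any integer
#'   matrix of codes in 0..255).
#' @param band integer pair `c(low, high)`, `0 <= low <= high <= 255`.
#' @return Binary integer matrix of class `"recurrence_matrix"` with
#'   attributes `source = "code_band"` and `band`.
#' @export
code_band_mask <- function(codes, band = c(64L, 191L)) {
  if (length(band) != 2L) stop("band must be c(low, high)")
  lo <- band[1]; hi <- band[2]
  if (lo > hi) stop("inverted band: low must not exceed high")
  if (lo < 0 || hi > 255) stop("band must lie within 0..255")
  m <- (unclass(codes) >= lo & unclass(codes) <= hi) + 0L
  structure(m, source = "code_band", band = c(lo, hi),
            class = c("recurrence_matrix", "matrix", "array"))
}

#' Thresholded recurrence matrix
#'
#' Classical recurrence plot: entry `(i, j)` is 1 when the phase-space
#' distance `D_ij` is within `epsilon` (Heaviside step, ties recurrent).
#'
#' @param D distance matrix.
#' @param epsilon threshold radius (`>= 0`).
#' @return Binary integer matrix of class `"recurrence_matrix"`, symmetric
#'   with an all-ones diagonal, attributes `source = "threshold"` and
#'   `epsilon`.
#' @export
recurrence_matrix <- function(D, epsilon) {
  if (!is.matrix(D) || !is.numeric(D)) stop("D must be a numeric matrix")
  if (epsilon < 0) stop("epsilon must be nonnegative")
  m <- (D <= epsilon) + 0L
  structure(m, source = "threshold", epsilon = epsilon,
            class = c("recurrence_matrix", "matrix", "array"))
}

#' Calibrate the recurrence threshold to a target recurrence rate
#'
#' Practitioners set the threshold indirectly, via the recurrence rate it
#' produces (e.g. 4--5% for periodic gait, ~2% for non-periodic photometry).
#' The empirical distance spectrum is searched exactly: the returned epsilon
#' is the smallest off-diagonal distance value whose recurrence rate
#' (diagonal included) reaches the target.
#'
#' @param D distance matrix.
#' @param target_rr target recurrence rate in (0, 1).
#' @return List with `epsilon` and `rr` (the achieved rate — the smallest
#'   attainable rate `>=` `target_rr` given the discreteness of the distance
#'   spectrum). Recomputing [recurrence_matrix()] at `epsilon` reproduces
#'   `rr` exactly.
#' @export
calibrate_epsilon <- function(D, target_rr) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  n <- nrow(D)
  if (target_rr <= 0 || target_rr >= 1) stop("target_rr must be in (0, 1)")
  if (target_rr < 1 / n)
    stop(sprintf("target below attainable minimum: diagonal-only RR is 1/N = %.4g",
                 1 / n))
  up <- sort(unique(D[upper.tri(D)]))
  # RR at epsilon = up[k]: diagonal (n ones) plus both triangles
  counts <- cumsum(tabulate(findInterval(D[upper.tri(D)], up), nbins = length(up)))
  rr <- (n + 2 * counts) / n^2
  k <- which(rr >= target_rr)[1]
  if (is.na(k)) { # target below every off-diagonal step but >= 1/n
    return(list(epsilon = 0, rr = 1 / n))
  }
  list(epsilon = up[k], rr = rr[k])
}

## ---- the analysis object ---------------------------------------------------

#' Local topological recurrence analysis of a time series
#'
#' One-call pipeline: (optionally) embed, compute the distance matrix, apply
#' the local-binary-pattern transform, and derive the high-curvature band
#' mask. Multi-channel input with `dimension = 1` (the default for `d > 1`)
#' skips embedding, as multi-dimensional recordings already live in phase
#' space.
#'
#' @param x numeric vector, matrix or data frame (samples x channels).
#' @param delay embedding delay; ignored when `dimension = 1`.
#' @param dimension embedding dimension; defaults to 2 for scalar input and
#'   1 for multi-channel input.
#' @param band code band kept in the binary mask (default `c(64, 191)`).
#' @param scale z-score each channel first (default TRUE; disable for data
#'   already on a common scale).
#' @return Object of class `"lotra"`: list with the embedded `trajectory`,
#'   `distance` matrix, `codes` (class `"code_matrix"`), `mask` (class
#'   `"recurrence_matrix"`), and the parameters used.
#' @examples
#' s <- sine_series()
#' fit <- lotra(s$values, delay = 15, scale = FALSE)
#' fit
#' @export
lotra <- function(x, delay = 1L, dimension = NULL, band = c(64L, 191L),
                  scale = TRUE) {
  xm <- as_series_matrix(x, min_n = 3L)
  if (is.null(dimension)) dimension <- if (ncol(xm) > 1L) 1L else 2L
  if (scale) xm <- apply(xm, 2L, zscore)
  traj <- delay_embed(xm, delay = delay, dimension = dimension)
  D <- distance_matrix(traj)
  codes <- lotra_transform(D)
  mask <- code_band_mask(codes, band)
  structure(list(trajectory = traj, distance = D, codes = codes,
                 mask = mask, delay = as.integer(delay),
                 dimension = as.integer(dimension), band = band),
            class = "lotra")
}

#' @export
print.lotra <- function(x, ...) {
  n <- nrow(x$distance)
  occ <- mean(x$mask)
  cat("Local topological recurrence analysis\n")
  cat(sprintf("  trajectory: %d points in %d dims (t = %d, m = %d)\n",
              n, ncol(x$trajectory), x$delay, x$dimension))
  cat(sprintf("  code matrix: %d x %d, band [%d, %d] occupancy %.1f%%\n",
              nrow(x$codes), ncol(x$codes), x$band[1], x$band[2], 100 * occ))
  invisible(x)
}

#' @export
summary.lotra <- function(object, l_min = 2L, v_min = 2L, ...) {
  feats <- rqa_features(object$mask, l_min = l_min, v_min = v_min)
  structure(list(features = feats, band = object$band,
                 n = nrow(object$distance)),
            class = "summary.lotra")
}

#' @export
print.summary.lotra <- function(x, ...) {
  cat(sprintf("Recurrence statistics of the band-[%d, %d] mask (N = %d):\n",
              x$band[1], x$band[2], x$n))
  print(round(x$features, 4))
  invisible(x)
}

#' Plot method: code matrix quartile image
#'
#' @param x a `"lotra"` object.
#' @param palette four colours for the code quartiles
#'   `[0,63], [64,127], [128,191], [192,255]`.
#' @param ... passed to [graphics::image()].
#' @export
plot.lotra <- function(x, palette = c("black", "blue", "red", "green3"), ...) {
  q <- code_quartiles(x$codes)
  graphics::image(t(q)[, rev(seq_len(nrow(q)))], col = palette,
                  breaks = c(0.5, 1.5, 2.5, 3.5, 4.5), axes = FALSE,
                  asp = 1, ...)
  invisible(x)
}
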