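## Recurrence quantification on binary matrices (thresholded or code-band).

#' Recurrence rate
#'
#' Density of nonzero entries of a binary matrix: `sum(B) / N^2` (the
#' diagonal, when present, counts).
#'
#' @param B binary matrix.
#' @return Value in `[0, 1]`.
#' @export
recurrence_rate <- function(B) {
  B <- unclass(B)
  if (!is.matrix(B)) stop("B must be a matrix")
  sum(B != 0) / length(B)
}

# run lengths of 1s along every diagonal (optionally without the main
# diagonal) or along every column, as a plain integer vector
.diag_runs <- function(B, include_loi) {
  n <- nrow(B)
  off <- col(B) - row(B)
  groups <- split(B != 0, off)   # column-major order == along-diagonal order
  if (!include_loi) groups[["0"]] <- NULL
  unlist(lapply(groups, function(v) {
    r <- rle(v)
    r$lengths[r$values]
  }), use.names = FALSE)
}

.vert_runs <- function(B) {
  unlist(apply(B != 0, 2L, function(v) {
    r <- rle(v)
    r$lengths[r$values]
  }), use.names = FALSE)
}

#' Histogram of diagonal line lengths
#'
#' Counts maximal runs of 1s along every diagonal of a binary matrix (both
#' triangles). Runs touching the matrix border count with their observed
#' length.
#'
#' @param B binary matrix.
#' @param l_min minimum length for a run to count as a "line" (default 2 —
#'   it takes two points to define a line). Shorter runs are retained in the
#'   histogram but excluded from `n_lines` and from the probabilities.
#' @param include_loi count the main diagonal (line of identity)? Default
#'   FALSE, the standard practice for thresholded matrices whose diagonal is
#'   identically 1.
#' @return Object of class `"diag_hist"`: list with `lengths` (sorted unique
#'   run lengths), `counts` (`P(l)`), `l_min`, and `n_lines` (total lines of
#'   length `>= l_min`). `p(l) = counts/n_lines` over `lengths >= l_min`
#'   sums to 1 whenever `n_lines > 0`.
#' @export
diagonal_histogram <- function(B, l_min = 2L, include_loi = FALSE) {
  B <- unclass(B)
  if (!is.matrix(B)) stop("B must be a matrix")
  if (l_min < 1L) stop("l_min must be at least 1")
  runs <- .diag_runs(B, include_loi)
  if (length(runs) == 0L) {
    return(structure(list(lengths = integer(0), counts = integer(0),
                          l_min = as.integer(l_min), n_lines = 0L),
                     class = "diag_hist"))
  }
  tab <- table(runs)
  lengths <- as.integer(names(tab))
  counts <- as.integer(tab)
  structure(list(lengths = lengths, counts = counts,
                 l_min = as.integer(l_min),
                 n_lines = sum(counts[lengths >= l_min])),
            class = "diag_hist")
}

#' @export
print.diag_hist <- function(x, ...) {
  cat(sprintf("diagonal-line histogram: %d line(s) of length >= %d\n",
              x$n_lines, x$l_min))
  if (length(x$lengths))
    print(data.frame(length = x$lengths, count = x$counts), row.names = FALSE)
  invisible(x)
}

#' Shannon entropy of the diagonal-line length distribution
#'
#' `ENT = -sum p(l) log p(l)` in nats, over lines of length `>= l_min`, where
#' `p(l)` is the fraction of lines with exact length `l`. Defined as 0 when
#' there are no qualifying lines or all lines share one length, so feature
#' vectors stay finite.
#'
#' @param h `"diag_hist"` from [diagonal_histogram()] (the vertical-run
#'   variant works identically).
#' @return Entropy in nats (`>= 0`).
#' @export
line_entropy <- function(h) {
  stopifnot(inherits(h, "diag_hist"))
  keep <- h$lengths >= h$l_min
  cnt <- h$counts[keep]
  if (h$n_lines == 0L || length(cnt) == 0L) return(0)
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  -sum(p * log(p))
}

# line-based summary of one run-length vector: used for both diagonal and
# vertical structures
.line_stats <- function(runs, lmin) {
  pts_total <- sum(runs)
  qual <- runs[runs >= lmin]
  if (length(qual) == 0L)
    return(list(frac = 0, mean_l = 0, max_l = 0, ent = 0))
  tab <- table(qual)
  p <- as.integer(tab) / length(qual)
  list(frac = if (pts_total > 0) sum(qual) / pts_total else 0,
       mean_l = mean(qual),
       max_l = max(qual),
       ent = -sum(p * log(p)))
}

#' The recurrence-statistics feature vector
#'
#' The nine classical recurrence statistics of a binary matrix, in a fixed
#' order suitable for direct use as a classifier feature vector:
#' `rr` (recurrence rate), `det` (determinism: fraction of recurrent points
#' on diagonal lines of length `>= l_min`), `mean_diag_l`, `max_diag_l`,
#' `div` (divergence, `1/max_diag_l`), `ent` (diagonal-line entropy, nats),
#' `lam` (laminarity: fraction of recurrent points on vertical lines of
#' length `>= v_min`), `tt` (trapping time: mean vertical line length), and
#' `max_vert_l`.
#'
#' @param B binary matrix ([recurrence_matrix()] or [code_band_mask()]
#'   output, or any 0/1 matrix).
#' @param l_min minimum diagonal line length (default 2).
#' @param v_min minimum vertical line length (default 2).
#' @param include_loi count the main diagonal in the diagonal-line
#'   statistics? Default FALSE (standard for thresholded matrices; code-band
#'   masks of the default 64--191 band have an all-zero diagonal anyway, so
#'   the flag is moot there).
#' @return Named numeric vector of length 9. Ratios with empty denominators
#'   (no qualifying lines) are reported as 0.
#' @export
rqa_features <- function(B, l_min = 2L, v_min = 2L, include_loi = FALSE) {
  B <- unclass(B)
  if (!is.matrix(B) || length(B) == 0L) stop("B must be a nonempty matrix")
  dstats <- .line_stats(.diag_runs(B, include_loi), l_min)
  vstats <- .line_stats(.vert_runs(B), v_min)
  c(rr = recurrence_rate(B),
    det = dstats$frac,
    mean_diag_l = dstats$mean_l,
    max_diag_l = dstats$max_l,
    div = if (dstats$max_l > 0) 1 / dstats$max_l else 0,
    ent = dstats$ent,
    lam = vstats$frac,
    tt = vstats$mean_l,
    max_vert_l = vstats$max_l)
}
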