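## Readers, preprocessing, serialization and image rendering.

#' Read a digitised spiral-drawing record
#'
#' Parses a per-subject tablet file into an (x, y, pressure) time series.
#' The default dialect is semicolon-delimited with columns
#' `X;Y;Z;Pressure;GripAngle;Timestamp;TestID`; both the delimiter and the
#' column map can be overridden for other dialects.
#'
#' @param path file path.
#' @param schema named integer vector mapping the channels `x`, `y`,
#'   `pressure` (and optionally `timestamp`, `test_id`) to column indices.
#' @param sep field delimiter (default `";"`).
#' @param test_id if the schema maps a `test_id` column, keep only rows with
#'   this test id (e.g. the dynamic spiral test); `NULL` keeps all rows.
#' @param strict if TRUE (default) a malformed line is an error naming its
#'   line number; if FALSE malformed lines are skipped with a warning.
#' @return List with `values` (n x 3 matrix, channels x/y/pressure),
#'   `timestamp` (or NULL) and `n_skipped`.
#' @export
read_spiral_file <- function(path,
                             schema = c(x = 1L, y = 2L, pressure = 4L,
                                        timestamp = 6L, test_id = 7L),
                             sep = ";", test_id = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!all(c("x", "y", "pressure") %in% names(schema)))
    stop("schema must map columns 'x', 'y' and 'pressure'")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)

  need <- max(schema)
  fields <- strsplit(lines, sep, fixed = TRUE)
  parsed <- lapply(fields, function(f) {
    if (length(f) < need) return(NULL)
    v <- suppressWarnings(as.numeric(f[schema]))
    if (anyNA(v)) NULL else v
  })
  bad <- which(vapply(parsed, is.null, logical(1)))
  if (length(bad) > 0L) {
    if (strict)
      stop("malformed line(s) at: ", paste(bad, collapse = ", "))
    warning(sprintf("skipped %d malformed line(s): %s", length(bad),
                    paste(head(bad, 10L), collapse = ", ")))
    parsed <- parsed[-bad]
  }
  if (length(parsed) == 0L) stop("no parseable rows in ", path)
  m <- do.call(rbind, parsed)
  colnames(m) <- names(schema)

  if (!is.null(test_id)) {
    if (!"test_id" %in% names(schema))
      stop("schema does not map a 'test_id' column")
    m <- m[m[, "test_id"] == test_id, , drop = FALSE]
    if (nrow(m) == 0L) stop("no rows with test_id ", test_id)
  }
  if (nrow(m) < 3L) stop("fewer than 3 usable samples in ", path)
  ts <- if ("timestamp" %in% colnames(m)) m[, "timestamp"] else NULL
  if (!is.null(ts) && is.unsorted(ts))
    warning("timestamps are not monotone nondecreasing")
  list(values = m[, c("x", "y", "pressure"), drop = FALSE],
       timestamp = ts, n_skipped = length(bad))
}

#' Downsample and z-score a series
#'
#' Keeps every `downsample_factor`-th sample (starting at the first), then
#' z-scores each channel to mean 0 and SD 1. Downsampling by 3 or 4 is how
#' recordings captured at unequal device rates are brought to approximately
#' equal sampling rates before analysis.
#'
#' @param x numeric vector or matrix (samples x channels).
#' @param downsample_factor keep every k-th sample (default 1 = z-score
#'   only).
#' @return Numeric matrix of standardised samples.
#' @export
standardize_series <- function(x, downsample_factor = 1L) {
  xm <- as_series_matrix(x)
  k <- as.integer(downsample_factor)
  if (k < 1L) stop("downsample_factor must be at least 1")
  xm <- xm[seq(1L, nrow(xm), by = k), , drop = FALSE]
  if (nrow(xm) < 2L) stop("downsampling left fewer than 2 samples")
  apply(xm, 2L, zscore)
}

#' Choose the downsampling factor from the source rate
#'
#' Policy for mixed-rate recordings: downsample by 4 when the source rate is
#' about 4/3 of the reference rate, otherwise by 3.
#'
#' @param source_rate recording sampling rate (Hz).
#' @param reference_rate target post-downsampling comparison rate (Hz).
#' @param rel_tol relative tolerance for "about 4/3" (default 0.1).
#' @return Integer factor, 3 or 4.
#' @export
downsample_factor_rule <- function(source_rate, reference_rate,
                                   rel_tol = 0.1) {
  if (source_rate <= 0 || reference_rate <= 0) stop("rates must be positive")
  if (abs(source_rate / reference_rate - 4 / 3) < rel_tol * 4 / 3) 4L else 3L
}

#' Photometry signal conditioning
#'
#' Removes slow bleaching artifacts by fitting and subtracting a quadratic
#' trend in time per channel, then z-scores against the mean and SD of a
#' designated baseline window.
#'
#' @param x numeric vector or matrix (samples x channels).
#' @param baseline_window integer vector of sample indices defining the
#'   baseline (default: all samples).
#' @param normalize apply the baseline z-score after detrending (default
#'   TRUE); FALSE returns the raw detrended residuals.
#' @return Matrix of detrended, baseline-normalised samples.
#' @export
detrend_photometry <- function(x, baseline_window = NULL, normalize = TRUE) {
  xm <- as_series_matrix(x, min_n = 3L)
  n <- nrow(xm)
  if (is.null(baseline_window)) baseline_window <- seq_len(n)
  bw <- as.integer(baseline_window)
  if (length(bw) == 0L || any(bw < 1L) || any(bw > n))
    stop("baseline_window must be a nonempty index range inside the record")
  tt <- seq_len(n)
  apply(xm, 2L, function(v) {
    fit <- lm(v ~ tt + I(tt^2))
    resid <- v - predict(fit)
    if (!normalize) return(resid)
    mu <- mean(resid[bw]); s <- sd(resid[bw])
    # an exactly-fitted (constant or quadratic) channel leaves numerically
    # zero residual variance
    if (!is.finite(s) || s <= 1e-8 * max(sd(v), 1)) stop("zero-variance baseline")
    (resid - mu) / s
  })
}

#' Quartile binning of a code matrix
#'
#' Bins 8-bit codes into the four fixed quartiles `[0,63]`, `[64,127]`,
#' `[128,191]`, `[192,255]` used for plotting.
#'
#' @param codes code matrix.
#' @return Integer matrix of bin indices 1..4.
#' @export
code_quartiles <- function(codes) {
  codes <- unclass(codes)
  q <- findInterval(codes, c(0L, 64L, 128L, 192L))
  matrix(as.integer(q), nrow = nrow(codes))
}

#' Render a code matrix as a quartile-coloured PNG
#'
#' One pixel per code cell (no smoothing), coloured by code quartile. The
#' bin boundaries and colours are also written to a plain-text legend file.
#'
#' @param codes code matrix from [lotra_transform()].
#' @param path output PNG path.
#' @param palette four colours for the quartiles, low to high. The defaults
#'   follow the usual reading of the plots: black/blue for the outer
#'   (shallow-curvature / directionality) quartiles, red/green for the inner
#'   high-curvature band.
#' @param legend_path legend text path (default `path` with `.legend.txt`).
#' @return Invisibly, `path`.
#' @export
render_code_quartiles <- function(codes, path,
                                  palette = c("black", "red", "green3", "blue"),
                                  legend_path = paste0(path, ".legend.txt")) {
  if (length(palette) != 4L) stop("palette must have 4 colors")
  q <- code_quartiles(codes)
  rgbm <- grDevices::col2rgb(palette) / 255
  img <- array(0, dim = c(nrow(q), ncol(q), 3L))
  for (ch in 1:3)
    img[, , ch] <- matrix(rgbm[ch, q], nrow = nrow(q))
  ok <- try(png::writePNG(img, target = path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write PNG: ", path)
  writeLines(c("code quartile -> color",
               sprintf("[%3d, %3d] -> %s", c(0L, 64L, 128L, 192L),
                       c(63L, 127L, 191L, 255L), palette)),
             legend_path)
  invisible(path)
}

#' Write / read a numeric matrix as CSV
#'
#' Full-precision round-trip serialization for series, code matrices and
#' masks.
#'
#' @param x numeric matrix (or vector).
#' @param path file path.
#' @return `write_matrix_csv` invisibly returns `path`; `read_matrix_csv`
#'   returns a numeric matrix.
#' @export
write_matrix_csv <- function(x, path) {
  m <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  unname(as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                     colClasses = "numeric")))
}

#' Sparse coordinate-list serialization of a binary mask
#'
#' Writes the nonzero cells of a binary matrix as `row,col,value` text, with
#' a header line recording the matrix dimensions.
#'
#' @param B binary matrix.
#' @param path file path.
#' @return Invisibly, `path`; `read_sparse_mask` reconstructs the dense
#'   matrix.
#' @export
write_sparse_mask <- function(B, path) {
  B <- unclass(B)
  idx <- which(B != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims,%d,%d", nrow(B), ncol(B)), con)
  writeLines("row,col,value", con)
  if (nrow(idx) > 0L)
    writeLines(sprintf("%d,%d,1", idx[, 1], idx[, 2]), con)
  invisible(path)
}

#' @rdname write_sparse_mask
#' @export
read_sparse_mask <- function(path) {
  hdr <- readLines(path, n = 1L)
  dims <- as.integer(strsplit(sub("^# dims,", "", hdr), ",")[[1]])
  tab <- utils::read.csv(path, skip = 1L)
  m <- matrix(0L, dims[1], dims[2])
  if (nrow(tab) > 0L) m[cbind(tab$row, tab$col)] <- as.integer(tab$value)
  m
}
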