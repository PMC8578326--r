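## Time-delay embedding and data-driven parameter selection.

#' Average mutual information profile
#'
#' Estimates the average mutual information (AMI) between a scalar series and
#' its lagged copy, for lags `0:max_lag`, from an equal-width two-dimensional
#' histogram. The first local minimum of this profile is the standard choice
#' of embedding delay.
#'
#' @param x numeric vector (or single-channel matrix): the time series.
#' @param max_lag largest lag to evaluate, in samples; must be `< length(x)`.
#' @param bins number of equal-width histogram bins per axis. Default
#'   `max(8, floor(n^(1/3)))`, a deterministic rule that keeps the plug-in
#'   estimator's bias (of order `(bins - 1)^2 / (2n)` nats for independent
#'   data) well below the scale of the profile's structure.
#' @param channel channel to use for multi-channel input (default first).
#' @return An object of class `"lag_profile"`: a list with `lags` (integer
#'   vector) and `score` (AMI in nats). `score[1]` is the lag-0 value, i.e.
#'   the marginal entropy estimate, and bounds all other values from above.
#' @details AMI is estimated as `H(X) + H(Y) - H(X, Y)` with plug-in entropies
#'   from the binned joint distribution of `(x_i, x_{i+k})`. Equal-width
#'   binning over the observed range makes the estimate exactly invariant to
#'   orientation-preserving affine transforms of `x`.
#' @seealso [fnn_profile()], [select_params()], [delay_embed()]
#' @examples
#' x <- sine_series()$values[, 1]
#' p <- ami_profile(x, max_lag = 40)
#' which.min(p$score[-1])  # candidate delay
#' @export
ami_profile <- function(x, max_lag, bins = NULL, channel = 1L) {
  v <- as_scalar_series(x, channel)
  n <- length(v)
  if (max_lag >= n) stop("max_lag must be smaller than the series length")
  if (max_lag < 0L) stop("max_lag must be nonnegative")
  if (sd(v) == 0) stop("zero-variance input")
  if (is.null(bins)) bins <- max(8L, floor(n^(1 / 3)))
  if (bins < 2L) stop("bins must be at least 2")

  # fixed equal-width bins over the full observed range
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)

  lags <- 0:max_lag
  score <- vapply(lags, function(k) {
    a <- idx[seq_len(n - k)]
    b <- idx[seq_len(n - k) + k]
    joint <- table(factor(a, levels = seq_len(bins)),
                   factor(b, levels = seq_len(bins)))
    p <- joint / sum(joint)
    px <- rowSums(p); py <- colSums(p)
    ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
    max(0, ent(px) + ent(py) - ent(p))
  }, numeric(1))

  structure(list(lags = lags, score = score, kind = "ami"),
            class = "lag_profile")
}

#' False nearest neighbour profile
#'
#' Fraction of false nearest neighbours (FNN) as a function of embedding
#' dimension, using the classical distance-ratio and attractor-size criteria.
#' The first dimension at which the fraction drops to (near) zero is the
#' standard choice of embedding dimension.
#'
#' @param x numeric vector (or single-channel matrix).
#' @param delay embedding delay in samples.
#' @param max_dim largest dimension to evaluate (>= 2).
#' @param r_tol distance-ratio tolerance (classical value 15).
#' @param a_tol attractor-size tolerance (classical value 2).
#' @param channel channel to use for multi-channel input.
#' @return A `"lag_profile"` with `lags` = dimensions `1:max_dim` and `score`
#'   = FNN fractions in `[0, 1]`.
#' @details For each dimension `m`, every point's nearest neighbour in the
#'   `m`-dimensional embedding is found (points that also exist in dimension
#'   `m + 1`); the neighbour is "false" if the extra coordinate jumps by more
#'   than `r_tol` times the `m`-dimensional distance, or if the lifted
#'   distance exceeds `a_tol` times the attractor size (the series standard
#'   deviation). Coincident points (zero nearest-neighbour distance) are
#'   judged by the attractor-size criterion alone.
#' @export
fnn_profile <- function(x, delay, max_dim, r_tol = 15, a_tol = 2,
                        channel = 1L) {
  v <- as_scalar_series(x, channel)
  n <- length(v)
  if (max_dim < 2L) stop("max_dim must be at least 2")
  if (delay < 1L) stop("delay must be a positive integer")
  # dimension m+1 must still embed: m*delay lags consumed at m = max_dim
  if (max_dim * delay >= n)
    stop(sprintf("series too short for max_dim %d at delay %d: need n > %d",
                 max_dim, delay, max_dim * delay))
  sigma <- sd(v)
  if (sigma == 0) stop("zero-variance input")

  fracs <- vapply(seq_len(max_dim), function(m) {
    # points that exist in both dimension m and m+1
    np <- n - m * delay
    emb <- vapply(0:(m - 1L), function(k) v[seq_len(np) + k * delay],
                  numeric(np))
    if (m == 1L) emb <- matrix(emb, ncol = 1L)
    lifted <- v[seq_len(np) + m * delay]
    if (nrow(unique(emb)) == 1L) stop("degenerate neighborhoods")
    dm <- as.matrix(dist(emb))
    diag(dm) <- Inf
    nn <- max.col(-dm, ties.method = "first")
    dnn <- dm[cbind(seq_len(np), nn)]
    extra <- abs(lifted - lifted[nn])
    dlift <- sqrt(dnn^2 + extra^2)
    false_r <- ifelse(dnn > 0, extra / dnn > r_tol, FALSE)
    false_a <- dlift / sigma > a_tol
    mean(false_r | false_a)
  }, numeric(1))

  structure(list(lags = seq_len(max_dim), score = fracs, kind = "fnn"),
            class = "lag_profile")
}

#' @export
print.lag_profile <- function(x, ...) {
  lab <- if (identical(x$kind, "fnn")) "FNN fraction by dimension"
         else "Average mutual information (nats) by lag"
  cat(lab, "\n")
  print(data.frame(lag = x$lags, score = signif(x$score, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Select embedding parameters from AMI and FNN profiles
#'
#' Applies the first-local-minimum / level-off rule to an AMI profile to pick
#' the delay, and the floor / level-off rule to an FNN profile to pick the
#' dimension.
#'
#' @param ami `"lag_profile"` from [ami_profile()].
#' @param fnn `"lag_profile"` from [fnn_profile()].
#' @param level_off_frac relative-change threshold declaring a profile
#'   "levelled off" (default 0.05).
#' @param fnn_floor FNN fraction regarded as negligible (default 0.05).
#' @return A list of class `"embedding_params"` with `delay`, `dimension`,
#'   and `rule` (which criterion fired for each).
#' @details Delay: the first strict local minimum of the AMI scores; if none,
#'   the first lag at which the relative drop from the previous lag falls
#'   below `level_off_frac`. Dimension: the first dimension whose FNN
#'   fraction is below `fnn_floor`; if none, the first level-off. An error is
#'   raised when neither rule fires within the profiled range.
#' @export
select_params <- function(ami, fnn, level_off_frac = 0.05,
                          fnn_floor = 0.05) {
  stopifnot(inherits(ami, "lag_profile"), inherits(fnn, "lag_profile"))
  if (length(ami$lags) == 0 || length(fnn$lags) == 0)
    stop("empty profile")

  first_local_min <- function(s) {
    k <- length(s)
    if (k < 3L) return(NA_integer_)
    for (i in 2:(k - 1L))
      if (s[i] < s[i - 1L] && s[i] < s[i + 1L]) return(i)
    NA_integer_
  }
  first_level_off <- function(s, frac) {
    k <- length(s)
    if (k < 2L) return(NA_integer_)
    for (i in 2:k) {
      denom <- abs(s[i - 1L])
      rel <- if (denom > 0) abs(s[i] - s[i - 1L]) / denom else 0
      if (rel < frac) return(i)
    }
    NA_integer_
  }

  i <- first_local_min(ami$score)
  delay_rule <- "first_local_minimum"
  if (is.na(i)) {
    i <- first_level_off(ami$score, level_off_frac)
    delay_rule <- "level_off"
  }
  if (is.na(i)) stop("no embedding parameter found: AMI has no local minimum or level-off")
  delay <- ami$lags[i]

  j <- which(fnn$score < fnn_floor)[1]
  dim_rule <- "below_floor"
  if (is.na(j)) {
    j <- first_level_off(fnn$score, level_off_frac)
    dim_rule <- "level_off"
  }
  if (is.na(j)) stop("no embedding parameter found: FNN has no floor crossing or level-off")
  dimension <- fnn$lags[j]

  structure(list(delay = as.integer(delay), dimension = as.integer(dimension),
                 rule = c(delay = delay_rule, dimension = dim_rule)),
            class = "embedding_params")
}

#' @export
print.embedding_params <- function(x, ...) {
  cat(sprintf("embedding delay t = %d (%s), dimension m = %d (%s)\n",
              x$delay, x$rule[["delay"]], x$dimension, x$rule[["dimension"]]))
  invisible(x)
}

#' Time-delay embedding
#'
#' Reconstructs a phase-space trajectory from a scalar (or multi-channel)
#' series: row `i` of the result is `(x_i, x_{i+t}, ..., x_{i+(m-1)t})`,
#' per channel.
#'
#' @param x numeric vector, matrix or data frame (n samples x d channels).
#' @param delay embedding delay `t` in samples (positive integer).
#' @param dimension embedding dimension `m` (integer >= 1). With `m = 1` the
#'   input is returned unchanged — the natural setting for data that are
#'   already multi-dimensional (e.g. x/y/pressure tablet traces).
#' @return Numeric matrix with `n - (m-1)*t` rows and `m*d` columns; the `m`
#'   delayed copies of each channel are contiguous columns.
#' @examples
#' delay_embed(1:10, delay = 2, dimension = 3)[1, ]  # (x1, x3, x5)
#' @export
delay_embed <- function(x, delay, dimension) {
  xm <- as_series_matrix(x)
  n <- nrow(xm); d <- ncol(xm)
  m <- as.integer(dimension); t <- as.integer(delay)
  if (m < 1L) stop("dimension must be at least 1")
  if (m > 1L && t < 1L) stop("delay must be a positive integer")
  if ((m - 1L) * t >= n)
    stop(sprintf("series too short to embed: need n > (m-1)*t = %d, got n = %d",
                 (m - 1L) * t, n))
  if (m == 1L) return(xm)
  np <- n - (m - 1L) * t
  out <- matrix(0, nrow = np, ncol = m * d)
  for (ch in seq_len(d))
    for (k in 0:(m - 1L))
      out[, (ch - 1L) * m + k + 1L] <- xm[seq_len(np) + k * t, ch]
  out
}
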