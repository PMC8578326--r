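# Independent brute-force oracles: per-cell loops written directly from the
# definitions, deliberately kept separate from the package's vectorised code
# paths.

naive_distance_matrix <- function(traj) {
  n <- nrow(traj)
  out <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      out[i, j] <- sqrt(sum((traj[i, ] - traj[j, ])^2))
  out
}

# neighbour order (i-1,j-1), (i-1,j), (i-1,j+1), (i,j+1), (i+1,j+1),
# (i+1,j), (i+1,j-1), (i,j-1) with weights 2^0..2^7, ties set the bit
naive_lbp_transform <- function(D) {
  n <- nrow(D)
  out <- matrix(NA_integer_, n - 2L, n - 2L)
  w <- as.integer(2^(0:7))
  for (i in 2:(n - 1L)) {
    for (j in 2:(n - 1L)) {
      g0 <- D[i, j]
      nb <- c(D[i - 1, j - 1], D[i - 1, j], D[i - 1, j + 1], D[i, j + 1],
              D[i + 1, j + 1], D[i + 1, j], D[i + 1, j - 1], D[i, j - 1])
      out[i - 1L, j - 1L] <- sum(w[nb >= g0])
    }
  }
  out
}

naive_recurrence_rate <- function(B) {
  n_ones <- 0L
  for (i in seq_len(nrow(B)))
    for (j in seq_len(ncol(B)))
      if (B[i, j] != 0) n_ones <- n_ones + 1L
  n_ones / (nrow(B) * ncol(B))
}

# maximal runs of 1s along one vector, by explicit scan
naive_runs <- function(v) {
  out <- integer(0)
  run <- 0L
  for (x in c(v, 0)) {
    if (x != 0) run <- run + 1L
    else { if (run > 0L) out <- c(out, run); run <- 0L }
  }
  out
}

naive_diag_runs <- function(B, include_loi = FALSE) {
  n <- nrow(B)
  offsets <- setdiff(-(n - 1L):(n - 1L), if (include_loi) NULL else 0L)
  unlist(lapply(offsets, function(k) {
    i <- if (k >= 0) 1:(n - k) else (1 - k):n
    j <- i + k
    naive_runs(B[cbind(i, j)])
  }))
}

naive_vert_runs <- function(B) {
  unlist(lapply(seq_len(ncol(B)), function(j) naive_runs(B[, j])))
}

naive_rqa <- function(B, l_min = 2L, v_min = 2L, include_loi = FALSE) {
  dr <- naive_diag_runs(B, include_loi)
  vr <- naive_vert_runs(B)
  dq <- dr[dr >= l_min]; vq <- vr[vr >= v_min]
  ent <- function(q) {
    if (length(q) == 0L) return(0)
    p <- table(q) / length(q)
    -sum(p * log(p))
  }
  c(rr = naive_recurrence_rate(B),
    det = if (sum(dr) > 0 && length(dq)) sum(dq) / sum(dr) else 0,
    mean_diag_l = if (length(dq)) mean(dq) else 0,
    max_diag_l = if (length(dq)) max(dq) else 0,
    div = if (length(dq)) 1 / max(dq) else 0,
    ent = ent(dq),
    lam = if (sum(vr) > 0 && length(vq)) sum(vq) / sum(vr) else 0,
    tt = if (length(vq)) mean(vq) else 0,
    max_vert_l = if (length(vq)) max(vq) else 0)
}

random_symmetric_distlike <- function(n) {
  m <- matrix(abs(rnorm(n * n)), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

random_binary_matrix <- function(n, p = 0.3) {
  matrix(rbinom(n * n, 1L, p), n, n)
}
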