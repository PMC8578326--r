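test_that("delay_embed reproduces the lagged-copy construction", {
  # n=10, m=3, t=2: row 1 is (x1, x3, x5), 6 rows
  emb <- delay_embed(1:10, delay = 2, dimension = 3)
  expect_equal(dim(emb), c(6L, 3L))
  expect_equal(emb[1, ], c(1, 3, 5))
  expect_equal(emb[6, ], c(6, 8, 10))

  # the sine setup: 300 points, m=2, t=15 -> 285 x 2
  s <- sine_series()
  expect_equal(dim(delay_embed(s$values, delay = 15, dimension = 2)),
               c(285L, 2L))

  # m = 1 is the identity, for scalar and multi-channel input alike
  x <- matrix(rnorm(30), ncol = 3)
  expect_identical(delay_embed(x, delay = 7, dimension = 1), x)

  expect_error(delay_embed(1:10, delay = 5, dimension = 3), "too short")
})

test_that("delay_embed row count and projection invariants hold over random cases", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(10:80, 1)
    m <- sample(1:4, 1)
    t <- if (m > 1) sample(seq_len((n - 1) %/% (m - 1) - 1), 1) else 1L
    x <- rnorm(n)
    emb <- delay_embed(x, delay = t, dimension = m)
    expect_equal(nrow(emb), n - (m - 1) * t)
    if (m == 2) expect_equal(emb[, 1], x[1:(n - t)])
  }
})

test_that("AMI profile has the self-information bound and detects periodicity", {
  # exact period P in samples (bit-identical tiling): the lag-P copy is the
  # signal itself, and whole periods remain after dropping the last P samples
  P <- 25L
  x <- rep(sin(2 * pi * (0:(P - 1)) / P), 12)
  p <- ami_profile(x, max_lag = 60)
  expect_equal(p$score[p$lags == P], p$score[1])
  expect_true(all(p$score[1] >= p$score - 1e-12))
  expect_true(all(p$score >= 0))

  expect_error(ami_profile(rep(1, 50), max_lag = 5), "zero-variance")
})

test_that("AMI of iid noise is near zero and AMI is affine invariant", {
  set.seed(21)
  u <- runif(10000)
  p <- ami_profile(u, max_lag = 5)
  # independence: true MI is 0; histogram bias at n=1e4, 100 bins stays small
  expect_lt(max(p$score[-1]), 0.05)

  x <- rnorm(400)
  p1 <- ami_profile(x, max_lag = 10, bins = 16)
  p2 <- ami_profile(3.7 * x + 11, max_lag = 10, bins = 16)
  expect_lt(max(abs(p1$score - p2$score)), 1e-9)
})

test_that("FNN collapses for a plane-unfoldable oscillation but not for noise", {
  s <- sine_series()
  fnn <- fnn_profile(s$values, delay = 15, max_dim = 4)
  expect_true(all(fnn$score >= 0 & fnn$score <= 1))
  expect_lt(fnn$score[2], 0.05)  # a 1-D oscillation unfolds in the plane

  set.seed(5)
  w <- rnorm(400)
  fw <- fnn_profile(w, delay = 1, max_dim = 3)
  expect_gt(fw$score[1], 0.2)  # white noise keeps false neighbours at m=1

  expect_error(fnn_profile(rnorm(20), delay = 8, max_dim = 3), "too short")
  # non-constant series whose embedded points are all coincident
  flat <- c(rep(0, 90), seq(0.1, 1, by = 0.1))
  expect_error(fnn_profile(flat, delay = 10, max_dim = 2),
               "degenerate neighborhoods")
})

test_that("select_params applies first-local-minimum, level-off and floor rules", {
  prof <- function(lags, score, kind) {
    structure(list(lags = lags, score = score, kind = kind),
              class = "lag_profile")
  }
  fnn <- prof(1:4, c(1.0, 0.6, 0.01, 0.0), "fnn")

  # first strict local minimum of AMI at lag 2
  ami <- prof(0:4, c(2.0, 1.0, 0.5, 0.7, 0.6), "ami")
  p <- select_params(ami, fnn)
  expect_equal(p$delay, 2L)
  expect_equal(p$rule[["delay"]], "first_local_minimum")

  # monotone AMI: level-off at lag 2 (relative change 0.05/1.5 = 0.033 < 0.05)
  ami2 <- prof(0:3, c(2.0, 1.5, 1.45, 1.44), "ami")
  p2 <- select_params(ami2, fnn, level_off_frac = 0.05)
  expect_equal(p2$delay, 2L)
  expect_equal(p2$rule[["delay"]], "level_off")

  # FNN floor: first dimension below 0.05 is m = 3
  expect_equal(p$dimension, 3L)
  expect_equal(p$rule[["dimension"]], "below_floor")

  # nothing fires -> error
  ami3 <- prof(0:2, c(2.0, 1.0, 0.5), "ami")
  fnn3 <- prof(1:3, c(1.0, 0.9, 0.8), "fnn")
  expect_error(select_params(ami3, fnn3, level_off_frac = 0.01,
                             fnn_floor = 0.05),
               "no embedding parameter found")
})
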