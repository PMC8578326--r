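## Simulators: idealised periodic signal, Lorenz attractor, and a synthetic
## labelled spiral-drawing cohort.

#' Sine-wave test signal
#'
#' `sin(u)` sampled on the grid `u = start, start + step, ..., stop`
#' (inclusive up to half-step floating tolerance). The defaults give the
#' standard 300-point test signal (0.1 to 30, step 0.1) whose 2-D delay
#' embeddings at t = 15, 20 and 3 (see [sine_delay_presets()]) trace loops
#' of increasing eccentricity.
#'
#' @param start,stop,step grid parameters; `step > 0`, `stop >= start`.
#' @return List with `values` (n x 1 matrix), `grid` (the sample points `u`),
#'   and the grid parameters.
#' @examples
#' nrow(sine_series()$values)  # 300
#' @export
sine_series <- function(start = 0.1, stop = 30, step = 0.1) {
  if (step <= 0) stop("step must be positive")
  if (stop < start) stop("stop must be at least start")
  n <- floor((stop - start) / step + 1e-9) + 1L
  u <- start + step * (0:(n - 1L))
  u <- u[u <= stop + step / 2]
  list(values = matrix(sin(u), ncol = 1L), grid = u,
       start = start, stop = stop, step = step)
}

#' Embedding-delay presets for the sine test signal
#'
#' The three 2-D embedding delays used to produce sine-wave phase-space
#' trajectories of increasing eccentricity: t = 15 (quarter period: a
#' near-circular loop), t = 20, and t = 3 (a highly eccentric ellipse).
#'
#' @return Named integer vector of delays, all at dimension m = 2.
#' @export
sine_delay_presets <- function() {
  c(circular = 15L, intermediate = 20L, eccentric = 3L)
}

#' Lorenz attractor trajectory
#'
#' Integrates the Lorenz system
#' `dx = sigma (y - x); dy = x (r - z) - y; dz = x y - beta z`
#' with fixed-step 4th-order Runge-Kutta at step `dt`. Deterministic: the
#' same parameters always give bit-identical output.
#'
#' @param r,sigma,beta system parameters. Defaults r = 28, sigma = 15,
#'   beta = 8/3 — note sigma = 15, a strongly chaotic variant of the
#'   classical sigma = 10.
#' @param dt integrator time step (default 0.025).
#' @param n_steps number of integration steps (default 4000).
#' @param init initial state `(x, y, z)` (default `c(1, 1, 1)`).
#' @param burn_in initial rows to discard (transient; default 0).
#' @return List with `values` (`(n_steps + 1 - burn_in) x 3` matrix of
#'   states, including the initial state when `burn_in = 0`), `time`, and
#'   the parameters.
#' @export
lorenz_series <- function(r = 28, sigma = 15, beta = 8 / 3, dt = 0.025,
                          n_steps = 4000L, init = c(1, 1, 1), burn_in = 0L) {
  if (dt <= 0) stop("dt must be positive")
  if (n_steps < 1L) stop("n_steps must be at least 1")
  if (length(init) != 3L || !all(is.finite(init)))
    stop("init must be a finite 3-vector")
  if (burn_in < 0L || burn_in > n_steps) stop("invalid burn_in")
  deriv <- function(t, y, parms) {
    list(c(parms$sigma * (y[2] - y[1]),
           y[1] * (parms$r - y[3]) - y[2],
           y[1] * y[2] - parms$beta * y[3]))
  }
  times <- dt * (0:n_steps)
  sol <- deSolve::rk4(y = c(x = init[1], y = init[2], z = init[3]),
                      times = times, func = deriv,
                      parms = list(r = r, sigma = sigma, beta = beta))
  vals <- unname(as.matrix(sol[, 2:4]))
  if (!all(is.finite(vals))) {
    bad <- which(!apply(is.finite(vals), 1L, all))[1]
    stop(sprintf("integration blew up to non-finite values at step %d", bad - 1L))
  }
  keep <- (burn_in + 1L):(n_steps + 1L)
  list(values = vals[keep, , drop = FALSE], time = times[keep],
       r = r, sigma = sigma, beta = beta, dt = dt,
       n_steps = n_steps, init = init, burn_in = burn_in)
}

#' Lorenz vector field
#'
#' The instantaneous derivative of the Lorenz system at a state — useful for
#' checking fixed points, e.g. `(sqrt(beta (r-1)), sqrt(beta (r-1)), r-1)`.
#'
#' @param state numeric 3-vector `(x, y, z)`.
#' @param r,sigma,beta system parameters.
#' @return Numeric 3-vector of derivatives.
#' @export
lorenz_field <- function(state, r = 28, sigma = 15, beta = 8 / 3) {
  c(sigma * (state[2] - state[1]),
    state[1] * (r - state[3]) - state[2],
    state[1] * state[2] - beta * state[3])
}

#' Synthetic labelled spiral-drawing cohort
#'
#' Generates a two-class cohort of 3-channel (x, y, pressure) traces
#' emulating digitised Archimedean-spiral drawing: the control class traces
#' a smooth spiral `radius = a * theta` with small Gaussian jitter and a
#' smooth pressure profile; the disease class overlays a tremor oscillation
#' on x and y plus intermittent pressure drops. Entirely synthetic — a
#' stand-in with known ground truth for tablet recordings of real subjects,
#' for end-to-end pipeline testing.
#'
#' @param n_per_class subjects per class (>= 2; default 20).
#' @param length samples per trace (default 300).
#' @param sample_rate nominal sampling rate in Hz (default 50) — fixes the
#'   physical duration and hence how many tremor cycles fit in a trace.
#' @param tremor_amplitude tremor displacement amplitude as a fraction of
#'   the outer spiral radius (default 0.08, i.e. a conspicuous 8% tremor;
#'   0 gives two identical generative classes).
#' @param tremor_freq tremor frequency in Hz (default 5, in the 4--6 Hz
#'   parkinsonian resting/action tremor band).
#' @param jitter_sd motor-noise SD for all subjects, as a fraction of the
#'   outer radius (default 0.01).
#' @param turns number of spiral turns drawn (default 4).
#' @param seed RNG seed; the cohort is a deterministic function of the seed.
#' @return List of class `"spiral_cohort"` with `series` (list of
#'   `length x 3` matrices, channels x/y/pressure), `labels` (integer 0 =
#'   control, 1 = disease), `subject_ids`, and the generator parameters.
#' @export
synthetic_cohort <- function(n_per_class = 20L, length = 300L,
                             sample_rate = 50, tremor_amplitude = 0.08,
                             tremor_freq = 5, jitter_sd = 0.01,
                             turns = 4, seed = 1L) {
  if (n_per_class < 2L) stop("need at least 2 subjects per class")
  if (tremor_amplitude < 0 || jitter_sd < 0) stop("amplitudes must be >= 0")
  if (length < 10L) stop("traces must have at least 10 samples")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  n <- as.integer(length)
  tt <- (0:(n - 1L)) / sample_rate
  theta <- seq(0, turns * 2 * pi, length.out = n)
  r_outer <- 1  # arbitrary device units; classifier z-scores per channel

  draw_subject <- function(diseased) {
    # subject-level variation in drawing speed/size
    a <- r_outer / max(theta) * exp(rnorm(1, 0, 0.05))
    phase <- runif(1, 0, 2 * pi)
    radius <- a * theta
    x <- radius * cos(theta + phase)
    y <- radius * sin(theta + phase)
    pressure <- 0.6 + 0.3 * sin(pi * seq(0, 1, length.out = n)) +
      rnorm(n, 0, 0.02)
    if (diseased && tremor_amplitude > 0) {
      amp <- tremor_amplitude * r_outer * exp(rnorm(1, 0, 0.15))
      f <- tremor_freq * exp(rnorm(1, 0, 0.05))
      ph <- runif(2, 0, 2 * pi)
      x <- x + amp * sin(2 * pi * f * tt + ph[1])
      y <- y + amp * sin(2 * pi * f * tt + ph[2])
      # intermittent pressure drops: a few short dips per trace
      n_dips <- 2L + stats::rpois(1, 2)
      for (d in seq_len(n_dips)) {
        at <- sample.int(n - 10L, 1L)
        w <- sample(5:10, 1L)
        pressure[at:(at + w - 1L)] <-
          pressure[at:(at + w - 1L)] * runif(1, 0.3, 0.7)
      }
    }
    x <- x + rnorm(n, 0, jitter_sd * r_outer)
    y <- y + rnorm(n, 0, jitter_sd * r_outer)
    cbind(x = x, y = y, pressure = pressure)
  }

  labels <- rep(c(0L, 1L), each = n_per_class)
  series <- lapply(labels, function(lb) draw_subject(lb == 1L))
  structure(list(series = series, labels = labels,
                 subject_ids = sprintf("S%02d", seq_along(labels)),
                 n_per_class = as.integer(n_per_class), length = n,
                 sample_rate = sample_rate,
                 tremor_amplitude = tremor_amplitude,
                 tremor_freq = tremor_freq, jitter_sd = jitter_sd,
                 turns = turns, seed = seed),
            class = "spiral_cohort")
}

#' @export
print.spiral_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic spiral cohort: %d + %d subjects, %d samples",
                     " each, tremor amplitude %.3g (seed %d)\n"),
              sum(x$labels == 0L), sum(x$labels == 1L), x$length,
              x$tremor_amplitude, x$seed))
  invisible(x)
}
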