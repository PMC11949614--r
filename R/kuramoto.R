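#' Draw natural frequencies in the BOLD band
#'
#' Natural angular frequencies are drawn i.i.d. uniform on
#' \[`lo`, `hi`\] Hz (defaults 0.01–0.1 Hz, the BOLD frequency range) and
#' returned in rad/s (multiplied by 2*pi).
#'
#' @param n Number of oscillators.
#' @param seed Integer seed.
#' @param lo,hi Frequency band bounds in Hz.
#' @return Numeric vector of length `n`, rad/s.
#' @export
draw_frequencies <- function(n, seed, lo = 0.01, hi = 0.1) {
  if (n < 1) stop("`n` must be >= 1")
  set.seed(as.integer(seed))
  2 * pi * stats::runif(n, lo, hi)
}

#' Draw uniform initial phases
#'
#' @param n Number of oscillators.
#' @param seed Integer seed.
#' @return Phases in rad, uniform on \[0, 2*pi).
#' @export
draw_phases <- function(n, seed) {
  if (n < 1) stop("`n` must be >= 1")
  set.seed(as.integer(seed))
  stats::runif(n, 0, 2 * pi)
}

#' Oscillator simulation configuration
#'
#' Bundles the per-node natural frequencies, initial phases, global coupling
#' strength and integration settings for one Kuramoto run. With the default
#' protocol a run lasts `duration_s` = 600 s (ten minutes) and the first
#' `transient_s` = 120 s are discarded to avoid transient effects.
#'
#' @param omega Per-node natural angular frequency, rad/s.
#' @param theta0 Per-node initial phase, rad; if `NULL`, drawn uniform on
#'   \[0, 2*pi) from `seed`.
#' @param g Global coupling strength (dimensionless).
#' @param duration_s Total simulated seconds.
#' @param transient_s Initial seconds discarded from all statistics.
#' @param dt_s Integrator step (fixed-step RK4).
#' @param sample_dt_s Output sampling interval.
#' @param seed Integer seed (used only when `theta0` is `NULL`).
#' @return An object of class `oscillator_config`.
#' @export
oscillator_config <- function(omega, theta0 = NULL, g = 1,
                              duration_s = 600, transient_s = 120,
                              dt_s = 0.05, sample_dt_s = 0.5, seed = NULL) {
  if (duration_s <= transient_s || transient_s < 0)
    stop("need duration_s > transient_s >= 0")
  if (dt_s <= 0) stop("`dt_s` must be positive")
  if (is.null(theta0)) {
    if (is.null(seed)) stop("supply `theta0` or `seed`")
    theta0 <- draw_phases(length(omega), seed)
  }
  if (length(theta0) != length(omega))
    stop("`theta0` and `omega` lengths differ")
  structure(list(omega = omega, theta0 = theta0, g = g,
                 duration_s = duration_s, transient_s = transient_s,
                 dt_s = dt_s, sample_dt_s = sample_dt_s, seed = seed),
            class = "oscillator_config")
}

#' Kuramoto order parameter
#'
#' `R(t) = | mean_b exp(i * theta_b(t)) |`, the magnitude of the mean unit
#' phasor over oscillators: 1 at full synchrony, 0 at incoherence.
#'
#' @param theta Numeric matrix (time by node) or a single phase vector.
#' @return Numeric vector of `R(t)` values in \[0, 1\].
#' @export
order_parameter <- function(theta) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  Mod(rowMeans(exp(1i * theta)))
}

#' Simulate Kuramoto dynamics on a structural connectome
#'
#' Integrates `dtheta_a/dt = omega_a + g * sum_b A_ba sin(theta_b - theta_a)`
#' with fixed-step RK4, where `A_ba` (row = source, column = target) couples
#' oscillator `b` into oscillator `a`. Phases are sampled every
#' `sample_dt_s` after the transient; synchrony and metastability are the
#' mean and standard deviation of the order parameter over the retained
#' samples.
#'
#' @param sc A [structural_connectome()].
#' @param cfg An [oscillator_config()] with `length(omega)` equal to the
#'   network size.
#' @return An object of class `kuramoto_run` with elements `theta`
#'   (time-by-node phase matrix), `times`, `order_param`, `synchrony`,
#'   `metastability`, `regions`, and `config`.
#' @export
simulate_kuramoto <- function(sc, cfg) {
  stopifnot(inherits(sc, "structural_connectome"),
            inherits(cfg, "oscillator_config"))
  n <- length(sc$regions)
  if (length(cfg$omega) != n)
    stop("`omega` length must equal network size")
  if (any(!is.finite(sc$weights))) stop("non-finite connectome weights")
  res <- kuramoto_rk4_cpp(sc$weights, cfg$omega, cfg$theta0, cfg$g,
                          cfg$dt_s, cfg$duration_s, cfg$transient_s,
                          cfg$sample_dt_s)
  if (res$max_rate * cfg$dt_s > 0.5)
    warning(sprintf(
      "dt_s may be too large: max |dtheta/dt| * dt = %.3f rad exceeds 0.5",
      res$max_rate * cfg$dt_s))
  R <- order_parameter(res$theta)
  structure(list(theta = res$theta, times = as.numeric(res$times),
                 order_param = R,
                 synchrony = mean(R), metastability = stats::sd(R),
                 regions = sc$regions, config = cfg),
            class = "kuramoto_run")
}

#' @export
print.kuramoto_run <- function(x, ...) {
  cat(sprintf(
    "kuramoto_run: %d nodes, %d samples | synchrony %.3f, metastability %.4f\n",
    ncol(x$theta), nrow(x$theta), x$synchrony, x$metastability))
  invisible(x)
}

#' Simulated functional connectivity from a Kuramoto run
#'
#' Neural activity fluctuations are represented as `sin(theta)` and FC is
#' the pairwise Pearson correlation of `sin(theta)` across nodes over the
#' post-transient samples. Nodes with numerically constant signal get zero
#' correlations (with a warning).
#'
#' @param run A `kuramoto_run`.
#' @param regions Optional region labels (defaults to the run's regions).
#' @return An [fc_network()] with `source = "simulated"`.
#' @export
simulated_fc <- function(run, regions = NULL) {
  stopifnot(inherits(run, "kuramoto_run"))
  if (nrow(run$theta) < 3) stop("need at least 3 post-transient samples")
  if (is.null(regions)) regions <- run$regions
  x <- sin(run$theta)
  sds <- apply(x, 2, stats::sd)
  const <- sds < .Machine$double.eps^0.5
  fc <- suppressWarnings(stats::cor(x))
  if (any(const)) {
    warning(sum(const), " node(s) with constant signal; correlations set to 0")
    fc[const, ] <- 0
    fc[, const] <- 0
  }
  fc[!is.finite(fc)] <- 0
  diag(fc) <- 1
  fc_network(fc, regions, source = "simulated")
}

#' Sweep the global coupling strength
#'
#' Runs seeded simulations across a grid of coupling strengths, sharing the
#' same `n_seeds` frequency/initial-phase draws across all grid points, and
#' averages synchrony and metastability per `g`. The grid point maximizing
#' mean metastability is reported — the coupling at which the network
#' dynamics are most flexible.
#'
#' @param sc A [structural_connectome()].
#' @param g_grid Numeric vector of coupling strengths.
#' @param n_seeds Number of seeded (omega, theta0) draws per grid point.
#' @param base_seed Integer; run `k` uses seeds derived from `base_seed + k`.
#' @param duration_s,transient_s,dt_s,sample_dt_s Passed to
#'   [oscillator_config()].
#' @return A data.frame with columns `g`, `synchrony`, `metastability`, and
#'   attribute `g_max_metastability`.
#' @export
coupling_sweep <- function(sc, g_grid, n_seeds = 25, base_seed = 1,
                           duration_s = 600, transient_s = 120,
                           dt_s = 0.05, sample_dt_s = 0.5) {
  if (!length(g_grid)) stop("`g_grid` must be nonempty")
  if (n_seeds < 1) stop("`n_seeds` must be >= 1")
  n <- length(sc$regions)
  draws <- lapply(seq_len(n_seeds), function(k) {
    list(omega = draw_frequencies(n, base_seed + 2L * k),
         theta0 = draw_phases(n, base_seed + 2L * k + 1L))
  })
  syn <- met <- matrix(NA_real_, length(g_grid), n_seeds)
  for (gi in seq_along(g_grid)) {
    for (k in seq_len(n_seeds)) {
      cfg <- oscillator_config(draws[[k]]$omega, draws[[k]]$theta0,
                               g = g_grid[gi], duration_s = duration_s,
                               transient_s = transient_s, dt_s = dt_s,
                               sample_dt_s = sample_dt_s)
      run <- simulate_kuramoto(sc, cfg)
      syn[gi, k] <- run$synchrony
      met[gi, k] <- run$metastability
    }
  }
  out <- data.frame(g = g_grid,
                    synchrony = rowMeans(syn),
                    metastability = rowMeans(met))
  attr(out, "g_max_metastability") <- g_grid[which.max(out$metastability)]
  out
}
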