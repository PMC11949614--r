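#' Synthetic-data generator configuration
#'
#' Parameters of the synthetic study conditions: a bilaterally symmetric,
#' heavy-tailed, directionally biased connectome; per-subject target FC
#' networks with controllable mean edge strength, edge-strength spread and
#' region dropout; and BOLD-like series realizing a given FC. Defaults are
#' chosen to emulate tract-tracing connectomes and anesthetized-mouse FC
#' at desk scale: log-normal weights, ~35% directed edge density, a strong
#' directional bias, mean FC edge strength 0.25 with spread 0.12, and
#' dropout leaving roughly 65–82% of regions per subject.
#'
#' @param regions_per_hemisphere Regions per hemisphere (network size is
#'   twice this).
#' @param density Fraction of nonzero directed off-diagonal edges.
#' @param weight_meanlog,weight_sdlog Log-normal weight parameters.
#' @param direction_bias Probability that a connected pair has a single
#'   dominant direction (reciprocal otherwise), in \[0, 1\].
#' @param homotopic_prob Probability that a region connects to its
#'   contralateral homologue.
#' @param contra_scale Multiplier on contralateral weights relative to
#'   ipsilateral ones.
#' @param fc_mean Target mean FC edge strength for noisy targets.
#' @param fc_sd Target FC edge-strength standard deviation.
#' @param fc_noise Standard deviation of the edgewise jitter applied to
#'   noisy FC targets before projection to the nearest correlation matrix.
#' @param dropout_range Integer (min, max) count of surviving regions per
#'   subject.
#' @param n_subjects Number of synthetic subjects.
#' @param seed Master seed for the generator.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(regions_per_hemisphere = 30, density = 0.35,
                         weight_meanlog = 0, weight_sdlog = 1,
                         direction_bias = 0.8, homotopic_prob = 0.9,
                         contra_scale = 0.5, fc_mean = 0.25, fc_sd = 0.12,
                         fc_noise = 0.02,
                         dropout_range = round(c(0.65, 0.82) *
                                                 2 * regions_per_hemisphere),
                         n_subjects = 6, seed = 1) {
  if (density <= 0 || density > 1) stop("`density` must lie in (0, 1]")
  n <- 2 * regions_per_hemisphere
  if (any(dropout_range > n) || dropout_range[1] > dropout_range[2])
    stop("`dropout_range` must be an increasing pair bounded by the network size")
  if (direction_bias < 0 || direction_bias > 1)
    stop("`direction_bias` must lie in [0, 1]")
  structure(list(regions_per_hemisphere = regions_per_hemisphere,
                 density = density, weight_meanlog = weight_meanlog,
                 weight_sdlog = weight_sdlog,
                 direction_bias = direction_bias,
                 homotopic_prob = homotopic_prob,
                 contra_scale = contra_scale, fc_mean = fc_mean,
                 fc_sd = fc_sd, fc_noise = fc_noise,
                 dropout_range = dropout_range, n_subjects = n_subjects,
                 seed = seed),
            class = "synth_config")
}

# One hemisphere block: for each region pair, connect with probability
# p2 = 2 * density / (2 - bias); a connected pair is unidirectional with
# probability `bias` (one log-normal weight), reciprocal otherwise (two
# independent log-normal weights). This makes the expected directed edge
# density equal `density`.
synth_block <- function(h, density, bias, meanlog, sdlog) {
  p2 <- 2 * density / (2 - bias)
  if (p2 > 1) stop("`density` unattainable at this `direction_bias`")
  W <- matrix(0, h, h)
  pairs <- which(upper.tri(W), arr.ind = TRUE)
  conn <- stats::runif(nrow(pairs)) < p2
  for (k in which(conn)) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (stats::runif(1) < bias) {
      if (stats::runif(1) < 0.5) {
        W[i, j] <- stats::rlnorm(1, meanlog, sdlog)
      } else {
        W[j, i] <- stats::rlnorm(1, meanlog, sdlog)
      }
    } else {
      W[i, j] <- stats::rlnorm(1, meanlog, sdlog)
      W[j, i] <- stats::rlnorm(1, meanlog, sdlog)
    }
  }
  W
}

#' Generate a synthetic bilateral connectome
#'
#' Draws an ipsilateral and a contralateral hemisphere block with
#' log-normal weights at the configured density and direction bias, adds
#' homotopic (region-to-contralateral-homologue) connections, then mirrors
#' bilaterally and normalizes the result. The first region labels reuse
#' the default injury acronyms so the packaged injury specification
#' resolves on synthetic networks.
#'
#' @param cfg A [synth_config()].
#' @return A normalized, directed, bilaterally mirrored
#'   [structural_connectome()] on `2 * regions_per_hemisphere` nodes.
#' @export
synth_connectome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(as.integer(cfg$seed))
  h <- cfg$regions_per_hemisphere
  acr <- default_injury_regions()
  labels <- c(acr, sprintf("R%02d", seq_len(max(0, h - length(acr)))))[seq_len(h)]
  ipsi <- synth_block(h, cfg$density, cfg$direction_bias,
                      cfg$weight_meanlog, cfg$weight_sdlog)
  contra <- cfg$contra_scale *
    synth_block(h, cfg$density, cfg$direction_bias,
                cfg$weight_meanlog, cfg$weight_sdlog)
  homotopic <- stats::runif(h) < cfg$homotopic_prob
  diag(contra)[homotopic] <- cfg$contra_scale *
    stats::rlnorm(sum(homotopic), cfg$weight_meanlog, cfg$weight_sdlog)
  normalize_connectome(mirror_bilateral(ipsi, contra, labels))
}

#' Generate a synthetic target FC network
#'
#' Two modes. `"self_consistent"` draws known natural frequencies, runs the
#' Kuramoto model on a region-dropout reduction of `sc`, and returns the
#' simulated FC together with the ground-truth frequencies — the input for
#' parameter-recovery experiments. `"noisy"` builds a valid correlation
#' matrix from a two-factor construction steered toward the configured
#' mean and spread of edge strengths, jitters it, and projects to the
#' nearest correlation matrix. Both modes sample the number of surviving
#' regions uniformly within `dropout_range`.
#'
#' @param sc A [structural_connectome()].
#' @param mode `"self_consistent"` or `"noisy"`.
#' @param cfg A [synth_config()].
#' @param seed Integer seed (independent of `cfg$seed`).
#' @param g Coupling strength for self-consistent simulation.
#' @param duration_s,transient_s Self-consistent simulation length.
#' @return List with `fc` (an [fc_network()]), `regions`, and `omega`
#'   (ground-truth rad/s vector, or `NULL` in noisy mode).
#' @export
synth_target_fc <- function(sc, mode = c("noisy", "self_consistent"), cfg,
                            seed = 1, g = 3.5, duration_s = 200,
                            transient_s = 0.2 * duration_s) {
  mode <- match.arg(mode)
  stopifnot(inherits(sc, "structural_connectome"),
            inherits(cfg, "synth_config"))
  set.seed(as.integer(seed))
  dr <- cfg$dropout_range
  m <- dr[1] + sample.int(dr[2] - dr[1] + 1, 1) - 1
  keep <- sort(sample(seq_along(sc$regions), m))
  regions <- sc$regions[keep]
  if (mode == "self_consistent") {
    sc_red <- reduce_to_regions(sc, regions)
    omega <- draw_frequencies(m, seed + 1L)
    theta0 <- draw_phases(m, seed + 2L)
    cfg_run <- oscillator_config(omega, theta0, g = g,
                                 duration_s = duration_s,
                                 transient_s = transient_s)
    fc <- simulated_fc(simulate_kuramoto(sc_red, cfg_run))
    fc$source <- "empirical"
    return(list(fc = fc, regions = regions, omega = omega))
  }
  a2 <- cfg$fc_mean
  b2 <- cfg$fc_sd
  if (a2 < 0 || b2 < 0 || a2 + b2 > 0.98)
    stop(sprintf(
      "unattainable mean/SD combination: fc_mean + fc_sd = %.2f exceeds 0.98",
      a2 + b2))
  a <- rep(sqrt(a2), m)
  signs <- sample(rep(c(1, -1), length.out = m))
  b <- signs * sqrt(b2)
  C <- outer(a, a) + outer(b, b)
  diag(C) <- 1
  C <- C + cfg$fc_noise * make_sym_noise(m)
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8)
    C <- as.matrix(Matrix::nearPD(C, corr = TRUE)$mat)
  list(fc = fc_network(C, regions, source = "empirical"),
       regions = regions, omega = NULL)
}

make_sym_noise <- function(m) {
  Z <- matrix(stats::rnorm(m * m), m, m)
  (Z + t(Z)) / sqrt(2)
}

#' Generate a BOLD-like recording realizing a target FC
#'
#' Draws Gaussian time series whose population correlation matrix equals
#' the target FC, then overwrites the series of
#' `variance_floor_violators` regions (chosen among regions with
#' above-median voxel counts, so the variance filter — not the voxel
#' filter — removes them) with near-constant signals of variance below
#' 1e-6. Voxel counts are drawn spanning the median threshold so the
#' quality-control filters are all exercised.
#'
#' @param fc_target An [fc_network()].
#' @param n_timepoints Number of time points.
#' @param variance_floor_violators Number of near-constant regions to
#'   inject.
#' @param seed Integer seed.
#' @param subject_id Subject identifier.
#' @return A [bold_recording()]; the injected region labels are attached
#'   as attribute `violators`.
#' @export
synth_bold <- function(fc_target, n_timepoints, variance_floor_violators = 0,
                       seed = 1, subject_id = "synthetic") {
  stopifnot(inherits(fc_target, "fc_network"))
  set.seed(as.integer(seed))
  n <- length(fc_target$regions)
  S <- fc_target$matrix
  ch <- tryCatch(chol(S), error = function(e) chol(S + 1e-8 * diag(n)))
  X <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n) %*% ch
  voxel <- sample(20:400, n, replace = TRUE)
  high <- which(voxel > stats::median(voxel))
  if (variance_floor_violators > length(high))
    stop("more violators requested than above-median regions")
  violators <- integer(0)
  if (variance_floor_violators > 0) {
    violators <- high[sample.int(length(high), variance_floor_violators)]
    for (j in violators)
      X[, j] <- mean(X[, j]) + stats::rnorm(n_timepoints, sd = 1e-5)
  }
  rec <- bold_recording(X, fc_target$regions, voxel, subject_id)
  attr(rec, "violators") <- fc_target$regions[violators]
  rec
}
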