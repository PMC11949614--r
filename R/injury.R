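#' Default cortical/hippocampal injury region set
#'
#' The 14 cortical and hippocampal region acronyms targeted by the
#' unilateral connectivity-reduction injury model (regions showing
#' neurodegeneration after mild controlled cortical impact), shipped with
#' the package together with exclusion flags for regions that drop out of
#' reduced networks during quality control.
#'
#' @param with_flags If `TRUE`, return the full data.frame including the
#'   exclusion flags; otherwise just the acronym vector.
#' @return Character vector of acronyms, or a data.frame.
#' @export
default_injury_regions <- function(with_flags = FALSE) {
  path <- system.file("extdata", "injury_regions.csv", package = "kurnet")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (with_flags) df else df$acronym
}

#' Injury sweep specification
#'
#' Defines which base regions are lesioned (always in hemisphere A, the
#' first hemisphere of the mirrored connectome) and the graded fractions of
#' connectivity loss. The default grades run from 5% to 100% in steps of
#' 5% — twenty injured connectomes per model.
#'
#' @param target_regions Base region acronyms to lesion.
#' @param hemisphere Hemisphere tag; only `"A"` is supported.
#' @param levels Strictly increasing fractions in (0, 1\].
#' @return An object of class `injury_spec`.
#' @export
injury_spec <- function(target_regions = default_injury_regions(),
                        hemisphere = "A",
                        levels = seq(0.05, 1, by = 0.05)) {
  if (!identical(hemisphere, "A"))
    stop("injury is applied to hemisphere \"A\" (the first hemisphere)")
  if (any(levels <= 0) || any(levels > 1))
    stop("levels must lie in (0, 1]")
  if (is.unsorted(levels, strictly = TRUE))
    stop("levels must be strictly increasing")
  structure(list(target_regions = as.character(target_regions),
                 hemisphere = hemisphere, levels = levels),
            class = "injury_spec")
}

# Resolve base acronyms to hemisphere-A node indices; absent regions are
# skipped silently (reduced networks retain only eight or nine of the
# fourteen targets) and the match count is attached as an attribute.
resolve_injury_targets <- function(sc, regions, hemisphere = "A") {
  base <- if (!is.null(sc$base)) sc$base else sc$regions
  hemi <- if (!is.null(sc$hemisphere)) sc$hemisphere else
    rep("A", length(sc$regions))
  idx <- which(base %in% regions & hemi == hemisphere)
  attr(idx, "n_requested") <- length(regions)
  idx
}

#' Apply a graded connectivity injury
#'
#' Multiplies all edge weights directed to and from the targeted
#' hemisphere-A nodes by `(1 - fraction)`. The scaling is a single mask
#' multiplication, so an edge between two targeted nodes is scaled exactly
#' once per application. Target regions absent from the (possibly reduced)
#' connectome are skipped silently; the number matched is reported in the
#' `n_injured` attribute.
#'
#' @param sc A [structural_connectome()].
#' @param regions Base region acronyms to lesion (hemisphere A).
#' @param fraction Fraction of connectivity lost, in \[0, 1\].
#' @return The injured `structural_connectome`, with attributes
#'   `injured_nodes` (labels) and `n_injured`.
#' @export
apply_injury <- function(sc, regions, fraction) {
  stopifnot(inherits(sc, "structural_connectome"))
  if (fraction < 0 || fraction > 1) stop("`fraction` must lie in [0, 1]")
  idx <- resolve_injury_targets(sc, regions)
  if (!length(idx)) stop("no target region present in the connectome")
  W <- sc$weights
  mask <- matrix(1, nrow(W), ncol(W))
  mask[idx, ] <- 1 - fraction
  mask[, idx] <- 1 - fraction
  out <- structural_connectome(W * mask, sc$regions,
                               hemisphere = sc$hemisphere,
                               directed = sc$directed, base = sc$base)
  attr(out, "injured_nodes") <- sc$regions[idx]
  attr(out, "n_injured") <- length(idx)
  out
}

#' Mean regional distance between two FC networks
#'
#' For every shared, non-excluded node, the Euclidean distance between its
#' FC row vectors (restricted to the shared, non-excluded columns) is
#' computed; the mean over nodes is returned. Directly injured regions are
#' typically passed through `exclude`.
#'
#' @param fc1,fc2 [fc_network()] objects.
#' @param exclude Labels to drop before comparison.
#' @param method `"regional"` (default, mean row distance) or
#'   `"frobenius"` (whole-matrix distance normalized by the edge count).
#' @return Nonnegative scalar.
#' @export
fc_distance <- function(fc1, fc2, exclude = character(),
                        method = c("regional", "frobenius")) {
  method <- match.arg(method)
  common <- setdiff(common_regions(list(fc1, fc2)), exclude)
  if (length(common) < 2) stop("need at least 2 shared regions")
  m1 <- fc1$matrix[common, common]
  m2 <- fc2$matrix[common, common]
  d <- m1 - m2
  if (method == "regional") {
    mean(sqrt(rowSums(d^2)))
  } else {
    sqrt(sum(d[upper.tri(d)]^2) / sum(upper.tri(d)))
  }
}

#' Sweep graded injuries on an optimized model
#'
#' For each injury level, lesions the optimized connectome, re-simulates
#' Kuramoto dynamics with the optimized frequencies and the same initial
#' phases as the uninjured baseline (so FC differences are attributable to
#' structure alone), and derives: edge-strength correlation to the
#' uninjured FC, mean regional FC distance to the uninjured FC (excluding
#' directly injured nodes), structural global efficiency, and per-node FC
#' strengths.
#'
#' @param sc_opt The optimized [structural_connectome()].
#' @param omega_opt Optimized angular frequencies, rad/s.
#' @param g Global coupling strength used for the optimized model.
#' @param spec An [injury_spec()].
#' @param seed Integer seed for the shared initial phases.
#' @param duration_s,transient_s,dt_s,sample_dt_s Integrator settings for
#'   each simulation.
#' @return An object of class `injury_sweep_result`: `table` (one row per
#'   level: `level`, `corr_to_baseline`, `mean_distance`,
#'   `global_efficiency`, `n_injured`), `baseline_fc`, `fc` (list by
#'   level), `strengths` (level-by-node matrix including level 0),
#'   `injured_nodes`, and `spec`.
#' @export
injury_sweep <- function(sc_opt, omega_opt, g, spec = injury_spec(),
                         seed = 1, duration_s = 200,
                         transient_s = 0.2 * duration_s, dt_s = 0.05,
                         sample_dt_s = 0.5) {
  stopifnot(inherits(sc_opt, "structural_connectome"),
            inherits(spec, "injury_spec"))
  n <- length(sc_opt$regions)
  if (length(omega_opt) != n) stop("`omega_opt` length must match network")
  theta0 <- draw_phases(n, seed)
  run_one <- function(sc) {
    cfg <- oscillator_config(omega_opt, theta0, g = g,
                             duration_s = duration_s,
                             transient_s = transient_s,
                             dt_s = dt_s, sample_dt_s = sample_dt_s)
    simulated_fc(simulate_kuramoto(sc, cfg))
  }
  baseline_fc <- run_one(sc_opt)
  idx <- resolve_injury_targets(sc_opt, spec$target_regions)
  if (!length(idx)) stop("no target region present in the connectome")
  injured_nodes <- sc_opt$regions[idx]
  nl <- length(spec$levels)
  tab <- data.frame(level = spec$levels,
                    corr_to_baseline = NA_real_,
                    mean_distance = NA_real_,
                    global_efficiency = NA_real_,
                    n_injured = length(idx))
  fcs <- vector("list", nl)
  strengths <- matrix(NA_real_, nl + 1, n,
                      dimnames = list(c(0, spec$levels), sc_opt$regions))
  strengths[1, ] <- nodal_fc_strength(baseline_fc)
  for (li in seq_len(nl)) {
    inj <- apply_injury(sc_opt, spec$target_regions, spec$levels[li])
    fc <- run_one(inj)
    fcs[[li]] <- fc
    tab$corr_to_baseline[li] <- fc_similarity(fc, baseline_fc)
    tab$mean_distance[li] <- fc_distance(fc, baseline_fc,
                                         exclude = injured_nodes)
    tab$global_efficiency[li] <- global_efficiency(inj)
    strengths[li + 1, ] <- nodal_fc_strength(fc)
  }
  structure(list(table = tab, baseline_fc = baseline_fc, fc = fcs,
                 baseline_global_efficiency = global_efficiency(sc_opt),
                 strengths = strengths, injured_nodes = injured_nodes,
                 spec = spec),
            class = "injury_sweep_result")
}

#' @export
print.injury_sweep_result <- function(x, ...) {
  cat(sprintf(
    "injury_sweep_result: %d levels, %d injured nodes | GE %.4f -> %.4f\n",
    nrow(x$table), length(x$injured_nodes),
    x$baseline_global_efficiency,
    x$table$global_efficiency[nrow(x$table)]))
  invisible(x)
}

#' Frequency of post-injury nodal strength decrease across models
#'
#' Restricts to regions common to every model and not directly injured,
#' then, per region and injury level, counts the fraction of models in
#' which the node's FC strength on the injured network is strictly below
#' its uninjured strength (ties count as not decreased). Strengths are
#' recomputed on the common restricted submatrix so all models are
#' compared over the same edges.
#'
#' @param models List of [injury_sweep_result()] objects (one per model).
#' @param injured_regions Additional labels to exclude (defaults to the
#'   union of each model's directly injured nodes).
#' @return List with `freq` (level-by-region matrix of decrease
#'   frequencies in \[0, 1\]), `mean_by_level` (data.frame `level`,
#'   `mean_decrease_freq`), and `regions`.
#' @export
strength_change_analysis <- function(models, injured_regions = NULL) {
  stopifnot(length(models) >= 2)
  if (is.null(injured_regions))
    injured_regions <- unique(unlist(lapply(models,
                                            function(m) m$injured_nodes)))
  fcs <- lapply(models, function(m) m$baseline_fc)
  common <- setdiff(common_regions(fcs), injured_regions)
  if (!length(common)) stop("no common uninjured regions across models")
  levels <- models[[1]]$spec$levels
  strength_on <- function(fc) {
    nodal_fc_strength(fc_network(fc$matrix[common, common], common,
                                 source = fc$source))
  }
  freq <- matrix(0, length(levels), length(common),
                 dimnames = list(levels, common))
  for (m in models) {
    s0 <- strength_on(m$baseline_fc)
    for (li in seq_along(levels)) {
      si <- strength_on(m$fc[[li]])
      freq[li, ] <- freq[li, ] + as.numeric(si < s0)
    }
  }
  freq <- freq / length(models)
  list(freq = freq,
       mean_by_level = data.frame(level = levels,
                                  mean_decrease_freq = rowMeans(freq)),
       regions = common)
}
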