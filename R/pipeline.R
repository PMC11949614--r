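#' Pipeline configuration
#'
#' Bundles every tunable of the five analysis stages. Defaults mirror the
#' full study protocol: coupling grids 0.1–2 (undirected) and 0.1–4
#' (directed) at resolution 0.1, 25 seeded ten-minute simulations per grid
#' point with the first two minutes discarded, a 100-iteration optimizer
#' with 200-s iterations, step constant 0.005 and coupling 1.0/3.5
#' (undirected/directed), and a 20-level unilateral injury sweep. Every
#' stage seed is derived deterministically from `master_seed`. Desk-scale
#' runs shrink `n_seeds`, `n_iter` and the synthetic network size through
#' the same fields.
#'
#' @param synth A [synth_config()] used when no connectome/FC paths are
#'   supplied.
#' @param paths Optional named list: `matrix`, `labels` (connectome CSVs)
#'   and `targets` (directory of FC CSVs).
#' @param g_grid_undirected,g_grid_directed Coupling grids.
#' @param n_seeds Seeded draws per grid point.
#' @param duration_s,transient_s Simulation protocol for sweeps.
#' @param n_iter,iter_duration_s,c Optimizer settings.
#' @param g_undirected,g_directed Optimizer coupling strengths.
#' @param architectures Architectures to fit (`"directed"`,
#'   `"undirected"`, or both).
#' @param injury An [injury_spec()].
#' @param swaps_per_edge Randomization swaps per edge.
#' @param master_seed Master integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), paths = list(),
                            g_grid_undirected = seq(0.1, 2, by = 0.1),
                            g_grid_directed = seq(0.1, 4, by = 0.1),
                            n_seeds = 25, duration_s = 600,
                            transient_s = 120, n_iter = 100,
                            iter_duration_s = 200, c = 0.005,
                            g_undirected = 1.0, g_directed = 3.5,
                            architectures = c("directed", "undirected"),
                            injury = injury_spec(), swaps_per_edge = 20,
                            master_seed = 1) {
  stopifnot(inherits(synth, "synth_config"), inherits(injury, "injury_spec"))
  architectures <- match.arg(architectures, c("directed", "undirected"),
                             several.ok = TRUE)
  structure(list(synth = synth, paths = paths,
                 g_grid_undirected = g_grid_undirected,
                 g_grid_directed = g_grid_directed, n_seeds = n_seeds,
                 duration_s = duration_s, transient_s = transient_s,
                 n_iter = n_iter, iter_duration_s = iter_duration_s,
                 c = c, g_undirected = g_undirected,
                 g_directed = g_directed, architectures = architectures,
                 injury = injury, swaps_per_edge = swaps_per_edge,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Derive a stage seed from the master seed
#'
#' Deterministic 32-bit mix of the master seed and a stage label, so every
#' random draw in the pipeline is traceable to `master_seed`.
#'
#' @param master Integer master seed.
#' @param label Character stage label.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(master, label) {
  s <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 7919 + s * 104729) %% 2147483647)
}

log_stage <- function(out_dir, stage, seed, t0) {
  line <- jsonlite::toJSON(list(stage = stage, seed = seed,
                                wall_s = round(as.numeric(Sys.time()) - t0, 2),
                                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                           auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = file.path(out_dir, "pipeline.log.jsonl"),
      append = TRUE)
}

read_stage_sc <- function(out_dir, arch) {
  read_connectome(file.path(out_dir, sprintf("sc_%s.csv", arch)),
                  file.path(out_dir, "sc_labels.csv"),
                  directed = arch == "directed")
}

#' Run one pipeline stage
#'
#' Stages: `"build-sc"` (construct or load the directed connectome and its
#' undirected counterpart), `"sweep-g"` (coupling sweeps on both
#' architectures), `"randomize-control"` (degree-preserving randomization
#' plus sweeps), `"fit"` (frequency optimization against each target FC),
#' `"injure"` (graded injury sweeps on each fitted model), and `"report"`
#' (figure-analog summary tables and routine statistics: t tests, ANOVA,
#' Pearson correlations, Kolmogorov–Smirnov comparisons). Each stage reads
#' its upstream artifacts from `out_dir`, writes CSV/JSON artifacts back,
#' and appends a line-delimited JSON log entry. Given the same config a
#' stage rerun is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param stage Stage name.
#' @param out_dir Artifact directory (created if missing).
#' @return Invisibly, a list of the stage's main in-memory artifacts.
#' @export
run_stage <- function(config, stage = c("build-sc", "sweep-g",
                                        "randomize-control", "fit",
                                        "injure", "report"),
                      out_dir = ".") {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- match.arg(stage)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  seed <- derive_seed(config$master_seed, stage)
  out <- switch(stage,
    "build-sc" = stage_build_sc(config, out_dir),
    "sweep-g" = stage_sweep(config, out_dir, seed, randomized = FALSE),
    "randomize-control" = stage_sweep(config, out_dir, seed,
                                      randomized = TRUE),
    "fit" = stage_fit(config, out_dir, seed),
    "injure" = stage_injure(config, out_dir, seed),
    "report" = stage_report(config, out_dir))
  log_stage(out_dir, stage, seed, t0)
  invisible(out)
}

stage_build_sc <- function(config, out_dir) {
  if (!is.null(config$paths$matrix)) {
    sc <- read_connectome(config$paths$matrix, config$paths$labels,
                          directed = TRUE)
    sc <- normalize_connectome(sc)
  } else {
    sc <- synth_connectome(config$synth)
  }
  scu <- normalize_connectome(to_undirected(sc))
  write_connectome(sc, file.path(out_dir, "sc_directed.csv"),
                   file.path(out_dir, "sc_labels.csv"),
                   file.path(out_dir, "sc_directed.meta.json"))
  write_connectome(scu, file.path(out_dir, "sc_undirected.csv"),
                   meta_file = file.path(out_dir, "sc_undirected.meta.json"))
  list(directed = sc, undirected = scu)
}

stage_sweep <- function(config, out_dir, seed, randomized) {
  sc <- read_stage_sc(out_dir, "directed")
  if (randomized) {
    sc <- randomize_directed(sc, config$swaps_per_edge, seed)
    scu <- normalize_connectome(to_undirected(sc))
  } else {
    scu <- read_stage_sc(out_dir, "undirected")
  }
  tag <- if (randomized) "randomized_" else ""
  res <- list()
  for (arch in c("undirected", "directed")) {
    net <- if (arch == "directed") sc else scu
    grid <- if (arch == "directed") config$g_grid_directed else
      config$g_grid_undirected
    sw <- coupling_sweep(net, grid, n_seeds = config$n_seeds,
                         base_seed = seed,
                         duration_s = config$duration_s,
                         transient_s = config$transient_s)
    utils::write.table(
      cbind(sw, g_max_metastability = attr(sw, "g_max_metastability")),
      file.path(out_dir, sprintf("sweep_%s%s.csv", tag, arch)),
      sep = ",", row.names = FALSE, quote = FALSE)
    res[[arch]] <- sw
  }
  res
}

stage_fit <- function(config, out_dir, seed) {
  targets <- load_or_make_targets(config, out_dir, seed)
  summary_rows <- list()
  for (arch in config$architectures) {
    sc <- read_stage_sc(out_dir, arch)
    g <- if (arch == "directed") config$g_directed else config$g_undirected
    for (si in seq_along(targets)) {
      tgt <- targets[[si]]
      sc_red <- reduce_to_regions(sc, tgt$fc$regions)
      tr <- optimize_frequencies(sc_red, tgt$fc, g = g,
                                 n_iter = config$n_iter,
                                 iter_duration_s = config$iter_duration_s,
                                 seed = seed, c = config$c)
      id <- sprintf("%s_s%02d", arch, si)
      write_trace(tr, file.path(out_dir, sprintf("trace_%s.csv", id)))
      utils::write.table(
        data.frame(label = sc_red$regions,
                   omega = tr$omega_history[tr$best_iteration, ]),
        file.path(out_dir, sprintf("omega_%s.csv", id)),
        sep = ",", row.names = FALSE, quote = FALSE)
      summary_rows[[id]] <- data.frame(
        model_id = id, architecture = arch, subject = si,
        n_regions = length(sc_red$regions),
        pp_initial = tr$pp_history[1],
        pp_best = max(tr$pp_history),
        best_iteration = tr$best_iteration,
        mse_best = tr$mse_history[tr$best_iteration],
        target_mean_edge = mean(tgt$fc$matrix[upper.tri(tgt$fc$matrix)]),
        target_sd_edge = stats::sd(tgt$fc$matrix[upper.tri(tgt$fc$matrix)]))
    }
  }
  fit_summary <- do.call(rbind, summary_rows)
  utils::write.table(fit_summary, file.path(out_dir, "fit_summary.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  fit_summary
}

load_or_make_targets <- function(config, out_dir, seed) {
  if (!is.null(config$paths$targets)) {
    files <- sort(list.files(config$paths$targets, pattern = "\\.csv$",
                             full.names = TRUE))
    return(lapply(files, function(f) list(fc = read_fc(f))))
  }
  sc <- read_stage_sc(out_dir, "directed")
  lapply(seq_len(config$synth$n_subjects), function(si) {
    synth_target_fc(sc, "noisy", config$synth, seed = seed + si)
  })
}

stage_injure <- function(config, out_dir, seed) {
  fit_summary <- utils::read.csv(file.path(out_dir, "fit_summary.csv"),
                                 stringsAsFactors = FALSE)
  rows <- list()
  sweeps <- list()
  for (k in seq_len(nrow(fit_summary))) {
    id <- fit_summary$model_id[k]
    arch <- fit_summary$architecture[k]
    om <- utils::read.csv(file.path(out_dir, sprintf("omega_%s.csv", id)),
                          stringsAsFactors = FALSE)
    sc <- reduce_to_regions(read_stage_sc(out_dir, arch), om$label)
    g <- if (arch == "directed") config$g_directed else config$g_undirected
    res <- injury_sweep(sc, om$omega, g = g, spec = config$injury,
                        seed = seed,
                        duration_s = config$iter_duration_s)
    sweeps[[id]] <- res
    rows[[id]] <- cbind(model_id = id, architecture = arch, res$table)
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(out_dir, "injury_sweeps.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  # decrease-frequency analysis per architecture (needs >= 2 models)
  for (arch in unique(fit_summary$architecture)) {
    ms <- sweeps[fit_summary$model_id[fit_summary$architecture == arch]]
    if (length(ms) >= 2) {
      an <- tryCatch(strength_change_analysis(ms), error = function(e) NULL)
      if (!is.null(an)) {
        utils::write.table(
          data.frame(level = rownames(an$freq), an$freq,
                     check.names = FALSE),
          file.path(out_dir, sprintf("strength_decrease_%s.csv", arch)),
          sep = ",", row.names = FALSE, quote = FALSE)
      }
    }
  }
  tab
}

stage_report <- function(config, out_dir) {
  stats_out <- list()
  # sweep summary (coupling-response curves and argmax-metastability g)
  p <- file.path(out_dir, "sweep_directed.csv")
  if (file.exists(p)) {
    sw_d <- utils::read.csv(p)
    sw_u <- utils::read.csv(file.path(out_dir, "sweep_undirected.csv"))
    stats_out$g_max_metastability <- list(
      undirected = sw_u$g_max_metastability[1],
      directed = sw_d$g_max_metastability[1])
  }
  # fit summary: baseline vs optimized predictive power
  p <- file.path(out_dir, "fit_summary.csv")
  if (file.exists(p)) {
    fs <- utils::read.csv(p, stringsAsFactors = FALSE)
    utils::write.table(fs, file.path(out_dir, "report_fit.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    tt <- stats::t.test(fs$pp_best, fs$pp_initial, paired = TRUE)
    stats_out$optimization <- list(
      mean_pp_initial = mean(fs$pp_initial),
      mean_pp_best = mean(fs$pp_best),
      paired_t_p = tt$p.value)
    if (length(unique(fs$architecture)) > 1) {
      aov_p <- summary(stats::aov(pp_best ~ architecture,
                                  data = fs))[[1]][["Pr(>F)"]][1]
      stats_out$optimization$anova_architecture_p <- aov_p
    }
    for (v in c("target_mean_edge", "target_sd_edge", "n_regions")) {
      ct <- tryCatch(stats::cor.test(fs$pp_best, fs[[v]]),
                     error = function(e) NULL)
      if (!is.null(ct))
        stats_out$optimization[[paste0("pp_vs_", v, "_r")]] <- ct$estimate[[1]]
    }
  }
  # injury summary: level-averaged trends and their correlations
  p <- file.path(out_dir, "injury_sweeps.csv")
  if (file.exists(p)) {
    inj <- utils::read.csv(p, stringsAsFactors = FALSE)
    agg <- stats::aggregate(
      inj[c("corr_to_baseline", "mean_distance", "global_efficiency")],
      by = list(level = inj$level), FUN = mean)
    utils::write.table(agg, file.path(out_dir, "report_injury.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    stats_out$injury <- list(
      r_level_vs_corr = stats::cor(agg$level, agg$corr_to_baseline),
      r_level_vs_distance = stats::cor(agg$level, agg$mean_distance),
      r_level_vs_globaleff = stats::cor(agg$level, agg$global_efficiency),
      r_globaleff_vs_distance = stats::cor(agg$global_efficiency,
                                           agg$mean_distance))
  }
  # strength-decrease trend and K-S between injury levels
  for (arch in c("directed", "undirected")) {
    p <- file.path(out_dir, sprintf("strength_decrease_%s.csv", arch))
    if (!file.exists(p)) next
    sd_tab <- utils::read.csv(p, check.names = FALSE)
    lev <- as.numeric(sd_tab$level)
    freq <- as.matrix(sd_tab[, -1, drop = FALSE])
    trend <- stats::cor(rep(lev, ncol(freq)), as.vector(freq))
    entry <- list(r_level_vs_decrease_freq = trend)
    pick <- function(l) freq[which.min(abs(lev - l)), ]
    if (length(lev) >= 2) {
      ks <- suppressWarnings(stats::ks.test(pick(0.05), pick(0.25)))
      entry$ks_p_005_vs_025 <- ks$p.value
    }
    stats_out[[paste0("strength_", arch)]] <- entry
  }
  jsonlite::write_json(stats_out, file.path(out_dir, "report_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  stats_out
}
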