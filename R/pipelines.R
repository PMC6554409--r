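# End-to-end pipelines: the regime/duration atlas over a parameter plane,
# and the duration-distribution matching pipeline. Both take a plain config
# list (or YAML path), write TSV/JSON products plus a run manifest, and
# propagate stage-labelled errors.

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

load_config <- function(config) {
  if (is.character(config)) yaml::read_yaml(config) else config
}

write_manifest <- function(config, out_dir) {
  jsonlite::write_json(
    list(config = config,
         package_version = as.character(utils::packageVersion("nremdyn")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
}

#' Run the regime atlas pipeline
#'
#' Classifies regimes and simulates duration statistics over a parameter
#' plane, writing `regime_map.tsv`, `duration_map.tsv`, a
#' `regime_map.tsv.json` summary with per-row I/O-curve bifurcation drives,
#' and a `manifest.json` echoing the configuration.
#'
#' @param config list (or YAML path) with fields: `base` (list `w`, `b`,
#'   `I`), `axis1`/`axis2` (lists `name`, `values` or `from`/`to`/`n`),
#'   `seed`, `out_dir`, and optional `duration` (simulated time per cell)
#'   and `noise` (list `theta`, `sigma`).
#' @return Invisibly, the list of written paths.
#' @export
run_regime_atlas <- function(config) {
  cfg <- load_config(config)
  out_dir <- cfg$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  axis_vals <- function(ax) {
    if (!is.null(ax$values)) ax$values else seq(ax$from, ax$to, length.out = ax$n)
  }
  base <- run_stage("config", do.call(rate_pop_params, cfg$base))
  ax1 <- run_stage("config", list(name = cfg$axis1$name,
                                  values = axis_vals(cfg$axis1)))
  ax2 <- run_stage("config", list(name = cfg$axis2$name,
                                  values = axis_vals(cfg$axis2)))
  noise <- if (is.null(cfg$noise)) ou_params()
  else do.call(ou_params, cfg$noise)
  seed <- cfg$seed %||% 1L
  rmap <- run_stage("regime_map", regime_map(base, ax1, ax2))
  dmap <- run_stage("duration_map",
                    duration_map(base, ax1, ax2, noise = noise,
                                 duration = cfg$duration %||% 25000,
                                 seed = seed))
  # per-value-of-axis2 bifurcation drives along axis1 = I, when applicable
  bifs <- NULL
  if (ax1$name == "I") {
    bifs <- lapply(ax2$values, function(v2) {
      p <- base; p[[ax2$name]] <- v2
      bc <- run_stage("io_curve",
                      io_curve(p, range(ax1$values), n_points = 101))
      list(axis2 = v2, shape = bc$shape, bifurcations = bc$bifurcations)
    })
  }
  p1 <- file.path(out_dir, "regime_map.tsv")
  p2 <- file.path(out_dir, "duration_map.tsv")
  run_stage("write", {
    write_map(rmap, p1, summary = list(axes = attr(rmap, "axes"),
                                       io_curves = bifs))
    write_map(dmap$cells, p2)
    write_manifest(cfg, out_dir)
  })
  invisible(list(regime_map = p1, duration_map = p2,
                 manifest = file.path(out_dir, "manifest.json")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the duration-distribution matching pipeline
#'
#' Simulates duration samples over an (I, w) grid, computes best-time-scale
#' KS-product similarity against each observed recording, and writes the
#' mean similarity map, per-recording best fits (cell and time-scale), and
#' the constraint-region mask.
#'
#' @param config list (or YAML path) with fields: `base` (list `w`, `b`,
#'   `I`), `grid` (lists `I` and `w` of cell values), `recordings`
#'   (character vector of duration TSV paths, or a list of
#'   [duration_sample()] objects), optional `exp_stats` (fields of
#'   [exp_duration_stats()]), `duration`, `noise`, `seed`, `out_dir`.
#' @return Invisibly, the list of written paths plus the `similarity_map`.
#' @export
run_matching_pipeline <- function(config) {
  cfg <- load_config(config)
  out_dir <- cfg$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- run_stage("recordings", {
    if (is.null(cfg$recordings) || !length(cfg$recordings))
      stop("no recordings given")
    if (is.character(cfg$recordings)) lapply(cfg$recordings, read_durations)
    else cfg$recordings
  })
  base <- run_stage("config", do.call(rate_pop_params, cfg$base))
  noise <- if (is.null(cfg$noise)) ou_params() else do.call(ou_params, cfg$noise)
  seed <- cfg$seed %||% 1L
  dmap <- run_stage("simulate_grid",
                    duration_map(base,
                                 axis1 = list(name = "I", values = cfg$grid$I),
                                 axis2 = list(name = "w", values = cfg$grid$w),
                                 noise = noise,
                                 duration = cfg$duration %||% 25000,
                                 seed = seed))
  es <- if (!is.null(cfg$exp_stats)) do.call(exp_duration_stats, cfg$exp_stats)
  smap <- run_stage("similarity_map",
                    similarity_map(dmap$cells[, 1:2], dmap$samples, recs,
                                   exp_stats = es))
  best <- data.frame(recording = seq_along(recs),
                     I = smap$cells$I[smap$best_cells],
                     w = smap$cells$w[smap$best_cells],
                     s = vapply(seq_along(recs), function(j)
                       smap$per_recording[smap$best_cells[j], j], numeric(1)),
                     best_tau_ms = smap$best_taus)
  p1 <- file.path(out_dir, "similarity_map.tsv")
  p2 <- file.path(out_dir, "best_fits.tsv")
  # manifests echo the config; in-memory duration samples are summarized
  # rather than serialized wholesale
  if (!is.character(cfg$recordings))
    cfg$recordings <- sprintf("<%d in-memory duration samples>", length(recs))
  run_stage("write", {
    write_map(smap$cells, p1,
              summary = list(n_recordings = length(recs),
                             best_cells = smap$best_cells))
    write_map(best, p2)
    write_manifest(cfg, out_dir)
  })
  invisible(list(similarity_map = p1, best_fits = p2,
                 manifest = file.path(out_dir, "manifest.json"),
                 map = smap))
}
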