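#' Default pipeline configuration
#'
#' All stage parameters with package defaults: a 10^6-step Langevin
#' trajectory on the three-basin activation surface at kT = 0.596 kcal/mol,
#' a 200-microstate / 3-macrostate MSM at a lag past the implied-timescale
#' plateau, and tICA on the order parameters. Override any entry via
#' `modifyList`-style nesting in `run_pipeline(config = ...)`.
#'
#' @param seed global RNG seed; stage seeds are derived from it.
#' @return nested named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    sim = list(n_steps = 1e6, dt = 0.02, diffusion = c(1.5, 8), kT = 0.596,
               thin = 1L),
    landscape = list(bins = c(100L, 100L),
                     range = list(c(15, 25), c(30, 80))),
    msm = list(k = 200L, lag = 200L, max_iter = 200L, m = 3L,
               fit_sample = 200000L),
    tica = list(lag = 200L, n_components = 2L, k = 100L, m = 8L),
    representative = list(pool_size = 50L),
    frame_ns = 1)  # report timescales as if one frame = 1 ns
}

#' Run the activation-pathway analysis pipeline
#'
#' simulate -> featurize (the simulation already lives in order-parameter
#' space) -> landscape -> MSM (microstates, transition matrix, PCCA+) ->
#' TPT MFPT table -> tICA, writing plain-file artifacts (CSV/JSON) and a
#' machine-readable summary to `out_dir`. Deterministic for a fixed config:
#' rerunning writes byte-identical summaries.
#'
#' @param config nested list as from [default_config()]; partial configs are
#'   filled with defaults. Validated before any stage runs.
#' @param out_dir output directory (created; stamped with the config hash).
#' @return the summary list (invisibly written as `summary.json`), with
#'   elements `landscape_csv`, `macrostate_populations`, `macrostate_labels`,
#'   `mfpt_ns`, `tica_eigenvalues`, `representative_frames`, `config_hash`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("conformpath_")) {
  cfg <- modify_defaults(default_config(), config)
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  writeLines(hash, file.path(out_dir, "config_hash.txt"))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  surface <- make_three_basin_potential()
  stage <- "simulate"
  summary <- tryCatch({
    traj <- simulate_langevin(surface, langevin_config(
      n_steps = cfg$sim$n_steps, dt = cfg$sim$dt,
      diffusion = cfg$sim$diffusion, kT = cfg$sim$kT,
      seed = cfg$seed, thin = cfg$sim$thin))
    write_features(traj, file.path(out_dir, "trajectory.csv"))

    stage <- "landscape"
    ls <- estimate_landscape(traj, bins = cfg$landscape$bins,
                             kT = cfg$sim$kT, range = cfg$landscape$range)
    ls_csv <- file.path(out_dir, "landscape.csv")
    write_landscape(ls, ls_csv)

    stage <- "msm"
    micro <- cluster_microstates(traj, k = cfg$msm$k,
                                 max_iter = cfg$msm$max_iter,
                                 seed = cfg$seed + 1L,
                                 fit_sample = cfg$msm$fit_sample)
    C <- count_transitions(micro$dtraj, cfg$msm$lag)
    tm <- estimate_T(C, lag = cfg$msm$lag, dt_frame = cfg$frame_ns)
    macro <- pcca(tm, cfg$msm$m)
    labels <- label_macrostates(macro, micro, pi = tm$pi)

    stage <- "tpt"
    mf <- mfpt_matrix(tm, macro, labels = labels)

    stage <- "tica"
    tica <- fit_tica(traj, lag = cfg$tica$lag,
                     n_components = cfg$tica$n_components)
    # tICA-space MSM: cluster the projections and coarse-grain into the
    # configured number of global-motion macrostates (msm module reused)
    proj <- tica_transform(tica, traj)
    tmicro <- cluster_microstates(proj, k = cfg$tica$k,
                                  max_iter = cfg$msm$max_iter,
                                  seed = cfg$seed + 2L,
                                  fit_sample = cfg$msm$fit_sample)
    ttm <- estimate_T(count_transitions(tmicro$dtraj, cfg$msm$lag),
                      lag = cfg$msm$lag, dt_frame = cfg$frame_ns)
    tmacro <- pcca(ttm, cfg$tica$m)

    stage <- "representative"
    rep_frames <- lapply(seq_len(macro$m), function(j) {
      pool <- representative_pool(traj, micro, macro, j,
                                  cfg$representative$pool_size)
      rc <- representative_conformation(traj[pool, , drop = FALSE])
      list(frame = pool[rc$index], pool_size = length(pool))
    })
    names(rep_frames) <- labels

    list(landscape_csv = basename(ls_csv),
         n_frames = nrow(traj),
         macrostate_populations = as.list(stats::setNames(
           round(macro$macro_pi, 10), labels)),
         macrostate_labels = labels,
         mfpt_ns = round(mf, 6),
         tica_eigenvalues = round(tica$eigenvalues, 10),
         tica_macrostate_count = tmacro$m,
         tica_macrostate_populations = round(tmacro$macro_pi, 10),
         representative_frames = rep_frames,
         config_hash = hash)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage `%s`: %s (partial artifacts in %s)",
                 stage, conditionMessage(e), out_dir), call. = FALSE)
  })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

# frames nearest the microstate centres of one macrostate (the Eq.-5 pool)
representative_pool <- function(traj, micro, macro, j, pool_size) {
  micro_ids <- macro$states[macro$crisp == j]
  X <- as.matrix(traj)
  Z <- sweep(sweep(X, 2L, micro$center), 2L, micro$scale, "/")
  sel <- which(micro$dtraj %in% micro_ids)
  cz <- micro$centers_z[micro$dtraj[sel], , drop = FALSE]
  d2 <- rowSums((Z[sel, , drop = FALSE] - cz)^2)
  sel[order(d2)[seq_len(min(pool_size, length(sel)))]]
}

write_landscape <- function(ls, path) {
  grid <- expand.grid(i = seq_along(ls$mids[[1]]), j = seq_along(ls$mids[[2]]))
  df <- data.frame(x = ls$mids[[1]][grid$i], y = ls$mids[[2]][grid$j],
                   p = as.numeric(ls$p), F = as.numeric(ls$F))
  names(df)[1:2] <- ls$labels
  occupied <- df$p > 0
  utils::write.csv(df[occupied, , drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

modify_defaults <- function(defaults, overrides) {
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]))
      defaults[[nm]] <- modify_defaults(defaults[[nm]], overrides[[nm]])
    else defaults[[nm]] <- overrides[[nm]]
  }
  defaults
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(sim$n_steps >= 1, sim$dt > 0, sim$kT > 0, sim$diffusion >= 0,
              msm$k >= 2, msm$lag >= 1, msm$m >= 2, msm$m <= msm$k,
              tica$lag >= 1, frame_ns > 0)
  })
  n_frames <- cfg$sim$n_steps %/% (cfg$sim$thin %||% 1L) + 1L
  if (cfg$msm$k > n_frames)
    stop("config invalid: more microstates (k) than trajectory frames")
  if (cfg$msm$lag >= n_frames)
    stop("config invalid: MSM lag not shorter than the trajectory")
  invisible(TRUE)
}

config_hash <- function(cfg) {
  # stable content hash without extra dependencies: md5 of canonical JSON
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(json, f)
  unname(tools::md5sum(f))
}
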