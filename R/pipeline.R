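#' Read and validate a run configuration
#'
#' A run is described by one flat YAML file with an `experiment` name, a
#' global `seed`, an `output` directory, a `stages` list and per-stage
#' parameter blocks (`synthetic`, `morphometry`, `membrane`, `cable`).
#' Per-stage seeds are derived deterministically from the global seed and
#' the stage name, so the whole run is reproducible from the file alone.
#'
#' @param path path to a YAML config file.
#' @return a validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list (as from [yaml::read_yaml()]).
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$experiment) || !nzchar(cfg$experiment))
    stop("config needs an 'experiment' name", call. = FALSE)
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    stop("config needs a numeric global 'seed'", call. = FALSE)
  if (is.null(cfg$output)) stop("config needs an 'output' directory", call. = FALSE)
  known <- c("synthetic", "morphometry", "membrane", "cable")
  cfg$stages <- cfg$stages %||% known
  bad <- setdiff(cfg$stages, known)
  if (length(bad))
    stop("unknown stages: ", paste(bad, collapse = ", "), call. = FALSE)
  if ("morphometry" %in% cfg$stages && !("synthetic" %in% cfg$stages))
    stop("the morphometry stage needs the synthetic stage", call. = FALSE)
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname read_run_config
#' @param file output path.
#' @export
write_run_config <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' Run a configured multi-stage experiment
#'
#' Executes the requested stages in dependency order — generate a synthetic
#' cohort, measure it, relax a membrane tube, and predict conduction
#' velocities from geometry rows — writing each stage's outputs as
#' delimited text/JSON under the config's output directory and recording a
#' manifest. A stage failure is recorded in the manifest without corrupting
#' the outputs of completed stages.
#'
#' @param cfg a `run_config` (or path to one).
#' @return a `run_manifest`: config hash, per-stage status and file lists,
#'   wall times, and convergence flags where applicable.
#' @export
run_experiment <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  out <- cfg$output
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out, "config.yaml")
  write_run_config(cfg, cfg_path)
  manifest <- list(experiment = cfg$experiment,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   seed = cfg$seed, stages = list())
  state <- new.env(parent = emptyenv())
  for (stage in cfg$stages) {
    t0 <- Sys.time()
    res <- tryCatch(
      .run_stage(stage, cfg, out, state),
      error = function(e) list(ok = FALSE, error = conditionMessage(e),
                               files = character()))
    res$wall_s <- as.numeric(Sys.time() - t0, units = "secs")
    res$ok <- res$ok %||% TRUE
    manifest$stages[[stage]] <- res
  }
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  structure(c(manifest, list(path = manifest_path)), class = "run_manifest")
}

.run_stage <- function(stage, cfg, out, state) {
  seed <- derive_seed(cfg$seed, stage)
  switch(stage,
    synthetic = {
      p <- cfg$synthetic %||% list()
      pop <- gen_population(
        dim_means = unlist(p$dim_means %||% c(600, 311, 552, 127)),
        dim_sds = unlist(p$dim_sds %||% c(50, 30, 50, 10)),
        n_axons = p$n_axons %||% 20L,
        synaptic_fraction = p$synaptic_fraction %||% 0,
        n_periods = p$n_periods %||% 6L,
        noise_sd = p$noise_sd %||% 0,
        seed = seed)
      dir.create(file.path(out, "profiles"), showWarnings = FALSE)
      files <- vapply(seq_along(pop$profiles), function(i) {
        f <- file.path(out, "profiles", sprintf("axon_%03d.txt", i))
        write_radius_profile(pop$profiles[[i]], f)
        f
      }, character(1))
      tf <- file.path(out, "truth.tsv")
      utils::write.table(pop$truth, tf, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      state$population <- pop
      list(files = c(files, tf), n_axons = length(pop$profiles))
    },
    morphometry = {
      p <- cfg$morphometry %||% list()
      pop <- state$population
      recs <- lapply(pop$profiles, function(pr)
        measure_segments(segment_profile(pr, p$smoothing_nm %||% 15),
                         pr$annotations))
      ex <- apply_exclusions(recs)
      summ <- summarize_morphometry(ex$records,
                                    groups = cfg$experiment)
      sf <- file.path(out, "morphometry_summary.tsv")
      write_morphometry_summary(summ, sf)
      state$summary <- summ
      list(files = sf, removed_synaptic = ex$removed_synaptic,
           removed_axons = ex$removed_axons)
    },
    membrane = {
      p <- cfg$membrane %||% list()
      mp <- membrane_params(kappa_kbt = p$kappa_kbt %||% 50,
                            sigma = p$sigma %||% 0.02,
                            c_ext_mosm = p$c_ext_mosm %||% 300)
      radius <- p$radius %||% 85
      L <- p$domain_nm %||% fastest_growing_wavelength(radius, mp)
      if (is.na(L)) stop("membrane condition is pearling-stable")
      rl <- relax_shape(cylinder_state(radius, L, n = p$grid_n %||% 128),
                        mp, tol = p$tol %||% 1e-4,
                        max_iter = p$max_iter %||% 40000L)
      f <- file.path(out, "relaxed_shape.txt")
      write_radius_profile(shape_to_profile(rl$state), f)
      list(files = f, converged = rl$converged, pinched = rl$pinched,
           energy_kbt = rl$energy$total)
    },
    cable = {
      p <- cfg$cable %||% list()
      rows <- p$geometries %||% list(control = c(638, 309, 486, 136))
      ep <- ephys_params()
      tab <- data.frame(
        geometry = names(rows),
        t(vapply(rows, function(d) unlist(d)[1:4], numeric(4))))
      names(tab)[2:5] <- c("nsv_length", "nsv_width", "connector_length",
                           "connector_width")
      tab$velocity_m_s <- vapply(rows, function(d)
        predict_from_measurements(unlist(d), params = ep,
                                  layout_mode = p$layout %||% "periodic"),
        numeric(1))
      f <- file.path(out, "velocity_predictions.tsv")
      utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
      state$velocities <- tab
      list(files = f, n_geometries = nrow(tab))
    },
    stop("unknown stage: ", stage))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> '%s' (seed %s, config %s)\n", x$experiment,
              x$seed, substr(x$config_hash, 1, 8)))
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-12s %s  (%.1f s, %d file(s))\n", nm,
                if (isTRUE(s$ok)) "ok" else paste("FAILED:", s$error),
                s$wall_s %||% NA, length(s$files)))
  }
  invisible(x)
}

#' Human-readable report of a completed run
#'
#' Formats the stage outputs recorded by [run_experiment()] — the cohort
#' morphometry table (mean +/- s.e.m. per dimension), membrane relaxation
#' status, and predicted conduction velocities — as plain text. Stages that
#' did not run are marked unavailable.
#'
#' @param manifest a `run_manifest`.
#' @return the report, invisibly, as a character vector of lines (also
#'   printed).
#' @export
report_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  out_dir <- dirname(manifest$path)
  lines <- c(sprintf("Experiment: %s", manifest$experiment),
             sprintf("Config hash: %s", manifest$config_hash), "")
  sfile <- file.path(out_dir, "morphometry_summary.tsv")
  lines <- c(lines, "== Morphometry ==")
  if (file.exists(sfile)) {
    summ <- utils::read.delim(sfile)
    lines <- c(lines, sprintf("  %-18s %8.1f +/- %5.1f nm  (n = %d)",
                              summ$dimension, summ$mean_nm, summ$sem_nm,
                              summ$n_segments))
  } else lines <- c(lines, "  [unavailable]")
  vfile <- file.path(out_dir, "velocity_predictions.tsv")
  lines <- c(lines, "", "== Velocity predictions ==")
  if (file.exists(vfile)) {
    vt <- utils::read.delim(vfile)
    lines <- c(lines, sprintf("  %-12s %6.4f m/s", vt$geometry,
                              vt$velocity_m_s))
  } else lines <- c(lines, "  [unavailable]")
  ms <- manifest$stages$membrane
  lines <- c(lines, "", "== Membrane relaxation ==",
             if (!is.null(ms) && isTRUE(ms$ok))
               sprintf("  converged: %s, E = %.5g kT", ms$converged,
                       ms$energy_kbt)
             else "  [unavailable]")
  cat(lines, sep = "\n")
  invisible(lines)
}
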