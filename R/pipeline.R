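# Pipeline orchestration: staged runs with provenance, plus shape-space
# serialization.

#' Write a fitted shape space to a structured text file
#'
#' Single-file format: header metadata followed by labelled matrix
#' blocks (mean shape, centering vector, basis, eigenvalues), numbers at
#' full double precision.
#'
#' @param space a `shape_space`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_shape_space <- function(space, path) {
  stopifnot(inherits(space, "shape_space"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(
    "# tonguekin shape space v1",
    sprintf("n_markers: %d", nrow(space$mean_shape)),
    sprintf("n_components: %d", ncol(space$basis)),
    sprintf("n_frames: %d", space$n_frames),
    sprintf("allow_scale: %s", space$gpa$allow_scale),
    sprintf("markers: %s", paste(rownames(space$mean_shape), collapse = " ")),
    "[mean_shape]",
    apply(space$mean_shape, 1, num),
    "[center]", num(space$center),
    "[eigenvalues]", num(space$eigenvalues),
    "[basis]",
    apply(space$basis, 1, num))
  writeLines(lines, path)
  invisible(path)
}

#' Read a shape space written by [write_shape_space()]
#' @param path shape-space file.
#' @return A `shape_space` (training scores and GPA per-frame
#'   bookkeeping are not persisted).
#' @export
read_shape_space <- function(path) {
  ln <- readLines(path)
  meta <- function(key) {
    v <- grep(paste0("^", key, ": "), ln, value = TRUE)
    if (!length(v)) stop("malformed shape-space file: missing ", key)
    sub(paste0("^", key, ": "), "", v[1])
  }
  block <- function(name, n_rows) {
    i <- which(ln == paste0("[", name, "]"))
    if (!length(i)) stop("malformed shape-space file: missing block ", name)
    vals <- lapply(ln[(i + 1):(i + n_rows)], function(s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
    do.call(rbind, vals)
  }
  nm <- as.integer(meta("n_markers"))
  nc <- as.integer(meta("n_components"))
  markers <- strsplit(meta("markers"), " ")[[1]]
  mean_shape <- block("mean_shape", nm)
  dimnames(mean_shape) <- list(markers, c("X", "Y", "Z"))
  ev <- as.numeric(block("eigenvalues", 1))
  structure(list(
    mean_shape = mean_shape,
    basis = block("basis", 3 * nm),
    eigenvalues = ev, var_explained = ev / sum(ev),
    scores = NULL, center = as.numeric(block("center", 1)),
    gpa = list(allow_scale = as.logical(meta("allow_scale"))),
    n_frames = as.integer(meta("n_frames"))), class = "shape_space")
}

pipeline_log <- function(stage, msg, t0 = NULL) {
  elapsed <- if (!is.null(t0))
    sprintf(" [%.1f s]", as.numeric(Sys.time()) - t0) else ""
  message(sprintf("[tonguekin:%s] %s%s", stage, msg, elapsed))
}

write_provenance <- function(dir, stage, config_path, seed) {
  prov <- list(
    stage = stage,
    config_hash = if (!is.null(config_path) && file.exists(config_path))
      unname(tools::md5sum(config_path)) else NA_character_,
    seed = seed,
    package_version = as.character(utils::packageVersion("tonguekin")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(prov, file.path(dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (synthetic dataset to disk), `kinematics`
#' (standard variable table), `shape` (shape space + scores), `decode`
#' (cross-validated decoding results TSV), `analyze` (population
#' analyses), or `all`. Each stage is idempotent given the seed and
#' writes a provenance block (config hash, seed, versions) next to its
#' outputs. Stages that need upstream artifacts fail with an error
#' naming the stage to run first.
#'
#' @param config a config list (see [read_config()]) or a YAML file path.
#'   Recognised blocks: `simulation` (passed to [simulation_config()]),
#'   `decode` (`variables`, `region`, `n_neurons`, `n_eval_folds`,
#'   `hyperparams`), `analyze` (`which`, plus per-analysis settings).
#' @param stage one of `simulate`, `kinematics`, `shape`, `decode`,
#'   `analyze`, `all`.
#' @param out_dir output directory.
#' @return Invisibly, a list of the stage outputs produced.
#' @export
run_pipeline <- function(config, stage = "all", out_dir = "tonguekin_out") {
  stage <- match.arg(stage, c("simulate", "kinematics", "shape", "decode",
                              "analyze", "all"))
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- read_config(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- config$simulation %||% list()
  sim_cfg <- do.call(simulation_config, sim_args)
  seed <- sim_cfg$seed
  ds_dir <- file.path(out_dir, "dataset")
  stages <- if (stage == "all")
    c("simulate", "kinematics", "shape", "decode", "analyze") else stage
  out <- list()

  need_dataset <- function() {
    if (!file.exists(file.path(ds_dir, "landmarks.csv")))
      stop("dataset artifacts not found in ", ds_dir,
           ": run stage 'simulate' first")
    read_dataset(ds_dir)
  }

  if ("simulate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ds <- make_dataset(sim_cfg, dir = ds_dir)
    write_provenance(out_dir, "simulate", config_path, seed)
    pipeline_log("simulate", sprintf("%d trials, %d spikes written to %s",
                                     length(ds$markers), nrow(ds$spikes),
                                     ds_dir), t0)
    out$dataset <- ds
  }
  if ("kinematics" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ds <- out$dataset %||% need_dataset()
    kin <- do.call(rbind, lapply(seq_along(ds$kinematics), function(tr)
      cbind(trial = tr, ds$kinematics[[tr]])))
    utils::write.table(kin, file.path(out_dir, "kinematic_variables.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_provenance(out_dir, "kinematics", config_path, seed)
    pipeline_log("kinematics", sprintf("%d frames x %d variables",
                                       nrow(kin), ncol(kin) - 2), t0)
    out$kinematics <- kin
  }
  if ("shape" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ds <- out$dataset %||% need_dataset()
    ds <- add_shape_scores(ds, k = config$shape$k %||% 7)
    write_shape_space(ds$shape_space, file.path(out_dir, "shape_space.txt"))
    scores <- do.call(rbind, lapply(seq_along(ds$kinematics), function(tr) {
      k <- ds$kinematics[[tr]]
      cbind(trial = tr, k[c("time_s", grep("^shape_pc", names(k),
                                           value = TRUE))])
    }))
    utils::write.table(scores, file.path(out_dir, "shape_scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_provenance(out_dir, "shape", config_path, seed)
    pipeline_log("shape", sprintf("shape space (%d comps) + scores written",
                                  ncol(ds$shape_space$basis)), t0)
    out$dataset <- ds
  }
  if ("decode" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ds <- out$dataset %||% need_dataset()
    dc <- config$decode %||% list()
    vars <- dc$variables %||% standard_variables()
    if (any(grepl("^shape_pc", vars)) && is.null(ds$shape_space)) {
      if (file.exists(file.path(out_dir, "shape_space.txt"))) {
        ds <- add_shape_scores(ds, k = config$shape$k %||% 7,
                               space = read_shape_space(
                                 file.path(out_dir, "shape_space.txt")))
      } else stop("shape variables requested but no shape space found: ",
                  "run stage 'shape' first")
    }
    region <- dc$region %||% "M1"
    pool <- ds$neurons$neuron_id[ds$neurons$region == region]
    n_neur <- min(dc$n_neurons %||% 100, length(pool))
    ens <- sample_neurons(ds, region, n_neur, seed)
    hp <- utils::modifyList(decoder_hyperparams(), dc$hyperparams %||% list())
    folds <- make_folds(seq_along(ds$markers), seed = seed)
    rows <- lapply(vars, function(v) {
      cv <- cross_validate(ds, v, ensemble = ens, hyperparams = hp,
                           seed = seed, folds = folds,
                           n_eval_folds = dc$n_eval_folds)
      data.frame(variable = v, fold = names(cv$fold_fvaf),
                 fvaf = unname(cv$fold_fvaf), ensemble_size = n_neur,
                 region = region, seed = seed)
    })
    res <- do.call(rbind, rows)
    utils::write.table(res, file.path(out_dir, "decoding_results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_provenance(out_dir, "decode", config_path, seed)
    pipeline_log("decode", sprintf("%d variables decoded (mean FVAF %.3f)",
                                   length(vars),
                                   mean(stats::aggregate(
                                     fvaf ~ variable, res, mean)$fvaf)), t0)
    out$decoding <- res
  }
  if ("analyze" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ds <- out$dataset %||% need_dataset()
    an <- config$analyze %||% list()
    which_an <- an$which %||% "region"
    hp <- utils::modifyList(decoder_hyperparams(), an$hyperparams %||% list())
    res <- switch(which_an,
      region = {
        rc <- region_comparison(ds, n = an$n %||% 55, hyperparams = hp,
                                seed = seed,
                                n_eval_folds = an$n_eval_folds)
        utils::write.table(rc$table,
                           file.path(out_dir, "region_comparison.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        rc
      },
      ensemble = {
        ec <- ensemble_sweep(ds, sizes = an$sizes %||%
                               c(1, 2, 5, 10, 15, 25, 35, 50, 75, 100),
                             n_draws = an$n_draws %||% 10,
                             hyperparams = hp, seed = seed,
                             n_eval_folds = an$n_eval_folds)
        utils::write.table(ec$table, file.path(out_dir, "ensemble_sweep.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        ec
      },
      single = {
        sn <- single_neuron_screen(ds, n_neurons = an$n_neurons %||% 40,
                                   hyperparams = hp, seed = seed)
        utils::write.table(sn$accuracies,
                           file.path(out_dir, "single_neuron.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        sn
      },
      jawcontrol = {
        v <- an$variable %||% "roll"
        cv <- cross_validate(ds, v, hyperparams = hp, seed = seed,
                             n_eval_folds = 1, keep_predictions = TRUE)
        fm <- cv$fold_meta[[1]]
        dec <- unlist(cv$predictions[[1]])
        tru <- unlist(variable_series(ds, v, fm$test_trials))
        jaw <- unlist(variable_series(ds, "jaw_pitch", fm$test_trials))
        jc <- jaw_correlation_control(dec, tru, jaw,
                                      window_len = an$window_len %||% 200,
                                      step = an$step %||% 50)
        utils::write.table(jc$windows, file.path(out_dir, "jaw_control.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        jc
      },
      stop("unknown analysis: ", which_an,
           " (use region|ensemble|single|jawcontrol)"))
    write_provenance(out_dir, "analyze", config_path, seed)
    pipeline_log("analyze", sprintf("analysis '%s' written", which_an), t0)
    out$analysis <- res
  }
  invisible(out)
}
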