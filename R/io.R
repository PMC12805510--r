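#' Text serialization, configuration and the experiment driver
#'
#' All artifacts are plain text: trajectory datasets are tab-separated tables
#' with a mandatory JSON metadata sidecar, model checkpoints are JSON with
#' numbers written at 17 significant digits (bit-exact round trips), and
#' experiment configurations are YAML.  Running the same configuration twice
#' produces byte-identical artifacts and manifest hashes.
#'
#' @name esfm_io
NULL

.dataset_format_version <- 1L
.checkpoint_format_version <- 1L

# canonical ordering of trajectory metadata fields, so that re-serialization
# of a read dataset is byte-identical to the original sidecar
.canonical_metadata <- function(md) {
  keys <- c("system", "system_hash", "beta", "dt", "n_steps", "burn_in",
            "stride", "seed", "n_frames", "weight_log_shift")
  out <- list()
  for (k in keys) if (!is.null(md[[k]])) out[[k]] <- md[[k]]
  out
}

.dataset_columns <- function(ds) {
  dim <- ncol(ds$positions)
  cols <- c(paste0("pos_", seq_len(dim)), paste0("fbias_", seq_len(dim)))
  if (!is.null(ds$unbiased_forces))
    cols <- c(cols, paste0("funb_", seq_len(dim)))
  cols <- c(cols, "bias_energy")
  if (!is.null(ds$cv)) cols <- c(cols, paste0("cv_", seq_len(ncol(ds$cv))))
  if (!is.null(ds$weights)) cols <- c(cols, "weight")
  cols
}

#' Write a trajectory dataset as delimited text with a JSON sidecar
#'
#' The table (`<path>`) holds one frame per row: positions, biased forces,
#' unbiased forces (when present), bias energy, CV values (biased runs) and
#' importance weights (when present), all at 17 significant digits so reads
#' reproduce every double bit-exactly.  The sidecar (`<path>.meta.json`)
#' holds the column layout, frame count, an md5 hash of the table, the
#' trajectory metadata and the full bias state (including metadynamics
#' deposits).  Writing the same dataset twice produces byte-identical files.
#'
#' @param dataset a `cg_trajectory` with at least one frame
#' @param path output table path; the sidecar is written next to it
#' @return invisibly, `path`
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "cg_trajectory"))
  validate_trajectory(dataset)
  n <- nrow(dataset$positions)
  assert_that(n >= 1, "refusing to write a dataset with 0 frames")
  blocks <- list(dataset$positions, dataset$biased_forces)
  if (!is.null(dataset$unbiased_forces))
    blocks <- c(blocks, list(dataset$unbiased_forces))
  blocks <- c(blocks, list(matrix(dataset$bias_energy, ncol = 1)))
  if (!is.null(dataset$cv)) blocks <- c(blocks, list(dataset$cv))
  if (!is.null(dataset$weights))
    blocks <- c(blocks, list(matrix(dataset$weights, ncol = 1)))
  tab <- do.call(cbind, blocks)
  cols <- .dataset_columns(dataset)
  assert_that(ncol(tab) == length(cols), "internal column layout mismatch")
  body <- apply(matrix(fmt_num(tab), nrow = n), 1, paste, collapse = "\t")
  writeLines(c(paste(cols, collapse = "\t"), body), path)
  sidecar <- list(
    format_version = .dataset_format_version,
    n_frames = n,
    columns = cols,
    table_md5 = unname(tools::md5sum(path)),
    metadata = .canonical_metadata(dataset$metadata),
    bias = bias_to_list(dataset$bias))
  writeLines(as.character(jsonlite::toJSON(sidecar, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             paste0(path, ".meta.json"))
  invisible(path)
}

# parse a data line, reporting the first offending line/field on failure
.parse_table <- function(path, cols) {
  lines <- readLines(path)
  assert_that(length(lines) >= 2,
              "truncated dataset table '%s': no data rows", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, cols))
    stop_esfm(paste0("dataset table '%s' header does not match its sidecar ",
                     "(line 1: got %d columns [%s...], expected %d)"), path,
              length(header), paste(utils::head(header, 3), collapse = ", "),
              length(cols))
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(cols))) {
    bad <- which(nf != length(cols))[1]
    stop_esfm(paste0("parse error in '%s' at line %d: %d fields, expected ",
                     "%d"), path, bad + 1L, nf[bad], length(cols))
  }
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (anyNA(vals)) {
    flat <- which(is.na(vals))[1] - 1L
    row <- flat %/% length(cols)
    col <- flat %% length(cols) + 1L
    stop_esfm(paste0("parse error in '%s' at line %d, field %d ('%s'): not ",
                     "a number"), path, row + 2L, col,
              parts[[row + 1L]][col])
  }
  matrix(vals, ncol = length(cols), byrow = TRUE, dimnames = list(NULL, cols))
}

#' Read a trajectory dataset written by [write_dataset()]
#'
#' Verifies the sidecar's md5 hash of the table before parsing, and reports
#' parse failures with line and field positions.
#'
#' @param path dataset table path (the sidecar must sit at
#'   `<path>.meta.json`)
#' @return a `cg_trajectory`
#' @export
read_dataset <- function(path) {
  assert_that(file.exists(path), "dataset table '%s' does not exist", path)
  side_path <- paste0(path, ".meta.json")
  assert_that(file.exists(side_path),
              "dataset sidecar '%s' is missing", side_path)
  side <- jsonlite::fromJSON(side_path, simplifyVector = TRUE)
  assert_that(identical(as.integer(side$format_version),
                        .dataset_format_version),
              "unsupported dataset format version %s", side$format_version)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, side$table_md5))
    stop_esfm(paste0("hash mismatch for '%s': table md5 %s but sidecar ",
                     "records %s (table modified or truncated?)"), path, md5,
              side$table_md5)
  cols <- as.character(side$columns)
  tab <- .parse_table(path, cols)
  assert_that(nrow(tab) == side$n_frames,
              "'%s' has %d data rows but the sidecar records %d frames",
              path, nrow(tab), side$n_frames)
  pick <- function(prefix) {
    sel <- grep(paste0("^", prefix, "_[0-9]+$"), cols)
    if (length(sel)) unname(tab[, sel, drop = FALSE]) else NULL
  }
  bias <- bias_from_list(side$bias)
  weights <- if ("weight" %in% cols) as.numeric(tab[, "weight"]) else NULL
  md <- side$metadata
  md$bias <- bias_to_list(bias)
  ds <- structure(
    list(positions = pick("pos"), biased_forces = pick("fbias"),
         unbiased_forces = pick("funb"),
         bias_energy = as.numeric(tab[, "bias_energy"]),
         cv = pick("cv"), weights = weights, bias = bias, metadata = md),
    class = "cg_trajectory")
  validate_trajectory(ds)
  ds
}

#' Write a CG potential checkpoint (bit-exact JSON)
#'
#' Numeric payloads are stored as 17-significant-digit strings, so the model
#' read back predicts identically to the last bit.
#'
#' @param model a `cg_potential`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cg_potential"))
  ck <- list(
    format_version = .checkpoint_format_version,
    layer_sizes = as.integer(model$layer_sizes),
    activation = model$activation,
    rbf_width = fmt_num(model$rbf_width),
    out_scale = fmt_num(model$out_scale %||% 1),
    rbf_centers = fmt_num(model$rbf_centers),
    params = fmt_num(model$params),
    params_md5 = hash_object(fmt_num(model$params)))
  writeLines(as.character(jsonlite::toJSON(ck, auto_unbox = TRUE)), path)
  invisible(path)
}

#' Read a CG potential checkpoint written by [write_checkpoint()]
#' @param path checkpoint path
#' @return a `cg_potential`
#' @export
read_checkpoint <- function(path) {
  assert_that(file.exists(path), "checkpoint '%s' does not exist", path)
  ck <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  assert_that(identical(as.integer(ck$format_version),
                        .checkpoint_format_version),
              "unsupported checkpoint format version %s", ck$format_version)
  params <- as.numeric(ck$params)
  if (!identical(hash_object(fmt_num(params)), ck$params_md5))
    stop_esfm("hash mismatch in checkpoint '%s': parameters corrupted", path)
  sizes <- as.integer(ck$layer_sizes)
  cg_potential_model(centers = as.numeric(ck$rbf_centers),
                     width = as.numeric(ck$rbf_width),
                     hidden = sizes[-c(1L, length(sizes))],
                     params = params,
                     out_scale = as.numeric(ck$out_scale))
}

# ---------------------------------------------------------------------------
# experiment configuration

.config_schema <- list(
  top = c("seed", "system", "sampling", "training", "evaluation"),
  system = c("name", "overrides"),
  sampling = c("bias", "n_steps", "dt", "seed", "stride", "burn_in"),
  bias = c("kind", "kappa", "height", "width", "sigma", "tau", "gamma",
           "center", "cv"),
  training = c("mapping", "n_frames", "n_centers", "hidden", "epochs",
               "batch_size", "lr", "val_frac", "patience", "seed"),
  evaluation = c("n_bins", "n_traj", "n_steps", "dt", "seed", "stride",
                 "oracle_n", "oracle_ortho_n"))

.check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible(TRUE))
  assert_that(is.list(x), "config section '%s' must be a mapping", where)
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop_esfm("unknown config key(s) in %s: %s (allowed: %s)", where,
              paste(extra, collapse = ", "), paste(allowed, collapse = ", "))
  invisible(TRUE)
}

.config_cv <- function(spec, dim, where) {
  if (identical(spec, "dihedral")) return("dihedral")
  assert_that(is.list(spec) && !is.null(spec$axis),
              "%s must be 'dihedral' or a mapping with an 'axis' entry", where)
  .check_keys(spec, "axis", where)
  axis_mapping(as.integer(spec$axis), dim)
}

.config_bias <- function(spec, dim) {
  if (is.null(spec)) return(bias_none())
  .check_keys(spec, .config_schema$bias, "sampling.bias")
  kind <- spec$kind %||% "none"
  if (identical(kind, "none")) return(bias_none())
  cv <- .config_cv(spec$cv, dim, "sampling.bias.cv")
  need <- function(key) {
    assert_that(!is.null(spec[[key]]),
                "sampling.bias of kind '%s' requires '%s'", kind, key)
    spec[[key]]
  }
  switch(kind,
         harmonic_umbrella = bias_umbrella(need("kappa"),
                                           unlist(need("center")), cv),
         gaussian_restraint = bias_gaussian_restraint(need("height"),
                                                      need("width"),
                                                      unlist(need("center")),
                                                      cv),
         wt_metadynamics = bias_wt_metadynamics(need("height"), need("sigma"),
                                                need("tau"), need("gamma"),
                                                cv),
         stop_esfm("unknown bias kind '%s'", kind))
}

#' Read an experiment configuration (YAML)
#' @param path YAML file
#' @return the raw configuration list (validate with [validate_config()])
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), "config file '%s' does not exist", path)
  yaml::read_yaml(path)
}

#' Validate an experiment configuration
#'
#' Checks the schema (unknown keys are rejected at every level), constructs
#' the system, bias and mapping objects so that invalid scientific parameters
#' (e.g. a well-tempered bias factor of 0.5) fail before any simulation, and
#' returns the resolved pieces.
#'
#' @param config configuration list (from [read_config()]) or a YAML path
#' @param seed optional master seed overriding `config$seed`; section seeds
#'   default to master seed + 1, 2, 3 (sampling, training, evaluation)
#' @return list with `config` (echo), `system`, `bias`, `mapping` (NULL when
#'   no training section), and per-stage seeds
#' @export
validate_config <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  .check_keys(config, .config_schema$top, "top level")
  assert_that(!is.null(config$system) && !is.null(config$sampling),
              "config requires 'system' and 'sampling' sections")
  .check_keys(config$system, .config_schema$system, "system")
  .check_keys(config$sampling, .config_schema$sampling, "sampling")
  .check_keys(config$training, .config_schema$training, "training")
  .check_keys(config$evaluation, .config_schema$evaluation, "evaluation")
  assert_that(!is.null(config$system$name), "system.name is required")
  system <- make_builtin_system(config$system$name,
                                config$system$overrides %||% list())
  bias <- .config_bias(config$sampling$bias, system$dim)
  assert_that(!is.null(config$sampling$n_steps),
              "sampling.n_steps is required")
  mapping <- NULL
  if (!is.null(config$training)) {
    assert_that(!is.null(config$training$mapping),
                "training.mapping is required when a training section exists")
    mapping <- .config_cv(config$training$mapping, system$dim,
                          "training.mapping")
    assert_that(inherits(mapping, "cg_mapping"),
                "training.mapping must be a linear (axis) mapping")
  }
  master <- seed %||% config$seed %||% 1L
  assert_that(is.numeric(master) && length(master) == 1L &&
                is.finite(master) && master >= 0 && master < 2^31 - 4,
              "the master seed must lie in [0, 2^31 - 5)")
  master <- as.integer(master)
  list(config = config, system = system, bias = bias, mapping = mapping,
       seed = master,
       seed_sampling = as.integer(config$sampling$seed %||% (master + 1L)),
       seed_training = as.integer((config$training$seed %||% (master + 2L))),
       seed_evaluation = as.integer((config$evaluation$seed %||%
                                       (master + 3L))))
}

# ---------------------------------------------------------------------------
# experiment driver

.file_md5 <- function(dir, files) {
  h <- tools::md5sum(file.path(dir, files))
  stats::setNames(unname(h), files)
}

#' Run a configured experiment end to end
#'
#' Stages: exact oracle (when the mapping permits quadrature), trajectory
#' sampling (with unbiased-force recomputation and importance weights for
#' biased runs), force-matching training, and evaluation against the oracle.
#' Every artifact is plain text in `out_dir`; `manifest.json` records the
#' configuration echo, per-stage seeds and md5 hashes of all outputs.  The
#' manifest contains no timestamps, so re-running an identical configuration
#' reproduces it byte for byte; wall times go to `log.txt` only.  If a stage
#' fails, earlier artifacts are retained and the manifest marks the failed
#' stage before the error is re-signalled.
#'
#' @param config configuration list or YAML path (see [validate_config()])
#' @param out_dir output directory (created if needed)
#' @param seed optional master seed override
#' @param verbose print per-stage progress
#' @return invisibly, the manifest list
#' @export
run_experiment <- function(config, out_dir, seed = NULL, verbose = FALSE) {
  cv <- validate_config(config, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path)
  manifest <- list(format_version = 1L,
                   config = cv$config,
                   seed = cv$seed,
                   stages = list(),
                   status = "ok")
  log_rec <- function(rec) {
    cat(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)),
        "\n", sep = "", file = log_path, append = TRUE)
  }
  finish <- function() {
    writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                             digits = NA, null = "null")),
               file.path(out_dir, "manifest.json"))
  }
  state <- new.env(parent = emptyenv())
  stage <- function(name, seed_used, fun) {
    if (verbose) message("stage ", name, " ...")
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    wall <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      manifest$status <<- paste0("failed at stage '", name, "'")
      log_rec(list(stage = name, status = "failed", seed = seed_used,
                   wall_seconds = wall, error = conditionMessage(res)))
      finish()
      stop_esfm("experiment stage '%s' failed: %s", name,
                conditionMessage(res))
    }
    manifest$stages[[name]] <<- list(status = "ok", seed = seed_used,
                                     outputs = as.list(.file_md5(out_dir,
                                                                 res)))
    log_rec(list(stage = name, status = "ok", seed = seed_used,
                 wall_seconds = wall,
                 outputs = as.list(.file_md5(out_dir, res))))
  }

  if (!is.null(cv$mapping) && cv$system$dim <= 2L) {
    stage("oracle", NA, function() {
      ecfg <- cv$config$evaluation %||% list()
      state$oracle <- compute_oracle(cv$system, cv$mapping,
                                     n = ecfg$oracle_n %||% 2001,
                                     ortho_n = ecfg$oracle_ortho_n %||% 2001)
      write_oracle(state$oracle, file.path(out_dir, "oracle.tsv"))
      "oracle.tsv"
    })
  }

  stage("simulate", cv$seed_sampling, function() {
    scfg <- cv$config$sampling
    ds <- simulate_trajectory(cv$system, cv$bias,
                              n_steps = scfg$n_steps, dt = scfg$dt,
                              seed = cv$seed_sampling,
                              stride = scfg$stride %||% 10L,
                              burn_in = scfg$burn_in)
    if (cv$bias$kind != "none") {
      ds <- recompute_unbiased_forces(ds, cv$system)
      ds <- compute_importance_weights(ds)
    }
    state$dataset <- ds
    write_dataset(ds, file.path(out_dir, "dataset.tsv"))
    c("dataset.tsv", "dataset.tsv.meta.json")
  })

  if (!is.null(cv$config$training)) {
    stage("train", cv$seed_training, function() {
      tcfg <- cv$config$training
      args <- list(dataset = state$dataset, mapping = cv$mapping,
                   system = cv$system, seed = cv$seed_training)
      for (key in c("n_frames", "n_centers", "epochs", "batch_size", "lr",
                    "val_frac", "patience"))
        if (!is.null(tcfg[[key]])) args[[key]] <- tcfg[[key]]
      if (!is.null(tcfg$hidden)) args$hidden <- as.integer(unlist(tcfg$hidden))
      state$fit <- do.call(cg_forcematch, args)
      write_checkpoint(state$fit$model, file.path(out_dir, "model.json"))
      "model.json"
    })
  }

  if (!is.null(cv$config$training) && !is.null(state$oracle)) {
    stage("evaluate", cv$seed_evaluation, function() {
      ecfg <- cv$config$evaluation %||% list()
      rep <- evaluate_model(state$fit, state$oracle, beta = cv$system$beta,
                            n_bins = ecfg$n_bins %||% 50L,
                            n_traj = ecfg$n_traj %||% 20L,
                            n_steps = ecfg$n_steps %||% 10000L,
                            dt = ecfg$dt %||% cv$config$sampling$dt %||%
                              cv$system$dt,
                            stride = ecfg$stride %||% 10L,
                            seed = cv$seed_evaluation)
      write_evaluation_report(rep, file.path(out_dir, "report.json"))
      "report.json"
    })
  }

  finish()
  if (verbose) message("experiment complete: ", out_dir)
  invisible(manifest)
}
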