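# Persistence: parameter sets and run configs as structured text (JSON or
# YAML), per-run output files, and a manifest sufficient to replay a run.

.params_to_list <- function(params) {
  list(
    schema_version = params$schema_version,
    life_table = list(age = params$life_table$age, qx = params$life_table$qx),
    onset_hazard = params$onset_hazard,
    subtype_weights = as.list(params$subtype_weights),
    growth = params$growth,
    insitu_fraction = params$insitu_fraction,
    insitu_progression_prob = params$insitu_progression_prob,
    stage_model = params$stage_model,
    sensitivity = params$sensitivity,
    clinical_detection = params$clinical_detection,
    fp_recall_rate = params$fp_recall_rate,
    biopsy_given_recall = params$biopsy_given_recall,
    neg_biopsy_given_no_cancer = params$neg_biopsy_given_no_cancer,
    survival = list(stage = params$survival$stage,
                    cure = params$survival$cure,
                    rate = params$survival$rate),
    seed = params$seed
  )
}

.params_from_list <- function(x) {
  known <- names(.params_to_list(make_default_params()))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(known, names(x))
  if (length(missing)) {
    stop("config missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  params <- x
  params$schema_version <- as.integer(x$schema_version)
  params$life_table <- tibble::tibble(
    age = as.integer(unlist(x$life_table$age)),
    qx = as.numeric(unlist(x$life_table$qx))
  )
  params$onset_hazard <- as.numeric(unlist(x$onset_hazard))
  params$subtype_weights <- unlist(x$subtype_weights)
  params$survival <- tibble::tibble(
    stage = as.character(unlist(x$survival$stage)),
    cure = as.numeric(unlist(x$survival$cure)),
    rate = as.numeric(unlist(x$survival$rate))
  )
  params$seed <- as.integer(x$seed)
  params <- validate_params(params)
  params
}

.write_structured <- function(x, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path, precision = 15)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

.read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Read and write parameter sets
#'
#' Serializes a parameter set to a structured config file - JSON by default,
#' YAML when the path ends in `.yaml`/`.yml` - with a `schema_version`
#' field. Reading validates the set and rejects unknown or missing fields by
#' name. A JSON write/read round trip reproduces identical values.
#'
#' @param params A parameter set.
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @return `read_params()` the validated parameter set; `write_params()`
#'   `path`, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  .write_structured(.params_to_list(params), path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  .params_from_list(.read_structured(path))
}

#' Load a full run configuration
#'
#' A run config bundles a parameter set, a regimen list and run settings
#' (`n_women`, `seed`, `window`). Unknown keys anywhere in the structure are
#' rejected with an error naming them. The package ships a default config at
#' `system.file("extdata", "default_config.json", package = "mammosim")`.
#'
#' @param path Config file (`.json`, `.yaml` or `.yml`).
#' @return List with elements `params` (validated parameter set), `regimens`
#'   (named list of [regimen()] objects) and `run` (list `n_women`, `seed`,
#'   `window`).
#' @export
load_config <- function(path) {
  x <- .read_structured(path)
  unknown <- setdiff(names(x), c("schema_version", "params", "regimens",
                                 "run"))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(x$params)) stop("config missing field(s): params", call. = FALSE)
  params <- .params_from_list(x$params)
  regimens <- purrr::map(x$regimens, function(r) {
    unknown <- setdiff(names(r), c("name", "phases", "participation"))
    if (length(unknown)) {
      stop("unknown regimen field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    phases <- tibble::as_tibble(r$phases)
    regimen_phases(r$name, phases,
                   participation = r$participation %||% 1)
  })
  run <- x$run %||% list()
  unknown <- setdiff(names(run), c("n_women", "seed", "window"))
  if (length(unknown)) {
    stop("unknown run field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  list(
    params = params,
    regimens = regimens,
    run = list(
      n_women = as.integer(run$n_women %||% 100000L),
      seed = as.integer(run$seed %||% params$seed),
      window = as.numeric(unlist(run$window %||% c(40, 76)))
    )
  )
}

#' Save a full run configuration
#'
#' Inverse of [load_config()]; a save/load round trip reproduces an
#' equivalent configuration.
#'
#' @param config List as returned by [load_config()].
#' @param path Destination file (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- list(
    schema_version = config$params$schema_version,
    params = .params_to_list(config$params),
    regimens = purrr::map(config$regimens, function(r) {
      list(name = r$name,
           phases = as.list(r$phases),
           participation = r$participation)
    }),
    run = config$run
  )
  .write_structured(x, path)
}

#' Stable content hash of a parameter set
#'
#' Folds the canonical JSON serialization of the parameter set through the
#' package's 32-bit mixer; used in run manifests to detect parameter drift.
#'
#' @param params A parameter set.
#' @return Eight-character hex string.
#' @export
params_hash <- function(params) {
  txt <- jsonlite::toJSON(.params_to_list(params), auto_unbox = TRUE,
                          digits = I(17))
  bytes <- as.numeric(utf8ToInt(as.character(txt)))
  h <- 2166136261
  for (i in seq(1, length(bytes), by = 512)) {
    chunk <- bytes[i:min(i + 511, length(bytes))]
    h <- .fmix32(.xor32(h, sum(chunk * (seq_along(chunk) %% 97 + 1)) %% .M32))
  }
  sprintf("%08x", h)
}

#' Write run outputs and a reproducibility manifest
#'
#' Writes, under `outdir`: `outcomes.csv` (per-regimen outcome counts),
#' `stage_table.csv` (stage distribution per 100,000, published-table
#' layout), `report.csv` and `report.json` (the comparison report), the
#' parameter set (`params.json`) and `manifest.json` recording seed, cohort
#' size, window, regimen definitions, parameter hash and package version -
#' enough to replay the run bit-for-bit with [run_from_manifest()].
#'
#' @param outcomes Outcomes tibble from [compare_regimens()].
#' @param report Report tibble from [build_report()].
#' @param outdir Output directory (created if needed).
#' @param params Parameter set used for the run.
#' @param regimens Named list of [regimen()] objects used.
#' @param seed,n_women,window Run settings to record.
#' @return Named character vector of written paths, invisibly.
#' @export
write_outputs <- function(outcomes, report, outdir, params, regimens,
                          seed, n_women, window = c(40, 76)) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(
    outcomes = file.path(outdir, "outcomes.csv"),
    stage_table = file.path(outdir, "stage_table.csv"),
    report_csv = file.path(outdir, "report.csv"),
    report_json = file.path(outdir, "report.json"),
    params = file.path(outdir, "params.json"),
    manifest = file.path(outdir, "manifest.json")
  )
  utils::write.csv(outcomes, paths["outcomes"], row.names = FALSE)
  utils::write.csv(stage_table(outcomes), paths["stage_table"],
                   row.names = FALSE)
  utils::write.csv(report, paths["report_csv"], row.names = FALSE)
  jsonlite::write_json(report, paths["report_json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_params(params, paths["params"])
  manifest <- list(
    schema_version = params$schema_version,
    package_version = as.character(utils::packageVersion("mammosim")),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    n_women = n_women,
    window = window,
    params_hash = params_hash(params),
    params_file = "params.json",
    regimens = purrr::map(regimens, function(r) {
      list(name = r$name, phases = as.list(r$phases),
           participation = r$participation)
    }),
    outputs = as.list(basename(paths[names(paths) != "manifest"]))
  )
  .write_structured(manifest, paths["manifest"])
  invisible(paths)
}

#' Replay a run from its manifest
#'
#' Re-runs the simulation recorded in a manifest (parameters, regimens,
#' seed, cohort size, window) and writes the same set of output files to a
#' new directory. Because all randomness is counter-based, the regenerated
#' CSVs are byte-identical to the originals apart from the manifest
#' timestamp.
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_outputs()].
#' @param outdir Directory for the regenerated outputs.
#' @return Named character vector of written paths, invisibly.
#' @export
run_from_manifest <- function(manifest_path, outdir) {
  m <- .read_structured(manifest_path)
  params <- read_params(file.path(dirname(manifest_path), m$params_file))
  stopifnot(identical(params_hash(params), m$params_hash))
  regimens <- purrr::map(m$regimens, function(r) {
    regimen_phases(r$name, tibble::as_tibble(r$phases),
                   participation = r$participation)
  })
  window <- as.numeric(unlist(m$window))
  outcomes <- compare_regimens(params, regimens, n_women = m$n_women,
                               seed = m$seed, window = window)
  report <- build_report(outcomes, baseline = regimens[[1]]$name)
  write_outputs(outcomes, report, outdir, params, regimens,
                seed = m$seed, n_women = m$n_women, window = window)
}
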