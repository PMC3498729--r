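#' Run manifest for a pipeline output directory
#'
#' Every pipeline run writes exactly one `manifest.json` into its output
#' directory recording the package version, a hash of the configuration, the
#' input paths, the seeds in play, and a timestamp, so results can be traced
#' back to their inputs.
#'
#' @param config The configuration list of the run.
#' @param input_paths Character vector of input file paths.
#' @param seeds Integer vector of seeds used (may be empty).
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(config, input_paths = character(0), seeds = integer(0)) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  structure(list(
    tool_version = as.character(packageVersion("paradiv")),
    config_hash = unname(tools::md5sum(tmp)),
    input_paths = input_paths,
    seeds = seeds,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param dir Output directory.
#' @export
write_manifest <- function(manifest, dir) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) pd_io_error(sprintf("manifest not found in %s", dir))
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "run_manifest")
}

#' Run the configured analysis stages end to end
#'
#' Executes any of the `profile`, `compare` and `share` stages named in the
#' configuration, writing each stage's outputs and a single run manifest
#' into `out`. The configuration is a named list (or a path to a YAML/JSON
#' file holding one) with optional entries:
#' \describe{
#'   \item{profile}{list with `alignment` (aligned FASTA), `roles` (role-map
#'     TSV), optional `mode` (`"identity"`/`"groups"`) and `subfamily` (name
#'     recorded on the profile; defaults to the FASTA file name).}
#'   \item{compare}{list with `annotations`, `territories`, `stage_map`
#'     (TSV paths), `subfamily` (scalar or vector), optional `aggregation`.}
#'   \item{share}{list with `matrix` (presence-matrix TSV) — or omit
#'     `matrix` to reuse the matrix derived by `compare` inputs.}
#' }
#'
#' @param config Named list or path to a YAML/JSON configuration file.
#' @param out Output directory (created if needed).
#' @param seed Optional integer seed recorded in the manifest and applied
#'   before any stage that draws random numbers.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config, out, seed = NULL) {
  if (is.character(config)) {
    path <- config
    if (!file.exists(path)) pd_io_error(sprintf("config file not found: %s", path))
    config <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        pd_io_error("reading YAML configs requires the 'yaml' package")
      }
      yaml::read_yaml(path)
    }
  }
  if (!is.list(config)) pd_validation_error("config must be a named list")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (!is.null(config$profile)) {
    p <- config$profile
    aln <- read_subfamily_alignment(p$alignment, p$roles,
                                    subfamily = p$subfamily)
    mode <- if (is.null(p$mode)) "identity" else p$mode
    prof <- profile_alignment(aln, match_policy(mode))
    write_profile(prof, out)
    inputs <- c(inputs, p$alignment, p$roles)
  }
  if (!is.null(config$compare)) {
    cmp <- config$compare
    ann <- read_annotations(cmp$annotations)
    terr <- read_territories(cmp$territories)
    sm <- if (is.null(cmp$stage_map)) default_stage_map() else read_stage_map(cmp$stage_map)
    agg <- if (is.null(cmp$aggregation)) "union" else cmp$aggregation
    for (sf in cmp$subfamily) {
      res <- compare_subfamily(ann, sf, terr, sm, agg)
      write_comparison(res, out)
    }
    m <- build_presence_matrix(ann, terr)
    write_presence_matrix(m, file.path(out, "presence_matrix.tsv"))
    inputs <- c(inputs, cmp$annotations, cmp$territories, cmp$stage_map)
  }
  if (!is.null(config$share)) {
    m <- if (!is.null(config$share$matrix)) {
      inputs <- c(inputs, config$share$matrix)
      read_presence_matrix(config$share$matrix)
    } else if (file.exists(file.path(out, "presence_matrix.tsv"))) {
      read_presence_matrix(file.path(out, "presence_matrix.tsv"))
    } else {
      pd_validation_error("share stage needs a 'matrix' path or a preceding compare stage")
    }
    write_sharing_report(shared_territories(m), out)
  }
  manifest <- run_manifest(config, input_paths = inputs,
                           seeds = if (is.null(seed)) integer(0) else as.integer(seed))
  write_manifest(manifest, out)
  invisible(out)
}
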