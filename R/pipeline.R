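#' Read and validate a pipeline run configuration
#'
#' The YAML configuration has top-level blocks `paths` (matrix, metadata,
#' x_axis, y_axis, out_dir), `params` (toggle-switch constants and
#' integration settings, see [toggle_params()]), `scaling`
#' (`pooled: true/false`), `selection` (`immunogenic_pool`,
#' `tolerogenic_pool`, `condition_pair`), `synth` (see [synth_config()])
#' and `seed`. Unknown keys are rejected; all validation failures are
#' reported at once.
#'
#' @param path Path to the YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  validate_run_config(yaml::read_yaml(path))
}

known_blocks <- c("paths", "params", "scaling", "selection", "synth", "seed",
                  "log_level")

validate_run_config <- function(cfg) {
  errs <- character()
  unknown <- setdiff(names(cfg), known_blocks)
  if (length(unknown))
    errs <- c(errs, paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", ")))
  if (!is.null(cfg$params)) {
    pv <- tryCatch({ do.call(toggle_params, cfg$params); NULL },
                   error = function(e) conditionMessage(e))
    if (!is.null(pv)) errs <- c(errs, paste0("params: ", pv))
  }
  if (!is.null(cfg$synth)) {
    sv <- tryCatch({ build_synth_config(cfg$synth, cfg$seed); NULL },
                   error = function(e) conditionMessage(e))
    if (!is.null(sv)) errs <- c(errs, paste0("synth: ", sv))
  }
  for (p in c("matrix", "metadata", "x_axis", "y_axis")) {
    f <- cfg$paths[[p]]
    if (!is.null(f) && !file.exists(f))
      errs <- c(errs, paste0("paths$", p, ": file not found: ", f))
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(cfg, class = "run_config")
}

build_synth_config <- function(synth, seed = NULL) {
  synth <- synth %||% list()
  if (!is.null(synth$conditions))
    synth$conditions <- lapply(synth$conditions, unlist)
  if (!is.null(synth$n_cells_per_condition))
    synth$n_cells_per_condition <- unlist(synth$n_cells_per_condition)
  if (!is.null(seed) && is.null(synth$seed)) synth$seed <- seed
  do.call(synth_config, synth)
}

#' Run a pipeline stage and write its artifacts
#'
#' Dispatches one of the five stages over a validated configuration:
#' \describe{
#'   \item{model}{fixed points (`fixed_points.tsv`) and basin map
#'     (`basin_map.tsv`) of the configured dynamical system}
#'   \item{score}{per-cell signature scores for both axes (`scores.tsv`)}
#'   \item{classify}{per-cell fates (`cell_fates.tsv`) and per-condition
#'     proportions (`proportions.json`)}
#'   \item{select}{ranked TF-combination models (`model_ranking.tsv`)}
#'   \item{synth}{a synthetic fixture bundle via [write_fixture()]}
#' }
#' Every run writes `manifest.json` (configuration echo, package version,
#' md5 checksums of the inputs, timestamp) into the output directory.
#'
#' @param config A `run_config` (from [read_run_config()]) or a list with
#'   the same structure.
#' @param subcommand One of `"model"`, `"score"`, `"classify"`,
#'   `"select"`, `"synth"`.
#' @param out_dir Output directory; overrides `config$paths$out_dir`.
#' @return Invisibly, a named list of the written artifact paths.
#' @export
run_pipeline <- function(config,
                         subcommand = c("classify", "model", "score",
                                        "select", "synth"),
                         out_dir = NULL) {
  subcommand <- match.arg(subcommand)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  out_dir <- out_dir %||% config$paths$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- do.call(toggle_params, config$params %||% list())
  artifacts <- list()

  load_inputs <- function() {
    for (p in c("matrix", "metadata", "x_axis", "y_axis"))
      if (is.null(config$paths[[p]]))
        stop("'", subcommand, "' requires paths$", p, call. = FALSE)
    mat <- read_expression(config$paths$matrix)
    if (mat$layer_tag == "counts") mat <- normalize_counts(mat)
    list(mat = mat,
         metadata = read_metadata(config$paths$metadata),
         x_axis = read_signature(config$paths$x_axis, "immunogenic_axis"),
         y_axis = read_signature(config$paths$y_axis, "tolerogenic_axis"))
  }

  if (subcommand == "model") {
    fp <- find_fixed_points(params)
    bm <- basin_map(params)
    artifacts$fixed_points <- file.path(out_dir, "fixed_points.tsv")
    utils::write.table(as.data.frame(fp), artifacts$fixed_points,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts$basin_map <- file.path(out_dir, "basin_map.tsv")
    utils::write.table(as.data.frame(bm), artifacts$basin_map,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (subcommand == "score") {
    inp <- load_inputs()
    artifacts$scores <- file.path(out_dir, "scores.tsv")
    write_scores(list(immunogenic = score_signature(inp$mat, inp$x_axis),
                      tolerogenic = score_signature(inp$mat, inp$y_axis)),
                 inp$metadata, artifacts$scores)
  } else if (subcommand == "classify") {
    inp <- load_inputs()
    res <- classify_cells(inp$mat, inp$metadata, inp$x_axis, inp$y_axis,
                          params,
                          pooled_scaling = config$scaling$pooled %||% TRUE)
    artifacts$cell_fates <- file.path(out_dir, "cell_fates.tsv")
    utils::write.table(res$cells, artifacts$cell_fates, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts$proportions <- file.path(out_dir, "proportions.json")
    jsonlite::write_json(split(res$proportions[, c("fate", "count",
                                                   "proportion")],
                               res$proportions$condition),
                         artifacts$proportions, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  } else if (subcommand == "select") {
    inp <- load_inputs()
    sel <- config$selection %||% list()
    cand <- enumerate_models(
      sel$immunogenic_pool %||% c("IRF1", "IRF4"),
      sel$tolerogenic_pool %||% c("KRAS", "SOX4", "IRF4", "RELB", "ELK1"))
    rk <- evaluate_models(cand, inp$mat, inp$metadata, params,
                          unlist(sel$condition_pair %||%
                                   c("unstimulated", "TNF")))
    artifacts$model_ranking <- file.path(out_dir, "model_ranking.tsv")
    utils::write.table(as.data.frame(rk), artifacts$model_ranking,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (subcommand == "synth") {
    pop <- generate_population(build_synth_config(config$synth, config$seed))
    write_fixture(pop, out_dir)
    artifacts$fixture <- out_dir
  }

  artifacts$manifest <- file.path(out_dir, "manifest.json")
  write_manifest(config, subcommand, artifacts, artifacts$manifest)
  invisible(artifacts)
}

write_manifest <- function(config, subcommand, artifacts, path) {
  inputs <- unlist(config$paths[c("matrix", "metadata", "x_axis", "y_axis")])
  checksums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(subcommand = subcommand,
         package_version =
           as.character(utils::packageVersion("togglefate")),
         config = unclass(config),
         input_md5 = checksums,
         artifacts = unlist(artifacts[names(artifacts) != "manifest"]),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
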