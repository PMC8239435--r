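#' Configuration for the synthetic UMI-count generator
#'
#' Describes a droplet-style single-cell experiment with three latent fate
#' states (immunogenic, tolerogenic, ambivalent). Programme-defining genes
#' (the axis transcription factors plus additional signature genes) are
#' negative-binomially distributed around a base mean, multiplicatively
#' lifted in cells of the matching fate; ambivalent cells carry an
#' intermediate lift (`sqrt(effect_size)`) on both programmes, which places
#' them near the diagonal of the score space. Per-cell sequencing-depth
#' variation is lognormal.
#'
#' The default condition layout mirrors a two-condition stimulation
#' experiment: an unstimulated population with a near-equal three-way fate
#' split and a TNF-stimulated population with an increased immunogenic and
#' decreased tolerogenic fraction.
#'
#' @param conditions Named list: per condition, a length-3 probability
#'   vector over (immunogenic, tolerogenic, ambivalent).
#' @param n_cells_per_condition Cells per condition; a single number or a
#'   named vector aligned with `conditions`.
#' @param tf_genes_x,tf_genes_y Transcription-factor symbols defining the
#'   immunogenic (x) and tolerogenic (y) axes. A symbol may appear on both
#'   axes; it is then lifted in both single-programme fates.
#' @param n_signature_genes Additional programme-specific genes per axis
#'   (named `IMM01..`, `TOL01..`), carrying the same lifts as the axis TFs.
#'   The default of 200 matches the scale of a programme-level expression
#'   signature (order 10^2 genes) and keeps the planted three-state
#'   structure identifiable from the aggregate z-score at the default
#'   effect size; axes built from the handful of TFs alone give
#'   directionally correct but attenuated proportions.
#' @param n_background_genes Unstructured background genes (`BG0001..`).
#' @param base_mean Negative-binomial mean of an unlifted gene at unit
#'   depth.
#' @param effect_size Multiplicative lift (fold, >= 1) of programme genes in
#'   their matching fate; `effect_size = 1` gives a structureless null.
#' @param dispersion Negative-binomial size parameter (inverse dispersion;
#'   smaller = noisier).
#' @param depth_variation Lognormal sigma of per-cell size factors (0 =
#'   uniform depth); size factors have unit mean.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return A `synth_config` object.
#' @export
synth_config <- function(conditions = list(
                           unstimulated = c(immunogenic = 0.3493,
                                            tolerogenic = 0.3360,
                                            ambivalent = 0.3147),
                           TNF = c(immunogenic = 0.4199,
                                   tolerogenic = 0.1796,
                                   ambivalent = 0.4005)),
                         n_cells_per_condition = c(unstimulated = 375,
                                                   TNF = 362),
                         tf_genes_x = c("IRF1", "IRF4"),
                         tf_genes_y = c("KRAS", "SOX4", "IRF4", "RELB",
                                        "ELK1"),
                         n_signature_genes = 200,
                         n_background_genes = 200,
                         base_mean = 2,
                         effect_size = 4,
                         dispersion = 2,
                         depth_variation = 0.3,
                         seed = 1L) {
  if (!is.list(conditions) || is.null(names(conditions)))
    stop("'conditions' must be a named list of fate-proportion vectors",
         call. = FALSE)
  conditions <- lapply(conditions, function(p) {
    p <- unname(as.numeric(p))
    if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop("each condition needs 3 non-negative proportions summing to 1",
           call. = FALSE)
    p / sum(p)
  })
  if (length(n_cells_per_condition) == 1L)
    n_cells_per_condition <- stats::setNames(
      rep(n_cells_per_condition, length(conditions)), names(conditions))
  if (!all(names(conditions) %in% names(n_cells_per_condition)))
    stop("'n_cells_per_condition' must cover every condition", call. = FALSE)
  if (effect_size < 1) stop("'effect_size' must be >= 1", call. = FALSE)
  for (f in c("base_mean", "dispersion"))
    if (get(f) <= 0) stop("'", f, "' must be positive", call. = FALSE)
  if (depth_variation < 0)
    stop("'depth_variation' must be non-negative", call. = FALSE)
  structure(list(conditions = conditions,
                 n_cells_per_condition = n_cells_per_condition,
                 tf_genes_x = tf_genes_x, tf_genes_y = tf_genes_y,
                 n_signature_genes = as.integer(n_signature_genes),
                 n_background_genes = as.integer(n_background_genes),
                 base_mean = base_mean, effect_size = effect_size,
                 dispersion = dispersion, depth_variation = depth_variation,
                 seed = as.integer(seed)),
            class = "synth_config")
}

fate_levels <- c("immunogenic", "tolerogenic", "ambivalent")

#' Generate a synthetic single-cell population with known fate structure
#'
#' Draws, per cell: a latent fate from the condition's fate proportions, a
#' lognormal size factor, and negative-binomial counts for every gene with
#' mean `base_mean * size_factor * lift`. The lift is `effect_size` for
#' x-programme genes in immunogenic cells and y-programme genes in
#' tolerogenic cells, `sqrt(effect_size)` for both programmes in ambivalent
#' cells, and 1 otherwise.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_population`: `matrix`
#'   (counts [expression_matrix()]), `metadata` (cell_id, condition),
#'   `truth` (per-cell latent fate and the generating proportions as
#'   attribute `"proportions"`), and the echoed `config`.
#' @export
generate_population <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  sig_x <- if (config$n_signature_genes > 0)
    sprintf("IMM%02d", seq_len(config$n_signature_genes)) else character()
  sig_y <- if (config$n_signature_genes > 0)
    sprintf("TOL%02d", seq_len(config$n_signature_genes)) else character()
  bg <- if (config$n_background_genes > 0)
    sprintf("BG%04d", seq_len(config$n_background_genes)) else character()
  x_prog <- unique(c(config$tf_genes_x, sig_x))
  y_prog <- unique(c(config$tf_genes_y, sig_y))
  genes <- unique(c(x_prog, y_prog, bg))
  G <- length(genes)
  in_x <- genes %in% x_prog
  in_y <- genes %in% y_prog

  cells <- character(); conds <- character(); fates <- character()
  counts <- NULL
  for (cn in names(config$conditions)) {
    n <- config$n_cells_per_condition[[cn]]
    fate <- sample(fate_levels, n, replace = TRUE,
                   prob = config$conditions[[cn]])
    sf <- if (config$depth_variation > 0)
      stats::rlnorm(n, meanlog = -config$depth_variation^2 / 2,
                    sdlog = config$depth_variation) else rep(1, n)
    ## lift matrix: cells x genes
    lift <- matrix(1, n, G)
    E <- config$effect_size
    lift[fate == "immunogenic", in_x] <- E
    lift[fate == "tolerogenic", in_y] <- E
    lift[fate == "ambivalent", in_x | in_y] <- sqrt(E)
    mu <- config$base_mean * sf * lift
    cm <- matrix(stats::rnbinom(n * G, mu = mu, size = config$dispersion),
                 n, G)
    counts <- rbind(counts, cm)
    cells <- c(cells, sprintf("%s_cell%04d", cn, seq_len(n)))
    conds <- c(conds, rep(cn, n))
    fates <- c(fates, fate)
  }
  mat <- expression_matrix(counts, gene_ids = genes, cell_ids = cells,
                           layer_tag = "counts")
  metadata <- data.frame(cell_id = cells, condition = conds,
                         stringsAsFactors = FALSE)
  truth <- data.frame(cell_id = cells, condition = conds, fate = fates,
                      stringsAsFactors = FALSE)
  attr(truth, "proportions") <- config$conditions
  structure(list(matrix = mat, metadata = metadata, truth = truth,
                 config = config),
            class = "synth_population")
}

#' @export
print.synth_population <- function(x, ...) {
  cat(sprintf("synth_population: %d cells x %d genes, conditions: %s\n",
              length(x$matrix$cell_ids), length(x$matrix$gene_ids),
              paste(names(x$config$conditions), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic population to disk as a reusable fixture
#'
#' Writes the MTX triplet (`matrix.mtx`, `genes.tsv`, `barcodes.tsv`), the
#' cell metadata (`metadata.tsv`), the ground-truth fates (`truth.tsv`) and
#' the generating configuration (`config.yaml`), so that the fixture can be
#' reproduced bit-exactly from the echoed configuration.
#'
#' @param population A `synth_population` from [generate_population()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(population, out_dir) {
  stopifnot(inherits(population, "synth_population"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(population$matrix, file.path(out_dir, "matrix.mtx"))
  utils::write.table(population$metadata, file.path(out_dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(population$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- population$config
  cfg_list <- unclass(cfg)
  cfg_list$conditions <- lapply(cfg_list$conditions, as.list)
  cfg_list$n_cells_per_condition <- as.list(cfg_list$n_cells_per_condition)
  yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Planted axis signatures of a synthetic configuration
#'
#' The gene signatures that the generator actually lifted: axis TFs plus
#' the programme-specific signature genes. Scoring cells with these
#' signatures is the matched analysis of a synthetic population.
#'
#' @param config A [synth_config()].
#' @return List with elements `x` and `y`, each a [gene_signature()].
#' @export
synth_axes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sig <- function(tfs, prefix, name) {
    extra <- if (config$n_signature_genes > 0)
      sprintf("%s%02d", prefix, seq_len(config$n_signature_genes))
    else character()
    gene_signature(unique(c(tfs, extra)), name)
  }
  list(x = sig(config$tf_genes_x, "IMM", "immunogenic_axis"),
       y = sig(config$tf_genes_y, "TOL", "tolerogenic_axis"))
}

#' Rebuild a synth_config from an echoed config.yaml
#'
#' @param path Path to a `config.yaml` written by [write_fixture()].
#' @return A [synth_config()].
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$conditions <- lapply(y$conditions, unlist)
  y$n_cells_per_condition <- unlist(y$n_cells_per_condition)
  do.call(synth_config, y)
}
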