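#' Per-cell signature z-scores
#'
#' For each signature gene present in the matrix and varying across cells,
#' expression is standardized across cells (gene mean subtracted, divided by
#' the population standard deviation, i.e. dividing by n). The per-cell
#' signature score is the unweighted mean of these per-gene z-scores —
#' the standard "signature z-score" construction. Genes absent from the
#' matrix or constant across cells are dropped with a warning.
#'
#' @param mat An [expression_matrix()] with `layer_tag = "normalized"`.
#' @param signature A [gene_signature()].
#' @return Named numeric vector of per-cell scores (names = cell barcodes),
#'   with the genes actually used attached as attribute `"genes_used"`.
#' @examples
#' m <- expression_matrix(matrix(c(0, 2), 2, 1,
#'                               dimnames = list(c("c1", "c2"), "IRF1")),
#'                        layer_tag = "normalized")
#' score_signature(m, gene_signature("IRF1"))  # c1 = -1, c2 = +1
#' @export
score_signature <- function(mat, signature) {
  stopifnot(inherits(mat, "expression_matrix"),
            inherits(signature, "gene_signature"))
  if (mat$layer_tag != "normalized")
    stop("score_signature expects a normalized layer; run normalize_counts()",
         call. = FALSE)
  present <- intersect(signature$genes, mat$gene_ids)
  absent <- setdiff(signature$genes, mat$gene_ids)
  if (!length(present))
    stop("no gene of signature '", signature$name, "' present in the matrix",
         call. = FALSE)
  sub <- mat$values[, present, drop = FALSE]
  mu <- colMeans(sub)
  sd_pop <- sqrt(colMeans(sweep(sub, 2, mu)^2))
  constant <- present[sd_pop < .Machine$double.eps * 100]
  dropped <- c(absent, constant)
  if (length(dropped))
    warning("signature '", signature$name, "': dropped ",
            length(dropped), " gene(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  keep <- setdiff(present, constant)
  if (!length(keep))
    stop("all present genes of signature '", signature$name,
         "' have zero variance", call. = FALSE)
  z <- sweep(sweep(sub[, keep, drop = FALSE], 2, mu[keep]), 2,
             sd_pop[keep], "/")
  scores <- rowMeans(z)
  names(scores) <- mat$cell_ids
  attr(scores, "genes_used") <- keep
  scores
}

#' Compare signature scores between two conditions
#'
#' Reports the per-group medians of the raw scores, their ratio
#' (`median_b / median_a`, the fold change, conventionally reported to two
#' decimals) and a two-sided Mann-Whitney (Wilcoxon rank-sum) p-value.
#'
#' @param scores Named per-cell score vector, as from [score_signature()].
#' @param metadata Cell-metadata data frame with `cell_id` and `condition`.
#' @param group_a,group_b Condition labels to compare (a = reference).
#' @return A list of class `condition_comparison`: `group_a`, `group_b`,
#'   `n_a`, `n_b`, `median_a`, `median_b`, `fold_change` (unrounded) and
#'   `p_value`.
#' @export
compare_conditions <- function(scores, metadata, group_a, group_b) {
  idx <- match(names(scores), metadata$cell_id)
  if (any(is.na(idx)))
    stop("scored cells missing from metadata", call. = FALSE)
  cond <- metadata$condition[idx]
  for (g in c(group_a, group_b))
    if (!any(cond == g))
      stop("unknown or empty group label: ", g, call. = FALSE)
  sa <- scores[cond == group_a]
  sb <- scores[cond == group_b]
  wt <- stats::wilcox.test(sb, sa, exact = FALSE)
  structure(list(group_a = group_a, group_b = group_b,
                 n_a = length(sa), n_b = length(sb),
                 median_a = stats::median(sa), median_b = stats::median(sb),
                 fold_change = stats::median(sb) / stats::median(sa),
                 p_value = wt$p.value),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("%s (n=%d, median=%.4f) vs %s (n=%d, median=%.4f)\n",
              x$group_a, x$n_a, x$median_a, x$group_b, x$n_b, x$median_b))
  cat(sprintf("  fold change = %.2f, Mann-Whitney p = %.3g\n",
              x$fold_change, x$p_value))
  invisible(x)
}

#' Write per-cell scores as TSV
#'
#' @param scores Named list of score vectors (one element per signature),
#'   or a single score vector.
#' @param metadata Cell-metadata data frame.
#' @param path Output TSV path.
#' @return The written data frame, invisibly.
#' @export
write_scores <- function(scores, metadata, path) {
  if (!is.list(scores)) scores <- list(score = scores)
  cells <- names(scores[[1]])
  idx <- match(cells, metadata$cell_id)
  df <- data.frame(cell_id = cells, condition = metadata$condition[idx],
                   stringsAsFactors = FALSE)
  for (nm in names(scores)) df[[nm]] <- unname(scores[[nm]][cells])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
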