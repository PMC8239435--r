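#' Enumerate candidate transcription-factor toggle models
#'
#' Builds every candidate pairing of an immunogenic-axis TF set with a
#' tolerogenic-axis TF set. Immunogenic candidates are the non-empty
#' subsets of `immunogenic_pool` that contain its first element (the anchor
#' TF, by default IRF1 alone or together with IRF4); tolerogenic candidates
#' are all non-empty subsets of `tolerogenic_pool`. With the default pools
#' this yields 2 x (2^5 - 1) = 62 candidates with deterministic, stable
#' model ids.
#'
#' @param immunogenic_pool Character vector; first element is the anchor.
#' @param tolerogenic_pool Character vector.
#' @return A list of `candidate_model` objects (`model_id`,
#'   `immunogenic_tfs`, `tolerogenic_tfs`).
#' @export
enumerate_models <- function(immunogenic_pool = c("IRF1", "IRF4"),
                             tolerogenic_pool = c("KRAS", "SOX4", "IRF4",
                                                  "RELB", "ELK1")) {
  if (!length(immunogenic_pool) || !length(tolerogenic_pool))
    stop("empty TF pool", call. = FALSE)
  anchor <- immunogenic_pool[1]
  others <- immunogenic_pool[-1]
  imm_sets <- list(anchor)
  if (length(others)) {
    for (k in seq_along(others)) {
      cmb <- utils::combn(others, k, simplify = FALSE)
      imm_sets <- c(imm_sets, lapply(cmb, function(s) c(anchor, s)))
    }
  }
  tol_sets <- list()
  for (k in seq_along(tolerogenic_pool)) {
    tol_sets <- c(tol_sets,
                  utils::combn(tolerogenic_pool, k, simplify = FALSE))
  }
  out <- list(); id <- 0L
  for (im in imm_sets) {
    for (tl in tol_sets) {
      id <- id + 1L
      out[[id]] <- structure(list(model_id = id, immunogenic_tfs = im,
                                  tolerogenic_tfs = tl),
                             class = "candidate_model")
    }
  }
  out
}

#' @export
print.candidate_model <- function(x, ...) {
  cat(sprintf("model %d: x = {%s}  vs  y = {%s}\n", x$model_id,
              paste(x$immunogenic_tfs, collapse = ", "),
              paste(x$tolerogenic_tfs, collapse = ", ")))
  invisible(x)
}

#' Evaluate and rank candidate TF-combination models
#'
#' Runs the full fate classification ([classify_cells()]) once per
#' candidate and scores each against two directional selection criteria on
#' a stimulated-vs-unstimulated condition pair: (1) the stimulated
#' immunogenic fraction exceeds the unstimulated one; (2) the stimulated
#' tolerogenic fraction is below the unstimulated one. Candidates are
#' ranked by number of criteria satisfied, then by the margin
#' `(delta immunogenic) + (-delta tolerogenic)`; ties break on model id.
#' A candidate none of whose axis genes are present in the matrix is
#' marked unevaluable rather than aborting the run.
#'
#' @param candidates List of `candidate_model`s from [enumerate_models()].
#' @param mat An [expression_matrix()].
#' @param metadata Cell metadata (`cell_id`, `condition`).
#' @param params A [toggle_params()].
#' @param condition_pair Length-2 character: (unstimulated, stimulated).
#' @return A data frame of class `model_ranking`, one row per candidate in
#'   rank order: TF sets, per-condition fate proportions, `criterion_1`,
#'   `criterion_2`, `margin`, `evaluable`, `rank`.
#' @export
evaluate_models <- function(candidates, mat, metadata,
                            params = toggle_params(),
                            condition_pair = c("unstimulated", "TNF")) {
  stopifnot(length(condition_pair) == 2)
  if (!all(condition_pair %in% metadata$condition))
    stop("condition(s) absent from metadata: ",
         paste(setdiff(condition_pair, metadata$condition), collapse = ", "),
         call. = FALSE)
  if (mat$layer_tag == "counts") mat <- normalize_counts(mat)
  rows <- lapply(candidates, function(cm) {
    row <- data.frame(
      model_id = cm$model_id,
      immunogenic_tfs = paste(cm$immunogenic_tfs, collapse = "+"),
      tolerogenic_tfs = paste(cm$tolerogenic_tfs, collapse = "+"),
      imm_unstim = NA_real_, tol_unstim = NA_real_, amb_unstim = NA_real_,
      imm_stim = NA_real_, tol_stim = NA_real_, amb_stim = NA_real_,
      criterion_1 = NA, criterion_2 = NA, margin = NA_real_,
      evaluable = FALSE, stringsAsFactors = FALSE)
    res <- tryCatch(
      suppressWarnings(classify_cells(
        mat, metadata,
        gene_signature(cm$immunogenic_tfs, "immunogenic_axis"),
        gene_signature(cm$tolerogenic_tfs, "tolerogenic_axis"),
        params)),
      error = function(e) NULL)
    if (is.null(res)) return(row)
    pr <- res$proportions
    gp <- function(cond, fate)
      pr$proportion[pr$condition == cond & pr$fate == fate]
    row$imm_unstim <- gp(condition_pair[1], "immunogenic")
    row$tol_unstim <- gp(condition_pair[1], "tolerogenic")
    row$amb_unstim <- gp(condition_pair[1], "ambivalent")
    row$imm_stim <- gp(condition_pair[2], "immunogenic")
    row$tol_stim <- gp(condition_pair[2], "tolerogenic")
    row$amb_stim <- gp(condition_pair[2], "ambivalent")
    row$criterion_1 <- row$imm_stim > row$imm_unstim
    row$criterion_2 <- row$tol_stim < row$tol_unstim
    row$margin <- (row$imm_stim - row$imm_unstim) +
      (row$tol_unstim - row$tol_stim)
    row$evaluable <- TRUE
    row
  })
  out <- do.call(rbind, rows)
  n_crit <- rowSums(cbind(out$criterion_1, out$criterion_2), na.rm = TRUE)
  n_crit[!out$evaluable] <- -1
  ord <- order(-n_crit, -ifelse(is.na(out$margin), -Inf, out$margin),
               out$model_id)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("model_ranking", "data.frame")
  out
}
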