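#' Scale raw signature scores into phase-portrait coordinates
#'
#' Each axis is independently min-max scaled to `[0, x_max]` over the union
#' of all cells supplied, so that conditions analysed together share one
#' coordinate system and their fate proportions remain comparable. A
#' degenerate axis (single distinct value) maps every cell to `x_max / 2`
#' with a warning.
#'
#' @param x_raw,y_raw Numeric per-cell raw scores (immunogenic and
#'   tolerogenic axes).
#' @param x_max Upper bound of the phase-portrait window.
#' @return A data frame with columns `x_scaled`, `y_scaled` in
#'   `[0, x_max]`.
#' @export
scale_scores <- function(x_raw, y_raw, x_max = 2.2) {
  if (length(x_raw) != length(y_raw))
    stop("score vectors differ in length", call. = FALSE)
  if (length(x_raw) < 2)
    stop("at least 2 cells are required for scaling", call. = FALSE)
  if (any(!is.finite(x_raw)) || any(!is.finite(y_raw)))
    stop("non-finite scores", call. = FALSE)
  scale1 <- function(v, axis) {
    r <- range(v)
    if (diff(r) == 0) {
      warning("constant ", axis, " axis: all cells mapped to x_max/2",
              call. = FALSE)
      return(rep(x_max / 2, length(v)))
    }
    (v - r[1]) / diff(r) * x_max
  }
  data.frame(x_scaled = scale1(x_raw, "x"), y_scaled = scale1(y_raw, "y"))
}

#' Classify cells into toggle-switch fates
#'
#' The full per-cell pipeline: score the immunogenic (x) and tolerogenic
#' (y) axes as signature z-scores, min-max scale the scores into the phase
#' portrait, integrate each cell's trajectory from its scaled coordinates
#' to an attractor, and tally per-condition fate proportions. Cells whose
#' trajectories have not converged after `t_max` are re-integrated with a
#' tenfold horizon; any still unresolved are reported as unconverged and
#' excluded from the proportions.
#'
#' @param mat An [expression_matrix()]; counts are normalized on the fly
#'   with [normalize_counts()], a normalized layer is used as-is.
#' @param metadata Cell-metadata data frame (`cell_id`, `condition`).
#' @param immunogenic_axis,tolerogenic_axis [gene_signature()]s defining
#'   the two axes. Sharing a gene between axes is allowed (each axis is
#'   scored independently).
#' @param params A [toggle_params()].
#' @param pooled_scaling Scale scores over all cells jointly (default) or
#'   within each condition separately.
#' @return An object of class `fate_result`: `cells` (per-cell data frame
#'   with raw and scaled scores, fate label and convergence flag),
#'   `proportions` (per-condition long table of counts and proportions over
#'   converged cells), `attractors` (the located fixed points) and
#'   `params`.
#' @export
classify_cells <- function(mat, metadata, immunogenic_axis,
                           tolerogenic_axis, params = toggle_params(),
                           pooled_scaling = TRUE) {
  params <- as_toggle_params(params)
  if (mat$layer_tag == "counts") mat <- normalize_counts(mat)
  meta <- check_metadata(mat, metadata)
  x_raw <- score_signature(mat, immunogenic_axis)
  y_raw <- score_signature(mat, tolerogenic_axis)
  if (pooled_scaling) {
    sc <- scale_scores(x_raw, y_raw, params$x_max)
  } else {
    sc <- data.frame(x_scaled = rep(NA_real_, length(x_raw)),
                     y_scaled = NA_real_)
    for (cn in unique(meta$condition)) {
      i <- meta$condition == cn
      sc[i, ] <- scale_scores(x_raw[i], y_raw[i], params$x_max)
    }
  }
  fp <- find_fixed_points(params)
  starts <- cbind(sc$x_scaled, sc$y_scaled)
  res <- integrate_batch(starts, params)
  term <- res$terminal
  conv <- res$converged
  ## unconverged cells get one retry with a 10x horizon
  if (any(!conv)) {
    retry <- integrate_batch(starts[!conv, , drop = FALSE], params,
                             t_max = 10 * params$t_max)
    term[!conv, ] <- retry$terminal
    conv[!conv] <- retry$converged
  }
  fate <- assign_attractor_mat(term, fp, params$attract_eps)
  fate[!conv] <- "unconverged"
  cells <- data.frame(cell_id = mat$cell_ids, condition = meta$condition,
                      x_raw = unname(x_raw), y_raw = unname(y_raw),
                      x_scaled = sc$x_scaled, y_scaled = sc$y_scaled,
                      fate = fate, converged = fate != "unconverged",
                      stringsAsFactors = FALSE)
  structure(list(cells = cells,
                 proportions = fate_proportions(cells),
                 attractors = fp, params = params),
            class = "fate_result")
}

fate_label_map <- c(A_immunogenic = "immunogenic",
                    B_tolerogenic = "tolerogenic",
                    C_ambivalent = "ambivalent")

fate_proportions <- function(cells) {
  out <- NULL
  for (cn in unique(cells$condition)) {
    sub <- cells[cells$condition == cn & cells$converged, ]
    counts <- vapply(names(fate_label_map), function(l)
      sum(sub$fate == l), integer(1))
    n <- sum(counts)
    out <- rbind(out, data.frame(
      condition = cn, fate = unname(fate_label_map),
      count = unname(counts),
      proportion = if (n > 0) unname(counts) / n else rep(NA_real_, 3),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.fate_result <- function(x, ...) {
  cat(sprintf("fate_result: %d cells (%d unconverged)\n",
              nrow(x$cells), sum(!x$cells$converged)))
  print(summarize_fates(x))
  invisible(x)
}

#' Per-condition fate summary table
#'
#' Counts and percentages (two decimals) of converged cells assigned to
#' each of the three fates, plus the number of unconverged cells, per
#' condition — the tabular form of the classification pie charts.
#'
#' @param result A `fate_result` from [classify_cells()].
#' @return A data frame with one row per condition and columns
#'   `n_converged`, `n_unconverged`, `immunogenic`, `tolerogenic`,
#'   `ambivalent` (counts) and `pct_*` (percentages).
#' @export
summarize_fates <- function(result) {
  stopifnot(inherits(result, "fate_result"))
  pr <- result$proportions
  out <- NULL
  for (cn in unique(pr$condition)) {
    sub <- pr[pr$condition == cn, ]
    n <- sum(sub$count)
    row <- data.frame(condition = cn, n_converged = n,
                      n_unconverged = sum(result$cells$condition == cn &
                                            !result$cells$converged),
                      stringsAsFactors = FALSE)
    for (f in sub$fate) {
      row[[f]] <- sub$count[sub$fate == f]
      row[[paste0("pct_", f)]] <-
        round(100 * sub$count[sub$fate == f] / max(n, 1), 2)
    }
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}

#' Pie charts of per-condition fate proportions
#'
#' One pie per condition over the three fates, labelled with counts and
#' percentages.
#'
#' @param result A `fate_result`.
#' @param colors Fill colors for (immunogenic, tolerogenic, ambivalent).
#' @return Invisibly, the summary table that was plotted.
#' @export
plot_fate_pies <- function(result,
                           colors = c("#d95f02", "#7570b3", "#1b9e77")) {
  s <- summarize_fates(result)
  old <- graphics::par(mfrow = c(1, nrow(s)), mar = c(1, 1, 3, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(nrow(s))) {
    counts <- c(s$immunogenic[i], s$tolerogenic[i], s$ambivalent[i])
    lab <- sprintf("%s\n%d (%.2f%%)", c("immunogenic", "tolerogenic",
                                        "ambivalent"),
                   counts, 100 * counts / max(sum(counts), 1))
    graphics::pie(counts, labels = lab, col = colors,
                  main = s$condition[i])
  }
  invisible(s)
}

#' Phase portrait of the toggle switch
#'
#' Vector-field quiver over `[0, x_max]^2` with nullclines, fixed points
#' (filled = stable, open = saddle) and, optionally, overlaid cell starting
#' points colored by assigned fate.
#'
#' @param params A [toggle_params()].
#' @param result Optional `fate_result` whose scaled cell coordinates are
#'   overlaid.
#' @param quiver_n Arrows per axis.
#' @return Invisibly, the fixed-point table.
#' @export
plot_phase_portrait <- function(params = toggle_params(), result = NULL,
                                quiver_n = 18) {
  params <- as_toggle_params(params)
  fp <- if (!is.null(result)) result$attractors else find_fixed_points(params)
  g <- seq(0.02, params$x_max, length.out = quiver_n)
  gr <- as.matrix(expand.grid(g, g))
  v <- velocity_mat(gr[, 1], gr[, 2], params)
  sp <- sqrt(rowSums(v^2)); sp[sp == 0] <- 1
  sc <- 0.35 * diff(g[1:2])
  graphics::plot(NA, xlim = c(0, params$x_max), ylim = c(0, params$x_max),
                 xlab = "immunogenic programme (I)",
                 ylab = "tolerogenic programme (T)", asp = 1)
  graphics::arrows(gr[, 1], gr[, 2],
                   gr[, 1] + sc * v[, 1] / sp, gr[, 2] + sc * v[, 2] / sp,
                   length = 0.03, col = "grey60")
  ## nullclines dI/dt = 0 and dT/dt = 0
  fine <- seq(0, params$x_max, length.out = 151)
  fg <- as.matrix(expand.grid(fine, fine))
  vv <- velocity_mat(fg[, 1], fg[, 2], params)
  graphics::contour(fine, fine, matrix(vv[, 1], 151, 151), levels = 0,
                    add = TRUE, drawlabels = FALSE, col = "steelblue")
  graphics::contour(fine, fine, matrix(vv[, 2], 151, 151), levels = 0,
                    add = TRUE, drawlabels = FALSE, col = "firebrick")
  if (!is.null(result)) {
    cols <- c(A_immunogenic = "#d95f02", B_tolerogenic = "#7570b3",
              C_ambivalent = "#1b9e77", unconverged = "grey40")
    graphics::points(result$cells$x_scaled, result$cells$y_scaled,
                     pch = 16, cex = 0.4, col = cols[result$cells$fate])
  }
  st <- fp$stability == "stable"
  graphics::points(fp$I[st], fp$T[st], pch = 21, bg = "black", cex = 1.4)
  graphics::points(fp$I[!st], fp$T[!st], pch = 21, bg = "white", cex = 1.2)
  invisible(fp)
}
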