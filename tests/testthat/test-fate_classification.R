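test_that("min-max scaling maps score ranges onto the portrait window", {
  sc <- scale_scores(c(-2, 0, 2), c(1, 2, 3), x_max = 2.2)
  expect_equal(sc$x_scaled, c(0, 1.1, 2.2))
  expect_equal(sc$y_scaled, c(0, 1.1, 2.2))
  expect_warning(flat <- scale_scores(c(1, 1, 1), c(0, 1, 2), 2.2),
                 "constant")
  expect_equal(flat$x_scaled, rep(1.1, 3))
  expect_error(scale_scores(c(1, NA), c(0, 1)), "non-finite")
  expect_error(scale_scores(1, 1), "2 cells")
})

test_that("joint scaling equals scaling of the concatenation", {
  set.seed(41)
  xa <- rnorm(30); ya <- rnorm(30)
  xb <- rnorm(20, 1); yb <- rnorm(20, -1)
  joint <- scale_scores(c(xa, xb), c(ya, yb))
  expect_equal(joint[1:30, ], scale_scores(c(xa, xb), c(ya, yb))[1:30, ])
})

test_that("cells with identical axis scores are all ambivalent", {
  set.seed(42)
  vals <- matrix(rexp(200), 20, 10)
  m <- make_norm(vals)
  meta <- data.frame(cell_id = m$cell_ids, condition = "only")
  sig <- gene_signature(sprintf("g%02d", 1:10), "both_axes")
  res <- classify_cells(m, meta, sig, sig)
  expect_true(all(res$cells$fate == "C_ambivalent"))
  pr <- res$proportions
  expect_equal(pr$proportion[pr$fate == "ambivalent"], 1)
})

test_that("swapping the axes swaps the immunogenic and tolerogenic fractions", {
  sp <- small_population()
  res <- classify_cells(sp$population$matrix, sp$population$metadata,
                        sp$axes$x, sp$axes$y)
  res_sw <- classify_cells(sp$population$matrix, sp$population$metadata,
                           sp$axes$y, sp$axes$x)
  pr <- res$proportions; pr_sw <- res_sw$proportions
  gp <- function(p, f) p$proportion[p$fate == f]
  expect_equal(gp(pr, "immunogenic"), gp(pr_sw, "tolerogenic"))
  expect_equal(gp(pr, "tolerogenic"), gp(pr_sw, "immunogenic"))
  expect_equal(gp(pr, "ambivalent"), gp(pr_sw, "ambivalent"))
})

test_that("classification is deterministic end to end", {
  sp <- small_population(seed = 9, n = 60)
  r1 <- classify_cells(sp$population$matrix, sp$population$metadata,
                       sp$axes$x, sp$axes$y)
  r2 <- classify_cells(sp$population$matrix, sp$population$metadata,
                       sp$axes$x, sp$axes$y)
  expect_identical(r1$cells, r2$cells)
  expect_identical(r1$proportions, r2$proportions)
})

test_that("per-cell labels match the basin-map oracle at its starting point", {
  sp <- small_population(seed = 5, n = 80)
  res <- classify_cells(sp$population$matrix, sp$population$metadata,
                        sp$axes$x, sp$axes$y)
  p <- res$params
  bm <- basin_map(p, grid_resolution = 111)
  g <- seq(0, p$x_max, length.out = 111)
  gi <- function(v) pmin(pmax(round(v / p$x_max * 110) + 1, 1), 111)
  oracle <- bm$label[(gi(res$cells$y_scaled) - 1) * 111 +
                       gi(res$cells$x_scaled)]
  disagree <- mean(oracle != res$cells$fate)
  expect_lt(disagree, 0.01)
})

test_that("raising the immunogenic axis never shrinks the immunogenic pool", {
  p <- toggle_params()
  fp <- find_fixed_points(p)
  set.seed(43)
  starts <- cbind(runif(150, 0, p$x_max), runif(150, 0, p$x_max))
  lab0 <- assign_attractor_mat(integrate_batch(starts, p)$terminal, fp,
                               p$attract_eps)
  shifted <- cbind(pmin(starts[, 1] + 0.25, p$x_max), starts[, 2])
  lab1 <- assign_attractor_mat(integrate_batch(shifted, p)$terminal, fp,
                               p$attract_eps)
  expect_gte(sum(lab1 == "A_immunogenic"), sum(lab0 == "A_immunogenic"))
})

test_that("fate summaries report counts and two-decimal percentages", {
  cells <- data.frame(
    cell_id = sprintf("c%03d", 1:100), condition = "only",
    x_raw = 0, y_raw = 0, x_scaled = 0, y_scaled = 0,
    fate = rep(c("A_immunogenic", "B_tolerogenic", "C_ambivalent"),
               c(35, 34, 31)),
    converged = TRUE, stringsAsFactors = FALSE)
  res <- structure(list(cells = cells, proportions = fate_proportions(cells),
                        attractors = NULL, params = toggle_params()),
                   class = "fate_result")
  s <- summarize_fates(res)
  expect_equal(c(s$pct_immunogenic, s$pct_tolerogenic, s$pct_ambivalent),
               c(35, 34, 31))
  expect_equal(s$pct_immunogenic + s$pct_tolerogenic + s$pct_ambivalent,
               100, tolerance = 0.01)

  cells$fate <- "C_ambivalent"
  res$proportions <- fate_proportions(cells)
  res$cells <- cells
  s2 <- summarize_fates(res)
  expect_equal(c(s2$pct_immunogenic, s2$pct_tolerogenic, s2$pct_ambivalent),
               c(0, 0, 100))
})
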