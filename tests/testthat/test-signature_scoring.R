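test_that("single-gene z-scores use the population standard deviation", {
  m <- make_norm(matrix(c(0, 2), 2, 1), genes = "IRF1")
  s <- score_signature(m, gene_signature("IRF1"))
  expect_equal(as.numeric(s), c(-1, 1))  # mean 1, population SD 1
})

test_that("zero-variance genes are dropped; sole constant gene errors", {
  m <- make_norm(cbind(a = c(0, 2, 4), b = c(1, 1, 1)),
                 genes = c("A", "B"))
  expect_warning(s <- score_signature(m, gene_signature(c("A", "B"))),
                 "dropped")
  expect_equal(attr(s, "genes_used"), "A")
  expect_error(
    suppressWarnings(score_signature(m, gene_signature("B"))),
    "zero variance")
})

test_that("opposing per-gene z-scores cancel in the signature mean", {
  m <- make_norm(cbind(c(0, 2), c(2, 0)), genes = c("A", "B"))
  s <- score_signature(m, gene_signature(c("A", "B")))
  expect_equal(as.numeric(s), c(0, 0))
})

test_that("per-gene z-score vectors have mean 0 and population SD 1", {
  set.seed(11)
  m <- make_norm(matrix(rexp(200), 20, 10))
  sig <- gene_signature(sprintf("g%02d", 1:10))
  s <- score_signature(m, sig)
  z_check <- apply(m$values, 2, function(v) {
    z <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
    c(mean(z), sqrt(mean((z - mean(z))^2)))
  })
  expect_true(all(abs(z_check[1, ]) < 1e-10))
  expect_true(all(abs(z_check[2, ] - 1) < 1e-10))
  expect_equal(as.numeric(s), unname(rowMeans(
    apply(m$values, 2, function(v)
      (v - mean(v)) / sqrt(mean((v - mean(v))^2))))))
})

test_that("scores are invariant under per-gene positive affine transforms", {
  set.seed(12)
  vals <- matrix(rexp(150), 15, 10)
  m <- make_norm(vals)
  sig <- gene_signature(sprintf("g%02d", 1:10))
  base <- score_signature(m, sig)
  scale <- runif(10, 0.5, 3)
  shift <- runif(10, 0, 2)  # non-negative shift keeps values in-domain
  m2 <- make_norm(sweep(sweep(vals, 2, scale, "*"), 2, shift, "+"))
  s2 <- score_signature(m2, sig)
  expect_equal(as.numeric(s2), as.numeric(base), tolerance = 1e-10)
})

test_that("scoring is permutation-equivariant in cells", {
  set.seed(13)
  vals <- matrix(rexp(80), 8, 10)
  m <- make_norm(vals)
  sig <- gene_signature(sprintf("g%02d", 1:10))
  s <- score_signature(m, sig)
  perm <- sample(8)
  mp <- make_norm(vals[perm, ], cells = m$cell_ids[perm])
  sp <- score_signature(mp, sig)
  expect_equal(as.numeric(sp), as.numeric(s)[perm])
})

test_that("scoring requires a normalized layer and present genes", {
  counts <- make_counts(matrix(1:4, 2, 2))
  expect_error(score_signature(counts, gene_signature("g01")), "normalized")
  m <- make_norm(matrix(rexp(4), 2, 2))
  expect_error(score_signature(m, gene_signature("ABSENT")), "present")
})

test_that("condition comparison reports medians, fold change and rank test", {
  scores <- c(seq(0.2033, 0.4033, length.out = 11),   # median 0.3033
              seq(0.3669, 0.5669, length.out = 11))   # median 0.4669
  names(scores) <- sprintf("c%02d", 1:22)
  meta <- data.frame(cell_id = names(scores),
                     condition = rep(c("unstim", "TNF"), each = 11))
  cmp <- compare_conditions(scores, meta, "unstim", "TNF")
  expect_equal(cmp$median_a, 0.3033)
  expect_equal(cmp$median_b, 0.4669)
  expect_equal(round(cmp$fold_change, 2), 1.54)
})

test_that("identical groups give unit fold change and p near 1", {
  set.seed(21)
  v <- rexp(40)
  scores <- c(v, v)
  names(scores) <- sprintf("c%03d", 1:80)
  meta <- data.frame(cell_id = names(scores),
                     condition = rep(c("a", "b"), each = 40))
  cmp <- compare_conditions(scores, meta, "a", "b")
  expect_equal(cmp$fold_change, 1)
  expect_gt(cmp$p_value, 0.9)
})

test_that("a rank shift between large groups is detected", {
  set.seed(22)
  a <- rnorm(200, 1, 0.2)
  b <- rnorm(200, 1.3, 0.2)
  scores <- c(a, b)
  names(scores) <- sprintf("c%03d", 1:400)
  meta <- data.frame(cell_id = names(scores),
                     condition = rep(c("a", "b"), each = 200))
  cmp <- compare_conditions(scores, meta, "a", "b")
  expect_lt(cmp$p_value, 1e-10)
  expect_equal(cmp$fold_change, median(b) / median(a))
  expect_error(compare_conditions(scores, meta, "a", "nonexistent"),
               "unknown")
})
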