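test_that("the vector field matches its closed-form anchor points", {
  p <- toggle_params()
  expect_equal(velocity_field(c(0, 0), p), c(dI = 1, dT = 1))
  expect_equal(velocity_field(c(1, 1), p), c(dI = 0, dT = 0))
  expect_equal(velocity_field(c(0.5, 0.5), p), c(dI = 0.5, dT = 0.5))
  expect_error(velocity_field(c(-0.1, 0), p), "non-negative")
})

test_that("the field is symmetric under programme exchange", {
  p <- toggle_params()
  set.seed(31)
  for (i in 1:25) {
    s <- runif(2, 0, p$x_max)
    v <- velocity_field(s, p)
    v_swap <- velocity_field(rev(s), p)
    expect_equal(unname(v), unname(rev(v_swap)), tolerance = 1e-12)
  }
})

test_that("the analytic Jacobian agrees with finite differences", {
  p <- toggle_params(a = 1.3, b = 0.8, k = 1.1, n = 3, theta = 0.6)
  set.seed(32)
  h <- 1e-6
  for (i in 1:10) {
    s <- runif(2, 0.05, 2)
    J <- toggle_jacobian(s, p)
    J_fd <- matrix(0, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h
      J_fd[, j] <- (velocity_field(s + e, p) - velocity_field(s - e, p)) /
        (2 * h)
    }
    expect_equal(J, J_fd, tolerance = 1e-5)
  }
})

test_that("default parameters give the tri-stable landscape", {
  fp <- find_fixed_points(toggle_params())
  st <- fp[fp$stability == "stable", ]
  expect_equal(nrow(st), 3)
  ## the balanced attractor is exactly (1, 1): on the diagonal the two Hill
  ## terms sum to 1, so the fixed-point condition is 1 - I = 0
  amb <- st[st$label == "C_ambivalent", ]
  expect_equal(c(amb$I, amb$T), c(1, 1), tolerance = 1e-9)
  expect_true(all(c(amb$eig1, amb$eig2) < 0))
  ## the asymmetric pair is mirror-symmetric
  a <- st[st$label == "A_immunogenic", ]
  b <- st[st$label == "B_tolerogenic", ]
  expect_equal(nrow(a), 1)
  expect_equal(c(a$I, a$T), c(b$T, b$I), tolerance = 1e-8)
  expect_gt(a$I, a$T)
})

test_that("pure decay collapses the landscape to the origin", {
  p <- toggle_params(a = 1e-12, b = 1e-12, k = 1)
  fp <- find_fixed_points(p)
  st <- fp[fp$stability == "stable", ]
  expect_equal(nrow(st), 1)
  expect_equal(c(st$I, st$T), c(0, 0), tolerance = 1e-6)
})

test_that("an independent root finder confirms the asymmetric attractor", {
  p <- toggle_params()
  fp <- find_fixed_points(p)
  a <- fp[fp$label %in% "A_immunogenic", ]
  f <- function(x) {
    v <- velocity_field(pmax(x, 0), p)
    c(v[1], v[2])
  }
  root <- pracma::fsolve(f, c(2, 0.01))$x
  expect_equal(c(a$I, a$T), root, tolerance = 1e-6)
})

test_that("a fixed-point start stays put and converges immediately", {
  tr <- integrate_trajectory(c(1, 1), toggle_params())
  expect_true(tr$converged)
  expect_equal(unname(tr$terminal), c(1, 1), tolerance = 1e-8)
})

test_that("diagonal trajectories follow the scalar closed form", {
  p <- toggle_params()
  for (c0 in c(0, 0.2, 2)) {
    tr <- integrate_trajectory(c(c0, c0), p)
    expected <- 1 - (1 - c0) * exp(-tr$times)
    expect_lt(max(abs(tr$states[, "I"] - expected)), 1e-6)
    expect_lt(max(abs(tr$states[, "I"] - tr$states[, "T"])), 1e-8)
  }
})

test_that("an immunogenic start reaches the immunogenic attractor", {
  p <- toggle_params()
  fp <- find_fixed_points(p)
  a <- fp[fp$label %in% "A_immunogenic", ]
  tr <- integrate_trajectory(c(2, 0.05), p)
  expect_true(tr$converged)
  expect_lt(sqrt((tr$terminal[1] - a$I)^2 + (tr$terminal[2] - a$T)^2),
            p$attract_eps)
})

test_that("attractor assignment follows the nearest-within-radius rule", {
  fp <- find_fixed_points(toggle_params())
  expect_equal(assign_attractor(c(1.0001, 0.9999), fp, 0.05),
               "C_ambivalent")
  expect_equal(assign_attractor(c(2.2, 2.2), fp, 0.05), "unconverged")
  a <- fp[fp$label %in% "A_immunogenic", ]
  expect_equal(assign_attractor(c(a$I, a$T), fp, 0.05), "A_immunogenic")
  expect_error(assign_attractor(c(1, 1), fp[fp$stability == "saddle", ],
                                0.05), "empty attractor")
})

test_that("the basin map is diagonal-ambivalent, mirror-symmetric and converged", {
  p <- toggle_params()
  bm <- basin_map(p, grid_resolution = 21)
  on_diag <- abs(bm$I0 - bm$T0) < 1e-12
  expect_true(all(bm$label[on_diag] == "C_ambivalent"))
  ## A <-> B mirror symmetry across the diagonal
  key <- paste(round(bm$I0, 9), round(bm$T0, 9))
  mirror_key <- paste(round(bm$T0, 9), round(bm$I0, 9))
  mirror_label <- bm$label[match(mirror_key, key)]
  swap <- c(A_immunogenic = "B_tolerogenic", B_tolerogenic = "A_immunogenic",
            C_ambivalent = "C_ambivalent", unconverged = "unconverged")
  expect_equal(unname(swap[bm$label]), mirror_label)
  expect_gte(mean(bm$label != "unconverged"), 0.99)
})

test_that("random starts converge onto independently located fixed points", {
  p <- toggle_params()
  fp <- find_fixed_points(p)
  st <- fp[fp$stability == "stable", ]
  set.seed(33)
  for (i in 1:20) {
    s <- runif(2, 0, p$x_max)
    tr <- integrate_trajectory(s, p)
    if (!tr$converged) next
    d <- sqrt((st$I - tr$terminal[1])^2 + (st$T - tr$terminal[2])^2)
    expect_lt(min(d), p$attract_eps)
  }
})

test_that("stability labels agree with perturbed long-time behaviour", {
  p <- toggle_params()
  fp <- find_fixed_points(p)
  set.seed(34)
  for (i in seq_len(nrow(fp))) {
    for (rep in 1:2) {
      delta <- runif(2, -0.02, 0.02)
      start <- pmax(c(fp$I[i], fp$T[i]) + delta, 0)
      tr <- integrate_trajectory(start, p)
      dist_back <- sqrt(sum((tr$terminal - c(fp$I[i], fp$T[i]))^2))
      if (fp$stability[i] == "stable") {
        expect_lt(dist_back, p$attract_eps)
      } else {
        ## saddles: generic perturbations depart to some other attractor
        expect_gt(dist_back, 1e-3)
      }
    }
  }
})
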