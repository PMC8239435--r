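## Hill building blocks, vectorised over the state.
hill_act <- function(x, n, theta) x^n / (theta^n + x^n)
hill_inh <- function(x, n, theta) theta^n / (theta^n + x^n)

## d/dx of a^? terms: derivative of x^n/(theta^n + x^n) is
## n theta^n x^(n-1) / (theta^n + x^n)^2.
hill_act_d <- function(x, n, theta) {
  n * theta^n * x^(n - 1) / (theta^n + x^n)^2
}

## Vectorised right-hand side over parallel (I, T) columns.
velocity_mat <- function(I, T_, p) {
  dI <- p$a * hill_act(I, p$n, p$theta) +
    p$b * hill_inh(T_, p$n, p$theta) - p$k * I
  dT <- p$a * hill_act(T_, p$n, p$theta) +
    p$b * hill_inh(I, p$n, p$theta) - p$k * T_
  cbind(dI, dT, deparse.level = 0)
}

#' Time-derivatives of the toggle-switch system
#'
#' Each programme auto-amplifies through a Hill activation of itself, is
#' driven by Hill repression from the opposing programme, and decays at a
#' constant first-order rate:
#' \deqn{dI/dt = a I^n/(\theta^n + I^n) + b \theta^n/(\theta^n + T^n) - k I}
#' and symmetrically for \eqn{T} with \eqn{I} and \eqn{T} exchanged.
#'
#' @param state Numeric length-2 vector `c(I, T)`, both non-negative.
#' @param params A [toggle_params()] object.
#' @return Named numeric vector `c(dI, dT)`.
#' @export
velocity_field <- function(state, params = toggle_params()) {
  params <- as_toggle_params(params)
  if (length(state) != 2L || !is.numeric(state) || any(!is.finite(state)))
    stop("'state' must be a finite numeric vector c(I, T)", call. = FALSE)
  if (any(state < 0))
    stop("programme levels must be non-negative", call. = FALSE)
  v <- velocity_mat(state[1], state[2], params)
  c(dI = v[1, 1], dT = v[1, 2])
}

#' Jacobian of the toggle-switch vector field
#'
#' Analytic 2x2 Jacobian used for Newton root refinement and for stability
#' classification of fixed points.
#'
#' @inheritParams velocity_field
#' @return A 2x2 numeric matrix of partial derivatives.
#' @export
toggle_jacobian <- function(state, params = toggle_params()) {
  params <- as_toggle_params(params)
  I <- state[1]; T_ <- state[2]
  with(params, matrix(c(
    a * hill_act_d(I, n, theta) - k, -b * hill_act_d(T_, n, theta),
    -b * hill_act_d(I, n, theta),    a * hill_act_d(T_, n, theta) - k
  ), nrow = 2, byrow = TRUE))
}

## One Newton run from a seed; returns the root or NULL.
newton_root <- function(x0, params, tol = 1e-12, max_iter = 60) {
  x <- x0
  for (i in seq_len(max_iter)) {
    f <- drop(velocity_mat(x[1], x[2], params))
    if (sqrt(sum(f^2)) < tol) return(pmax(x, 0))
    J <- toggle_jacobian(x, params)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    ## damping keeps iterates inside the non-negative quadrant, where the
    ## Hill terms are defined
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      if (all(xn >= 0)) break
      lambda <- lambda / 2
      if (lambda < 1e-6) return(NULL)
    }
    if (sqrt(sum((xn - x)^2)) < 1e-14 && sqrt(sum(f^2)) < 1e-8)
      return(pmax(xn, 0))
    x <- xn
  }
  f <- drop(velocity_mat(x[1], x[2], params))
  if (sqrt(sum(f^2)) < 1e-8) pmax(x, 0) else NULL
}

#' Locate and classify the fixed points of the toggle switch
#'
#' Multi-start Newton root finding seeded on a regular grid over the
#' phase-portrait window `[0, x_max]^2`, followed by de-duplication and
#' Jacobian-eigenvalue stability classification. Stable points are labelled
#' `A_immunogenic` (I > T), `B_tolerogenic` (T > I) or `C_ambivalent`
#' (balanced, |I - T| below tolerance).
#'
#' @param params A [toggle_params()] object.
#' @param seed_grid_resolution Number of Newton seeds per axis (>= 10).
#' @param dedup_tol Roots closer than this (Euclidean) are merged.
#' @return A data frame of class `toggle_fixed_points` with columns
#'   `I`, `T`, `stability` (`stable`/`saddle`/`unstable`), `label`
#'   (fate label for stable points, `NA` otherwise), `eig1`, `eig2`
#'   (real parts of the Jacobian eigenvalues).
#' @examples
#' fp <- find_fixed_points(toggle_params())
#' subset(fp, stability == "stable")  # the three attractors A, B, C
#' @export
find_fixed_points <- function(params = toggle_params(),
                              seed_grid_resolution = 25,
                              dedup_tol = 1e-6) {
  params <- as_toggle_params(params)
  if (seed_grid_resolution < 10)
    stop("'seed_grid_resolution' must be at least 10", call. = FALSE)
  g <- seq(0, params$x_max, length.out = seed_grid_resolution)
  seeds <- as.matrix(expand.grid(I = g, T = g))
  roots <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(seeds))) {
    r <- newton_root(seeds[i, ], params)
    if (is.null(r)) next
    if (any(r > params$x_max + 0.5)) next
    if (nrow(roots) == 0 ||
        min(sqrt(rowSums((roots - matrix(r, nrow(roots), 2,
                                         byrow = TRUE))^2))) > dedup_tol) {
      roots <- rbind(roots, r)
    }
  }
  if (nrow(roots) == 0)
    return(empty_fixed_points())
  stab <- character(nrow(roots)); lab <- rep(NA_character_, nrow(roots))
  e1 <- e2 <- numeric(nrow(roots))
  for (i in seq_len(nrow(roots))) {
    ev <- Re(eigen(toggle_jacobian(roots[i, ], params),
                   only.values = TRUE)$values)
    e1[i] <- max(ev); e2[i] <- min(ev)
    stab[i] <- if (all(ev < 0)) "stable"
    else if (all(ev > 0)) "unstable"
    else "saddle"
    if (stab[i] == "stable") {
      d <- roots[i, 1] - roots[i, 2]
      lab[i] <- if (d > dedup_tol) "A_immunogenic"
      else if (d < -dedup_tol) "B_tolerogenic"
      else "C_ambivalent"
    }
  }
  out <- data.frame(I = roots[, 1], T = roots[, 2], stability = stab,
                    label = lab, eig1 = e1, eig2 = e2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$stability != "stable", -out$I + out$T), ]
  rownames(out) <- NULL
  class(out) <- c("toggle_fixed_points", "data.frame")
  out
}

empty_fixed_points <- function() {
  out <- data.frame(I = numeric(0), T = numeric(0),
                    stability = character(0), label = character(0),
                    eig1 = numeric(0), eig2 = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("toggle_fixed_points", "data.frame")
  out
}

## deSolve right-hand side for a stack of N independent (I, T) systems.
## y = c(I_1..I_N, T_1..T_N); states are clamped at 0 against solver
## undershoot (the field itself never pushes a non-negative state negative).
rhs_stacked <- function(t, y, p) {
  N <- length(y) / 2
  I <- pmax(y[seq_len(N)], 0)
  T_ <- pmax(y[N + seq_len(N)], 0)
  v <- velocity_mat(I, T_, p)
  list(c(v[, 1], v[, 2]))
}

## Integrate N starting points to t_max; returns list(terminal = Nx2,
## converged = logical N). Used by basin_map and classify_cells.
integrate_batch <- function(starts, params, t_max = params$t_max) {
  starts <- matrix(as.numeric(starts), ncol = 2)
  N <- nrow(starts)
  y0 <- c(starts[, 1], starts[, 2])
  sol <- deSolve::ode(y = y0, times = c(0, t_max), func = rhs_stacked,
                      parms = params, method = "ode45",
                      rtol = 1e-8, atol = 1e-10)
  yT <- sol[nrow(sol), -1]
  if (any(!is.finite(yT)))
    stop("non-finite state encountered during integration", call. = FALSE)
  term <- pmax(cbind(yT[seq_len(N)], yT[N + seq_len(N)]), 0)
  v <- velocity_mat(term[, 1], term[, 2], params)
  list(terminal = term, converged = sqrt(rowSums(v^2)) < params$conv_tol)
}

#' Integrate a single trajectory of the toggle switch
#'
#' Adaptive Runge-Kutta (Dormand-Prince 4(5)) integration from a starting
#' state until the velocity norm drops below `conv_tol` or `t_max` is
#' reached. The returned path is truncated at the first converged output
#' time.
#'
#' @param start Numeric `c(I, T)` within `[0, x_max]^2`.
#' @param params A [toggle_params()] object.
#' @param n_out Number of output time points spanning `[0, t_max]`.
#' @return An object of class `toggle_trajectory`: list with `times`,
#'   `states` (matrix with columns `I`, `T`), `converged`, `terminal`.
#' @examples
#' tr <- integrate_trajectory(c(2, 0.05), toggle_params())
#' tr$terminal  # near the immunogenic attractor (~2, ~0.004)
#' @export
integrate_trajectory <- function(start, params = toggle_params(),
                                 n_out = 201) {
  params <- as_toggle_params(params)
  if (length(start) != 2L || any(!is.finite(start)) || any(start < 0))
    stop("'start' must be a non-negative finite c(I, T)", call. = FALSE)
  times <- seq(0, params$t_max, length.out = n_out)
  sol <- deSolve::ode(y = c(I = start[1], T = start[2]), times = times,
                      func = function(t, y, p) {
                        list(drop(velocity_mat(max(y[1], 0), max(y[2], 0), p)))
                      },
                      parms = params, method = "ode45",
                      rtol = 1e-8, atol = 1e-10)
  states <- pmax(unname(sol[, 2:3]), 0)
  if (any(!is.finite(states)))
    stop("non-finite state encountered during integration", call. = FALSE)
  colnames(states) <- c("I", "T")
  vnorm <- sqrt(rowSums(velocity_mat(states[, 1], states[, 2], params)^2))
  hit <- which(vnorm < params$conv_tol)
  if (length(hit)) {
    cut <- hit[1]
    structure(list(times = times[seq_len(cut)],
                   states = states[seq_len(cut), , drop = FALSE],
                   converged = TRUE,
                   terminal = states[cut, ]),
              class = "toggle_trajectory")
  } else {
    structure(list(times = times, states = states, converged = FALSE,
                   terminal = states[nrow(states), ]),
              class = "toggle_trajectory")
  }
}

#' @export
print.toggle_trajectory <- function(x, ...) {
  cat(sprintf("Toggle trajectory: %d points, t in [0, %.3g], %s\n",
              length(x$times), max(x$times),
              if (x$converged) sprintf("converged at (%.4g, %.4g)",
                                       x$terminal[1], x$terminal[2])
              else "not converged"))
  invisible(x)
}

#' Assign a terminal state to its attractor
#'
#' Labels a trajectory end point with the fate of the nearest stable fixed
#' point if it lies within `attract_eps` of it; otherwise returns
#' `"unconverged"`. Saddles are never assignment targets.
#'
#' @param terminal Numeric `c(I, T)` terminal state.
#' @param attractors A `toggle_fixed_points` data frame (only its stable
#'   rows are used).
#' @param attract_eps Assignment radius.
#' @return A fate label (`"A_immunogenic"`, `"B_tolerogenic"`,
#'   `"C_ambivalent"`) or `"unconverged"`.
#' @export
assign_attractor <- function(terminal, attractors, attract_eps = 0.05) {
  st <- attractors[attractors$stability == "stable", , drop = FALSE]
  if (nrow(st) == 0) stop("empty attractor set", call. = FALSE)
  d <- sqrt((st$I - terminal[1])^2 + (st$T - terminal[2])^2)
  i <- which.min(d)
  if (d[i] < attract_eps) st$label[i] else "unconverged"
}

## Vectorised assignment of an N x 2 matrix of terminal states.
assign_attractor_mat <- function(term, attractors, attract_eps) {
  st <- attractors[attractors$stability == "stable", , drop = FALSE]
  if (nrow(st) == 0) stop("empty attractor set", call. = FALSE)
  d <- vapply(seq_len(nrow(st)), function(i) {
    sqrt((term[, 1] - st$I[i])^2 + (term[, 2] - st$T[i])^2)
  }, numeric(nrow(term)))
  d <- matrix(d, nrow = nrow(term))
  best <- max.col(-d, ties.method = "first")
  lab <- st$label[best]
  lab[d[cbind(seq_len(nrow(term)), best)] >= attract_eps] <- "unconverged"
  lab
}

#' Brute-force basin-of-attraction map
#'
#' Integrates every point of a regular grid over `[0, x_max]^2` to its
#' attractor. Serves as the independent oracle for cell classification and
#' as the data behind basin/phase-portrait plots.
#'
#' @param params A [toggle_params()] object.
#' @param grid_resolution Grid points per axis.
#' @return A data frame of class `toggle_basin_map` with columns `I0`, `T0`
#'   (starting point) and `label`; the located fixed points are attached as
#'   attribute `"fixed_points"`.
#' @export
basin_map <- function(params = toggle_params(), grid_resolution = 41) {
  params <- as_toggle_params(params)
  fp <- find_fixed_points(params)
  g <- seq(0, params$x_max, length.out = grid_resolution)
  starts <- as.matrix(expand.grid(I0 = g, T0 = g))
  res <- integrate_batch(starts, params)
  lab <- assign_attractor_mat(res$terminal, fp, params$attract_eps)
  lab[!res$converged] <- "unconverged"
  out <- data.frame(I0 = starts[, 1], T0 = starts[, 2], label = lab,
                    stringsAsFactors = FALSE)
  attr(out, "fixed_points") <- fp
  class(out) <- c("toggle_basin_map", "data.frame")
  out
}
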