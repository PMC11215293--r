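# Independent oracles used across the suite. None of these share code with
# the package's own solvers: the LP oracle enumerates basic solutions
# exhaustively, the front oracle sweeps an epsilon-constraint grid, areas
# come from the shoelace/trapezoid formulas written out directly, and hull
# volumes from Monte-Carlo membership counting.

# exhaustive vertex enumeration for tiny LPs (max cc'x, Ax = b, lb<=x<=ub):
# fix n-m variables at a bound in all ways, solve for the rest, keep the
# best feasible value
enum_lp_oracle <- function(cc, A, b, lb, ub) {
  A <- as.matrix(A)
  n <- ncol(A); m <- nrow(A)
  nf <- n - m
  stopifnot(nf >= 0)
  best <- -Inf
  combs <- if (nf > 0) utils::combn(n, nf) else matrix(integer(), 0, 1)
  for (ci in seq_len(ncol(combs))) {
    fixidx <- combs[, ci]
    freeidx <- setdiff(seq_len(n), fixidx)
    Af <- A[, freeidx, drop = FALSE]
    if (qr(Af)$rank < m) next
    grid <- as.matrix(expand.grid(rep(list(1:2), nf)))
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      x[fixidx] <- ifelse(grid[g, ] == 1, lb[fixidx], ub[fixidx])
      rhs <- b - drop(A[, fixidx, drop = FALSE] %*% x[fixidx])
      xf <- tryCatch(solve(Af, rhs), error = function(e) NULL)
      if (is.null(xf)) next
      x[freeidx] <- xf
      if (all(x >= lb - 1e-7) && all(x <= ub + 1e-7))
        best <- max(best, sum(cc * x))
    }
  }
  best
}

# epsilon-constraint oracle: best f2 achievable at f1 pinned to x
eps_constraint_value <- function(eco, x) {
  c1 <- drop(c(1, 0) %*% eco$objectives)
  c2 <- drop(c(0, 1) %*% eco$objectives)
  res <- ecoscore:::eco_lp(eco, c2, extra_A = matrix(c1, 1), extra_b = x)
  stopifnot(res$status == "optimal")
  res$objval
}

# value of the front polyline at first coordinate x (linear interpolation)
front_polyline_value <- function(pts, x) {
  pts <- unname(as.matrix(pts))
  pts <- pts[order(pts[, 1]), , drop = FALSE]
  if (x <= pts[1, 1] + 1e-12) return(pts[1, 2])
  np <- nrow(pts)
  if (x >= pts[np, 1] - 1e-12) return(pts[np, 2])
  i <- max(which(pts[, 1] <= x + 1e-12))
  if (pts[i + 1, 1] - pts[i, 1] < 1e-12) return(pts[i, 2])
  frac <- (x - pts[i, 1]) / (pts[i + 1, 1] - pts[i, 1])
  pts[i, 2] + frac * (pts[i + 1, 2] - pts[i, 2])
}

# signed trapezoid area, written out directly
trapezoid_area <- function(p) {
  sum(abs(diff(p[, 1])) * (p[-nrow(p), 2] + p[-1, 2]) / 2)
}

# Monte-Carlo membership estimate of vol conv({0, e1, e2, e3, (1,1,1)}).
# Membership derived by hand: the hull's facets are the coordinate planes
# and the three planes x+y-z<=1, x+z-y<=1, y+z-x<=1.
mc_simplex_ones_volume <- function(n = 1e6, seed = 42) {
  set.seed(seed)
  x <- runif(n); y <- runif(n); z <- runif(n)
  inside <- (x + y - z <= 1) & (x + z - y <= 1) & (y + z - x <= 1)
  mean(inside) # cube volume is 1
}

build_pair_eco <- function(kind, ...) {
  p <- generate_pair(toy_spec(kind, ...))
  eco <- suppressMessages(apply_diet(build_ecosystem(p$models), p$diet))
  list(pair = p, eco = eco)
}

score_pair <- function(kind, ...) {
  x <- build_pair_eco(kind, ...)
  fr <- compute_pareto_front(x$eco)
  nf <- suppressMessages(normalize_front(fr, x$eco))
  rep <- interaction_score(nf)
  list(eco = x$eco, front = fr, nf = nf, report = rep, truth = x$pair$truth)
}
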