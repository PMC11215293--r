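#' Solve a bounded-variable linear program
#'
#' Solves `max (or min) c'x  subject to  A x = b,  lb <= x <= ub` with a dense
#' two-phase primal simplex supporting general (finite) variable bounds.
#' All flux balance problems in this package reduce to this form: the
#' steady-state constraint `S v = 0` plus flux bounds, optionally extended with
#' equality rows pinning objective values.
#'
#' Bounds must be finite; metabolic models use a finite default flux cap
#' (see [metabolic_model()]), which also keeps every LP bounded.
#'
#' The solver is deterministic: Dantzig pricing with smallest-index
#' tie-breaking, switching to Bland's rule after a fixed number of iterations
#' to guarantee termination under degeneracy.
#'
#' @param obj numeric objective vector (length n).
#' @param A constraint matrix (m x n), dense or a `Matrix` sparse matrix.
#' @param b right-hand side (length m).
#' @param lb,ub finite lower/upper variable bounds (length n).
#' @param maximize logical; maximize (default) or minimize.
#' @param tol numeric feasibility/optimality tolerance (default 1e-9).
#' @return list with `status` ("optimal" or "infeasible"), `x` (solution,
#'   length n), and `objval` (objective value on the original min/max scale;
#'   `NA` unless optimal).
#' @examples
#' # max x1 + x2 s.t. x1 + x2 <= 1 written as x1 + x2 + s = 1
#' lp_solve(c(1, 1, 0), matrix(c(1, 1, 1), 1), 1, rep(0, 3), rep(10, 3))
#' @export
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  n <- ncol(A)
  m <- nrow(A)
  obj <- as.numeric(obj)
  b <- as.numeric(b)
  lb <- as.numeric(lb)
  ub <- as.numeric(ub)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds")
  if (any(lb > ub + tol))
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  # clamp crossing bounds from roundoff
  ub <- pmax(ub, lb)
  cvec <- if (maximize) obj else -obj

  if (m == 0L) {
    x <- ifelse(cvec > 0, ub, lb)
    val <- sum(cvec * x)
    return(list(status = "optimal", x = x,
                objval = if (maximize) val else -val))
  }

  # --- extended problem with one artificial per row -------------------------
  x0 <- lb
  r <- b - drop(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, abs(r) + 1)
  nx <- n + m
  art <- seq.int(n + 1L, nx)

  st <- new.env(parent = emptyenv())
  st$x <- c(x0, abs(r))
  st$basis <- art
  st$at_upper <- rep(FALSE, nx) # status of nonbasic variables

  run_simplex <- function(cost, fixed_ub) {
    # fixed_ub: current upper bounds (artificials get pinned to 0 in phase 2)
    maxit <- 20000L
    bland_after <- 1000L
    for (it in seq_len(maxit)) {
      B <- Aext[, st$basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cost[st$basis]),
                    error = function(e) stop("singular basis in lp_solve"))
      nonbasic <- setdiff(seq_len(nx), st$basis)
      dred <- cost[nonbasic] - drop(crossprod(Aext[, nonbasic, drop = FALSE], y))
      free <- fixed_ub[nonbasic] - lbe[nonbasic] > tol
      enter_lo <- !st$at_upper[nonbasic] & dred > tol & free
      enter_hi <- st$at_upper[nonbasic] & dred < -tol & free
      cand <- which(enter_lo | enter_hi)
      if (length(cand) == 0L) return("optimal")
      if (it > bland_after) {
        e_i <- cand[which.min(nonbasic[cand])]
      } else {
        e_i <- cand[which.max(abs(dred[cand]))]
      }
      e <- nonbasic[e_i]
      dirn <- if (st$at_upper[e]) -1 else 1
      w <- drop(solve(B, Aext[, e]))
      # ratio test: basic variables move by -dirn * step * w
      xb <- st$x[st$basis]
      tw <- dirn * w
      lims <- rep(Inf, m)
      to_upper <- rep(FALSE, m)
      pos <- tw > tol
      neg <- tw < -tol
      lims[pos] <- (xb[pos] - lbe[st$basis[pos]]) / tw[pos]
      lims[neg] <- (fixed_ub[st$basis[neg]] - xb[neg]) / (-tw[neg])
      to_upper[neg] <- TRUE
      lims[lims < 0] <- 0 # degenerate, slightly out-of-bound basics
      step_e <- fixed_ub[e] - lbe[e] # self-limit: entering variable bound flip
      min_lim <- min(lims)
      if (step_e < min_lim - tol) {
        # bound flip of the entering variable, basis unchanged
        st$x[st$basis] <- xb - tw * step_e
        st$x[e] <- st$x[e] + dirn * step_e
        st$at_upper[e] <- !st$at_upper[e]
      } else {
        if (!is.finite(min_lim)) stop("unbounded direction despite finite bounds")
        ties <- which(lims <= min_lim + tol)
        leave_pos <- ties[which.min(st$basis[ties])]
        step <- max(min(min_lim, step_e), 0)
        st$x[st$basis] <- xb - tw * step
        st$x[e] <- st$x[e] + dirn * step
        lv <- st$basis[leave_pos]
        st$x[lv] <- if (to_upper[leave_pos]) fixed_ub[lv] else lbe[lv]
        st$at_upper[lv] <- to_upper[leave_pos]
        st$basis[leave_pos] <- e
        st$at_upper[e] <- FALSE
      }
    }
    stop("lp_solve: iteration limit reached")
  }

  # phase 1: minimize sum of artificials
  c1 <- c(rep(0, n), rep(-1, m))
  run_simplex(c1, ube)
  if (sum(st$x[art]) > 1e-7)
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  # phase 2: pin artificials to zero, optimize the true objective
  st$x[art] <- 0
  ub2 <- ube
  ub2[art] <- 0
  c2 <- c(cvec, rep(0, m))
  run_simplex(c2, ub2)
  x <- st$x[seq_len(n)]
  # snap to bounds to remove roundoff dust
  x[abs(x - lb) < 1e-9] <- lb[abs(x - lb) < 1e-9]
  x[abs(x - ub) < 1e-9] <- ub[abs(x - ub) < 1e-9]
  val <- sum(cvec * x)
  list(status = "optimal", x = x, objval = if (maximize) val else -val)
}
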