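# Build and solve flux LPs on an assembled ecosystem.
#
# All problems share the steady-state rows S v = 0 and the flux bounds of the
# reaction table; callers may pin individual reactions (lb = ub = value) or
# append extra equality rows (used to pin objective VALUES c_i'v = y_i when
# sampling the Pareto front).

eco_lp <- function(eco, obj, fixed = NULL, extra_A = NULL, extra_b = NULL,
                   maximize = TRUE, min_total_flux = FALSE) {
  n <- nrow(eco$rxns)
  lb <- eco$rxns$lb; ub <- eco$rxns$ub
  if (!is.null(fixed) && length(fixed)) {
    idx <- match(names(fixed), eco$rxns$id)
    if (anyNA(idx)) stop("unknown reaction in `fixed`: ",
                         paste(names(fixed)[is.na(idx)], collapse = ", "))
    val <- as.numeric(fixed)
    if (any(val < lb[idx] - 1e-9 | val > ub[idx] + 1e-9))
      stop("fixed value outside reaction bounds")
    lb[idx] <- ub[idx] <- val
  }
  A <- as.matrix(eco$S)
  b <- rep(0, nrow(A))
  if (!is.null(extra_A)) {
    A <- rbind(A, extra_A)
    b <- c(b, extra_b)
  }
  if (!min_total_flux)
    return(lp_solve(obj, A, b, lb, ub, maximize = maximize))
  # parsimonious step: variables (v, p, q), v = p - q, minimize sum(p + q)
  m0 <- nrow(A)
  A2 <- cbind(A, matrix(0, m0, 2 * n))
  link <- cbind(diag(n), -diag(n), diag(n)) # v - p + q = 0
  A2 <- rbind(A2, link)
  b2 <- c(b, rep(0, n))
  lb2 <- c(lb, rep(0, 2 * n))
  ub2 <- c(ub, pmax(ub, 0), pmax(-lb, 0))
  c2 <- c(rep(0, n), rep(1, 2 * n))
  res <- lp_solve(c2, A2, b2, lb2, ub2, maximize = FALSE)
  if (res$status == "optimal") res$x <- res$x[seq_len(n)]
  res
}

objective_rows <- function(eco) eco$objectives # k x n weight matrix

#' Flux balance analysis on an ecosystem model
#'
#' Maximizes a weighted sum of the member objectives subject to the
#' steady-state constraint `S_sigma v = 0`, the flux bounds, and optional
#' equality pins on individual reactions. Because every reaction carries
#' finite bounds (the flux cap), the LP is always bounded; infeasible pins
#' are reported through `status`, never silently clipped.
#'
#' @param eco an `ecosystem_model`.
#' @param objective_weights numeric vector, one weight per member (default:
#'   all 1, the ecosystem-biomass direction).
#' @param fixed optional named numeric vector `reaction_id -> value` pinning
#'   fluxes (`lb = ub = value`).
#' @return a `flux_solution`: list with `status` ("optimal"/"infeasible"),
#'   `fluxes` (named vector over all ecosystem reactions), and
#'   `objective_values` (named per-member objective values).
#' @export
solve_fba <- function(eco, objective_weights = NULL, fixed = NULL) {
  stopifnot(inherits(eco, "ecosystem_model"))
  k <- length(eco$members)
  if (is.null(objective_weights)) objective_weights <- rep(1, k)
  stopifnot(length(objective_weights) == k, all(is.finite(objective_weights)))
  cvec <- drop(objective_weights %*% eco$objectives)
  res <- eco_lp(eco, cvec, fixed = fixed)
  if (res$status != "optimal")
    return(structure(list(status = res$status, fluxes = res$x,
                          objective_values = rep(NA_real_, k)),
                     class = "flux_solution"))
  ov <- drop(eco$objectives %*% res$x)
  structure(list(status = "optimal",
                 fluxes = stats::setNames(res$x, eco$rxns$id),
                 objective_values = stats::setNames(ov, names(eco$members))),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status, "\n")
  if (x$status == "optimal") {
    cat("objective values:\n")
    print(x$objective_values)
  }
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum attainable flux under the ecosystem
#' constraints and optional pins: the classical tool for calling a reaction
#' obligatory (its interval excludes zero) or blocked.
#'
#' @param eco an `ecosystem_model`.
#' @param reactions character vector of reaction ids (default: all).
#' @param fixed optional named pins as in [solve_fba()].
#' @param extra_A,extra_b optional extra equality rows (used internally to
#'   pin objective values).
#' @return data.frame with columns `id`, `min`, `max`.
#' @export
solve_fva <- function(eco, reactions = NULL, fixed = NULL,
                      extra_A = NULL, extra_b = NULL) {
  stopifnot(inherits(eco, "ecosystem_model"))
  if (is.null(reactions)) reactions <- eco$rxns$id
  idx <- match(reactions, eco$rxns$id)
  if (anyNA(idx)) stop("unknown reactions: ",
                       paste(reactions[is.na(idx)], collapse = ", "))
  n <- nrow(eco$rxns)
  res <- lapply(idx, function(i) {
    ei <- numeric(n); ei[i] <- 1
    lo <- eco_lp(eco, ei, fixed = fixed, extra_A = extra_A, extra_b = extra_b,
                 maximize = FALSE)
    hi <- eco_lp(eco, ei, fixed = fixed, extra_A = extra_A, extra_b = extra_b,
                 maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("infeasible constraints in solve_fva")
    c(lo$objval, hi$objval)
  })
  out <- do.call(rbind, res)
  data.frame(id = reactions, min = out[, 1], max = out[, 2],
             stringsAsFactors = FALSE)
}

nondominated <- function(P, tol = 1e-9) {
  keep <- rep(TRUE, nrow(P))
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(nrow(P))) {
      if (i == j || !keep[j]) next
      if (all(P[j, ] >= P[i, ] - tol) && any(P[j, ] > P[i, ] + tol)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  P[keep, , drop = FALSE]
}

dedupe_points <- function(P, tol = 1e-6) {
  if (nrow(P) <= 1) return(P)
  keep <- rep(TRUE, nrow(P))
  for (i in seq_len(nrow(P) - 1)) {
    if (!keep[i]) next
    for (j in seq((i + 1), nrow(P))) {
      if (keep[j] &&
          max(abs(P[i, ] - P[j, ])) < tol * (1 + max(abs(P[i, ]))))
        keep[j] <- FALSE
    }
  }
  P[keep, , drop = FALSE]
}

# maximize w'f, then (optionally) refine to a nondominated point by
# maximizing the unweighted sum at fixed w'f value
solve_weighted <- function(eco, w, refine = TRUE) {
  k <- length(eco$members)
  cvec <- drop(w %*% eco$objectives)
  res <- eco_lp(eco, cvec)
  if (res$status != "optimal")
    stop("weighted-sum solve failed (", res$status, ")")
  if (refine && any(w <= 1e-12)) {
    pin_row <- matrix(cvec, 1)
    res2 <- eco_lp(eco, drop(rep(1, k) %*% eco$objectives),
                   extra_A = pin_row, extra_b = res$objval)
    if (res2$status == "optimal") res <- res2
  }
  drop(eco$objectives %*% res$x)
}

#' Enumerate the Pareto front of an ecosystem model
#'
#' Computes the set of extreme points of the multi-objective LP
#' `max (f_1, ..., f_k) s.t. S_sigma v = 0, l <= v <= u` in objective space.
#' For two members the non-inferior set estimation (NISE) recursion is used:
#' the two lexicographic endpoints are computed, then each chord is probed
#' with its normal as weight vector until no chord can be improved beyond
#' `tol` - exact for LPs. For three or more members a facet-driven
#' generalization is used: the convex hull of the current point set is
#' computed, every hull facet with a nonnegative outward normal is probed as
#' a weight vector, and points beyond a facet are added until no facet
#' improves; if the front is rank-deficient (degenerate in objective space)
#' a deterministic weight-grid scan is used instead, which recovers all
#' vertices supported by the scanned weights.
#'
#' @param eco an `ecosystem_model`.
#' @param tol vertex deduplication/improvement tolerance (default 1e-6).
#' @param grid_q resolution of the fallback weight grid for degenerate
#'   fronts with k >= 3 (default 6).
#' @return a `pareto_front`: list with `points` (matrix, one row per extreme
#'   point, columns in member order), `organism_order`, `dimension`, and
#'   `solver_tolerance`.
#' @export
compute_pareto_front <- function(eco, tol = 1e-6, grid_q = 6L) {
  stopifnot(inherits(eco, "ecosystem_model"))
  k <- length(eco$members)
  # boundedness / feasibility pre-solves, one per member
  alone <- vapply(seq_len(k), function(i) {
    w <- numeric(k); w[i] <- 1
    cvec <- drop(w %*% eco$objectives)
    res <- eco_lp(eco, cvec)
    if (res$status != "optimal")
      stop("objective of member '", names(eco$members)[i],
           "' cannot be optimized (", res$status,
           "); constrain the diet or check the model")
    res$objval
  }, numeric(1))

  pts <- if (k == 1L) {
    matrix(alone, 1)
  } else if (k == 2L) {
    nise_front(eco, tol)
  } else {
    kd_front(eco, tol, grid_q)
  }
  pts <- dedupe_points(nondominated(pts, tol), tol)
  if (k == 2L) pts <- pts[order(pts[, 1], -pts[, 2]), , drop = FALSE]
  colnames(pts) <- names(eco$members)
  structure(list(points = pts, organism_order = names(eco$members),
                 dimension = k, solver_tolerance = tol),
            class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  cat("<pareto_front> k =", x$dimension, "-", nrow(x$points),
      "extreme points\n")
  print(utils::head(x$points, 10))
  if (nrow(x$points) > 10) cat("...\n")
  invisible(x)
}

# two-stage lexicographic solve: max f_i, then max f_j (j != i) at that value
lex_point <- function(eco, i) {
  k <- length(eco$members)
  w <- numeric(k); w[i] <- 1
  cvec <- drop(w %*% eco$objectives)
  res <- eco_lp(eco, cvec)
  others <- drop((1 - w) %*% eco$objectives)
  res2 <- eco_lp(eco, others, extra_A = matrix(cvec, 1), extra_b = res$objval)
  if (res2$status != "optimal") stop("lexicographic refinement failed")
  drop(eco$objectives %*% res2$x)
}

nise_front <- function(eco, tol) {
  p_left <- lex_point(eco, 2)  # max f2 first: left end (low f1, high f2)
  p_right <- lex_point(eco, 1)
  pts <- list(p_left, p_right)
  probe <- function(pa, pb, depth) {
    if (depth > 60) return(invisible())
    w <- c(pa[2] - pb[2], pb[1] - pa[1])
    if (max(abs(w)) < tol) return(invisible())
    w <- w / sum(abs(w))
    cvec <- drop(w %*% eco$objectives)
    res <- eco_lp(eco, cvec)
    if (res$status != "optimal") stop("NISE probe failed")
    p <- drop(eco$objectives %*% res$x)
    if (res$objval > sum(w * pa) + tol * (1 + abs(res$objval))) {
      pts[[length(pts) + 1L]] <<- p
      probe(pa, p, depth + 1)
      probe(p, pb, depth + 1)
    }
  }
  probe(p_left, p_right, 1)
  do.call(rbind, pts)
}

kd_front <- function(eco, tol, grid_q) {
  k <- length(eco$members)
  pts <- lapply(seq_len(k), function(i) lex_point(eco, i))
  pts[[k + 1L]] <- solve_weighted(eco, rep(1 / k, k), refine = FALSE)
  P <- dedupe_points(do.call(rbind, pts), tol)
  if (nrow(P) == 1L) return(P) # single-vertex front (e.g. fully coupled)
  for (iter in seq_len(40L)) {
    anchor <- apply(P, 2, min) - 1
    fac <- hull_facets(rbind(P, anchor), tol = 1e-9)
    if (is.null(fac)) return(kd_front_grid(eco, P, grid_q))
    added <- FALSE
    for (f in fac) {
      w <- f$normal
      if (any(w < -1e-7) || sum(w) <= 1e-9) next
      w <- pmax(w, 0); w <- w / sum(w)
      y <- solve_weighted(eco, w, refine = FALSE)
      if (sum(w * y) > max(drop(P %*% w)) + tol * (1 + abs(sum(w * y)))) {
        P <- rbind(P, y)
        added <- TRUE
      }
    }
    if (!added) break
    P <- dedupe_points(P, tol)
  }
  P
}

# deterministic weight-grid scan: all compositions of grid_q over k weights
kd_front_grid <- function(eco, P, grid_q) {
  comps <- compositions_of(grid_q, length(eco$members))
  for (i in seq_len(nrow(comps))) {
    w <- comps[i, ]
    if (sum(w) == 0) next
    P <- rbind(P, solve_weighted(eco, w / sum(w)))
  }
  P
}

compositions_of <- function(q, k) {
  if (k == 1L) return(matrix(q, 1))
  out <- list()
  for (first in 0:q) {
    rest <- compositions_of(q - first, k - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  unname(do.call(rbind, out))
}
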