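# Exact convex-hull facet enumeration and volume for small point sets in low
# dimension (the objective space of an ecosystem: k <= ~6, tens of points).
# Facets are found by brute force over d-subsets: a subset spans a supporting
# hyperplane iff all points lie on one side. Coplanar subsets are merged by
# hyperplane identity, so degenerate (non-simplicial) facets such as the
# faces of a hypercube are handled exactly. Volume is the sum of pyramids
# from the centroid to each facet, with facet areas obtained recursively in
# the facet's own hyperplane.

affine_rank <- function(X, tol = 1e-9) {
  if (nrow(X) <= 1L) return(0L)
  C <- sweep(X, 2, colMeans(X))
  sv <- svd(C, nu = 0, nv = 0)$d
  sum(sv > tol * max(1, sv[1]))
}

# list of facets (outward unit `normal`, `offset`, point indices `idx`),
# or NULL when the points do not span the full dimension
hull_facets <- function(X, tol = 1e-9) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < d + 1L || affine_rank(X, tol) < d) return(NULL)
  scale <- max(1, max(abs(X)))
  tola <- tol * scale
  seen <- character()
  facets <- list()
  subsets <- utils::combn(n, d)
  for (s in seq_len(ncol(subsets))) {
    S <- subsets[, s]
    M <- t(X[S[-1], , drop = FALSE] -
             matrix(X[S[1], ], d - 1, d, byrow = TRUE))
    qrM <- qr(M)
    if (qrM$rank < d - 1L) next # degenerate subset
    normal <- qr.Q(qrM, complete = TRUE)[, d]
    offset <- sum(normal * X[S[1], ])
    side <- drop(X %*% normal) - offset
    if (max(side) <= tola) {
      # points on the non-positive side: outward is +normal
    } else if (min(side) >= -tola) {
      normal <- -normal; offset <- -offset; side <- -side
    } else next
    key <- paste(round(c(normal, offset / scale), 7), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    facets[[length(facets) + 1L]] <-
      list(normal = normal, offset = offset, idx = which(abs(side) <= tola))
  }
  facets
}

#' Volume of the convex hull of a point set
#'
#' Exact (up to floating point) hypervolume of `conv(points)`, the quantity
#' the k-dimensional interaction score is built from. Rank-deficient point
#' sets (a hull flat in some direction) have volume 0.
#'
#' @param points numeric matrix, one point per row, `k >= 2` columns.
#' @param tol degeneracy tolerance (default 1e-9).
#' @return non-negative numeric scalar.
#' @examples
#' hypervolume(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) # unit square: 1
#' @export
hypervolume <- function(points, tol = 1e-9) {
  points <- as.matrix(points)
  if (ncol(points) < 2L) stop("hypervolume requires k >= 2 dimensions")
  hull_volume_rec(points, tol)
}

hull_volume_rec <- function(X, tol) {
  d <- ncol(X)
  if (d == 1L) return(max(X) - min(X))
  X <- unique(round(X, 12))
  if (nrow(X) < d + 1L || affine_rank(X, tol) < d) return(0)
  facets <- hull_facets(X, tol)
  if (is.null(facets)) return(0)
  ctr <- colMeans(X)
  vol <- 0
  for (f in facets) {
    Fp <- X[f$idx, , drop = FALSE]
    c0 <- colMeans(Fp)
    Cf <- sweep(Fp, 2, c0)
    B <- svd(Cf, nu = 0, nv = d - 1L)$v # orthonormal basis of the facet plane
    area <- hull_volume_rec(Cf %*% B, tol)
    h <- abs(sum(f$normal * ctr) - f$offset)
    vol <- vol + area * h / d
  }
  vol
}
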