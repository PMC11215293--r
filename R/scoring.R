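#' Normalize a Pareto front by alone-growth maxima
#'
#' Each objective axis is divided by the member's maximal objective value
#' when the organism is alone under the same diet: the member model is
#' assembled into a one-member ecosystem (its own pool), the diet is applied,
#' and a standalone FBA is solved. This normalization makes fronts of
#' ecosystems built from different organisms comparable: a coordinate of 1
#' means "as well as alone", above 1 means the partner improves it. The
#' "original growth points" (the k unit vectors) are appended to the
#' normalized front, exactly once each.
#'
#' @param front a [compute_pareto_front()] result.
#' @param eco the `ecosystem_model` the front was computed on.
#' @param diet optional [diet_spec()]; defaults to the diet stored in `eco`.
#' @return a `normalized_front`: list with `base`, `alone_maxima`,
#'   `points` (normalized front points), `augmented` (points plus unit
#'   vectors), `organism_order`.
#' @export
normalize_front <- function(front, eco, diet = NULL) {
  stopifnot(inherits(front, "pareto_front"), inherits(eco, "ecosystem_model"))
  if (is.null(diet)) diet <- eco$diet
  k <- front$dimension
  alone <- vapply(names(eco$members), function(id) {
    one <- build_ecosystem(eco$members[id], default_bound = eco$default_bound)
    if (!is.null(diet)) one <- suppressMessages(apply_diet(one, diet))
    sol <- solve_fba(one, 1)
    if (sol$status != "optimal") return(NA_real_)
    unname(sol$objective_values)
  }, numeric(1))
  bad <- is.na(alone) | alone <= 1e-6
  if (any(bad))
    stop("score undefined: zero standalone growth for ",
         paste(names(eco$members)[bad], collapse = ", "))
  pts <- sweep(front$points, 2, alone, "/")
  pts[abs(pts) < 1e-9] <- 0
  aug <- rbind(pts, diag(k))
  aug <- dedupe_points(aug, 1e-7)
  structure(list(base = front, alone_maxima = alone, points = pts,
                 augmented = aug, organism_order = front$organism_order),
            class = "normalized_front")
}

#' Area under an ordered 2-D front polyline
#'
#' Trapezoidal area under a polyline whose x coordinates increase, except
#' possibly at the final point. A normalized bi-objective Pareto front
#' augmented with the original growth points can be non-monotone only at its
#' last point (when the first member's ecosystem optimum exceeds its alone
#' optimum, the appended point (1, 0) steps backwards); in that case the
#' area of the final segment is subtracted from the area of the monotone
#' prefix. A break anywhere else is an input error.
#'
#' @param points numeric matrix (n x 2) of ordered polyline points.
#' @return numeric scalar.
#' @examples
#' auc_2d(rbind(c(0, 1), c(1, 0))) # 0.5
#' @export
auc_2d <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("auc_2d needs at least 2 points")
  dx <- diff(points[, 1])
  if (n > 2L && any(dx[-length(dx)] < -1e-9))
    stop("interior monotonicity break: a Pareto front can be non-monotone ",
         "only at its last point")
  trap <- function(p) {
    sum(abs(diff(p[, 1])) * (utils::head(p[, 2], -1) + p[-1, 2]) / 2)
  }
  if (dx[length(dx)] < -1e-12) {
    trap(points[-n, , drop = FALSE]) -
      trap(points[(n - 1):n, , drop = FALSE])
  } else {
    trap(points)
  }
}

# order the augmented normalized points as the scored polyline:
# (0,1), front points by ascending first coordinate, then (1,0)
augmented_polyline <- function(nf) {
  pts <- nf$points
  pts <- pts[order(pts[, 1], -pts[, 2]), , drop = FALSE]
  out <- rbind(c(0, 1), pts, c(1, 0))
  keep <- c(TRUE, vapply(seq_len(nrow(out))[-1], function(i) {
    max(abs(out[i, ] - out[i - 1, ])) > 1e-7
  }, logical(1)))
  out[keep, , drop = FALSE]
}

#' Ecosystem interaction score from a normalized front
#'
#' For two members the score is `S = AUC_P - AUC_NI`: the area under the
#' augmented normalized front minus the area under the non-interaction front
#' (the front of a neutral ecosystem, the square through (0,1), (1,1),
#' (1,0), of area 1). For k >= 3 members the same construction uses
#' hypervolumes: the convex-hull volume of the augmented points plus the
#' origin, minus the non-interaction hypervolume (hull of the origin, the k
#' unit vectors and the all-ones point - the neutral front's single point
#' under the same augmentation). Positive scores indicate mutualistic
#' interactions, zero neutrality, negative competition. Scores of different
#' dimensionality are not mutually comparable.
#'
#' @param nf a [normalize_front()] result.
#' @param type_tol tolerance used for the interaction-type flags (k = 2).
#' @return an `interaction_report`: list with `score`, `auc_p`, `auc_ni`,
#'   `flags`, `interaction_type` (k = 2 only, else NA), `k`,
#'   `organism_order`, `removal_scores` (NULL here; see
#'   [removal_analysis()]).
#' @export
interaction_score <- function(nf, type_tol = 1e-6) {
  stopifnot(inherits(nf, "normalized_front"))
  k <- length(nf$organism_order)
  if (k == 2L) {
    poly <- augmented_polyline(nf)
    auc_p <- auc_2d(poly)
    auc_ni <- 1
    s <- auc_p - auc_ni
  } else {
    aug <- rbind(nf$augmented, rep(0, k))
    auc_p <- hypervolume(aug)
    auc_ni <- hypervolume(rbind(diag(k), rep(1, k), rep(0, k)))
    s <- auc_p - auc_ni
  }
  rep <- structure(list(score = s, auc_p = auc_p, auc_ni = auc_ni,
                        flags = NULL, interaction_type = NA_character_,
                        k = k, organism_order = nf$organism_order,
                        alone_maxima = nf$alone_maxima,
                        removal_scores = NULL),
                   class = "interaction_report")
  if (k == 2L) {
    rep$interaction_type <- classify_interaction(nf, rep, tol = type_tol)
    rep$flags <- attr(rep$interaction_type, "flags")
    attr(rep$interaction_type, "flags") <- NULL
  }
  rep
}

#' @export
print.interaction_report <- function(x, ...) {
  cat("<interaction_report> k =", x$k, "\n")
  cat("  S =", format(x$score, digits = 6),
      " (AUC_P =", format(x$auc_p, digits = 6),
      ", AUC_NI =", format(x$auc_ni, digits = 6), ")\n")
  if (!is.na(x$interaction_type))
    cat("  type:", x$interaction_type, "\n")
  if (!is.null(x$removal_scores)) {
    cat("  removal scores (k-1 dimensional, not comparable to S):\n")
    print(x$removal_scores)
  }
  invisible(x)
}

#' Classify a bi-objective interaction from the front's shape
#'
#' Four boolean conditions summarize the normalized front: the sign of the
#' score; whether some front point puts the first member (the host in a
#' host-bacterium pair) above its alone optimum (E+); the same for the
#' second member (B+); and, when both hold, whether a single front point
#' attains both members' front maxima simultaneously (E+B+). The six
#' combinations observed in bi-objective fronts map to interaction types;
#' anything else is reported as `Unclassified`. Scores within `tol` of zero
#' count as the "+" sign row, so exact neutrality classifies as Neutralism.
#'
#' @param nf a [normalize_front()] result (must have k = 2).
#' @param report an [interaction_score()] report for `nf` (for the score);
#'   may be NULL, in which case the score is recomputed.
#' @param tol relative tolerance for the flags (default 1e-6).
#' @return character scalar, one of Neutralism, Competition, FavorsHost,
#'   FavorsBacteria, LimitedMutualism, Mutualism, Unclassified; with
#'   attribute `flags`.
#' @export
classify_interaction <- function(nf, report = NULL, tol = 1e-6) {
  stopifnot(inherits(nf, "normalized_front"))
  if (length(nf$organism_order) != 2L)
    stop("interaction types are defined for two-member ecosystems only")
  s <- if (is.null(report)) {
    auc_2d(augmented_polyline(nf)) - 1
  } else report$score
  pts <- nf$points
  e_plus <- any(pts[, 1] > 1 + tol)
  b_plus <- any(pts[, 2] > 1 + tol)
  eb_plus <- FALSE
  if (e_plus && b_plus) {
    m1 <- max(pts[, 1]); m2 <- max(pts[, 2])
    eb_plus <- any(pts[, 1] >= m1 - tol * (1 + m1) &
                     pts[, 2] >= m2 - tol * (1 + m2))
  }
  sign_plus <- s >= -tol
  type <- if (!e_plus && !b_plus && !eb_plus) {
    if (sign_plus) "Neutralism" else "Competition"
  } else if (sign_plus && e_plus && !b_plus) {
    "FavorsHost"
  } else if (sign_plus && !e_plus && b_plus) {
    "FavorsBacteria"
  } else if (sign_plus && e_plus && b_plus && !eb_plus) {
    "LimitedMutualism"
  } else if (sign_plus && e_plus && b_plus && eb_plus) {
    "Mutualism"
  } else {
    "Unclassified"
  }
  structure(type, flags = list(sign = if (sign_plus) "+" else "-",
                               E_plus = e_plus, B_plus = b_plus,
                               EB_plus = eb_plus))
}

#' Organism-removal decomposition of the interaction score
#'
#' Rebuilds and re-scores the ecosystem with each member removed in turn,
#' under the same diet. A cross-feeder's removal collapses the interactions
#' it sustains (low residual score); a bystander's removal leaves the score
#' high. The returned scores live in k-1 dimensions and are not
#' mathematically comparable to the full k-dimensional score (or across
#' different k); they are a ranking tool.
#'
#' @param eco an `ecosystem_model` with k >= 3 members.
#' @param diet optional [diet_spec()]; defaults to the diet stored in `eco`.
#' @return named numeric vector of removal scores, one per removed member,
#'   with attribute `dimension` = k - 1.
#' @export
removal_analysis <- function(eco, diet = NULL) {
  stopifnot(inherits(eco, "ecosystem_model"))
  k <- length(eco$members)
  if (k < 3L) stop("removal analysis needs at least 3 members")
  if (!is.null(diet)) eco <- apply_diet(eco, diet)
  out <- vapply(names(eco$members), function(id) {
    sub <- remove_member(eco, id)
    fr <- compute_pareto_front(sub)
    nf <- normalize_front(fr, sub)
    interaction_score(nf)$score
  }, numeric(1))
  attr(out, "dimension") <- k - 1L
  out
}

#' Score an ecosystem end to end
#'
#' Full pipeline: read the member models, assemble the ecosystem, apply the
#' diet, enumerate the Pareto front, normalize it, and compute the
#' interaction score (plus the interaction type for two members and,
#' optionally, the removal decomposition for three or more). Deterministic:
#' repeated runs on the same inputs give identical reports.
#'
#' @param model_paths character vector of model paths (see [read_model()]),
#'   or a list of `metabolic_model` objects. At least 2 members.
#' @param diet_path path to a diet TSV ([read_diet()]), a `diet_spec`, or
#'   NULL for the unconstrained diet.
#' @param removal logical; also run [removal_analysis()] (k >= 3 only).
#' @param default_bound flux cap for assembly (default 1000).
#' @return an `interaction_report` with the extra elements `front` and
#'   `normalized`.
#' @export
score_ecosystem <- function(model_paths, diet_path = NULL, removal = FALSE,
                            default_bound = 1000) {
  models <- if (is.list(model_paths) &&
                all(vapply(model_paths, inherits, TRUE, "metabolic_model"))) {
    model_paths
  } else {
    lapply(model_paths, read_model)
  }
  if (length(models) < 2L)
    stop("score_ecosystem needs at least 2 member models")
  diet <- if (is.null(diet_path)) NULL
          else if (inherits(diet_path, "diet_spec")) diet_path
          else read_diet(diet_path)
  eco <- build_ecosystem(models, default_bound = default_bound)
  if (!is.null(diet)) eco <- apply_diet(eco, diet)
  front <- compute_pareto_front(eco)
  nf <- normalize_front(front, eco)
  report <- interaction_score(nf)
  if (removal && length(models) >= 3L)
    report$removal_scores <- removal_analysis(eco)
  report$front <- front
  report$normalized <- nf
  report
}
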