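#' Sample flux distributions along a bi-objective Pareto front
#'
#' Places `n` points uniformly by arc length along the front polyline
#' (endpoints included) and, for each point, solves one FBA with both member
#' objectives pinned at the point's coordinates. Because pinning two
#' objectives usually leaves the flux space under-determined, a secondary
#' criterion selects the reported solution: `min_total_flux` (default)
#' minimizes the summed absolute flux, giving a deterministic parsimonious
#' representative; `none` accepts an arbitrary optimal basis.
#'
#' @param eco a two-member `ecosystem_model`.
#' @param front its [compute_pareto_front()] result.
#' @param n number of samples, >= 2 (the reference analyses in the field use
#'   1e5; small toy fronts saturate far earlier).
#' @param secondary `"min_total_flux"` or `"none"`.
#' @return a `flux_sample_matrix`: list with `samples` (n x n_bar flux
#'   matrix), `front_points` (the pinned objective pairs), and
#'   `ecosystem_biomass` (rowwise sum of the pinned objective values).
#' @export
sample_front <- function(eco, front, n = 100000,
                         secondary = c("min_total_flux", "none")) {
  secondary <- match.arg(secondary)
  stopifnot(inherits(eco, "ecosystem_model"), inherits(front, "pareto_front"))
  if (front$dimension != 2L)
    stop("front sampling is defined for bi-objective fronts")
  if (n < 2L) stop("need n >= 2 samples")
  pts <- front$points[order(front$points[, 1]), , drop = FALSE]
  if (nrow(pts) == 1L) {
    targets <- pts[rep(1L, n), , drop = FALSE]
  } else {
    seg <- sqrt(rowSums(diff(pts)^2))
    cum <- c(0, cumsum(seg))
    at <- seq(0, cum[length(cum)], length.out = n)
    targets <- t(vapply(at, function(a) {
      i <- max(which(cum <= a + 1e-12))
      if (i >= nrow(pts)) return(pts[nrow(pts), ])
      frac <- (a - cum[i]) / seg[i]
      pts[i, ] + frac * (pts[i + 1, ] - pts[i, ])
    }, numeric(2)))
  }
  ctr <- colMeans(pts)
  k <- 2L
  obj <- eco$objectives
  rows <- vector("list", n)
  kept <- logical(n)
  for (s in seq_len(n)) {
    p <- targets[s, ]
    res <- eco_lp(eco, numeric(nrow(eco$rxns)), extra_A = obj, extra_b = p,
                  min_total_flux = (secondary == "min_total_flux"))
    if (res$status != "optimal") {
      p2 <- p + 1e-9 * (ctr - p)
      res <- eco_lp(eco, numeric(nrow(eco$rxns)), extra_A = obj,
                    extra_b = p2, min_total_flux =
                      (secondary == "min_total_flux"))
    }
    if (res$status != "optimal") {
      warning("dropping infeasible sample point (", paste(signif(p, 6),
              collapse = ", "), ")")
      next
    }
    rows[[s]] <- res$x
    kept[s] <- TRUE
  }
  samples <- do.call(rbind, rows[kept])
  colnames(samples) <- eco$rxns$id
  structure(list(samples = samples,
                 front_points = targets[kept, , drop = FALSE],
                 ecosystem_biomass = rowSums(targets[kept, , drop = FALSE])),
            class = "flux_sample_matrix")
}

#' @export
print.flux_sample_matrix <- function(x, ...) {
  cat("<flux_sample_matrix>", nrow(x$samples), "samples x",
      ncol(x$samples), "reactions\n")
  invisible(x)
}

exchange_columns <- function(eco) {
  which(eco$rxns$type %in% c("TR", "blood"))
}

#' Identify interaction-driver exchanges by correlation with ecosystem biomass
#'
#' Spearman rank correlation (average ranks on ties) of every transport
#' (organism-pool) and host-blood flux against the ecosystem biomass across
#' the front samples. Under the negative-flux-is-uptake convention, a
#' correlation at or above `threshold` marks a secretion that accompanies
#' ecosystem growth, at or below `-threshold` an uptake that does; both are
#' reported as drivers of the interaction. Constant flux columns (undefined
#' correlation) are skipped.
#'
#' @param fsm a [sample_front()] result.
#' @param eco the matching `ecosystem_model`.
#' @param threshold absolute correlation cut-off (default 0.95).
#' @return data.frame with columns `reaction_id`, `metabolite_id`,
#'   `member_id`, `direction` ("secreted"/"uptaken"), `rho`.
#' @export
correlate_drivers <- function(fsm, eco, threshold = 0.95) {
  stopifnot(inherits(fsm, "flux_sample_matrix"),
            inherits(eco, "ecosystem_model"))
  if (nrow(fsm$samples) < 3L)
    stop("need at least 3 samples to correlate")
  bio <- fsm$ecosystem_biomass
  out <- list()
  for (j in exchange_columns(eco)) {
    v <- fsm$samples[, j]
    rho <- suppressWarnings(stats::cor(v, bio, method = "spearman"))
    if (is.na(rho) || abs(rho) < threshold) next
    met <- eco$rxns$pool_met[j]
    if (is.na(met)) { # blood reaction: its single metabolite
      m <- eco$members[[eco$rxns$member[j]]]
      met <- rownames(m$S)[which(m$S[, eco$rxns$orig_id[j]] != 0)][1]
    }
    out[[length(out) + 1L]] <- data.frame(
      reaction_id = eco$rxns$id[j], metabolite_id = met,
      member_id = eco$rxns$member[j],
      direction = if (rho > 0) "secreted" else "uptaken",
      rho = rho, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(reaction_id = character(), metabolite_id = character(),
                      member_id = character(), direction = character(),
                      rho = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Detect exchanged (cross-fed) metabolites from front samples
#'
#' For every pool metabolite transported by at least two members, correlates
#' one member's secretion flux with another member's uptake flux across the
#' samples (Spearman). Pairs exceeding `threshold`, with actual secretion and
#' uptake occurring, are reported as exchanged metabolites with their
#' producer and consumer.
#'
#' @param fsm a [sample_front()] result.
#' @param eco the matching `ecosystem_model`.
#' @param threshold pairing correlation cut-off (default 0.5).
#' @return data.frame with columns `metabolite_id`, `producer_id`,
#'   `consumer_id`, `rho_pair`.
#' @export
find_exchanged <- function(fsm, eco, threshold = 0.5) {
  stopifnot(inherits(fsm, "flux_sample_matrix"),
            inherits(eco, "ecosystem_model"))
  if (nrow(fsm$samples) < 3L)
    stop("need at least 3 samples to correlate")
  tr <- eco$rxns[eco$rxns$type == "TR", ]
  out <- list()
  for (met in unique(tr$pool_met)) {
    sub <- tr[tr$pool_met == met, ]
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub))) for (j in seq_len(nrow(sub))) {
      if (i == j) next
      sec <- fsm$samples[, sub$id[i]]   # positive = secretion into the pool
      upt <- -fsm$samples[, sub$id[j]]  # positive = uptake from the pool
      if (max(sec) <= 1e-9 || max(upt) <= 1e-9) next
      rho <- suppressWarnings(stats::cor(sec, upt, method = "spearman"))
      if (is.na(rho) || rho <= threshold) next
      out[[length(out) + 1L]] <- data.frame(
        metabolite_id = met, producer_id = sub$member[i],
        consumer_id = sub$member[j], rho_pair = rho,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(metabolite_id = character(), producer_id = character(),
                      consumer_id = character(), rho_pair = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Obligatory reactions at a point of the objective space
#'
#' Pins the member objectives at `point` and runs a flux variability
#' analysis: reactions whose flux interval excludes zero cannot be inactive
#' in any flux distribution realizing that community phenotype - they are
#' obligatory for it.
#'
#' @param eco an `ecosystem_model`.
#' @param point numeric vector of k objective values (on or inside the
#'   front; infeasible points raise an error).
#' @param reactions reaction ids to test (default: all).
#' @param eps activity tolerance (default 1e-6).
#' @return character vector of obligatory reaction ids.
#' @export
find_obligatory <- function(eco, point, reactions = NULL, eps = 1e-6) {
  stopifnot(inherits(eco, "ecosystem_model"),
            length(point) == length(eco$members))
  fva <- solve_fva(eco, reactions, extra_A = eco$objectives,
                   extra_b = as.numeric(point))
  fva$id[fva$min > eps | fva$max < -eps]
}
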