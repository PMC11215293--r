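#' Assemble member models into a pool-compartment ecosystem
#'
#' The member stoichiometric matrices are diagonally assembled into one
#' ecosystem matrix. Each member's exchange reactions become transport
#' reactions (TR) between the member's external compartment and a shared pool
#' compartment, and every metabolite exchanged by at least one member gets a
#' single pool exchange reaction (ER) connecting the pool to the environment.
#' TR are left unconstrained (at the numerical flux cap) so metabolites
#' transit freely; diets constrain the ER only (see [apply_diet()]).
#'
#' Pool metabolite identity is by metabolite id: two members sharing an
#' exchange metabolite id share the pool species. Namespace mapping
#' ([apply_namespace()]) is therefore the user's contract for cross-model
#' compatibility. Host blood reactions are kept inside the member block and
#' are not routed through the pool.
#'
#' @param members list of [metabolic_model()] objects (unique `model_id`s).
#' @param default_bound flux cap used for TR and unconstrained ER bounds
#'   (default 1000 mmol/gDW/h).
#' @return an object of class `ecosystem_model` with elements `members`,
#'   `rxns` (reaction table: id, member, type internal/blood/TR/ER, orig_id,
#'   pool_met, lb, ub), `S` (sparse ecosystem stoichiometric matrix),
#'   `objectives` (k x n weight matrix, one row per member) and `diet`.
#' @export
build_ecosystem <- function(members, default_bound = 1000) {
  stopifnot(is.list(members), length(members) >= 1L)
  lapply(members, validate_metabolic_model)
  ids <- vapply(members, `[[`, "", "model_id")
  if (anyDuplicated(ids))
    stop("build error: duplicate member ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(members) > 11L)
    warning("ecosystem has more than 11 members; multi-objective ",
            "enumeration may become expensive")
  names(members) <- ids

  met_rows <- character(); rxn_tab <- list()
  trip <- list() # (i, j, x) triplets for the sparse assembly
  pool_mets <- character()
  for (m in members) {
    if (length(m$exchange_ids) == 0L)
      warning("member '", m$model_id, "' has no exchange reactions; ",
              "it is joined to the ecosystem but isolated from the pool")
    pref <- function(x) paste0(m$model_id, ":", x)
    met_rows <- c(met_rows, pref(m$metabolites$id))
    nm <- Matrix::colSums(m$S != 0)
    single_met <- vapply(m$reactions$id, function(r) {
      if (nm[[r]] != 1) return(NA_character_)
      rownames(m$S)[which(m$S[, r] != 0)]
    }, character(1))
    comp <- m$metabolites$compartment[match(single_met, m$metabolites$id)]
    for (i in seq_len(nrow(m$reactions))) {
      rid <- m$reactions$id[i]
      is_tr <- rid %in% m$exchange_ids
      type <- if (is_tr) "TR"
              else if (!is.na(comp[i]) && comp[i] %in% m$blood_compartment)
                "blood"
              else "internal"
      pm <- NA_character_
      lb <- m$reactions$lb[i]; ub <- m$reactions$ub[i]
      if (is_tr) {
        pm <- single_met[[rid]]
        pool_mets <- union(pool_mets, pm)
        lb <- -default_bound; ub <- default_bound # TR unconstrained
      }
      rxn_tab[[length(rxn_tab) + 1L]] <- data.frame(
        id = pref(rid), member = m$model_id, type = type, orig_id = rid,
        pool_met = pm, lb = lb, ub = ub, stringsAsFactors = FALSE)
      v <- m$S[, rid]
      nz <- which(v != 0)
      trip[[length(trip) + 1L]] <- data.frame(
        met = pref(rownames(m$S)[nz]), rxn = pref(rid), x = v[nz],
        stringsAsFactors = FALSE)
      if (is_tr) {
        # positive TR flux moves the metabolite into the pool (secretion)
        coef <- v[[pm]]
        trip[[length(trip) + 1L]] <- data.frame(
          met = paste0("pool:", pm), rxn = pref(rid), x = -coef,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (pm in pool_mets) {
    rxn_tab[[length(rxn_tab) + 1L]] <- data.frame(
      id = paste0("ER_", pm), member = NA_character_, type = "ER",
      orig_id = NA_character_, pool_met = pm,
      lb = -default_bound, ub = default_bound, stringsAsFactors = FALSE)
    trip[[length(trip) + 1L]] <- data.frame(
      met = paste0("pool:", pm), rxn = paste0("ER_", pm), x = -1,
      stringsAsFactors = FALSE)
  }
  rxns <- do.call(rbind, rxn_tab)
  met_rows <- c(met_rows, paste0("pool:", pool_mets))
  tr <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(
    i = match(tr$met, met_rows), j = match(tr$rxn, rxns$id), x = tr$x,
    dims = c(length(met_rows), nrow(rxns)),
    dimnames = list(met_rows, rxns$id))
  objectives <- matrix(0, length(members), nrow(rxns),
                       dimnames = list(ids, rxns$id))
  for (m in members) {
    sel <- m$reactions$objective != 0
    objectives[m$model_id, paste0(m$model_id, ":", m$reactions$id[sel])] <-
      m$reactions$objective[sel]
  }
  structure(list(members = members, rxns = rxns, S = S,
                 objectives = objectives, diet = NULL,
                 default_bound = default_bound,
                 skipped_diet_ids = character()),
            class = "ecosystem_model")
}

#' @export
print.ecosystem_model <- function(x, ...) {
  cat("<ecosystem_model> ", length(x$members), " members (",
      paste(names(x$members), collapse = ", "), "), ",
      nrow(x$rxns), " reactions (", sum(x$rxns$type == "TR"), " TR, ",
      sum(x$rxns$type == "ER"), " ER), diet: ",
      if (is.null(x$diet)) "none" else x$diet$name, "\n", sep = "")
  invisible(x)
}

#' Number of ecosystem reactions
#'
#' Total reaction count of the assembled problem: the sum of the members'
#' reaction counts plus the pool exchange reactions.
#'
#' @param eco an `ecosystem_model`.
#' @return integer scalar.
#' @export
n_bar <- function(eco) nrow(eco$rxns)

#' Constrain an ecosystem with a diet
#'
#' Sets the pool exchange (ER) bounds from the diet's lumen table (negative
#' flux = supply into the pool). ER absent from the diet follow the diet's
#' `default_policy`: unconstrained diets leave them at the flux cap, blocked
#' diets close them. Host blood reactions are constrained from the diet's
#' blood table by reaction id. Diet entries matching neither an ER metabolite
#' nor a blood reaction are collected in the returned model's
#' `skipped_diet_ids` (with a message), not treated as fatal.
#'
#' @param eco an `ecosystem_model`.
#' @param diet a [diet_spec()].
#' @return a new constrained `ecosystem_model`.
#' @export
apply_diet <- function(eco, diet) {
  stopifnot(inherits(eco, "ecosystem_model"), inherits(diet, "diet_spec"))
  cap <- eco$default_bound
  er <- eco$rxns$type == "ER"
  eco$rxns$lb[er] <- if (diet$default_policy == "blocked") 0 else -cap
  eco$rxns$ub[er] <- if (diet$default_policy == "blocked") 0 else cap
  skipped <- character()
  for (met in names(diet$lumen_bounds)) {
    hit <- er & eco$rxns$pool_met == met
    hit[is.na(hit)] <- FALSE
    if (!any(hit)) { skipped <- c(skipped, met); next }
    eco$rxns$lb[hit] <- diet$lumen_bounds[[met]][1]
    eco$rxns$ub[hit] <- diet$lumen_bounds[[met]][2]
  }
  for (rid in names(diet$blood_bounds)) {
    hit <- eco$rxns$id == rid |
      (!is.na(eco$rxns$orig_id) & eco$rxns$orig_id == rid &
         eco$rxns$type == "blood")
    if (!any(hit)) { skipped <- c(skipped, rid); next }
    eco$rxns$lb[hit] <- diet$blood_bounds[[rid]][1]
    eco$rxns$ub[hit] <- diet$blood_bounds[[rid]][2]
  }
  if (length(skipped))
    message("diet ids not matching any pool exchange or blood reaction ",
            "(skipped): ", paste(skipped, collapse = ", "))
  eco$diet <- diet
  eco$skipped_diet_ids <- skipped
  eco
}

#' Remove one member from an ecosystem
#'
#' Rebuilds the ecosystem from the remaining source models: the member's
#' block and transport reactions disappear, pool exchanges are kept only for
#' metabolites still exchanged by a remaining member, and the diet (if any)
#' is re-applied.
#'
#' @param eco an `ecosystem_model`.
#' @param member_id id of the member to drop.
#' @return a new `ecosystem_model` with `k - 1` members.
#' @export
remove_member <- function(eco, member_id) {
  stopifnot(inherits(eco, "ecosystem_model"))
  if (!member_id %in% names(eco$members))
    stop("no such member: ", member_id)
  if (length(eco$members) <= 2L)
    stop("removal would leave fewer than 2 members; no interaction to score")
  out <- build_ecosystem(eco$members[names(eco$members) != member_id],
                         default_bound = eco$default_bound)
  if (!is.null(eco$diet)) out <- apply_diet(out, eco$diet)
  out
}
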